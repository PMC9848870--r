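test_that("solve_base_freqs inverts the composition summary exactly", {
  fr <- solve_base_freqs(55, 0.1, -0.3)
  expect_equal(sum(fr), 1)
  expect_equal(unname(fr["A"] + fr["T"]), 0.55)
  expect_equal(unname((fr["A"] - fr["T"]) / (fr["A"] + fr["T"])), 0.1)
  expect_equal(unname((fr["G"] - fr["C"]) / (fr["G"] + fr["C"])), -0.3)
  expect_error(solve_base_freqs(120, 0, 0))
  expect_error(solve_base_freqs(50, 2, 0))
})

test_that("simulated composition targets are recovered at 100 kb", {
  s <- simulate_sequence(100000, pct_at = 53.5, at_skew = 0.12,
                         gc_skew = -0.35, seed = 404)
  cc <- base_composition(s)
  expect_lt(abs(cc$pct_at / 100 - 0.535), 0.02)
  expect_lt(abs(cc$at_skew - 0.12), 0.02)
  expect_lt(abs(cc$gc_skew - (-0.35)), 0.02)
})

test_that("generation is deterministic per seed", {
  a <- generate_genome(genome_spec(seed = 5))
  b <- generate_genome(genome_spec(seed = 5))
  d <- generate_genome(genome_spec(seed = 6))
  expect_identical(a$record$sequence, b$record$sequence)
  expect_identical(a$truth$cr_motifs, b$truth$cr_motifs)
  expect_false(identical(a$record$sequence, d$record$sequence))
})

test_that("the synthetic genome carries the canonical architecture", {
  g <- fixture_genome()
  rec <- g$record
  expect_equal(length(rec$features), 38)
  go <- extract_gene_order(rec)
  expect_true(compare_orders(go, reference_gene_order())$identical)
  expect_length(attr(go, "missing"), 0)
  # genome size in the passerine ballpark
  expect_gt(nchar(rec$sequence), 16000)
  expect_lt(nchar(rec$sequence), 18000)
})

test_that("the planted spacer/overlap plan is realised", {
  g <- fixture_genome()
  tab <- spacer_table(g$record)
  key <- paste(tab$upstream, tab$downstream, sep = "|")
  expect_equal(tab$gap[key == "trnP|nad6"], 23L)
  expect_equal(tab$gap[key == "atp8|atp6"], -10L)
  expect_equal(tab$gap[key == "atp6|cox3"], -1L)
  s <- spacer_summary(g$record)
  expect_equal(s$max, 23L)
  expect_equal(s$longest$upstream, "trnP")
  expect_equal(s$longest$downstream, "nad6")
  # every realised gap matches the plan (unplanned pairs are 0)
  plan <- g$truth$spacers
  for (k in names(plan)) {
    expect_equal(tab$gap[key == k], unname(plan[k]), label = k)
  }
  expect_true(all(tab$gap[!key %in% names(plan)] == 0))
})

test_that("overlapping genes still translate cleanly", {
  g <- fixture_genome()
  for (gene in c("atp8", "atp6", "cox3")) {
    f <- mitocomp:::find_feature(g$record, gene)
    info <- extract_codons(g$record, f, warn = FALSE)
    expect_false(any(info$codons[-1] %in% mito_stop_codons()),
                 label = paste(gene, "internal stops"))
  }
})

test_that("RSCU targets from weights are internally consistent", {
  t <- rscu_targets_from_weights()
  sums <- tapply(t$rscu_target, t$aa, sum)
  sizes <- tapply(t$rscu_target, t$aa, length)
  expect_equal(as.numeric(sums), as.numeric(sizes))
  # the boosted codons carry the top target values in their families
  expect_equal(t$codon[t$aa == "L"][which.max(t$rscu_target[t$aa == "L"])],
               "CUA")
  expect_equal(t$codon[t$aa == "S"][which.max(t$rscu_target[t$aa == "S"])],
               "UCC")
})

test_that("planted RSCU bias shows through on a single genome", {
  # one genome is ~3.8k codons, so exact +-0.1 recovery is a large-sample
  # property (covered in the acceptance suite with a 100k-codon sample);
  # here: high agreement plus the planted family leaders
  g <- fixture_genome()
  obs <- rscu(codon_count_table(g$record))
  tgt <- g$truth$rscu_targets
  m <- merge(obs, tgt, by = c("aa", "codon"))
  expect_equal(nrow(m), 60)
  expect_gt(stats::cor(m$rscu, m$rscu_target), 0.95)
  top_of <- function(tab, aa, col) tab$codon[tab$aa == aa][
    which.max(tab[[col]][tab$aa == aa])]
  for (aa in c("L", "S", "R")) {
    expect_equal(top_of(m, aa, "rscu"), top_of(m, aa, "rscu_target"),
                 label = paste("family", aa))
  }
})

test_that("evolve_alignment respects rates and determinism", {
  root <- strrep("ACGT", 250)
  tree <- "((a:0.05,b:0.05):0.02,c:0.07);"
  rates <- rep(c(0, 1), 500)
  a1 <- evolve_alignment(root, tree, kappa = 4, rates = rates, seed = 9)
  a2 <- evolve_alignment(root, tree, kappa = 4, rates = rates, seed = 9)
  expect_identical(a1, a2)
  expect_equal(sort(names(a1)), c("a", "b", "c"))
  expect_true(all(nchar(a1) == 1000))
  rv <- strsplit(root, "")[[1]]
  for (tip in a1) {
    tv <- strsplit(tip, "")[[1]]
    expect_true(all(tv[rates == 0] == rv[rates == 0]))
  }
  expect_false(identical(a1[["a"]], root))
})

test_that("evolved divergence scales with branch length", {
  root <- strrep("ACGT", 2500)
  tips <- evolve_alignment(root, "(near:0.005,far:0.2);", seed = 10)
  pd <- function(x) mean(strsplit(x, "")[[1]] != strsplit(root, "")[[1]])
  expect_lt(pd(tips[["near"]]), 0.02)
  expect_gt(pd(tips[["far"]]), 0.1)
})

test_that("study-set phylogeny recovers the guide tree topology", {
  st <- fixture_study()
  expect_equal(sort(names(st$records)),
               sort(default_study_tree()$tip.label))
  seqs <- vapply(st$records, function(r) r$sequence, character(1))
  d <- distance_matrix(seqs, model = "K2P")
  nj <- neighbor_joining(d)
  expect_equal(rf_distance(nj, default_study_tree()), 0)
  expect_true(is_monophyletic(nj, c("M_alba_1", "M_alba_2"), "D_indicus"))
})

test_that("evolved tips keep foldable tRNAs with invariant anticodons", {
  st <- fixture_study()
  tab <- fold_record_trnas(st$records$D_indicus)  # most diverged tip
  expect_true(all(!is.na(tab$score)))
  root_tab <- fold_record_trnas(st$root)
  expect_equal(tab$dhu_present, root_tab$dhu_present)
})

test_that("CR domain variability ranks III > I > II in the study set", {
  st <- fixture_study()
  crf <- mitocomp:::find_feature(st$root, "CR")
  al <- vapply(st$records, function(r) extract_feature_sequence(r, crf),
               character(1))
  b <- st$truth$cr_boundaries
  L <- nchar(al[[1]])
  vI <- variable_site_proportion(al, c(0, b[1]))
  vII <- variable_site_proportion(al, c(b[1], b[2]))
  vIII <- variable_site_proportion(al, c(b[2], L))
  expect_gt(vIII, vI)
  expect_gt(vI, vII)
})

test_that("truth sidecar serialises to JSON", {
  g <- fixture_genome()
  path <- tempfile(fileext = ".json")
  on.exit(unlink(path), add = TRUE)
  write_truth_sidecar(g$truth, path)
  back <- jsonlite::read_json(path)
  expect_equal(back$seed, 42L)
  expect_equal(length(back$trna), 22)
  expect_equal(back$cr_motifs[[1]]$motif, "polyc")
})
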