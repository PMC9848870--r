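test_that("p distance matches hand counts", {
  d <- distance_matrix(c(a = "AAAA", b = "AAAT"), model = "p")
  expect_equal(d["a", "b"], 0.25)
  expect_equal(d["a", "a"], 0)
  expect_equal(d, t(d))
})

test_that("K2P distance matches the closed-form formula", {
  # 10 sites: one transition (A->G), one transversion (A->C)
  a <- strrep("A", 10)
  b <- paste0("G", strrep("A", 8), "C")
  d <- distance_matrix(c(x = a, y = b), model = "K2P")
  P <- 0.1; Q <- 0.1
  expect_equal(d["x", "y"],
               -0.5 * log((1 - 2 * P - Q) * sqrt(1 - 2 * Q)))
})

test_that("gapped sites are pairwise-deleted", {
  d <- distance_matrix(c(a = "AA-A", b = "AACT"), model = "p")
  expect_equal(d["a", "b"], 1 / 3)
})

test_that("NJ exactly recovers random additive trees (n = 5, 6)", {
  set.seed(41)
  for (n in c(5, 6)) {
    for (i in 1:5) {
      tr <- ape::rtree(n, rooted = FALSE)
      tr$edge.length <- stats::runif(length(tr$edge.length), 0.05, 1)
      d <- ape::cophenetic.phylo(tr)
      nj <- neighbor_joining(d)
      expect_equal(rf_distance(nj, tr), 0)
      # additive metric: recovered path lengths equal the input matrix
      expect_equal(ape::cophenetic.phylo(nj)[rownames(d), colnames(d)], d,
                   tolerance = 1e-8)
    }
  }
})

test_that("neighbor_joining validates input and clamps negatives", {
  expect_error(neighbor_joining(matrix(0, 2, 2)), "at least three")
  d <- matrix(c(0, 1, NA, 1, 0, 1, NA, 1, 0), 3, 3,
              dimnames = list(letters[1:3], letters[1:3]))
  expect_error(neighbor_joining(d), "undefined")
})

test_that("rf_distance separates topologies", {
  t1 <- ape::read.tree(text = "((a,b),(c,d),(e,f));")
  t2 <- ape::read.tree(text = "((a,c),(b,d),(e,f));")
  expect_equal(rf_distance(t1, t1), 0)
  expect_gt(rf_distance(t1, t2), 0)
  expect_error(rf_distance(t1, ape::read.tree(text = "((a,b),(c,d),e);")))
})

test_that("topology_matches prunes to the pattern's taxa", {
  tr <- default_study_tree()
  expect_true(topology_matches(tr,
    "((M_flava,M_tschutschensis),(M_alba_1,M_alba_2),D_indicus);"))
  expect_false(topology_matches(tr,
    "((M_flava,M_alba_1),(M_tschutschensis,M_alba_2),D_indicus);"))
  expect_error(topology_matches(tr, "(M_flava,nosuch);"), "unknown taxon")
})

test_that("is_monophyletic roots at the outgroup first", {
  tr <- default_study_tree()
  expect_true(is_monophyletic(tr, c("M_flava", "M_tschutschensis"),
                              "D_indicus"))
  expect_true(is_monophyletic(tr, c("M_cinerea_1", "M_cinerea_2"),
                              "D_indicus"))
  expect_false(is_monophyletic(tr, c("M_flava", "M_alba_1"), "D_indicus"))
})

test_that("concatenate tiles partitions and gap-fills missing taxa", {
  al <- list(g1 = c(a = "AAA", b = "CCC"),
             g2 = c(a = "GGGG", d = "TTTT"))
  sm <- concatenate(al)
  expect_equal(sm$taxa, c("a", "b", "d"))
  expect_equal(unname(sm$sequences["b"]), "CCC----")
  expect_equal(unname(sm$sequences["d"]), "---TTTT")
  expect_equal(sm$partitions$start, c(0L, 3L))
  expect_equal(sm$partitions$end, c(3L, 7L))
  expect_error(concatenate(list(g = c(a = "AA", b = "A"))), "unequal")
})

test_that("supermatrix export/read round-trips in PHYLIP and NEXUS", {
  al <- list(g1 = c("tax one" = "ACGTAA", tax2 = "ACGTTT"),
             g2 = c("tax one" = "GG", tax2 = "CC"))
  sm <- concatenate(al)
  phy <- tempfile(fileext = ".phy")
  nex <- tempfile(fileext = ".nex")
  on.exit(unlink(c(phy, nex, paste0(c(phy, nex), ".names.tsv"))),
          add = TRUE)
  export_supermatrix(sm, phy, "phylip")
  export_supermatrix(sm, nex, "nexus")

  rp <- read_supermatrix(phy, "phylip")
  expect_equal(unname(rp$sequences), unname(sm$sequences))
  expect_equal(rp$taxa, c("tax_one", "tax2"))  # sanitized
  expect_true(file.exists(paste0(phy, ".names.tsv")))

  rn <- read_supermatrix(nex, "nexus")
  expect_equal(unname(rn$sequences), unname(sm$sequences))
  expect_equal(rn$partitions$gene, c("g1", "g2"))
  expect_equal(rn$partitions$start, sm$partitions$start)
  expect_equal(rn$partitions$end, sm$partitions$end)
  # header sanity
  expect_match(readLines(phy)[1], "^2 8$")
  expect_true(any(grepl("CHARSET g2 = 7-8;", readLines(nex))))
})
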