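test_that("variable_site_proportion hand-checked on 4-column toys", {
  expect_equal(variable_site_proportion(c(a = "ACGT", b = "ACGA")), 25)
  expect_equal(variable_site_proportion(c(a = "ACGT", b = "ACGT")), 0)
  expect_equal(variable_site_proportion(c(a = "ACGT", b = "TGCA")), 100)
  # window restriction
  expect_equal(
    variable_site_proportion(c(a = "ACGT", b = "ACAA"), c(2, 4)), 100)
})

test_that("gap columns are excluded from the informative denominator", {
  al <- c(a = "AC-T", b = "ACGA")
  expect_equal(variable_site_proportion(al), 100 * 1 / 3)
  expect_equal(variable_site_proportion(al, denominator = "total"), 25)
  # a column with a gap but two disagreeing residues is still variable
  al2 <- c(a = "AC-T", b = "ACGA", d = "ACGC")
  expect_equal(variable_site_proportion(al2), 25)  # col 4 of 4 informative
})

test_that("variable_site_proportion validates input", {
  expect_error(variable_site_proportion(c(a = "ACGT")), "at least two")
  expect_error(variable_site_proportion(c(a = "ACGT", b = "ACG")),
               "equal length")
})

test_that("partition_cr splits domains at explicit boundaries", {
  p <- partition_cr(strrep("A", 100), c(30, 60))
  expect_equal(p$domain, c("I", "II", "III"))
  expect_equal(p$start, c(0L, 30L, 60L))
  expect_equal(p$end, c(30L, 60L, 100L))
  expect_error(partition_cr(strrep("A", 100), c(60, 30)))
  expect_error(partition_cr(strrep("A", 100), c(0, 60)))
})

test_that("anchor mode places boundaries at the F-box and CSB1 hits", {
  g <- fixture_genome()
  cr <- extract_feature_sequence(g$record,
                                 mitocomp:::find_feature(g$record, "CR"))
  p <- partition_cr(cr, boundaries = NULL)
  truth <- g$truth$cr_motifs
  expect_equal(p$start[2], truth$at[truth$motif == "fbox"])
  expect_equal(p$start[3], truth$at[truth$motif == "csb1"])
})

test_that("find_motif locates exact, mismatched, and IUPAC matches", {
  h <- find_motif("GGATCGG", "ATC")
  expect_equal(h$start, 2L)
  expect_equal(h$end, 5L)
  expect_equal(h$mismatches, 0L)
  expect_equal(h$match, "ATC")

  h2 <- find_motif("GGATCGG", "ATG", max_mismatch = 1)
  expect_equal(h2$start, 2L)
  expect_equal(h2$mismatches, 1L)
  expect_equal(nrow(find_motif("GGATCGG", "ATG")), 0)

  # Y = C or T; N matches anything including ambiguous subject bases
  expect_equal(find_motif("AACA", "AYA")$start, 1L)
  expect_equal(find_motif("AATA", "AYA")$start, 1L)
  # ambiguous subject base counts as a mismatch unless the pattern is N
  expect_equal(find_motif("ANG", "AAG", max_mismatch = 1)$mismatches, 1L)
  expect_equal(find_motif("ANG", "NNN")$mismatches, 0L)
})

test_that("find_motif returns overlapping hits sorted by quality", {
  h <- find_motif("AAAA", "AA")
  expect_equal(h$start, c(0L, 1L, 2L))
  h2 <- find_motif("ATTAAT", "AAT", max_mismatch = 1)
  expect_equal(h2$start[1], 3L)  # exact hit first
  expect_equal(h2$mismatches[1], 0L)
})

test_that("scan_cr_boxes finds every implanted box exactly", {
  g <- fixture_genome()
  cr <- extract_feature_sequence(g$record,
                                 mitocomp:::find_feature(g$record, "CR"))
  hits <- scan_cr_boxes(cr)
  truth <- g$truth$cr_motifs
  m <- merge(hits, truth, by = "motif")
  expect_equal(nrow(m), 8)
  expect_equal(m$start, m$at)
  expect_true(all(m$mismatches == 0))
})

test_that("tandem-repeat finder equals the exhaustive oracle ({A,C} strings)", {
  # every {A,C} string of length 4..12, pure repeats, no length floor
  cols <- c("unit", "unit_length", "start", "end")
  bad <- character()
  for (n in 4:12) {
    grid <- expand.grid(rep(list(c("A", "C")), n), stringsAsFactors = FALSE)
    strs <- do.call(paste0, grid)
    for (s in strs) {
      got <- find_tandem_repeats(s, min_unit = 1, max_unit = nchar(s) %/% 2,
                                 min_copies = 2, min_purity = 1,
                                 min_length = 0)
      want <- oracle_tandem_repeats(s)
      if (!isTRUE(all.equal(got[, cols], want[, cols],
                            check.attributes = FALSE)) ||
          (nrow(got) && any(got$purity != 1))) {
        bad <- c(bad, s)
      }
    }
  }
  expect_identical(bad, character(0))
})

test_that("tandem-repeat finder equals the oracle on random 4-letter strings", {
  set.seed(5)
  for (i in 1:25) {
    s <- mitocomp:::sample_bases(40,
      c(A = 0.4, C = 0.3, G = 0.15, T = 0.15))
    got <- find_tandem_repeats(s, min_unit = 1, max_unit = 20,
                               min_copies = 2, min_purity = 1,
                               min_length = 0)
    want <- oracle_tandem_repeats(s, max_unit = 20)
    expect_equal(got[, c("unit", "unit_length", "start", "end")],
                 want[, c("unit", "unit_length", "start", "end")],
                 ignore_attr = TRUE, label = paste("repeats of", s))
  }
})

test_that("impure arrays are merged across a single substitution", {
  s <- strrep("AC", 20)
  substr(s, 21, 21) <- "G"
  r <- find_tandem_repeats(s, min_unit = 2, max_unit = 20, min_copies = 2,
                           min_purity = 0.9, min_length = 0)
  expect_equal(nrow(r), 1)
  expect_equal(r$unit, "AC")
  expect_equal(r$start, 0L)
  expect_equal(r$end, 40L)
  expect_equal(r$purity, 0.95)
  expect_equal(r$copies, 20)
})

test_that("the default scan applies the 36 bp array-length floor", {
  # a 2x16 bp repeat is reported without the floor but not with it
  s <- paste0("GATTACAGATTACA", strrep("T", 30), "CGCGAT")
  expect_gt(nrow(find_tandem_repeats(s, min_length = 0, min_unit = 7)), 0)
  expect_equal(nrow(find_tandem_repeats(s, min_unit = 7)), 0)
})

test_that("an implanted CR tandem repeat is recovered exactly", {
  spec <- genome_spec(seed = 21, tandem_repeat = list(
    unit_length = 12L, copies = 4, at = 1050L))
  g <- generate_genome(spec)
  cr <- extract_feature_sequence(g$record,
                                 mitocomp:::find_feature(g$record, "CR"))
  found <- find_tandem_repeats(cr)
  tr <- g$truth$cr_tandem_repeat
  # the reported array may legitimately extend into chance flanking
  # periodicity, so ask for a unit-12 array covering the implant
  i <- which(found$unit_length == tr$unit_length &
               found$start <= tr$start & found$end >= tr$end)
  expect_equal(length(i), 1L)
  expect_gte(found$copies[i], tr$copies)
  expect_gte(found$purity[i], 0.9)
})

test_that("motif config round-trips through read_motif_config", {
  path <- tempfile(fileext = ".tsv")
  on.exit(unlink(path), add = TRUE)
  tab <- data.frame(name = c("fbox", "csb1"),
                    pattern = c("ATGTACTATTGTACCATAAA",
                                "TTAATGCTCGTTATACATA"),
                    max_mismatch = c(2L, 2L))
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  got <- read_motif_config(path)
  expect_equal(got$pattern, tab$pattern)
  g <- fixture_genome()
  cr <- extract_feature_sequence(g$record,
                                 mitocomp:::find_feature(g$record, "CR"))
  hits <- scan_cr_boxes(cr, got)
  expect_equal(nrow(hits), 2)
  expect_true(all(!is.na(hits$start)))
})
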