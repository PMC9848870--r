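test_that("identical and rotated orders have zero breakpoints", {
  a <- toy_order(c("A", "B", "C", "D", "E"))
  rot <- toy_order(c("C", "D", "E", "A", "B"))
  expect_true(compare_orders(a, a)$identical)
  expect_equal(compare_orders(a, rot)$breakpoints, 0)
})

test_that("an adjacent swap in a 5-gene circle gives 3 breakpoints", {
  a <- toy_order(c("A", "B", "C", "D", "E"))
  b <- toy_order(c("A", "C", "B", "D", "E"))
  cmp <- compare_orders(a, b)
  expect_equal(cmp$breakpoints, 3)
  expect_false(cmp$identical)
  expect_equal(cmp$breakpoints, oracle_breakpoints(a, b))
})

test_that("reading the circle from the other strand is the same order", {
  a <- toy_order(c("A", "B", "C"), c("J", "N", "J"))
  # other-strand reading: reverse the sequence of genes, flip every strand
  b <- toy_order(c("C", "B", "A"), c("N", "J", "N"))
  expect_equal(compare_orders(a, b)$breakpoints, 0)
})

test_that("a strand flip alone is a breakpoint", {
  a <- toy_order(c("A", "B", "C", "D"))
  b <- toy_order(c("A", "B", "C", "D"), c("J", "N", "J", "J"))
  expect_gt(compare_orders(a, b)$breakpoints, 0)
})

test_that("breakpoint counts agree with the oracle on random shuffles", {
  set.seed(77)
  genes <- paste0("g", 1:8)
  for (i in 1:12) {
    a <- toy_order(sample(genes), sample(c("J", "N"), 8, replace = TRUE))
    b <- toy_order(sample(genes), sample(c("J", "N"), 8, replace = TRUE))
    expect_equal(compare_orders(a, b)$breakpoints,
                 oracle_breakpoints(a, b))
    # symmetry for equal token sets
    expect_equal(compare_orders(a, b)$breakpoints,
                 compare_orders(b, a)$breakpoints)
  }
})

test_that("non-shared tokens are dropped pairwise with a warning", {
  a <- toy_order(c("A", "B", "C", "X"))
  b <- toy_order(c("A", "B", "C", "Y"))
  expect_warning(cmp <- compare_orders(a, b), "X, Y")
  expect_equal(cmp$breakpoints, 0)
})

test_that("extract_gene_order sorts, anchors, and flags missing genes", {
  rec <- toy_record(strrep("A", 100), list(
    list(name = "nad2", kind = "PCG", intervals = c(40, 70)),
    list(name = "trnF", kind = "tRNA", intervals = c(5, 20)),
    list(name = "trnQ", kind = "tRNA", strand = "N",
         intervals = c(75, 95))))
  go <- extract_gene_order(rec)
  expect_equal(go$name, c("trnF", "nad2", "trnQ"))
  expect_equal(go$strand, c("J", "J", "N"))
  expect_true("cox1" %in% attr(go, "missing"))
  expect_equal(format_gene_order(go), "trnF-nad2--trnQ")
})

test_that("duplicate gene names are rejected", {
  rec <- toy_record(strrep("A", 50), list(
    list(name = "trnF", kind = "tRNA", intervals = c(0, 20)),
    list(name = "trnF", kind = "tRNA", intervals = c(25, 45))))
  expect_error(extract_gene_order(rec), "duplicate")
})

test_that("spacer_table computes circular gaps and overlaps", {
  rec <- toy_record(strrep("A", 100), list(
    list(name = "trnF", kind = "tRNA", intervals = c(0, 10)),
    list(name = "trnV", kind = "tRNA", intervals = c(15, 30)),
    list(name = "trnI", kind = "tRNA", intervals = c(28, 90))))
  tab <- spacer_table(rec)
  expect_equal(tab$gap, c(5L, -2L, 10L))
  expect_equal(tab$upstream, c("trnF", "trnV", "trnI"))
  expect_equal(tab$downstream, c("trnV", "trnI", "trnF"))

  s <- spacer_summary(rec)
  expect_equal(s$n_spacers, 2L)
  expect_equal(s$max, 10L)
  expect_equal(s$longest$upstream, "trnI")
})

test_that("linear records get no origin-spanning spacer", {
  rec <- toy_record(strrep("A", 100), list(
    list(name = "trnF", kind = "tRNA", intervals = c(0, 10)),
    list(name = "trnV", kind = "tRNA", intervals = c(20, 30))),
    circular = FALSE)
  expect_equal(nrow(spacer_table(rec)), 1)
})

test_that("the reference order is the canonical 38-element circle", {
  ref <- reference_gene_order()
  expect_equal(nrow(ref), 38)
  expect_equal(ref$name[1], "trnF")
  expect_equal(sum(ref$strand == "N"), 9)
  expect_equal(compare_orders(ref, ref)$breakpoints, 0)
})
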