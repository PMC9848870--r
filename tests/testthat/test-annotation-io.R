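test_that("feature and genome_record validate their inputs", {
  expect_error(feature("nad1", "PCG", intervals = c(10, 5)), "invalid")
  expect_error(feature("nad1", "PCG", intervals = c(-1, 5)), "invalid")
  expect_error(feature("nad1", "PCG", intervals = c(0, 9),
                       reading_offset = 5L), "reading_offset")
  expect_error(feature("trnF", "bogus", intervals = c(0, 9)))
  expect_error(genome_record("X", ""), "empty")
  expect_error(genome_record("X", "ACGT", list(
    feature("trnF", "tRNA", intervals = c(0, 10)))), "beyond")
  expect_error(genome_record("X", strrep("A", 100), list(
    feature("CR", "CR", intervals = c(0, 10)),
    feature("CR", "CR", intervals = c(20, 30)))), "one control-region")
})

test_that("extract_feature_sequence honours strand and split intervals", {
  rec <- genome_record("X", "AACCGGTTACGT", list(
    feature("trnF", "tRNA", "J", c(2, 6)),
    feature("trnQ", "tRNA", "N", c(2, 6)),
    feature("CR", "CR", "J", list(c(10, 12), c(0, 2)))))
  expect_equal(extract_feature_sequence(rec, rec$features[[1]]), "CCGG")
  expect_equal(extract_feature_sequence(rec, rec$features[[2]]), "CCGG")
  # origin-spanning: [10,12) + [0,2) in gene order
  expect_equal(extract_feature_sequence(rec, rec$features[[3]]), "GTAA")
  expect_equal(feature_length(rec$features[[3]]), 4L)
})

test_that("feature_table summarises a record", {
  g <- fixture_genome()
  tab <- feature_table(g$record)
  expect_equal(nrow(tab), 38)
  expect_setequal(tab$name, canonical_tokens())
  expect_equal(sum(tab$kind == "PCG"), 13)
  expect_equal(sum(tab$kind == "tRNA"), 22)
})

test_that("canonical_gene_name normalises the usual label zoo", {
  cases <- list(
    list("ND2", "nad2", "PCG"),
    list("nad4L", "nad4l", "PCG"),
    list("NADH dehydrogenase subunit 4", "nad4", "PCG"),
    list("COIII", "cox3", "PCG"),
    list("COX1", "cox1", "PCG"),
    list("cytochrome c oxidase subunit II", "cox2", "PCG"),
    list("CYTB", "cob", "PCG"),
    list("ATPase6", "atp6", "PCG"),
    list("ATP8", "atp8", "PCG"),
    list("12S ribosomal RNA", "rrnS", "rRNA"),
    list("16S ribosomal RNA", "rrnL", "rRNA"),
    list("D-loop", "CR", "CR"),
    list("control region", "CR", "CR"),
    list("tRNA-Phe", "trnF", "tRNA"),
    list("tRNA-Leu", "trnL", "tRNA"),
    list("tRNA-Ser", "trnS", "tRNA"),
    list("tRNA-Leu(CUN)", "trnL(cun)", "tRNA"),
    list("trnS(ucn)", "trnS(ucn)", "tRNA"))
  for (cs in cases) {
    got <- canonical_gene_name(cs[[1]], warn = FALSE)
    expect_equal(got$name, cs[[2]], label = cs[[1]])
    expect_equal(got$kind, cs[[3]], label = cs[[1]])
  }
  # anticodon disambiguation for the isoacceptors
  expect_equal(canonical_gene_name("tRNA-Leu", anticodon = "TAA")$name,
               "trnL(uur)")
  expect_equal(canonical_gene_name("tRNA-Leu", anticodon = "TAG")$name,
               "trnL(cun)")
  expect_equal(canonical_gene_name("tRNA-Ser", anticodon = "TGA")$name,
               "trnS(ucn)")
  expect_equal(canonical_gene_name("tRNA-Ser", anticodon = "GCT")$name,
               "trnS(agy)")
  expect_warning(got <- canonical_gene_name("mystery ORF"), "unknown")
  expect_equal(got$name, "other")
})

test_that("parse_location converts GenBank coordinates", {
  p <- mitocomp:::parse_location("123..456")
  expect_equal(p$strand, "J")
  expect_equal(p$intervals, list(c(122L, 456L)))

  pc <- mitocomp:::parse_location("complement(123..456)")
  expect_equal(pc$strand, "N")

  # origin-spanning N-strand gene: gene 5' interval listed first
  pj <- mitocomp:::parse_location("complement(join(15000..16000,1..20))")
  expect_equal(pj$strand, "N")
  expect_equal(pj$intervals, list(c(0L, 20L), c(14999L, 16000L)))

  expect_error(mitocomp:::parse_location("order(1..5)"), "cannot parse")
})

test_that("GenBank write/read round-trips a synthetic genome", {
  g <- fixture_genome()
  path <- tempfile(fileext = ".gb")
  on.exit(unlink(path), add = TRUE)
  write_genbank(g$record, path)
  back <- read_genbank(path)
  expect_length(back, 1)
  r2 <- back[[1]]
  expect_equal(r2$identifier, g$record$identifier)
  expect_true(r2$circular)
  expect_equal(r2$sequence, g$record$sequence)
  expect_equal(length(r2$features), length(g$record$features))
  for (i in seq_along(r2$features)) {
    expect_equal(r2$features[[i]]$name, g$record$features[[i]]$name)
    expect_equal(r2$features[[i]]$kind, g$record$features[[i]]$kind)
    expect_equal(r2$features[[i]]$strand, g$record$features[[i]]$strand)
    expect_equal(r2$features[[i]]$intervals,
                 g$record$features[[i]]$intervals)
  }
  # a second round trip is the identity on the file content
  path2 <- tempfile(fileext = ".gb")
  on.exit(unlink(path2), add = TRUE)
  write_genbank(r2, path2)
  expect_identical(readLines(path2), readLines(path))
})

test_that("read_genbank handles qualifiers, gene keys, and ambiguity", {
  txt <- c(
    "LOCUS       TST00001            120 bp    DNA     circular VRT",
    "DEFINITION  test record.",
    "ACCESSION   TST00001",
    "FEATURES             Location/Qualifiers",
    "     source          1..120",
    "     gene            1..30",
    '                     /gene="ND1"',
    "     CDS             1..30",
    '                     /gene="ND1"',
    "                     /codon_start=2",
    "     rRNA            31..60",
    '                     /product="16S ribosomal RNA"',
    "     tRNA            61..80",
    '                     /product="tRNA-Leu"',
    "     gene            complement(81..100)",
    '                     /gene="tRNA-Gln"',
    "     D-loop          101..120",
    "ORIGIN",
    paste0("        1 ", paste(rep("acgtacgtac", 6)[1:6],
                               collapse = " ")),
    paste0("       61 ", paste(rep("acgtacgtac", 6)[1:6],
                               collapse = " ")),
    "//")
  path <- tempfile(fileext = ".gb")
  on.exit(unlink(path), add = TRUE)
  writeLines(txt, path)
  recs <- read_genbank(path)
  rec <- recs[[1]]
  expect_equal(nchar(rec$sequence), 120)
  names <- vapply(rec$features, `[[`, character(1), "name")
  kinds <- vapply(rec$features, `[[`, character(1), "kind")
  expect_setequal(names, c("nad1", "rrnL", "trnL(uur)", "trnQ", "CR"))
  # gene+CDS merged into one PCG with codon_start honoured
  expect_equal(sum(names == "nad1"), 1)
  expect_equal(rec$features[[which(names == "nad1")]]$reading_offset, 1L)
  # lone gene key became a typed feature on the minor strand
  expect_equal(rec$features[[which(names == "trnQ")]]$strand, "N")
  expect_equal(kinds[names == "CR"], "CR")
  # ambiguous tRNA-Leu resolved by the rrnL neighbourhood
  expect_true("trnL(uur)" %in% names)
})

test_that("FASTA I/O round-trips and rejects duplicate names", {
  seqs <- c(s1 = "ACGTACGT", s2 = paste0(strrep("ACGT", 20), "--TT"))
  path <- tempfile(fileext = ".fa")
  on.exit(unlink(path), add = TRUE)
  write_fasta(seqs, path)
  back <- read_fasta(path)
  expect_equal(back, seqs)
  writeLines(c(">a", "ACGT", ">a", "GGCC"), path)
  expect_error(read_fasta(path), "[Dd]uplicate")
})
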