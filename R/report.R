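# Report assembly: one function per analysis stage, each writing the TSV /
# Newick / FASTA products of the corresponding module into an output
# directory. These are the entry points the analysis scripts drive; each
# returns its main table invisibly so it can also be used interactively.

write_tsv <- function(tab, dir, name) {
  path <- file.path(dir, name)
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  path
}

#' Composition summary report (per-partition table)
#'
#' One row per record x partition plus per-partition means: length, T%,
#' C%, A%, G%, A+T%, AT-skew, GC-skew.
#'
#' @param records list of [genome_record()]s
#' @param outdir output directory (created if needed)
#' @param partitions named list of [partition_spec()]s
#'   (default [standard_partitions()])
#' @return invisibly, the combined table (also written to
#'   `composition.tsv`)
#' @export
report_composition <- function(records, outdir,
                               partitions = standard_partitions()) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  tab <- do.call(rbind, lapply(partitions, function(p)
    partition_summary(records, p)))
  rownames(tab) <- NULL
  write_tsv(tab, outdir, "composition.tsv")
  invisible(tab)
}

#' RSCU report (long table + start/stop matrix)
#'
#' Writes `rscu.tsv` (record, aa, codon, count, rscu; one block per record,
#' stackable into the usual RSCU bar plot) and `start_stop.tsv` (rows =
#' PCG, columns = record).
#'
#' @inheritParams report_composition
#' @return invisibly, the RSCU long table
#' @export
report_rscu <- function(records, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  long <- do.call(rbind, lapply(records, function(rec) {
    r <- rscu(codon_count_table(rec))
    cbind(record = rec$identifier, r)
  }))
  rownames(long) <- NULL
  write_tsv(long, outdir, "rscu.tsv")
  ss <- start_stop_table(records)
  wide <- stats::reshape(
    ss[, c("record", "gene", "start", "stop")],
    direction = "wide", idvar = "gene", timevar = "record")
  write_tsv(wide, outdir, "start_stop.tsv")
  invisible(long)
}

#' Gene-order report
#'
#' Writes `gene_order.tsv` (record, order string, breakpoints vs the
#' canonical passerine order, identical flag).
#'
#' @inheritParams report_composition
#' @param reference "gene_order" object to compare against
#' @return invisibly, the table
#' @export
report_gene_order <- function(records, outdir,
                              reference = reference_gene_order()) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  tab <- do.call(rbind, lapply(records, function(rec) {
    go <- extract_gene_order(rec)
    cmp <- compare_orders(go, reference)
    data.frame(record = rec$identifier,
               order = format_gene_order(go),
               breakpoints = cmp$breakpoints,
               identical_to_reference = cmp$identical,
               missing = paste(attr(go, "missing"), collapse = ","),
               stringsAsFactors = FALSE)
  }))
  write_tsv(tab, outdir, "gene_order.tsv")
  invisible(tab)
}

#' Intergenic spacer / overlap report
#'
#' Writes `spacers.tsv` (record, upstream, downstream, gap) and
#' `spacer_summary.tsv` (record, n_spacers, min, max, longest pair).
#'
#' @inheritParams report_composition
#' @return invisibly, the per-pair table
#' @export
report_spacers <- function(records, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  tab <- do.call(rbind, lapply(records, function(rec)
    cbind(record = rec$identifier, spacer_table(rec))))
  rownames(tab) <- NULL
  write_tsv(tab, outdir, "spacers.tsv")
  summ <- do.call(rbind, lapply(records, function(rec) {
    s <- spacer_summary(rec)
    data.frame(record = rec$identifier, n_spacers = s$n_spacers,
               min = s$min, max = s$max,
               longest = if (is.null(s$longest)) NA_character_ else
                 paste(s$longest$upstream, s$longest$downstream,
                       sep = "-"),
               stringsAsFactors = FALSE)
  }))
  write_tsv(summ, outdir, "spacer_summary.tsv")
  invisible(tab)
}

#' Control-region report
#'
#' Writes `cr_boxes.tsv` (conserved-box hits per record), `cr_repeats.tsv`
#' (tandem repeats per record) and, when an alignment is supplied,
#' `cr_variability.tsv` (variable-site proportion per domain).
#'
#' @inheritParams report_composition
#' @param boundaries CR-local starts of domains II and III
#' @param alignment optional gapped CR alignment (named character vector)
#'   in the same local coordinates
#' @param motif_config optional motif config data.frame
#'   (see [read_motif_config()])
#' @return invisibly, list(boxes, repeats, variability)
#' @export
report_cr <- function(records, outdir, boundaries = c(430L, 900L),
                      alignment = NULL, motif_config = NULL) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  boxes <- list(); reps <- list()
  for (rec in records) {
    crf <- Filter(function(f) f$kind == "CR", rec$features)
    if (!length(crf)) next
    cr <- extract_feature_sequence(rec, crf[[1]])
    b <- scan_cr_boxes(cr, motif_config)
    boxes[[length(boxes) + 1L]] <- cbind(record = rec$identifier, b)
    r <- find_tandem_repeats(cr)
    if (nrow(r)) {
      reps[[length(reps) + 1L]] <- cbind(record = rec$identifier, r)
    }
  }
  boxes <- do.call(rbind, boxes)
  reps <- if (length(reps)) do.call(rbind, reps) else
    data.frame(record = character(), unit = character(),
               unit_length = integer(), copies = numeric(),
               start = integer(), end = integer(), purity = numeric())
  write_tsv(boxes, outdir, "cr_boxes.tsv")
  write_tsv(reps, outdir, "cr_repeats.tsv")
  variability <- NULL
  if (!is.null(alignment)) {
    part <- partition_cr(alignment[[1]], boundaries)
    variability <- data.frame(
      domain = part$domain,
      pct_variable = vapply(seq_len(nrow(part)), function(i)
        round_half_up(variable_site_proportion(
          alignment, c(part$start[i], part$end[i])), 1), numeric(1)))
    write_tsv(variability, outdir, "cr_variability.tsv")
  }
  invisible(list(boxes = boxes, repeats = reps,
                 variability = variability))
}

#' tRNA structure report
#'
#' Writes `trna.tsv`: per record x tRNA, length, fold score, DHU-arm
#' presence, mismatch count, dot-bracket string.
#'
#' @inheritParams report_composition
#' @return invisibly, the table
#' @export
report_trna <- function(records, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  tab <- fold_record_trnas(records)
  write_tsv(tab, outdir, "trna.tsv")
  invisible(tab)
}

#' Distance/NJ phylogeny report
#'
#' Concatenates per-gene alignments, writes the supermatrix (relaxed
#' PHYLIP + NEXUS with charsets), the K2P distance matrix
#' (`distances.tsv`) and the NJ tree (`nj.nwk`).
#'
#' @param alignments named list of per-gene alignments (named character
#'   vectors)
#' @param outdir output directory
#' @param model distance model, "p" or "K2P"
#' @return invisibly, list(supermatrix, distances, tree)
#' @export
report_phylo <- function(alignments, outdir, model = "K2P") {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  sm <- concatenate(alignments)
  export_supermatrix(sm, file.path(outdir, "supermatrix.phy"), "phylip")
  export_supermatrix(sm, file.path(outdir, "supermatrix.nex"), "nexus")
  d <- distance_matrix(sm, model)
  utils::write.table(round(d, 6), file.path(outdir, "distances.tsv"),
                     sep = "\t", quote = FALSE)
  tr <- neighbor_joining(d)
  ape::write.tree(tr, file.path(outdir, "nj.nwk"))
  invisible(list(supermatrix = sm, distances = d, tree = tr))
}
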