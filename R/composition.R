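# Base composition and strand-asymmetry (skew) statistics.
#
# AT-skew = (A - T) / (A + T); GC-skew = (G - C) / (G + C). Positive AT-skew
# is an excess of A over T (A-skew); negative GC-skew is an excess of C
# (C-skew). Ambiguous bases are excluded from numerators and denominators,
# so both skews stay exactly within [-1, 1]; a zero denominator yields NA
# rather than a fake 0.

#' Base composition and skews of a sequence
#'
#' @param seq DNA string (case-insensitive; IUPAC ambiguity codes counted
#'   as ambiguous; gaps ignored entirely)
#' @return object of class "composition_summary": list with counts a, c, g,
#'   t, n_ambiguous, length, and derived pct_at, pct_gc, pct per base,
#'   at_skew, gc_skew (NA when the denominator is zero)
#' @export
base_composition <- function(seq) {
  if (length(seq) != 1 || is.na(seq) || nchar(seq) == 0) {
    stop("base_composition: empty sequence")
  }
  s <- toupper(seq)
  s <- gsub("-", "", s, fixed = TRUE)
  if (nchar(s) == 0) stop("base_composition: sequence is all gaps")
  v <- s2c(s)
  a <- sum(v == "A"); cc <- sum(v == "C")
  g <- sum(v == "G"); t <- sum(v == "T" | v == "U")
  len <- length(v)
  amb <- len - (a + cc + g + t)
  composition_from_counts(a, cc, g, t, amb)
}

composition_from_counts <- function(a, cc, g, t, amb = 0L) {
  len <- a + cc + g + t + amb
  tot <- a + cc + g + t
  at_skew <- if (a + t > 0) (a - t) / (a + t) else NA_real_
  gc_skew <- if (g + cc > 0) (g - cc) / (g + cc) else NA_real_
  structure(list(
    a = a, c = cc, g = g, t = t, n_ambiguous = amb, length = len,
    pct_a = if (tot) 100 * a / tot else NA_real_,
    pct_c = if (tot) 100 * cc / tot else NA_real_,
    pct_g = if (tot) 100 * g / tot else NA_real_,
    pct_t = if (tot) 100 * t / tot else NA_real_,
    pct_at = if (tot) 100 * (a + t) / tot else NA_real_,
    pct_gc = if (tot) 100 * (g + cc) / tot else NA_real_,
    at_skew = at_skew, gc_skew = gc_skew
  ), class = "composition_summary")
}

#' @export
print.composition_summary <- function(x, ...) {
  cat(sprintf(
    "<composition> %d bp  A+T %.1f%%  AT-skew %s  GC-skew %s\n",
    x$length, x$pct_at,
    ifelse(is.na(x$at_skew), "NA", sprintf("%.3f", x$at_skew)),
    ifelse(is.na(x$gc_skew), "NA", sprintf("%.3f", x$gc_skew))))
  invisible(x)
}

# add two composition summaries (concatenation invariance)
add_composition <- function(x, y) {
  composition_from_counts(x$a + y$a, x$c + y$c, x$g + y$g, x$t + y$t,
                          x$n_ambiguous + y$n_ambiguous)
}

#' Split protein-coding genes into codon-position streams
#'
#' Each PCG is taken in gene orientation (N-strand genes are
#' reverse-complemented first), its reading offset is dropped, any trailing
#' partial codon is dropped, and a trailing complete stop codon (TAA, TAG,
#' AGA, AGG under the vertebrate mitochondrial code) is removed. The
#' remaining bases are routed to position streams 1, 2 and 3, concatenated
#' across genes in genome order.
#'
#' @param rec a [genome_record()]
#' @param pcg_features list of PCG [feature()]s; default: all PCGs of `rec`
#' @return list with elements pos1, pos2, pos3 (DNA strings)
#' @export
codon_position_split <- function(rec, pcg_features = NULL) {
  if (is.null(pcg_features)) {
    pcg_features <- Filter(function(f) f$kind == "PCG", rec$features)
  }
  streams <- list(pos1 = character(), pos2 = character(),
                  pos3 = character())
  for (f in pcg_features) {
    s <- extract_feature_sequence(rec, f)
    s <- substr(s, f$reading_offset + 1, nchar(s))
    ncod <- nchar(s) %/% 3
    if (ncod < 1) {
      warning("PCG ", f$name, " shorter than one codon after trimming; ",
              "skipped", call. = FALSE)
      next
    }
    s <- substr(s, 1, ncod * 3)
    last <- substr(s, nchar(s) - 2, nchar(s))
    if (last %in% mito_stop_codons()) {
      s <- substr(s, 1, nchar(s) - 3)
      if (nchar(s) == 0) next
    }
    v <- s2c(s)
    pos <- rep_len(1:3, length(v))
    streams$pos1 <- c(streams$pos1, v[pos == 1])
    streams$pos2 <- c(streams$pos2, v[pos == 2])
    streams$pos3 <- c(streams$pos3, v[pos == 3])
  }
  lapply(streams, c2s)
}

#' Define a sequence partition for composition summaries
#'
#' @param name partition label
#' @param members character vector of canonical gene names, or one of the
#'   shorthands "genome", "PCG", "tRNA", "rRNA", "CR"
#' @param codon_positions optional subset of 1:3; only valid for PCG
#'   members, selects codon-position streams
#' @param orientation "gene" (default; members extracted in reading
#'   orientation) or "genome" (major-strand sequence as-is)
#' @return object of class "partition_spec"
#' @export
partition_spec <- function(name, members, codon_positions = NULL,
                           orientation = c("gene", "genome")) {
  orientation <- match.arg(orientation)
  if (!is.null(codon_positions)) {
    stopifnot(all(codon_positions %in% 1:3))
    if (!identical(members, "PCG") && !all(members %in% pcg_tokens())) {
      stop("codon_positions only valid for PCG partitions")
    }
  }
  structure(list(name = name, members = members,
                 codon_positions = codon_positions,
                 orientation = orientation),
            class = "partition_spec")
}

# resolve a partition to one concatenated sequence for a record;
# NULL when no member is present
partition_sequence <- function(rec, spec) {
  if (identical(spec$members, "genome")) return(rec$sequence)
  feats <- if (identical(spec$members, "PCG")) {
    Filter(function(f) f$kind == "PCG", rec$features)
  } else if (identical(spec$members, "tRNA")) {
    Filter(function(f) f$kind == "tRNA", rec$features)
  } else if (identical(spec$members, "rRNA")) {
    Filter(function(f) f$kind == "rRNA", rec$features)
  } else if (identical(spec$members, "CR")) {
    Filter(function(f) f$kind == "CR", rec$features)
  } else {
    Filter(function(f) f$name %in% spec$members, rec$features)
  }
  if (!length(feats)) return(NULL)
  if (!is.null(spec$codon_positions)) {
    st <- codon_position_split(rec, feats)
    return(c2s(unlist(st[spec$codon_positions])))
  }
  if (all(vapply(feats, function(f) f$kind == "PCG", logical(1)))) {
    # PCG partitions exclude stop codons (complete and incomplete)
    seqs <- vapply(feats, function(f) {
      info <- extract_codons(rec, f, warn = FALSE)
      paste0(info$codons, collapse = "")
    }, character(1))
    return(paste0(seqs, collapse = ""))
  }
  seqs <- vapply(feats, function(f) {
    if (spec$orientation == "genome") {
      f2 <- f; f2$strand <- "J"
      extract_feature_sequence(rec, f2)
    } else {
      extract_feature_sequence(rec, f)
    }
  }, character(1))
  paste0(seqs, collapse = "")
}

#' Per-record composition summaries for a partition, plus cross-record mean
#'
#' @param records list of [genome_record()]s
#' @param spec a [partition_spec()]
#' @return data.frame: one row per record plus a "mean" row; columns
#'   record, partition, length, pct_t, pct_c, pct_a, pct_g, pct_at,
#'   at_skew, gc_skew. Percent columns are reported rounded half-up to one
#'   decimal; skews to three decimals. Records lacking every member get NA
#'   cells, and the mean is over present cells.
#' @export
partition_summary <- function(records, spec) {
  rows <- lapply(records, function(rec) {
    s <- partition_sequence(rec, spec)
    if (is.null(s) || nchar(gsub("-", "", s)) == 0) {
      return(data.frame(record = rec$identifier, partition = spec$name,
                        length = NA_integer_, pct_t = NA_real_,
                        pct_c = NA_real_, pct_a = NA_real_,
                        pct_g = NA_real_, pct_at = NA_real_,
                        at_skew = NA_real_, gc_skew = NA_real_))
    }
    comp <- base_composition(s)
    data.frame(record = rec$identifier, partition = spec$name,
               length = comp$length,
               pct_t = round_half_up(comp$pct_t, 1),
               pct_c = round_half_up(comp$pct_c, 1),
               pct_a = round_half_up(comp$pct_a, 1),
               pct_g = round_half_up(comp$pct_g, 1),
               pct_at = round_half_up(comp$pct_at, 1),
               at_skew = round_half_up(comp$at_skew, 3),
               gc_skew = round_half_up(comp$gc_skew, 3))
  })
  tab <- do.call(rbind, rows)
  mean_row <- data.frame(
    record = "mean", partition = spec$name,
    length = round_half_up(mean(tab$length, na.rm = TRUE), 1),
    pct_t = round_half_up(mean(tab$pct_t, na.rm = TRUE), 1),
    pct_c = round_half_up(mean(tab$pct_c, na.rm = TRUE), 1),
    pct_a = round_half_up(mean(tab$pct_a, na.rm = TRUE), 1),
    pct_g = round_half_up(mean(tab$pct_g, na.rm = TRUE), 1),
    pct_at = round_half_up(mean(tab$pct_at, na.rm = TRUE), 1),
    at_skew = round_half_up(mean(tab$at_skew, na.rm = TRUE), 3),
    gc_skew = round_half_up(mean(tab$gc_skew, na.rm = TRUE), 3))
  rbind(tab, mean_row)
}

#' Standard comparative partitions for avian mitogenomes
#'
#' Whole genome, PCGs (excluding stop codons), the three codon positions,
#' concatenated tRNAs, both rRNAs individually and together, and the
#' control region.
#'
#' @return named list of [partition_spec()]s
#' @export
standard_partitions <- function() {
  list(
    genome = partition_spec("genome", "genome"),
    pcg = partition_spec("PCGs", "PCG"),
    pcg_pos1 = partition_spec("PCG position 1", "PCG", codon_positions = 1),
    pcg_pos2 = partition_spec("PCG position 2", "PCG", codon_positions = 2),
    pcg_pos3 = partition_spec("PCG position 3", "PCG", codon_positions = 3),
    trna = partition_spec("tRNAs", "tRNA"),
    rrns = partition_spec("rrnS", "rrnS"),
    rrnl = partition_spec("rrnL", "rrnL"),
    rrna = partition_spec("rRNAs", "rRNA"),
    cr = partition_spec("CR", "CR")
  )
}
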