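# Codon extraction, start/stop tabulation and relative synonymous codon
# usage (RSCU) under the vertebrate mitochondrial genetic code.
#
# RSCU of codon c in synonymous family F: rscu(c) = count(c) * |F| /
# sum over F of counts. 1 means no bias; families with zero usage have
# undefined (NA) RSCU.

#' Vertebrate mitochondrial stop codons
#' @return character vector (DNA alphabet)
#' @export
mito_stop_codons <- function() c("TAA", "TAG", "AGA", "AGG")

# codon (DNA) -> amino acid, vertebrate mitochondrial code (NCBI table 2)
mito_genetic_code <- function() {
  gc <- Biostrings::getGeneticCode("2")
  names(gc) <- chartr("U", "T", names(gc))
  gc
}

#' Extract codons, start and stop from a protein-coding gene
#'
#' The gene-orientation sequence is taken, the reading offset applied, and
#' the terminal codon classified: a trailing 3-mer that is a vertebrate
#' mitochondrial stop (TAA/TAG/AGA/AGG) is a complete stop; otherwise a
#' trailing "T" or "TA" remainder is an incomplete stop (completed to TAA
#' by polyadenylation in vivo). The returned codon list excludes the stop.
#'
#' @param rec a [genome_record()]
#' @param pcg a PCG [feature()]
#' @param warn warn on internal stop codons (possible mis-annotation)
#' @return list: codons (character vector), start, stop, complete (logical)
#' @export
extract_codons <- function(rec, pcg, warn = TRUE) {
  stopifnot(pcg$kind == "PCG")
  s <- extract_feature_sequence(rec, pcg)
  s <- substr(s, pcg$reading_offset + 1, nchar(s))
  n <- nchar(s)
  ncod <- n %/% 3
  rem <- n - ncod * 3
  codons <- substring(s, seq(1, ncod * 3, by = 3), seq(3, ncod * 3, by = 3))
  complete <- FALSE
  stop_codon <- ""
  if (ncod >= 1 && rem == 0 && codons[ncod] %in% mito_stop_codons()) {
    stop_codon <- codons[ncod]
    codons <- codons[-ncod]
    complete <- TRUE
  } else if (rem > 0) {
    tail_mer <- substr(s, ncod * 3 + 1, n)
    if (tail_mer %in% c("T", "TA")) {
      stop_codon <- tail_mer
    } else if (warn) {
      warning("PCG ", pcg$name, ": trailing ", tail_mer,
              " is neither a stop nor an incomplete stop", call. = FALSE)
    }
  } else if (warn) {
    warning("PCG ", pcg$name, ": no stop codon at 3' end", call. = FALSE)
  }
  if (warn && length(codons) > 1) {
    internal <- which(codons[-1] %in% mito_stop_codons()) + 1L
    if (length(internal)) {
      warning("PCG ", pcg$name, ": internal stop codon at codon position ",
              paste(internal, collapse = ", "),
              " (possible mis-annotation)", call. = FALSE)
    }
  }
  list(codons = codons,
       start = if (length(codons)) codons[1] else "",
       stop = stop_codon, complete = complete)
}

#' Count codon usage over the PCGs of one or more records
#'
#' Stop codons (complete and incomplete) are excluded.
#'
#' @param records a [genome_record()] or list of them
#' @return object of class "codon_count_table": named integer vector over
#'   all 64 codons (DNA alphabet) with attributes n_incomplete_stops and
#'   genetic_code
#' @export
codon_count_table <- function(records) {
  if (inherits(records, "mito_genome")) records <- list(records)
  bases <- c("T", "C", "A", "G")
  all64 <- as.vector(outer(outer(bases, bases, paste0), bases, paste0))
  counts <- stats::setNames(integer(64), all64)
  n_inc <- 0L
  for (rec in records) {
    for (f in Filter(function(f) f$kind == "PCG", rec$features)) {
      info <- extract_codons(rec, f, warn = FALSE)
      tb <- table(info$codons)
      counts[names(tb)] <- counts[names(tb)] + as.integer(tb)
      if (nzchar(info$stop) && !info$complete) n_inc <- n_inc + 1L
    }
  }
  structure(counts, n_incomplete_stops = n_inc,
            genetic_code = "vertebrate mitochondrial (table 2)",
            class = "codon_count_table")
}

#' Relative synonymous codon usage
#'
#' @param counts a [codon_count_table()], or any named count vector over
#'   DNA codons
#' @return data.frame with columns aa (one-letter amino acid), codon (RNA
#'   alphabet for display), count, rscu; stop codons excluded; NA rscu for
#'   families with zero total. Within every nonzero family the rscu values
#'   sum to the family size.
#' @export
rscu <- function(counts) {
  code <- mito_genetic_code()
  code <- code[code != "*"]
  cod <- names(code)
  cnt <- stats::setNames(rep(0L, length(cod)), cod)
  present <- intersect(names(counts), cod)
  cnt[present] <- as.integer(counts[present])
  fam_tot <- tapply(cnt, code, sum)
  fam_size <- tapply(cnt, code, length)
  val <- ifelse(fam_tot[code] > 0,
                cnt * fam_size[code] / fam_tot[code], NA_real_)
  out <- data.frame(aa = unname(code),
                    codon = chartr("T", "U", cod),
                    count = unname(cnt),
                    rscu = unname(val),
                    stringsAsFactors = FALSE)
  out[order(out$aa, out$codon), , drop = FALSE]
}

#' Most frequently used codons by RSCU
#'
#' Ranked by RSCU descending; ties broken by raw count, then
#' alphabetically by codon.
#'
#' @param rscu_table output of [rscu()]
#' @param k number of codons to return
#' @return data.frame of the top k rows (aa, codon, count, rscu)
#' @export
most_frequent_codons <- function(rscu_table, k = 5) {
  stopifnot(k >= 1)
  tab <- rscu_table[!is.na(rscu_table$rscu), , drop = FALSE]
  ord <- order(-tab$rscu, -tab$count, tab$codon)
  utils::head(tab[ord, , drop = FALSE], k)
}

#' Start and stop codons of every PCG across records
#'
#' @param records list of [genome_record()]s
#' @return data.frame: record, gene, start, stop, complete
#' @export
start_stop_table <- function(records) {
  if (inherits(records, "mito_genome")) records <- list(records)
  rows <- list()
  for (rec in records) {
    for (f in Filter(function(f) f$kind == "PCG", rec$features)) {
      info <- extract_codons(rec, f, warn = FALSE)
      rows[[length(rows) + 1L]] <- data.frame(
        record = rec$identifier, gene = f$name,
        start = info$start, stop = info$stop,
        complete = info$complete, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
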