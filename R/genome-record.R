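# Canonical in-memory model of an annotated mitogenome.
#
# Coordinates are 0-based half-open throughout the package; GenBank I/O
# converts at the boundary. A feature spanning the circular origin is
# represented as two intervals.

#' Construct a genome feature
#'
#' @param name canonical gene token (see [canonical_tokens()]) or "other"
#' @param kind one of "PCG", "tRNA", "rRNA", "CR", "other"
#' @param strand "J" (major) or "N" (minor)
#' @param intervals list of c(start, end) pairs, 0-based half-open, ordered
#'   5'->3' in gene orientation
#' @param reading_offset 0, 1 or 2 (from GenBank codon_start - 1); required
#'   for PCGs
#' @param anticodon optional anticodon 3-mer for tRNAs
#' @return object of class "mito_feature"
#' @export
feature <- function(name, kind, strand = "J", intervals,
                    reading_offset = if (kind == "PCG") 0L else NA_integer_,
                    anticodon = NULL) {
  stopifnot(kind %in% c("PCG", "tRNA", "rRNA", "CR", "other"),
            strand %in% c("J", "N"),
            length(intervals) >= 1)
  if (is.numeric(intervals)) intervals <- list(intervals)
  intervals <- lapply(intervals, function(iv) {
    iv <- as.integer(iv)
    if (length(iv) != 2 || iv[2] <= iv[1] || iv[1] < 0) {
      stop("invalid interval for feature ", name)
    }
    iv
  })
  if (kind == "PCG" && (is.na(reading_offset) ||
                        !reading_offset %in% 0:2)) {
    stop("PCG feature ", name, " requires reading_offset in {0,1,2}")
  }
  structure(list(name = name, kind = kind, strand = strand,
                 intervals = intervals,
                 reading_offset = as.integer(reading_offset),
                 anticodon = anticodon),
            class = "mito_feature")
}

#' Feature length in bp
#' @param f a [feature()]
#' @return integer total length over all intervals
#' @export
feature_length <- function(f) {
  sum(vapply(f$intervals, function(iv) iv[2] - iv[1], integer(1)))
}

#' Construct an annotated genome record
#'
#' @param identifier accession-like identifier string
#' @param sequence uppercase DNA string (IUPAC codes allowed)
#' @param features list of [feature()] objects
#' @param circular logical; circular topology
#' @return object of class "mito_genome"
#' @export
genome_record <- function(identifier, sequence, features = list(),
                          circular = TRUE) {
  sequence <- toupper(sequence)
  n <- nchar(sequence)
  if (n == 0) stop("empty sequence")
  for (f in features) {
    for (iv in f$intervals) {
      if (iv[2] > n) {
        stop("feature ", f$name, " interval beyond sequence end")
      }
    }
  }
  ncr <- sum(vapply(features, function(f) f$kind == "CR", logical(1)))
  if (ncr > 1) stop("at most one control-region feature allowed")
  structure(list(identifier = identifier, sequence = sequence,
                 circular = circular, features = features),
            class = "mito_genome")
}

#' @export
print.mito_genome <- function(x, ...) {
  cat("<mito_genome> ", x$identifier, ": ", nchar(x$sequence), " bp, ",
      if (x$circular) "circular" else "linear", ", ",
      length(x$features), " features\n", sep = "")
  invisible(x)
}

#' @export
print.mito_feature <- function(x, ...) {
  ivs <- paste(vapply(x$intervals,
                      function(iv) paste0("[", iv[1], ",", iv[2], ")"),
                      character(1)), collapse = "+")
  cat("<feature> ", x$name, " (", x$kind, ", ", x$strand, "-strand) ",
      ivs, "\n", sep = "")
  invisible(x)
}

#' Tabulate a record's features
#'
#' @param rec a [genome_record()]
#' @return data.frame with columns name, kind, strand, start, end, length;
#'   start/end are of the first/last interval (0-based half-open)
#' @export
feature_table <- function(rec) {
  if (length(rec$features) == 0) {
    return(data.frame(name = character(), kind = character(),
                      strand = character(), start = integer(),
                      end = integer(), length = integer()))
  }
  do.call(rbind, lapply(rec$features, function(f) {
    data.frame(name = f$name, kind = f$kind, strand = f$strand,
               start = f$intervals[[1]][1],
               end = f$intervals[[length(f$intervals)]][2],
               length = feature_length(f),
               stringsAsFactors = FALSE)
  }))
}

#' Write a feature table to TSV
#' @param rec a [genome_record()]
#' @param path output file
#' @return invisibly, the table written
#' @export
write_feature_table <- function(rec, path) {
  tab <- feature_table(rec)
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(tab)
}

#' Extract the sequence of a feature
#'
#' Concatenates the feature's intervals in order and reverse-complements
#' the result for N-strand features, so the returned string is always in
#' gene orientation (5'->3' of the encoded gene). Origin-spanning features
#' are supported through their two-interval representation.
#'
#' @param rec a [genome_record()]
#' @param f a [feature()] of that record
#' @return DNA string in gene orientation
#' @export
extract_feature_sequence <- function(rec, f) {
  n <- nchar(rec$sequence)
  parts <- vapply(f$intervals, function(iv) {
    if (iv[2] > n || iv[1] < 0) stop("interval out of bounds")
    substr(rec$sequence, iv[1] + 1, iv[2])
  }, character(1))
  s <- paste0(parts, collapse = "")
  if (f$strand == "N") s <- revcomp(s)
  s
}

# find the (unique) feature with a canonical name; NULL when absent
find_feature <- function(rec, name) {
  for (f in rec$features) if (f$name == name) return(f)
  NULL
}
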