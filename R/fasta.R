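# FASTA I/O (gapped alignments allowed), via Biostrings.

#' Read a FASTA file into a named character vector
#'
#' Gap characters ('-') in alignment files are preserved verbatim.
#'
#' @param path FASTA file
#' @return named character vector of uppercase sequences
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readBStringSet(path)
  out <- toupper(as.character(x))
  names(out) <- sub("\\s.*$", "", names(x))
  if (anyDuplicated(names(out))) {
    stop("duplicate sequence names in ", path)
  }
  out
}

#' Write named sequences to FASTA
#'
#' @param seqs named character vector (or named list) of sequences
#' @param path output file
#' @param width line-wrap width (default 60)
#' @export
write_fasta <- function(seqs, path, width = 60) {
  seqs <- unlist(seqs)
  if (is.null(names(seqs)) || any(names(seqs) == "")) {
    stop("all sequences must be named")
  }
  if (anyDuplicated(names(seqs))) stop("duplicate sequence names")
  x <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(x, path, width = width)
  invisible(path)
}
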