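# Internal helpers shared across modules.

#' Round half away from zero
#'
#' Decimal rounding where ties go away from zero (".5 rounds up"), matching
#' the convention of most spreadsheet/report software, rather than base R's
#' round-half-even. Used for all percent reporting.
#'
#' @param x numeric vector
#' @param digits number of decimal places
#' @return rounded numeric vector
#' @export
round_half_up <- function(x, digits = 1) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# split a string into a character vector of single bases
s2c <- function(s) strsplit(s, "", fixed = TRUE)[[1]]
c2s <- function(x) paste0(x, collapse = "")

#' Reverse complement of a DNA string
#'
#' IUPAC-aware; gaps ('-') and case are preserved positionally reversed.
#'
#' @param s DNA string
#' @return reverse-complemented string
#' @export
revcomp <- function(s) {
  comp <- chartr("ACGTUMRWSYKVHDBNacgtumrwsykvhdbn",
                 "TGCAAKYWSRMBDHVNtgcaakywsrmbdhvn", s)
  vapply(comp, function(x) c2s(rev(s2c(x))), character(1), USE.NAMES = FALSE)
}

# IUPAC compatibility: does pattern base p admit subject base b?
iupac_expand <- c(
  A = "A", C = "C", G = "G", T = "T", U = "T",
  R = "AG", Y = "CT", S = "CG", W = "AT", K = "GT", M = "AC",
  B = "CGT", D = "AGT", H = "ACT", V = "ACG", N = "ACGT"
)

# 16x4 logical lookup used by the motif scanner
iupac_match_matrix <- local({
  bases <- c("A", "C", "G", "T")
  m <- matrix(FALSE, nrow = length(iupac_expand), ncol = 4,
              dimnames = list(names(iupac_expand), bases))
  for (p in names(iupac_expand)) {
    m[p, s2c(iupac_expand[[p]])] <- TRUE
  }
  m
})

# Deterministic per-component substream: one root seed, named substreams,
# so adding a component does not shift another component's draws.
substream_seed <- function(seed, name) {
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)))
  as.integer((as.numeric(seed) * 1009 + h) %% 2147483647)
}

with_substream <- function(seed, name, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  set.seed(substream_seed(seed, name))
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  force(expr)
}

# sample n bases from named frequencies (A,C,G,T)
sample_bases <- function(n, freqs) {
  stopifnot(all(names(freqs) %in% c("A", "C", "G", "T")))
  c2s(sample(names(freqs), n, replace = TRUE, prob = freqs))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
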