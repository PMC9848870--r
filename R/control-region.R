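# Control-region analysis: domain partitioning, alignment variability,
# conserved-box motif search, tandem-repeat detection.
#
# The avian control region is conventionally divided into ETAS domain I
# (5'), the central conserved domain II, and CSB domain III (3'). Domain
# boundaries are not universal; they are user configuration here, with an
# anchor-motif mode (domain II starts at the F-box hit, domain III at the
# CSB1 hit) as a fallback.

#' Proportion of variable sites in an alignment
#'
#' A column is variable iff it contains at least two distinct non-gap
#' residues. The denominator is, by default, the number of columns with at
#' least two non-gap residues (configurable to all columns).
#'
#' @param alignment named character vector of equal-length gapped sequences
#' @param interval optional c(start, end) 0-based half-open column window
#' @param denominator "informative" (default: columns with >= 2 non-gap
#'   residues) or "total" (all columns in the window)
#' @return percent of variable sites, full precision (round for reporting)
#' @export
variable_site_proportion <- function(alignment, interval = NULL,
                                     denominator = c("informative",
                                                     "total")) {
  denominator <- match.arg(denominator)
  if (length(alignment) < 2) stop("need at least two sequences")
  L <- unique(nchar(alignment))
  if (length(L) != 1) stop("sequences must be aligned (equal length)")
  m <- do.call(rbind, strsplit(toupper(alignment), ""))
  if (!is.null(interval)) {
    stopifnot(interval[1] >= 0, interval[2] <= L)
    m <- m[, (interval[1] + 1):interval[2], drop = FALSE]
  }
  gap <- m == "-" | m == "."
  n_res <- colSums(!gap)
  variable <- vapply(seq_len(ncol(m)), function(j) {
    r <- m[!gap[, j], j]
    length(unique(r)) >= 2
  }, logical(1))
  denom <- if (denominator == "informative") sum(n_res >= 2) else ncol(m)
  if (denom == 0) return(NA_real_)
  100 * sum(variable & n_res >= 2) / denom
}

#' Partition a control region into its three domains
#'
#' @param cr_seq control-region sequence (or one row of an alignment; the
#'   coordinates are local to what is passed)
#' @param boundaries either a list of two numbers `c(b1, b2)` giving the
#'   starts of domain II and domain III (explicit mode), or NULL to use
#'   anchor mode
#' @param anchors anchor-mode configuration: list with `fbox` and `csb1`
#'   IUPAC patterns and `max_mismatch`; domain II starts at the first F-box
#'   hit, domain III at the first CSB1 hit
#' @return object of class "domain_partition": data.frame with columns
#'   domain ("I","II","III"), start, end (0-based half-open, CR-local)
#' @export
partition_cr <- function(cr_seq, boundaries = NULL,
                         anchors = list(fbox = cr_box_patterns()$fbox,
                                        csb1 = cr_box_patterns()$csb1,
                                        max_mismatch = 2)) {
  L <- nchar(cr_seq)
  if (is.null(boundaries)) {
    hf <- find_motif(cr_seq, anchors$fbox, anchors$max_mismatch)
    hc <- find_motif(cr_seq, anchors$csb1, anchors$max_mismatch)
    if (!nrow(hf)) stop("anchor mode: F-box motif not found")
    if (!nrow(hc)) stop("anchor mode: CSB1 motif not found")
    boundaries <- c(hf$start[1], hc$start[1])
  }
  b <- as.integer(boundaries)
  if (length(b) != 2 || b[1] <= 0 || b[2] <= b[1] || b[2] >= L) {
    stop("domain boundaries must satisfy 0 < b1 < b2 < CR length")
  }
  out <- data.frame(domain = c("I", "II", "III"),
                    start = c(0L, b[1], b[2]),
                    end = c(b[1], b[2], L))
  class(out) <- c("domain_partition", "data.frame")
  out
}

#' Default conserved-box patterns for the avian control region
#'
#' Package-defined IUPAC consensus patterns for the conserved elements
#' usually annotated in avian CRs (poly-C tract of ETAS domain I; F, E, D,
#' C and B boxes plus the bird similarity box of domain II; CSB1 of domain
#' III). These are configuration data, editable via the motif-config file
#' (see [read_motif_config()]); they make no claim of universality, and the
#' synthetic-genome generator implants exactly these defaults so detection
#' can be validated against ground truth. Only the poly-C tract is an
#' empirical wagtail sequence.
#'
#' @return named list of IUPAC pattern strings
#' @export
cr_box_patterns <- function() {
  list(
    polyc = "CCCCCCCCCCTTCCCCCCCC",
    fbox  = "ATGTACTATTGTACCATAAA",
    ebox  = "AGGGGAACTTCCAGGGG",
    dbox  = "CCTGGTTCTTACTTCAGG",
    cbox  = "TATGTATGGGGTTACA",
    bbox  = "TCTTGATTTCACGTGAGG",
    bird  = "CACGTGAGGAATTACCAGG",
    csb1  = "TTAATGCTCGTTATACATA"
  )
}

#' Read a motif configuration file
#'
#' Tab-separated columns: name, pattern (IUPAC), max_mismatch.
#'
#' @param path TSV file
#' @return data.frame with those columns
#' @export
read_motif_config <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("name", "pattern", "max_mismatch") %in% names(tab)))
  tab
}

#' IUPAC-aware approximate motif search
#'
#' Finds every position where the pattern matches with at most
#' `max_mismatch` Hamming mismatches; ambiguity codes in the pattern match
#' their IUPAC expansion (N matches everything, Y matches C/T, ...).
#' Overlapping hits are allowed. Hits are sorted by (mismatches, start).
#'
#' @param seq subject DNA string
#' @param motif IUPAC pattern
#' @param max_mismatch maximum Hamming mismatches (default 0)
#' @param name optional motif name recorded in the output
#' @return data.frame: motif, start, end (0-based half-open), mismatches,
#'   match (matched substring); zero rows when nothing matches or the
#'   pattern is longer than the sequence
#' @export
find_motif <- function(seq, motif, max_mismatch = 0, name = NA_character_) {
  if (!nzchar(motif)) stop("empty pattern")
  s <- s2c(toupper(seq))
  p <- s2c(toupper(chartr("U", "T", motif)))
  L <- length(s); m <- length(p)
  empty <- data.frame(motif = character(), start = integer(),
                      end = integer(), mismatches = integer(),
                      match = character(), stringsAsFactors = FALSE)
  if (m > L) return(empty)
  # mismatch counts for all windows via per-offset compatibility
  subj_idx <- match(s, colnames(iupac_match_matrix))  # NA for non-ACGT
  nwin <- L - m + 1L
  mis <- integer(nwin)
  for (j in seq_len(m)) {
    pj <- p[j]
    if (!pj %in% rownames(iupac_match_matrix)) stop("bad pattern base: ", pj)
    ok <- iupac_match_matrix[pj, ]
    sj <- subj_idx[j:(j + nwin - 1L)]
    hit <- !is.na(sj) & ok[sj]
    # ambiguous subject base: count as mismatch unless pattern is N
    if (pj == "N") hit <- rep(TRUE, nwin)
    mis <- mis + !hit
  }
  at <- which(mis <= max_mismatch)
  if (!length(at)) return(empty)
  out <- data.frame(motif = name, start = at - 1L, end = at - 1L + m,
                    mismatches = mis[at],
                    match = substring(toupper(seq), at, at + m - 1L),
                    stringsAsFactors = FALSE)
  out[order(out$mismatches, out$start), , drop = FALSE]
}

#' Scan a control region for all configured conserved boxes
#'
#' @param cr_seq CR sequence
#' @param config motif configuration data.frame (name, pattern,
#'   max_mismatch); default: [cr_box_patterns()] with 2 mismatches allowed
#'   (0 for the poly-C tract)
#' @return data.frame of best hit per motif (NA row when absent)
#' @export
scan_cr_boxes <- function(cr_seq, config = NULL) {
  if (is.null(config)) {
    pats <- cr_box_patterns()
    config <- data.frame(name = names(pats),
                         pattern = unlist(pats),
                         max_mismatch = ifelse(names(pats) == "polyc", 0, 2),
                         stringsAsFactors = FALSE)
  }
  rows <- lapply(seq_len(nrow(config)), function(i) {
    h <- find_motif(cr_seq, config$pattern[i], config$max_mismatch[i],
                    name = config$name[i])
    if (nrow(h)) h[1, , drop = FALSE] else
      data.frame(motif = config$name[i], start = NA_integer_,
                 end = NA_integer_, mismatches = NA_integer_,
                 match = NA_character_, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Detect tandem repeats
#'
#' Scan over all unit lengths: positions where s[i] == s[i - u] define
#' match runs; maximal runs meeting the copy-number and purity thresholds
#' are reported. Under purity < 1, pure runs separated by single
#' mismatches are merged greedily while the overall purity stays above the
#' threshold. Nested reports of the same locus are collapsed to the
#' smallest unit.
#'
#' @param seq DNA string
#' @param min_unit,max_unit unit-length range (bp)
#' @param min_copies minimum copy number (fractional allowed, >= 2)
#' @param min_purity minimum fraction of positions matching the
#'   unit-periodic prediction (first unit counts as matching)
#' @param min_length minimum total array length (bp). Random sequence is
#'   dense in incidental short periodicities (any 4-mer "xyxy" is a 2 bp
#'   unit at 2 copies), so a floor on the array length -- analogous to the
#'   alignment-score threshold of seed-and-extend repeat finders -- is what
#'   makes the default scan report only biologically notable arrays. Set
#'   to 0 for exhaustive behaviour.
#' @return data.frame: unit, unit_length, copies, start, end, purity
#' @export
find_tandem_repeats <- function(seq, min_unit = 2, max_unit = 200,
                                min_copies = 2, min_purity = 0.9,
                                min_length = 36) {
  s <- s2c(toupper(seq))
  L <- length(s)
  max_unit <- min(max_unit, L %/% 2)
  out <- list()
  if (max_unit < min_unit) return(tandem_df(out))
  for (u in min_unit:max_unit) {
    match_at <- c(rep(FALSE, u), s[(u + 1):L] == s[1:(L - u)])
    # candidate maximal runs of periodicity u: stretches where match_at is
    # TRUE, extended back by the u seed positions
    r <- rle(match_at)
    pos <- cumsum(r$lengths)
    starts <- c(1L, utils::head(pos, -1) + 1L)
    for (k in seq_along(r$values)) {
      if (!r$values[k]) next
      run_start <- starts[k] - u       # include the seed unit
      run_end <- pos[k]                # inclusive
      if (run_start < 1) run_start <- 1L
      reps <- merge_runs(match_at, run_start, run_end, u, min_purity)
      for (rp in reps) {
        len <- rp[2] - rp[1] + 1L
        copies <- len / u
        if (copies < min_copies || len < min_length) next
        matches <- sum(match_at[(rp[1] + u):rp[2]])
        purity <- (u + matches) / len
        if (purity < min_purity) next
        out[[length(out) + 1L]] <- data.frame(
          unit = c2s(s[rp[1]:(rp[1] + u - 1L)]), unit_length = u,
          copies = copies, start = rp[1] - 1L, end = rp[2],
          purity = purity, stringsAsFactors = FALSE)
      }
    }
  }
  collapse_repeats(tandem_df(out))
}

# merge a pure run with following near-pure extensions; returns list of
# c(start, end) inclusive 1-based. For purity 1 this is just the run.
merge_runs <- function(match_at, run_start, run_end, u, min_purity) {
  if (min_purity >= 1) return(list(c(run_start, run_end)))
  L <- length(match_at)
  end <- run_end
  repeat {
    # try to bridge a single mismatch and continue the periodic run
    nxt <- end + 1L
    if (nxt > L || match_at[nxt]) break
    j <- nxt + 1L
    while (j <= L && match_at[j]) j <- j + 1L
    ext_end <- j - 1L
    if (ext_end <= nxt) break
    len <- ext_end - run_start + 1L
    matches <- sum(match_at[(run_start + u):ext_end])
    if ((u + matches) / len >= min_purity) end <- ext_end else break
  }
  list(c(run_start, end))
}

tandem_df <- function(rows) {
  if (!length(rows)) {
    return(data.frame(unit = character(), unit_length = integer(),
                      copies = numeric(), start = integer(),
                      end = integer(), purity = numeric(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

# drop repeats whose interval is contained in a reported repeat with a
# smaller (or equal, preferring earlier) unit
collapse_repeats <- function(tab) {
  if (nrow(tab) < 2) return(tab)
  ord <- order(tab$unit_length, tab$start)
  tab <- tab[ord, , drop = FALSE]
  keep <- rep(TRUE, nrow(tab))
  for (i in seq_len(nrow(tab))) {
    if (!keep[i]) next
    for (j in seq_len(nrow(tab))) {
      if (i == j || !keep[j]) next
      if (tab$unit_length[j] >= tab$unit_length[i] &&
          tab$start[j] >= tab$start[i] && tab$end[j] <= tab$end[i] &&
          !(tab$unit_length[j] == tab$unit_length[i] &&
            tab$start[j] == tab$start[i] && tab$end[j] == tab$end[i])) {
        keep[j] <- FALSE
      }
    }
  }
  res <- tab[keep, , drop = FALSE]
  rownames(res) <- NULL
  res
}
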