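# Circular gene order, breakpoint comparison, and intergenic spacers.

#' Extract the circular gene order of a record
#'
#' Features are sorted by the start of their first interval (an
#' origin-spanning feature is positioned by its 5' end) and the order is
#' rotated so the anchor gene comes first. Equality of gene orders is
#' rotation-invariant by construction.
#'
#' @param rec a [genome_record()]
#' @param anchor canonical name to rotate to front (default "trnF")
#' @return object of class "gene_order": data.frame with columns name,
#'   strand, in J-strand 5'->3' genome order; attribute "missing" lists
#'   expected tokens absent from the record
#' @export
extract_gene_order <- function(rec, anchor = "trnF") {
  feats <- Filter(function(f) f$kind != "other", rec$features)
  if (!length(feats)) stop("record has no features")
  starts <- vapply(feats, function(f) {
    # origin-spanning N-strand features: 5' end in genome coordinates is
    # still the first listed interval's start (intervals are gene-ordered);
    # position by the genome-coordinate start of the feature body
    min(vapply(f$intervals, `[`, integer(1), 1))
  }, integer(1))
  # an origin-spanning feature (two intervals, one ending at genome end)
  # is positioned by its genome 5' interval
  for (i in seq_along(feats)) {
    f <- feats[[i]]
    if (length(f$intervals) > 1) {
      ends <- vapply(f$intervals, `[`, integer(1), 2)
      if (any(ends == nchar(rec$sequence))) {
        starts[i] <- f$intervals[[which(ends == nchar(rec$sequence))[1]]][1]
      }
    }
  }
  ord <- order(starts)
  name <- vapply(feats[ord], function(f) f$name, character(1))
  strand <- vapply(feats[ord], function(f) f$strand, character(1))
  if (anyDuplicated(name)) {
    stop("duplicate canonical gene name: ",
         paste(unique(name[duplicated(name)]), collapse = ", "))
  }
  i <- match(anchor, name)
  if (!is.na(i) && i > 1) {
    idx <- c(i:length(name), 1:(i - 1))
    name <- name[idx]; strand <- strand[idx]
  }
  out <- data.frame(name = name, strand = strand, stringsAsFactors = FALSE)
  attr(out, "missing") <- setdiff(canonical_tokens(), name)
  class(out) <- c("gene_order", "data.frame")
  out
}

#' Format a gene order as a dash-separated string
#'
#' N-strand genes carry a leading "-".
#'
#' @param go a [extract_gene_order()] result
#' @return single string
#' @export
format_gene_order <- function(go) {
  paste(ifelse(go$strand == "N", paste0("-", go$name), go$name),
        collapse = "-")
}

#' The canonical passerine gene order as a gene_order object
#' @return "gene_order" data.frame
#' @export
reference_gene_order <- function() {
  out <- passerine_gene_order()
  attr(out, "missing") <- character()
  class(out) <- c("gene_order", "data.frame")
  out
}

# strand-aware circular adjacency set; adjacency (x,sx)->(y,sy) equals its
# reading on the other strand (y,!sy)->(x,!sx); stored canonically
adjacency_set <- function(go) {
  n <- nrow(go)
  flip <- function(s) ifelse(s == "J", "N", "J")
  enc <- function(x, sx, y, sy) paste(x, sx, y, sy, sep = "|")
  out <- character(n)
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    a <- enc(go$name[i], go$strand[i], go$name[j], go$strand[j])
    b <- enc(go$name[j], flip(go$strand[j]), go$name[i], flip(go$strand[i]))
    out[i] <- min(a, b)
  }
  out
}

#' Compare two circular gene orders
#'
#' Breakpoints are the strand-aware circular adjacencies present in `a`
#' but not in `b`. Tokens missing from either order are dropped pairwise
#' (with a warning) before comparison.
#'
#' @param a,b "gene_order" objects
#' @return list: identical (logical), breakpoints (integer), differing
#'   (character vector of a's adjacencies absent from b, "x|sx|y|sy"
#'   encoded)
#' @export
compare_orders <- function(a, b) {
  common <- intersect(a$name, b$name)
  if (length(common) < nrow(a) || length(common) < nrow(b)) {
    warning("dropping tokens not shared by both orders: ",
            paste(union(setdiff(a$name, common), setdiff(b$name, common)),
                  collapse = ", "), call. = FALSE)
    a <- a[a$name %in% common, , drop = FALSE]
    b <- b[b$name %in% common, , drop = FALSE]
  }
  sa <- adjacency_set(a)
  sb <- adjacency_set(b)
  diff <- setdiff(sa, sb)
  list(identical = length(diff) == 0, breakpoints = length(diff),
       differing = diff)
}

#' Intergenic spacers and overlaps between adjacent features
#'
#' Gap = next feature's start minus previous feature's end on the circular
#' topology; negative values are overlaps; the pair spanning the origin is
#' included for circular records.
#'
#' @param rec a [genome_record()] with at least two features
#' @return data.frame: upstream, downstream, gap (bp; negative = overlap)
#' @export
spacer_table <- function(rec) {
  feats <- Filter(function(f) f$kind != "other", rec$features)
  if (length(feats) < 2) stop("need at least two features")
  n <- nchar(rec$sequence)
  bounds <- t(vapply(feats, function(f) {
    ivs <- do.call(rbind, f$intervals)
    # genome-coordinate span; origin-spanning handled via modular end
    if (nrow(ivs) > 1 && any(ivs[, 2] == n) && any(ivs[, 1] == 0)) {
      c(start = ivs[ivs[, 2] == n, 1][1], end = ivs[ivs[, 1] == 0, 2][1] + n)
    } else {
      c(start = min(ivs[, 1]), end = max(ivs[, 2]))
    }
  }, c(start = 0, end = 0)))
  ord <- order(bounds[, "start"])
  feats <- feats[ord]; bounds <- bounds[ord, , drop = FALSE]
  k <- length(feats)
  rows <- lapply(seq_len(k), function(i) {
    j <- if (i == k) 1L else i + 1L
    gap <- if (i == k) {
      if (rec$circular) bounds[j, "start"] + n - bounds[i, "end"] else NA
    } else {
      bounds[j, "start"] - bounds[i, "end"]
    }
    data.frame(upstream = feats[[i]]$name, downstream = feats[[j]]$name,
               gap = as.integer(gap), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[!is.na(out$gap), , drop = FALSE]
}

#' Summarise intergenic spacers (gaps >= 1 bp)
#'
#' @param rec a [genome_record()]
#' @return list: n_spacers, min, max, longest (upstream/downstream pair of
#'   the longest spacer), table (gaps >= 1 only)
#' @export
spacer_summary <- function(rec) {
  tab <- spacer_table(rec)
  sp <- tab[tab$gap >= 1, , drop = FALSE]
  if (!nrow(sp)) {
    return(list(n_spacers = 0L, min = NA, max = NA, longest = NULL,
                table = sp))
  }
  i <- which.max(sp$gap)
  list(n_spacers = nrow(sp), min = min(sp$gap), max = max(sp$gap),
       longest = sp[i, c("upstream", "downstream", "gap")],
       table = sp)
}
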