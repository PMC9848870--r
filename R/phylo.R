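# Desk-scale phylogenetics: supermatrix concatenation, p/K2P distances,
# neighbor joining, tree queries, and supermatrix export. Distance and
# tree machinery is delegated to ape; this module owns the supermatrix
# bookkeeping and the deterministic conventions around it.

#' Concatenate per-gene alignments into a supermatrix
#'
#' @param alignments named list of alignments; each alignment is a named
#'   character vector of equal-length gapped sequences
#' @param taxa optional master taxon list (default: union over genes, in
#'   first-appearance order); a taxon missing from a gene gets an all-gap
#'   block
#' @return object of class "supermatrix": list with taxa, sequences (named
#'   character vector), partitions (data.frame gene, start, end; 0-based
#'   half-open column intervals tiling the matrix)
#' @export
concatenate <- function(alignments, taxa = NULL) {
  stopifnot(length(alignments) >= 1, !is.null(names(alignments)))
  if (is.null(taxa)) {
    taxa <- unique(unlist(lapply(alignments, names)))
  }
  for (g in names(alignments)) {
    al <- alignments[[g]]
    if (anyDuplicated(names(al))) {
      stop("duplicated taxon within gene ", g)
    }
    if (!all(names(al) %in% taxa)) {
      stop("gene ", g, " contains taxa not in the master list")
    }
    if (length(unique(nchar(al))) != 1) {
      stop("gene ", g, ": unequal sequence lengths (not an alignment)")
    }
  }
  blocks <- list()
  parts <- list()
  off <- 0L
  for (g in names(alignments)) {
    al <- alignments[[g]]
    w <- nchar(al[[1]])
    block <- stats::setNames(rep(strrep("-", w), length(taxa)), taxa)
    block[names(al)] <- unname(al)
    blocks[[g]] <- block
    parts[[g]] <- data.frame(gene = g, start = off, end = off + w,
                             stringsAsFactors = FALSE)
    off <- off + w
  }
  seqs <- stats::setNames(do.call(paste0, blocks), taxa)
  structure(list(taxa = taxa, sequences = seqs,
                 partitions = do.call(rbind, parts)),
            class = "supermatrix")
}

#' @export
print.supermatrix <- function(x, ...) {
  cat("<supermatrix> ", length(x$taxa), " taxa x ",
      nchar(x$sequences[[1]]), " columns, ", nrow(x$partitions),
      " partitions\n", sep = "")
  invisible(x)
}

as_DNAbin <- function(seqs) {
  ape::as.DNAbin(t(sapply(strsplit(tolower(seqs), ""), identity)))
}

#' Pairwise distance matrix from a supermatrix
#'
#' p distance (proportion of mismatching sites) or Kimura two-parameter
#' distance, with pairwise deletion of gapped/ambiguous sites.
#'
#' @param sm a [concatenate()] supermatrix, or a named character vector of
#'   aligned sequences
#' @param model "p" or "K2P"
#' @return symmetric matrix with taxon dimnames; NaN entries where a pair
#'   shares no valid site
#' @export
distance_matrix <- function(sm, model = c("p", "K2P")) {
  model <- match.arg(model)
  seqs <- if (inherits(sm, "supermatrix")) sm$sequences else sm
  if (length(seqs) < 2) stop("need at least two taxa")
  dna <- as_DNAbin(seqs)
  d <- ape::dist.dna(dna, model = if (model == "p") "raw" else "K80",
                     pairwise.deletion = TRUE)
  as.matrix(d)
}

#' Neighbor-joining tree
#'
#' Standard NJ agglomeration (ape's implementation). Negative branch
#' lengths are clamped to zero with a warning.
#'
#' @param d symmetric distance matrix with taxon dimnames
#' @return ape "phylo" tree (unrooted)
#' @export
neighbor_joining <- function(d) {
  d <- as.matrix(d)
  if (any(!is.finite(d))) {
    stop("distance matrix contains undefined entries")
  }
  if (nrow(d) < 3) stop("need at least three taxa")
  tr <- ape::nj(as.dist(d))
  if (any(tr$edge.length < 0)) {
    warning("negative NJ branch lengths clamped to 0", call. = FALSE)
    tr$edge.length[tr$edge.length < 0] <- 0
  }
  tr
}

#' Is a taxon set monophyletic?
#'
#' The tree is rooted at the outgroup, then the subset is monophyletic iff
#' it forms a complete clade.
#'
#' @param tree ape "phylo"
#' @param taxa character vector of tip labels
#' @param outgroup tip label used to root
#' @return logical
#' @export
is_monophyletic <- function(tree, taxa, outgroup) {
  labs <- tree$tip.label
  if (!all(c(taxa, outgroup) %in% labs)) {
    stop("unknown taxon: ",
         paste(setdiff(c(taxa, outgroup), labs), collapse = ", "))
  }
  rooted <- ape::root(tree, outgroup = outgroup, resolve.root = TRUE)
  ape::is.monophyletic(rooted, taxa)
}

#' Does a tree match a Newick topology pattern?
#'
#' Branch lengths and rotations are ignored. The tree is pruned to the
#' pattern's taxa and compared as unrooted topologies (Robinson-Foulds
#' distance zero).
#'
#' @param tree ape "phylo"
#' @param pattern Newick string (may cover a subset of the tree's taxa)
#' @return logical
#' @export
topology_matches <- function(tree, pattern) {
  pat <- ape::read.tree(text = pattern)
  if (!all(pat$tip.label %in% tree$tip.label)) {
    stop("unknown taxon in pattern: ",
         paste(setdiff(pat$tip.label, tree$tip.label), collapse = ", "))
  }
  sub <- ape::keep.tip(tree, pat$tip.label)
  topo_rf(ape::unroot(sub), ape::unroot(pat)) == 0
}

# unrooted RF distance via bipartition comparison (no phangorn dependency
# in the package itself)
topo_rf <- function(a, b) {
  bip <- function(tr) {
    labs <- sort(tr$tip.label)
    pp <- ape::prop.part(tr)
    sets <- lapply(pp, function(i) attr(pp, "labels")[i])
    keys <- vapply(sets, function(s) {
      s <- sort(s)
      comp <- sort(setdiff(labs, s))
      # canonical side: lexicographically smaller encoding, ignore trivial
      if (length(s) <= 1 || length(comp) <= 1) return(NA_character_)
      min(paste(s, collapse = ","), paste(comp, collapse = ","))
    }, character(1))
    unique(keys[!is.na(keys)])
  }
  ba <- bip(ape::unroot(a)); bb <- bip(ape::unroot(b))
  length(setdiff(ba, bb)) + length(setdiff(bb, ba))
}

#' Robinson-Foulds distance between two trees
#' @param a,b ape "phylo" trees over the same taxa
#' @return integer RF distance (0 = identical unrooted topologies)
#' @export
rf_distance <- function(a, b) {
  stopifnot(setequal(a$tip.label, b$tip.label))
  topo_rf(a, b)
}

# sanitize taxon names for PHYLIP/NEXUS; returns c(clean = original)
sanitize_names <- function(taxa) {
  clean <- gsub("[^A-Za-z0-9_.|-]", "_", taxa)
  if (anyDuplicated(clean)) {
    clean <- make.unique(clean, sep = "_")
  }
  stats::setNames(taxa, clean)
}

#' Export a supermatrix to relaxed PHYLIP or NEXUS (with charsets)
#'
#' Taxon names containing whitespace are sanitized; the mapping is written
#' alongside as `<path>.names.tsv` when any name changed.
#'
#' @param sm a [concatenate()] supermatrix
#' @param path output file
#' @param format "phylip" (relaxed, sequential) or "nexus" (with a sets
#'   block of charsets mirroring the partition map)
#' @export
export_supermatrix <- function(sm, path, format = c("phylip", "nexus")) {
  format <- match.arg(format)
  map <- sanitize_names(sm$taxa)
  clean <- names(map)
  seqs <- unname(sm$sequences[map])
  ncol <- nchar(seqs[[1]])
  if (format == "phylip") {
    lines <- c(sprintf("%d %d", length(clean), ncol),
               sprintf("%s  %s", clean, seqs))
  } else {
    lines <- c(
      "#NEXUS", "BEGIN DATA;",
      sprintf("  DIMENSIONS NTAX=%d NCHAR=%d;", length(clean), ncol),
      "  FORMAT DATATYPE=DNA GAP=- MISSING=?;",
      "  MATRIX",
      sprintf("    %s  %s", clean, seqs),
      "  ;", "END;", "BEGIN SETS;",
      sprintf("  CHARSET %s = %d-%d;", sm$partitions$gene,
              sm$partitions$start + 1L, sm$partitions$end),
      "END;")
  }
  writeLines(lines, path)
  if (!all(map == clean)) {
    utils::write.table(
      data.frame(sanitized = clean, original = unname(map)),
      paste0(path, ".names.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
  }
  invisible(path)
}

#' Read back a supermatrix written by [export_supermatrix()]
#'
#' @param path file produced by [export_supermatrix()]
#' @param format "phylip" or "nexus"
#' @return "supermatrix" object (partitions only recovered from NEXUS)
#' @export
read_supermatrix <- function(path, format = c("phylip", "nexus")) {
  format <- match.arg(format)
  lines <- readLines(path)
  if (format == "phylip") {
    hdr <- as.integer(strsplit(trimws(lines[1]), "\\s+")[[1]])
    rows <- strsplit(trimws(lines[2:(1 + hdr[1])]), "\\s+")
    taxa <- vapply(rows, `[`, character(1), 1)
    seqs <- stats::setNames(vapply(rows, `[`, character(1), 2), taxa)
    parts <- data.frame(gene = "all", start = 0L, end = hdr[2])
  } else {
    mat_at <- grep("^\\s*MATRIX", lines)
    end_at <- grep("^\\s*;", lines)
    end_at <- end_at[end_at > mat_at][1]
    rows <- strsplit(trimws(lines[(mat_at + 1):(end_at - 1)]), "\\s+")
    taxa <- vapply(rows, `[`, character(1), 1)
    seqs <- stats::setNames(vapply(rows, `[`, character(1), 2), taxa)
    cs <- grep("^\\s*CHARSET", lines, value = TRUE)
    gene <- sub("^\\s*CHARSET\\s+(\\S+)\\s*=.*$", "\\1", cs)
    rng <- regmatches(cs, regexpr("\\d+-\\d+", cs))
    se <- do.call(rbind, lapply(strsplit(rng, "-"), as.integer))
    parts <- data.frame(gene = gene, start = se[, 1] - 1L, end = se[, 2],
                        stringsAsFactors = FALSE)
  }
  structure(list(taxa = taxa, sequences = toupper(seqs),
                 partitions = parts),
            class = "supermatrix")
}
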