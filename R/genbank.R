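# GenBank flat-file reader/writer.
#
# The reader handles the subset of the format produced for mitogenome
# records: LOCUS/ACCESSION/DEFINITION header, a FEATURES table with
# gene/CDS/tRNA/rRNA/D-loop/misc_feature keys, join()/complement()
# locations, and an ORIGIN sequence block. GenBank 1-based inclusive
# coordinates are converted to 0-based half-open at this boundary;
# complement strands become "N".

# ---- location strings ----------------------------------------------------

# "complement(join(123..456,1..20))" -> list(strand, intervals 0-based)
parse_location <- function(loc) {
  strand <- "J"
  loc <- gsub("[<>]", "", loc)      # drop partial markers
  if (grepl("^complement\\(", loc)) {
    strand <- "N"
    loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
  }
  if (grepl("^join\\(", loc)) {
    loc <- sub("^join\\((.*)\\)$", "\\1", loc)
  }
  parts <- strsplit(loc, ",", fixed = TRUE)[[1]]
  intervals <- lapply(parts, function(p) {
    if (grepl("^\\d+\\.\\.\\d+$", p)) {
      se <- as.integer(strsplit(p, "..", fixed = TRUE)[[1]])
    } else if (grepl("^\\d+$", p)) {
      se <- rep(as.integer(p), 2)
    } else {
      stop("cannot parse location component: ", p)
    }
    c(se[1] - 1L, se[2])            # 1-based inclusive -> 0-based half-open
  })
  # complement(join(a,b)) lists intervals in genome order; gene order on the
  # minor strand is the reverse
  if (strand == "N") intervals <- rev(intervals)
  list(strand = strand, intervals = intervals)
}

# ---- reader --------------------------------------------------------------

#' Read GenBank flat-file mitogenome records
#'
#' @param path GenBank flat file (may contain several records separated
#'   by "//")
#' @param warn warn on unknown gene labels and feature-less records
#' @return list of [genome_record()] objects
#' @export
read_genbank <- function(path, warn = TRUE) {
  lines <- readLines(path, warn = FALSE)
  recs <- list()
  starts <- grep("^LOCUS", lines)
  if (length(starts) == 0) stop("malformed GenBank file: no LOCUS line")
  ends <- c(grep("^//\\s*$", lines))
  if (length(ends) < length(starts)) ends <- c(ends, length(lines))
  for (i in seq_along(starts)) {
    chunk <- lines[starts[i]:ends[i]]
    recs[[length(recs) + 1L]] <- parse_genbank_record(chunk, warn = warn)
  }
  recs
}

parse_genbank_record <- function(lines, warn = TRUE) {
  locus <- lines[1]
  circular <- grepl("circular", locus, ignore.case = TRUE)
  acc_line <- grep("^ACCESSION", lines, value = TRUE)
  identifier <- if (length(acc_line)) {
    strsplit(trimws(sub("^ACCESSION", "", acc_line[1])), "\\s+")[[1]][1]
  } else {
    strsplit(trimws(sub("^LOCUS\\s+", "", locus)), "\\s+")[[1]][1]
  }

  feat_start <- grep("^FEATURES", lines)
  origin <- grep("^ORIGIN", lines)
  if (length(origin) == 0) {
    stop("malformed GenBank record ", identifier, ": no ORIGIN block")
  }

  # sequence
  seq_lines <- lines[(origin[1] + 1):length(lines)]
  seq_lines <- seq_lines[!grepl("^//", seq_lines)]
  sequence <- toupper(gsub("[^A-Za-z]", "", paste0(seq_lines, collapse = "")))

  feats <- list()
  if (length(feat_start)) {
    fl <- lines[(feat_start[1] + 1):(origin[1] - 1)]
    feats <- parse_feature_block(fl, identifier, warn = warn)
  }
  if (length(feats) == 0 && warn) {
    warning("record ", identifier, " has no gene features", call. = FALSE)
  }

  feats <- resolve_ambiguous_trna(feats)
  genome_record(identifier, sequence, feats, circular = circular)
}

parse_feature_block <- function(fl, identifier, warn = TRUE) {
  # group physical lines into one entry per feature key
  is_key <- grepl("^ {5}\\S", fl)
  idx <- cumsum(is_key)
  keep <- idx > 0
  entries <- split(fl[keep], idx[keep])

  feats <- list()
  seen <- character()   # track (key, location) to merge gene/CDS duplicates
  for (e in entries) {
    key <- sub("^ {5}(\\S+).*$", "\\1", e[1])
    rest <- paste0(trimws(sub("^ {5}\\S+\\s*", "", e[1])),
                   collapse = "")
    # continuation lines before the first qualifier extend the location
    quals_at <- grep("^\\s*/", e)
    loc_end <- if (length(quals_at)) quals_at[1] - 1 else length(e)
    if (loc_end >= 2) {
      rest <- paste0(rest, paste0(trimws(e[2:loc_end]), collapse = ""))
    }
    qual_lines <- if (length(quals_at)) e[quals_at[1]:length(e)] else character()
    quals <- parse_qualifiers(qual_lines)

    if (!key %in% c("CDS", "tRNA", "rRNA", "D-loop", "misc_feature",
                    "gene")) next
    if (key == "misc_feature" &&
        !grepl("control", tolower(paste(quals$note %||% "", quals$product %||% "")))) next

    loc <- tryCatch(parse_location(rest), error = function(e2) {
      stop("malformed record ", identifier, ": ", conditionMessage(e2))
    })

    label <- quals$gene %||% quals$product %||% quals$note %||%
      if (key == "D-loop") "D-loop" else "unknown"
    if (key == "D-loop") label <- "D-loop"

    ac <- NULL
    if (!is.null(quals$anticodon)) {
      # formats: (pos:..,aa:Ser,seq:gcu) or plain "gcu"
      m <- regmatches(quals$anticodon,
                      regexpr("seq:[A-Za-z]{3}", quals$anticodon))
      ac <- if (length(m)) toupper(sub("seq:", "", m)) else
        toupper(gsub("[^A-Za-z]", "", quals$anticodon))
      if (nchar(ac) != 3) ac <- NULL
      if (!is.null(ac)) ac <- chartr("U", "T", ac)
    }

    cn <- canonical_gene_name(label, anticodon = ac, warn = warn)
    kind <- switch(key, CDS = "PCG", tRNA = "tRNA", rRNA = "rRNA",
                   "D-loop" = "CR", misc_feature = "CR", gene = cn$kind)
    # "gene" keys duplicate CDS/tRNA/rRNA annotations; keep only typed keys,
    # but let a lone "gene" through if nothing typed covers that locus
    sig <- paste(cn$name, loc$intervals[[1]][1])
    if (key == "gene") {
      seen_gene <- attr(feats, "gene_only") %||% list()
      seen_gene[[sig]] <- list(cn = cn, loc = loc, quals = quals)
      attr(feats, "gene_only") <- seen_gene
      next
    }
    if (sig %in% seen) next
    seen <- c(seen, sig)

    offset <- if (kind == "PCG") {
      as.integer(quals$codon_start %||% "1") - 1L
    } else NA_integer_
    feats[[length(feats) + 1L]] <- feature(
      name = cn$name, kind = if (kind == "CR") "CR" else cn$kind,
      strand = loc$strand, intervals = loc$intervals,
      reading_offset = offset, anticodon = ac)
  }
  # lone "gene" keys with no typed feature covering the same locus become
  # features themselves (kind inferred from the canonical name)
  gene_only <- attr(feats, "gene_only") %||% list()
  attr(feats, "gene_only") <- NULL
  for (sig in names(gene_only)) {
    if (sig %in% seen) next
    e <- gene_only[[sig]]
    if (e$cn$kind == "other") next
    offset <- if (e$cn$kind == "PCG") {
      as.integer(e$quals$codon_start %||% "1") - 1L
    } else NA_integer_
    feats[[length(feats) + 1L]] <- feature(
      name = e$cn$name, kind = e$cn$kind, strand = e$loc$strand,
      intervals = e$loc$intervals, reading_offset = offset)
  }
  feats
}

parse_qualifiers <- function(lines) {
  if (!length(lines)) return(list())
  txt <- trimws(lines)
  # join continuation lines onto their qualifier
  starts <- grepl("^/", txt)
  idx <- cumsum(starts)
  joined <- vapply(split(txt, idx), paste, character(1), collapse = " ")
  out <- list()
  for (q in joined) {
    if (grepl("=", q, fixed = TRUE)) {
      k <- sub("^/([^=]+)=.*$", "\\1", q)
      v <- sub("^/[^=]+=", "", q)
      v <- gsub("^\"|\"$", "", v)
      out[[k]] <- v
    } else {
      out[[sub("^/", "", q)]] <- TRUE
    }
  }
  out
}

# trnL/trnS left ambiguous by label: disambiguate from genomic context.
# trnL adjacent to rrnL is trnL(uur); trnL near trnS(agy)/trnH is trnL(cun);
# trnS between cox1 and trnD is trnS(ucn); trnS near trnH is trnS(agy).
resolve_ambiguous_trna <- function(feats) {
  if (!length(feats)) return(feats)
  starts <- vapply(feats, function(f) f$intervals[[1]][1], integer(1))
  ord <- order(starts)
  names_ord <- vapply(feats[ord], function(f) f$name, character(1))
  for (i in seq_along(ord)) {
    f <- feats[[ord[i]]]
    if (!f$name %in% c("trnL", "trnS")) next
    nb <- names_ord[setdiff(seq(i - 2, i + 2), i)]
    nb <- nb[!is.na(nb)]
    new <- if (f$name == "trnL") {
      if ("rrnL" %in% nb) "trnL(uur)" else "trnL(cun)"
    } else {
      if ("cox1" %in% nb || "trnD" %in% nb) "trnS(ucn)" else "trnS(agy)"
    }
    feats[[ord[i]]]$name <- new
    names_ord[i] <- new
  }
  feats
}

# ---- writer --------------------------------------------------------------

#' Write genome records to a GenBank flat file
#'
#' Writes the subset of the format that [read_genbank()] parses, so that a
#' write/read round trip is the identity on sequence and features. Used
#' mainly to serialise synthetic genomes.
#'
#' @param recs a [genome_record()] or list of them
#' @param path output file
#' @export
write_genbank <- function(recs, path) {
  if (inherits(recs, "mito_genome")) recs <- list(recs)
  con <- file(path, "w")
  on.exit(close(con))
  for (rec in recs) {
    writeLines(format_genbank_record(rec), con)
  }
  invisible(path)
}

format_genbank_record <- function(rec) {
  n <- nchar(rec$sequence)
  out <- c(
    sprintf("LOCUS       %-16s %6d bp    DNA     %-8s VRT",
            rec$identifier, n, if (rec$circular) "circular" else "linear"),
    sprintf("DEFINITION  %s mitochondrion.", rec$identifier),
    sprintf("ACCESSION   %s", rec$identifier),
    "FEATURES             Location/Qualifiers",
    sprintf("     source          1..%d", n)
  )
  for (f in rec$features) {
    key <- switch(f$kind, PCG = "CDS", tRNA = "tRNA", rRNA = "rRNA",
                  CR = "D-loop", other = "misc_feature")
    ivs <- vapply(f$intervals,
                  function(iv) sprintf("%d..%d", iv[1] + 1L, iv[2]),
                  character(1))
    if (f$strand == "N") ivs <- rev(ivs)   # genome order inside complement()
    loc <- if (length(ivs) > 1) {
      sprintf("join(%s)", paste(ivs, collapse = ","))
    } else ivs
    if (f$strand == "N") loc <- sprintf("complement(%s)", loc)
    out <- c(out, sprintf("     %-15s %s", key, loc))
    if (f$kind != "CR") {
      out <- c(out, sprintf("                     /gene=\"%s\"", f$name))
    }
    if (f$kind == "PCG") {
      out <- c(out, sprintf("                     /codon_start=%d",
                            f$reading_offset + 1L))
    }
    if (f$kind == "tRNA" && !is.null(f$anticodon)) {
      out <- c(out, sprintf(
        "                     /anticodon=\"(pos:complement,aa:Xxx,seq:%s)\"",
        tolower(f$anticodon)))
    }
  }
  out <- c(out, "ORIGIN")
  s <- tolower(rec$sequence)
  pos <- seq(1, n, by = 60)
  for (p in pos) {
    chunk <- substr(s, p, min(p + 59, n))
    groups <- substring(chunk, seq(1, nchar(chunk), 10),
                        pmin(seq(10, nchar(chunk) + 9, 10), nchar(chunk)))
    out <- c(out, sprintf("%9d %s", p, paste(groups, collapse = " ")))
  }
  c(out, "//")
}
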