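# Independent brute-force oracles used by the property tests. These are
# deliberately naive re-implementations that share no code with the
# package internals they check.

# --- exhaustive tandem-repeat oracle (pure repeats only) ------------------
# Enumerate every (unit, start, end) with exact period `u`, maximal in both
# directions, meeting copy/length thresholds; then collapse any interval
# contained in (or equal to) a kept interval that has a smaller unit.
oracle_tandem_repeats <- function(s, min_unit = 1, max_unit = nchar(s) %/% 2,
                                  min_copies = 2, min_length = 0) {
  v <- strsplit(s, "")[[1]]
  L <- length(v)
  found <- list()
  for (u in min_unit:max_unit) {
    for (st in 1:(L - 2 * u + 1)) {
      # extend the periodic stretch starting at st as far as possible
      en <- st + u - 1
      while (en + 1 <= L && v[en + 1] == v[en + 1 - u]) en <- en + 1
      len <- en - st + 1
      # maximal to the left?
      left_ext <- st > 1 && (st - 1 + u) <= L && v[st - 1] == v[st - 1 + u]
      if (left_ext) next
      if (len < u * min_copies || len < min_length) next
      key <- paste(u, st, en)
      found[[key]] <- data.frame(unit = paste(v[st:(st + u - 1)],
                                              collapse = ""),
                                 unit_length = u, copies = len / u,
                                 start = st - 1L, end = en, purity = 1,
                                 stringsAsFactors = FALSE)
    }
  }
  if (!length(found)) {
    return(data.frame(unit = character(), unit_length = integer(),
                      copies = numeric(), start = integer(),
                      end = integer(), purity = numeric()))
  }
  tab <- unique(do.call(rbind, found))
  keep <- rep(TRUE, nrow(tab))
  for (i in seq_len(nrow(tab))) {
    for (j in seq_len(nrow(tab))) {
      if (i == j || !keep[i]) next
      contained <- tab$start[j] >= tab$start[i] && tab$end[j] <= tab$end[i]
      same <- tab$start[j] == tab$start[i] && tab$end[j] == tab$end[i] &&
        tab$unit_length[j] == tab$unit_length[i]
      if (contained && tab$unit_length[j] >= tab$unit_length[i] && !same) {
        keep[j] <- FALSE
      }
    }
  }
  tab <- tab[keep, , drop = FALSE]
  tab <- tab[order(tab$unit_length, tab$start), , drop = FALSE]
  rownames(tab) <- NULL
  tab
}

# --- exhaustive cloverleaf score oracle -----------------------------------
# Naive re-enumeration of the fold template with explicit loops; returns
# the best achievable score (not the fold).
oracle_best_cloverleaf_score <- function(seq) {
  v <- strsplit(chartr("Tt", "Uu", toupper(seq)), "")[[1]]
  L <- length(v)
  sc1 <- function(a, b) {
    if ((a == "A" && b == "U") || (a == "U" && b == "A") ||
        (a == "G" && b == "C") || (a == "C" && b == "G")) return(2)
    if ((a == "G" && b == "U") || (a == "U" && b == "G")) return(1)
    -1
  }
  stem <- function(i5, j3, len) {
    s <- 0
    for (k in 0:(len - 1)) s <- s + sc1(v[i5 + k], v[j3 - k])
    s
  }
  best <- -Inf
  for (disc in 0:3) {
    j_acc <- L - disc
    for (s1 in 0:2) for (pd in 0:4) {
      dls <- if (pd == 0) 3:12 else 4:11
      for (dl in dls) for (s2 in 0:1) for (al in 7:9) {
        for (pt in 4:5) for (tl in 5:9) {
          d5 <- 7 + s1 + 1
          a5 <- d5 + 2 * pd + dl + s2
          v_start <- a5 + 10 + al
          t_end <- j_acc - 7
          t5 <- t_end - (2 * pt + tl) + 1
          vl <- t5 - v_start
          if (vl < 3 || vl > 23) next
          s <- stem(1, j_acc, 7) + stem(a5, a5 + 10 + al - 1, 5) +
            stem(t5, t_end, pt)
          if (pd > 0) s <- s + stem(d5, d5 + 2 * pd + dl - 1, pd)
          if (s > best) best <- s
        }
      }
    }
  }
  best
}

# --- adjacency-set breakpoint oracle (strand-aware, circular) -------------
oracle_breakpoints <- function(a, b) {
  adj <- function(go) {
    n <- nrow(go)
    out <- character(0)
    for (i in seq_len(n)) {
      j <- if (i == n) 1 else i + 1
      x <- paste0(ifelse(go$strand[i] == "N", "-", "+"), go$name[i])
      y <- paste0(ifelse(go$strand[j] == "N", "-", "+"), go$name[j])
      neg <- function(t) {
        if (startsWith(t, "-")) sub("^-", "+", t) else sub("^\\+", "-", t)
      }
      fwd <- paste(x, y); rev <- paste(neg(y), neg(x))
      out <- c(out, min(fwd, rev))
    }
    out
  }
  length(setdiff(adj(a), adj(b)))
}

# tiny helper: gene_order object from name/strand vectors
toy_order <- function(names, strands = rep("J", length(names))) {
  out <- data.frame(name = names, strand = strands,
                    stringsAsFactors = FALSE)
  class(out) <- c("gene_order", "data.frame")
  out
}

# tiny annotated record: features laid end-to-end on a given sequence
toy_record <- function(sequence, specs, circular = TRUE,
                       identifier = "TOY") {
  feats <- lapply(specs, function(s) do.call(feature, s))
  genome_record(identifier, sequence, feats, circular = circular)
}
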