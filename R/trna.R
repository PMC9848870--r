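# Template-based tRNA cloverleaf folding.
#
# Mitochondrial tRNAs (66-75 nt in passerines) are folded by exhaustive
# search over cloverleaf arm-length combinations rather than by an energy
# model: acceptor stem fixed at 7 pairs, D-stem 0-4 pairs (0 = DHU arm
# replaced by a loop, as in metazoan mitochondrial trnS(agy)), anticodon
# stem 5 pairs, T-stem 4-5 pairs, with bounded loop and spacer windows.
# Each candidate is scored +2 per Watson-Crick pair, +1 per G-U wobble
# pair, -1 per mismatched pair; mismatches are permitted (at the penalty)
# because real mitochondrial tRNAs carry them (C-C, A-A, U-U pairs are
# routinely reported). The best-scoring fold is returned; ties prefer a
# larger D-stem, then arm lengths closest to the canonical 7/4/5/5.

# pair score lookup over RNA bases
.pair_score <- local({
  b <- c("A", "C", "G", "U")
  m <- matrix(-1, 4, 4, dimnames = list(b, b))
  m["A", "U"] <- m["U", "A"] <- 2
  m["G", "C"] <- m["C", "G"] <- 2
  m["G", "U"] <- m["U", "G"] <- 1
  m
})

#' Fold a tRNA sequence onto the cloverleaf template
#'
#' @param seq tRNA sequence, DNA or RNA alphabet (T mapped to U), in gene
#'   orientation
#' @param anticodon optional anticodon 3-mer; when given, only folds whose
#'   anticodon-loop centre matches it are considered
#' @param min_score minimum acceptable score; below it an error
#'   "no cloverleaf" is thrown
#' @return object of class "cloverleaf": list with arms (named list of
#'   stem pair index matrices and loop intervals), pairs (data.frame arm,
#'   pos5, pos3, base5, base3, score), mismatches (subset with score < 0),
#'   dhu_present (D-stem >= 2 pairs), score, dotbracket, length
#' @export
fold_cloverleaf <- function(seq, anticodon = NULL, min_score = 15) {
  rna <- chartr("Tt", "Uu", toupper(seq))
  v <- s2c(rna)
  L <- length(v)
  if (L < 55 || L > 100) {
    stop("sequence length ", L, " outside plausible tRNA range (55-100)")
  }
  if (!all(v %in% c("A", "C", "G", "U"))) {
    stop("sequence contains non-ACGU characters")
  }
  if (!is.null(anticodon)) {
    anticodon <- chartr("T", "U", toupper(anticodon))
    stopifnot(nchar(anticodon) == 3)
  }

  S <- outer(seq_len(L), seq_len(L),
             function(i, j) .pair_score[cbind(v[i], v[j])])

  stem_score <- function(i5, j3, len) {
    # pairs (i5+k, j3-k), k = 0..len-1; i5/j3 1-based 5' start and 3' end
    idx <- cbind(i5 + 0:(len - 1), j3 - 0:(len - 1))
    sum(S[idx])
  }

  best <- NULL
  # enumeration windows (nt): spacer1 0-2 between acceptor and D arm,
  # D-loop 4-11 (or 3-12 replacement loop when D-stem absent), spacer2 0-1,
  # anticodon loop 7-9, variable loop 3-23 (implied), T-loop 5-9,
  # 0-3 trailing discriminator nt
  acc <- 7L
  for (disc in 0:3) {
    j_acc <- L - disc            # 3' end of acceptor stem
    if (j_acc - acc + 1 <= acc) next
    for (s1 in 0:2) {
      d5 <- acc + s1 + 1L        # D-arm start
      for (pd in c(4:1, 0)) {
        dloops <- if (pd == 0) 3:12 else 4:11
        for (dl in dloops) {
          ac5 <- d5 + 2L * pd + dl   # start of spacer2 region
          for (s2 in 0:1) {
            a5 <- ac5 + s2          # anticodon stem 5' start
            for (al in 7:9) {
              for (pt in 5:4) {
                for (tl in 5:9) {
                  # T-arm sits immediately 5' of acceptor 3' side
                  t_end <- j_acc - acc      # last nt before acceptor 3' side
                  t5 <- t_end - (2L * pt + tl) + 1L
                  v_start <- a5 + 2L * 5L + al   # after anticodon arm
                  vl <- t5 - v_start
                  if (vl < 3 || vl > 23) next
                  # score
                  sc <- stem_score(1L, j_acc, acc) +
                    (if (pd > 0) stem_score(d5, d5 + 2L * pd + dl - 1L, pd)
                     else 0) +
                    stem_score(a5, a5 + 10L + al - 1L, 5L) +
                    stem_score(t5, t_end, pt)
                  if (!is.null(anticodon)) {
                    loop_start <- a5 + 5L
                    ac_pos <- loop_start + (al - 3L) %/% 2L
                    if (c2s(v[ac_pos:(ac_pos + 2L)]) != anticodon) next
                  }
                  cand <- list(score = sc, disc = disc, s1 = s1, pd = pd,
                               dl = dl, s2 = s2, al = al, pt = pt, tl = tl,
                               d5 = d5, a5 = a5, t5 = t5, j_acc = j_acc,
                               vl = vl)
                  if (is.null(best) || better_fold(cand, best)) best <- cand
                }
              }
            }
          }
        }
      }
    }
  }
  if (is.null(best) || best$score < min_score) {
    stop("no cloverleaf: best score ",
         if (is.null(best)) "-Inf" else best$score,
         " below threshold ", min_score)
  }
  build_fold(v, best)
}

# tie-break: higher score; then larger D-stem; then closer to canonical
# arm lengths (D-loop 8, anticodon loop 7, T-stem 5, T-loop 7), then fewer
# trailing nt
better_fold <- function(a, b) {
  if (a$score != b$score) return(a$score > b$score)
  if (a$pd != b$pd) return(a$pd > b$pd)
  da <- abs(a$dl - 8) + abs(a$al - 7) + abs(5 - a$pt) + abs(a$tl - 7)
  db <- abs(b$dl - 8) + abs(b$al - 7) + abs(5 - b$pt) + abs(b$tl - 7)
  if (da != db) return(da < db)
  a$disc < b$disc
}

build_fold <- function(v, f) {
  L <- length(v)
  pairs <- list()
  add_arm <- function(arm, i5, j3, len) {
    if (len == 0) return()
    idx <- cbind(i5 + 0:(len - 1), j3 - 0:(len - 1))
    pairs[[length(pairs) + 1L]] <<- data.frame(
      arm = arm, pos5 = idx[, 1] - 1L, pos3 = idx[, 2] - 1L,
      base5 = v[idx[, 1]], base3 = v[idx[, 2]],
      score = .pair_score[cbind(v[idx[, 1]], v[idx[, 2]])],
      stringsAsFactors = FALSE)
  }
  add_arm("acceptor", 1L, f$j_acc, 7L)
  if (f$pd > 0) add_arm("D", f$d5, f$d5 + 2L * f$pd + f$dl - 1L, f$pd)
  add_arm("anticodon", f$a5, f$a5 + 10L + f$al - 1L, 5L)
  add_arm("T", f$t5, f$t5 + 2L * f$pt + f$tl - 1L, f$pt)
  ptab <- do.call(rbind, pairs)

  loop_start <- f$a5 + 5L
  ac_pos <- loop_start + (f$al - 3L) %/% 2L

  db <- rep(".", L)
  db[ptab$pos5 + 1L] <- "("
  db[ptab$pos3 + 1L] <- ")"

  structure(list(
    length = L,
    score = f$score,
    arms = list(
      acceptor = c(pairs = 7L),
      D = c(pairs = f$pd, loop = f$dl),
      anticodon = c(pairs = 5L, loop = f$al),
      T = c(pairs = f$pt, loop = f$tl),
      variable = c(length = f$vl)),
    anticodon = c2s(v[ac_pos:(ac_pos + 2L)]),
    anticodon_at = ac_pos - 1L,
    pairs = ptab,
    mismatches = ptab[ptab$score < 0, , drop = FALSE],
    dhu_present = f$pd >= 2,
    dotbracket = c2s(db),
    sequence = c2s(v)
  ), class = "cloverleaf")
}

#' @export
print.cloverleaf <- function(x, ...) {
  cat("<cloverleaf> ", x$length, " nt, score ", x$score,
      ", D-arm ", if (x$dhu_present) "present" else "absent",
      ", ", nrow(x$mismatches), " mismatched pair(s)\n", sep = "")
  cat(" ", x$sequence, "\n ", x$dotbracket, "\n", sep = "")
  invisible(x)
}

#' Fold every tRNA of one or more records
#'
#' @param records a [genome_record()] or list of them
#' @param min_score passed to [fold_cloverleaf()]
#' @return data.frame: record, gene, length, score, dhu_present,
#'   n_mismatches, dotbracket (NA row with a warning when a tRNA cannot be
#'   folded)
#' @export
fold_record_trnas <- function(records, min_score = 15) {
  if (inherits(records, "mito_genome")) records <- list(records)
  rows <- list()
  for (rec in records) {
    for (f in Filter(function(f) f$kind == "tRNA", rec$features)) {
      s <- extract_feature_sequence(rec, f)
      fold <- tryCatch(
        fold_cloverleaf(s, anticodon = f$anticodon, min_score = min_score),
        error = function(e) e)
      if (inherits(fold, "error")) {
        warning(rec$identifier, " ", f$name, ": ",
                conditionMessage(fold), call. = FALSE)
        rows[[length(rows) + 1L]] <- data.frame(
          record = rec$identifier, gene = f$name, length = nchar(s),
          score = NA_integer_, dhu_present = NA, n_mismatches = NA_integer_,
          dotbracket = NA_character_, stringsAsFactors = FALSE)
      } else {
        rows[[length(rows) + 1L]] <- data.frame(
          record = rec$identifier, gene = f$name, length = fold$length,
          score = fold$score, dhu_present = fold$dhu_present,
          n_mismatches = nrow(fold$mismatches),
          dotbracket = fold$dotbracket, stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}
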