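# Canonical gene vocabulary and annotation-label normalisation.
#
# The controlled vocabulary follows the naming used throughout the avian
# mitogenomics literature: 13 protein-coding genes (nad1..nad6, nad4l,
# cox1..cox3, cob, atp6, atp8), 22 tRNAs (trnX, with the leucine and serine
# isoacceptors disambiguated as trnL(uur)/trnL(cun) and trnS(ucn)/trnS(agy)),
# two rRNAs (rrnS, rrnL) and the control region (CR).

#' Canonical mitochondrial gene tokens
#'
#' @return character vector of the 37 gene tokens plus "CR"
#' @export
canonical_tokens <- function() {
  c(pcg_tokens(), trna_tokens(), "rrnS", "rrnL", "CR")
}

#' @rdname canonical_tokens
#' @export
pcg_tokens <- function() {
  c("nad1", "nad2", "nad3", "nad4", "nad4l", "nad5", "nad6",
    "cox1", "cox2", "cox3", "cob", "atp6", "atp8")
}

#' @rdname canonical_tokens
#' @export
trna_tokens <- function() {
  c("trnF", "trnV", "trnL(uur)", "trnI", "trnQ", "trnM", "trnW", "trnA",
    "trnN", "trnC", "trnY", "trnS(ucn)", "trnD", "trnK", "trnG", "trnR",
    "trnH", "trnS(agy)", "trnL(cun)", "trnT", "trnP", "trnE")
}

#' Canonical passerine mitochondrial gene order
#'
#' The arrangement shared by most Passeriformes: the conventional vertebrate
#' order with the cob-trnT-trnP-nad6-trnE-CR-trnF-rrnS segment around the
#' control region. Returned anchored at trnF.
#'
#' @return data.frame with columns `name` and `strand` ("J" major /
#'   "N" minor), one row per gene/CR in genome order
#' @export
passerine_gene_order <- function() {
  name <- c("trnF", "rrnS", "trnV", "rrnL", "trnL(uur)", "nad1", "trnI",
            "trnQ", "trnM", "nad2", "trnW", "trnA", "trnN", "trnC", "trnY",
            "cox1", "trnS(ucn)", "trnD", "cox2", "trnK", "atp8", "atp6",
            "cox3", "trnG", "nad3", "trnR", "nad4l", "nad4", "trnH",
            "trnS(agy)", "trnL(cun)", "nad5", "cob", "trnT", "trnP",
            "nad6", "trnE", "CR")
  n_strand <- c("trnQ", "trnA", "trnN", "trnC", "trnY", "trnS(ucn)",
                "trnP", "nad6", "trnE")
  data.frame(name = name,
             strand = ifelse(name %in% n_strand, "N", "J"),
             stringsAsFactors = FALSE)
}

# anticodon -> serine/leucine isoacceptor
.anticodon_isoacceptor <- c(
  "TAA" = "trnL(uur)", "UAA" = "trnL(uur)",
  "TAG" = "trnL(cun)", "UAG" = "trnL(cun)",
  "TGA" = "trnS(ucn)", "UGA" = "trnS(ucn)",
  "GCT" = "trnS(agy)", "GCU" = "trnS(agy)"
)

.aa3_to_trna <- c(
  Phe = "trnF", Val = "trnV", Ile = "trnI", Gln = "trnQ", Met = "trnM",
  Trp = "trnW", Ala = "trnA", Asn = "trnN", Cys = "trnC", Tyr = "trnY",
  Asp = "trnD", Lys = "trnK", Gly = "trnG", Arg = "trnR", His = "trnH",
  Thr = "trnT", Pro = "trnP", Glu = "trnE"
)

#' Canonicalize a raw annotation label
#'
#' Maps the labels found in GenBank records ("ND2", "COIII", "CYTB",
#' "12S ribosomal RNA", "tRNA-Leu", "D-loop", ...) onto the canonical
#' vocabulary. Leucine/serine tRNAs are disambiguated by anticodon when one
#' is given; otherwise they are returned as the bare ambiguous token
#' ("trnL"/"trnS") for later contextual disambiguation. Unknown labels map
#' to "other" with a warning.
#'
#' @param label raw gene/product label
#' @param anticodon optional anticodon 3-mer
#' @param warn warn on unknown labels
#' @return list with `name` (canonical token or "other") and `kind`
#'   (one of "PCG", "tRNA", "rRNA", "CR", "other")
#' @export
canonical_gene_name <- function(label, anticodon = NULL, warn = TRUE) {
  raw <- label
  x <- toupper(trimws(label))
  x <- gsub("[ _]+", " ", x)

  ans <- function(name, kind) list(name = name, kind = kind)

  # control region
  if (grepl("D-?LOOP|CONTROL REGION|^CR$", x)) return(ans("CR", "CR"))

  # rRNAs
  if (grepl("12S|RRNS|SMALL SUBUNIT RIBOSOMAL|S-RRNA", x)) {
    return(ans("rrnS", "rRNA"))
  }
  if (grepl("16S|RRNL|LARGE SUBUNIT RIBOSOMAL|L-RRNA", x)) {
    return(ans("rrnL", "rRNA"))
  }

  # PCGs: normalise the usual synonym zoo
  pcg_syn <- c(
    "^ND ?1$" = "nad1", "^ND ?2$" = "nad2", "^ND ?3$" = "nad3",
    "^ND ?4$" = "nad4", "^ND ?4L$" = "nad4l", "^ND ?5$" = "nad5",
    "^ND ?6$" = "nad6",
    "^NAD1$" = "nad1", "^NAD2$" = "nad2", "^NAD3$" = "nad3",
    "^NAD4$" = "nad4", "^NAD4L$" = "nad4l", "^NAD5$" = "nad5",
    "^NAD6$" = "nad6",
    "NADH DEHYDROGENASE SUBUNIT 1" = "nad1",
    "NADH DEHYDROGENASE SUBUNIT 2" = "nad2",
    "NADH DEHYDROGENASE SUBUNIT 3" = "nad3",
    "NADH DEHYDROGENASE SUBUNIT 4L" = "nad4l",
    "NADH DEHYDROGENASE SUBUNIT 4" = "nad4",
    "NADH DEHYDROGENASE SUBUNIT 5" = "nad5",
    "NADH DEHYDROGENASE SUBUNIT 6" = "nad6",
    "^CO ?(X ?)?1$|^COI$" = "cox1", "^CO ?(X ?)?2$|^COII$" = "cox2",
    "^CO ?(X ?)?3$|^COIII$" = "cox3",
    "CYTOCHROME C OXIDASE SUBUNIT III$" = "cox3",
    "CYTOCHROME C OXIDASE SUBUNIT II$" = "cox2",
    "CYTOCHROME C OXIDASE SUBUNIT I$" = "cox1",
    "CYTOCHROME C OXIDASE SUBUNIT 1" = "cox1",
    "CYTOCHROME C OXIDASE SUBUNIT 2" = "cox2",
    "CYTOCHROME C OXIDASE SUBUNIT 3" = "cox3",
    "^CYT ?B$|^COB$|CYTOCHROME B" = "cob",
    "^ATP ?6$|ATP SYNTHASE F0 SUBUNIT 6|ATPASE ?6" = "atp6",
    "^ATP ?8$|ATP SYNTHASE F0 SUBUNIT 8|ATPASE ?8" = "atp8"
  )
  for (pat in names(pcg_syn)) {
    if (grepl(pat, x)) return(ans(pcg_syn[[pat]], "PCG"))
  }

  # tRNAs: canonical form already?
  low <- sub("^TRN", "trn", x)
  if (tolower(raw) %in% tolower(trna_tokens())) {
    tok <- trna_tokens()[match(tolower(raw), tolower(trna_tokens()))]
    return(ans(tok, "tRNA"))
  }
  if (grepl("^TRNA[- ]|^TRN.", x)) {
    ac <- if (!is.null(anticodon)) toupper(anticodon) else NULL
    # three-letter amino-acid form: tRNA-Leu, tRNA-Ser(GCU), ...
    aa <- sub("^TRNA[- ]([A-Z]{3}).*$", "\\1", x)
    aa <- paste0(substr(aa, 1, 1), tolower(substr(aa, 2, 3)))
    paren <- if (grepl("\\(([A-Z]{3})\\)", x)) {
      sub("^.*\\(([A-Z]{3})\\).*$", "\\1", x)
    } else NULL
    ac <- ac %||% paren
    if (aa %in% c("Leu", "Ser")) {
      if (!is.null(ac) && ac %in% names(.anticodon_isoacceptor)) {
        return(ans(unname(.anticodon_isoacceptor[ac]), "tRNA"))
      }
      # codon-family parenthetical e.g. tRNA-Leu(CUN)
      fam <- toupper(sub("^.*\\((UUR|CUN|UCN|AGY)\\).*$", "\\1", x))
      if (fam %in% c("UUR", "CUN", "UCN", "AGY")) {
        tok <- c(UUR = "trnL(uur)", CUN = "trnL(cun)",
                 UCN = "trnS(ucn)", AGY = "trnS(agy)")[[fam]]
        return(ans(tok, "tRNA"))
      }
      # ambiguous; resolve later from genomic context
      return(ans(if (aa == "Leu") "trnL" else "trnS", "tRNA"))
    }
    if (aa %in% names(.aa3_to_trna)) {
      return(ans(unname(.aa3_to_trna[aa]), "tRNA"))
    }
    # single-letter form trnX
    if (grepl("^TRN[A-Z]$", x)) {
      tok <- paste0("trn", substr(x, 4, 4))
      if (tok %in% trna_tokens()) return(ans(tok, "tRNA"))
      if (tok %in% c("trnL", "trnS")) return(ans(tok, "tRNA"))
    }
  }

  if (warn) warning("unknown gene label: ", raw, call. = FALSE)
  ans("other", "other")
}
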