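# Shared loader for the analysis stages: reads the study records written
# by 01_simulate.R back from results/data/. Sourced, not run directly.

suppressPackageStartupMessages(library(mitocomp))

load_study <- function(datadir = "results/data") {
  gb <- list.files(datadir, pattern = "\\.gb$", full.names = TRUE)
  if (!length(gb)) stop("no GenBank records in ", datadir,
                        "; run analysis/01_simulate.R first")
  recs <- lapply(gb, function(p) read_genbank(p)[[1]])
  names(recs) <- sub("\\.gb$", "", basename(gb))
  list(root = recs[["root"]],
       records = recs[names(recs) != "root"],
       truth = jsonlite::read_json(file.path(datadir, "truth.json"),
                                   simplifyVector = TRUE))
}
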