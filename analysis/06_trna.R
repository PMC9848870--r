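#!/usr/bin/env Rscript
# Stage 6: tRNA secondary structure. Folds all 22 tRNAs of every record
# into cloverleaves. Writes results/trna/trna.tsv.

source("analysis/00_common.R")
st <- load_study()
tab <- report_trna(st$records, "results/trna")
cat(sum(!is.na(tab$score)), "of", nrow(tab), "tRNAs folded;",
    sum(!tab$dhu_present, na.rm = TRUE), "without a DHU arm\n")
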