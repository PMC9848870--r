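#!/usr/bin/env Rscript
# Stage 3: codon usage. Writes results/codon_usage/rscu.tsv (per-record
# RSCU long table) and start_stop.tsv (start/stop codon matrix).

source("analysis/00_common.R")
st <- load_study()
long <- report_rscu(st$records, "results/codon_usage")
one <- long[long$record == long$record[1], ]
top <- one[order(-one$rscu), ][1:3, ]
cat("top RSCU codons in", one$record[1], ":",
    paste(sprintf("%s (%s, %.2f)", top$codon, top$aa, top$rscu),
          collapse = ", "), "\n")
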