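#!/usr/bin/env Rscript
# Stage 4: gene order vs the canonical passerine arrangement, plus
# intergenic spacers and overlaps. Writes results/gene_order/ and
# results/spacers/.

source("analysis/00_common.R")
st <- load_study()
go <- report_gene_order(st$records, "results/gene_order")
report_spacers(st$records, "results/spacers")
cat("breakpoint distances to the canonical order:",
    paste(go$breakpoints, collapse = " "), "\n")
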