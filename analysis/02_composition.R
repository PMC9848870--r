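#!/usr/bin/env Rscript
# Stage 2: nucleotide composition and skews per partition (whole genome,
# PCGs by codon position, tRNAs, rRNAs, control region).
# Writes results/composition/composition.tsv.

source("analysis/00_common.R")
st <- load_study()
tab <- report_composition(st$records, "results/composition")
gm <- tab[tab$partition == "genome" & tab$record == "mean", ]
cat(sprintf("genome mean: %.1f%% A+T, AT-skew %.3f, GC-skew %.3f\n",
            gm$pct_at, gm$at_skew, gm$gc_skew))
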