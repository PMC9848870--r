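#!/usr/bin/env Rscript
# Stage 1: generate the synthetic wagtail-like study set and write the
# raw data products under results/data/: one annotated GenBank record per
# taxon, a whole-genome FASTA, the guide tree, and the generator's truth
# sidecar (planted motifs, boundaries, tRNA plan) used by later stages.
#
# Usage: Rscript analysis/01_simulate.R [--seed <int>]

suppressPackageStartupMessages(library(mitocomp))

args <- commandArgs(trailingOnly = TRUE)
seed <- 42L
if (length(args) >= 2 && args[1] == "--seed") seed <- as.integer(args[2])

outdir <- "results/data"
dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

st <- generate_study_set(genome_spec(seed = seed))

write_genbank(st$root, file.path(outdir, "root.gb"))
for (nm in names(st$records)) {
  write_genbank(st$records[[nm]], file.path(outdir, paste0(nm, ".gb")))
}
write_fasta(vapply(st$records, function(r) r$sequence, character(1)),
            file.path(outdir, "genomes.fasta"))
writeLines(st$truth$tree, file.path(outdir, "guide_tree.nwk"))
write_truth_sidecar(st$truth, file.path(outdir, "truth.json"))

cat("wrote", length(st$records), "records (+ root) to", outdir,
    "with seed", seed, "\n")
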