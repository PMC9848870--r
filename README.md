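# mitocomp

Comparative analysis of annotated animal mitogenomes, with a focus on
passerine birds.

Animal mitochondrial genomes are compact (~16–17 kb), circular, and
almost always carry the same 37 genes (13 protein-coding genes, 22
tRNAs, 2 rRNAs) plus a non-coding control region. Because the gene
content is fixed, comparative mitogenomics revolves around a standard
battery of descriptive statistics: strand-asymmetric base composition
(AT/GC skew) by partition and codon position, relative synonymous codon
usage (RSCU) under the vertebrate mitochondrial code, gene order and
rearrangement distance, intergenic spacers and overlaps, control-region
domain structure with conserved boxes and tandem repeats, tRNA
cloverleaf integrity, and distance-based phylogenetics on concatenated
protein-coding genes. `mitocomp` implements that battery end to end on
GenBank/FASTA input, with a deterministic synthetic-genome generator
(with ground-truth sidecars) so that every stage is demonstrable and
testable fully offline.

See `vignettes/mitocomp-methods.Rmd` for the models, conventions
(0-based half-open coordinates, skew definitions, incomplete stops,
breakpoint distance), and the rationale behind every default parameter.

## Worked example

```r
library(mitocomp)

# A 7-taxon wagtail-like study set: one root genome with the canonical
# passerine architecture, evolved along a fixed guide tree.
st <- generate_study_set(genome_spec(seed = 42))

# Composition: genome-wide means across the 7 records
tab <- partition_summary(st$records, standard_partitions()$genome)
tab[tab$record == "mean", c("pct_at", "at_skew", "gc_skew")]
#>   pct_at at_skew gc_skew
#>     53.6   0.082  -0.197      # A+T-rich, positive AT-skew, negative GC-skew

# Codon usage: CUA (Leu) leads, as planted by the generator
r <- rscu(codon_count_table(st$records[[1]]))
head(r[order(-r$rscu), c("aa", "codon", "rscu")], 3)
#>   aa codon rscu
#>    L   CUA 2.23
#>    R   CGA 2.11
#>    S   UCC 2.10

# Gene order: identical to the canonical passerine arrangement
compare_orders(extract_gene_order(st$root), reference_gene_order())
#> $breakpoints 0   $identical TRUE

# Spacers: the diagnostic 23 bp trnP-nad6 spacer and 10 bp atp8-atp6 overlap
s <- spacer_summary(st$root)
c(s$max, s$longest$upstream, s$longest$downstream)
#> "23" "trnP" "nad6"

# Control region: all 8 implanted conserved boxes recovered exactly
crf <- Filter(function(f) f$kind == "CR", st$root$features)[[1]]
cr <- extract_feature_sequence(st$root, crf)
sum(scan_cr_boxes(cr)$mismatches == 0)
#> 8

# tRNAs: all 22 x 7 fold into cloverleaves; one DHU-less serine per record
f <- fold_record_trnas(st$records)
c(folded = sum(!is.na(f$score)), dhu_less = sum(!f$dhu_present))
#> folded 154   dhu_less 7

# Phylogeny: NJ on the 13-PCG K2P supermatrix recovers the guide tree
aln <- lapply(setNames(nm = pcg_tokens()), function(g) {
  ft <- Filter(function(x) x$name == g, st$root$features)[[1]]
  vapply(st$records, function(r) extract_feature_sequence(r, ft), character(1))
})
tr <- neighbor_joining(distance_matrix(concatenate(aln), "K2P"))
rf_distance(tr, default_study_tree())
#> 0
```

Real data goes through the same functions: `read_genbank()` +
`canonical_gene_name()` normalise any conventionally annotated
mitogenome record to the package's vocabulary.

## Analysis pipeline

The numbered scripts under `analysis/` are thin drivers that run the
whole pipeline and write tables under `results/`:

```sh
Rscript analysis/01_simulate.R --seed 42   # data: GenBank, FASTA, truth sidecar
Rscript analysis/02_composition.R          # results/composition/composition.tsv
Rscript analysis/03_codon_usage.R          # rscu.tsv, start_stop.tsv
Rscript analysis/04_gene_order_spacers.R   # gene_order.tsv, spacers.tsv
Rscript analysis/05_control_region.R       # cr_boxes.tsv, cr_repeats.tsv, cr_variability.tsv
Rscript analysis/06_trna.R                 # trna.tsv
Rscript analysis/07_phylogeny.R            # supermatrix.{phy,nex}, distances.tsv, nj.nwk
```

## Tests

```r
testthat::test_dir("tests/testthat", package = "mitocomp",
                   load_package = "installed")
```

The suite pairs every non-trivial algorithm with an independent naive
oracle (tandem repeats, cloverleaf folding, breakpoint distance, NJ via
brute-force least-squares over all topologies) plus hand-computed small
cases. One acceptance block validates the GenBank pipeline against real
wagtail records; it requires the flat files to be downloaded beforehand
into `inst/extdata/genbank-cache/<accession>.gb` and fails with
instructions when they are absent (this sandbox has no network access).

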