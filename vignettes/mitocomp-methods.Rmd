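---
title: "Comparative mitogenomics with mitocomp: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparative mitogenomics with mitocomp: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitocomp)
```

`mitocomp` implements the standard descriptive toolkit of comparative
mitogenomics — the set of analyses a typical "complete mitochondrial
genome of species X" paper reports — for annotated circular mitogenomes,
with a focus on passerine birds. This vignette documents the models and
conventions behind each analysis, the default parameters, and why those
defaults were chosen. A fully deterministic synthetic-genome generator
with ground-truth sidecars makes every stage demonstrable (and testable)
offline; it is used for the examples throughout.

```{r simulate}
st <- generate_study_set(genome_spec(seed = 42))
root <- st$root
```

## 1. Records, annotation, and I/O

A `genome_record()` is an identifier, an upper-case DNA string, a
circularity flag, and a list of `feature()`s. All coordinates are
**0-based, half-open, top-strand** throughout the package; GenBank's
1-based inclusive coordinates are converted at the file boundary and
nowhere else. Features on the minus strand carry `strand = "N"`; a
feature's location is a list of intervals so that genes spanning the
circular origin are first-class.

`read_genbank()` parses the mitogenome subset of the flat-file format
(gene/CDS/tRNA/rRNA/D-loop/misc_feature keys, `join()`/`complement()`
locations, ORIGIN block). Paired `gene` + `CDS`/`tRNA`/`rRNA` entries are
merged into one feature; a `codon_start` qualifier becomes a reading
offset. Annotation labels are normalised by `canonical_gene_name()` to a
fixed 37-gene vocabulary (`nad1`–`nad6`, `nad4l`, `cox1`–`cox3`, `cob`,
`atp6`, `atp8`, `rrnS`, `rrnL`, 22 tRNAs, plus `CR`), including the usual
ambiguities: `trnL`/`trnS` are disambiguated by anticodon when given,
otherwise by neighbourhood (`trnL` next to `rrnL` is `trnL(uur)`).

## 2. Composition and skew

`base_composition()` reports percentages of A, C, G, T, A+T, and the two
skews, with ambiguity codes and gaps excluded from every denominator:

- AT-skew = (A − T) / (A + T)
- GC-skew = (G − C) / (G + C)

A zero denominator yields `NA` rather than an error. Reported
percentages are rounded half-up to one decimal (`round_half_up()`), the
convention of the comparative literature, while all internal arithmetic
is done at full precision. `codon_position_split()` decomposes
protein-coding sequence into first/second/third codon-position streams,
honouring the reading offset and **dropping the complete stop codon** so
that position streams describe coding positions only; a trailing partial
codon contributes its available positions. `partition_summary()` applies
this machinery across records to the `standard_partitions()`: whole
genome, concatenated PCGs (and each codon position), tRNAs, `rrnS`,
`rrnL`, and the control region.

```{r composition}
partition_summary(st$records, standard_partitions()$genome)[1:3, ]
```

## 3. Codon usage

Codons are extracted per gene with `extract_codons()`, which understands
the vertebrate mitochondrial code's incomplete stops (`T` or `TA`
completed by polyadenylation): a trailing 1–2 nt remainder is reported
as an incomplete stop, not discarded as noise. RSCU for a codon *c* in a
synonymous family of size *k* is

RSCU(c) = k · n(c) / Σ n(family),

computed under the vertebrate mitochondrial code (AGA/AGG are stop,
ATA is Met, TGA is Trp); stop codons are excluded, leaving 60 codons. An
unobserved family gives `NA` for all its members rather than 0, since an
RSCU of 0 is a claim about usage, not absence of data.
`start_stop_table()` tabulates start/stop codons per PCG per record and
flags incomplete stops.

## 4. Gene order and spacers

`extract_gene_order()` reads the annotated order around the circle,
anchored at `trnF` (the conventional starting point for avian
mitogenomes) and oriented along the top strand. `compare_orders()`
computes the strand-aware circular breakpoint distance: each adjacency
`(x, strand) → (y, strand)` is stored under a canonical encoding that
identifies it with its reverse-complement reading, and the distance is
the number of adjacencies of one order absent from the other. Genes
present in only one order are dropped (with a warning) before the
comparison. `spacer_table()` reports the signed gap between consecutive
features — positive spacer, negative overlap — including the wrap-around
pair on circular records.

## 5. Control region

`partition_cr()` divides the CR into the classical domains I/II/III,
either at explicit boundaries or by anchoring on the F-box and CSB-1
motif hits. `variable_site_proportion()` computes, over a positional
alignment, the percentage of variable sites; by default the denominator
counts only columns with ≥ 2 non-gap residues ("informative"), with
`denominator = "total"` as an option.

`find_motif()` is an IUPAC-aware sliding scan with a mismatch budget:
pattern ambiguity codes match their expansion, an ambiguous *subject*
base is a mismatch unless the pattern position is `N`, hits are returned
sorted by mismatch count then position. `scan_cr_boxes()` applies a
configurable table of conserved avian CR boxes (F/E/D/C boxes, Bird
similarity box, CSB-1, poly-C stretch, TAS-like motif; see
`cr_box_patterns()`); `read_motif_config()` loads a custom TSV of
name/pattern/max_mismatch so the motif set is data, not code.

`find_tandem_repeats()` detects tandem arrays by per-unit periodicity
(`s[i] == s[i − u]` run-length encoding), extends arrays across isolated
mismatches while purity = (unit + matches) / length stays at or above
`min_purity` (default 0.9), collapses nested reports to the smallest
unit, and applies a `min_length = 36` floor by default — two copies of
an 18-mer — so that the default scan reports repeats of the size class
discussed for avian CRs rather than di-nucleotide wobble. All
parameters are exposed; oracle-style exhaustive comparisons in the test
suite run with `min_length = 0`.

## 6. tRNA cloverleaf folding

`fold_cloverleaf()` folds a tRNA by exhaustive search over a
parameterised cloverleaf template rather than free-energy minimisation —
the appropriate tool when the question is "does this annotated tRNA
still form the canonical secondary structure, and is the DHU arm
reduced?". Template dimensions (acceptor stem 7 bp; D-stem 0–4 bp, with
0 meaning a 3–12 nt replacement loop; anticodon stem 5 bp; T-stem
4–5 bp; loop and spacer ranges as in `fold_cloverleaf()`'s
documentation) cover vertebrate mitochondrial tRNAs including the
DHU-less serine tRNA. Scoring is +2 per Watson–Crick pair, +1 per G·U
pair, −1 per mismatch; a perfect 21-pair cloverleaf scores 42. The
fold can be constrained to place a known anticodon, and
`fold_record_trnas()` applies the annotated anticodons of a record's 22
tRNAs, reporting score, dot-bracket string, DHU-arm presence, and
mismatch count.

```{r trna}
head(fold_record_trnas(root)[, c("name", "length", "score", "dhu_present")])
```

## 7. Distance phylogenetics

`concatenate()` builds a supermatrix from per-gene alignments (missing
taxa gap-filled) with partition bookkeeping; `export_supermatrix()`
writes relaxed PHYLIP and NEXUS (with `CHARSET` blocks), sanitising taxon
names and writing a `names.tsv` map when needed. `distance_matrix()`
offers p-distance and Kimura two-parameter distances with pairwise
deletion of ambiguous/gapped sites. `neighbor_joining()` is exact NJ; on
additive matrices it provably recovers the generating topology, which is
the basis of its tests. `rf_distance()`, `is_monophyletic()`, and
`topology_matches()` support the usual hypothesis checks.

## 8. The synthetic study system

`generate_genome()` builds a complete passerine-architecture mitogenome
(37 genes + CR in the canonical order anchored at `trnF`, ~16.8 kb) from
a `genome_spec()`, and returns it together with a **truth sidecar**
recording every planted parameter. Defaults were chosen to sit inside
the envelope reported for passerine mitogenomes, with engineered
features that downstream modules must recover exactly:

- composition targets per partition (genome ≈ 53.5% A+T, positive
  AT-skew, negative GC-skew; distinct targets for codon positions, RNAs,
  CR), realised by `solve_base_freqs()` inverting the summary statistics
  to base frequencies;
- a codon model biased through `default_codon_weights()` so that CUA
  leads leucine and UCC leads serine, with RSCU targets derivable in
  closed form (`rscu_targets_from_weights()`);
- a spacer/overlap plan including the diagnostic 23 bp `trnP`–`nad6`
  spacer and the 10 bp `atp8`–`atp6` overlap;
- CR boxes implanted at recorded offsets, optional tandem repeat, and
  domain boundaries;
- 22 tRNAs built from the cloverleaf template with planted mismatches
  and one DHU-less serine.

`generate_study_set()` evolves the root along a fixed 7-taxon guide tree
under K2P with per-site rate multipliers (`study_site_rates()`): PCGs 1,
RNAs 0.35, CR domains 0.7 / 0.25 / 1.8, implanted boxes 0.05, and rate 0
at start/stop codons **and tRNA anticodons** (both under absolute
purifying selection in real mitogenomes). All randomness flows through
named, seed-derived substreams, so every product is a pure function of
the seed.

## 9. Reports

The `report_*()` family (`report_composition()`, `report_rscu()`,
`report_gene_order()`, `report_spacers()`, `report_cr()`,
`report_trna()`, `report_phylo()`) are the pipeline entry points: each
writes the TSV/Newick/PHYLIP products of one analysis stage into an
output directory and returns its main table invisibly. The numbered
scripts under `analysis/` are thin drivers over these functions; the
whole pipeline is reproduced by running them in order after
`analysis/01_simulate.R`.
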