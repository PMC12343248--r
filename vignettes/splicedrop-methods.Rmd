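---
title: "splicedrop: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{splicedrop: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`splicedrop` analyses droplet-based single-cell *full-length* transcriptome
(scFL) barnyard experiments: two species' cells mixed in one run, so that
cross-species signal exposes empties, doublets, ambient RNA and ruptured
cells, while full-length read placement supports gene-body coverage and
splice-junction analysis. This vignette explains the statistical model
behind each stage, the parameters that matter, and the choices made where
the design was genuinely open. It states no empirical result that the test
suite and `scripts/acceptance.R` do not themselves compute.

## The simulator and what it emulates

All development and testing runs against `simulate_annotation()` +
`simulate_droplets()`, which generate a complete experiment with ground
truth.

**Annotation.** Each species gets `n_genes_per_species` genes laid along
one chromosome (`A_chr1`, `B_chr1`; the chromosome prefix doubles as the
species tag in every file format). Exon counts, exon lengths, intron
lengths and intergenic gaps are uniform draws over configurable ranges
(defaults 4–8 exons of 100–400 bp, introns 200–2,000 bp, gaps
1,000–5,000 bp — compact but transcript-like geometry that keeps every
transcript much longer than one read). A fraction `frac_genes_with_SE`
(default 0.5) of multi-isoform genes receives exactly one skipped-exon
pair: isoform 2 equals isoform 1 minus one random internal exon. Other
multi-isoform genes differ by terminal truncation only, which deliberately
creates *no* skipped-exon events, so the planted SE set is exactly
recoverable and is verified in tests against a brute-force pairwise
exon-set comparison.

**Droplet composition.** `n_cells_A` + `n_cells_B` cells (defaults
500 + 500), of which `round(doublet_rate · n_cells)` A/B pairs are merged
into cross-species doublets (default 5%; same-species doublets are
invisible to count-based barnyard rules and are not simulated), a fraction
`contaminated_cell_rate` (default 5%) of remaining cells are "ruptured"
(elevated ambient content), and `n_empty_droplets` (default 5,000)
ambient-only barcodes are added.

**Counts.** Each species has one log-normal expression program
(`sdlog = 1.5`), drawn under `program_seed` so that replicate simulations
can share a program while resampling everything else. Per-droplet totals
are negative binomial (`mu = mean_counts_per_cell`, default 5,000;
`size = dispersion`, default 10); empty totals use
`empty_total_frac = 0.01` of the cell mean, giving the sharp knee the
rank-based empty threshold assumes. Each droplet's counts are a two-stage
mixture: `n_amb ~ Binomial(total, f)` counts from the ambient pool and the
rest from the droplet's own program, where `f` is `ambient_fraction`
(default 0.02), `contaminated_ambient_fraction` (default 0.6) for ruptured
cells, or 1 for empties. The ambient pool is the cell-number-weighted
average of the two programs — the "soup" of ruptured cells — so with equal
cell numbers half of ambient content is cross-species, and the expected
cross-species fraction of a pure cell is `f/2` (a relation the tests
check). The 0.6 rupture fraction is chosen so that ruptured cells cross
the 0.25 cross-fraction boundary of the contamination rule; a ruptured
cell that had lost less of its content would be indistinguishable from an
ordinarily ambient-contaminated one.

**Reads.** One block-aligned read per matrix count. Within a gene the
transcript is chosen with probability proportional to *molar weight ×
transcript length* — the shotgun-coverage model in which read counts are
proportional to molecule number times length. This matters for
skipped-exon analysis: with length-blind weights a 70/30 molar isoform
mixture yields junction-read proportions biased low by several percent,
because the longer (inclusion) isoform offers proportionally more fragment
start positions overall but the same ~`read_length − 1` junction-spanning
ones. SE genes use `se_inclusion_prop` (default 0.7) for the inclusion
isoform; other genes use uniform molar weights.

Fragment starts follow a truncated exponential in transcript coordinates:
the density of the start's distance `d` from the 3' end is
∝ `exp(−λ·d/L)` on `[read_length, L]`, with `λ = three_prime_bias`
(default 1, a mild 3' bias; 0 gives exactly uniform starts, verified by a
chi-square test). The fragment's genomic blocks follow the chosen
transcript's exon chain, so reads crossing exon boundaries are
junction-spanning by construction and fragment length is fixed at
`read_length` (150 bp) — short-read geometry where only block structure,
not sequence, matters downstream.

Two artifact classes are emitted *on top of* the matrix-backed reads, so
that the count matrix equals the read set after preprocessing (a
conservation law the tests assert): cross-genome-ambiguous decoys
(`ambiguous_read_rate`, default 2%; fresh placements flagged in the BED
score column) and PCR duplicates (`duplicate_rate`, default 10%; identical
placement re-emitted under a new read id).

**What the simulator does not emulate.** No sequences, base errors,
alignment noise or fuzzy junction coordinates (junction matching is
exact-coordinate by design); no UMIs (the assay is read-count based); no
per-cell expression heterogeneity beyond sampling noise (one program per
species); no intronic or intergenic read placement (so region assignment
is exercised by constructed fixtures, not by the simulator); gene counts
per species are tens, not tens of thousands. Passing tests therefore
demonstrate the *procedures* are correct under the stated statistical
structure, not that real libraries look like this.

## Read preprocessing

Ambiguity filtering keeps exactly the reads not flagged as mapping to both
genomes. Deduplication keys on (barcode, chromosome, block structure) —
placement determines sequence in the simulator, so this is exact — with
first-seen-wins retention (stable and deterministic without sorting). The
bulk-style variant drops the barcode from the key (`ignore_barcode`),
since bulk deduplication has no barcode to use.

One consequence of read-level (non-UMI) deduplication is worth knowing: at
high per-gene depth, independent fragments from *distinct* molecules
coincide in placement and are collapsed too. With ~150 distinct start
positions per junction, junction counts saturate per barcode, pulling deep
genes' inclusion proportions toward 0.5 after deduplication. This mirrors
real read-count assays. Tests that assert exact recovery of the simulator's
duplicate truth therefore run at low per-gene density (far below one read
per transcript position), where coincidence is vanishingly rare;
skipped-exon recovery experiments disable PCR duplication and quantify
pre-deduplication reads.

## Cell calling

The empty threshold is `C(knee_rank)/knee_divisor` (defaults 100 and 10)
on totals sorted in decreasing order; ranks are 1-based and ties are broken
lexicographically by barcode for determinism. Fewer than `knee_rank`
nonzero barcodes is a hard error instructing the user to lower the rank —
no silent fallback. Classification then applies, in order: the two pure
species rules (own counts > 1,000, cross fraction < 0.25), the
contamination rule (cross fraction > 0.25, total < 30,000), else filtered.
All inequalities are strict: a droplet sitting exactly at a 0.25 cross
fraction satisfies neither the pure rules (which need < 0.25) nor the
contamination rule (> 0.25) and falls to filtered; "exceeding 1,000" is
read as strictly greater. The pure rules cannot conflict with each other
(both cross fractions < 0.25 would have to sum below 0.5 while the
fractions sum to 1) nor with the contamination rule. "Cross fraction"
means cross-species counts over *total* droplet counts, matching the count
percentage axis of barnyard scatter plots, not a species-conditional
share.

The category set names contaminated cells but folds doublets into
"filtered"; because cross-species doublets usually satisfy the
contamination rule (balanced counts, total < 30,000), the package
additionally flags filtered barcodes with both species above the count
floor as `is_likely_doublet`, preserving the procedure while keeping the
doublet vocabulary available. A natural monotonicity caveat: as a
droplet's cross-species counts grow without bound, the rules eventually —
and correctly — call it a pure cell *of the other species*; the invariant
the package tests is that a droplet never *returns* to its own species'
pure category as contamination grows.

## Coverage and region assignment

Gene-body coverage uses the longest transcript per gene (standard
metagene practice; ties broken by transcript id), 100 equal-length bins in
transcript coordinates (the common convention for gene-body plots; the bin
count is a parameter), and strand-aware orientation so bin 1 is always the
5' end. `raw_depth` is the per-bin *summed* base count over genes — the
form under which binning is conservative: its total equals the number of
exon-overlapping read bases on representative transcripts, an invariant
the tests check exactly. The normalized track is the per-bin mean over
expressed genes, divided by total read count, then `log10(x + 1e-9)`; the
pseudocount (exposed) only guards empty bins and is far below any
depth-normalized value actually attained.

Region assignment is per-read by base majority with precedence exonic >
intronic > intergenic on ties. "Intergenic" means outside every gene's
genomic span; "intronic" means inside a span but outside the exon union.
A read may overlap several genes' features; only its base totals in the
three classes matter.

## Junctions, skipped exons, selection

Junction extraction is a pure aggregation of inter-block gaps, checked
against a brute-force per-read scan. Classification is an exact-coordinate
join against the annotation's adjacent-exon pairs — a 1-bp shift of any
annotated junction must and does yield `novel` — and gene assignment
requires both endpoints within a single gene's span. Exactness is
appropriate because the simulator emits exact coordinates; tolerance
windows for real aligner wobble are out of scope.

Skipped-exon inclusion support combines the two inclusion junctions with
`min` — the conservative, standard choice where the quantification needs a
single number and the two counts are noisy observations of the same
molecular quantity. The inclusion proportion is undefined (NA) with no
supporting reads at all.

Gene selection for splicing analysis keeps genes with an SE event, a
same-transcript-type proportion strictly above 0.5, at least 5 supporting
reads, and TPM strictly above 16. The supporting-reads criterion is
phrased in its source as "fewer than 5 reads supporting the same
transcript type", which can only be meant as an exclusion; it is
implemented as ≥ 5 required, with the threshold exposed.

## Quantification and correlation

TPM uses exonic-union gene lengths (all isoforms merged) — the common
choice when quantification is per-gene, and the one that is stable under
isoform re-annotation; it is a parameter of the pipeline, not a constant.
The correlation transform is `log10(TPM + 1)` over all shared genes by
default, with an expressed-in-either filter available, since double-zero
inclusion is a legitimate analysis choice that changes r on sparse data.

## Problem sizes and determinism

Every random draw flows from a single integer seed (`sim_config(seed =)`;
expression programs take `program_seed` so replicates can share them), and
identical configurations produce byte-identical outputs — the pipeline
writes only deterministic, Unix-newline text files, and the test suite
compares two full runs by checksum. Test and acceptance experiments use
deliberately compact instances chosen to make each property measurable
with comfortable statistical margins: droplet-scale checks at the default
500 + 500 cells vs 5,000 empties (matrix-only mode, no read emission);
read-scale checks at 20k–200k reads; skipped-exon recovery with two
single-SE genes at 10,000 reads each, exon lengths ≥ 250 bp so every
junction sits more than one read length from transcript ends (interior
junctions have the full `read_length − 1` spanning-start window, so the
junction-read proportion is an unbiased estimate of the molar mixture).

## Known limitations

Region assignment and coverage assume a read maps to one chromosome;
reads spanning genes of both species cannot occur by construction. The
`filtered` category mixes low-quality cells with doublets exactly as the
rule set defines, so doublet sensitivity is bounded by the contamination
rule's thresholds. The simulator's ambient pool is expression-weighted and
static; it does not model droplet-size-dependent soup composition. And the
exact-coordinate junction model means the package, as shipped, is a
desk-scale analysis and validation harness, not an aligner-facing variant
caller for noisy real-world junctions.
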