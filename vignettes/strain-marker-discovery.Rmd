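---
title: "Strain-specific qPCR marker discovery with strainmark"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Strain-specific qPCR marker discovery with strainmark}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(strainmark)
```

## The problem

A bacterial strain deployed at scale — here the leaf endophyte
*Methylobacterium symbioticum* SB0023/3, sold as a crop biostimulant — needs a
detection assay that distinguishes it from the hundreds of close relatives
already living on and in plants. 16S rRNA cannot do this (close congeners sit
at ~98.7% identity, above the usual species cutoff), and genus-level
functional markers such as *xoxF*, the lanthanide-dependent methanol
dehydrogenase gene, detect the whole genus rather than the strain.

`strainmark` implements the genome-informed route from an assembled genome to
a validated strain-specific real-time PCR assay:

1. **Singleton screen** — cluster the pan-proteome of the focal strain plus a
   background panel; proteins whose cluster contains only themselves are
   candidate strain-unique markers.
2. **Refinement** — rank candidates by how many significant homologs a larger
   background database holds, preferring fewest homologs and lowest identity;
   drop short genes and genes with uninformative annotations.
3. **Primer design** — enumerate primer pairs on the retained genes under
   explicit quality criteria.
4. **In-silico PCR** — verify the pair amplifies the target and does not
   misprime on related genomes with a comparably long product.
5. **Classification** — call field samples positive/negative from Ct and melt
   Tm, and tabulate detection rates per crop and timepoint.
6. **Novelty scan** — independently of the assay work, compare a resequenced
   assembly against the prior deposit and report regions without significant
   similarity.

## Models and decision rules

### Clustering and singletons

Clustering is greedy and representative-based in the CD-HIT style: proteins
are sorted by length (descending, ties by id) and each joins the first
representative reached at identity ≥ 0.80 with aligned coverage ≥ 0.80 **of
both sequences**, otherwise it founds a new cluster. Pairwise comparison is
Smith–Waterman local alignment under BLOSUM62 with affine gaps (open 11,
extend 1); identity counts matches over all alignment columns, gap columns
included. A shared 5-mer prefilter skips hopeless representative comparisons;
it is an accelerator and the test suite checks it never changes the partition
on package fixtures. A *singleton* is a cluster of exactly one protein
belonging to the focal strain — the standard reading, since larger
focal-only clusters are paralog families rather than single-copy markers.

### Background significance

A background protein counts as a homolog of a candidate when the local
alignment score `S` is significant under the ungapped Karlin–Altschul model

`E = K · m · n · exp(−λ·S)`, λ = 0.3176, K = 0.134,

with `m` the candidate length and `n` the **total residue count of the
panel**. Using the panel size rather than an external database size keeps the
statistic reproducible: significance depends only on inputs the user
controls. The homolog threshold defaults to `E ≤ 1e-3`, matching common
protein-search practice. Candidates are ranked ascending by (homolog count,
best identity, id); the final lexicographic key makes the ranking a total
order, so any permutation of the input yields the same list.

### Primer quality criteria

Defaults encode the assay rules the package is built around:

| parameter | default | meaning |
|---|---|---|
| `min_amplicon_bp` | 301 | product strictly longer than 300 bp |
| `gc_min_pct, gc_max_pct` | 40, 60 | primer GC, inclusive bounds |
| `selfcomp_max` | 4 | self-complementarity score |
| `primer_len_range` | 18–24 nt | enumerated window lengths |
| `tm_range_c` | 57–63 °C | primer Tm under the NN model |
| `max_pair_tm_diff_c` | 2 °C | pair Tm balance |

*Self-complementarity* is scored by exhaustive enumeration: over all ungapped
antiparallel alignments of the oligo against itself, the best contiguous
window at +1 per Watson–Crick pair and −1 per non-pair (floored at zero).
The published criterion gives the 0–4 band without defining the scorer; the
gap-free ±1 window score is the minimal reproducible reading, and both the
whole-oligo (`any`) and 3'-anchored (`end3`) variants are implemented. The
`any` score is what the criteria check. One published assay primer
(GTTCCTTGCGAATGCGGG) computes to 61.1% GC, outside its own stated band; the
scorer reports the exact value and the discrepancy is simply visible.

*Primer Tm* uses the SantaLucia (1998) unified nearest-neighbor ΔH/ΔS table
with initiation terms, `Tm = ΔH / (ΔS + R·ln(C/4)) − 273.15 +
16.6·log10([Na+])`, at 50 mM Na⁺ and 500 nM oligo by default. No symmetry
correction is applied (the formula is used as stated and is configurable via
its salt/concentration arguments). Under this model and these conditions,
18–20-mers at 40–60% GC sit near 48–53 °C, so the default 57–63 °C band is
reached mostly by 22–24-mers; tests that plant 20-mer sites pass an explicit
`tm_range_c = c(46, 56)` instead of silently retuning the defaults.

Pairs are ranked by (|ΔTm|, combined self-complementarity, |mean GC − 50|),
ties broken by coordinates, making the design fully deterministic.

### In-silico PCR

Binding sites are ungapped windows with at most 2 total mismatches and **zero
mismatches in the 3'-terminal 3 bases**, modeling the polymerase's extension
sensitivity; both knobs are assay-stringency parameters. `N` never matches a
primer base, which makes ambiguity conservative for specificity claims. No
thermodynamic binding model is used for mispriming — the mismatch-count model
keeps the site rule exactly checkable against a brute-force oracle. Products
are all convergent site pairs within 2,000 bp, measured 5' end to 5' end.
Mispriming is flagged when an off-target genome yields a product within ±25%
of the target product length ("comparably long" made quantitative; the
fraction is configurable).

### Melt curves and the positivity rule

Amplicon melt Tm uses the empirical long-duplex formula
`81.5 + 16.6·log10([Na+]) + 0.41·GC% − 675/length` (domain ≥ 50 bp). The
derivative melt curve is simulated as the analytic −dF/dT of a sum of
sigmoidal helicity transitions (width 1 °C) evaluated on the instrument grid
72–95 °C in 0.5 °C steps — the grid spacing is the measurement uncertainty of
the method. Predicted Tm values are **never** compared with instrument peak
temperatures: dye chemistry and the empirical formula differ systematically.
Classification therefore always works on the difference to a positive
control measured under the same model or on the same instrument.

A well is positive iff Ct is present, `Ct ≤ 30`, and `|Tm − control Tm| ≤
0.5 °C`, all boundaries inclusive. Negative calls carry reason codes
(`no_amplification`, `ct_above_threshold`, `tm_mismatch`). A sample-level
"colonized" verdict is an OR over the sample's assays by default
(`min_assays_positive = 1`). Detection rates are percent positive per
(crop, timepoint, assay) at one decimal; empty cells of the level crossing
render as `"ND"`.

### Novelty scan

The scanner seeds on shared 15-mers (both strands), extends ungapped at
match +1 / mismatch −2 under an X-drop of 20, and keeps alignments with
`E = K·m·n·exp(−λ·S) ≤ 1e-10` (λ = 1.28, K = 0.46 for +1/−2). Query intervals
covered by a kept alignment are conserved; maximal uncovered intervals of at
least 10 bp are novel regions. Coordinates are linear — circular replicons
must be rotated to a common start first, otherwise the breakpoint shows up as
one spurious region. The resolution limit at region boundaries is `seed_k −
1` bp per side, and the tests assert recovery of planted insertions within
that tolerance. The published analysis this models reported its novel-region
set at a 1e-10 threshold while describing a 1e-20 nucleotide search
elsewhere; the default follows the threshold attached to the reported
regions, and both are configurable. Region counts from different aligner
stacks are not expected to match exactly, so no fixed region count is
asserted anywhere.

## What the synthetic data emulates — and what it does not

Every stage has a generator with planted ground truth
(`generate_pangenome()`, `generate_primer_target()`,
`generate_offtarget_panel()`, `generate_qpcr_dataset()`,
`plant_insertions()`), each a pure function of (parameters, seed):

* **Pan-proteome**: core families are mutated per strain by substitutions
  only, so identity audits are exact under near-ungapped comparison; planted
  focal-only genes are random sequences. Real pan-genomes have indels,
  paralogs and horizontal transfer; passing tests show the screen's logic is
  correct, not that 80/80 thresholds are optimal for any real genus.
  Defaults (4 background strains, 50 core families at 0.95 identity, 5
  planted singletons, genes 150–1200 bp) are a desk-scale stand-in for a
  RefSeq genus panel.
* **Primer target**: planted primer windows in an A/T-only background make
  the planted sites the only fully criterion-compliant windows; real genes
  offer many near-equivalent windows.
* **qPCR runs**: colonized wells draw Ct from a truncated N(22, 3) and Tm
  from N(control, 0.15 °C); negatives are absent, late (N(35, 2)) or
  off-peak (≥ 1.5 °C shift). Real instruments add between-run drift and
  occasional primer-dimer signals that this model does not include.
* **Insertions**: random sequence at non-overlapping positions with exact
  truth intervals; real structural novelty includes duplications and
  rearrangements the scanner reports only as uncovered sequence.

## Numerical and scale choices

Test and acceptance fixtures are sized for a single CPU: pan-proteomes of
~70–260 proteins (20 seeds), genomes of 2–20 kb for site-search and novelty
sweeps, 1,000 random oligos and 100 random alignment pairs against
brute-force oracles, and 10,000 random observations for classifier
monotonicity. These sizes exercise every code path; the algorithms are
quadratic at worst in the aligned lengths and scale to bacterial-genome
inputs in minutes.

Degenerate inputs are handled explicitly: a target shorter than the minimum
amplicon returns an empty design with reason `target_too_short` rather than
an error; a primer pair with no target product is a hard error in the
specificity check (a specificity claim without a target product is
meaningless); melt grids that do not divide the ramp are clamped at the end
temperature; all tie-breaks are lexicographic so every ranked output is a
total order.

## Known limitations

* The e-value model is ungapped Karlin–Altschul applied to gapped local
  scores — standard in spirit, but not a calibrated BLAST statistic.
* Mispriming uses mismatch counts, not hybridization thermodynamics; a
  thermodynamically weak site with few mismatches is still counted.
* The novelty scanner does not model circularity or rearrangements.
* Absolute melt Tm predictions are not instrument-calibrated (by design; use
  ΔTm to a control).
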