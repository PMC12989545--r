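# strainmark

Genome-informed discovery and in-silico validation of **strain-specific qPCR
biomarkers**, built for the situation where a deployed bacterial strain — for
example the leaf endophyte *Methylobacterium symbioticum* SB0023/3, used as a
crop biostimulant — must be detected against a background of near-identical
relatives that 16S rRNA or genus-level markers such as *xoxF* cannot resolve.

The toolkit covers the whole route from assembled genome to field-sample
classification:

* **Singleton screen** (`cluster_proteins`, `find_singletons`,
  `refine_by_background`, `filter_candidates`) — greedy CD-HIT-style
  clustering of a pan-proteome at 80% identity / 80% two-sided coverage
  (Smith–Waterman, BLOSUM62, affine gaps 11/1); clusters of exactly one
  focal-strain protein are marker candidates, ranked by homolog count under
  the ungapped Karlin–Altschul statistic `E = K·m·n·e^(−λS)` (λ = 0.3176,
  K = 0.134) against a background panel, then filtered by gene length
  (≥ 300 bp) and annotation (hypothetical products excluded).
* **Primer design** (`design_primer_pairs`, `gc_content`,
  `self_complementarity`, `primer_tm`) — exhaustive window enumeration under
  explicit criteria: amplicon > 300 bp, GC 40–60%, self-complementarity ≤ 4
  (best ungapped antiparallel window, +1 per Watson–Crick pair, −1
  otherwise), nearest-neighbor Tm (SantaLucia 1998 unified parameters).
* **In-silico PCR** (`find_binding_sites`, `predict_amplicons`,
  `specificity_check`) — mismatch-count site model with an exact 3' anchor;
  mispriming is flagged when an off-target genome yields a product within
  ±25% of the target product length.
* **qPCR classification** (`call_samples`, `detection_rates`,
  `simulate_melt_curve`, `amplicon_melt_tm`) — positive iff Ct ≤ 30 and
  |Tm − control Tm| ≤ 0.5 °C (inclusive), with reason codes, melt-curve
  simulation on the 72–95 °C / 0.5 °C instrument grid, and per-group
  detection-rate tables (`"ND"` for empty cells).
* **Novelty scan** (`find_novel_regions`, `summarize_novelty`) — seed-and-
  extend comparison of a resequenced assembly against a prior deposit;
  maximal query intervals (≥ 10 bp) not covered by an alignment with
  e-value ≤ 1e-10 are reported as novel regions.
* **Synthetic data** (`generate_pangenome`, `generate_primer_target`,
  `generate_offtarget_panel`, `generate_qpcr_dataset`, `plant_insertions`) —
  deterministic generators with planted ground truth for every stage.
* **Pipeline** (`run_pipeline`, `exec/strainmark`) — YAML-configured
  subcommands (`screen`, `design`, `validate`, `melt`, `classify`,
  `novelty`, `simulate`) writing manifests with content hashes; identical
  inputs, config and seed reproduce byte-identical outputs.

See the methods vignette (`vignettes/strain-marker-discovery.Rmd`) for the
models, their assumptions and the design decisions.

## Worked example

Score the three published SB0023/3 assay primer pairs against the design
criteria:

```r
library(strainmark)
pr <- read.delim(system.file("extdata", "gobio_primers.tsv",
                             package = "strainmark"))
data.frame(name = pr$name,
           gc = round(vapply(pr$sequence, gc_content, 0), 1),
           selfcomp = vapply(pr$sequence, self_complementarity, 0L,
                             mode = "any"),
           tm = round(vapply(pr$sequence, primer_tm, 0), 1))
#>          name   gc selfcomp   tm
#>  GoBio_Xoxf_f 60.0        4 50.9
#>  GoBio_Xoxf_r 55.0        2 51.1
#>  GoBio_CopG_f 55.0        2 51.6
#>  GoBio_CopG_r 55.0        4 51.4
#>  GoBio_Ubik_f 55.0        4 49.0
#>  GoBio_Ubik_r 61.1        4 50.5
```

Every primer scores self-complementarity within the published 0–4 band. GC
sits in the published 40–60% band for five of six primers; `GoBio_Ubik_r`
computes to 61.1%, a small excursion the original assay accepted. Tm values
are model Tm under 50 mM Na⁺ / 500 nM oligo — comparable between primers,
not instrument temperatures.

Classify a qPCR well against a positive control at 84.6 °C:

```r
call_sample(list(ct = 20, tm_c = 84.6), control_tm_c = 84.6)
#> <qpcr_call> POSITIVE
call_sample(list(ct = 32, tm_c = 84.6), control_tm_c = 84.6)
#> <qpcr_call> negative: ct_above_threshold
```

Run the whole synthetic pipeline from the shell:

```sh
exec/strainmark simulate --out-dir run/sim --seed 42
exec/strainmark screen   --config cfg.yaml --out-dir run/screen --seed 42
```

where `cfg.yaml` points `io.proteome_dir` at `run/sim/pangenome`. The screen
writes `candidates.tsv` with exactly the planted focal-only genes ranked
first, plus a manifest of md5-hashed outputs.

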