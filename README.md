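# starrkit

Quantification, significance testing, and chromatin-context
classification of enhancer activity from whole-genome STARR-seq
(self-transcribing active regulatory region sequencing). In STARR-seq,
candidate DNA fragments cloned downstream of a minimal promoter drive
their own transcription, so the ratio of reporter-transcript reads to
transfected-input reads at a locus measures its autonomous enhancer
strength. `starrkit` is written for analysts comparing enhancer
landscapes between two cell states (the motivating design is mouse
embryonic stem cells in 2i+LIF "ground state" versus serum+LIF
"metastable" culture, two biological replicates each), but all of its
machinery is generic.

## The model

For peak *i* in library *j*, with *k* total STARR reads, *u* unique
(deduplicated) STARR reads, and *r* raw input reads:

- **Trials bound.** Input counts are scaled to the STARR library depth,
  `m = ceil(r * N_starr / N_input)`, and the binomial trials are
  `T = max(m, u)` — a fragment cannot report unless it was in the input,
  so the unique STARR count is a lower bound on the input complexity at
  the locus.
- **Significance.** A right-tailed binomial test of *k* successes in
  `n = k + T` trials at success probability 0.5 (after depth scaling,
  half of the reads are expected to be input under the null), BH-adjusted
  per library.
- **Shrinkage.** Enrichment `e = k / T` is unstable at low counts, so a
  beta-binomial prior `Beta(alpha, beta)` is fitted across all peaks by
  maximum likelihood and each peak reports the posterior-mean odds
  `e_shrunk = (k + alpha) / (T + beta)`.
- **Empirical FDR.** The 3-fold enrichment threshold is validated by
  sampling GC- and length-matched random genomic regions and measuring
  the fraction that reach 3-fold shrunken enrichment (< 3% under the
  null).
- **Final call.** `e_shrunk >= 3` on merged replicates per condition and
  adjusted binomial `p < 0.05` in both replicate libraries.
- **Differential activity.** Within the union peak set, a per-peak
  negative-binomial Wald test with log-link offsets
  `log NF_ij`, where `NF_ij = sizeFactor(STARR_j) / sizeFactor(input_j) *
  max(m_ij, u_ij)` (rows scaled to geometric mean 1) couples the test to
  the local input abundance; `|FC| >= 2.5` and `p < 0.05` flags a peak as
  differential. The per-peak dispersion is
  `phi_i = phi0 + c * mean_j(1 / r_ij)`, a pooled residual term plus the
  delta-method variance that input-count noise contributes through the
  offsets, both fitted by Cox–Reid adjusted profile likelihood.
- **Classification.** A called peak overlapping "active"
  chromatin-segmentation intervals is **C1** (active enhancer); a called
  peak without active chromatin is **C2** (chromatin-masked enhancer); an
  APK element (ATAC ∩ P300 ∩ H3K27ac) with binomial `p > 0.1` in every
  library and ≥ 1 kb from any TSS is **C3** (dormant: active chromatin,
  no autonomous activity).

A synthetic-data generator (`sim_config()`, `simulate_genome()`,
`simulate_experiment()`, `simulate_chromatin()`) plants known enhancer
strengths, condition effects, duplication, GC structure and chromatin
labels, so that every stage is testable against ground truth without any
sequencing data.

## Worked example

The `analysis/` directory is a numbered workflow over the package. On the
default synthetic study (5,000 regions, ~850 bp median, 9× mean input
coverage, 2 conditions × 2 replicates):

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_enrichment.R
Rscript analysis/03_differential.R
Rscript analysis/04_classify.R
Rscript analysis/05_annotate.R
```

prints, among other things:

```
regions: 5000 (median 847 bp), planted classes: C1=1050 C2=450 C3=350 none=3150
2iL prior: alpha=3.83 beta=2.5 (mean odds 1.53)
final peaks: 1146 in 2iL, 1153 in SL, union 1349
recall of planted enhancers: 0.899; null regions called: 0.0000
empirical FDR at 3-fold on 100000 matched background regions: 0.0000
differential calls: ns=1012 up_2iL=175 up_SL=162
recovery of planted condition effects: power 0.888, observed FDR 0.012
2iL: C1=818 C2=328 C3=328; dropped with reason: ambiguous_signal=25 starr_signal=227 tss_proximal=2
luciferase vs STARR on n = 39 loci: Pearson r = 0.821
```

The prior's mean odds (~1.5) is what zero-count loci shrink towards; the
final-peak counts show the threshold pair at work (90% of planted
enhancers recovered, no null region called); the classification counts
match the planted classes on every locus whose peak-call status agrees
with its planted activity. Stage outputs (enrichment tables, BED files,
differential and classification tables) land under `results/`.

`run_demo()` runs the same pipeline in one call and writes a summary
table; every output file carries the config hash and master seed, and a
fixed seed reproduces every file byte for byte.

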