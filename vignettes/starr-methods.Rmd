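---
title: "Models and methods behind starrkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind starrkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`starrkit` quantifies autonomous enhancer activity from STARR-seq read
counts and interprets it against chromatin context. This vignette
explains the statistical models, the choices made where the design was
genuinely open, and what the synthetic-data generator does and does not
emulate. It states no empirical result beyond what the package's tests
and the acceptance script themselves compute.

## The enrichment model

STARR-seq measures, per candidate locus, reporter-transcript reads
against transfected-input reads. Three counts enter per peak *i* and
library *j*: total STARR reads $k_{ij}$, unique STARR reads $u_{ij}$
(distinct fragment coordinates, i.e. PCR duplicates collapsed), and raw
input reads $r_{ij}$.

**Scaled input and the trials bound.** Input is sequenced at its own
depth, so it is rescaled to the STARR library:
$m_{ij} = \lceil r_{ij}\, N^{STARR}_j / N^{input}_j \rceil$ with
genome-wide library totals $N$. The binomial trials are
$T_{ij} = \max(m_{ij}, u_{ij})$: every distinct transcribed fragment
must have existed in the input, so $u$ is a lower bound on the local
input complexity that protects loci whose input happens to be
undersampled.

**Binomial test.** The null hypothesis is that STARR reads match scaled
input (enrichment 1). After scaling, half of the reads at a null locus
are expected to be input, so we test $k$ successes among $n = k + T$
trials at $p = 0.5$, right-tailed, using the stable survival function
(`pbinom(k - 1, n, 0.5, lower.tail = FALSE)`), and BH-adjust per library
across all candidates. A strict-literal mode (`literal_trials = TRUE` in
`enrichment_table()`) instead clamps successes to $T$ trials; it exists
for comparison because the trials wording admits both readings, but the
ratio-vs-1 form is the default since successes can legitimately exceed
the trials bound and the 0.5 success probability is exactly the
"half of the reads are input" rationale.

**Beta-binomial shrinkage.** Raw enrichment $k/T$ explodes at low
counts. We fit $\theta_i \sim \mathrm{Beta}(\alpha, \beta)$,
$k_i \sim \mathrm{Binom}(k_i + T_i, \theta_i)$ across peaks by maximum
likelihood (BFGS on $\log\alpha, \log\beta$, method-of-moments
initialization; the optimum is asserted to be at least as good as the
initializer) and report the posterior-mean odds

$$\tilde e_{i} = \frac{k_i + \alpha}{T_i + \beta},$$

which reproduces $k/T$ in the data-rich limit and pulls empty loci to
the prior mean odds $\alpha/\beta$. The prior is fitted per condition on
merged-replicate counts over the whole candidate set (the natural
population for "typical enrichment"); per-library fitting would be a
one-line change but halves the records per fit. On a pure-null
experiment the beta-binomial has almost no extra-binomial dispersion to
absorb, so $\hat\alpha, \hat\beta$ grow very large and every locus
shrinks hard toward odds ≈ 1; that is correct behaviour, not a fit
failure, and it is why the background exceedance in the acceptance
script is conservative.

**Final call.** A candidate is a final peak in a condition when the
merged-replicate $\tilde e \ge 3$ *and* the BH-adjusted binomial p is
below 0.05 in each replicate separately. Shrunken (not raw) enrichment
is thresholded by default — shrinkage exists precisely to make that
threshold meaningful at low counts — with `use_shrunken = FALSE`
available.

**Matched background and empirical FDR.** The 3-fold threshold is
calibrated by sampling random genomic regions that match the candidate
peaks' GC histogram (2% bins) at the candidates' median length, avoiding
assembly gaps, scoring them exactly like peaks, and reporting the
fraction at ≥ 3-fold. Sampling is batched rejection per GC bin with a
cap; a thin tail of the peak GC histogram (shorter peaks have wider GC
spread than fixed-length windows can reach) may be filled from the
closest reachable GC values, bounded by `slack` (default 0.5% of n) so
the histogram still matches within 0.01 per bin; a larger unreachable
mass is an error naming the bin. At desk scale the default is 100,000
background regions (the full-scale analysis would use 1 million).

## Differential activity

Testing condition differences in $k$ alone would confound reporter
activity with input abundance and depth. Both are folded into per-peak,
per-library normalization factors inside a negative-binomial regression:

$$NF_{ij} = \frac{sf^{STARR}_j}{sf^{input}_j}\,\max(m_{ij}, u_{ij}, 1),$$

row-rescaled to geometric mean 1 across libraries, with $sf$ the
median-of-ratios size factors of the total-STARR and scaled-input count
matrices. The $\max(\cdot, 1)$ floor keeps offsets finite for peaks with
no input evidence in some library. Per peak we fit
$k_{ij} \sim \mathrm{NB}(\mu_{ij}, \phi_i)$,
$\log \mu_{ij} = \beta_0 + \beta_1 x_j + \log NF_{ij}$, by IRLS and
report the two-sided Wald test on $\beta_1$. The default differential
call uses unadjusted $p < 0.05$ with $|FC| \ge 2.5$; `adjusted = TRUE`
switches the rule to BH-adjusted p values.

**Dispersion.** With two replicates per condition a peak-wise dispersion
MLE is hopeless — it is biased low and makes the Wald test strongly
anticonservative. Two observations rescue it. First, residual
overdispersion beyond Poisson is largely shared across peaks, so a
pooled component $\phi_0$ can be estimated by summing Cox–Reid adjusted
profile likelihoods over a subsample of peaks. Second, the offsets are
themselves estimates: $\log NF_{ij}$ carries the Poisson noise of
$r_{ij}$, whose delta-method contribution to the log-scale variance is
$1/r_{ij}$. We therefore model

$$\phi_i = \phi_0 + c\,\overline{1/r_{i\cdot}}$$

and fit $(\phi_0, c)$ jointly by pooled adjusted profile likelihood.
The scale $c$ is estimated rather than fixed at 1 because the
$\max(m, u)$ selection and unique-count saturation make the analytic
term an upper bound. This replaces a peak-by-peak ML dispersion with an
input-coverage-indexed dispersion model; it is the package's own design
and differs from generic RNA-seq tools (which share information through
a mean-dispersion trend instead). The test suite checks the resulting
calibration (null p < 0.05 fraction within [0.03, 0.07]) and power
(4-fold effects at 9× coverage recovered with ≥ 80% power, observed FDR
≤ 10%) through the full generative pipeline.

## Classification

Putative chromatin enhancers (APK elements) are the ATAC peaks carrying
≥ 1 bp overlap with both P300 and H3K27ac peaks; reporting the ATAC
anchor keeps downstream signal windows on the accessibility summit, and
a raw bp-intersection mode exists. Per condition: final STARR peaks
overlapping "active" segmentation intervals are C1, other final peaks
are C2; APK elements that are not final peaks are C3 when the unadjusted
binomial p exceeds 0.1 in all four libraries and the element lies at
least `tss_min_distance` from an annotated TSS. "Near a TSS" has no
canonical distance; the default of 1,000 bp is recorded in the output
and configurable. Elements with a library p in
[0.05, 0.1] sit between "significant" and "demonstrably silent" and are
returned unlabeled with reason `ambiguous_signal` rather than forced
into a class; likewise `starr_signal`, `tss_proximal` and `no_records`
drops are recorded, so the output is an explicit partition of every
evaluated locus.

## The synthetic-data generator

The generator emulates the statistical structure the models assume:

- Region input intensity $\lambda_i \sim \Gamma(\text{shape} =
  \texttt{input\_dispersion}, \text{mean} = \texttt{input\_depth})$ —
  NB-marginal input counts, matching the differential stage's count
  model. Default depth 9 reads/region and median region length ~850 bp
  are the study conditions the pipeline targets; depth multipliers per
  library are log-uniform within 2-fold to exercise normalization, and
  library totals are genome-wide (background-dominated), so the
  input-to-STARR scaling ratio reflects depth, not peak enrichment.
- STARR counts $k_{ij} \sim \mathrm{Pois}(e_{ic}\lambda_i d_j)$ with
  planted enrichment $e$ (log-normal above a floor of 3 for active
  regions, 1 otherwise) and symmetric condition effects
  $e \cdot 2^{\pm l/2}$ for differential regions.
- Duplication: all libraries derive from one plasmid pool whose local
  complexity scales with input diversity, $C_i =
  \max(\texttt{complexity\_factor}\,\lambda_i, 1)$; unique counts follow
  the expected-distinct formula $u = C(1 - (1 - 1/C)^k)$ capped at $k$.
  An exact fragment-resampling mode validates the formula at small n.
  This saturation is what makes $\max(m, u)$ a stable trials bound at
  strongly active loci.
- Genome: random DNA in 10-kb blocks with per-block GC drawn uniformly
  in [0.35, 0.65], two chromosomes, regions placed uniformly without
  overlap.
- Chromatin: C1 and C3 regions carry all three marks plus an "active"
  interval (jittered inward so neighbouring regions stay bare), C2 and
  unlabeled regions carry none, TSSs are kept clear of C3 regions, and
  a label-noise rate flips coverage for robustness tests.

What it does **not** emulate: sequence-driven enhancer grammar, GC bias
of sequencing itself, transfection-efficiency variation, fragment-level
positional structure inside regions, mappability, or real chromatin
correlation structure. Passing tests therefore demonstrate statistical
correctness of the pipeline under its stated assumptions, not
performance on any particular real dataset.

## Numerical choices and degenerate inputs

- Coordinates are BED 0-based half-open at every file boundary; summit
  columns are absolute 0-based positions; book-ended intervals merge.
- $k = T = 0$: p = 1, raw enrichment undefined (flagged), shrunken
  enrichment $\alpha/\beta$; such loci are reported but can never pass.
- Beta-binomial fit: errors on all-zero successes or fewer than 100
  usable records; optimization on log-parameters keeps the domain open.
- NB fits that fail to converge are flagged and reported with p = 1
  (conservative), never silently dropped.
- Dispersion floor $10^{-8}$; IRLS capped at 30 iterations with a mean
  cap of $10^8$.
- `depth_convergence()` thins counts binomially (fraction grid 0.2–0.9)
  and re-derives unique counts through the duplication model so
  $u \le k$ survives thinning; library totals are scaled accordingly,
  and the full call (including fresh prior fits) is repeated per
  fraction.
- All randomness flows from explicit integer seeds; the demo derives
  per-stage seeds from one master seed and stamps every output with the
  config hash and seed, making reruns byte-identical.

## Problem sizes

The test suite and acceptance script run the statistical checks at the
sizes the methods are specified for: 5,000 candidate regions and 100,000
matched background regions for the empirical-FDR bound, 50,000 records
for beta-binomial parameter recovery, 2,000 peaks for differential
calibration and power, 1,000 regions (plus 1,000 randomized fixtures)
for classification, and 1,000 random instances for the interval-oracle
equivalences. The end-to-end reproducibility check uses a 400-region
demo, which exercises every stage in a few tens of seconds.

## Known limitations

- The dispersion model shares $(\phi_0, c)$ across all peaks; strong
  dispersion heterogeneity uncorrelated with input coverage would not be
  captured.
- The background sampler matches GC and length, not higher-order
  sequence composition, and its slack redistribution slightly smooths
  unreachable histogram tails.
- Luciferase batch correction removes any true signal component
  confounded with batch, as any linear batch regression does.
- The naive candidate source in the simulation (regions are known) means
  candidate-detection behaviour of external peak callers is entirely out
  of scope; candidate peaks are always an input.
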