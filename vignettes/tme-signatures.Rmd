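---
title: "Training and applying immune/stromal tumor-microenvironment signatures"
author: "tmesig maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Training and applying immune/stromal tumor-microenvironment signatures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tmesig)
```

## The problem

Bulk tumor expression profiles mix malignant cells with immune and
non-immune stromal cells. The composition of that microenvironment (TME)
carries prognostic information: immune infiltration is typically protective,
while a fibrotic/stromal phenotype is typically adverse. `tmesig` implements
a two-part system:

* a **training pipeline** that isolates the prognosis-linked immune and
  stromal transcriptional programs of a cohort and distils them into two
  gene signatures, and
* a **scoring pipeline** that converts any expression matrix into
  per-sample immune and stromal enrichment scores and a four-class TME
  subtype, using those signatures (or any signature pair supplied as a GMT).

## The training model, step by step

### Normalization

Expression is normalized gene-wise: z-score (population SD, i.e. the
`n`-denominator — one variant had to be fixed for bit-reproducibility and
both pass all rank-based checks) followed by min–max onto [0, 1]. The
min–max step last guarantees a non-negative matrix, which the factorization
requires. Constant genes cannot be scaled and are dropped with a count.
Z-scoring is applied across samples within each gene, the standard choice
for cross-sample comparability.

### Latent factors (NMF)

The normalized matrix `V` (genes × samples) is factorized as `V ≈ W H` with
non-negative `W` (genes × k) and `H` (k × samples) by the classical
multiplicative updates minimizing the generalized Kullback–Leibler
divergence. Each row of `H` is a per-sample *eigenvalue* — the activity of
one latent transcriptional program — and each column of `W` carries the
program's gene loadings. The updates guarantee a non-increasing objective;
entries are clipped at `1e-12` so multiplicative updates cannot lock at
zero, and initialization is seeded uniform noise scaled so the initial
reconstruction matches `mean(V)` — fits are deterministic given the seed.

The rank `k` defaults to 11 in `run_train()` (a typical choice for large
tumor cohorts); `select_k()` surveys candidate ranks by the cophenetic
correlation of consensus matrices over seeded restarts when a data-driven
choice is wanted. Rank provisioning matters: `k` must cover every major
transcriptional program *plus* a baseline component, otherwise two programs
share a factor and one eigenvalue degrades. On the default synthetic preset
(two planted programs, four noise programs) we use `k = 8` — the six
programs, a baseline, and one slack factor.

### Recognizing the immune and stromal factors

Each factor is annotated two ways: the hypergeometric enrichment of its top
100 weighted genes against user-supplied immune and stromal reference sets
(BH-adjusted across sets), and a univariate Cox fit of its eigenvalue
(Breslow ties). The immune factor must be significantly *protective*
(Wald p < 0.05, HR < 1) and maximally immune-enriched; the stromal factor
significantly *adverse* (HR > 1) and maximally stromal-enriched. The
direction constraints are hard requirements, so the two roles can never
collapse onto the same factor.

### Joint gene selection (ℓ2,1 multitask regression)

With the two eigenvalues as tasks `Y = (H_immune, H_stromal)` (z-scored by
default so the penalties act on a comparable scale), the model minimizes

$$\sum_{t}\|W_t^{\top}X - Y_t\|_F^2
  + \rho_1\|W\|_{2,1} + \rho_{L2}\|W\|_F^2,$$

where `X` is the normalized matrix and the ℓ2,1 norm sums the row-wise
(per-gene) Euclidean norms across tasks. The ℓ2,1 penalty zeroes whole gene
rows jointly across the two tasks — a gene is either in or out for both
programs — while the Frobenius ridge spreads weight across correlated
module genes instead of picking arbitrary representatives. The solver is
FISTA: accelerated proximal gradient with the row-wise group
soft-threshold as the proximal step, backtracking line search, restart of
the momentum whenever the cost would rise (so the recorded trace is
non-increasing), `W = 0` start, `tol = 1e-6`, `max_iter = 10^4`.

The penalties are exposed as configuration. `rho1_max()` gives the smallest
ℓ2,1 weight that zeroes everything; the pipeline default is
`rho1 = 0.2 * rho1_max` with `rhoL2 = 10`, which on the default synthetic
preset keeps ~170 of 2000 genes including every planted module gene. The
hyperparameters interact with cohort size and module strength, so
`rho1_grid()` is provided for data-driven sweeps.

### Consensus refinement and the sign split

The multitask gene list intentionally over-selects; differential expression
across a stable two-group structure cleans it up. Samples are
consensus-clustered (rank-2 NMF over `n_runs = 20` seeded restarts on the
gene-restricted matrix; co-assignment fractions; average-linkage cut at 2).
Per-run labels use the argmax of the *row-standardized* `H`: the raw argmax
is ill-posed because `WH` is invariant to rescaling individual factors, and
on skewed data it isolates only the extreme tail of one factor;
standardizing assigns each sample to the factor with the highest relative
activity and yields balanced, reproducible splits.

The cluster with the higher mean immune eigenvalue is the logFC reference,
so immune genes come out positive. Differential expression uses limma's
moderated t (a Welch-t fallback is available behind `moderated = FALSE`),
with BH adjustment over all genes. Multitask genes with adjusted P < 0.05
split by logFC sign into the immune (positive) and stromal (negative)
signatures; the adjusted-P reading is the default because the threshold is
introduced alongside BH adjustment, and a flag restores raw-P behavior.

### Scoring and subtypes

Signature scores are single-sample GSEA: per sample, genes are ranked by
decreasing expression (average ranks on ties; ties between equal ranks are
walked in gene-identifier order for determinism) and the enrichment score
integrates the difference between the weighted cumulative distribution of
signature genes (rank statistic `n - rank + 1` raised to `alpha = 0.25`,
the usual ssGSEA exponent, normalized over the signature) and the uniform
cumulative distribution of the remaining genes. Because only ranks enter,
scores are invariant to any strictly increasing per-sample transform —
which is what makes them portable across platforms and tolerant of missing
signature genes (absent genes are dropped with a floor of 10 per signature
and a warning below 50% coverage).

Raw scores are min–max normalized across the scored cohort. Subtypes are a
cohort-relative median split on each normalized score — strictly above the
median is "high", values exactly at the median are "low" — combined as
HH/HL/LH/LL with the immune axis first. The medians used are recorded in
the output so frozen thresholds can be re-applied to other cohorts.

### Marker ratios

`marker_ratio()` computes per-sample ratios of summed marker expression on
a linear scale. Bundled panels: the T-cell exhaustion ratio
(PD-1 + CTLA4 + LAG3 + TIM-3)/(CD28 + CD40LG), with PD-1 mapped to PDCD1
and TIM-3 to HAVCR2, and the angiopoietin ratio ANGPT1/ANGPT2. Samples
with a zero denominator are flagged `NA` rather than dropped.

## What the synthetic generator emulates — and what it does not

`simulate_tme()` plants the structure the training pipeline assumes:

* disjoint immune (60) and stromal (40) gene modules among 2000 genes,
  plus four 50-gene noise programs, each driven by a log-normal(0, 1)
  per-sample activity with loading 1.0 and Gaussian noise (SD 0.5);
* immune and stromal log-activities correlated at −0.7. Real cohorts show
  a polarized inflamed-versus-fibrotic axis, and the sign-split refinement
  *requires* it: a single two-cluster split can only make immune genes rise
  and stromal genes fall simultaneously when the two programs oppose each
  other. With weakly opposed programs the smaller module is under-recovered
  — a genuine property of the method, not of the simulator;
* exponential survival with log-hazard −0.8 per SD of immune activity
  (protective) and +0.8 per SD of stromal activity (adverse), baseline
  median 10 time units; ~30% of samples censored uniformly on (0, T);
* non-negativity by a global shift, not truncation, so module–activity
  correlations are preserved exactly.

It does **not** emulate batch effects, count noise, compositional
(purity) effects, correlated measurement error, or any mutation/CNA
structure. Tests passing on this generator therefore show that the
pipeline recovers the signal it is designed for; they do not show
robustness to artefacts the generator omits.

## Numerical and design choices

* Population-SD z-score; normalization order z-score → min–max (fixed).
* NMF: KL objective, seeded uniform init, `1e-12` clipping, relative
  objective change as stopping rule.
* Argmax ties anywhere break toward the lowest index, and top-gene ties
  toward the lexicographically smaller identifier, for reproducibility.
* Cox models use Breslow tie handling throughout; Harrell's C counts risk
  ties as 1/2; categorical covariates need explicit reference levels.
* Duplicate gene rows on input collapse to the max-mean row (a common
  microarray convention; the merge rule for array probes is otherwise
  unspecified, so it is a declared convention and logged).
* Samples without survival data are dropped, never imputed.
* Consensus per-run labels from row-standardized `H` (see above).

## Problem sizes used by the test suite

The end-to-end checks train on the default preset (2000 genes × 200
samples) across 20 seeds with `k = 8` and an NMF tolerance of `1e-5`, which
keeps a full training run around 20 s; unit tests use a 400 × 100 preset.
These sizes were chosen as the smallest at which every stage operates in
its intended regime (enrichment screens with a real universe, stable
consensus splits, adequately powered survival fits).

## Known limitations

* The two-cluster refinement assumes one dominant polarized TME axis; in
  cohorts where immune and stromal programs vary independently, the
  stromal arm of the split loses power (see the generator discussion).
* `rho1`/`rhoL2` have no universal defaults; the shipped values are tuned
  to the synthetic preset's scale and should be swept on real cohorts.
* Subtypes are cohort-relative by construction; comparing subtype labels
  across cohorts requires frozen medians, which the scoring output records
  but the package does not manage automatically.
* ssGSEA scores are comparable within a scored cohort (min–max across the
  cohort); single-sample deployment against a frozen reference range
  simply reuses recorded min/max values.

## A worked example

```{r example, eval = FALSE}
sim <- simulate_tme(sim_params(seed = 1))
refs <- make_reference_sets(sim$truth, rownames(sim$expression),
                            contamination = 0.2, seed = 1)
tr <- run_train(sim$expression, sim$clinical,
                immune_refs = refs["IMMUNE_REF"],
                stromal_refs = refs["STROMAL_REF"],
                k = 8, seed = 1, nmf_tol = 1e-5)
sc <- run_score(sim$expression, tr$signatures)
table(sc$subtypes$subtype)
```
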