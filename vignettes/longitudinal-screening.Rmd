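---
title: "Screening longitudinal proteomics with per-protein mixed models"
author: "longiprot"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening longitudinal proteomics with per-protein mixed models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(longiprot)
```

## The problem and the model

Longitudinal biofluid proteomics in small-animal disease models asks, for
each of hundreds to thousands of proteins, whether its abundance changes as
disease progresses within the same animals. The data are short panel series
— here three time points (baseline, a pre-symptomatic point T1, a
symptomatic point T2) from five or six mice — with two structural
nuisances: strong, stable between-animal abundance differences, and
pervasive missingness, from stochastic data-dependent MS acquisition up to
entire visits that could not be sampled.

`longiprot` fits, per protein, a linear mixed-effects model on log2
intensities:

$$y_{k,j} = (\beta_0 + \nu_{0,k}) + \beta_{1,j}\,\tau_j + \varepsilon_{k,j}$$

with time categorical (baseline as reference), a random intercept
$\nu_{0,k} \sim N(0, \sigma^2_{mouse})$ per mouse $k$, and i.i.d. Gaussian
residuals. The fixed coefficients $\beta_{1,j}$ are log2 fold changes of T1
and T2 versus baseline. The random intercept absorbs each animal's
baseline offset, so the time effects are estimated from within-animal
changes, and animals with missing observations still contribute whatever
they have. The model is deliberately minimal: no random slopes, no residual
autocorrelation, no variance moderation across proteins, no imputation.
Each protein is fitted independently.

## Pipeline order

1. **Ingest and exclusion.** Wide protein × sample tables (generic, or
   MaxQuant proteinGroups-style with `Intensity <sample>` columns and `+`
   flags) are read with raw-scale zeros treated as missing — the search
   engines' "not quantified" convention; a switch retains literal zeros for
   non-MS matrices. Assay-specific exclusion rules then remove
   contaminant-flagged rows and configured accessions: serum drops
   contaminants, albumin, serotransferrin and IgG constant regions (their
   residual levels track depletion efficiency, not biology); the sEV rule
   drops albumin and IgGs only (isolation-efficiency-dependent) and keeps
   serotransferrin. The shipped accession config is an editable stand-in
   (mouse UniProt accessions), not a reconstruction of any particular
   search database.
2. **Normalization** (after exclusion, so excluded high-abundance rows
   cannot distort totals). TMT: within-set loading correction then
   between-set reference calibration, both on raw (pre-log) intensities,
   then log2. Label-free: log2 then per-sample median centering.
3. **Eligibility.** Valid-value rules per dataset (below).
4. **Model fit, normality gate, omnibus test, BH** across the gate-passing
   proteins of one assay.

## Normalization details

**Within-set (loading).** Each channel's observed values are multiplied by
(mean channel total in the set)/(channel total); totals use observed values
only, since missing entries carry no intensity. Afterwards channel totals
within a set are equal; the map is idempotent. Note that the target — the
set's mean total — changes if the input channels are rescaled, so
renormalizing a rescaled table reproduces the original only up to one
constant per set (exactly, if the rescaling preserves the set's mean
total); relative channel factors are always recovered exactly.

**Between-set (reference calibration).** Each 10-plex set carries two
channels of one common pooled sample. For protein $p$ and set $s$ the
reference level $\mathrm{ref}(p,s)$ is the arithmetic mean of the observed
reference-channel intensities, and all of $p$'s values in $s$ are
multiplied by $\overline{\mathrm{ref}}(p,\cdot)/\mathrm{ref}(p,s)$. The
calibration is per protein — protein-specific correction factors — and the
averaging is arithmetic on raw intensities, consistent with running before
the log2 transform; this choice (rather than geometric/log-scale averaging)
is a documented convention of this package. A protein unobserved in a set's
reference channels cannot be calibrated for that set: its values there are
set to missing and reported, rather than mixing calibrated and uncalibrated
values within one model fit.

**Median centering** subtracts each sample's observed median (log2 scale),
correcting small loading differences in label-free runs; idempotent,
mask-preserving.

**PCA QC** scores use complete-case proteins, per-protein mean-centered,
unscaled — the simplest reproducible convention for a quality-control-only
output. After calibration the pooled samples should cluster centrally and
the leading component should no longer separate TMT sets; the test suite
checks exactly this on simulated batch structure.

## Eligibility rules

- serum rule: ≥ 4 valid values per time point;
- sEV rule: ≥ 3 valid values per time point;
- CSF rule: a valid value in every collected sample.

Counts are over animals with an observed value at that time point;
pooled-reference channels never count. Visits that never happened simply
contribute nothing — for CSF, where some animals miss whole time points,
"every sample" means every sample that exists. Thresholds are
config-surfaced; relaxing a threshold can only grow the eligible set
(tested as a monotonicity property).

## Estimation and inference choices

**Fitting.** The likelihood is profiled analytically over the fixed effects
and residual variance, leaving a one-dimensional search in the variance
ratio $\lambda = \sigma^2_{mouse}/\sigma^2$; with one grouping factor the
marginal covariance is block diagonal and each profile evaluation is closed
form. The search runs on $\log\lambda \in [-14, 14]$ with an explicit
boundary check at $\lambda = 0$. This gives millisecond fits — a screen of
thousands of proteins in seconds — while agreeing with `lme4` to ~1e-8 on
coefficients, variance components, likelihoods, and predicted random
effects (cross-checked in the test suite on balanced and unbalanced data).
ML is the default, REML an option; with 18 observations the two differ
little for the coefficients, and ML makes likelihood-ratio comparisons
valid.

**Standard errors and intervals.** Reported SEs, 95% CIs and the
coefficient covariance of the omnibus test always use the bias-adjusted
residual variance $RSS_V/(n-p)$, including under ML point estimation: the
ML variance divides by $n$, and at $n = 18$, $p = 3$ that downward bias
(factor 15/18) makes Wald intervals undercover badly. CIs default to the
normal quantile ($\pm 1.96\,SE$); a $t$ option on the containment degrees
of freedom is available. With the normal quantile, simulated coverage at
this design is ~0.91 — inside the accepted 0.90–0.99 band, slightly below
nominal because the small-sample $t$ width is not used by default.

**Normality gate.** Both the within-fit residuals and the random effects
should look Gaussian. The latent random effects are unobservable, so the
gate tests their predictions (the empirical best predictions / BLUPs of the
per-mouse intercepts). If the random-intercept variance collapses
(below $10^{-8}\times$ the residual variance) the predictions are all ~0
and the test is meaningless, as it is for constant vectors or n < 3: those
cases are *indeterminate* and the protein is excluded from testing with a
logged reason rather than crashing or silently passing. Constant-response
proteins (zero variance) likewise return a degenerate zero-effect fit and
route to the indeterminate gate. On Gaussian data the residual gate fails
at close to its nominal 5% (the fitted residuals are mildly constrained by
the projection, which pulls the rate slightly below α).

**Omnibus test.** The null hypothesis is
$\beta(T1) = \beta(T2) = 0$, tested jointly. The default refers the Wald
statistic $W/2$ to $F(2, \nu)$ with containment denominator df
$\nu = n - \mathrm{rank}(X) - (K - 1)$ ($K$ mice) — for the balanced
6-mouse design, $F(2, 10)$, which matches the classical repeated-measures
error stratum and what Satterthwaite approximation yields on balanced data.
This choice is deliberate: at these sample sizes the naive Wald chi-square
reference is badly anti-conservative (simulated null size ~0.09 at α=0.05,
with an extreme tail inflated by orders of magnitude — enough to destroy
FDR control across a 1000-protein screen), and the ML likelihood-ratio
chi-square is moderately anti-conservative. Both remain available
(`omnibus = "wald_chisq"`, `"lrt"`) for sensitivity analysis; the F default
is calibrated (simulated null size 0.050, KS distance from uniform < 0.01).

**Multiplicity.** BH step-up at FDR 0.05 (via `stats::p.adjust`,
brute-force-verified in tests), applied within one assay's screen across
gate-passing proteins only. Gate failures never receive q-values — the
discard-then-test order means the tested family is the gate survivors. Ties
share q-values; the procedure is deterministic.

## The synthetic-data generator

`simulate_longitudinal()` draws data exactly from the model above: protein
baselines uniform on 20–30 log2 units (typical raw MS intensity scale),
per-(protein, mouse) intercepts $N(0, \sigma_{mouse})$, categorical time
effects, Gaussian residuals, then exponentiates to the raw scale. Affected
proteins (an exact rounded count) get $|\beta(T2)|$ uniform on a configured
range with random (or all-positive) sign and $\beta(T1)$ half of
$\beta(T2)$ — the pre-symptomatic change smaller than the symptomatic one.
Noise defaults $\sigma_{mouse} = \sigma_{resid} = 0.5$ log2 units are
generic placeholders for biofluid MS data, not estimates from any specific
study. TMT designs distribute the 18 biological samples over three 10-plex
sets, add two pooled-reference channels per set whose expected value is the
per-set average of the protein's biological intensities, and inject known
per-channel loading factors and per-set offsets, all recorded in the truth
object. `apply_missingness()` then removes configured whole visits
(dropping the samples entirely — they never existed), applies MCAR
deletion, and MNAR deletion with probability
$\mathrm{logit}^{-1}((\theta - x)\,s)$ rising as log2 intensity $x$ falls
below a threshold $\theta$.

Presets mirror the study shapes the pipeline targets: `serum6x3` (TMT, 6
mice complete), `sev6x3` (label-free, one missing T2 and one missing
baseline in different mice), `csf5` (label-free, 5 mice, three missing T2
and one missing both baseline and T1).

What the generator does *not* emulate: peptide-level identification,
reporter-ion interference/compression, retention-time drift, shared
correlation of animals across proteins (per-protein independence matches
the fitted model; a shared-intercept realism mode is off by default),
non-Gaussian biological noise, and abundance-dependent variance. Passing
tests therefore demonstrate correctness of the pipeline under its own
assumptions, not robustness to every failure mode of real MS data.

## Validation and problem sizes

The test suite validates, on generated data with known truth: the
balanced-design oracle (fixed effects = group-mean contrasts, ≤ 1e-6, 50
proteins); effect recovery and CI coverage (500 proteins, true
$\beta(T2) = 1$; mean estimate within 0.05, coverage in 0.90–0.99); null
calibration (100 all-null replicates × 1000 proteins: mean false-discovery
proportion ≤ 0.07 at FDR 0.05 — per-replicate FDP is 0/1 under the global
null with hit probability near the Simes level 0.05, so ~100 replicates
are needed for the estimate to resolve that bound — and KS distance of
omnibus p-values from uniform < 0.1); gate calibration (1000 proteins,
failure rate within 3 Monte-Carlo SEs of 0.05, plus frozen-vector agreement
with an independent Shapiro–Wilk implementation); normalization exactness
(relative loading factors to ≤ 1e-10, reference equalization, zero medians,
idempotence); BH against a brute-force step-up oracle on vectors up to
length 10; eligibility semantics and conservation; and an end-to-end TMT
screen flagging a single large-effect protein among 20 nulls with
byte-identical reruns. Note the single-protein end-to-end scenario has an
inherent ~10% miss probability per random draw — the affected protein's own
residuals can fail the normality gate — which is why the calibrated
quantities above, not one-off flag counts, are the primary evidence.

## Known limitations

- The omnibus F reference and containment df are exact only for the
  balanced design; under heavy unbalance they are an approximation (though
  a far better one than the chi-square).
- Default z-based CIs run ~1–4 points below nominal coverage at n = 18;
  use `ci_df = "t"` for conservative intervals.
- No between-protein information sharing: low-abundance proteins with few
  valid values are simply excluded rather than stabilized.
- The CSF complete-case rule discards most proteins in sparse datasets by
  design; that is the rule's semantics, not a bug.
- Gene-symbol export falls back to accessions when symbols are absent;
  enrichment analysis itself is out of scope.
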