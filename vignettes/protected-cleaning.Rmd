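---
title: "Protected-design surrogate variable estimation and expression cleaning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Protected-design surrogate variable estimation and expression cleaning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(svclean)
```

## The problem

High-dimensional expression data carry systematic variation that has nothing
to do with the biology under study: scan-date batches, RNA quality, residual
sample handling. Because such artifacts affect many genes at once, they can
be estimated from the data themselves as sample-level latent factors —
*surrogate variables* (SVs) — and removed. The catch is that "remove
everything systematic" is not a well-posed goal: any real biological effect
that touches many genes (sex, a copy-number polymorphism, age) looks exactly
like an artifact to a latent-factor method. The analyst must therefore
declare up front, as a *protected model*, which effects are biology; the
cleaning then removes latent heterogeneity *orthogonal to that declaration*,
and everything left out of it is fair game for removal.

This package implements that workflow end to end and, just as importantly,
makes its failure modes measurable: its synthetic-data generators plant
known effects so that every claim — power gained for protected effects,
destruction of unprotected ones — is a computed number, not an anecdote.

## Model and procedure

Write the data as a genes-by-samples matrix $E$ (log2 scale, $G \times n$).
The working model is

$$E = B X^\top + \Gamma S^\top + U,$$

where $X$ ($n \times p$) is the protected design built from the declared
model (always including the intercept), $S$ ($n \times k$) holds the
surrogate variables, $\Gamma$ their gene loadings, and $U$ is noise.

**Choosing $k$.** `num_sv()` residualizes $E$ on $X$ and compares each
eigenvalue proportion of the residual cross-product with a permutation null:
every gene's values are shuffled independently across samples (destroying
sample-level structure, preserving each gene's marginal distribution) and
re-residualized on the same $X$. Component $i$ receives the finite-sample
permutation p-value $(1 + \#\{\text{perm} \ge \text{obs}\})/(B+1)$, and $k$
is the largest count of components significant at level $\alpha$
*contiguously from the first*. Defaults are $B = 20$ and $\alpha = 0.10$;
both are ordinary test parameters, so the procedure has a false-positive
rate of about $\alpha$ per dataset on pure noise — on ten null datasets,
one spurious SV is the expected outcome, not a defect.

**Estimating $S$.** `estimate_svs()` uses iteratively re-weighted
extraction. The initial $S$ is the leading right singular vectors of the
residualized data. Each iteration then scores every gene twice: an F-test of
$[X, S]$ against $X$ (association with the current SVs given the protected
model) and an F-test of $X$ against the intercept (association with the
protected effects). Both p-value sets are converted to posterior null
probabilities with a Storey-type $\pi_0$ (smoothed over the grid
$\lambda \in \{0, 0.05, \ldots, 0.95\}$) and a local false-discovery rate
built from a kernel density on the probit scale, made monotone in $p$. The
gene weight is
$w_g = P(\text{assoc. with } S) \times P(\text{null w.r.t. } X)$, and $S$ is
re-extracted from the row-weighted matrix $\mathrm{diag}(w)\,E$. Genes
driven by protected effects get weight near zero — that is the mechanism by
which declared biology survives the cleaning. Five iterations are the
default; with zero iterations the estimator reduces exactly to the
unweighted SVD of residuals, which the test suite pins as the
initialization contract. With an intercept-only protected model there is
nothing to shield, so the second factor of the weight is identically one.

**Cleaning.** `regress_out_svs()` fits the *joint* model $W = [X, S]$ per
gene and subtracts only the SV component: $E_{\text{clean}} = E -
\hat B_S S^\top$. Joint fitting matters: when $S$ correlates with $X$,
sequential residualization (project out $S$, ignore $X$) removes protected
signal, whereas under the joint fit the protected coefficients refit on
cleaned data equal the joint-fit coefficients exactly (to numerical
precision; the suite asserts $10^{-8}$ and constructs a correlated case
where the two routes demonstrably differ). The intercept — mean expression —
is always part of $X$ and therefore always retained.

Cleaned data are a visualization product. Testing hypotheses on them treats
estimated nuisance parameters as known, which biases significance
anti-conservatively; the API enforces the rule by refusing cleaned objects
in `fit_linear_models()`. Inference instead fits $[X, S]$ on the raw data
and moderates the variances.

**Moderated statistics.** `moderate()` shrinks per-gene residual variances
toward a common prior with the standard empirical-Bayes scaled-F model:
$\tilde s^2_g = (d_0 s_0^2 + d_g s^2_g)/(d_0 + d_g)$, hyperparameters by
moment matching on $\log s^2$ through the digamma/trigamma identities (the
trigamma inverse by monotone root finding on the log scale). Degenerate
inputs are handled as limits: when the spread of $\log s^2$ does not exceed
pure sampling noise the prior df is infinite and all variances pool; forcing
$d_0 = 0$ recovers ordinary t-statistics, which doubles as a regression
test. Genes with exactly zero residual variance are set to the smallest
positive one (with a message) before moment matching. The suite cross-checks
$d_0$, $s_0^2$ and the moderated t against the independent limma
implementation to $10^{-8}$. Multiple testing uses Benjamini–Hochberg.

**Known-batch comparison.** `combat_adjust()` implements the parametric
empirical-Bayes location/scale batch adjustment: standardize each gene with
the pooled fit (batch indicators plus optional protected covariates, the
grand mean taken as the sample-size-weighted combination of batch means);
estimate per-batch per-gene location and scale; shrink both toward
cross-gene priors (normal and inverse-gamma, method-of-moments
hyperparameters) by iterating the coupled point estimates to a relative
change below $10^{-4}$; back-transform. Two deliberate choices: the output
is re-centered per gene so the pooled grand mean is restored *exactly*
(plain EB shrinkage leaves a small residual location of the order of the
shrinkage fraction; re-centering is a per-gene constant and does not affect
batch-difference removal or covariate preservation), and batches of size one
or batch–covariate confounding are hard errors — the latter being precisely
the situation (e.g. a continuous RNA-quality artifact) in which a
known-batch method cannot be used at all and the surrogate-variable route
is the only option.

## Lifespan spline models

For expression across the human lifespan (fetal through old age, ages in
years with fetal ages negative) `lifespan_design()` builds three nested
shapes, each with an intercept and a birth-offset indicator
$\mathbf 1\{\text{age} > 0\}$ that allows a jump at birth — justified
because there are no third-trimester samples to enforce continuity:

* **A** — linear spline with a knot at birth (`age`, `max(age, 0)`; 2 df);
* **B** — quadratic B-spline with one interior knot at birth (3 df);
* **C** — quadratic B-spline with interior knots at birth, 1, 10, 20 and 50
  years (7 basis columns).

The conventional df counts (2, 3, 8) are not consistent under any single
rule: A and B count the age basis alone, while 8 for C counts the basis
*plus* the birth offset. `lifespan_df()` freezes exactly that convention so
the printed numbers are unambiguous. B-spline boundary knots sit at the data
range; basis evaluation is delegated to `splines::splineDesign()`-backed
`bs()`.

`age_smooth()` (used in the diagnostics) fits a GCV-tuned smoothing spline;
with `birth_offset = TRUE` each side of birth is smoothed separately and the
fitted jump is reported. Predictions are clamped to each side's data range —
splines extrapolate wildly across the third-trimester age gap otherwise.

## What the generators emulate — and what they do not

`simulate_stemcell()` produces a differentiation experiment: cell lines in
duplicate under three conditions (undifferentiated, mesendoderm,
neurectoderm). The default conditions were fixed once to reproduce the
qualitative structure of real differentiation series and then frozen:

* 30% of genes respond to treatment with 2-log2-unit shifts, split 60/20/20
  into a shared differentiation program (same shift in both differentiated
  conditions — this is what makes the dominant principal component a
  differentiation axis, as in real data) and mesendoderm-/neurectoderm-
  specific programs;
* scan-date batches act through a single shared factor (rank one) loading on
  30% of genes with per-batch levels standardized to sd 0.8 — "batch
  correlated with a global PC" by construction, landing on PC2 below the
  differentiation axis;
* ten Y-linked genes carry an 8-log2-unit male-only shift (a >256-fold
  difference, matching the extreme of a Y-linked transcript);
* twenty genes follow a 0/1/2 copy-number dosage at 3 log2 units per copy —
  a presence/absence polymorphism whose null state sits at background, which
  is what makes the dosage factor large enough for a latent-factor method to
  find and (when unprotected) remove;
* batch assignment at the default confounding degree 0 is *stratified*:
  exactly balanced within condition, so "no confounding" means independence
  by construction, not on average; degrees above 0 send that fraction of
  samples to a condition-linked scan date;
* per-line offsets (sd 0.2) and Gaussian noise (sd 0.5) complete the model.

`simulate_lifespan()` draws 269 samples with a fetal block (ages in
$[-0.5, -0.17]$), an infancy-heavy postnatal mixture and an adult tail to 80
years, leaving the third-trimester gap $(-0.17, 0)$ empty. Gene trajectories
come from four families — fetal exponential decay, a birth jump, a
childhood-confined quadratic bump (exactly flat outside $(0, 10)$), and a
late-life linear slope — plus a continuous RNA-quality-like factor loading
on 30% of genes.

Both generators record complete ground truth: `reconstruct_signal()`
rebuilds the noise-free matrix exactly, so the residual against the
generated data is pure Gaussian noise and every recovery experiment has an
oracle. What the generators do *not* emulate: probe-level physics (dye bias,
spatial artifacts, background), heavy-tailed or heteroscedastic noise,
within-line replicate correlation, and batch effects on the scale (variance)
of genes — the cleaning operator is location-based, and scale jitter is off
by default. Passing tests therefore demonstrate the algebra and the
statistical calibration of the methods under an additive Gaussian regime,
not robustness to every microarray pathology.

A note on the power experiments: under the default conditions the treatment
effect is strong enough that detection saturates near 100% with or without
SVs. The power-gain comparisons therefore run at the documented power-study
conditions (four lines, effect size 1 log2 unit, 24 arrays), where the gain
from SV adjustment is strict in essentially every seed.

## Numerical choices

* Quantile normalization maps each column to the reference distribution
  (row-wise mean of column-sorted values); a tie group spanning sorted
  positions $i..j$ receives $\mathrm{mean}(\text{ref}[i..j])$. The operation
  is idempotent and rank-preserving, and the tie rule is pinned by a
  brute-force oracle in the tests.
* Least squares everywhere via QR; rank deficiency is an error naming the
  offending columns, never a silent drop.
* SVD sign ambiguity: SVs are flipped so their first element is
  nonnegative; principal components so the largest-magnitude gene loading
  is positive.
* Missing values are rejected at load time; no silent imputation.
* The permutation workload of `num_sv()` is capped (configurable) so a
  pathological call fails fast rather than running unbounded.
* Every stochastic operation takes an explicit seed, restores the caller's
  RNG state, and records the seed in its provenance.

## Problem sizes

The test suite and the acceptance script run on simulated matrices of 300 to
2000 genes and 20 to 60 samples (269 for the lifespan design), ten seeds per
calibration claim — sizes chosen so the whole battery completes in a few
minutes while keeping every Monte-Carlo criterion comfortably away from its
sampling noise.

## Known limitations

* Duplicate replicates per line are treated as independent samples; no
  within-line correlation structure is modelled in inference.
* Only additive protected models (no interactions, no natural splines).
* Known-batch adjustment implements the parametric priors only, with no
  reference-batch or mean-only modes.
* The SV count procedure tests components contiguously from the first; a
  weak factor hiding behind a non-significant stronger one is not counted.
* Cleaned data are the supported input for visualization and the
  diagnostics module only; that restriction is enforced, not advisory.
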