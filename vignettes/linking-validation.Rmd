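---
title: "Validating three approaches to linking PF-10 scores onto the PROMIS physical-function T-metric"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating three approaches to linking PF-10 scores onto the PROMIS physical-function T-metric}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pfcrosslink)
```

## The measurement model and its assumptions

All computations rest on the graded response model (GRM) in
slope–threshold form. Item $i$ with $K_i$ ordered categories has a
discrimination $a_i > 0$ and strictly increasing thresholds
$b_{i,1} < \dots < b_{i,K_i-1}$ on the latent trait $\theta$; the
cumulative category probabilities are logistic,

$$P(X_i \ge k \mid \theta) = \frac{1}{1 + e^{-a_i(\theta - b_{i,k-1})}},$$

and category probabilities are adjacent differences. We use the pure
logistic metric (no 1.7 scaling constant) throughout, because that is
the convention of the PROMIS calibrations whose parameters a user will
supply; mixing metrics would silently rescale every slope by 1.7. Person
scores are expected a posteriori (EAP) estimates against a standard
normal prior, reported on the T metric, $T = 50 + 10\,\theta$. The
N(0, 1) prior is not sample-dependent by design: the T metric is only
meaningful relative to the fixed reference population, so scoring onto a
sample-centered prior would defeat the purpose of linking.

Unidimensional linking assumes the pooled item set (20-item anchor short
form plus the 10-item legacy scale) measures one construct, and that
items function equally across the groups being compared. The
`assumption_checks` functions screen both: a one-factor fit of the
polychoric correlation matrix with conventional benchmark flags
(CFI > 0.95, TLI > 0.95, RMSEA < 0.06, SRMR < 0.08), an exploratory
bifactor decomposition summarized by ECV (> 0.60) and
omega-hierarchical (> 0.80), and per-item DIF screening by nested
proportional-odds models with the Nagelkerke $\Delta R^2 > 0.03$ rule.

## The three linking approaches

**Item-level linking** (`item_level_link`) scores each person's PF-10
response pattern by EAP using fixed original-metric item parameters.
Partial patterns are scored on the observed items without proration —
pattern scoring handles missingness natively, and the half-scale
proration rule of summed-score scoring is a different convention that
belongs to the crosswalk side. Persons with no observed item on the
instrument cannot be scored and are dropped with a record.

**Crosswalk linking** (`build_crosswalk`, `apply_crosswalk`) tabulates,
for every achievable raw summed score $s$, the posterior mean and SD of
$\theta$ given $s$. The summed-score likelihoods $L(s \mid \theta_g)$
come from the Lord–Wingersky recursion over items; for a 10-item
3-category instrument the table spans raw scores 10–30 (21 rows). The
table is an exact lookup: no interpolation, and an out-of-range score is
treated as corrupt input rather than extrapolated, because the tabulated
range is mathematically exhaustive. Construction defaults to a N(0, 1)
prior; whether published tables used a normal or an empirical-histogram
prior is not documented in general, so the prior is injectable through
the grid argument. Applying a table requires a complete response
(a summed score is undefined otherwise); incomplete responders are
skipped and listed.

**Fixed-parameter re-estimation** (`calibrate_fixed`) re-fits the PF-10
item parameters by marginal-maximum-likelihood EM while the anchor
items' parameters — and the latent density — stay fixed at the
reference metric. We fix the latent density at N(0, 1) rather than
re-estimating its mean/variance: freeing it while anchoring items is a
legitimate alternative, but fixing both is the convention that most
directly transfers the metric, and the choice is exposed through the
grid's prior should a user want otherwise.

## Numerical choices

* **Quadrature**: 49 equally spaced nodes on $[-6, 6]$ with
  normal-density weights renormalized to 1. This resolves EAPs to about
  $10^{-3}$ on the $\theta$ scale (verified in tests against a
  2001-node grid), far below the 0.1-T reporting precision. Weighted
  prior moments are exact to ~$10^{-8}$ because the Gaussian's
  trapezoidal error is exponentially small.
* **EM convergence**: stop when the largest absolute parameter change
  falls below $10^{-4}$ (cap 500 cycles). The M-step maximizes each
  item's expected complete-data log-likelihood by quasi-Newton (BFGS
  with an analytic gradient) on the unconstrained scale
  $(\log a,\, b_1,\, \log \text{gaps})$ — the log-gap
  reparameterization keeps thresholds ordered by construction — with a
  safeguard that never accepts a worse objective, preserving EM ascent.
  The observed-data log-likelihood trace is returned and tested to be
  nondecreasing.
* **Sparse categories**: a free-item category observed fewer than 5
  times is collapsed into its neighbor toward the modal category before
  estimation, with the mapping recorded and re-applied at scoring time.
  At clinical sample sizes a 3-category item with a rare top category is
  otherwise unidentifiable in its upper threshold.
* **Polychoric correlations**: two-step estimates (thresholds from
  marginals, $\rho$ by 1-D likelihood maximization on the open
  $(-1, 1)$), with the bivariate normal CDF computed by 48-node
  Gauss–Legendre quadrature on the arcsine-substituted
  correlation-parameter integral; the substitution removes the
  square-root singularity so accuracy is ~$10^{-8}$ even at
  $|\rho|$ near 1. Structurally inestimable pairs fall back to Spearman
  with a warning.
* **Factor fits**: unweighted least squares on the polychoric matrix
  (iterated principal axes), with eigenvalue clipping at $10^{-6}$ for
  indefinite matrices and Heywood communalities capped at 0.995. Fit
  indices use the $\chi^2$-type statistic $T = (n-1)F$ with the
  standard CFI/TLI/RMSEA/SRMR formulas. This is an approximation: it is
  *not* the WLSMV estimator used in production CFA software, and its
  printed indices should be read as benchmark flags, not as
  reproductions of published WLSMV values.
* **Bifactor indices**: promax-rotated ULS factors, a second-order
  one-factor fit to the factor correlations, and Schmid–Leiman
  orthogonalization. Second-order loadings keep their signs (a
  reflected first-order factor must contribute negatively in the
  product), and extracted factors with negligible loading sums of
  squares are dropped before rotation — forcing four factors onto a
  perfectly unidimensional matrix is otherwise rotation-indeterminate.
* **DIF**: proportional-odds fits via `MASS::polr`; the intercept-only
  log-likelihood has the closed form $\sum_k n_k \log(n_k/n)$ and is
  the Nagelkerke baseline for *both* M1 and M3, so $\Delta R^2$ is a
  difference of comparable quantities. $\Delta R^2$ compares M3
  (trait × group) against M1 (trait only): total DIF, uniform plus
  non-uniform, matching the single published criterion. No iterative
  purification of the matching trait is applied — the matching score is
  a single-pass pooled EAP — since purification is a refinement the
  screening rule does not require.
* **Agreement**: the mean difference is *observed − linked*; the paired
  SMD divides by the pooled SD of the two score sets,
  $\sqrt{(s_o^2 + s_l^2)/2}$. The pooled-SD denominator is the one
  under which published per-sample SMD tables reconcile exactly with
  their own mean-difference and SD columns (an SD-of-differences
  denominator contradicts them). Bootstrap CIs are percentile intervals
  over B = 1000 person-level resamples with a mandatory seed. Report
  tables round to 2 decimals, half away from zero.

## What the synthetic generator emulates — and what it does not

`synthetic_config()` encodes the study conditions: three clinical
subsamples of 185, 172 and 262 persons whose latent traits are normal
with means/SDs obtained from the subsamples' benchmark T-score profiles
through the only transform the metric admits, $\theta = (T - 50)/10$:
N(−0.65, 0.78), N(−1.06, 0.90), N(−0.60, 0.86). The anchor bank (20
items, 5 categories) draws slopes from U(1.5, 3.5) and threshold centers
from U(−2.5, 1.0) with offsets (−1.5, −0.5, 0.5, 1.5); the linked bank
(10 items, 3 categories) draws from U(1.2, 3.0) and U(−2.5, 0.5) with
offsets ±0.8. These ranges put the 10-item instrument's marginal
reliability near 0.85–0.90, consistent with the high observed
correlation between the real instruments. Contamination defaults are
43/667 reversed-coding responders and 5/667 wholly missing
questionnaires — the rates behind the realistic exclusion screen.

The generator is *correctly specified* for the linking model:
unidimensional, GRM-distributed, no DIF between subsamples (DIF can be
planted explicitly for power tests). Passing tests therefore show that
the three approaches agree when their assumptions hold; they do not
show robustness to multidimensionality, local dependence, floor/ceiling
compression of the legacy scale, or disease-related DIF — all of which
real data may exhibit. In particular the legacy scale's restricted
measurement range, a known driver of disagreement at the extremes of
the continuum, is only partly emulated by its narrower threshold range.

The reversed-coding detection rule is our construction (real screens
rarely document one): a person is flagged when their standardized
within-subsample scores on the two instruments conflict in sign by more
than 3 SD, or when the linked responses are more likely under the
reversed key than the normal key by more than 5 nats at the person's
anchor-based EAP $\theta$. Both thresholds are exposed, and the rule is
validated only against planted synthetic truth (sensitivity ≥ 0.9,
false-positive rate ≤ 0.01 in tests) — it is never claimed to reproduce
any particular study's exclusion count beyond expectation.

## Design points that were genuinely open

* **Partially missing legacy patterns before linking**: complete cases
  are the natural summed-score convention, but EAP needs no proration,
  so pattern-based approaches score partial patterns and only the
  crosswalk enforces completeness. Both behaviors are surfaced rather
  than hidden behind a single rule.
* **Metric-transfer evaluation**: EAP estimates shrink toward the prior
  mean, so the mean of linked $\theta$ in a low-functioning sample is
  biased toward zero by roughly (1 − reliability) · |mean| even under
  the true generating parameters. Metric transfer after re-estimation
  is therefore judged by comparing scores under re-estimated versus
  generating parameters (which shrink identically), not by comparing a
  shrunken mean against the unshrunken generating mean.
* **DIF grouping**: with no demographics in the synthetic samples, the
  three-level clinical-sample label is the default grouping, entered as
  dummy variables in M2/M3; for real data any factor works, and an age
  median split is the recommended default when age is continuous.

## Problem sizes used by the test suite

Unit tests run at deliberately small scale: oracle equivalences on 2–10
item banks, recovery simulations at n = 500–4000, DIF calibration at
n = 619–1000, and the end-to-end pipeline at 60–70 persons per
subsample (with bootstrap B = 200) plus one full-size correctly
specified run (n = 619, the study split) for the headline agreement
bounds. These sizes were chosen as the smallest at which the respective
statistical claims are stable across seeds.

## Known limitations

* The factor-analytic indices approximate WLSMV output only in spirit;
  real-data index values from production SEM software will differ,
  especially RMSEA.
* The EM calibration assumes ignorable missingness and a fixed latent
  density; nonignorable dropout or true latent-scale drift violate it.
* Bifactor indices on forced group factors are descriptive; with
  strongly unidimensional data the group-factor split is
  noise-driven and ECV should be read qualitatively.
* Equipercentile linking is deliberately out of scope.
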