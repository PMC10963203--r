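---
title: "Calibration estimation of small-domain totals under unit non-response"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calibration estimation of small-domain totals under unit non-response}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(domcalib)
```

## The estimation problem

A finite population `U` of `N` units is partitioned into `L` domains, and
the target is the total `Ya` of a study variable `y` in each domain. An
SRSWOR sample of size `n` splits into `n1` respondents and `n2`
non-respondents; an SRSWOR subsample of `n2r` non-respondents is
re-contacted (Hansen–Hurwitz device), so the usable sample has `n1 + n2r`
units with base design weights `d1 = N/n` and `d1 * k`, `k = n2/n2r`. The
base weighted total is design-unbiased for the population total `Y` but
says nothing sharp about a small domain.

The package's estimators adjust the base weights, per domain, so that the
weighted auxiliary sums hit the domain's respondent and non-respondent
auxiliary totals `(X1a, X2a)`, moving minimally in the chi-square distance
`sum (t - d)^2 / (2 d q)` per stratum. The q-weights select the system:
`q = 1/x` collapses to the classical ratio estimator, `q = 1` to GREG, and
two implicit systems give multiplicative weights `d * exp(l x)`
(exponential) and `d * eta^x` (power), intended for positively skewed
auxiliaries where a heavy right tail should be up- or down-weighted
smoothly rather than linearly.

Two structural facts are worth stating plainly:

* **Indirect (synthetic) estimation.** The calibration constraint and the
  estimate both run over the *full* respondent sample and non-respondent
  subsample, calibrated to the *domain's* totals. This borrows strength
  from surrounding units when few sampled units fall inside the domain —
  at the price of design bias whenever the domain's own `y/x` ratio
  deviates from the population-wide one. The bias is intrinsic to the
  method (all four systems are design-biased for `Ya`) and is exactly what
  the Monte Carlo engine measures. `estimate_all(scope = "direct")`
  restricts sums to in-domain units for comparison; indirect is the
  default.
* **Exponential and power coincide.** Solving the constraint
  `sum d x eta^x = X_a` exactly in `eta` is the same problem as
  `sum d x exp(l x) = X_a` in `l = log(eta)`. Presentations that truncate
  the two systems' series-defined q-constants at different orders obtain
  different numbers; this package solves the constraint itself, for which
  the two systems are one family parameterized two ways. Both names are
  kept in the interface, and the equality `eta = exp(l)` is asserted in the
  test suite rather than hidden.

## Two-phase (double) sampling

When `(X1a, X2a)` are unknown, a first-phase sample — here a per-domain
SRSWOR of `floor(f * Na + 0.5)` units, default `f = 0.6` — measures `x`,
and its Hansen–Hurwitz domain totals `x1a' = sum d' x` (respondents) and
`x2a' = sum d' k' x` (subsampled non-respondents) replace the unknown
targets. The per-unit first-phase weight is the exact inverse inclusion
probability `Na / n'a`. Phase-1 weights are calibrated to `(x1a', x2a')`;
phase 2 draws `n''` units from the whole phase-1 sample (conditional weight
`n'/n''`), and its weights — each unit's *own* phase-1 calibrated weight
times the phase-2 design weight(s) — are calibrated to the same targets.

Two design choices resolve ambiguities in this chaining:

* **Nested non-respondent subsampling.** Only phase-1-subsampled
  non-respondents have `x` observed, so the phase-2 non-respondent
  subsample is drawn from phase-2 units already in the phase-1 subsample.
  Every chained weight is then defined and weights multiply across phases.
* **Same auxiliary at both phases.** The phase-2 constraint matches the
  phase-1 weighted totals of the same `x`; no second auxiliary is modeled.

Consequences worth knowing: under `y = beta * x` exactly, a two-phase
estimate equals `beta * (x1a' + x2a')` — exact relative to the *estimated*
targets, hence equal to `Ya` only when phase 1 is a full-response census.
And the census limit (phase-1 fraction 1, full response) reproduces the
single-phase estimate exactly for the ratio system, whose phase-1
adjustment is a scalar that cancels; for GREG the phase-1 multiplier
re-weights units by `1 + l x`, so exact equality cannot hold under
indirect calibration. Both facts are asserted in the tests at precisely
that strength.

## The synthetic population generator

The generator emulates the structure of the reference population behind the
packaged domain totals (`swedish_totals()`): 203 units in six domains of
sizes 48/32/38/41/15/29, about 30% of each domain in a fixed
non-respondent stratum, a positively skewed auxiliary, and `y` roughly
proportional to `x`. Defaults, chosen once:

| parameter          | default | meaning / rationale                               |
|--------------------|---------|---------------------------------------------------|
| `domain_sizes`     | 48/32/38/41/15/29 | the reference domain sizes              |
| `nonresponse_rate` | 0.30    | the reference non-response level; realized count is `floor(rate * Na + 0.5)` — half-up rounding is what reproduces the reference stratum counts (a 15-unit domain has 5 non-respondents, not 4) |
| `x_skew_shape`     | 1       | `sdlog` of the lognormal auxiliary; skewness ≈ 6, a strong but realistic right tail for municipal real-estate values |
| `link_slope`       | 1.8     | ≈ the reference `Ya/Xa` ratios (1.5–2.4 across domains) |
| `noise_scale`      | 0.3     | relative dispersion of `y` about `beta x`; puts domain SRSEs in the tens of percent at `n = 70`, the regime such studies report |

With `target_totals` supplied, `x` and `y` are rescaled multiplicatively
per domain and stratum so the realized stratum totals match exactly;
rescaling preserves the shape of the skewed law while pinning the totals.
The non-respondent stratum is drawn once per population and then fixed —
the Hansen–Hurwitz construction and fixed reference stratum counts
presuppose deterministic strata — and is assigned completely at random
within each domain, a stand-in for an unknown real designation mechanism.

What the generator does *not* emulate: spatial or serial correlation,
response propensity tied to `x` or `y` (informative non-response),
measurement error, or domain-specific slopes. Tests passing on these
populations therefore certify the estimators' algebra and design
properties, not robustness to informative non-response.

## Numerical choices

* Linear systems use the closed-form multiplier
  `l = (target - sum d x) / sum d q x^2`; only a vanishing denominator is
  an error. Negative calibrated weights are possible (chi-square
  calibration does not bound weights), permitted, and counted per estimate
  (`negative_weights`); chained two-phase baselines may therefore be
  negative, which the linear solve accepts.
* The exponential/power constraint is solved by Newton–Raphson from
  `l = 0` with the analytic derivative, safeguarded by bisection on a
  sign-bracketing interval that starts at ±50 on the max-rescaled axis and
  doubles until it straddles the target (a large dynamic range in `x`
  needs a wide bracket). Rescaling `x` by its maximum prevents `exp`
  overflow; the multiplier is transformed back. Convergence is a relative
  constraint residual ≤ 1e-10 within 100 iterations; failures carry
  diagnostics and surface as `NA` cells, never as silent values.
* Consistent targets return the identity element exactly (`l = 0`,
  `eta = 1`), so calibration leaves base weights untouched — asserted as
  an identity, not a tolerance.
* Degenerate replicates: no sampled non-respondents means the respondent
  constraint alone is applied and the estimate is flagged `degenerate`;
  a domain with no phase-1 respondents is non-estimable for that
  replicate. Both are counted in simulation output, not dropped silently.

## The Monte Carlo engine

`run_study()` repeats draw → response realization → subsampling →
calibration per estimator and domain, then aggregates
`ARB = 100 |mean(T) - Ya| / Ya`, `SMSE = mean (T - Ya)^2`, and
`SRSE = 100 sqrt(SMSE) / Ya`. One master seed drives a single sequential
replicate stream, making the whole study reproducible bit-for-bit. Failed
solver cells drop only that (estimator, domain, replicate) cell, with
`reps_used` reporting the effective count. The base Hansen–Hurwitz
estimator targets the population total and is reported as one
population-level row.

Problem sizes used in the packaged checks: the shipped test suite runs
studies of 25–2000 replicates on the 203-unit population and 30-unit toy
populations (20000 replicates for the design-unbiasedness check);
`scripts/acceptance.R` uses 1500 single-phase and 600 two-phase
replicates. These are the package's own desk-scale defaults; the
full-scale studies (15000/6000 replicates) are a `reps` argument away.

## Known limitations

* Unit non-response only; item non-response is out of scope.
* The first stage is SRSWOR; no unequal-probability or stratified designs.
* No analytic variance estimators for a single realized estimate — the
  package evaluates estimators by simulation, as design-based comparisons
  of biased estimators require.
* Exact reproduction of results computed from the original unit-level
  Swedish municipality data is impossible from published information
  (only domain totals are public); the generator provides a synthetic
  stand-in matching those totals.
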