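---
title: "Unanchored simulated treatment comparison for survival: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Unanchored simulated treatment comparison for survival: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stcsurv)
```

## Why an unanchored comparison

Standard indirect comparison (network meta-analysis) needs a common control
arm. When control arms are incomparable — the motivating situation is
first-line renal cell carcinoma trials whose sunitinib control arms
received very different amounts of PD-1/PD-L1 rescue therapy — anchoring on
them biases the comparison, and an unanchored population-adjusted method is
needed. `stcsurv` implements the outcome-regression flavour (simulated
treatment comparison, STC): a covariate-adjusted survival model is fitted
to the index trial's IPD and evaluated at the comparator trial's aggregate
baseline characteristics, so the target population is the comparator's.
Unlike weighting methods (MAIC) followed by a Cox analysis, nothing here
assumes proportional hazards: the index arm gets a full parametric curve,
the comparator is represented only by its (reconstructed) Kaplan-Meier
data, and effects are read off as RMST differences and time-varying
landmark hazard ratios.

The price of working unanchored is well known and applies to this package:
validity rests on the regression containing *all* prognostic factors and
effect modifiers, which is untestable; and prediction is at mean covariate
values, not averaged over the target population (by non-linearity these are
not identical, though usually close). Both limitations are inherited from
the method, not artifacts of the implementation.

## Models

Six AFT families (exponential, Weibull, gamma, log-logistic, log-normal,
generalized F) model `S(t|X) = S0(t * theta)`, `log theta = mu + X . beta`,
so positive coefficients shorten survival and `beta = log 2` halves the
expected survival time per unit of covariate. Gompertz is kept in
proportional-hazards form. Royston-Parmar splines model
`g(S) = s(log t, gamma) + X . beta` with a restricted cubic spline `s` and
the hazard / odds / normal links; covariates act on the intercept
coefficient only (no time-varying covariate effects). We use the convention
`S = pnorm(-eta)` for the normal link, i.e. `eta` increasing in log time,
matching the nested log-normal parameterisation; an equivalent formulation
writes the link as the survival quantile with the sign of `gamma` flipped.

Internal knots sit at equally spaced quantiles of the log uncensored event
times, boundary knots at its extremes (m = 1: median; m = 2: 33.3/66.7th;
m = 3: quartiles). "1-knot" counts internal knots: the default candidate
space of 16 distributions is the 7 parametric families plus
{1, 2, 3 knots} x {hazard, odds, normal}.

### Fitting and numerical choices

Maximum likelihood under right censoring is delegated to `flexsurv`
(`flexsurvreg` / `flexsurvspline`), the standard engine for these models;
knots are placed by this package and passed in, so the placement rule is
the one documented above regardless of engine defaults. Coefficients are
re-expressed on the package's acceleration scale (`flexsurv` places
covariates on each family's location parameter; the mapping is a sign flip
for scale/meanlog/mu-located families). All prediction, basis, link and
hazard evaluation is implemented in the package from the stored
coefficients, and is cross-checked against the engine in the test suite.

Continuous covariates (anything not coded 0/1) are centered at their IPD
sample means before optimisation, recorded in the model's `centering`
field. This is numerically helpful and mathematically neutral: the
likelihood and `beta` are unchanged, only the intercept shifts; the test
suite asserts this invariance.

A failed fit is retried up to four times from jittered method-of-moments
starting values; spline fits falling back to starting values derived from
the nested m = 0 parametric analogue (with zero knot coefficients). A fit
that still fails, or whose fitted `s(u)` is not non-decreasing over the
observed log-time range (an invalid survival function), is returned with
`converged = FALSE` and excluded by model selection — exclusion, rather
than constrained optimisation, keeps the selection filter simple and
conservative. Model variance-covariance matrices are stored for
diagnostics only; all reported uncertainty comes from the bootstrap.

## Two-stage selection and sensitivity set

Searching distributions and covariate subsets jointly would be 16 x 2^p
fits; the workflow assumes the optimal covariate choice does not depend on
the baseline distribution. Stage 1 fits all 16 candidates without
covariates and ranks converged fits by AIC (ties: fewer parameters, then
candidate order — the tie-break is this package's choice). Stage 2
exhaustively fits every covariate subset (2^10 = 1,024 by default;
capped at p = 16) on the winning distribution, keeping the ten best as a
report. Two covariate strategies are exposed, `aic_subset` (the search
winner) and `all_reported` (adjust for every candidate covariate the
comparator reports), because published practice uses both; the run
manifest records which was used. The sensitivity set has six entries: the
next three stage-1 distributions with the selected covariates, the winner
with all and with no covariates, and a naive KM-only comparison.

## Comparator data: reconstruction and hazard smoothing

Published comparators arrive as digitized KM coordinates, a
numbers-at-risk table, an optional total event count, and a baseline-characteristics-table-style
baseline summary. Digitized survival is clamped to its running minimum
(with a logged clamp count) and anchored at (0, 1); values outside [0, 1]
by more than 0.005 are rejected.

Pseudo-IPD is recovered by the iterative Guyot algorithm: censorings are
spread uniformly within each risk-table interval and their count adjusted
until the implied number at risk matches the published one, then events
follow from the survival drops. Three implementation details are worth
stating. Subjects still at risk at the last digitized time are emitted as
administratively censored there (otherwise they silently vanish and all
at-risk counts are understated). The final interval, which has no
right-hand at-risk constraint, assumes censoring continues at the earlier
*per-person-time* rate rather than a span-proportional count — by the tail
the risk set is far smaller, and the span-proportional guess systematically
overstates late censoring. Finally, when the total event count is reported,
the reconstruction is calibrated to it exactly by swapping events and
censorings at the digitized points where the integer rounding was most
marginal; a same-point swap leaves every at-risk count intact, so the
calibration cannot break risk-table consistency. Round-trip fidelity
(simulate, render, reconstruct, compare KM curves) is measured in the test
suite; reconstruction error is dominated by 1/n-at-risk granularity in the
curve tail.

The comparator hazard for landmark ratios is a kernel-smoothed
Nelson-Aalen estimate: Epanechnikov kernel on the increments `d_i/n_i`,
with a cut-and-renormalise boundary correction (the kernel mass inside the
observed window divides the estimate) and default bandwidth
`(t_last - t_first_event)/8`, configurable in months. The smoother choice
is this package's; landmark-ratio checks therefore use tolerance bands
around known truths rather than exact values.

## Estimands and uncertainty

RMST is truncated at the shorter of the index horizon and the comparator
follow-up. The index RMST integrates the predicted parametric curve
(composite trapezoid from 10,000 intervals, doubled until successive
estimates agree to 1e-6 relative); the comparator RMST is the exact
rectangle area under its KM step function, extended flat (with a warning)
in the rare replicate whose resample ends short of the truncation time.
Landmark hazard ratios are `exp(log h_index(t) - log h_comp(t))` with the
index hazard analytic from the model; HR < 1 favours the index treatment.

Uncertainty is a dual bootstrap: each replicate resamples index subjects
and comparator pseudo-IPD rows with replacement, refits the *fixed* model
specification (knots re-placed as data-derived quantities, coefficients
re-estimated; distribution and covariate selection are not repeated —
freezing selection before the bootstrap is a declared simplification), and
recomputes every estimand. Replicate medians are reported with 2.5/97.5
percentile intervals — percentile, rather than another bootstrap flavour,
is the package default — and one-sided p-values use the add-one estimator
`p = (1 + #(diff_b <= 0)) / (B + 1)` (and `#(log HR_b >= 0)` for ratios),
which cannot return exactly zero. Non-converged replicates are dropped and
counted; more than 20% dropped aborts the comparison as an unstable
specification. With the seed fixed in `stc_config()`, a rerun is
bit-identical down to the results CSV.

When a comparator does not report a selected covariate, the covariate is
dropped and the model refit on the reduced set (`align_covariates()` plus
refit), so different comparisons may legitimately use different
regressions; the run manifest records the per-comparator dropped
covariates. Binary covariates plug in reported proportions; continuous age
plugs in the reported central value (published tables typically give
medians — using a median where a mean is ideal is a declared
approximation, and both are supported).

## The synthetic-data generator

`generate_ipd()` draws event times by inverse transform from any supported
family (numeric link inversion for splines), with Bernoulli and normal
covariates acting through the model's own linear predictor, and censoring
as the minimum of an administrative cutoff and an exponential random
censor. `render_comparator()` then "publishes" an arm: KM computed, clicks
taken at the KM step times (thinned evenly to the point budget — a
digitizer clicks where the curve visibly steps; an equally spaced grid
would bound reconstruction fidelity by the inter-click event mass rather
than by algorithm quality), optional bounded uniform jitter then
re-monotonisation, numbers at risk tabulated at fixed intervals, and
covariates summarised as proportions/medians. `make_rcc_scenario()`
assembles an RCC-flavoured study: an index arm (n = 350 by default, ten
baseline covariates with realistic marginals — age ~ N(62, 9), IMDC
favourable 0.31, lung lesions 0.71, and so on), four comparator bundles
with deliberately different reported-covariate subsets so the alignment
path is exercised, Weibull event times (shape 1.25, index scale 42 months,
comparator scale 32) and light random censoring under trial-length
administrative cutoffs. A `null_effect` switch zeroes all covariate and
between-arm effects for coverage studies.

What passing tests on these fixtures shows — and what it does not: the
generator produces clean, correctly specified data (no covariate
missingness, no informative censoring, true model inside the candidate
set, digitization error bounded at 0.005). Green tests demonstrate the
estimators and algorithms are implemented correctly and recover known
truths under fair conditions; they do not certify performance under model
misspecification, unmeasured confounding, or sloppy digitization, which
are the real hazards of unanchored comparisons.

## Validation problem sizes

The test suite and `scripts/acceptance.R` use problem sizes chosen to make
Monte-Carlo assertions sharp while keeping a full run in minutes on one
CPU: nesting identities on 20 datasets of n = 300; Guyot round trips on 25
arms of n = 200-500 with 20-45% censoring, 100-150 digitized points and
6-month risk tables (fixture shape mirrors advanced-RCC OS: Weibull shape
1.25, scale 34-46 months, 48-month horizon); Wald coverage over 200
replicates of n = 2,000; stage-2 recovery of a beta = 1 covariate among 5
noise covariates over 30 replicates of n = 800 (the 10-covariate search is
exercised for its count, 1,024, not repeated per replicate); estimand truth
with exponential(0.1) vs exponential(0.2) arms at B = 300, and landmark
ratios at n = 10,000 vs 50,000; null coverage over 50 repetitions at
B = 200.

## Known limitations

* Unanchored logic: no randomisation is preserved; omitted prognostic
  factors or effect modifiers bias the comparison undetectably.
* Prediction at mean covariates, not population-averaged survival.
* Selection is frozen before the bootstrap, so selection uncertainty is
  not propagated.
* No extrapolation beyond the shorter trial horizon is attempted anywhere;
  the estimands are defined within follow-up.
* Interval/left censoring, time-varying covariates and competing risks are
  out of scope.
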