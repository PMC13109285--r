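---
title: "Anchor-based MIC estimation for the FIM: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Anchor-based MIC estimation for the FIM: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(micfim)
```

## The problem

Rehabilitation outcomes on the Functional Independence Measure (FIM) are
only interpretable once we know how large a change matters. The *minimal
important change* (MIC) is the smallest change score that patients or
clinicians consider important; a change beyond the MIC is read as
clinically meaningful. micfim estimates the MIC of the FIM motor
(13–91 points), cognitive (5–35) and total (18–126) scores from a
dichotomous *anchor* — here whether the patient was discharged home
(improved, coded 1) or elsewhere (0).

## The estimators

Let $X$ be the change score (discharge − admission) and $A$ the anchor.

**ROC/Youden (`mic_roc`).** The cutoff $c$ maximizing the Youden index
$J(c) = \mathrm{se}(c) + \mathrm{sp}(c) - 1$, with sensitivity defined as
$P(X \ge c \mid A=1)$: higher FIM change is better, so change at or above
the cutoff classifies a patient as improved. Candidate cutoffs are the
midpoints between consecutive distinct observed change values — on integer
scores these are half-integers, which is why ROC-based MIC values are
typically reported as x.5. On ties in $J$ we return the smallest tying
cutoff, the conservative choice (the smallest change labelled important).

**Predictive modeling (`mic_pred`).** Fit the logistic regression
$\operatorname{logit} P(A=1 \mid X=x) = C + Bx$ and solve for the change
score at which the posterior odds equal the pre-test odds
$\mathrm{odds}_{pre} = p/(1-p)$, $p$ the improvement prevalence:

$$\mathrm{MIC}_{pred} = \frac{\ln(\mathrm{odds}_{pre}) - C}{B}.$$

**Bias-adjusted predictive modeling (`mic_adj`).** When the improved
proportion is not 50%, $\mathrm{MIC}_{pred}$ is biased — upward for
prevalence above one half, downward below. The adjustment subtracts an
estimate of that bias,

$$\mathrm{MIC}_{adj} = \mathrm{MIC}_{pred} - S\,\ln(\mathrm{odds}_{pre}),
\qquad S = 0.09\,SD_{chang} + 0.103\,SD_{chang}\,\mathrm{Cor},$$

where $SD_{chang}$ is the sample standard deviation of the change score
(n − 1 denominator, the clinimetric norm) and $\mathrm{Cor}$ the
point-biserial anchor–change correlation (the Pearson correlation of the
0/1 anchor with the change). At prevalence one half the adjustment
vanishes and $\mathrm{MIC}_{adj} = \mathrm{MIC}_{pred} = -C/B$; for
prevalence above one half (and $S>0$) it pulls the estimate down. Note
$S \ge 0$ whenever $\mathrm{Cor} \ge -0.874$, so on any realistic anchor
the adjustment direction is governed by the prevalence alone.

Headline MIC values are conventionally reported as integers; the package
rounds $\mathrm{MIC}_{adj}$ half *up* (`round_half_up()`), because banker's
rounding would change values such as 3.5 and is not how clinical tables
round.

## Numerical choices

* The logistic model is fitted by IRLS (`stats::glm`) with convergence
  tolerance 1e−10. Complete separation (anchor classes on disjoint change
  ranges) raises a classed error rather than returning a divergent slope:
  a MIC computed from an unbounded $B$ is meaningless, and a penalized fit
  would silently change the estimand. Quasi-complete separation is caught
  after fitting when $|B|\cdot SD(X) > 30$, i.e. when one SD of change
  moves the log-odds by more than 30.
* `mic_pred()` refuses slopes with $|B| < 10^{-12}$ (anchor uninformative).
* Mean-centering the change score before the logistic fit is exposed as an
  option (`center = TRUE`); the intercept is back-shifted so all MIC
  values are invariant to it. The default is the uncentered,
  formula-literal fit.
* Bootstrap percentiles use linear interpolation between order statistics
  (`quantile` type 7); percentile conventions differ across software, so
  this is stated explicitly.

## Uncertainty

`bootstrap_ci()` implements the percentile bootstrap with 2000 replicates
by default: patients (change, anchor pairs) are resampled with
replacement, unstratified by anchor — prevalence then varies across
replicates, which matters because the adjustment formula consumes it. The
95% CI is the 2.5th–97.5th percentile of the replicate estimates.
Replicates on which an estimator is undefined (single-class anchor,
separation, constant change) are dropped and counted by failure type,
never imputed; if fewer than half the replicates are valid the bootstrap
aborts with the failure taxonomy. One root seed drives a pre-drawn
per-replicate seed stream, so results are reproducible and independent of
evaluation order.

## Floor and ceiling screening

A floor (ceiling) effect is declared when ≥ 15% of patients sit at the
scale minimum (maximum) *at baseline*, i.e. on admission scores only —
discharge scores never enter the check. The threshold is inclusive, and
the scale constants are motor 13/91, cognitive 5/35, total 18/126.
Score-range saturation truncates measurable change and distorts any MIC.

## The synthetic-cohort generator

No patient-level data ship with the package, so all pipeline-level testing
runs on synthetic cohorts from a two-group, equal-variance normal change
model: anchor $A \sim \mathrm{Bernoulli}(p)$ and
$X \mid A \sim N(\mu_A, \sigma_w^2)$. `calibrate_change_model()`
moment-matches the four observable summaries — marginal mean and SD of
change, prevalence, point-biserial correlation — via
$d = r_{pb}\,SD/\sqrt{p(1-p)}$, $\mu_1 = m + (1-p)d$, $\mu_0 = m - pd$,
$\sigma_w^2 = SD^2 - d^2 p(1-p) = SD^2(1 - r_{pb}^2)$, which is feasible
for every $|r_{pb}| < 1$. The default calibration constants are the
published cohort summaries of the subacute-stroke study the package is
designed around: motor change 21.7 (SD 14.5), cognitive 4.3 (4.8), total
26.0 (16.9), prevalence 187/277 discharged home, correlations
0.29/0.02/0.25, with admission means 39.1 (21.2) motor and 19.7 (8.5)
cognitive for full-schema cohorts.

Two properties make this generator a sharp oracle. First, the *genuine*
MIC — the point where the improved and non-improved densities cross — is
simply $(\mu_1+\mu_0)/2$. Second, equal-variance normals imply an exactly
linear logit, so the logistic model is correctly specified and
$\mathrm{MIC}_{pred}$ is consistent for the genuine MIC; at
$n = 100{,}000$ the pipeline must recover it within 0.5 points, and does.

The generator matches first and second moments and the anchor association
only. It does not emulate skew, the discreteness-induced clustering near
scale bounds, length-of-stay effects or covariate structure of real
rehabilitation data — so passing recovery tests validates the estimator
chain, not the clinical model. Continuous change scores are the default;
integer rounding and range clamping are opt-in (`integerize`, `clamp`)
because they perturb the matched moments (by well under 0.5% at motor
scale, which the tests assert). Full-schema cohorts
(`simulate_fim_cohort()`) back-fill admission scores around the baseline
means and clamp admission and discharge into the FIM ranges, slightly
truncating extreme changes; such cohorts carry a `synthetic` attribute.

A consequence worth stating plainly: because $\mathrm{MIC}_{pred}$ is
*unbiased* for the genuine MIC under this generator, the adjusted
estimator converges to $\mathrm{genuine} - S\ln(\mathrm{odds}_{pre})$,
*below* the crossing point when prevalence exceeds one half. The
adjustment corrects a bias that arises in the broader MIC framework (and
in real cohorts), not under this idealized generator, so the recovery
study (`run_recovery_study()`) reports the adjusted estimator as
systematically shifted at unbalanced prevalence. The recovery table
therefore measures each estimator against the genuine MIC and leaves the
interpretation of the adjustment to this documented asymptotic.

## Design decisions that were genuinely open

* **Missing data**: records with any missing score or anchor are excluded
  listwise with a logged count. The data provenance (routine hospital
  records) makes transparent exclusion preferable to imputation, which is
  out of scope.
* **Anchor coding**: home = 1 = improved, fixed so the signs of $C$, $B$
  and the adjustment are reproducible.
* **Resampling unit**: whole patients, unstratified (see above).
* **Tie-break and candidate set** for the ROC cutoff: midpoints between
  distinct observed values, smallest tying cutoff (see above); published
  half-integer ROC MIC values support the midpoint convention.
* **Degenerate inputs**: single-class anchors, constant change, zero
  slope, prevalence 0 or 1 are all hard classed errors at the point of
  use; the pipeline never silently substitutes a value, and a failure in
  any domain fails the whole `mic_fim()` run with a domain-tagged error.

## Problem sizes used by the test suite

Deterministic formula checks run on printed summary constants (instant).
Stochastic checks use: $n = 100{,}000$ single cohorts for moment and
$\mathrm{MIC}_{pred}$ recovery (about a second each); $n = 277$ cohorts
with 120–200 bootstrap replicates for CI behaviour; and recovery grids of
12–25 replicates at $n$ between 150 and 10,000. These sizes keep the full
suite well under a minute while leaving Monte-Carlo error far below every
asserted tolerance.

## Limitations

The package estimates the MIC for one anchor, dichotomized one way, on
one instrument family. It deliberately omits distribution-based MIC
variants (0.5·SD, SEM), multi-anchor triangulation, BCa or studentized
bootstraps, and any modeling of the 1–7 item response process. Bootstrap
CIs on real data inherit the empirical joint distribution of change and
anchor; the synthetic generator cannot stand in for that distribution, so
CI widths obtained on calibrated cohorts are not comparable to published
ones.
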