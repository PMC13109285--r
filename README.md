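# micfim

Anchor-based estimation of the **minimal important change (MIC)** for the
Functional Independence Measure (FIM) — the smallest change in the motor
(13–91 points), cognitive (5–35) or total (18–126) score that counts as
clinically meaningful. It is written for clinimetric and rehabilitation
researchers who have a cohort with FIM scores at admission and discharge
and a dichotomous improvement anchor, here discharge destination
(home = improved vs elsewhere).

Three estimators are implemented, in the field's standard notation:

- **MIC_roc** — the ROC cutoff maximizing the Youden index
  J = sensitivity + specificity − 1, with candidate cutoffs at midpoints
  between consecutive distinct change values;
- **MIC_pred** — predictive modeling:
  `MIC_pred = (ln(odds_pre) − C) / B`, where C and B are the intercept and
  slope of the logistic regression of the anchor on the change score and
  `odds_pre = p/(1 − p)` the pre-test odds of improvement;
- **MIC_adj** — the prevalence-bias adjustment
  `MIC_adj = MIC_pred − S·ln(odds_pre)`,
  `S = 0.09·SD_chang + 0.103·SD_chang·Cor`, with `SD_chang` the SD of the
  change score and `Cor` the point-biserial anchor–change correlation.

Around them: percentile bootstrap confidence intervals (2000 replicates
by default, patients resampled whole), floor/ceiling screening at
baseline (15% rule), a moment-matched two-group normal synthetic-cohort
generator, and a Monte-Carlo estimator-recovery study. The methods
vignette (`vignettes/mic-estimation-methods.Rmd`) documents every model
assumption and numerical choice.

## Worked example

The package ships a small synthetic demonstration cohort (60 patients,
generated from the calibrated two-group model — see
`inst/extdata/synthetic_cohort.csv`):

```r
library(micfim)
cohort <- read_cohort(system.file("extdata", "synthetic_cohort.csv",
                                  package = "micfim"))
fit <- mic_fim(cohort, n_boot = 200, seed = 42)
summary(fit)
```

```
Anchor-based MIC estimation for the FIM (n = 60)
Improved (discharged home): 43 (71.7%); bootstrap n = 200, level 95%, seed 42

Change-score descriptives:
  motor     mean   17.0 (SD  13.6)   anchor r_pb  0.26
  cognitive mean    4.3 (SD   4.3)   anchor r_pb 0.042
  total     mean   21.3 (SD  13.7)   anchor r_pb  0.27

MIC estimates (score points):
    domain  n mic_roc mic_roc_lo mic_roc_hi mic_pred mic_pred_lo mic_pred_hi
     motor 60    15.5        2.5       19.5     15.3        11.8        19.0
 cognitive 60     7.5        1.5       10.5      4.2         3.0         5.2
     total 60    21.5       10.0       26.5     19.5        14.9        23.4
 mic_adj mic_adj_lo mic_adj_hi mic_headline prevalence odds_pre cor sd_chang
    13.8        9.7       18.1           14        0.7      2.5 0.3     13.6
     3.8        2.6        5.2            4        0.7      2.5 0.0      4.3
    18.0       14.4       22.1           18        0.7      2.5 0.3     13.7

Floor/ceiling at baseline (15% rule):
  motor     floor  11.7% no   ceiling   0.0% no
  cognitive floor   3.3% no   ceiling   6.7% no
  total     floor   0.0% no   ceiling   0.0% no
```

Reading this: 71.7% of the synthetic cohort went home, so `odds_pre` is
about 2.5 and the adjustment pulls each `MIC_adj` below its `MIC_pred`
(e.g. motor 13.8 vs 15.3). A motor FIM gain of at least the headline
integer MIC (14 points here) would be labelled clinically important;
`predict(fit, change, domain = "motor")` applies that threshold to new
change scores. No domain shows a floor or ceiling effect, so the MIC
estimates are not range-distorted. At n = 60 the bootstrap intervals are
wide — the ROC interval especially, which is the known instability of the
Youden cutoff at small samples.

Other entry points: `coef(fit)`, `confint(fit)`, `plot(fit, "motor")`,
`simulate(fit)` (calibrated synthetic cohorts in the ingestion schema),
`write_mic_report(fit, "mic.json")`, and `run_recovery_study()` for
bias/RMSE/coverage of all three estimators under known ground truth.

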