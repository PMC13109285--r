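# Independent oracles and fixture builders shared across test files.

# Brute-force Youden scan: every midpoint between consecutive distinct
# values, plain mean() arithmetic, smallest tying cutoff.
oracle_youden <- function(change, anchor) {
  v <- sort(unique(change))
  cuts <- (v[-1] + v[-length(v)]) / 2
  J <- vapply(cuts, function(cut) {
    sens <- mean(change[anchor == 1] >= cut)
    spec <- mean(change[anchor == 0] < cut)
    sens + spec - 1
  }, numeric(1))
  best <- which(J >= max(J) - 1e-12)[1]
  list(cutoff = cuts[best], J = J[best])
}

# Direct maximum-likelihood logistic fit by Nelder-Mead on the binomial
# log-likelihood: independent of the IRLS route used by the package.
oracle_logit <- function(change, anchor) {
  nll <- function(par) {
    eta <- par[1] + par[2] * change
    -sum(anchor * eta - log1p(exp(eta)))
  }
  fit <- stats::optim(c(0, 0), nll, method = "Nelder-Mead",
                      control = list(reltol = 1e-12, maxit = 5000))
  list(C = fit$par[1], B = fit$par[2])
}

# Pearson correlation from raw sums (no call to stats::cor).
oracle_pearson <- function(x, y) {
  n <- length(x)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  sxy / sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
}

# Small random integer-scored datasets with both anchor classes.
random_change_data <- function(seed, n = 30, domain = "motor") {
  set.seed(seed)
  repeat {
    anchor <- rbinom(n, 1, 0.6)
    if (length(unique(anchor)) == 2) break
  }
  change <- round(rnorm(n, 15 + 8 * anchor, 10))
  change_data(change, anchor, domain)
}

# A 6-patient hand-written cohort in the ingestion schema.
hand_cohort <- function() {
  data.frame(
    patient_id = paste0("P", 1:6),
    motor_adm = c(39, 50, 13, 70, 45, 60),
    cognitive_adm = c(20, 19, 5, 30, 22, 25),
    motor_dis = c(60, 70, 30, 85, 50, 62),
    cognitive_dis = c(25, 24, 10, 35, 23, 26),
    anchor = c(1, 1, 0, 1, 0, 1)
  )
}

# Paper-scale calibrated generator specs (printed cohort summaries).
motor_summary <- list(mean = 21.7, sd = 14.5, prev = 187 / 277, r = 0.29)
cog_summary <- list(mean = 4.3, sd = 4.8, prev = 187 / 277, r = 0.02)
total_summary <- list(mean = 26.0, sd = 16.9, prev = 187 / 277, r = 0.25)

calibrated_spec <- function(s)
  calibrate_change_model(s$mean, s$sd, s$prev, s$r)
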