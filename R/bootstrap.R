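# Percentile bootstrap confidence intervals for the MIC estimators.

estimator_fun <- function(estimator) {
  switch(estimator,
    roc  = function(d) as.numeric(mic_roc(d)),
    pred = function(d) {
      odds <- compute_odds_pre(sum(d$anchor), d$n)
      mic_pred(fit_anchor_logistic(d), odds)
    },
    adj = function(d) {
      odds <- compute_odds_pre(sum(d$anchor), d$n)
      pred <- mic_pred(fit_anchor_logistic(d), odds)
      mic_adj(pred, compute_S(stats::sd(d$change), point_biserial(d)), odds)
    }
  )
}

#' Percentile bootstrap CI for a MIC estimator
#'
#' Resamples whole patients (change, anchor pairs) with replacement,
#' re-estimates the chosen MIC per replicate, and takes empirical
#' percentiles (linear interpolation between order statistics) as the
#' confidence bounds.  Resampling is unstratified so prevalence varies
#' across replicates, which the adjustment formula consumes.  Replicates on
#' which the estimator is undefined (single-class anchor, separation,
#' constant change) are dropped and counted by failure type; if fewer than
#' half the replicates are valid the bootstrap is declared unstable and an
#' error is raised.
#'
#' One root seed drives a pre-drawn per-replicate seed stream, so results
#' do not depend on evaluation order.
#'
#' @param data A `change_data` object.
#' @param estimator `"roc"`, `"pred"` or `"adj"`.
#' @param n_boot Number of bootstrap replicates (2000 by default).
#' @param level Confidence level (0.95).
#' @param seed Integer root seed.
#' @return An object of class `mic_boot`: list with `estimator`,
#'   `replicates` (valid replicate estimates), `n_requested`, `n_valid`,
#'   `failures` (named counts by error class), `ci_lower`, `ci_upper`,
#'   `level`, `seed`.
#' @export
bootstrap_ci <- function(data, estimator = c("roc", "pred", "adj"),
                         n_boot = 2000, level = 0.95, seed = 1L) {
  stopifnot(inherits(data, "change_data"), n_boot >= 2, level > 0, level < 1)
  estimator <- match.arg(estimator)
  f <- estimator_fun(estimator)
  seeds <- child_seeds(seed, n_boot)
  fails <- c(degenerate = 0L, separation = 0L, convergence = 0L, other = 0L)
  reps <- numeric(n_boot); valid <- logical(n_boot)
  for (b in seq_len(n_boot)) {
    idx <- with_seed(seeds[b], sample.int(data$n, data$n, replace = TRUE))
    d <- structure(list(domain = data$domain, change = data$change[idx],
                        anchor = data$anchor[idx], n = data$n),
                   class = "change_data")
    est <- tryCatch(f(d),
      micfim_degenerate_error  = function(e) { fails["degenerate"]  <<- fails["degenerate"] + 1L; NA_real_ },
      micfim_separation_error  = function(e) { fails["separation"]  <<- fails["separation"] + 1L; NA_real_ },
      micfim_convergence_error = function(e) { fails["convergence"] <<- fails["convergence"] + 1L; NA_real_ },
      micfim_error             = function(e) { fails["other"]       <<- fails["other"] + 1L; NA_real_ })
    reps[b] <- est; valid[b] <- !is.na(est)
  }
  n_valid <- sum(valid)
  if (n_valid < n_boot / 2)
    mic_stop("micfim_bootstrap_error", paste0(
      "unstable bootstrap: only ", n_valid, "/", n_boot,
      " valid replicates (degenerate ", fails["degenerate"],
      ", separation ", fails["separation"],
      ", non-convergence ", fails["convergence"],
      ", other ", fails["other"], ")"))
  alpha <- (1 - level) / 2
  qs <- stats::quantile(reps[valid], c(alpha, 1 - alpha),
                        names = FALSE, type = 7)
  structure(list(estimator = estimator, replicates = reps[valid],
                 n_requested = n_boot, n_valid = n_valid, failures = fails,
                 ci_lower = qs[1], ci_upper = qs[2],
                 level = level, seed = seed),
            class = "mic_boot")
}

#' @export
print.mic_boot <- function(x, ...) {
  cat("Percentile bootstrap (", x$estimator, "): ",
      100 * x$level, "% CI [", fmt1(x$ci_lower), ", ", fmt1(x$ci_upper),
      "] from ", x$n_valid, "/", x$n_requested, " valid replicates\n",
      sep = "")
  invisible(x)
}
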