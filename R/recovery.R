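# Monte-Carlo estimator-recovery study.
#
# Under the two-group equal-variance generator the genuine MIC is known
# (the density-crossing midpoint), so bias, RMSE and bootstrap CI coverage
# of the three estimators can be measured directly.  Note that under this
# generator the logit model is correctly specified, so MIC_pred is
# consistent for the genuine MIC while MIC_adj converges to
# genuine - S*ln(odds_pre); the adjustment targets a bias that arises
# under the broader MIC framework, not under this idealized generator
# (see the methods vignette).

#' Read a scenario grid from a config file
#'
#' Reads a plain-text key:value (YAML-subset) file describing calibration
#' scenarios.  The file holds a top-level `scenarios:` list; each entry
#' has `name`, `mean_change`, `sd_change`, `prevalence`, `r_pb`, `n`.
#'
#' @param path Path to the config file.
#' @return A data frame with one row per scenario.
#' @export
read_scenarios <- function(path) {
  if (!file.exists(path)) stop_config(paste0("file not found: ", path))
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$scenarios)) stop_config("config has no 'scenarios' key")
  do.call(rbind, lapply(cfg$scenarios, function(s) {
    # YAML 1.1 reads a bare `n` key as boolean FALSE; map it back
    names(s)[names(s) %in% c("FALSE", "no")] <- "n"
    need <- c("name", "mean_change", "sd_change", "prevalence", "r_pb", "n")
    missing <- setdiff(need, names(s))
    if (length(missing))
      stop_config(paste0("scenario missing field(s): ",
                         paste(missing, collapse = ", ")))
    data.frame(name = s$name, mean_change = s$mean_change,
               sd_change = s$sd_change, prevalence = s$prevalence,
               r_pb = s$r_pb, n = s$n)
  }))
}

#' Estimator-recovery simulation study
#'
#' For each scenario, repeatedly simulates cohorts from the calibrated
#' two-group model, applies all three MIC estimators, and summarizes mean
#' bias (estimate minus genuine MIC), RMSE, and -- when `n_boot > 0` --
#' the coverage of the percentile bootstrap CI for the genuine MIC.
#' Infeasible scenarios (calibration error) are skipped with a warning.
#' Replicates on which an estimator is undefined are dropped and counted.
#'
#' @param scenarios Data frame as returned by [read_scenarios()] (columns
#'   `name`, `mean_change`, `sd_change`, `prevalence`, `r_pb`, `n`).
#' @param n_reps Replicates per scenario.
#' @param seed Integer root seed; child seeds are derived per scenario and
#'   replicate so results do not depend on evaluation order.
#' @param n_boot Bootstrap replicates for coverage (0 skips coverage,
#'   which is much faster).
#' @param level Confidence level for coverage.
#' @return A data frame of class `mic_recovery`: one row per scenario and
#'   estimator with `scenario`, `n`, `estimator`, `genuine`, `mean_bias`,
#'   `rmse`, `coverage`, `n_valid`.
#' @export
run_recovery_study <- function(scenarios, n_reps = 200, seed = 1L,
                               n_boot = 0, level = 0.95) {
  stopifnot(is.data.frame(scenarios), n_reps >= 1)
  seeds <- matrix(child_seeds(seed, nrow(scenarios) * n_reps),
                  nrow = nrow(scenarios))
  out <- list()
  for (i in seq_len(nrow(scenarios))) {
    sc <- scenarios[i, ]
    spec <- tryCatch(
      calibrate_change_model(sc$mean_change, sc$sd_change,
                             sc$prevalence, sc$r_pb),
      micfim_error = function(e) {
        warning("scenario '", sc$name, "' infeasible, skipped: ",
                conditionMessage(e), call. = FALSE)
        NULL
      })
    if (is.null(spec)) next
    truth <- genuine_mic(spec)
    ests <- matrix(NA_real_, n_reps, 3,
                   dimnames = list(NULL, c("roc", "pred", "adj")))
    cover <- matrix(NA, n_reps, 3,
                    dimnames = list(NULL, c("roc", "pred", "adj")))
    for (r in seq_len(n_reps)) {
      d <- simulate_change_data(spec, sc$n, seed = seeds[i, r])
      for (e in c("roc", "pred", "adj")) {
        val <- tryCatch(estimator_fun(e)(d),
                        micfim_error = function(err) NA_real_)
        ests[r, e] <- val
        if (n_boot > 0 && !is.na(val)) {
          ci <- tryCatch(
            bootstrap_ci(d, e, n_boot = n_boot, level = level,
                         seed = seeds[i, r]),
            micfim_error = function(err) NULL)
          if (!is.null(ci))
            cover[r, e] <- ci$ci_lower <= truth && truth <= ci$ci_upper
        }
      }
    }
    for (e in c("roc", "pred", "adj")) {
      v <- ests[, e]; ok <- !is.na(v)
      out[[length(out) + 1L]] <- data.frame(
        scenario = sc$name, n = sc$n, estimator = e, genuine = truth,
        mean_bias = mean(v[ok] - truth),
        rmse = sqrt(mean((v[ok] - truth)^2)),
        coverage = if (n_boot > 0) mean(cover[ok, e], na.rm = TRUE)
                   else NA_real_,
        n_valid = sum(ok)
      )
    }
  }
  if (!length(out)) stop_config("no feasible scenarios")
  structure(do.call(rbind, out), class = c("mic_recovery", "data.frame"))
}

#' @export
print.mic_recovery <- function(x, digits = 3, ...) {
  cat("Estimator recovery study (", length(unique(x$scenario)),
      " scenario(s))\n", sep = "")
  df <- as.data.frame(x)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], signif, digits)
  print(df, row.names = FALSE)
  invisible(x)
}
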