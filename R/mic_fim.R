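# The main model-fitting entry point: estimate the MIC of the FIM motor,
# cognitive and total scores from a cohort with a dichotomous anchor.

#' Estimate minimal important change for the FIM
#'
#' Fits the complete anchor-based MIC analysis to a patient cohort: for
#' each requested FIM domain it computes the ROC/Youden cutoff
#' (`MIC_roc`), the predictive-modeling estimate
#' `MIC_pred = (ln(odds_pre) - C)/B` from the logistic regression of the
#' discharge-home anchor on the change score, and the prevalence-bias
#' adjusted `MIC_adj = MIC_pred - S*ln(odds_pre)` with
#' `S = 0.09*SD + 0.103*SD*Cor`; attaches percentile bootstrap confidence
#' intervals; screens baseline scores for floor/ceiling effects (15%
#' rule); and reports the headline integer MIC as the half-up rounded
#' `MIC_adj`.  A failure in any domain fails the whole run with a
#' domain-tagged error; partial reports are never returned.
#'
#' @param data A cohort data frame in the ingestion schema (see
#'   [read_cohort()]); validated with [validate_cohort()] unless it
#'   already is a `fim_cohort`.
#' @param n_boot Bootstrap replicates per estimator (2000 by default;
#'   0 skips confidence intervals).
#' @param seed Integer root seed driving all bootstrap resampling.
#' @param level Confidence level for the bootstrap intervals.
#' @param domains FIM domains to analyse.
#' @param center Mean-center change scores inside the logistic fit (the
#'   MIC values are invariant to this; off by default).
#' @return An object of class `mic_fim`; see [summary.mic_fim()],
#'   [coef.mic_fim()], [confint.mic_fim()], [plot.mic_fim()],
#'   [predict.mic_fim()], [simulate.mic_fim()].
#' @examples
#' spec <- calibrate_change_model(21.7, 14.5, 187 / 277, 0.29)
#' cog <- calibrate_change_model(4.3, 4.8, 187 / 277, 0.02)
#' coh <- simulate_fim_cohort(300, spec, cog, seed = 7)
#' fit <- mic_fim(coh, n_boot = 50, seed = 7)
#' fit
#' coef(fit)
#' @export
mic_fim <- function(data, n_boot = 2000, seed = 1L, level = 0.95,
                    domains = c("motor", "cognitive", "total"),
                    center = FALSE) {
  domains <- match.arg(domains, several.ok = TRUE)
  cohort <- if (inherits(data, "fim_cohort")) data else validate_cohort(data)
  seeds <- matrix(child_seeds(seed, 3L * length(domains)),
                  nrow = length(domains), ncol = 3L,
                  dimnames = list(domains, c("roc", "pred", "adj")))
  estimates <- list(); boots <- list(); fc <- list()
  for (dom in domains) {
    res <- tryCatch({
      d <- build_change_dataset(cohort, dom)
      est <- estimate_mic(d, center = center)
      bt <- if (n_boot > 0)
        lapply(stats::setNames(c("roc", "pred", "adj"),
                               c("roc", "pred", "adj")),
               function(e) bootstrap_ci(d, e, n_boot = n_boot,
                                        level = level,
                                        seed = seeds[dom, e]))
      else NULL
      list(est = est, bt = bt)
    }, micfim_error = function(e) {
      mic_stop(class(e)[1], paste0("[", dom, "] ", conditionMessage(e)))
    })
    estimates[[dom]] <- res$est
    boots[[dom]] <- res$bt
    fc[[dom]] <- assess_floor_ceiling(cohort, dom)
  }
  structure(list(
    estimates = estimates, boot = boots, floor_ceiling = fc,
    headline = vapply(estimates, function(e) round_half_up(e$mic_adj),
                      numeric(1)),
    descriptives = cohort_descriptives(cohort, domains),
    n = nrow(cohort), n_excluded = attr(cohort, "n_excluded") %||% 0L,
    n_boot = n_boot, level = level, seed = seed, center = center,
    domains = domains, call = match.call(),
    version = as.character(utils::packageVersion("micfim"))
  ), class = "mic_fim")
}

cohort_descriptives <- function(cohort, domains) {
  out <- lapply(stats::setNames(domains, domains), function(dom) {
    adm <- domain_score(cohort, dom, "adm")
    dis <- domain_score(cohort, dom, "dis")
    ch <- dis - adm
    list(adm_mean = mean(adm), adm_sd = stats::sd(adm),
         dis_mean = mean(dis), dis_sd = stats::sd(dis),
         change_mean = mean(ch), change_sd = stats::sd(ch))
  })
  out$prevalence <- mean(cohort$anchor)
  out$n_improved <- sum(cohort$anchor)
  out
}

#' @export
print.mic_fim <- function(x, digits = 1, ...) {
  cat("Anchor-based MIC estimation for the FIM\n")
  cat("  n = ", x$n, ", improved (home) = ", x$descriptives$n_improved,
      " (", fmt1(100 * x$descriptives$prevalence), "%)",
      if (x$n_excluded > 0) paste0(", ", x$n_excluded, " incomplete excluded"),
      "\n\n", sep = "")
  print(round(coef(x), digits))
  cat("\nHeadline integer MIC (half-up rounded MIC_adj):\n")
  print(x$headline)
  invisible(x)
}

#' MIC point estimates
#'
#' @param object A `mic_fim` fit.
#' @param ... Unused.
#' @return Matrix of MIC estimates, domains in rows, estimators
#'   (`mic_roc`, `mic_pred`, `mic_adj`) in columns.
#' @export
coef.mic_fim <- function(object, ...) {
  t(vapply(object$estimates,
           function(e) c(mic_roc = e$mic_roc, mic_pred = e$mic_pred,
                         mic_adj = e$mic_adj),
           numeric(3)))
}

#' Bootstrap confidence intervals of the MIC estimates
#'
#' @param object A `mic_fim` fit produced with `n_boot > 0`.
#' @param parm Estimators to include (`"roc"`, `"pred"`, `"adj"`).
#' @param level Ignored; intervals were computed at the level stored in
#'   the fit.
#' @param ... Unused.
#' @return Matrix with one row per domain-estimator pair and columns
#'   `lower`, `upper`.
#' @export
confint.mic_fim <- function(object, parm = c("roc", "pred", "adj"),
                            level = NULL, ...) {
  if (!length(object$boot) || is.null(object$boot[[1]]))
    stop_config("fit was run with n_boot = 0; no bootstrap intervals")
  parm <- match.arg(parm, several.ok = TRUE)
  rows <- do.call(rbind, lapply(object$domains, function(dom) {
    t(vapply(parm, function(e) {
      b <- object$boot[[dom]][[e]]
      c(lower = b$ci_lower, upper = b$ci_upper)
    }, numeric(2)))
  }))
  rownames(rows) <- as.vector(outer(parm, object$domains,
                                    function(e, d) paste(d, e, sep = ".")))
  rows
}

#' Summarize a MIC fit
#'
#' @param object A `mic_fim` fit.
#' @param ... Unused.
#' @return A `summary.mic_fim` object: the Table-style estimate data frame
#'   ([mic_table()]), floor/ceiling reports, descriptives and provenance.
#' @export
summary.mic_fim <- function(object, ...) {
  structure(list(table = mic_table(object), fit = object),
            class = "summary.mic_fim")
}

#' @export
print.summary.mic_fim <- function(x, ...) {
  f <- x$fit
  cat("Anchor-based MIC estimation for the FIM (n = ", f$n, ")\n", sep = "")
  cat("Improved (discharged home): ", f$descriptives$n_improved, " (",
      fmt1(100 * f$descriptives$prevalence), "%); bootstrap n = ",
      f$n_boot, ", level ", 100 * f$level, "%, seed ", f$seed, "\n\n",
      sep = "")
  cat("Change-score descriptives:\n")
  for (dom in f$domains) {
    d <- f$descriptives[[dom]]
    cat(sprintf("  %-9s mean %6s (SD %5s)   anchor r_pb %5s\n", dom,
                fmt1(d$change_mean), fmt1(d$change_sd),
                format(f$estimates[[dom]]$cor, digits = 2)))
  }
  cat("\nMIC estimates (score points):\n")
  tab <- x$table
  num <- vapply(tab, is.numeric, logical(1))
  tab[num] <- lapply(tab[num], round, 1)
  print(tab, row.names = FALSE)
  cat("\nFloor/ceiling at baseline (15% rule):\n")
  for (dom in f$domains) {
    fc <- f$floor_ceiling[[dom]]
    cat(sprintf("  %-9s floor %5s%% %-3s  ceiling %5s%% %-3s\n", dom,
                fmt1(fc$pct_min), if (fc$floor_flag) "YES" else "no",
                fmt1(fc$pct_max), if (fc$ceiling_flag) "YES" else "no"))
  }
  if (f$n_excluded > 0)
    cat("\n", f$n_excluded, " incomplete record(s) excluded listwise\n",
        sep = "")
  invisible(x)
}

#' Tabulate a MIC fit
#'
#' Flattens a fit into one row per domain with the three MIC estimates,
#' their bootstrap CIs, the headline integer MIC and the anchor summaries
#' -- the machine-readable analogue of a published MIC table.
#'
#' @param object A `mic_fim` fit.
#' @return A data frame.
#' @export
mic_table <- function(object) {
  stopifnot(inherits(object, "mic_fim"))
  rows <- lapply(object$domains, function(dom) {
    e <- object$estimates[[dom]]
    b <- object$boot[[dom]]
    ci <- function(est, side)
      if (is.null(b)) NA_real_ else b[[est]][[side]]
    data.frame(
      domain = dom, n = e$n,
      mic_roc = e$mic_roc,
      mic_roc_lo = ci("roc", "ci_lower"), mic_roc_hi = ci("roc", "ci_upper"),
      mic_pred = e$mic_pred,
      mic_pred_lo = ci("pred", "ci_lower"), mic_pred_hi = ci("pred", "ci_upper"),
      mic_adj = e$mic_adj,
      mic_adj_lo = ci("adj", "ci_lower"), mic_adj_hi = ci("adj", "ci_upper"),
      mic_headline = unname(object$headline[dom]),
      prevalence = e$prevalence, odds_pre = e$odds_pre,
      cor = e$cor, sd_chang = e$sd_chang, S = e$S
    )
  })
  do.call(rbind, rows)
}

#' Export a MIC fit to delimited text and JSON
#'
#' Writes the [mic_table()] as tab-separated text and/or JSON.  Exports
#' are byte-stable for a given fit, so identical inputs and seed give
#' identical files.
#'
#' @param object A `mic_fim` fit.
#' @param file Output path; the format is chosen by extension unless
#'   `format` is given.
#' @param format `"tsv"` or `"json"`.
#' @return `file`, invisibly.
#' @export
write_mic_report <- function(object, file,
                             format = c("auto", "tsv", "json")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.json$", file)) "json" else "tsv"
  tab <- mic_table(object)
  if (format == "json") {
    payload <- list(
      table = tab,
      headline = as.list(object$headline),
      provenance = list(n = object$n, n_excluded = object$n_excluded,
                        n_boot = object$n_boot, level = object$level,
                        seed = object$seed, package_version = object$version)
    )
    jsonlite::write_json(payload, file, auto_unbox = TRUE, digits = NA)
  } else {
    utils::write.table(tab, file, sep = "\t", row.names = FALSE,
                       quote = FALSE)
  }
  invisible(file)
}

#' Classify change scores against the fitted MIC
#'
#' Labels new change scores as clinically important when they reach the
#' fitted threshold for the chosen domain and estimator.
#'
#' @param object A `mic_fim` fit.
#' @param newdata Numeric vector of change scores, or a cohort data frame
#'   in the ingestion schema from which changes are built.
#' @param domain Domain whose threshold to apply.
#' @param estimator `"adj"` (default), `"pred"`, `"roc"` or `"headline"`
#'   (the integer MIC).
#' @param ... Unused.
#' @return Logical vector: `TRUE` where change >= MIC.
#' @export
predict.mic_fim <- function(object, newdata,
                            domain = c("motor", "cognitive", "total"),
                            estimator = c("adj", "pred", "roc", "headline"),
                            ...) {
  domain <- match.arg(domain)
  estimator <- match.arg(estimator)
  if (!domain %in% object$domains)
    stop_config(paste0("domain '", domain, "' was not fitted"))
  if (is.data.frame(newdata)) {
    coh <- if (inherits(newdata, "fim_cohort")) newdata else
      validate_cohort(newdata)
    newdata <- domain_score(coh, domain, "dis") -
      domain_score(coh, domain, "adm")
  }
  thr <- switch(estimator,
    headline = unname(object$headline[domain]),
    roc = object$estimates[[domain]]$mic_roc,
    pred = object$estimates[[domain]]$mic_pred,
    adj = object$estimates[[domain]]$mic_adj)
  newdata >= thr
}

#' Plot change-score distributions with the fitted MIC thresholds
#'
#' Overlaid histograms of change scores for improved and non-improved
#' patients with vertical lines at the three MIC estimates.
#'
#' @param x A `mic_fim` fit.
#' @param domain Domain to plot.
#' @param data Optional cohort data frame to draw the histograms from
#'   (required because the fit stores summaries, not raw data, when you
#'   want the empirical distributions; defaults to simulating from the
#'   fitted two-group model).
#' @param ... Passed to [graphics::hist()].
#' @return Invisibly, `x`.
#' @export
plot.mic_fim <- function(x, domain = c("motor", "cognitive", "total"),
                         data = NULL, ...) {
  domain <- match.arg(domain)
  e <- x$estimates[[domain]]
  if (!is.null(data)) {
    coh <- if (inherits(data, "fim_cohort")) data else validate_cohort(data)
    d <- build_change_dataset(coh, domain)
    ch <- d$change; an <- d$anchor
  } else {
    spec <- calibrate_change_model(
      x$descriptives[[domain]]$change_mean,
      x$descriptives[[domain]]$change_sd,
      e$prevalence, e$cor)
    d <- simulate_change_data(spec, max(x$n, 1000), seed = x$seed,
                              domain = domain)
    ch <- d$change; an <- d$anchor
  }
  brk <- pretty(range(ch), 30)
  h1 <- graphics::hist(ch[an == 1], breaks = brk, plot = FALSE)
  h0 <- graphics::hist(ch[an == 0], breaks = brk, plot = FALSE)
  ylim <- c(0, max(h1$counts, h0$counts))
  graphics::plot(h0, col = grDevices::adjustcolor("firebrick", 0.5),
                 ylim = ylim, xlab = paste(domain, "FIM change"),
                 main = paste("MIC,", domain, "FIM"), ...)
  graphics::plot(h1, col = grDevices::adjustcolor("steelblue", 0.5),
                 add = TRUE)
  graphics::abline(v = c(e$mic_roc, e$mic_pred, e$mic_adj),
                   lty = c(3, 2, 1), lwd = 2)
  graphics::legend("topright", bty = "n",
                   legend = c("non-improved", "improved",
                              sprintf("MIC_roc = %s", fmt1(e$mic_roc)),
                              sprintf("MIC_pred = %s", fmt1(e$mic_pred)),
                              sprintf("MIC_adj = %s", fmt1(e$mic_adj))),
                   fill = c(grDevices::adjustcolor("firebrick", 0.5),
                            grDevices::adjustcolor("steelblue", 0.5),
                            NA, NA, NA),
                   border = c("black", "black", NA, NA, NA),
                   lty = c(NA, NA, 3, 2, 1))
  invisible(x)
}

#' Simulate synthetic cohorts from a MIC fit
#'
#' Calibrates the two-group equal-variance change model to the fitted
#' cohort's summaries (change mean/SD, prevalence, anchor correlation per
#' domain) and draws synthetic cohorts in the ingestion schema, so a
#' fitted analysis can be stress-tested without the original data.
#'
#' @param object A `mic_fim` fit covering the motor and cognitive domains.
#' @param nsim Number of cohorts.
#' @param seed Integer seed.
#' @param n Patients per cohort (defaults to the fitted cohort size).
#' @param ... Unused.
#' @return A list of `nsim` synthetic `fim_cohort` data frames.
#' @export
simulate.mic_fim <- function(object, nsim = 1, seed = 1L, n = object$n,
                             ...) {
  if (!all(c("motor", "cognitive") %in% object$domains))
    stop_config("simulate() needs motor and cognitive domains in the fit")
  specs <- lapply(c(motor = "motor", cognitive = "cognitive"), function(dom) {
    d <- object$descriptives[[dom]]
    calibrate_change_model(d$change_mean, d$change_sd,
                           object$descriptives$prevalence,
                           object$estimates[[dom]]$cor)
  })
  baseline <- list(
    motor = c(object$descriptives$motor$adm_mean,
              object$descriptives$motor$adm_sd),
    cognitive = c(object$descriptives$cognitive$adm_mean,
                  object$descriptives$cognitive$adm_sd))
  seeds <- child_seeds(seed, nsim)
  lapply(seq_len(nsim), function(i)
    simulate_fim_cohort(n, specs$motor, specs$cognitive,
                        baseline = baseline, seed = seeds[i]))
}
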