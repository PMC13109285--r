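# Anchor-based MIC estimators.
#
# Three estimators of the minimal important change from a dichotomous
# improvement anchor:
#   MIC_roc  -- ROC cutoff maximizing the Youden index J = se + sp - 1;
#   MIC_pred -- predictive modeling: (ln(odds_pre) - C)/B from the logistic
#               regression of the anchor on the change score;
#   MIC_adj  -- prevalence-bias adjustment
#               MIC_pred - S*ln(odds_pre),  S = 0.09*SD + 0.103*SD*Cor.

#' Point-biserial correlation between anchor and change
#'
#' The Pearson product-moment correlation of the 0/1 anchor with the change
#' score; the conventional check of anchor credibility for MIC estimation
#' (values of at least 0.3 are usually recommended).
#'
#' @param data A `change_data` object.
#' @return Correlation in \[-1, 1\].
#' @examples
#' d <- change_data(c(1, 2, 3, 4), c(0, 0, 1, 1), "motor")
#' point_biserial(d)  # 0.894
#' @export
point_biserial <- function(data) {
  stopifnot(inherits(data, "change_data"))
  if (data$n < 3) stop_validation("need n >= 3 for a correlation")
  if (length(unique(data$anchor)) < 2)
    stop_degenerate("anchor has a single class; correlation undefined")
  if (stats::sd(data$change) == 0)
    stop_degenerate("change score is constant; correlation undefined")
  stats::cor(data$change, data$anchor)
}

# Complete separation: the two anchor classes occupy disjoint change
# intervals, so the logistic slope is unbounded.
is_separated <- function(change, anchor) {
  c1 <- change[anchor == 1]; c0 <- change[anchor == 0]
  max(c0) < min(c1) || max(c1) < min(c0)
}

#' Logistic regression of the anchor on the change score
#'
#' Fits the binary logit model `anchor ~ change` by maximum likelihood
#' (IRLS), yielding the intercept `C` and slope `B` that the
#' predictive-modeling MIC consumes.  Complete separation and
#' non-convergence are raised as classed errors rather than returned as
#' unusable coefficients: a MIC computed from an unbounded slope is
#' meaningless.
#'
#' @param data A `change_data` object.
#' @param center Mean-center the change score before fitting.  Off by
#'   default: the MIC formulas use the intercept on the raw change scale.
#' @return An object of class `anchor_logit`: list with `C`, `B`,
#'   `converged`, `n_iter`, `n`, `center` (the centering constant used,
#'   0 when `center = FALSE`).
#' @export
fit_anchor_logistic <- function(data, center = FALSE) {
  stopifnot(inherits(data, "change_data"))
  if (data$n < 10)
    stop_validation("need n >= 10 for a stable logistic fit")
  if (length(unique(data$anchor)) < 2)
    stop_degenerate("anchor has a single class; logistic model undefined")
  shift <- if (center) mean(data$change) else 0
  x <- data$change - shift
  if (is_separated(x, data$anchor))
    stop_separation("complete separation: anchor classes occupy disjoint change ranges")
  fit <- suppressWarnings(
    stats::glm(data$anchor ~ x, family = stats::binomial(),
               control = stats::glm.control(epsilon = 1e-10, maxit = 100))
  )
  if (!fit$converged)
    stop_convergence(paste0("logistic fit did not converge after ",
                            fit$iter, " iterations"))
  B <- unname(stats::coef(fit)[2])
  # quasi-complete separation escapes the pre-check but shows up as a slope
  # that is huge on the scale of the data
  if (is.finite(B) && abs(B) * stats::sd(x) > 30)
    stop_separation("quasi-complete separation: slope diverges")
  structure(list(C = unname(stats::coef(fit)[1]), B = B,
                 converged = fit$converged, n_iter = fit$iter,
                 n = data$n, center = shift),
            class = "anchor_logit")
}

#' @export
print.anchor_logit <- function(x, ...) {
  cat("Anchor logit: logit P(improved) = C + B * change\n")
  cat("  C = ", format(x$C, digits = 4), ", B = ", format(x$B, digits = 4),
      "  (n = ", x$n, ", ", x$n_iter, " IRLS iterations",
      if (x$center != 0) paste0(", change centered at ", fmt1(x$center)),
      ")\n", sep = "")
  invisible(x)
}

#' Pre-test odds of improvement
#'
#' `odds_pre = p/(1 - p)` where `p` is the anchor's improvement rate.
#'
#' @param n_improved Number of improved (anchor = 1) patients.
#' @param n_total Total number of patients.
#' @return Positive odds ratio.
#' @examples
#' compute_odds_pre(187, 277)  # 2.078
#' @export
compute_odds_pre <- function(n_improved, n_total) {
  stopifnot(n_total >= 1)
  if (n_improved <= 0 || n_improved >= n_total)
    stop_degenerate("improvement prevalence is 0 or 1; odds undefined")
  p <- n_improved / n_total
  p / (1 - p)
}

#' Predictive-modeling MIC
#'
#' `MIC_pred = (ln(odds_pre) - C) / B`: the change score at which the
#' fitted probability of improvement equals the pre-test prevalence.
#'
#' @param fit An `anchor_logit` object (or a list with `C` and `B`).
#' @param odds_pre Positive pre-test odds from [compute_odds_pre()].
#' @return MIC in score points.
#' @examples
#' mic_pred(list(C = 0, B = 0.5), odds_pre = 2)  # log(2)/0.5
#' @export
mic_pred <- function(fit, odds_pre) {
  stopifnot(odds_pre > 0)
  if (abs(fit$B) < 1e-12)
    stop_degenerate("logistic slope is zero; anchor uninformative, MIC_pred undefined")
  shift <- fit$center %||% 0
  (log(odds_pre) - fit$C) / fit$B + shift
}

#' Bias-correction term S
#'
#' `S = 0.09 * SD_chang + 0.103 * SD_chang * Cor`, where `SD_chang` is the
#' change-score standard deviation and `Cor` the point-biserial
#' anchor-change correlation.
#'
#' @param sd_chang Non-negative standard deviation of the change score.
#' @param cor Point-biserial correlation in \[-1, 1\].
#' @return S in score points (non-negative whenever `cor >= -0.874`).
#' @examples
#' compute_S(14.5, 0.29)
#' @export
compute_S <- function(sd_chang, cor) {
  stopifnot(sd_chang >= 0, abs(cor) <= 1)
  0.09 * sd_chang + 0.103 * sd_chang * cor
}

#' Adjusted predictive-modeling MIC
#'
#' `MIC_adj = MIC_pred - S * ln(odds_pre)`.  The predictive-modeling MIC is
#' biased upward when the improved proportion exceeds 50% (and downward
#' below 50%); this subtracts the estimated bias.
#'
#' @param mic_pred Predictive-modeling MIC in score points.
#' @param S Bias-correction term from [compute_S()].
#' @param odds_pre Pre-test odds of improvement.
#' @return Adjusted MIC in score points.
#' @examples
#' mic_adj(19.9, compute_S(14.5, 0.29), 187 / 90)  # 18.63
#' @export
mic_adj <- function(mic_pred, S, odds_pre) {
  stopifnot(odds_pre > 0)
  mic_pred - S * log(odds_pre)
}

#' ROC/Youden MIC
#'
#' The change-score cutoff maximizing the Youden index
#' J = sensitivity + specificity - 1, where a patient is classified improved
#' when change >= cutoff.  Candidate cutoffs are the midpoints between
#' consecutive distinct observed change values (half-integers on integer
#' scores); on ties the smallest tying cutoff is returned, i.e. the most
#' conservative labelling of change as important.
#'
#' @param data A `change_data` object with both anchor classes and at least
#'   two distinct change values.
#' @return The optimal cutoff in score points, with attributes `youden`,
#'   `sensitivity`, `specificity`.
#' @examples
#' d <- change_data(c(0, 1, 2, 10, 11, 12), c(0, 0, 0, 1, 1, 1), "motor")
#' mic_roc(d)  # 6
#' @export
mic_roc <- function(data) {
  stopifnot(inherits(data, "change_data"))
  if (length(unique(data$anchor)) < 2)
    stop_degenerate("anchor has a single class; ROC undefined")
  v <- sort(unique(data$change))
  if (length(v) < 2)
    stop_degenerate("change score is constant; no candidate cutoffs")
  cuts <- (v[-1] + v[-length(v)]) / 2
  idx <- match(data$change, v)
  n1 <- sum(data$anchor == 1); n0 <- data$n - n1
  cnt1 <- tabulate(idx[data$anchor == 1], nbins = length(v))
  cnt0 <- tabulate(idx[data$anchor == 0], nbins = length(v))
  # at cutoff between v[k] and v[k+1]: sens = P1(change > v[k]), spec = P0(<=)
  F1 <- cumsum(cnt1)[-length(v)] / n1
  F0 <- cumsum(cnt0)[-length(v)] / n0
  J <- F0 - F1
  best <- which(J >= max(J) - 1e-12)[1]
  structure(cuts[best], youden = J[best],
            sensitivity = 1 - F1[best], specificity = F0[best])
}

#' Estimate all MIC quantities for one domain
#'
#' Composes the full per-domain estimate: prevalence and pre-test odds from
#' the anchor, change-score SD (sample, n-1 denominator), point-biserial
#' correlation, the bias term S, and the three MIC estimators.  Confidence
#' intervals are added separately by [bootstrap_ci()] or [mic_fim()].
#'
#' @param data A `change_data` object.
#' @param center Passed to [fit_anchor_logistic()].
#' @return An object of class `mic_estimate`: list with `domain`, `n`,
#'   `prevalence`, `odds_pre`, `cor`, `sd_chang`, `S`, `mic_roc`,
#'   `mic_pred`, `mic_adj`, `fit`.
#' @export
estimate_mic <- function(data, center = FALSE) {
  stopifnot(inherits(data, "change_data"))
  n1 <- sum(data$anchor)
  odds <- compute_odds_pre(n1, data$n)
  r <- point_biserial(data)
  sdch <- stats::sd(data$change)
  fit <- fit_anchor_logistic(data, center = center)
  pred <- mic_pred(fit, odds)
  S <- compute_S(sdch, r)
  roc <- mic_roc(data)
  structure(list(
    domain = data$domain, n = data$n,
    prevalence = n1 / data$n, odds_pre = odds,
    cor = r, sd_chang = sdch, S = S,
    mic_roc = as.numeric(roc), mic_pred = pred,
    mic_adj = mic_adj(pred, S, odds),
    fit = fit
  ), class = "mic_estimate")
}

#' @export
print.mic_estimate <- function(x, ...) {
  cat("MIC estimate (", x$domain, " FIM, n = ", x$n, ")\n", sep = "")
  cat("  prevalence improved: ", fmt1(100 * x$prevalence), "%  (odds_pre ",
      format(x$odds_pre, digits = 4), ")\n", sep = "")
  cat("  anchor correlation (point-biserial): ",
      format(x$cor, digits = 2), "\n", sep = "")
  cat("  MIC_roc  = ", fmt1(x$mic_roc),
      "\n  MIC_pred = ", fmt1(x$mic_pred),
      "\n  MIC_adj  = ", fmt1(x$mic_adj),
      "  (headline integer ", round_half_up(x$mic_adj), ")\n", sep = "")
  invisible(x)
}
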