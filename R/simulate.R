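# Synthetic cohorts: a two-group equal-variance normal change model.
#
# The anchor-based framework posits improved and non-improved patients
# whose change scores come from two distributions; the genuine MIC is
# where the densities cross.  With equal within-group variance the two
# normals can be calibrated from four observable summaries (marginal mean
# and SD of change, improvement prevalence, point-biserial correlation) by
# moment matching, and the crossing point is simply the midpoint of the
# group means.  Under this model the logistic regression of anchor on
# change is correctly specified, so MIC_pred is consistent for the genuine
# MIC -- making large-n recovery a sharp end-to-end test of the pipeline.

#' Calibrate the two-group change model from cohort summaries
#'
#' Solves the moment equations so that the generated marginal mean, SD,
#' prevalence and point-biserial correlation match the supplied summaries
#' in expectation.  With `d = r_pb * sd_change / sqrt(p*(1-p))`:
#' `mu_improved = mean + (1-p)*d`, `mu_nonimproved = mean - p*d`,
#' `sd_within = sqrt(sd_change^2 - d^2*p*(1-p))`.
#'
#' @param mean_change Marginal mean change score.
#' @param sd_change Marginal SD of the change score (> 0).
#' @param prevalence Improvement prevalence in (0, 1).
#' @param r_pb Point-biserial anchor-change correlation.  Infeasible
#'   combinations (|r_pb| too large for the SD) raise a calibration error.
#' @return An object of class `sim_spec`: list with `mu_improved`,
#'   `mu_nonimproved`, `sd_within`, `prevalence`, plus the calibrating
#'   summaries.
#' @examples
#' calibrate_change_model(21.7, 14.5, 187 / 277, 0.29)
#' @export
calibrate_change_model <- function(mean_change, sd_change, prevalence, r_pb) {
  stopifnot(sd_change > 0, abs(r_pb) <= 1)
  if (prevalence <= 0 || prevalence >= 1)
    stop_degenerate("prevalence must lie strictly between 0 and 1")
  pq <- prevalence * (1 - prevalence)
  d <- r_pb * sd_change / sqrt(pq)
  resid_var <- sd_change^2 - d^2 * pq
  if (resid_var <= 0)
    mic_stop("micfim_calibration_error",
             "infeasible summary: |r_pb| too large for the stated SD")
  structure(list(
    mu_improved = mean_change + (1 - prevalence) * d,
    mu_nonimproved = mean_change - prevalence * d,
    sd_within = sqrt(resid_var),
    prevalence = prevalence,
    mean_change = mean_change, sd_change = sd_change, r_pb = r_pb
  ), class = "sim_spec")
}

#' Construct a simulation spec directly
#'
#' @param mu_improved,mu_nonimproved Group mean change scores.
#' @param sd_within Common within-group SD (> 0).
#' @param prevalence Improvement prevalence in (0, 1).
#' @return An object of class `sim_spec`.
#' @export
sim_spec <- function(mu_improved, mu_nonimproved, sd_within, prevalence) {
  stopifnot(sd_within > 0)
  if (prevalence <= 0 || prevalence >= 1)
    stop_degenerate("prevalence must lie strictly between 0 and 1")
  structure(list(mu_improved = mu_improved, mu_nonimproved = mu_nonimproved,
                 sd_within = sd_within, prevalence = prevalence),
            class = "sim_spec")
}

#' @export
print.sim_spec <- function(x, ...) {
  cat("Two-group equal-variance change model\n")
  cat("  improved:     N(", fmt1(x$mu_improved), ", ", fmt1(x$sd_within),
      "^2), prevalence ", fmt1(100 * x$prevalence), "%\n", sep = "")
  cat("  non-improved: N(", fmt1(x$mu_nonimproved), ", ", fmt1(x$sd_within),
      "^2)\n", sep = "")
  cat("  genuine MIC (density crossing): ", fmt1(genuine_mic(x)), "\n",
      sep = "")
  invisible(x)
}

#' Genuine MIC of a simulation spec
#'
#' The density-intersection point of the two equal-variance normal change
#' distributions, `(mu_improved + mu_nonimproved)/2` -- the ground truth
#' that estimator-recovery studies target.
#'
#' @param spec A `sim_spec`.
#' @return Score points.
#' @export
genuine_mic <- function(spec) {
  stopifnot(inherits(spec, "sim_spec"))
  (spec$mu_improved + spec$mu_nonimproved) / 2
}

#' Simulate a change dataset from the two-group model
#'
#' Draws `anchor ~ Bernoulli(prevalence)` and, given the group, `change ~
#' Normal(group mean, sd_within)`.  Optionally rounds changes to integers
#' and clamps them to the domain's attainable range for realism; both are
#' off by default because they perturb the matched moments slightly.
#'
#' @param spec A `sim_spec`.
#' @param n Number of patients.
#' @param seed Integer seed; the draw is fully reproducible.
#' @param domain FIM domain label for the resulting dataset.
#' @param integerize Round change scores to integers.
#' @param clamp Clamp changes to the domain's attainable range.
#' @return A `change_data` object.
#' @export
simulate_change_data <- function(spec, n, seed = 1L,
                                 domain = fim_domains,
                                 integerize = FALSE, clamp = FALSE) {
  stopifnot(inherits(spec, "sim_spec"), n >= 1)
  domain <- match.arg(domain)
  dat <- with_seed(seed, {
    anchor <- stats::rbinom(n, 1L, spec$prevalence)
    mu <- ifelse(anchor == 1, spec$mu_improved, spec$mu_nonimproved)
    list(anchor = anchor, change = stats::rnorm(n, mu, spec$sd_within))
  })
  ch <- dat$change
  if (integerize) ch <- round(ch)
  if (clamp) {
    rng <- fim_ranges[[domain]]
    span <- unname(rng["max"] - rng["min"])
    ch <- pmin(pmax(ch, -span), span)
  }
  change_data(ch, dat$anchor, domain, check_range = clamp)
}

#' Simulate a full FIM cohort in the ingestion schema
#'
#' Generates a synthetic patient table with admission and discharge motor
#' and cognitive scores plus the anchor, suitable for [read_cohort()] /
#' [mic_fim()].  One anchor is drawn per patient; motor and cognitive
#' changes are then drawn from their two-group models conditionally on it.
#' Admission scores are drawn around supplied baseline means and clamped
#' into the FIM range; discharge = admission + change, clamped likewise,
#' so realized changes near the scale bounds are slightly truncated.  The
#' output is synthetic and flagged as such via the `synthetic` attribute.
#'
#' @param n Number of patients.
#' @param motor_spec,cognitive_spec `sim_spec` objects for the two domains.
#' @param baseline Named list with `motor` and `cognitive`, each `c(mean,
#'   sd)` of the admission score.
#' @param seed Integer seed.
#' @return A validated `fim_cohort` with attribute `synthetic = TRUE`.
#' @export
simulate_fim_cohort <- function(n, motor_spec, cognitive_spec,
                                baseline = list(motor = c(39.1, 21.2),
                                                cognitive = c(19.7, 8.5)),
                                seed = 1L) {
  stopifnot(inherits(motor_spec, "sim_spec"),
            inherits(cognitive_spec, "sim_spec"), n >= 1)
  seeds <- child_seeds(seed, 4L)
  anchor <- with_seed(seeds[1], stats::rbinom(n, 1L, motor_spec$prevalence))
  draw_domain <- function(spec, bl, rng, s_adm, s_ch) {
    mu <- ifelse(anchor == 1, spec$mu_improved, spec$mu_nonimproved)
    adm <- with_seed(s_adm, round(stats::rnorm(n, bl[1], bl[2])))
    adm <- pmin(pmax(adm, rng["min"]), rng["max"])
    ch <- with_seed(s_ch, round(stats::rnorm(n, mu, spec$sd_within)))
    dis <- pmin(pmax(adm + ch, rng["min"]), rng["max"])
    list(adm = adm, dis = dis)
  }
  mot <- draw_domain(motor_spec, baseline$motor, fim_ranges$motor,
                     seeds[2], seeds[3])
  cog <- draw_domain(cognitive_spec, baseline$cognitive, fim_ranges$cognitive,
                     seeds[2] + 1L, seeds[4])
  coh <- validate_cohort(data.frame(
    patient_id = sprintf("SYN%05d", seq_len(n)),
    motor_adm = mot$adm, cognitive_adm = cog$adm,
    motor_dis = mot$dis, cognitive_dis = cog$dis,
    anchor = anchor
  ))
  attr(coh, "synthetic") <- TRUE
  coh
}
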