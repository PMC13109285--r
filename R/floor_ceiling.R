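# Floor/ceiling screening at baseline: the 15% rule.
#
# A floor (ceiling) effect exists when at least 15% of patients sit at the
# scale minimum (maximum) at baseline, which truncates measurable change
# and distorts the MIC.  Only admission scores enter this check.

#' Floor and ceiling effects at baseline
#'
#' Computes the share of patients at the FIM domain's minimum and maximum
#' admission score and flags a floor/ceiling effect when either reaches
#' 15%.
#'
#' @param records A `fim_cohort` data frame.
#' @param domain `"motor"`, `"cognitive"` or `"total"`.
#' @param threshold Flagging threshold in percent (15 by convention).
#' @return An object of class `floor_ceiling`: list with `domain`, `n`,
#'   `n_at_min`, `n_at_max`, `pct_min`, `pct_max`, `floor_flag`,
#'   `ceiling_flag`, `min_score`, `max_score`.
#' @examples
#' coh <- validate_cohort(data.frame(
#'   motor_adm = c(13, 40), cognitive_adm = c(5, 20),
#'   motor_dis = c(30, 60), cognitive_dis = c(10, 25), anchor = c(0, 1)))
#' assess_floor_ceiling(coh, "motor")
#' @export
assess_floor_ceiling <- function(records, domain = fim_domains,
                                 threshold = 15) {
  domain <- match.arg(domain)
  if (!nrow(records)) stop_validation("empty cohort")
  rng <- fim_ranges[[domain]]
  baseline <- domain_score(records, domain, "adm")
  n <- length(baseline)
  n_min <- sum(baseline == rng["min"])
  n_max <- sum(baseline == rng["max"])
  structure(list(
    domain = domain, n = n, n_at_min = n_min, n_at_max = n_max,
    pct_min = 100 * n_min / n, pct_max = 100 * n_max / n,
    floor_flag = 100 * n_min / n >= threshold,
    ceiling_flag = 100 * n_max / n >= threshold,
    min_score = unname(rng["min"]), max_score = unname(rng["max"])
  ), class = "floor_ceiling")
}

#' @export
print.floor_ceiling <- function(x, ...) {
  cat(x$domain, " FIM baseline (n = ", x$n, "): ",
      x$n_at_min, " at minimum ", x$min_score, " (", fmt1(x$pct_min), "%), ",
      x$n_at_max, " at maximum ", x$max_score, " (", fmt1(x$pct_max), "%)\n",
      "  floor effect: ", if (x$floor_flag) "YES" else "no",
      ";  ceiling effect: ", if (x$ceiling_flag) "YES" else "no", "\n",
      sep = "")
  invisible(x)
}
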