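test_that("point-biserial correlation equals the Pearson correlation", {
  d <- change_data(c(1, 2, 3, 4), c(0, 0, 1, 1), "motor")
  expect_equal(point_biserial(d), 2 / sqrt(5), tolerance = 1e-12)  # 0.8944

  for (seed in 1:10) {
    d <- random_change_data(seed)
    expect_equal(point_biserial(d), oracle_pearson(d$change, d$anchor),
                 tolerance = 1e-12)
  }
})

test_that("correlation is zero in expectation for an exchangeable anchor", {
  # average the correlation over all distinct balanced labellings of a
  # 4-point change vector: exchangeability forces mean zero
  ch <- c(2, 5, 9, 14)
  perms <- unique(combn(4, 2, simplify = FALSE))
  r <- vapply(perms, function(idx) {
    an <- rep(0, 4); an[idx] <- 1
    point_biserial(change_data(ch, an, "motor"))
  }, numeric(1))
  expect_equal(mean(r), 0, tolerance = 1e-12)
})

test_that("degenerate inputs to point_biserial raise classed errors", {
  expect_error(point_biserial(change_data(c(5, 5, 5), c(0, 1, 1), "motor")),
               class = "micfim_degenerate_error")
  expect_error(point_biserial(change_data(c(1, 2, 3), c(1, 1, 1), "motor")),
               class = "micfim_degenerate_error")
})

test_that("logistic fit recovers a known generating logit", {
  # simulate from logit P(y=1) = -0.5 + 0.3*x at large n, refit
  set.seed(101)
  n <- 10000
  x <- round(rnorm(n, 10, 8))
  pr <- plogis(-0.5 + 0.3 * x)
  y <- rbinom(n, 1, pr)
  fit <- fit_anchor_logistic(change_data(x, y, "motor"))
  expect_true(fit$converged)
  expect_equal(fit$C, -0.5, tolerance = 0.05)
  expect_equal(fit$B, 0.3, tolerance = 0.05)
})

test_that("logistic fit agrees with a direct likelihood maximization", {
  for (seed in c(3, 7)) {
    d <- random_change_data(seed, n = 60)
    fit <- fit_anchor_logistic(d)
    ora <- oracle_logit(d$change, d$anchor)
    expect_equal(fit$C, ora$C, tolerance = 1e-3)
    expect_equal(fit$B, ora$B, tolerance = 1e-3)
  }
})

test_that("balanced symmetric classes give a zero logit intercept", {
  # classes are balanced so the intercept is 0 at the MLE; pad the
  # 4-point pattern to meet the n >= 10 floor
  ch <- rep(c(-2, -1, 1, 2), 3)
  an <- rep(c(0, 1, 0, 1), 3)
  fit <- fit_anchor_logistic(change_data(ch, an, "motor"))
  expect_equal(fit$C, 0, tolerance = 1e-6)
})

test_that("separation is a hard error, not a huge slope", {
  d <- change_data(rep(c(1, 2, 3, 4), 3), rep(c(0, 0, 1, 1), 3), "motor")
  expect_error(fit_anchor_logistic(d), class = "micfim_separation_error")
  expect_error(fit_anchor_logistic(
    change_data(rep(1, 12), rep(1, 12), "motor")),
    class = "micfim_degenerate_error")
})

test_that("centering the covariate leaves MIC_pred unchanged", {
  d <- random_change_data(11, n = 80)
  odds <- compute_odds_pre(sum(d$anchor), d$n)
  m0 <- mic_pred(fit_anchor_logistic(d, center = FALSE), odds)
  m1 <- mic_pred(fit_anchor_logistic(d, center = TRUE), odds)
  expect_equal(m0, m1, tolerance = 1e-6)
})

test_that("pre-test odds follow p/(1-p)", {
  expect_equal(compute_odds_pre(187, 277), (187 / 277) / (90 / 277),
               tolerance = 1e-12)
  expect_equal(compute_odds_pre(187, 277), 187 / 90, tolerance = 1e-12)
  expect_equal(compute_odds_pre(50, 100), 1)
  expect_error(compute_odds_pre(0, 100), class = "micfim_degenerate_error")
  expect_error(compute_odds_pre(100, 100), class = "micfim_degenerate_error")
})

test_that("MIC_pred evaluates (ln(odds_pre) - C)/B", {
  expect_equal(mic_pred(list(C = 0, B = 0.5), 2), log(2) / 0.5,
               tolerance = 1e-12)  # 1.3863
  expect_equal(mic_pred(list(C = log(3.7), B = 1.9), 3.7), 0,
               tolerance = 1e-12)
  # coefficients implied by the calibrated equal-variance motor model
  expect_equal(mic_pred(list(C = -0.2076, B = 0.04662), 2.0778), 20.13,
               tolerance = 0.02)
  expect_error(mic_pred(list(C = 1, B = 0), 2),
               class = "micfim_degenerate_error")
})

test_that("the bias term S follows 0.09*SD + 0.103*SD*Cor", {
  expect_equal(compute_S(14.5, 0.29), 1.738115, tolerance = 1e-6)
  expect_equal(compute_S(4.8, 0.02), 0.441888, tolerance = 1e-6)
  expect_equal(compute_S(0, 0.7), 0)
  # non-negative for any correlation above -0.874
  for (r in seq(-0.87, 1, by = 0.1))
    expect_gte(compute_S(10, r), 0)
})

test_that("MIC_adj subtracts S*ln(odds_pre) and reproduces printed values", {
  expect_equal(round(mic_adj(19.9, 1.7381, 2.0778), 1), 18.6)
  expect_equal(round(mic_adj(24.2, 1.9562, 2.0778), 1), 22.8)
  expect_equal(mic_adj(7.3, 2.2, 1), 7.3)  # ln(1) = 0
})

test_that("the Youden cutoff sits at the separating midpoint", {
  d <- change_data(c(0, 1, 2, 10, 11, 12), c(0, 0, 0, 1, 1, 1), "motor")
  cut <- mic_roc(d)
  expect_equal(as.numeric(cut), 6)
  expect_equal(attr(cut, "youden"), 1)
})

test_that("with zero discrimination every cutoff ties and the lowest wins", {
  d <- change_data(c(0, 0, 10, 10), c(0, 1, 0, 1), "motor")
  expect_equal(as.numeric(mic_roc(d)), 5)  # the only candidate, J = 0
  expect_equal(attr(mic_roc(d), "youden"), 0)
  expect_error(mic_roc(change_data(rep(3, 4), c(0, 1, 0, 1), "motor")),
               class = "micfim_degenerate_error")
  expect_error(mic_roc(change_data(c(1, 2), c(1, 1), "motor")),
               class = "micfim_degenerate_error")
})

test_that("the Youden search matches an exhaustive-midpoint oracle", {
  for (seed in 1:20) {
    d <- random_change_data(seed, n = 25)
    ora <- oracle_youden(d$change, d$anchor)
    cut <- mic_roc(d)
    expect_equal(as.numeric(cut), ora$cutoff)
    expect_equal(attr(cut, "youden"), ora$J, tolerance = 1e-12)
  }
})

test_that("the Youden cutoff agrees with pROC on a clean fixture", {
  skip_if_not_installed("pROC")
  d <- random_change_data(42, n = 80)
  r <- pROC::roc(d$anchor, d$change, direction = "<", quiet = TRUE)
  best <- pROC::coords(r, x = "best", best.method = "youden",
                       transpose = FALSE)
  expect_true(as.numeric(mic_roc(d)) %in% best$threshold)
})

test_that("estimate_mic composes the pieces coherently", {
  d <- random_change_data(5, n = 20)
  e <- estimate_mic(d)
  # spreadsheet-style oracle, field by field
  r <- oracle_pearson(d$change, d$anchor)
  ml <- oracle_logit(d$change, d$anchor)
  p <- mean(d$anchor); odds <- p / (1 - p)
  pred <- (log(odds) - ml$C) / ml$B
  S <- 0.09 * sd(d$change) + 0.103 * sd(d$change) * r
  expect_equal(e$prevalence, p)
  expect_equal(e$odds_pre, odds, tolerance = 1e-12)
  expect_equal(e$cor, r, tolerance = 1e-9)
  expect_equal(e$sd_chang, sd(d$change))
  expect_equal(e$S, S, tolerance = 1e-9)
  expect_equal(e$mic_pred, pred, tolerance = 1e-3)
  expect_equal(e$mic_adj, pred - S * log(odds), tolerance = 1e-3)
  expect_equal(e$mic_roc, oracle_youden(d$change, d$anchor)$cutoff)
  # internal consistency of the stored fields
  expect_equal(e$odds_pre, e$prevalence / (1 - e$prevalence))
  expect_equal(e$mic_adj, e$mic_pred - e$S * log(e$odds_pre),
               tolerance = 1e-12)
})

test_that("prevalence one half makes the adjustment vanish", {
  set.seed(8)
  an <- rep(c(0, 1), each = 15)
  ch <- round(rnorm(30, 10 + 6 * an, 8))
  e <- estimate_mic(change_data(ch, an, "motor"))
  expect_equal(e$mic_adj, e$mic_pred, tolerance = 1e-12)
  expect_equal(e$mic_pred, -e$fit$C / e$fit$B, tolerance = 1e-9)
})

test_that("adjustment direction follows the improvement prevalence", {
  for (seed in 1:6) {
    set.seed(seed)
    n <- 60
    p <- sample(c(0.2, 0.8), 1)
    an <- c(rep(1, round(n * p)), rep(0, n - round(n * p)))
    ch <- round(rnorm(n, 10 + 6 * an, 9))
    e <- tryCatch(estimate_mic(change_data(ch, an, "motor")),
                  micfim_error = function(err) NULL)
    if (is.null(e) || e$S <= 0) next
    if (e$prevalence > 0.5) expect_lt(e$mic_adj, e$mic_pred)
    if (e$prevalence < 0.5) expect_gt(e$mic_adj, e$mic_pred)
  }
})

test_that("all three estimators are shift and scale equivariant", {
  d <- random_change_data(13, n = 60)
  e <- estimate_mic(d)
  k <- 7; a <- 2.5
  shifted <- change_data(d$change + k, d$anchor, "motor")
  es <- estimate_mic(shifted)
  expect_equal(es$fit$B, e$fit$B, tolerance = 1e-6)
  expect_equal(es$fit$C, e$fit$C - e$fit$B * k, tolerance = 1e-5)
  expect_equal(es$mic_pred, e$mic_pred + k, tolerance = 1e-5)
  expect_equal(es$mic_adj, e$mic_adj + k, tolerance = 1e-5)
  expect_equal(es$mic_roc, e$mic_roc + k)

  scaled <- change_data(d$change * a, d$anchor, "motor",
                        check_range = FALSE)
  ea <- estimate_mic(scaled)
  expect_equal(ea$mic_pred, a * e$mic_pred, tolerance = 1e-5)
  expect_equal(ea$mic_adj, a * e$mic_adj, tolerance = 1e-5)
  expect_equal(ea$mic_roc, a * e$mic_roc)
  expect_equal(ea$sd_chang, a * e$sd_chang)
  expect_equal(ea$S, a * e$S, tolerance = 1e-9)
  expect_equal(ea$cor, e$cor, tolerance = 1e-12)
  expect_equal(ea$prevalence, e$prevalence)
})
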