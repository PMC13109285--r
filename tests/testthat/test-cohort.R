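test_that("well-formed cohorts pass through ingestion unchanged", {
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(hand_cohort()[1:3, ], path, row.names = FALSE, quote = FALSE)
  coh <- read_cohort(path)
  expect_s3_class(coh, "fim_cohort")
  expect_equal(nrow(coh), 3)
  expect_equal(coh$motor_adm, c(39, 50, 13))
  expect_identical(attr(coh, "n_excluded"), 0L)
})

test_that("ingestion round-trips losslessly through write_cohort", {
  p1 <- withr::local_tempfile(fileext = ".csv")
  p2 <- withr::local_tempfile(fileext = ".csv")
  write.csv(hand_cohort(), p1, row.names = FALSE, quote = FALSE)
  coh <- read_cohort(p1)
  write_cohort(coh, p2)
  expect_equal(as.data.frame(read_cohort(p2)), as.data.frame(coh))
})

test_that("tab-delimited input and column remapping are supported", {
  df <- hand_cohort()
  names(df)[2] <- "FIM_M_adm"
  path <- withr::local_tempfile(fileext = ".tsv")
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  coh <- read_cohort(path, delimiter = "\t",
                     column_map = c(motor_adm = "FIM_M_adm"))
  expect_equal(coh$motor_adm, hand_cohort()$motor_adm)
  expect_error(read_cohort(path, delimiter = "\t"),
               class = "micfim_config_error")
})

test_that("out-of-range scores are rejected with row and field named", {
  df <- hand_cohort()
  df$motor_adm[2] <- 12  # below the motor minimum of 13
  err <- expect_error(validate_cohort(df), class = "micfim_validation_error")
  expect_match(conditionMessage(err), "motor_adm")
  expect_match(conditionMessage(err), "13")
  expect_match(conditionMessage(err), "2")

  df2 <- hand_cohort(); df2$anchor[4] <- 2
  expect_error(validate_cohort(df2), class = "micfim_validation_error")

  df3 <- hand_cohort(); df3$cognitive_dis[1] <- 36
  expect_error(validate_cohort(df3), class = "micfim_validation_error")
})

test_that("records with missing values are excluded listwise and counted", {
  df <- hand_cohort()
  df$motor_dis[3] <- NA
  coh <- validate_cohort(df)
  expect_equal(nrow(coh), 5)
  expect_identical(attr(coh, "n_excluded"), 1L)
})

test_that("item-level input is summed to domain scores", {
  set.seed(1)
  items_m <- matrix(sample(1:7, 13 * 4, TRUE), 4)
  items_c <- matrix(sample(1:7, 5 * 4, TRUE), 4)
  df <- data.frame(items_m, items_c)
  names(df) <- c(paste0("m", 1:13), paste0("c", 1:5))
  df$motor_dis <- rowSums(items_m); df$cognitive_dis <- rowSums(items_c)
  df$anchor <- c(1, 0, 1, 0)
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  coh <- read_cohort(path, item_columns = list(
    motor_adm = paste0("m", 1:13), cognitive_adm = paste0("c", 1:5)))
  expect_equal(coh$motor_adm, rowSums(items_m))
  expect_equal(coh$cognitive_adm, rowSums(items_c))
})

test_that("change scores are discharge minus admission, totals summed first", {
  coh <- validate_cohort(hand_cohort())
  d <- build_change_dataset(coh, "motor")
  expect_equal(d$change, c(60, 70, 30, 85, 50, 62) - c(39, 50, 13, 70, 45, 60))
  expect_equal(d$anchor, c(1L, 1L, 0L, 1L, 0L, 1L))

  # extreme but legal case spans the full total range
  ext <- validate_cohort(data.frame(
    motor_adm = c(13, 40), cognitive_adm = c(5, 20),
    motor_dis = c(91, 60), cognitive_dis = c(35, 25), anchor = c(1, 0)))
  expect_equal(build_change_dataset(ext, "total")$change[1], 108)
})

test_that("total change equals motor change plus cognitive change", {
  for (seed in 1:5) {
    set.seed(seed)
    n <- 20
    df <- data.frame(
      motor_adm = sample(13:60, n, TRUE), cognitive_adm = sample(5:25, n, TRUE),
      motor_dis = sample(30:91, n, TRUE), cognitive_dis = sample(10:35, n, TRUE),
      anchor = rbinom(n, 1, 0.5))
    coh <- validate_cohort(df)
    expect_equal(build_change_dataset(coh, "total")$change,
                 build_change_dataset(coh, "motor")$change +
                   build_change_dataset(coh, "cognitive")$change)
  }
})

test_that("change_data enforces its invariants", {
  expect_error(change_data(1:3, c(0, 1), "motor"),
               class = "micfim_validation_error")
  expect_error(change_data(numeric(0), integer(0), "motor"),
               class = "micfim_validation_error")
  expect_error(change_data(c(1, 2), c(0, 2), "motor"),
               class = "micfim_validation_error")
  expect_error(change_data(c(1, 100), c(0, 1), "motor"),
               class = "micfim_validation_error")  # beyond +-78
  expect_silent(d <- change_data(c(-78, 78), c(0, 1), "motor"))
  expect_error(build_change_dataset(validate_cohort(hand_cohort())[0, ], "motor"),
               class = "micfim_validation_error")
})
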