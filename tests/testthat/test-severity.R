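test_that("intercept-only Poisson MLE is the log of the sample mean", {
  d <- data.frame(attack_count = c(0, 1, 2, 3))
  fit <- fit_poisson(d, covariate_names = character(0))
  expect_equal(unname(fit$coefficients[["(Intercept)"]]), log(1.5), tolerance = 1e-7)
  expect_true(fit$converged)
})

test_that("degenerate designs are rejected with named errors", {
  d <- data.frame(attack_count = rpois(30, 1), temperature = rnorm(30))
  d$temp2 <- 2 * d$temperature  # perfectly collinear
  expect_error(fit_poisson(d, c("temperature", "temp2")),
               class = "rpclim_design_error")
  z <- data.frame(attack_count = rep(0, 30), temperature = rnorm(30))
  expect_error(fit_poisson(z), class = "rpclim_degenerate_fit")
})

test_that("IRLS agrees with glm and recovers simulated coefficients", {
  truth <- c(0.3, -0.12)
  d <- gen_diaries(diary_sim_params(n_patients = 1, n_days = 2000, seed = 7))
  fit <- fit_poisson(d)
  se <- sqrt(diag(fit$covariance))
  expect_lt(abs(fit$coefficients[["(Intercept)"]] - truth[1]), 2 * se[1])
  expect_lt(abs(fit$coefficients[["temperature"]] - truth[2]), 2 * se[2])

  ref <- stats::glm(attack_count ~ temperature, family = poisson(), data = d)
  expect_equal(unname(fit$coefficients), unname(coef(ref)), tolerance = 1e-6)
  expect_equal(unname(diag(fit$covariance)), unname(diag(vcov(ref))),
               tolerance = 1e-4)
  expect_equal(fit$log_likelihood, as.numeric(logLik(ref)), tolerance = 1e-8)
})

test_that("IRLS matches an independent grid-search likelihood maximizer", {
  set.seed(19)
  for (rep in 1:5) {
    n <- sample(50:200, 1)
    temp <- runif(n, -5, 15)
    b <- c(runif(1, -0.5, 0.8), runif(1, -0.2, 0.05))
    d <- data.frame(attack_count = rpois(n, exp(b[1] + b[2] * temp)),
                    temperature = temp)
    if (all(d$attack_count == 0)) next
    fit <- fit_poisson(d)
    X <- cbind(1, temp)
    best <- poisson_grid_search(X, d$attack_count,
                                lower = c(-3, -1), upper = c(3, 1))
    expect_equal(unname(fit$coefficients), unname(best), tolerance = 1e-4)
  }
})

test_that("log-likelihood never decreases across IRLS iterations", {
  set.seed(3)
  for (rep in 1:10) {
    n <- sample(20:300, 1)
    temp <- runif(n, -10, 20)
    d <- data.frame(attack_count = rpois(n, exp(runif(1, -1, 1) - 0.1 * temp / 2)),
                    temperature = temp)
    if (all(d$attack_count == 0)) next
    fit <- fit_poisson(d)
    expect_true(all(diff(fit$ll_trace) >= -1e-9))
    expect_true(fit$converged)
  }
})

test_that("the covariance is symmetric positive semidefinite", {
  set.seed(2)
  d <- data.frame(attack_count = rpois(200, 1.2),
                  temperature = runif(200, -5, 15),
                  humidity = runif(200))
  fit <- fit_poisson(d, c("temperature", "humidity"))
  expect_equal(fit$covariance, t(fit$covariance))
  expect_true(all(eigen(fit$covariance, symmetric = TRUE)$values > -1e-12))
})

test_that("patient fixed effects add indicator coefficients", {
  set.seed(4)
  d <- gen_diaries(diary_sim_params(n_patients = 3, n_days = 120, seed = 4))
  fit <- fit_poisson(d, patient_effects = TRUE)
  expect_setequal(setdiff(names(fit$coefficients), c("(Intercept)", "temperature")),
                  c("patient:P02", "patient:P03"))
  ref <- stats::glm(attack_count ~ temperature + factor(patient_id),
                    family = poisson(), data = d)
  expect_equal(unname(sort(fit$coefficients)), unname(sort(coef(ref))),
               tolerance = 1e-6)
})

test_that("weekly predictions are 7x the daily rate, zeroed above the ceiling", {
  flat <- severity_fit_from_coefficients(c("(Intercept)" = log(2 / 7)))
  expect_equal(predict_weekly_attacks(flat, 5), 2.0)
  expect_equal(predict_weekly_attacks(flat, -20), 2.0)  # no temperature term

  fit <- severity_fit_from_coefficients(
    c("(Intercept)" = 0.3, temperature = -0.12), attack_threshold_temp = 13)
  expect_equal(predict_weekly_attacks(fit, 14), 0)
  expect_equal(predict_weekly_attacks(fit, 13), 0)   # at the ceiling
  expect_gt(predict_weekly_attacks(fit, 12.9), 0)
  expect_equal(predict_weekly_attacks(fit, 5),
               7 * exp(0.3 - 0.12 * 5))
  expect_equal(predict_weekly_attacks(fit, 14, threshold = FALSE),
               7 * exp(0.3 - 0.12 * 14))
  t <- seq(-30, 30, 0.25)
  expect_true(all(predict_weekly_attacks(fit, t) >= 0))
})

test_that("missing extra covariate values are an input error", {
  fit <- severity_fit_from_coefficients(
    c("(Intercept)" = 0, temperature = -0.1, humidity = 0.5))
  expect_error(predict_weekly_attacks(fit, 5), class = "rpclim_input_error")
  expect_equal(predict_weekly_attacks(fit, 5, extra_covariates = list(humidity = 0)),
               7 * exp(-0.5))
})

test_that("a linearised profile losing 0.4 attacks/week/degC needs 2.5 degC per attack", {
  # endpoints 5.2 at 0 degC and 0 at 13 degC: mean slope exactly -0.4
  b0 <- log(5.2 / 7)
  bT <- (log(1e-9) - b0) / 13  # essentially zero at the ceiling
  fit <- severity_fit_from_coefficients(c("(Intercept)" = b0, temperature = bT))
  eff <- weekly_temperature_effect(fit, 0, 13)
  expect_equal(eff$mean_slope, -0.4, tolerance = 1e-6)
  expect_equal(eff$degrees_per_one_fewer_attack, 2.5, tolerance = 1e-6)
  expect_true(eff$defined)
})

test_that("flat and log-linear fits summarise by endpoint evaluation", {
  flat <- severity_fit_from_coefficients(c("(Intercept)" = 0.2, temperature = 0))
  eff <- weekly_temperature_effect(flat, 0, 13)
  expect_equal(eff$mean_slope, 0)
  expect_false(eff$defined)
  expect_true(is.na(eff$degrees_per_one_fewer_attack))

  fit <- severity_fit_from_coefficients(c("(Intercept)" = 0.3, temperature = -0.12))
  eff <- weekly_temperature_effect(fit, 0, 10)
  p0 <- 7 * exp(0.3); p10 <- 7 * exp(0.3 - 1.2)
  expect_equal(eff$mean_slope, (p10 - p0) / 10)
  expect_equal(eff$degrees_per_one_fewer_attack, 10 / (p0 - p10))
})

test_that("diary readers validate schema and map foreign column names", {
  f <- withr::local_tempfile(fileext = ".csv")
  d <- data.frame(id = c("a", "a"), day = c("1999-01-01", "1999-01-02"),
                  nb_attacks = c(1, 0), temp_c = c(3.5, 7))
  utils::write.csv(d, f, row.names = FALSE)
  got <- read_attack_diaries(f, column_map = c(patient_id = "id",
                                               attack_count = "nb_attacks",
                                               temperature = "temp_c"))
  expect_equal(got$attack_count, c(1, 0))
  expect_s3_class(got$day, "Date")

  bad <- data.frame(patient_id = "a", day = "1999-01-01",
                    attack_count = -2, temperature = 1)
  utils::write.csv(bad, f, row.names = FALSE)
  expect_error(read_attack_diaries(f), class = "rpclim_validation_error")
})

test_that("severity fits round-trip through JSON, refit or imported", {
  set.seed(6)
  d <- gen_diaries(diary_sim_params(n_patients = 1, n_days = 300, seed = 6))
  fit <- fit_poisson(d)
  f <- withr::local_tempfile(fileext = ".json")
  write_severity_fit(fit, f)
  back <- read_severity_fit(f)
  expect_equal(back$coefficients, fit$coefficients, tolerance = 1e-12)
  expect_equal(predict_weekly_attacks(back, 4), predict_weekly_attacks(fit, 4))

  # a bare coefficient object, the "previously deposited model" path
  jsonlite::write_json(list(coefficients = list("(Intercept)" = 0.25,
                                                temperature = -0.1)),
                       f, auto_unbox = TRUE)
  imp <- read_severity_fit(f)
  expect_equal(imp$coefficients[["temperature"]], -0.1)
  expect_equal(imp$attack_threshold_temp, 13)
})
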