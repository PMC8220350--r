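table1_path <- system.file("extdata", "study_table.csv", package = "rpclim")

test_that("the bundled survey table parses into 20 linked records", {
  recs <- read_study_table(table1_path)
  expect_equal(nrow(recs), 20)
  first <- recs[1, ]
  expect_equal(first$study, "Brand")
  expect_equal(first$year, 1997)
  expect_equal(first$city, "Boston")
  expect_equal(first$latitude, 42.36)
  expect_equal(first$sample_size, 4182)
  expect_equal(first$prevalence, 7.20)
  olsen <- recs[recs$study == "Olsen", ]
  expect_equal(olsen$prevalence, 15.51)
  expect_equal(olsen$sample_size, 67)
  # gazetteer linkage filled every longitude
  expect_false(anyNA(recs$longitude))
  expect_lt(recs$longitude[recs$city == "Boston"][1], 0)
})

test_that("validation rejects out-of-range rows and unknown cities", {
  recs <- utils::read.csv(table1_path)
  bad <- recs; bad$prevalence[3] <- -1
  f <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(bad, f, row.names = FALSE)
  expect_error(read_study_table(f), class = "rpclim_validation_error")

  bad2 <- recs; bad2$city[5] <- "Atlantis"
  utils::write.csv(bad2, f, row.names = FALSE)
  expect_error(read_study_table(f), class = "rpclim_linkage_error")
})

test_that("assign_winter_temps links each study to its local winter mean", {
  recs <- read_study_table(table1_path)
  dates <- days_of("1976-07-01", "2011-06-30")

  got <- assign_winter_temps(recs, constant_grid(5, dates), window = winter_window())
  expect_equal(got$winter_temp, rep(5, 20))

  # a grid warming +1 degC per calendar year separates studies by year gap
  lat <- seq(-85, 85, 10); lon <- seq(-175, 175, 10)
  yr <- as.integer(format(dates, "%Y"))
  vals <- array(rep(yr - 1990, times = length(lat) * length(lon)),
                dim = c(length(dates), length(lat), length(lon)))
  warming <- temperature_grid(lat, lon, dates, vals)
  got <- assign_winter_temps(recs, warming)
  b97 <- got$winter_temp[got$study == "Brand"]      # winter 1996/97
  f99 <- got$winter_temp[got$study == "Fraenkel"]   # winter 1998/99
  expect_equal(f99 - b97, 2)

  # gradient grid reproduces the gradient at each site's nearest cell
  g <- gradient_grid(30, -0.3, dates, lat, lon)
  got <- assign_winter_temps(recs, g)
  nearest_lat <- vapply(recs$latitude, function(x) lat[which.min(abs(lat - x))],
                        numeric(1))
  expect_equal(got$winter_temp, 30 - 0.3 * nearest_lat)
})

test_that("coverage failures carry the study's label", {
  recs <- read_study_table(table1_path)
  short <- constant_grid(5, days_of("1998-01-01", "1999-12-31"))
  err <- expect_error(assign_winter_temps(recs, short),
                      class = "rpclim_coverage_error")
  expect_match(conditionMessage(err), "Brand")
})

test_that("collinear points are fitted exactly", {
  recs <- data.frame(winter_temp = c(0, 5, 10), prevalence = c(10, 7.5, 5),
                     latitude = 0, sample_size = 100)
  fit <- fit_prevalence(recs)
  expect_equal(fit$slope, -0.5)
  expect_equal(fit$intercept, 10)
  expect_equal(fit$residual_sd, 0, tolerance = 1e-12)

  two <- data.frame(winter_temp = c(0, 13), prevalence = c(6.5, 0),
                    latitude = 0, sample_size = 100)
  fit2 <- fit_prevalence(two)
  expect_equal(fit2$slope, -0.5)
  expect_equal(zero_crossing(fit2), 13)
})

test_that("OLS matches the closed-form normal equations", {
  set.seed(7)
  for (rep in 1:20) {
    n <- sample(5:40, 1)
    x <- rnorm(n, 0, 6)
    y <- pmin(pmax(6.5 - 0.5 * x + rnorm(n), 0), 100)
    w <- sample(67:4182, n, replace = TRUE)
    recs <- data.frame(winter_temp = x, prevalence = y,
                       latitude = 0, sample_size = w)
    for (wt in c("none", "sample_size")) {
      fit <- fit_prevalence(recs, weighting = wt)
      oracle <- ols_closed_form(x, y, if (wt == "none") rep(1, n) else w)
      expect_equal(fit$slope, oracle$slope, tolerance = 1e-10)
      expect_equal(fit$intercept, oracle$intercept, tolerance = 1e-10)
      expect_equal(fit$slope_se, oracle$slope_se, tolerance = 1e-10)
      expect_equal(fit$residual_sd, oracle$residual_sd, tolerance = 1e-10)
    }
  }
})

test_that("shifting all temperatures by c moves only the intercept", {
  set.seed(11)
  recs <- data.frame(winter_temp = rnorm(15, 2, 5),
                     prevalence = runif(15, 0, 20),
                     latitude = 0, sample_size = 100)
  f0 <- fit_prevalence(recs)
  shifted <- recs; shifted$winter_temp <- shifted$winter_temp + 3.7
  f1 <- fit_prevalence(shifted)
  expect_equal(f1$slope, f0$slope)
  expect_equal(f1$intercept, f0$intercept - f0$slope * 3.7)
})

test_that("refitting on the fit's own predictions reproduces the line exactly", {
  set.seed(5)
  recs <- data.frame(winter_temp = rnorm(12, 0, 4),
                     prevalence = runif(12, 1, 15),
                     latitude = 0, sample_size = 100)
  fit <- fit_prevalence(recs)
  recs2 <- recs
  recs2$prevalence <- fit$intercept + fit$slope * recs$winter_temp
  refit <- fit_prevalence(recs2)
  expect_equal(refit$slope, fit$slope)
  expect_equal(refit$intercept, fit$intercept)
})

test_that("identical temperatures give a degenerate-design error", {
  recs <- data.frame(winter_temp = rep(4, 5), prevalence = 1:5,
                     latitude = 0, sample_size = 100)
  expect_error(fit_prevalence(recs), class = "rpclim_degenerate_design")
})

test_that("predictions are clamped to [0, 100] and monotone for cooling fits", {
  fit <- fit_prevalence(data.frame(winter_temp = c(0, 5, 10),
                                   prevalence = c(10, 7.5, 5),
                                   latitude = 0, sample_size = 1))
  expect_equal(predict_prevalence(fit, 0), 10)
  expect_equal(predict_prevalence(fit, 4), 8)
  expect_equal(predict_prevalence(fit, 25), 0)     # clamp low
  expect_equal(predict_prevalence(fit, -500), 100) # clamp high
  t <- seq(-40, 40, by = 0.5)
  p <- predict_prevalence(fit, t)
  expect_true(all(diff(p) <= 0))
  expect_true(all(p >= 0 & p <= 100))
})

test_that("zero_crossing needs a negative slope", {
  fit <- fit_prevalence(data.frame(winter_temp = c(0, 10), prevalence = c(0, 1),
                                   latitude = 0, sample_size = 1))
  expect_error(zero_crossing(fit), class = "rpclim_no_crossing")
  down <- fit_prevalence(data.frame(winter_temp = c(0, 10), prevalence = c(10, 0),
                                    latitude = 0, sample_size = 1))
  expect_equal(zero_crossing(down), 10)
})

test_that("latitude-only fallback regresses prevalence on |latitude|", {
  recs <- data.frame(latitude = c(-30, 40, 50, 60),
                     prevalence = c(3, 4, 5, 6),
                     winter_temp = NA_real_, sample_size = 1)
  fit <- fit_prevalence(recs, predictor = "abs_latitude")
  oracle <- ols_closed_form(abs(recs$latitude), recs$prevalence)
  expect_equal(fit$slope, oracle$slope)
  expect_equal(fit$predictor, "abs_latitude")
})

test_that("prevalence fits survive a JSON round trip", {
  recs <- data.frame(winter_temp = c(0, 5, 10), prevalence = c(10, 7.5, 5),
                     latitude = 0, sample_size = 1)
  fit <- fit_prevalence(recs)
  f <- withr::local_tempfile(fileext = ".json")
  write_prevalence_fit(fit, f)
  back <- read_prevalence_fit(f)
  expect_equal(back$slope, fit$slope)
  expect_equal(back$intercept, fit$intercept)
  expect_equal(predict_prevalence(back, 4), 8)
})
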