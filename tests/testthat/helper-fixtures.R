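# In-code fixtures shared across test files.

# A grid holding the same value everywhere (all land), over `dates`.
constant_grid <- function(value, dates, lat = seq(-85, 85, by = 10),
                          lon = seq(-175, 175, by = 10)) {
  vals <- array(value, dim = c(length(dates), length(lat), length(lon)))
  temperature_grid(lat, lon, dates, vals)
}

# Purely latitudinal field T(lat) = a + b * lat, constant in time.
gradient_grid <- function(a, b, dates, lat, lon = seq(-175, 175, by = 10)) {
  one_day <- matrix(a + b * lat, nrow = length(lat), ncol = length(lon))
  vals <- aperm(array(one_day, dim = c(length(lat), length(lon), length(dates))),
                c(3, 1, 2))
  temperature_grid(lat, lon, dates, vals)
}

days_of <- function(from, to) seq(as.Date(from), as.Date(to), by = "day")

# Closed-form (weighted) simple linear regression: the textbook normal
# equations, independent of lm().
ols_closed_form <- function(x, y, w = rep(1, length(x))) {
  sw <- sum(w)
  xbar <- sum(w * x) / sw
  ybar <- sum(w * y) / sw
  slope <- sum(w * (x - xbar) * (y - ybar)) / sum(w * (x - xbar)^2)
  intercept <- ybar - slope * xbar
  res <- y - intercept - slope * x
  df <- length(x) - 2
  sigma2 <- sum(w * res^2) / df
  slope_se <- sqrt(sigma2 / sum(w * (x - xbar)^2))
  list(slope = slope, intercept = intercept, slope_se = slope_se,
       residual_sd = sqrt(sigma2))
}

# Independent Poisson ML: iterated grid search over the coefficients,
# refining the bracket around the best point each round.
poisson_grid_search <- function(X, y, lower, upper, rounds = 8, n_grid = 41) {
  ll <- function(b) sum(dpois(y, exp(as.vector(X %*% b)), log = TRUE))
  lo <- lower; hi <- upper
  best <- (lo + hi) / 2
  for (r in seq_len(rounds)) {
    grids <- Map(function(l, h) seq(l, h, length.out = n_grid), lo, hi)
    cand <- as.matrix(do.call(expand.grid, grids))
    vals <- apply(cand, 1, ll)
    best <- cand[which.max(vals), ]
    span <- (hi - lo) / (n_grid - 1)
    lo <- best - 2 * span
    hi <- best + 2 * span
  }
  best
}

# Exhaustive oracle for nearest-unmasked-cell extraction (small grids).
nearest_cell_bruteforce <- function(field, latitude, longitude) {
  cand <- which(!is.na(field$values), arr.ind = TRUE)
  clat <- field$lat[cand[, 1]]
  clon <- field$lon[cand[, 2]]
  d <- round(geosphere::distHaversine(cbind(longitude, latitude), cbind(clon, clat)))
  pick <- order(d, abs(clat), clon)[1]
  field$values[cand[pick, 1], cand[pick, 2]]
}

# End-to-end fixtures: an all-synthetic config with 1 historical + 4 scenario
# climates, a study table and diaries, built fresh in a temp dir.
make_pipeline_config <- function(root, seed = 1) {
  cp <- climate_sim_params(seed = seed)
  grids <- gen_climate(
    cp,
    hist_dates = days_of("1998-07-01", "1999-12-31"),
    scen_dates = days_of("2099-11-01", "2099-12-31"),
    out_dir = file.path(root, "climate"))
  paths <- attr(grids, "paths")
  studies_csv <- file.path(root, "studies.csv")
  gen_studies(study_sim_params(seed = seed), grids$historical,
              out_path = studies_csv)
  diaries_csv <- file.path(root, "diaries.csv")
  gen_diaries(diary_sim_params(seed = seed), out_path = diaries_csv)
  cfg <- list(
    seed = seed,
    output_dir = file.path(root, "out"),
    study_table = studies_csv,
    diaries = diaries_csv,
    climate = list(
      variable = "tasAdjust",
      historical = paths[["historical"]],
      scenarios = list("RCP2.6" = paths[["RCP2.6"]],
                       "RCP4.5" = paths[["RCP4.5"]],
                       "RCP6.0" = paths[["RCP6.0"]],
                       "RCP8.5" = paths[["RCP8.5"]])),
    baseline_year = 1999,
    target_year = 2099)
  cfg_path <- file.path(root, "config.yaml")
  yaml::write_yaml(cfg, cfg_path)
  cfg_path
}
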