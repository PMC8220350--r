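#' Read daily attack diaries
#'
#' Reads pooled n-of-1 daily symptom diaries: one row per patient-day with
#' the number of vasospastic attacks and the temperature recorded at the
#' nearest weather station. `column_map` renames source columns to the
#' canonical schema, so a deposited trial export with different headers can
#' be loaded directly (e.g. `column_map = c(attack_count = "nb_attacks")`).
#'
#' @param path CSV with header `patient_id, day, attack_count, temperature`
#'   plus optional extra covariate columns.
#' @param column_map named character vector, canonical name -> source name.
#' @return data frame, one row per (patient, day), counts validated as
#'   non-negative integers.
#' @export
read_attack_diaries <- function(path, column_map = NULL) {
  if (!file.exists(path))
    rp_stop("rpclim_io_error", sprintf("diary file not found: %s", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(column_map)) {
    for (canon in names(column_map)) {
      src <- column_map[[canon]]
      if (!src %in% names(df))
        rp_stop("rpclim_validation_error",
                sprintf("column_map source column '%s' not in file", src))
      names(df)[names(df) == src] <- canon
    }
  }
  need <- c("patient_id", "day", "attack_count", "temperature")
  miss <- setdiff(need, names(df))
  if (length(miss))
    rp_stop("rpclim_validation_error",
            sprintf("diary missing column(s): %s", paste(miss, collapse = ", ")))
  if (any(is.na(df$attack_count)) || any(df$attack_count < 0) ||
      any(df$attack_count != round(df$attack_count)))
    rp_stop("rpclim_validation_error", "attack_count must be non-negative integers")
  if (anyDuplicated(df[c("patient_id", "day")]))
    rp_stop("rpclim_validation_error", "duplicate (patient_id, day) rows")
  df$day <- as.Date(df$day)
  df
}

#' Fit the Poisson attack-frequency model by IRLS
#'
#' Maximum-likelihood log-link Poisson regression of daily attack counts on
#' temperature (and optional further covariates), fitted by iteratively
#' reweighted least squares with step halving, so the log-likelihood is
#' non-decreasing across iterations. Exposure is one day per row; weekly
#' frequencies are 7 times the fitted daily rate. Convergence is declared
#' when the relative log-likelihood change drops below `1e-8` (at most 100
#' iterations); the covariance is the inverse Fisher information at the
#' optimum.
#'
#' @param diaries data frame from [read_attack_diaries()] (or any frame with
#'   `attack_count` plus the covariate columns).
#' @param covariate_names covariates to include; default `"temperature"`.
#' @param patient_effects if `TRUE`, add per-patient fixed-effect indicator
#'   covariates (first patient as reference).
#' @param attack_threshold_temp temperature (degrees Celsius) at and above
#'   which predictions are zeroed, the empirical no-attack ceiling; carried
#'   on the fit, default 13.
#' @return object of class `severity_fit` with `coefficients`, `covariance`,
#'   `log_likelihood`, `ll_trace`, `n_obs`, `converged`, `iterations`,
#'   `attack_threshold_temp`.
#' @export
fit_poisson <- function(diaries, covariate_names = "temperature",
                        patient_effects = FALSE, attack_threshold_temp = 13) {
  y <- diaries$attack_count
  if (any(is.na(y)) || any(y < 0) || any(y != round(y)))
    rp_stop("rpclim_validation_error", "attack_count must be non-negative integers")
  miss <- setdiff(covariate_names, names(diaries))
  if (length(miss))
    rp_stop("rpclim_validation_error",
            sprintf("covariate(s) not in diaries: %s", paste(miss, collapse = ", ")))
  X <- cbind("(Intercept)" = 1,
             as.matrix(diaries[, covariate_names, drop = FALSE]))
  if (patient_effects) {
    ids <- factor(diaries$patient_id)
    if (nlevels(ids) > 1L) {
      P <- stats::model.matrix(~ ids)[, -1L, drop = FALSE]
      colnames(P) <- paste0("patient:", levels(ids)[-1L])
      X <- cbind(X, P)
    }
  }
  p <- ncol(X)
  if (nrow(X) <= p)
    rp_stop("rpclim_design_error",
            sprintf("need more observations (%d) than coefficients (%d)", nrow(X), p))
  if (qr(X)$rank < p)
    rp_stop("rpclim_design_error", "design matrix is rank deficient (collinear covariates?)")
  if (all(y == 0))
    rp_stop("rpclim_degenerate_fit",
            "all counts are zero: the log mean rate is unbounded below")

  beta <- c(log(mean(y) + 1e-6), rep(0, p - 1L))
  names(beta) <- colnames(X)
  loglik <- function(b) {
    eta <- pmin(as.vector(X %*% b), 30)
    sum(stats::dpois(y, exp(eta), log = TRUE))
  }
  ll <- loglik(beta)
  trace <- ll
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(100L)) {
    eta <- pmin(as.vector(X %*% beta), 30)
    mu <- exp(eta)
    XtW <- t(X * mu)
    step <- tryCatch(solve(XtW %*% X, crossprod(X, y - mu)),
                     error = function(e)
                       rp_stop("rpclim_design_error",
                               sprintf("Fisher information singular at iteration %d", iter)))
    # step-halve until the likelihood does not decrease
    lambda <- 1
    repeat {
      cand <- beta + lambda * as.vector(step)
      ll_new <- loglik(cand)
      if (ll_new >= ll - 1e-12 || lambda < 2^-20) break
      lambda <- lambda / 2
    }
    beta <- cand
    trace <- c(trace, ll_new)
    if (abs(ll_new - ll) / (abs(ll) + 1) < 1e-8) {
      ll <- ll_new
      converged <- TRUE
      break
    }
    ll <- ll_new
  }
  mu <- exp(pmin(as.vector(X %*% beta), 30))
  info <- t(X * mu) %*% X
  cov <- solve(info)
  cov <- (cov + t(cov)) / 2
  dimnames(cov) <- list(colnames(X), colnames(X))
  structure(
    list(coefficients = beta, covariance = cov,
         log_likelihood = ll, ll_trace = trace,
         n_obs = nrow(X), converged = converged, iterations = iter,
         covariate_names = setdiff(colnames(X), "(Intercept)"),
         attack_threshold_temp = attack_threshold_temp),
    class = "severity_fit")
}

#' Build a severity fit from imported coefficients
#'
#' A previously fitted model (for instance one deposited alongside a trial
#' dataset) can be used for projection without refitting: supply its
#' log-rate-scale coefficients directly, or a JSON file holding them.
#'
#' @param coefficients named numeric vector; must include `"(Intercept)"`,
#'   remaining names are covariates (typically `temperature`).
#' @param attack_threshold_temp no-attack ceiling, degrees Celsius.
#' @return a `severity_fit` (with `covariance = NULL`, `converged = TRUE`).
#' @export
severity_fit_from_coefficients <- function(coefficients, attack_threshold_temp = 13) {
  if (is.null(names(coefficients)) || !"(Intercept)" %in% names(coefficients))
    rp_stop("rpclim_validation_error", "coefficients must be named and include '(Intercept)'")
  structure(
    list(coefficients = coefficients, covariance = NULL,
         log_likelihood = NA_real_, ll_trace = numeric(),
         n_obs = NA_integer_, converged = TRUE, iterations = 0L,
         covariate_names = setdiff(names(coefficients), "(Intercept)"),
         attack_threshold_temp = attack_threshold_temp),
    class = "severity_fit")
}

#' @rdname severity_fit_from_coefficients
#' @param path JSON path written by [write_severity_fit()] or a bare
#'   `{"coefficients": {...}}` object.
#' @export
read_severity_fit <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(obj$coefficients)) {
    fit <- severity_fit_from_coefficients(
      unlist(obj$coefficients),
      attack_threshold_temp = obj$attack_threshold_temp %||% 13)
    if (!is.null(obj$covariance)) fit$covariance <- as.matrix(obj$covariance)
    for (f in c("log_likelihood", "n_obs", "converged", "iterations"))
      if (!is.null(obj[[f]])) fit[[f]] <- obj[[f]]
    fit
  } else {
    severity_fit_from_coefficients(unlist(obj))
  }
}

#' @rdname severity_fit_from_coefficients
#' @param fit a `severity_fit`.
#' @export
write_severity_fit <- function(fit, path) {
  out <- unclass(fit)
  out$coefficients <- as.list(out$coefficients)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @export
print.severity_fit <- function(x, ...) {
  cat("<severity_fit> log-link Poisson, daily attack rate\n")
  co <- x$coefficients
  se <- if (!is.null(x$covariance)) sqrt(diag(x$covariance)) else rep(NA_real_, length(co))
  for (i in seq_along(co))
    cat(sprintf("  %-14s %9.5f  (SE %s)\n", names(co)[i], co[i],
                ifelse(is.na(se[i]), "-", sprintf("%.5f", se[i]))))
  cat(sprintf("  n = %s, converged = %s in %d iteration(s); threshold %.1f degC\n",
              x$n_obs, x$converged, x$iterations, x$attack_threshold_temp))
  invisible(x)
}

#' Predicted weekly attack frequency
#'
#' Weekly frequency is 7 times the fitted daily rate `exp(x'beta)`. At and
#' above the no-attack temperature ceiling (default 13 degrees Celsius) the
#' prediction is zero when `threshold = TRUE`.
#'
#' @param fit a `severity_fit`.
#' @param temperature degrees Celsius (vector or matrix; `NA` passes through).
#' @param extra_covariates named list/vector of values for any covariates in
#'   the fit beyond temperature.
#' @param threshold apply the hard ceiling (default `TRUE`).
#' @return attacks per week, same shape as `temperature`.
#' @export
predict_weekly_attacks <- function(fit, temperature, extra_covariates = NULL,
                                   threshold = TRUE) {
  stopifnot(inherits(fit, "severity_fit"))
  co <- fit$coefficients
  eta <- rep(co[["(Intercept)"]], length(temperature))
  for (nm in fit$covariate_names) {
    if (nm == "temperature") {
      eta <- eta + co[[nm]] * as.vector(temperature)
    } else {
      if (is.null(extra_covariates) || is.null(extra_covariates[[nm]]))
        rp_stop("rpclim_input_error",
                sprintf("missing value for covariate '%s'", nm))
      eta <- eta + co[[nm]] * extra_covariates[[nm]]
    }
  }
  out <- 7 * exp(eta)
  if (threshold)
    out[!is.na(temperature) & as.vector(temperature) >= fit$attack_threshold_temp] <- 0
  out[is.na(temperature)] <- NA_real_
  if (is.matrix(temperature)) out <- matrix(out, nrow(temperature), ncol(temperature))
  out
}

#' Summarise the temperature effect as a weekly attack slope
#'
#' Mean slope of the predicted weekly frequency between two temperatures,
#' evaluated on the smooth (unthresholded) rate, and its reciprocal: the
#' warming in degrees Celsius needed for one fewer attack per week. When the
#' slope is not negative the reciprocal is undefined and flagged rather than
#' raised.
#'
#' @param fit a `severity_fit`.
#' @param t_low,t_high evaluation range in degrees Celsius
#'   (default 0 to the fit's threshold).
#' @param extra_covariates passed to [predict_weekly_attacks()].
#' @return list with `mean_slope` (attacks/week per degree),
#'   `degrees_per_one_fewer_attack` (degrees Celsius, `NA` when undefined)
#'   and `defined` (logical).
#' @export
weekly_temperature_effect <- function(fit, t_low = 0,
                                      t_high = fit$attack_threshold_temp,
                                      extra_covariates = NULL) {
  stopifnot(inherits(fit, "severity_fit"))
  if (!(t_low < t_high))
    rp_stop("rpclim_input_error", "t_low must be below t_high")
  p <- predict_weekly_attacks(fit, c(t_low, t_high),
                              extra_covariates = extra_covariates, threshold = FALSE)
  mean_slope <- (p[2] - p[1]) / (t_high - t_low)
  if (mean_slope < 0) {
    list(mean_slope = mean_slope,
         degrees_per_one_fewer_attack = 1 / abs(mean_slope),
         defined = TRUE)
  } else {
    list(mean_slope = mean_slope,
         degrees_per_one_fewer_attack = NA_real_,
         defined = FALSE)
  }
}
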