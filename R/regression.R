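#' Regression risk model (double-log scale)
#'
#' The original risk engine: an ordinary least-squares regression of
#' `ln(C8h)` on `ln(CLCR)`, where C8h is the total meropenem concentration
#' 8 h after the start of a standard dose (1 g, 0.5 h infusion).  Risk of
#' target non-attainment is the predictive probability that C8h falls below
#' the MIC, from classic linear-model prediction theory on the log scale.
#'
#' @param intercept Intercept on the ln(mg/L) scale.
#' @param slope Slope per ln(mL/min); negative for meropenem (higher
#'   clearance, lower trough).  A positive slope triggers a warning.
#' @param residual_sd Residual standard deviation on the ln scale
#'   (n - 2 denominator), > 0 (0 allowed for degenerate exact fits).
#' @param n_train Training sample size, >= 3.
#' @param mean_ln_x Mean of ln(CLCR) in the training data.
#' @param sxx Sum of squared deviations of ln(CLCR) in the training data.
#' @param clcr_range Applicability range in mL/min; inputs outside it are
#'   refused by default.
#' @return Object of class `meropta_regression`.
#' @seealso [fit_loglog_regression()], [risk_regression()]
#' @export
regression_model <- function(intercept, slope, residual_sd, n_train,
                             mean_ln_x, sxx, clcr_range = c(25, 255)) {
  assert_nonnegative(residual_sd, "residual_sd")
  assert_that(n_train >= 3, "n_train", "must be at least 3")
  assert_that(is.finite(sxx) && sxx > 0, "sxx", "must be positive")
  assert_that(length(clcr_range) == 2 && clcr_range[1] < clcr_range[2],
              "clcr_range", "must be c(min, max) with min < max")
  if (slope >= 0) {
    warning("slope >= 0: a fitted meropenem model should decrease with ",
            "creatinine clearance")
  }
  structure(list(intercept = intercept, slope = slope,
                 residual_sd = residual_sd, n_train = n_train,
                 mean_ln_x = mean_ln_x, sxx = sxx,
                 clcr_range = as.numeric(clcr_range)),
            class = "meropta_regression")
}

#' @export
print.meropta_regression <- function(x, ...) {
  cat(sprintf(
    "<log-log regression risk model>\n  ln(C8h) = %.4f %+.4f * ln(CLCR), residual sd %.4f (n = %d)\n  applicable for CLCR in [%g, %g] mL/min\n",
    x$intercept, x$slope, x$residual_sd, x$n_train,
    x$clcr_range[1], x$clcr_range[2]))
  invisible(x)
}

#' Fit the double-log regression from paired observations
#'
#' Ordinary least squares of `ln(c8h)` on `ln(clcr)`.  Enables parameter
#' recovery and local re-calibration; published coefficients can instead be
#' loaded from JSON via [read_regression_json()].
#'
#' @param clcr_values Creatinine clearances in mL/min, all > 0.
#' @param c8h_values Matching 8-h concentrations in mg/L, all > 0.
#' @param clcr_range Applicability range stored on the fitted model.
#' @return A [regression_model()].
#' @export
fit_loglog_regression <- function(clcr_values, c8h_values,
                                  clcr_range = c(25, 255)) {
  assert_positive(clcr_values, "clcr_values")
  assert_positive(c8h_values, "c8h_values")
  n <- length(clcr_values)
  assert_that(length(c8h_values) == n, "c8h_values",
              "must have the same length as clcr_values")
  assert_that(n >= 3, "clcr_values", "need at least 3 points")
  lx <- log(clcr_values)
  ly <- log(c8h_values)
  fit <- stats::lm(ly ~ lx)
  sigma <- sqrt(sum(stats::residuals(fit)^2) / (n - 2))
  co <- stats::coef(fit)
  suppressWarnings(  # positive slope already unusual; let the fit through
    m <- regression_model(
      intercept = unname(co[1]), slope = unname(co[2]),
      residual_sd = sigma, n_train = n,
      mean_ln_x = mean(lx), sxx = sum((lx - mean(lx))^2),
      clcr_range = clcr_range))
  if (m$slope >= 0) {
    warning("fitted slope is non-negative; check the input data")
  }
  m
}

check_clcr_range <- function(model, clcr, permissive = FALSE) {
  out <- clcr < model$clcr_range[1] | clcr > model$clcr_range[2]
  if (any(out)) {
    msg <- sprintf(
      "creatinine clearance %s mL/min outside the range of applicability (%g-%g mL/min); the risk calculator should not be used",
      paste(format(clcr[out]), collapse = ", "),
      model$clcr_range[1], model$clcr_range[2])
    if (permissive) warning(msg) else stop(msg, call. = FALSE)
  }
  invisible(TRUE)
}

#' Median 8-h concentration predicted by the regression engine
#'
#' Back-transformed point prediction `exp(intercept + slope * ln(clcr))`;
#' on the original scale this is the median of the lognormal predictive
#' distribution.
#'
#' @param model A [regression_model()].
#' @param clcr Creatinine clearance in mL/min (vectorised).
#' @param permissive If `TRUE`, out-of-range clcr warns instead of erroring.
#' @return Predicted median concentration in mg/L.
#' @export
predict_c8h <- function(model, clcr, permissive = FALSE) {
  stopifnot(inherits(model, "meropta_regression"))
  assert_positive(clcr, "clcr")
  check_clcr_range(model, clcr, permissive)
  exp(model$intercept + model$slope * log(clcr))
}

# standard error of a new-observation prediction on the ln scale
pred_se <- function(model, ln_clcr) {
  model$residual_sd * sqrt(1 + 1 / model$n_train +
                             (ln_clcr - model$mean_ln_x)^2 / model$sxx)
}

#' Prediction interval for the 8-h concentration
#'
#' Classic linear-model interval for a new observation on the ln scale,
#' `yhat +/- t * s * sqrt(1 + 1/n + (x - xbar)^2 / Sxx)`, back-transformed
#' with `exp`.  Uses the t distribution with `n_train - 2` degrees of
#' freedom (normal quantiles with `gaussian_approx = TRUE`).
#'
#' @inheritParams predict_c8h
#' @param level Coverage level in (0, 1), default 0.95.
#' @param gaussian_approx Use normal instead of t quantiles.
#' @return Data frame with columns `lower`, `fit`, `upper` (mg/L).
#' @export
prediction_interval <- function(model, clcr, level = 0.95,
                                gaussian_approx = FALSE,
                                permissive = FALSE) {
  stopifnot(inherits(model, "meropta_regression"))
  assert_that(level > 0 && level < 1, "level", "must be in (0, 1)")
  fit <- predict_c8h(model, clcr, permissive = permissive)
  se <- pred_se(model, log(clcr))
  q <- if (gaussian_approx) stats::qnorm((1 + level) / 2) else
    stats::qt((1 + level) / 2, df = model$n_train - 2)
  data.frame(lower = fit * exp(-q * se), fit = fit, upper = fit * exp(q * se))
}

#' Risk of target non-attainment from the regression engine
#'
#' Predictive probability that the 8-h concentration falls below the MIC,
#' i.e. that the 100% T>MIC target (assessed at the 8-h trough) is missed:
#' \deqn{P(C_{8h} < MIC) = T_{n-2}\!\left(\frac{\ln MIC - \hat y}
#'   {s \sqrt{1 + 1/n + (\ln clcr - \bar x)^2 / S_{xx}}}\right)}
#'
#' @inheritParams predict_c8h
#' @param mic Minimum inhibitory concentration in mg/L, > 0 (vectorised).
#' @param gaussian_approx Use the standard normal instead of the t
#'   predictive distribution.
#' @return Probability of target non-attainment in \[0, 1\].
#' @export
risk_regression <- function(model, clcr, mic, gaussian_approx = FALSE,
                            permissive = FALSE) {
  stopifnot(inherits(model, "meropta_regression"))
  assert_positive(mic, "mic")
  mu <- log(predict_c8h(model, clcr, permissive = permissive))
  se <- pred_se(model, log(clcr))
  z <- (log(mic) - mu) / se
  if (any(se == 0)) {
    # degenerate zero-dispersion model: point mass at the prediction
    z0 <- ifelse(log(mic) < mu, -Inf, ifelse(log(mic) > mu, Inf, 0))
    z <- ifelse(rep(se, length.out = length(z)) == 0, z0, z)
  }
  if (gaussian_approx) stats::pnorm(z) else
    stats::pt(z, df = model$n_train - 2)
}

#' Read / write a regression model as JSON
#'
#' Fields: `intercept, slope, residual_sd, n_train, mean_ln_x, sxx,
#' clcr_min, clcr_max`.
#'
#' @param path JSON file path.
#' @return For the reader, a [regression_model()].
#' @export
read_regression_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  need <- c("intercept", "slope", "residual_sd", "n_train",
            "mean_ln_x", "sxx")
  missing <- setdiff(need, names(j))
  if (length(missing)) {
    stop("regression JSON missing fields: ", paste(missing, collapse = ", "))
  }
  regression_model(
    intercept = j$intercept, slope = j$slope, residual_sd = j$residual_sd,
    n_train = j$n_train, mean_ln_x = j$mean_ln_x, sxx = j$sxx,
    clcr_range = c(j$clcr_min %||% 25, j$clcr_max %||% 255))
}

#' @rdname read_regression_json
#' @param model A [regression_model()] to serialise.
#' @export
write_regression_json <- function(model, path) {
  stopifnot(inherits(model, "meropta_regression"))
  jsonlite::write_json(
    list(intercept = model$intercept, slope = model$slope,
         residual_sd = model$residual_sd, n_train = model$n_train,
         mean_ln_x = model$mean_ln_x, sxx = model$sxx,
         clcr_min = model$clcr_range[1], clcr_max = model$clcr_range[2]),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Default regression risk model
#'
#' The coefficients shipped with the package were calibrated once against
#' the package's synthetic reference cohort (simulated 8-h concentrations
#' from the default population-PK model, see the methods vignette); they
#' stand in for coefficients estimated on clinical data and can be replaced
#' by editing one JSON file (`inst/extdata/regression_default.json`).
#'
#' @return A [regression_model()].
#' @export
default_regression_model <- function() {
  read_regression_json(system.file("extdata", "regression_default.json",
                                   package = "meropta", mustWork = TRUE))
}
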