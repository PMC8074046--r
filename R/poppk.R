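#' Two-compartment population pharmacokinetic model of meropenem
#'
#' Structural model: two compartments with constant-rate (zero-order)
#' infusion input.  Covariates follow the renal-drug convention for
#' meropenem: creatinine clearance acts on clearance through a
#' piecewise-linear function anchored so that anuric patients retain the
#' non-renal fraction of typical clearance, total body weight acts on the
#' central volume as a power model, and serum albumin acts linearly on the
#' peripheral volume.  Interindividual variability (IIV) is lognormal and
#' independent across parameters; residual error is combined
#' proportional + additive.
#'
#' @param cl_pop Typical clearance (L/h) at `clcr_ref`.
#' @param v1_pop Typical central volume (L) at `wt_ref`.
#' @param q Intercompartmental clearance (L/h); `0` degenerates to a
#'   one-compartment model.
#' @param v2_pop Typical peripheral volume (L) at `alb_ref`.
#' @param clcr_ref Reference creatinine clearance (mL/min).
#' @param wt_ref Reference total body weight (kg).
#' @param alb_ref Reference serum albumin (g/dL).
#' @param nonrenal_fraction Fraction of typical clearance remaining at
#'   CLCR = 0 (non-renal elimination), in \[0, 1).
#' @param clcr_breakpoint Knot (mL/min) of the piecewise-linear clearance
#'   function; with `slope_ratio = 1` (default) the function is a single
#'   straight line through the anuric and reference anchors.
#' @param slope_ratio Ratio of the slope above the knot to the slope below
#'   it; slopes are solved so the anchors at CLCR = 0 and `clcr_ref` hold.
#' @param wt_exponent Exponent of the weight power model on `v1`.
#' @param alb_slope Linear albumin coefficient on `v2` (per g/dL);
#'   negative for meropenem (lower albumin, larger peripheral volume).
#' @param omega Named lognormal IIV standard deviations (ln scale) for
#'   `cl`, `v1`, `q`, `v2`; missing names default to 0.
#' @param residual_prop_sd Proportional residual error SD.
#' @param residual_add_sd Additive residual error SD (mg/L).
#' @return Object of class `meropta_poppk`.
#' @export
poppk_model <- function(cl_pop = 12.5, v1_pop = 10.5, q = 15, v2_pop = 12,
                        clcr_ref = 100, wt_ref = 73, alb_ref = 2.5,
                        nonrenal_fraction = 0.2, clcr_breakpoint = 100,
                        slope_ratio = 1, wt_exponent = 0.75,
                        alb_slope = -0.3,
                        omega = c(cl = 0.30, v1 = 0.25, q = 0.30, v2 = 0.25),
                        residual_prop_sd = 0.20, residual_add_sd = 0.5) {
  for (f in c("cl_pop", "v1_pop", "v2_pop", "clcr_ref", "wt_ref",
              "alb_ref", "clcr_breakpoint")) {
    assert_positive(get(f), f)
  }
  assert_nonnegative(q, "q")
  assert_that(nonrenal_fraction >= 0 && nonrenal_fraction < 1,
              "nonrenal_fraction", "must lie in [0, 1)")
  assert_nonnegative(slope_ratio, "slope_ratio")
  om <- c(cl = 0, v1 = 0, q = 0, v2 = 0)
  om[names(omega)] <- omega
  assert_nonnegative(om, "omega")
  assert_nonnegative(residual_prop_sd, "residual_prop_sd")
  assert_nonnegative(residual_add_sd, "residual_add_sd")
  structure(list(cl_pop = cl_pop, v1_pop = v1_pop, q = q, v2_pop = v2_pop,
                 clcr_ref = clcr_ref, wt_ref = wt_ref, alb_ref = alb_ref,
                 nonrenal_fraction = nonrenal_fraction,
                 clcr_breakpoint = clcr_breakpoint,
                 slope_ratio = slope_ratio,
                 wt_exponent = wt_exponent, alb_slope = alb_slope,
                 omega = om, residual_prop_sd = residual_prop_sd,
                 residual_add_sd = residual_add_sd),
            class = "meropta_poppk")
}

#' @export
print.meropta_poppk <- function(x, ...) {
  cat(sprintf(
    "<two-compartment population PK model>\n  CL %g L/h @ CLCR %g, V1 %g L @ %g kg, Q %g L/h, V2 %g L @ albumin %g g/dL\n  non-renal fraction %g, omega(cl,v1,q,v2) = %s\n",
    x$cl_pop, x$clcr_ref, x$v1_pop, x$wt_ref, x$q, x$v2_pop, x$alb_ref,
    x$nonrenal_fraction, paste(x$omega, collapse = "/")))
  invisible(x)
}

#' Dosing regimen for intermittent infusion
#'
#' @param dose Dose per administration in mg.
#' @param infusion_duration Infusion duration in h; must be shorter than
#'   the dosing interval.
#' @param interval Dosing interval in h (q8h = 8).
#' @param n_doses Number of doses administered, >= 1.
#' @return Object of class `meropta_regimen`.  The default is meropenem
#'   standard dosing: 1 g over 0.5 h every 8 h.
#' @export
dosing_regimen <- function(dose = 1000, infusion_duration = 0.5,
                           interval = 8, n_doses = 1L) {
  assert_positive(dose, "dose")
  assert_positive(infusion_duration, "infusion_duration")
  assert_positive(interval, "interval")
  assert_that(infusion_duration < interval, "infusion_duration",
              "must be shorter than the dosing interval")
  assert_that(n_doses >= 1, "n_doses", "must be at least 1")
  structure(list(dose = dose, infusion_duration = infusion_duration,
                 interval = interval, n_doses = as.integer(n_doses)),
            class = "meropta_regimen")
}

#' Covariate function: creatinine clearance on meropenem clearance
#'
#' Piecewise-linear with two fixed anchors: at CLCR = 0 the clearance is
#' `nonrenal_fraction * cl_pop` (non-renal elimination persists in anuria)
#' and at `clcr_ref` it equals `cl_pop`.  A single knot at
#' `clcr_breakpoint` allows a two-slope shape; with the default
#' `slope_ratio = 1` the function is one straight line.
#'
#' @param model A [poppk_model()].
#' @param clcr Creatinine clearance in mL/min, >= 0 (vectorised).
#' @return Clearance in L/h.
#' @export
covariate_clearance <- function(model, clcr) {
  stopifnot(inherits(model, "meropta_poppk"))
  assert_nonnegative(clcr, "clcr")
  f0 <- model$nonrenal_fraction * model$cl_pop
  bp <- min(model$clcr_breakpoint, model$clcr_ref)
  r <- model$slope_ratio
  # slopes solved so f(0) = f0 and f(clcr_ref) = cl_pop hold exactly
  s1 <- (model$cl_pop - f0) / (bp + r * (model$clcr_ref - bp))
  s2 <- r * s1
  ifelse(clcr <= bp, f0 + s1 * clcr, f0 + s1 * bp + s2 * (clcr - bp))
}

#' Individual PK parameters for a patient
#'
#' Applies the covariate functions to the patient's creatinine clearance,
#' weight and albumin, then multiplies each parameter by an independent
#' lognormal IIV term `exp(eta)`, `eta ~ N(0, omega^2)`.  Missing albumin
#' is imputed at the reference value with a warning.  The peripheral
#' volume is floored at 0.1 L to keep the linear albumin model positive.
#'
#' @param model A [poppk_model()].
#' @param patient A [patient()] (needs `clcr` and `weight`).
#' @param seed Optional integer seed for the IIV draw.
#' @return Named list `cl, v1, q, v2` (class `meropta_individual`).
#' @export
individual_parameters <- function(model, patient, seed = NULL) {
  stopifnot(inherits(model, "meropta_poppk"),
            inherits(patient, "meropta_patient"))
  tv <- typical_parameters(model, patient)
  eta <- with_local_seed(seed, stats::rnorm(4L) * unname(model$omega))
  structure(list(cl = tv$cl * exp(eta[1]), v1 = tv$v1 * exp(eta[2]),
                 q = tv$q * exp(eta[3]), v2 = tv$v2 * exp(eta[4])),
            class = "meropta_individual")
}

typical_parameters <- function(model, patient) {
  assert_positive(patient$weight, "weight")
  alb <- patient$serum_albumin
  if (is.null(alb) || is.na(alb)) {
    warning("patient '", patient$id,
            "': serum albumin missing, imputed at reference (",
            model$alb_ref, " g/dL)")
    alb <- model$alb_ref
  }
  list(cl = covariate_clearance(model, patient$clcr),
       v1 = model$v1_pop * (patient$weight / model$wt_ref)^model$wt_exponent,
       q = model$q,
       v2 = max(model$v2_pop * (1 + model$alb_slope * (alb - model$alb_ref)),
                0.1))
}

# Concentration from one infusion started at time 0, vectorised over
# parameters and time (recycled element-wise).  Closed-form bi-exponential
# solution via macro-constants alpha/beta; q = 0 falls back to the
# one-compartment infusion solution.
conc_single_infusion <- function(t, cl, v1, q, v2, dose, tinf) {
  n <- max(length(t), length(cl), length(v1), length(q), length(v2))
  t <- rep_len(t, n); cl <- rep_len(cl, n); v1 <- rep_len(v1, n)
  q <- rep_len(q, n); v2 <- rep_len(v2, n)
  r0 <- dose / tinf
  te <- pmin(pmax(t, 0), tinf)   # elapsed infusion time
  ta <- pmax(t - tinf, 0)        # time since end of infusion
  k10 <- cl / v1
  one_cmt <- q == 0
  if (all(one_cmt)) {
    return(ifelse(t <= 0, 0,
                  r0 / cl * (1 - exp(-k10 * te)) * exp(-k10 * ta)))
  }
  k12 <- q / v1
  k21 <- q / v2
  s <- k10 + k12 + k21
  disc <- sqrt(pmax(s^2 - 4 * k10 * k21, 0))
  alpha <- (s + disc) / 2
  beta <- (s - disc) / 2
  c1 <- (alpha - k21) / (v1 * (alpha - beta))
  c2 <- (k21 - beta) / (v1 * (alpha - beta))
  out <- r0 * (c1 / alpha * (1 - exp(-alpha * te)) * exp(-alpha * ta) +
                 c2 / beta * (1 - exp(-beta * te)) * exp(-beta * ta))
  if (any(one_cmt)) {
    oc <- r0 / cl * (1 - exp(-k10 * te)) * exp(-k10 * ta)
    out <- ifelse(one_cmt, oc, out)
  }
  ifelse(t <= 0, 0, out)
}

#' Concentration-time solution for multiple intermittent infusions
#'
#' Analytic two-compartment solution (central compartment, total drug)
#' superposed over all doses of the regimen administered before `t`.
#' Linear in dose.
#'
#' @param params An [individual_parameters()] object or any list with
#'   positive `cl, v1, q, v2` (`q = 0` allowed).
#' @param regimen A [dosing_regimen()].
#' @param t Time(s) in h since the first infusion start, >= 0.
#' @return Concentration(s) in mg/L.
#' @export
concentration <- function(params, regimen, t) {
  stopifnot(inherits(regimen, "meropta_regimen"))
  assert_that(is.numeric(t) && all(is.finite(t)) && all(t >= 0),
              "t", "must be non-negative (hours)")
  conc_profile(params$cl, params$v1, params$q, params$v2, regimen, t)
}

# core superposition; cl/v1/q/v2 vectors of equal length n, t scalar or
# length n -> length-n result; or scalars with t a vector.
conc_profile <- function(cl, v1, q, v2, regimen, t) {
  total <- 0
  for (k in seq_len(regimen$n_doses)) {
    start <- (k - 1) * regimen$interval
    total <- total + conc_single_infusion(
      t - start, cl, v1, q, v2, regimen$dose, regimen$infusion_duration)
  }
  total
}

#' Monte-Carlo simulation of concentration profiles
#'
#' Each replicate draws fresh lognormal IIV on all four parameters; if
#' `with_residual = TRUE`, combined residual error is applied per
#' observation as `C * (1 + eps_prop) + eps_add` with simulated values
#' floored at 0 (the truncation rate is returned as an attribute).
#'
#' @inheritParams individual_parameters
#' @param regimen A [dosing_regimen()].
#' @param times Observation times in h, non-empty.
#' @param n_replicates Number of Monte-Carlo replicates, >= 1.
#' @param with_residual Apply residual variability per observation.
#' @param seed Optional integer seed; the same seed reproduces the output
#'   bit for bit.
#' @return Numeric matrix, `n_replicates` rows by `length(times)` columns.
#' @export
simulate_concentrations <- function(model, patient, regimen, times,
                                    n_replicates = 2000L,
                                    with_residual = TRUE, seed = NULL) {
  stopifnot(inherits(model, "meropta_poppk"),
            inherits(regimen, "meropta_regimen"))
  assert_that(length(times) >= 1, "times", "must be non-empty")
  assert_that(n_replicates >= 1, "n_replicates", "must be >= 1")
  tv <- typical_parameters(model, patient)
  with_local_seed(seed, {
    eta <- matrix(stats::rnorm(4L * n_replicates), ncol = 4L) %*%
      diag(model$omega)
    cl <- tv$cl * exp(eta[, 1]); v1 <- tv$v1 * exp(eta[, 2])
    qv <- tv$q * exp(eta[, 3]); v2 <- tv$v2 * exp(eta[, 4])
    conc <- vapply(times, function(tt)
      conc_profile(cl, v1, qv, v2, regimen, tt), numeric(n_replicates))
    conc <- matrix(conc, nrow = n_replicates)
    truncated <- 0L
    if (with_residual) {
      eps_p <- matrix(stats::rnorm(length(conc), sd = model$residual_prop_sd),
                      nrow = n_replicates)
      eps_a <- matrix(stats::rnorm(length(conc), sd = model$residual_add_sd),
                      nrow = n_replicates)
      conc <- conc * (1 + eps_p) + eps_a
      truncated <- sum(conc < 0)
      conc[conc < 0] <- 0
    }
    structure(conc, truncation_rate = truncated / length(conc))
  })
}

c8h_time <- function(regimen) (regimen$n_doses - 1L) * regimen$interval + 8

#' Monte-Carlo 8-h trough concentrations for a patient
#'
#' Simulates the concentration 8 h after the start of the assessed dose
#' (the last dose of the regimen) across IIV replicates.  Used by
#' [risk_pk()] and by the agreement evaluation; exposing the replicate
#' vector lets one cohort of virtual patients be reused across MIC levels.
#'
#' @inheritParams simulate_concentrations
#' @return Numeric vector of length `n_replicates` (mg/L).
#' @export
simulate_c8h <- function(model, patient, regimen = dosing_regimen(),
                         n_replicates = 2000L, with_residual = FALSE,
                         seed = NULL) {
  drop(simulate_concentrations(model, patient, regimen,
                               times = c8h_time(regimen),
                               n_replicates = n_replicates,
                               with_residual = with_residual, seed = seed))
}

#' Risk of target non-attainment from the population-PK engine
#'
#' Fraction of Monte-Carlo replicates whose (unbound) concentration 8 h
#' after the assessed dose falls below the MIC — the 100% T>MIC target
#' assessed at the trough.  By default only interindividual variability is
#' simulated (risk reflects between-patient uncertainty, not assay noise)
#' and total concentration is used (`unbound_fraction = 1`).
#'
#' @inheritParams simulate_concentrations
#' @param mic MIC(s) in mg/L, > 0.  A vector of MICs is evaluated against
#'   one shared replicate set, so the returned risks are exactly
#'   non-decreasing in MIC.
#' @param unbound_fraction Fraction of drug unbound, in (0, 1\].
#' @return Risk(s) of target non-attainment in \[0, 1\], named by MIC when
#'   `mic` has length > 1.
#' @export
risk_pk <- function(model, patient, regimen = dosing_regimen(), mic,
                    n_replicates = 2000L, unbound_fraction = 1,
                    with_residual = FALSE, seed = NULL) {
  assert_positive(mic, "mic")
  assert_that(unbound_fraction > 0 && unbound_fraction <= 1,
              "unbound_fraction", "must be in (0, 1]")
  c8h <- simulate_c8h(model, patient, regimen, n_replicates,
                      with_residual = with_residual, seed = seed)
  u <- unbound_fraction * c8h
  risks <- vapply(mic, function(m) mean(u < m), numeric(1))
  if (length(mic) > 1L) names(risks) <- format(mic) else risks <- unname(risks)
  risks
}

#' Read / write a population-PK model as JSON
#'
#' All fields of [poppk_model()]; `omega` is a named object.
#'
#' @param path JSON file path.
#' @return For the reader, a [poppk_model()].
#' @export
read_poppk_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  args <- j[intersect(names(j), names(formals(poppk_model)))]
  if (!is.null(args$omega)) args$omega <- unlist(args$omega)
  do.call(poppk_model, args)
}

#' @rdname read_poppk_json
#' @param model A [poppk_model()] to serialise.
#' @export
write_poppk_json <- function(model, path) {
  stopifnot(inherits(model, "meropta_poppk"))
  out <- unclass(model)
  out$omega <- as.list(out$omega)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Default population-PK model
#'
#' Typical two-compartment meropenem parameters for critically ill adults
#' (clearance 12.5 L/h at CLCR 100 mL/min, central volume 10.5 L at 73 kg,
#' 20% non-renal clearance), shipped as JSON so published estimates can be
#' substituted by editing one file (`inst/extdata/poppk_default.json`).
#'
#' @return A [poppk_model()].
#' @export
default_poppk_model <- function() {
  read_poppk_json(system.file("extdata", "poppk_default.json",
                              package = "meropta", mustWork = TRUE))
}
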