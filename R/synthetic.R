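#' Cohort specification for the synthetic patient generator
#'
#' Defines the marginal distributions of a simulated ICU cohort on standard
#' meropenem dosing.  Continuous characteristics are lognormal (positive,
#' right-skewed clinical variables), calibrated so the distribution's
#' median and 95th percentile hit the stated targets; the implied 5th
#' percentile is validated against its target and a warning is emitted when
#' it is off by more than 15%.  The defaults reproduce a critically ill
#' evaluation cohort: median creatinine clearance 86.4 mL/min (5th-95th
#' percentile 35.4-161), age 57.0 y (33.7-79.0), weight 73.0 kg
#' (50.0-97.3), serum albumin 2.5 g/dL (2.3-3.2), 65.2% male, a mean of
#' 5.7 TDM samples per patient, and routine sampling times with median
#' 6.2 h after the last dose (5th-95th percentile 3.72-8.13 h).
#'
#' @param n_patients Number of patients to generate.
#' @param clcr,age,weight,albumin Named vectors `c(median, p5, p95)`.
#' @param male_fraction Proportion of male patients.
#' @param samples_per_patient_mean Mean number of sampled dosing intervals
#'   per patient.
#' @param sampling_time Named vector `c(median, p5, p95)` of the sampling
#'   offset after the last dose, in h.
#' @return Object of class `meropta_cohort_spec`.
#' @export
cohort_spec <- function(n_patients = 155L,
                        clcr = c(median = 86.4, p5 = 35.4, p95 = 161),
                        age = c(median = 57.0, p5 = 33.7, p95 = 79.0),
                        weight = c(median = 73.0, p5 = 50.0, p95 = 97.3),
                        albumin = c(median = 2.5, p5 = 2.3, p95 = 3.2),
                        male_fraction = 0.652,
                        samples_per_patient_mean = 5.7,
                        sampling_time = c(median = 6.2, p5 = 3.72,
                                          p95 = 8.13)) {
  assert_that(n_patients >= 1, "n_patients", "must be at least 1")
  assert_probability(male_fraction, "male_fraction")
  assert_that(samples_per_patient_mean >= 1, "samples_per_patient_mean",
              "must be at least 1")
  for (f in c("clcr", "age", "weight", "albumin", "sampling_time")) {
    v <- get(f)
    assert_that(length(v) == 3 && all(v > 0), f,
                "must be c(median, p5, p95), all positive")
    degenerate <- v[2] == v[1] && v[1] == v[3]
    assert_that((v[2] < v[1] && v[1] < v[3]) || degenerate, f,
                "percentile targets must satisfy p5 < median < p95 (or all equal for a point mass)")
  }
  structure(list(n_patients = as.integer(n_patients), clcr = clcr, age = age,
                 weight = weight, albumin = albumin,
                 male_fraction = male_fraction,
                 samples_per_patient_mean = samples_per_patient_mean,
                 sampling_time = sampling_time),
            class = "meropta_cohort_spec")
}

# Solve lognormal (mu, sigma) from (median, p95); validate the implied p5.
calibrate_lognormal <- function(targets, what) {
  mu <- log(targets[["median"]])
  sigma <- (log(targets[["p95"]]) - mu) / stats::qnorm(0.95)
  if (sigma == 0) return(c(mu = mu, sigma = 0))  # point-mass spec
  implied_p5 <- exp(mu - stats::qnorm(0.95) * sigma)
  rel_off <- abs(implied_p5 - targets[["p5"]]) / targets[["p5"]]
  if (rel_off > 0.15) {
    warning(sprintf(
      "%s: lognormal calibrated on (median, p95) implies a 5th percentile of %.3g vs target %.3g (off by %.0f%%)",
      what, implied_p5, targets[["p5"]], 100 * rel_off))
  }
  c(mu = mu, sigma = sigma)
}

# Beta(a, b) on [0, interval] matched to the sampling-offset quantile
# targets by least squares; targets above the interval are clamped just
# below it (a sample cannot be later than the next scheduled dose).
calibrate_offset_beta <- function(targets, interval) {
  p <- c(0.05, 0.5, 0.95)
  qt <- pmin(unname(targets[c("p5", "median", "p95")]) / interval, 0.999)
  obj <- function(par) {
    a <- exp(par[1]); b <- exp(par[2])
    sum((stats::qbeta(p, a, b) - qt)^2)
  }
  fit <- stats::optim(c(log(4), log(2)), obj, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-12))
  c(a = exp(fit$par[1]), b = exp(fit$par[2]))
}

#' Generate a synthetic patient cohort
#'
#' Draws sex, age, weight, albumin and creatinine clearance from the
#' calibrated marginals (independently — no correlation structure is
#' imposed), then back-solves serum creatinine through the inverted
#' Cockcroft-Gault equation so each record is internally consistent.  With
#' `screen = TRUE` the clearance is resampled into the applicability range
#' (25-255 mL/min); the number of resampled draws is reported as an
#' attribute.
#'
#' @param spec A [cohort_spec()].
#' @param seed Optional integer seed (bit-reproducible output).
#' @param screen Resample creatinine clearance into \[25, 255\] mL/min.
#' @return List of [patient()] objects; attribute `n_resampled` counts
#'   screen resamples.
#' @export
generate_patients <- function(spec = cohort_spec(), seed = NULL,
                              screen = FALSE) {
  stopifnot(inherits(spec, "meropta_cohort_spec"))
  par_clcr <- calibrate_lognormal(spec$clcr, "clcr")
  par_age <- calibrate_lognormal(spec$age, "age")
  par_wt <- calibrate_lognormal(spec$weight, "weight")
  par_alb <- calibrate_lognormal(spec$albumin, "albumin")
  n <- spec$n_patients
  with_local_seed(seed, {
    sex <- ifelse(stats::runif(n) < spec$male_fraction, "male", "female")
    age <- pmin(stats::rlnorm(n, par_age["mu"], par_age["sigma"]), 110)
    wt <- stats::rlnorm(n, par_wt["mu"], par_wt["sigma"])
    alb <- stats::rlnorm(n, par_alb["mu"], par_alb["sigma"])
    clcr <- stats::rlnorm(n, par_clcr["mu"], par_clcr["sigma"])
    n_resampled <- 0L
    if (screen) {
      bad <- which(clcr < 25 | clcr > 255)
      while (length(bad)) {
        n_resampled <- n_resampled + length(bad)
        clcr[bad] <- stats::rlnorm(length(bad), par_clcr["mu"],
                                   par_clcr["sigma"])
        bad <- which(clcr < 25 | clcr > 255)
      }
    }
    # invert Cockcroft-Gault so (sex, age, weight, scr) reproduce the
    # drawn clearance exactly
    scr <- (140 - age) * wt * ifelse(sex == "female", 0.85, 1) / (72 * clcr)
    pats <- lapply(seq_len(n), function(i) {
      patient(id = sprintf("SIM%04d", i), sex = sex[i], age = age[i],
              weight = wt[i], serum_creatinine = scr[i],
              serum_albumin = alb[i], rrt = FALSE)
    })
    structure(pats, n_resampled = n_resampled)
  })
}

#' Generate synthetic TDM observations
#'
#' Emulates routine therapeutic drug monitoring: each patient is observed
#' over a Poisson-distributed number of consecutive q8h dosing intervals
#' (1 + Poisson(mean - 1), so the mean matches the spec), with one sample
#' per interval at an offset after the interval's dose drawn from a beta
#' distribution on \[0, interval\] calibrated to the spec's sampling-time
#' quantiles.  Concentrations are simulated from the population-PK model
#' with one interindividual-variability draw per patient plus residual
#' error per sample; the ground-truth individual parameters are retained
#' for recovery testing.
#'
#' @param patients List of [patient()] objects.
#' @param regimen A [dosing_regimen()] (its `n_doses` is ignored; doses
#'   run over the sampled intervals).
#' @param pk_model A [poppk_model()].
#' @param spec A [cohort_spec()] (sampling-time and samples-per-patient
#'   fields are used).
#' @param seed Optional integer seed.
#' @param fixed_offset Optional fixed sampling offset in h (overrides the
#'   beta draw; e.g. `8` samples every trough exactly).
#' @return Data frame of class `meropta_tdm` (columns as in
#'   [read_tdm_csv()]); attribute `individual_parameters` is a data frame
#'   of the true per-patient `cl, v1, q, v2`.
#' @export
generate_tdm <- function(patients, regimen = dosing_regimen(),
                         pk_model = default_poppk_model(),
                         spec = cohort_spec(), seed = NULL,
                         fixed_offset = NULL) {
  stopifnot(inherits(pk_model, "meropta_poppk"),
            inherits(regimen, "meropta_regimen"))
  beta_par <- calibrate_offset_beta(spec$sampling_time, regimen$interval)
  with_local_seed(seed, {
    truth <- list()
    rows <- lapply(patients, function(p) {
      n_int <- 1L + stats::rpois(1L, spec$samples_per_patient_mean - 1)
      ip <- individual_parameters(pk_model, p)
      truth[[length(truth) + 1L]] <<- data.frame(
        patient_id = as.character(p$id), cl = ip$cl, v1 = ip$v1,
        q = ip$q, v2 = ip$v2, stringsAsFactors = FALSE)
      offs <- if (is.null(fixed_offset)) {
        regimen$interval * stats::rbeta(n_int, beta_par["a"], beta_par["b"])
      } else rep(fixed_offset, n_int)
      dose_times <- (seq_len(n_int) - 1L) * regimen$interval
      sample_times <- dose_times + offs
      conc <- vapply(seq_len(n_int), function(j) {
        cc <- 0
        for (s in dose_times[dose_times <= sample_times[j]]) {
          cc <- cc + conc_single_infusion(
            sample_times[j] - s, ip$cl, ip$v1, ip$q, ip$v2,
            regimen$dose, regimen$infusion_duration)
        }
        cc
      }, numeric(1))
      obs <- conc * (1 + stats::rnorm(n_int, sd = pk_model$residual_prop_sd)) +
        stats::rnorm(n_int, sd = pk_model$residual_add_sd)
      obs[obs < 0] <- 0
      data.frame(patient_id = as.character(p$id), dose_mg = regimen$dose,
                 tinf_h = regimen$infusion_duration,
                 dose_time_h = dose_times, sample_time_h = sample_times,
                 conc_mg_l = obs, stringsAsFactors = FALSE)
    })
    out <- as_tdm(do.call(rbind, rows))
    row.names(out) <- NULL
    attr(out, "individual_parameters") <- do.call(rbind, truth)
    out
  })
}

#' Generate a synthetic MIC frequency distribution
#'
#' A discretised-lognormal stand-in for a published wild-type MIC
#' distribution: isolate counts are multinomial with bin probabilities
#' proportional to a normal density on the log2-MIC grid centred at the
#' modal MIC.
#'
#' @param pathogen_name Pathogen label.
#' @param modal_mic Modal MIC in mg/L; must be a power of two (doubling
#'   grid).
#' @param spread Standard deviation on the log2 scale; `0` puts every
#'   isolate in the modal bin.
#' @param n_isolates Total isolate count, >= 1.
#' @param seed Optional integer seed.
#' @param n_bins_each_side Grid half-width in doubling dilutions.
#' @return A [mic_distribution()] labelled as synthetic.
#' @export
generate_mic_distribution <- function(pathogen_name, modal_mic, spread = 0.8,
                                      n_isolates = 1000L, seed = NULL,
                                      n_bins_each_side = 5L) {
  assert_positive(modal_mic, "modal_mic")
  l2 <- log2(modal_mic)
  assert_that(abs(l2 - round(l2)) < 1e-8, "modal_mic",
              "must lie on the doubling-dilution grid (a power of two)")
  assert_nonnegative(spread, "spread")
  assert_that(n_isolates >= 1, "n_isolates", "must be at least 1")
  grid <- modal_mic * 2^seq(-n_bins_each_side, n_bins_each_side)
  prob <- if (spread == 0) {
    as.numeric(seq_along(grid) == n_bins_each_side + 1L)
  } else {
    stats::dnorm(log2(grid), mean = l2, sd = spread)
  }
  counts <- with_local_seed(
    seed, as.vector(stats::rmultinom(1L, n_isolates, prob)))
  keep <- counts > 0
  mic_distribution(pathogen_name, grid[keep], counts[keep],
                   source_label = paste0("synthetic discretised-lognormal (",
                                         "modal ", modal_mic, " mg/L)"))
}
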