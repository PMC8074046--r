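#' Lin's concordance correlation coefficient
#'
#' Agreement between two measurement methods,
#' \deqn{\rho_c = \frac{2\,\mathrm{cov}(x, y)}
#'   {\sigma_x^2 + \sigma_y^2 + (\mu_x - \mu_y)^2}}
#' with population (1/n) moments.  Unlike Pearson's r, the CCC penalises
#' location and scale shifts, so \eqn{|\rho_c| \le |r|} always.
#'
#' Degenerate cases: both sequences constant with equal values gives 1
#' (perfect agreement); both constant with different values gives 0.
#'
#' @param x,y Equal-length numeric vectors, n >= 2, finite.
#' @return The CCC in \[-1, 1\].
#' @export
lins_ccc <- function(x, y) {
  assert_that(length(x) == length(y), "y", "must match the length of x")
  assert_that(length(x) >= 2, "x", "need at least 2 pairs")
  assert_that(all(is.finite(x)) && all(is.finite(y)), "x",
              "all values must be finite")
  n <- length(x)
  mx <- mean(x); my <- mean(y)
  vx <- mean((x - mx)^2); vy <- mean((y - my)^2)
  sxy <- mean((x - mx) * (y - my))
  denom <- vx + vy + (mx - my)^2
  if (denom == 0) return(1)          # identical constants
  if (vx == 0 && vy == 0) return(0)  # distinct constants
  2 * sxy / denom
}

#' Confidence limits for Lin's CCC
#'
#' Normal-theory limits on the Fisher z scale using Lin's asymptotic
#' variance for the z-transformed CCC, back-transformed with `tanh`.  The
#' variance involves the Pearson correlation `r` and the standardised mean
#' shift `u = (mu_x - mu_y) / sqrt(sd_x sd_y)`; pass them for exact limits
#' (done automatically by [ccc_with_ci()]), otherwise the location-shift
#' terms are dropped (`r = ccc`, `u = 0`).
#'
#' @param ccc Point estimate in (-1, 1).
#' @param n Number of pairs, >= 4.
#' @param level Confidence level, default 0.95.
#' @param sided `"two"` for a two-sided interval, `"lower"` for the
#'   one-sided lower limit used by the evaluation success rule.
#' @param r Pearson correlation of the pairs (defaults to `ccc`).
#' @param u Standardised mean difference (defaults to 0).
#' @return For `sided = "two"`, `c(lower, upper)`; for `sided = "lower"`,
#'   the one-sided lower limit.
#' @export
ccc_confidence <- function(ccc, n, level = 0.95, sided = c("two", "lower"),
                           r = ccc, u = 0) {
  sided <- match.arg(sided)
  assert_that(n >= 4, "n", "need at least 4 pairs for confidence limits")
  if (abs(ccc) >= 1) {
    warning("|CCC| = 1: degenerate limit returned as the point value")
    return(if (sided == "lower") ccc else c(lower = ccc, upper = ccc))
  }
  if (r == 0) r <- .Machine$double.eps  # guard the r-denominators
  z <- atanh(ccc)
  var_z <- ((1 - r^2) * ccc^2 / ((1 - ccc^2) * r^2) +
              4 * ccc^3 * (1 - ccc) * u^2 / (r * (1 - ccc^2)^2) -
              2 * ccc^4 * u^4 / (r^2 * (1 - ccc^2)^2)) / (n - 2)
  se_z <- sqrt(max(var_z, 0))
  if (sided == "lower") {
    tanh(z - stats::qnorm(level) * se_z)
  } else {
    q <- stats::qnorm((1 + level) / 2)
    c(lower = tanh(z - q * se_z), upper = tanh(z + q * se_z))
  }
}

#' CCC with confidence limits from paired data
#'
#' @inheritParams lins_ccc
#' @param level Confidence level.
#' @return List with `ccc`, `lower`, `upper` (two-sided), `lower_one_sided`
#'   and `n`.
#' @export
ccc_with_ci <- function(x, y, level = 0.95) {
  ccc <- lins_ccc(x, y)
  n <- length(x)
  sdx <- stats::sd(x) * sqrt((n - 1) / n)
  sdy <- stats::sd(y) * sqrt((n - 1) / n)
  r <- if (sdx == 0 || sdy == 0) ccc else stats::cor(x, y)
  u <- if (sdx == 0 || sdy == 0) 0 else (mean(x) - mean(y)) / sqrt(sdx * sdy)
  if (abs(ccc) >= 1) {
    return(list(ccc = ccc, lower = ccc, upper = ccc,
                lower_one_sided = ccc, n = n))
  }
  two <- ccc_confidence(ccc, n, level, "two", r = r, u = u)
  low1 <- ccc_confidence(ccc, n, level, "lower", r = r, u = u)
  list(ccc = ccc, lower = unname(two[1]), upper = unname(two[2]),
       lower_one_sided = low1, n = n)
}

#' McBride strength-of-agreement grade
#'
#' Grades a CCC lower confidence limit: poor < 0.90, moderate 0.90-0.95,
#' substantial 0.95-0.99, almost perfect > 0.99 (boundaries belong to the
#' band they open or close as printed: 0.90 is moderate, 0.95 and 0.99 are
#' substantial).
#'
#' @param ccc_lower_limit Value(s) in \[-1, 1\].
#' @return Factor with levels `poor`, `moderate`, `substantial`,
#'   `almost_perfect`.
#' @export
mcbride_grade <- function(ccc_lower_limit) {
  assert_that(all(ccc_lower_limit >= -1 & ccc_lower_limit <= 1),
              "ccc_lower_limit", "must lie in [-1, 1]")
  cut(ccc_lower_limit, breaks = c(-Inf, 0.90, 0.95, 0.99, Inf),
      labels = c("poor", "moderate", "substantial", "almost_perfect"),
      right = FALSE, include.lowest = TRUE) ->
    g
  # 0.90 opens moderate and 0.95 opens substantial (left-closed, as above),
  # but 0.99 closes substantial, so shift exact 0.99 back down
  g[ccc_lower_limit == 0.99] <- "substantial"
  g
}

#' TDM observation table reader
#'
#' CSV with one row per (dose, sample) record: `patient_id, dose_mg,
#' tinf_h, dose_time_h, sample_time_h, conc_mg_l`.  Rows sharing a
#' `patient_id` define that patient's dose history; each unique
#' `(patient_id, sample_time_h, conc_mg_l)` pair is one observation.
#'
#' @param path CSV file path.
#' @return Data frame of class `meropta_tdm` with the columns above plus
#'   `time_after_last_dose_h`.
#' @export
read_tdm_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("patient_id", "dose_mg", "tinf_h", "dose_time_h",
            "sample_time_h", "conc_mg_l")
  if (!all(need %in% names(df))) {
    stop("TDM CSV must contain columns: ", paste(need, collapse = ", "))
  }
  extra <- setdiff(names(df), need)
  if (length(extra)) {
    warning("ignoring unknown columns: ", paste(extra, collapse = ", "))
  }
  as_tdm(df)
}

as_tdm <- function(df) {
  assert_nonnegative(df$conc_mg_l, "conc_mg_l")
  if (any(df$sample_time_h < df$dose_time_h[1])) {
    stop("sample predates the first dose", call. = FALSE)
  }
  df$time_after_last_dose_h <- vapply(seq_len(nrow(df)), function(i) {
    doses <- df[df$patient_id == df$patient_id[i], ]
    starts <- unique(doses$dose_time_h)
    # a sample taken exactly when the next dose starts belongs to the
    # interval that just ended (the new infusion has delivered nothing yet)
    prior <- starts[starts < df$sample_time_h[i]]
    last <- if (length(prior)) max(prior) else min(starts)
    df$sample_time_h[i] - last
  }, numeric(1))
  class(df) <- c("meropta_tdm", "data.frame")
  df
}

#' Prediction-error report: PK model vs observed TDM concentrations
#'
#' Step 1 of the two-step evaluation.  For each observation the model
#' prediction is the median of Monte-Carlo replicates (IIV + residual
#' variability) at the sample time under the patient's own dose history.
#' The per-sample prediction error is `predicted - observed` by default, so
#' that model underprediction yields negative bias (set
#' `sign_convention = "observed_minus_predicted"` for the opposite
#' convention).  Bias is the median PE (`center = "mean"` for the mean);
#' precision is the 50% prediction-error interval (25th-75th percentiles,
#' linear-interpolation quantiles).  Relative errors are PE divided by the
#' observed concentration.
#'
#' @param tdm A [read_tdm_csv()]-style data frame.
#' @param patients List of [patient()] objects covering every
#'   `patient_id`.
#' @param model A [poppk_model()].
#' @param n_replicates Monte-Carlo replicates per observation.
#' @param sign_convention `"predicted_minus_observed"` (default) or
#'   `"observed_minus_predicted"`.
#' @param center `"median"` (default) or `"mean"` for the bias statistic.
#' @param with_residual Include residual variability in the simulated
#'   replicates (default `TRUE`; `FALSE` gives population predictions of
#'   the underlying concentration).
#' @param seed Optional integer seed.
#' @return Object of class `meropta_pe_report`: list with `bias_abs`
#'   (mg/L), `bias_rel` (fraction), `pe_interval_50` and
#'   `pe_interval_50_rel` (named c(p25, p75)), `n_samples`, and the
#'   per-sample `errors` data frame.
#' @export
prediction_errors <- function(tdm, patients, model,
                              n_replicates = 2000L,
                              sign_convention = c("predicted_minus_observed",
                                                  "observed_minus_predicted"),
                              center = c("median", "mean"),
                              with_residual = TRUE, seed = NULL) {
  sign_convention <- match.arg(sign_convention)
  center <- match.arg(center)
  pat_by_id <- stats::setNames(
    patients, vapply(patients, function(p) as.character(p$id), character(1)))
  missing_ids <- setdiff(unique(as.character(tdm$patient_id)),
                         names(pat_by_id))
  if (length(missing_ids)) {
    stop("TDM rows reference unknown patient(s): ",
         paste(missing_ids, collapse = ", "))
  }
  with_local_seed(seed, {
    rows <- lapply(split(seq_len(nrow(tdm)), as.character(tdm$patient_id)),
                   function(idx) {
      d <- tdm[idx, ]
      d <- d[order(d$sample_time_h), ]  # RNG use independent of row order
      p <- pat_by_id[[as.character(d$patient_id[1])]]
      dose_starts <- sort(unique(d$dose_time_h))
      # uniform regimens only need interval/n; irregular histories are
      # superposed dose by dose
      preds <- vapply(seq_len(nrow(d)), function(i) {
        stats::median(predict_conc_history(
          model, p, d$dose_mg[i], d$tinf_h[i], dose_starts,
          d$sample_time_h[i], n_replicates, with_residual))
      }, numeric(1))
      data.frame(patient_id = d$patient_id, sample_time_h = d$sample_time_h,
                 observed = d$conc_mg_l, predicted = preds,
                 stringsAsFactors = FALSE)
    })
    err <- do.call(rbind, rows)
    row.names(err) <- NULL
    pe <- if (sign_convention == "predicted_minus_observed") {
      err$predicted - err$observed
    } else {
      err$observed - err$predicted
    }
    err$pe <- pe
    err$pe_rel <- pe / err$observed
    center_fn <- if (center == "median") stats::median else mean
    structure(list(
      bias_abs = center_fn(err$pe),
      bias_rel = center_fn(err$pe_rel),
      pe_interval_50 = stats::quantile(err$pe, c(0.25, 0.75), names = TRUE),
      pe_interval_50_rel = stats::quantile(err$pe_rel, c(0.25, 0.75),
                                           names = TRUE),
      n_samples = nrow(err),
      sign_convention = sign_convention,
      errors = err), class = "meropta_pe_report")
  })
}

# Monte-Carlo concentrations for one observation under an arbitrary dose
# history (equal dose/duration per administration, variable start times).
predict_conc_history <- function(model, patient, dose, tinf, dose_starts,
                                 sample_time, n_replicates, with_residual) {
  tv <- typical_parameters(model, patient)
  eta <- matrix(stats::rnorm(4L * n_replicates), ncol = 4L) %*%
    diag(model$omega)
  cl <- tv$cl * exp(eta[, 1]); v1 <- tv$v1 * exp(eta[, 2])
  qv <- tv$q * exp(eta[, 3]); v2 <- tv$v2 * exp(eta[, 4])
  conc <- 0
  for (s in dose_starts[dose_starts <= sample_time]) {
    conc <- conc + conc_single_infusion(sample_time - s, cl, v1, qv, v2,
                                        dose, tinf)
  }
  if (with_residual) {
    conc <- conc * (1 + stats::rnorm(n_replicates,
                                     sd = model$residual_prop_sd)) +
      stats::rnorm(n_replicates, sd = model$residual_add_sd)
    conc[conc < 0] <- 0
  }
  conc
}

#' @export
print.meropta_pe_report <- function(x, ...) {
  cat(sprintf(
    "<prediction-error report> (%d samples)\n  bias %.2f mg/L (%.0f%%); 50%% PE interval %.2f to %.2f mg/L (%.0f%% to %.0f%%)\n",
    x$n_samples, x$bias_abs, 100 * x$bias_rel,
    x$pe_interval_50[1], x$pe_interval_50[2],
    100 * x$pe_interval_50_rel[1], 100 * x$pe_interval_50_rel[2]))
  invisible(x)
}

#' Agreement analysis between the two risk engines
#'
#' Step 2 of the two-step evaluation.  For every patient and MIC level the
#' paired risks of target non-attainment are computed with the regression
#' engine (method 1) and the population-PK engine (method 2; one simulated
#' virtual cohort per patient reused across all MICs).  Lin's CCC with
#' confidence limits and a McBride grade is reported per MIC, for all
#' patients and for the stratum with creatinine clearance > 50 mL/min, and
#' pooled over the whole MIC grid (all patient-by-MIC pairs concatenated).
#'
#' @param patients List of [patient()] objects (must all pass the
#'   inclusion screen).
#' @param regression_model A [regression_model()].
#' @param pk_model A [poppk_model()].
#' @param regimen A [dosing_regimen()].
#' @param mic_grid MIC levels in mg/L; default the 8-level grid
#'   0.125-16.
#' @param strata_clcr_cut Creatinine-clearance cut defining the maintained
#'   renal-function stratum (`clcr > cut`), default 50 mL/min.
#' @param n_replicates Virtual patients per real patient for the PK
#'   engine.
#' @param seed Optional integer seed.
#' @return Object of class `meropta_agreement`: list with `paired` (tidy
#'   data frame: patient_id, clcr, mic, risk_regression, risk_pk,
#'   clcr_stratum), `ccc_table` (per MIC and pooled, per stratum, with CI
#'   and McBride grade) and `mic_grid`.
#' @export
compare_risk_methods <- function(patients, regression_model, pk_model,
                                 regimen = dosing_regimen(),
                                 mic_grid = default_mic_grid(),
                                 strata_clcr_cut = 50,
                                 n_replicates = 2000L, seed = NULL) {
  stopifnot(inherits(regression_model, "meropta_regression"),
            inherits(pk_model, "meropta_poppk"))
  assert_that(length(mic_grid) >= 1, "mic_grid", "must be non-empty")
  with_local_seed(seed, {
    rows <- lapply(patients, function(p) {
      r1 <- risk_regression(regression_model, p$clcr, mic_grid)
      c8h <- simulate_c8h(pk_model, p, regimen, n_replicates,
                          with_residual = FALSE)
      r2 <- vapply(mic_grid, function(m) mean(c8h < m), numeric(1))
      data.frame(patient_id = as.character(p$id), clcr = p$clcr,
                 mic = mic_grid, risk_regression = unname(r1),
                 risk_pk = r2, stringsAsFactors = FALSE)
    })
    paired <- do.call(rbind, rows)
    row.names(paired) <- NULL
    paired$clcr_stratum <- ifelse(paired$clcr > strata_clcr_cut,
                                  paste0("clcr_gt_", strata_clcr_cut), "all")
    ccc_table <- agreement_ccc_table(paired, mic_grid, strata_clcr_cut)
    structure(list(paired = paired, ccc_table = ccc_table,
                   mic_grid = mic_grid,
                   strata_clcr_cut = strata_clcr_cut),
              class = "meropta_agreement")
  })
}

agreement_ccc_table <- function(paired, mic_grid, cut) {
  strata <- list(all = rep(TRUE, nrow(paired)),
                 high_clcr = paired$clcr > cut)
  names(strata)[2] <- paste0("clcr_gt_", cut)
  mics <- c(as.list(mic_grid), list(mic_grid))
  mic_label <- c(format(mic_grid),
                 paste0(format(min(mic_grid)), "-", format(max(mic_grid))))
  out <- list()
  for (s in names(strata)) {
    for (j in seq_along(mics)) {
      sel <- strata[[s]] & paired$mic %in% mics[[j]]
      if (sum(sel) < 4) {
        warning("stratum '", s, "', MIC ", mic_label[j],
                ": fewer than 4 pairs, CCC omitted")
        next
      }
      ci <- ccc_with_ci(paired$risk_regression[sel], paired$risk_pk[sel])
      out[[length(out) + 1L]] <- data.frame(
        stratum = s, mic = mic_label[j],
        pooled = j == length(mics),
        ccc = ci$ccc, lower = ci$lower, upper = ci$upper,
        lower_one_sided = ci$lower_one_sided, n = ci$n,
        grade = as.character(mcbride_grade(ci$lower)),
        stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, out)
  row.names(tab) <- NULL
  tab
}

#' @export
print.meropta_agreement <- function(x, ...) {
  cat("<risk-agreement report>\n")
  print(x$ccc_table, digits = 3)
  invisible(x)
}

#' Evaluation success rule
#'
#' The agreement evaluation is successful if the one-sided 95% lower
#' confidence limit of the CCC pooled over all investigated MIC values
#' (all-patients stratum) is strictly greater than 0.95.
#'
#' @param report A [compare_risk_methods()] report.
#' @return `TRUE` or `FALSE`.
#' @export
success_criterion <- function(report) {
  stopifnot(inherits(report, "meropta_agreement"))
  tab <- report$ccc_table
  row <- tab[tab$stratum == "all" & tab$pooled, , drop = FALSE]
  if (nrow(row) != 1) {
    stop("report lacks a pooled all-patients CCC", call. = FALSE)
  }
  row$lower_one_sided > 0.95
}
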