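#' MIC frequency distribution of a pathogen
#'
#' A pathogen-labelled frequency table over the doubling-dilution MIC grid,
#' as published in EUCAST-style wild-type distribution reports.  MIC values
#' must be strictly increasing and lie on the doubling grid (each bin is a
#' power-of-two multiple of its predecessor; gaps are allowed).  A
#' provenance label is mandatory and is echoed to the user whenever a
#' distribution-based risk is reported.
#'
#' @param pathogen Pathogen name.
#' @param mic MIC bin values in mg/L, strictly increasing on the doubling
#'   grid.
#' @param count Non-negative isolate counts per bin; total must be > 0.
#' @param source_label Provenance string (e.g. data source and retrieval
#'   date) displayed with every risk result derived from this distribution.
#' @param top_censored If `TRUE`, the highest bin aggregates isolates at or
#'   above its MIC ("\eqn{\ge} x mg/L"); evaluating risk exactly at that
#'   MIC is then conservative, and a warning is emitted.
#' @return Object of class `meropta_micdist`.
#' @export
mic_distribution <- function(pathogen, mic, count, source_label,
                             top_censored = FALSE) {
  assert_positive(mic, "mic")
  assert_that(length(mic) == length(count), "count",
              "must match the length of mic")
  assert_nonnegative(count, "count")
  assert_that(sum(count) > 0, "count", "total isolate count must be > 0")
  if (is.unsorted(mic, strictly = TRUE)) {
    stop("mic values must be strictly increasing", call. = FALSE)
  }
  # successive bins must (nearly) double; the 10% slack accepts the
  # conventional rounding of published grids (e.g. 0.064 -> 0.125)
  ratios <- log2(mic[-1] / mic[-length(mic)])
  if (length(ratios) && any(abs(ratios - round(ratios)) > 0.1)) {
    stop("mic values must lie on the doubling-dilution grid", call. = FALSE)
  }
  assert_that(is.character(source_label) && nzchar(source_label),
              "source_label", "provenance label is mandatory")
  structure(list(pathogen = pathogen, mic = as.numeric(mic),
                 count = as.numeric(count),
                 frequency = count / sum(count),
                 source_label = source_label,
                 top_censored = isTRUE(top_censored)),
            class = "meropta_micdist")
}

#' @export
print.meropta_micdist <- function(x, ...) {
  cat(sprintf("<MIC distribution: %s> (%d isolates, %d bins)\n  source: %s\n",
              x$pathogen, round(sum(x$count)), length(x$mic), x$source_label))
  invisible(x)
}

#' Probability-of-target-attainment curve over a MIC grid
#'
#' Evaluates a bound risk function on a MIC grid; the default grid is the 8
#' doubling dilutions 0.125-16 mg/L used for risk reporting.
#'
#' @param risk_fn Function mapping a vector of MICs (mg/L) to risks of
#'   target non-attainment — typically [risk_regression()] or [risk_pk()]
#'   bound to a patient.
#' @param mic_grid Strictly positive, strictly increasing MIC grid.
#' @return Data frame with columns `mic`, `risk` (non-attainment) and
#'   `pta` (`1 - risk`).
#' @export
pta_curve <- function(risk_fn, mic_grid = default_mic_grid()) {
  assert_that(length(mic_grid) >= 1, "mic_grid", "must be non-empty")
  assert_positive(mic_grid, "mic_grid")
  if (is.unsorted(mic_grid, strictly = TRUE)) {
    stop("mic_grid must be strictly increasing", call. = FALSE)
  }
  risk <- unname(risk_fn(mic_grid))
  assert_probability(risk, "risk")
  data.frame(mic = mic_grid, risk = risk, pta = 1 - risk)
}

#' The standard 8-level MIC reporting grid
#'
#' @return `c(0.125, 0.25, 0.5, 1, 2, 4, 8, 16)` mg/L.
#' @export
default_mic_grid <- function() c(0.125, 0.25, 0.5, 1, 2, 4, 8, 16)

#' Risk of target non-attainment over a pathogen's MIC distribution
#'
#' Cumulative-fraction-of-response (CFR) analysis: the risk is the
#' frequency-weighted average of the per-MIC risks over the distribution's
#' bins, \eqn{\sum_i f_i \, risk(MIC_i) = 1 - CFR} where
#' \eqn{CFR = \sum_i f_i \, PTA(MIC_i)}.  Each bin is evaluated exactly at
#' its MIC (the risk engines are defined at arbitrary MIC, so no grid
#' interpolation is needed).
#'
#' @param risk_fn Function mapping MIC(s) to non-attainment risk(s), or a
#'   named numeric vector/`pta_curve` data frame covering every bin MIC.
#' @param dist A [mic_distribution()].
#' @return Risk of target non-attainment in \[0, 1\], with attribute
#'   `source_label` carrying the distribution's provenance.
#' @export
cfr_risk <- function(risk_fn, dist) {
  stopifnot(inherits(dist, "meropta_micdist"))
  if (is.function(risk_fn)) {
    risks <- unname(risk_fn(dist$mic))
  } else {
    lookup <- if (is.data.frame(risk_fn)) {
      stats::setNames(risk_fn$risk, format(risk_fn$mic))
    } else risk_fn
    key <- format(dist$mic)
    if (!all(key %in% names(lookup))) {
      stop("no risk value for MIC bin(s) ",
           paste(setdiff(key, names(lookup)), collapse = ", "),
           " and no extrapolation rule; supply a risk function instead",
           call. = FALSE)
    }
    risks <- unname(lookup[key])
  }
  assert_probability(risks, "risk")
  if (dist$top_censored) {
    warning("top MIC bin of '", dist$pathogen, "' is censored (>= ",
            dist$mic[length(dist$mic)], " mg/L); risk evaluated at the ",
            "stated concentration is conservative (an underestimate)")
  }
  structure(sum(dist$frequency * risks), source_label = dist$source_label)
}

#' Risk at a user-chosen MIC breakpoint
#'
#' The "pathogen and MIC unknown" mode: the single-MIC risk evaluated at a
#' susceptibility breakpoint chosen by the user.
#'
#' @inheritParams cfr_risk
#' @param breakpoint_mic Breakpoint in mg/L, > 0.
#' @return Risk of target non-attainment in \[0, 1\].
#' @export
breakpoint_risk <- function(risk_fn, breakpoint_mic) {
  assert_positive(breakpoint_mic, "breakpoint_mic")
  unname(risk_fn(breakpoint_mic))
}

#' Traffic-light classification of a risk value
#'
#' Fixed per-patient colour bands: green for risk \eqn{\le} 10%, orange for
#' >10% to \eqn{\le} 50%, red for >50%.
#'
#' @param risk Risk(s) in \[0, 1\].
#' @return Factor with levels `green`, `orange`, `red`.
#' @export
classify_risk <- function(risk) {
  assert_probability(risk, "risk")
  cut(risk, breaks = c(-Inf, 0.10, 0.50, Inf),
      labels = c("green", "orange", "red"), right = TRUE)
}

#' Assess the risk of meropenem target non-attainment for one patient
#'
#' Resolves one of the three input modes — known MIC, known pathogen
#' (CFR over its MIC distribution), or user-chosen breakpoint — with
#' precedence MIC > pathogen > breakpoint when several are given, then
#' computes the risk, its colour category and any disclaimers.  The
#' assessment refuses patients whose creatinine clearance lies outside the
#' applicability range, and flags results where the creatinine clearance is
#' below 50 mL/min and a contributing MIC of at least 8 mg/L is involved
#' (the regime in which the regression engine materially underestimates
#' risk and should not be used).
#'
#' @param patient A [patient()].
#' @param mic Known MIC in mg/L (or `NULL`).
#' @param pathogen Pathogen name to look up in `distributions` (or `NULL`).
#' @param breakpoint Breakpoint MIC in mg/L (or `NULL`).
#' @param distributions Named list of [mic_distribution()] objects (names =
#'   pathogen), required for pathogen mode.
#' @param engine `"regression"` (default) or `"pk"`.
#' @param regression A [regression_model()]; defaults to the shipped model.
#' @param pk A [poppk_model()] for `engine = "pk"`.
#' @param regimen Dosing regimen for the PK engine.
#' @param n_replicates,seed Monte-Carlo controls for the PK engine.
#' @return Object of class `meropta_risk_result`: a list with `risk`,
#'   `mode`, `category`, `inputs_echo` and `disclaimer_flags`.
#' @export
assess <- function(patient, mic = NULL, pathogen = NULL, breakpoint = NULL,
                   distributions = NULL,
                   engine = c("regression", "pk"),
                   regression = default_regression_model(),
                   pk = NULL, regimen = dosing_regimen(),
                   n_replicates = 2000L, seed = NULL) {
  stopifnot(inherits(patient, "meropta_patient"))
  engine <- match.arg(engine)
  check_clcr_range(regression, patient$clcr)
  risk_fn <- if (engine == "regression") {
    function(m) risk_regression(regression, patient$clcr, m)
  } else {
    if (is.null(pk)) pk <- default_poppk_model()
    function(m) risk_pk(pk, patient, regimen, m,
                        n_replicates = n_replicates, seed = seed)
  }
  flags <- character(0)
  if (!is.null(mic)) {
    mode <- "mic"
    assert_positive(mic, "mic")
    risk <- unname(risk_fn(mic))
    echo <- list(clcr = patient$clcr, mic = mic, source = "user-provided MIC")
    mics_used <- mic
  } else if (!is.null(pathogen)) {
    mode <- "pathogen_cfr"
    if (is.null(distributions) || is.null(distributions[[pathogen]])) {
      stop("no MIC distribution available for pathogen '", pathogen, "'",
           call. = FALSE)
    }
    dist <- distributions[[pathogen]]
    risk <- cfr_risk(risk_fn, dist)
    echo <- list(clcr = patient$clcr, pathogen = pathogen,
                 source = dist$source_label)
    mics_used <- dist$mic[dist$frequency > 0]
    risk <- as.numeric(risk)
  } else if (!is.null(breakpoint)) {
    mode <- "breakpoint"
    risk <- breakpoint_risk(risk_fn, breakpoint)
    echo <- list(clcr = patient$clcr, breakpoint = breakpoint,
                 source = "user-chosen breakpoint")
    mics_used <- breakpoint
  } else {
    stop("no resolvable input mode: supply `mic`, `pathogen` or ",
         "`breakpoint`", call. = FALSE)
  }
  if (patient$clcr < 50 && any(mics_used >= 8)) {
    flags <- c(flags, "clcr_below_50_with_high_mic")
  }
  structure(list(risk = risk, mode = mode,
                 category = as.character(classify_risk(risk)),
                 engine = engine, inputs_echo = echo,
                 disclaimer_flags = flags),
            class = "meropta_risk_result")
}

#' @export
print.meropta_risk_result <- function(x, ...) {
  cat(sprintf("Risk of target non-attainment: %.1f%%  [%s]\n",
              100 * x$risk, toupper(x$category)))
  cat(sprintf("  mode: %s (engine: %s), CLCR %.1f mL/min\n",
              x$mode, x$engine, x$inputs_echo$clcr))
  cat(sprintf("  MIC data source: %s\n", x$inputs_echo$source))
  if ("clcr_below_50_with_high_mic" %in% x$disclaimer_flags) {
    cat("  DISCLAIMER: should not be used for MIC >= 8 mg/L in patients\n",
        "  with creatinine clearance below 50 mL/min.\n", sep = "")
  }
  invisible(x)
}

#' Cohort-level pathogen risk summary
#'
#' For every pathogen, the median over patients of the distribution-based
#' (CFR) risk of target non-attainment, plus the fraction of pathogens
#' whose median falls in each reporting band.  The cohort bands use strict
#' boundaries (below 10%, 10-50% inclusive, above 50%), which differ from
#' the per-patient traffic-light rule ([classify_risk()], green \eqn{\le}
#' 10%); both are reported.
#'
#' @param patients List of [patient()] objects.
#' @param distributions Named list of [mic_distribution()] objects.
#' @param risk_fn_factory Function `patient -> (mic -> risk)`; defaults to
#'   the regression engine with the shipped model.
#' @return List with `per_pathogen` (data frame: pathogen, median_risk,
#'   band, category) and `band_fractions` (named vector over
#'   `below_10, 10_to_50, above_50`).
#' @export
cohort_pathogen_summary <- function(patients, distributions,
                                    risk_fn_factory = NULL) {
  assert_that(length(patients) >= 1, "patients", "need at least one patient")
  assert_that(length(distributions) >= 1, "distributions",
              "need at least one distribution")
  if (is.null(risk_fn_factory)) {
    rm_default <- default_regression_model()
    risk_fn_factory <- function(p) {
      function(m) risk_regression(rm_default, p$clcr, m)
    }
  }
  risk_fns <- lapply(patients, risk_fn_factory)
  med <- vapply(distributions, function(d) {
    stats::median(vapply(risk_fns, function(f)
      as.numeric(cfr_risk(f, d)), numeric(1)))
  }, numeric(1))
  band <- ifelse(med < 0.10, "below_10",
                 ifelse(med <= 0.50, "10_to_50", "above_50"))
  per_pathogen <- data.frame(
    pathogen = vapply(distributions, function(d) d$pathogen, character(1)),
    median_risk = unname(med),
    band = unname(band),
    category = as.character(classify_risk(unname(med))),
    stringsAsFactors = FALSE, row.names = NULL)
  bf <- c(below_10 = mean(band == "below_10"),
          `10_to_50` = mean(band == "10_to_50"),
          above_50 = mean(band == "above_50"))
  list(per_pathogen = per_pathogen, band_fractions = bf)
}

#' Read MIC distributions from CSV
#'
#' Columns `pathogen, mic_mg_l, count`; one file may hold many pathogens.
#'
#' @param path CSV file path.
#' @param source_label Provenance label applied to every distribution.
#' @return Named list of [mic_distribution()] objects.
#' @export
read_mic_distributions_csv <- function(path, source_label) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("pathogen", "mic_mg_l", "count")
  if (!all(need %in% names(df))) {
    stop("MIC distribution CSV must contain columns: ",
         paste(need, collapse = ", "))
  }
  extra <- setdiff(names(df), need)
  if (length(extra)) {
    warning("ignoring unknown columns: ", paste(extra, collapse = ", "))
  }
  out <- lapply(split(df, df$pathogen), function(d) {
    d <- d[order(d$mic_mg_l), ]
    mic_distribution(d$pathogen[1], d$mic_mg_l, d$count, source_label)
  })
  out[unique(df$pathogen)]
}

#' Write MIC distributions to CSV
#'
#' @param distributions Named list of [mic_distribution()] objects.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_mic_distributions_csv <- function(distributions, path) {
  rows <- do.call(rbind, lapply(distributions, function(d) {
    data.frame(pathogen = d$pathogen, mic_mg_l = d$mic, count = d$count,
               stringsAsFactors = FALSE)
  }))
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
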