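#' Tool configuration
#'
#' Bundles the two risk models, the dosing regimen, the colour thresholds,
#' the MIC reporting grid and the behavioural flags into one object.  A
#' JSON config file may override any subset of fields; everything else
#' falls back to the shipped defaults.
#'
#' @param regression A [regression_model()].
#' @param pk A [poppk_model()].
#' @param regimen A [dosing_regimen()].
#' @param risk_thresholds Named vector `c(green, orange)` upper bounds of
#'   the green and orange bands; must satisfy 0 < green <= orange < 1.
#' @param mic_grid Strictly increasing MIC reporting grid.
#' @param unbound_fraction Unbound fraction used by the PK engine.
#' @param pe_sign_convention Prediction-error sign convention, see
#'   [prediction_errors()].
#' @param gaussian_approx Use normal instead of t predictive quantiles in
#'   the regression engine.
#' @param n_replicates Monte-Carlo replicates for the PK engine.
#' @param seed Default seed for stochastic operations (`NULL` = use the
#'   global RNG stream).
#' @return Object of class `meropta_config`.
#' @export
tool_config <- function(regression = default_regression_model(),
                        pk = default_poppk_model(),
                        regimen = dosing_regimen(),
                        risk_thresholds = c(green = 0.10, orange = 0.50),
                        mic_grid = default_mic_grid(),
                        unbound_fraction = 1,
                        pe_sign_convention = "predicted_minus_observed",
                        gaussian_approx = FALSE,
                        n_replicates = 2000L,
                        seed = NULL) {
  assert_that(risk_thresholds[["green"]] > 0 &&
                risk_thresholds[["green"]] <= risk_thresholds[["orange"]] &&
                risk_thresholds[["orange"]] < 1,
              "risk_thresholds", "must satisfy 0 < green <= orange < 1")
  if (is.unsorted(mic_grid, strictly = TRUE)) {
    stop("mic_grid must be strictly increasing", call. = FALSE)
  }
  structure(list(regression = regression, pk = pk, regimen = regimen,
                 risk_thresholds = risk_thresholds, mic_grid = mic_grid,
                 unbound_fraction = unbound_fraction,
                 pe_sign_convention = pe_sign_convention,
                 gaussian_approx = isTRUE(gaussian_approx),
                 n_replicates = as.integer(n_replicates), seed = seed),
            class = "meropta_config")
}

#' Read a tool configuration from JSON
#'
#' Top-level keys `regression`, `pk`, `regimen`, `risk_thresholds`,
#' `mic_grid`, `unbound_fraction`, `pe_sign_convention`,
#' `gaussian_approx`, `n_replicates`, `seed`; any key may be omitted.
#'
#' @param path JSON file path.
#' @return A [tool_config()].
#' @export
read_config_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  args <- list()
  if (!is.null(j$regression)) {
    r <- j$regression
    args$regression <- regression_model(
      r$intercept, r$slope, r$residual_sd, r$n_train, r$mean_ln_x, r$sxx,
      clcr_range = c(r$clcr_min %||% 25, r$clcr_max %||% 255))
  }
  if (!is.null(j$pk)) {
    pk_args <- j$pk[intersect(names(j$pk), names(formals(poppk_model)))]
    if (!is.null(pk_args$omega)) pk_args$omega <- unlist(pk_args$omega)
    args$pk <- do.call(poppk_model, pk_args)
  }
  if (!is.null(j$regimen)) {
    args$regimen <- dosing_regimen(
      j$regimen$dose %||% 1000, j$regimen$infusion_duration %||% 0.5,
      j$regimen$interval %||% 8, j$regimen$n_doses %||% 1L)
  }
  for (f in c("risk_thresholds", "mic_grid", "unbound_fraction",
              "pe_sign_convention", "gaussian_approx", "n_replicates",
              "seed")) {
    if (!is.null(j[[f]])) args[[f]] <- unlist(j[[f]])
  }
  do.call(tool_config, args)
}

#' Provenance header for output files
#'
#' Every file the tool writes starts with comment lines recording the
#' package version, the seed, a config digest and the MIC-distribution
#' source label (when one was used), so results can be traced to their
#' inputs.
#'
#' @param config A [tool_config()].
#' @param source_label Optional MIC-distribution provenance string.
#' @return Character vector of `#`-prefixed header lines.
#' @export
provenance_header <- function(config, source_label = NULL) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  jsonlite::write_json(
    list(regression = unclass(config$regression),
         pk = lapply(unclass(config$pk),
                     function(x) if (is.numeric(x)) as.list(x) else x),
         regimen = unclass(config$regimen),
         mic_grid = config$mic_grid,
         flags = list(unbound_fraction = config$unbound_fraction,
                      pe_sign_convention = config$pe_sign_convention,
                      gaussian_approx = config$gaussian_approx)),
    tf, auto_unbox = TRUE, digits = NA)
  hash <- unname(tools::md5sum(tf))
  c(sprintf("# meropta %s",
            as.character(utils::packageVersion("meropta"))),
    sprintf("# config_md5: %s", hash),
    sprintf("# seed: %s",
            if (is.null(config$seed)) "none" else config$seed),
    if (!is.null(source_label)) sprintf("# mic_source: %s", source_label))
}

#' Write a data frame as CSV with a provenance header
#'
#' @param df Data frame to write.
#' @param path Output path.
#' @param config A [tool_config()].
#' @param source_label Optional MIC-distribution provenance string.
#' @return `path`, invisibly.
#' @export
write_csv_with_provenance <- function(df, path, config,
                                      source_label = NULL) {
  writeLines(provenance_header(config, source_label), path)
  suppressWarnings(
    utils::write.table(df, path, append = TRUE, sep = ",",
                       row.names = FALSE, quote = FALSE))
  invisible(path)
}

#' Run the full two-step evaluation workflow
#'
#' Convenience wrapper tying the modules together: applies the inclusion
#' screen, computes the step-1 prediction-error report from TDM data, the
#' step-2 agreement report between the two risk engines, and (optionally)
#' writes tidy CSV/JSON outputs with provenance headers.
#'
#' @param patients List of [patient()] objects.
#' @param tdm TDM observations ([read_tdm_csv()] format).
#' @param config A [tool_config()].
#' @param out_dir Optional output directory; when given, writes
#'   `prediction_errors.csv`, `risk_pairs.csv`, `ccc_table.csv` and
#'   `summary.json`.
#' @return List with `inclusion`, `pe_report`, `agreement`, `success`.
#' @export
run_evaluation <- function(patients, tdm, config = tool_config(),
                           out_dir = NULL) {
  incl <- apply_inclusion_criteria(patients, inclusion_criteria(
    clcr_min = config$regression$clcr_range[1],
    clcr_max = config$regression$clcr_range[2]))
  message(sprintf("inclusion screen: %d of %d patients retained",
                  length(incl$included), length(patients)))
  kept_ids <- vapply(incl$included, function(p) as.character(p$id),
                     character(1))
  tdm_kept <- tdm[as.character(tdm$patient_id) %in% kept_ids, ]
  pe <- prediction_errors(tdm_kept, incl$included, config$pk,
                          n_replicates = config$n_replicates,
                          sign_convention = config$pe_sign_convention,
                          seed = config$seed)
  agr <- compare_risk_methods(incl$included, config$regression, config$pk,
                              regimen = config$regimen,
                              mic_grid = config$mic_grid,
                              n_replicates = config$n_replicates,
                              seed = config$seed)
  ok <- success_criterion(agr)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_csv_with_provenance(pe$errors,
                              file.path(out_dir, "prediction_errors.csv"),
                              config)
    write_csv_with_provenance(agr$paired,
                              file.path(out_dir, "risk_pairs.csv"), config)
    write_csv_with_provenance(agr$ccc_table,
                              file.path(out_dir, "ccc_table.csv"), config)
    jsonlite::write_json(
      list(n_patients_included = length(incl$included),
           n_samples = pe$n_samples,
           bias_abs_mg_l = pe$bias_abs, bias_rel = pe$bias_rel,
           pe_interval_50 = as.list(pe$pe_interval_50),
           pooled_ccc = agr$ccc_table[agr$ccc_table$stratum == "all" &
                                        agr$ccc_table$pooled, "ccc"],
           success = ok),
      file.path(out_dir, "summary.json"), auto_unbox = TRUE, digits = NA)
  }
  list(inclusion = incl, pe_report = pe, agreement = agr, success = ok)
}
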