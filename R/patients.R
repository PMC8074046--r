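#' Cockcroft-Gault creatinine clearance
#'
#' Estimates creatinine clearance (CLCR, mL/min) from sex, age, total body
#' weight and serum creatinine using the Cockcroft-Gault equation:
#' \deqn{CLCR = \frac{(140 - age) \times weight}{72 \times SCr} \times
#'   (0.85\ \mathrm{if\ female})}
#' Serum creatinine is expected in mg/dL; set `scr_unit = "umol_l"` for
#' micromol/L input (divided by 88.4 internally).
#'
#' @param sex `"male"` or `"female"` (abbreviations `"m"`/`"f"` accepted).
#' @param age Age in years, in (0, 140).
#' @param weight Total body weight in kg, > 0.
#' @param serum_creatinine Serum creatinine concentration, > 0.
#' @param scr_unit Unit of `serum_creatinine`: `"mg_dl"` (default) or
#'   `"umol_l"`.
#' @return Creatinine clearance in mL/min. Vectorised over all inputs.
#' @examples
#' cockcroft_gault("male", 40, 72, 1.0)    # 100 mL/min
#' cockcroft_gault("female", 40, 72, 1.0)  # 85 mL/min
#' @export
cockcroft_gault <- function(sex, age, weight, serum_creatinine,
                            scr_unit = c("mg_dl", "umol_l")) {
  scr_unit <- match.arg(scr_unit)
  sex <- normalize_sex(sex)
  assert_that(is.numeric(age) && all(is.finite(age)) && all(age > 0),
              "age", "must be positive (years)")
  assert_that(all(age < 140), "age",
              "must be below 140 years (the (140 - age) term vanishes)")
  assert_positive(weight, "weight")
  assert_positive(serum_creatinine, "serum_creatinine")
  scr <- if (scr_unit == "umol_l") serum_creatinine / 88.4 else serum_creatinine
  clcr <- (140 - age) * weight / (72 * scr)
  ifelse(sex == "female", 0.85 * clcr, clcr)
}

normalize_sex <- function(sex) {
  s <- tolower(as.character(sex))
  s[s %in% c("m", "male")] <- "male"
  s[s %in% c("f", "female")] <- "female"
  assert_that(all(s %in% c("male", "female")), "sex",
              "must be 'male' or 'female'")
  s
}

#' Construct a patient record
#'
#' A patient is the unit of risk assessment.  Either `clcr` is supplied
#' directly or all four Cockcroft-Gault determinants (sex, age, weight,
#' serum creatinine) must be present so it can be computed.  If both paths
#' are given and disagree by more than 1%, the supplied `clcr` wins and a
#' warning is emitted.
#'
#' @param id Patient identifier.
#' @param sex,age,weight,serum_creatinine Cockcroft-Gault determinants
#'   (see [cockcroft_gault()]); may be `NA` if `clcr` is supplied.
#' @param serum_albumin Serum albumin in g/dL (optional; required by the
#'   population-PK engine's peripheral-volume covariate).
#' @param rrt Logical: renal replacement therapy.
#' @param clcr Optional creatinine clearance override in mL/min.
#' @param scr_unit Unit of `serum_creatinine`, see [cockcroft_gault()].
#' @return An object of class `meropta_patient` (a named list).
#' @export
patient <- function(id, sex = NA, age = NA, weight = NA,
                    serum_creatinine = NA, serum_albumin = NA,
                    rrt = FALSE, clcr = NULL, scr_unit = "mg_dl") {
  determinants_ok <- !is.na(sex) && !is.na(age) && !is.na(weight) &&
    !is.na(serum_creatinine)
  if (is.null(clcr) || is.na(clcr)) {
    if (!determinants_ok) {
      stop("patient '", id, "': supply either `clcr` or all of sex, age, ",
           "weight and serum_creatinine", call. = FALSE)
    }
    clcr <- cockcroft_gault(sex, age, weight, serum_creatinine,
                            scr_unit = scr_unit)
  } else {
    assert_positive(clcr, "clcr")
    if (determinants_ok) {
      cg <- cockcroft_gault(sex, age, weight, serum_creatinine,
                            scr_unit = scr_unit)
      if (abs(cg - clcr) / clcr > 0.01) {
        warning(sprintf(
          "patient '%s': supplied clcr (%.1f) disagrees with Cockcroft-Gault (%.1f) by >1%%; using supplied value",
          id, clcr, cg))
      }
    }
  }
  if (!is.na(serum_albumin)) assert_positive(serum_albumin, "serum_albumin")
  structure(
    list(id = id,
         sex = if (is.na(sex)) NA_character_ else normalize_sex(sex),
         age = age, weight = weight,
         serum_creatinine = serum_creatinine,
         serum_albumin = serum_albumin,
         rrt = isTRUE(rrt), clcr = clcr),
    class = "meropta_patient")
}

#' @export
print.meropta_patient <- function(x, ...) {
  cat(sprintf("<patient %s>  clcr %.1f mL/min%s\n", x$id, x$clcr,
              if (x$rrt) " [RRT]" else ""))
  invisible(x)
}

#' Inclusion criteria for a risk-assessment cohort
#'
#' The applicability screen: patients on renal replacement therapy and
#' patients with creatinine clearance outside the calculator's range of
#' applicability (25-255 mL/min by default) are excluded.  An optional
#' per-characteristic `(low, high)` screen mirrors restriction of a cohort
#' to the central range of a reference dataset.
#'
#' @param clcr_min,clcr_max Applicability bounds in mL/min.
#' @param exclude_rrt Exclude patients on renal replacement therapy.
#' @param characteristic_ranges Optional named list of `c(low, high)`
#'   bounds, names among `age`, `weight`, `serum_albumin`,
#'   `serum_creatinine`, `clcr`.
#' @return Object of class `meropta_inclusion`.
#' @export
inclusion_criteria <- function(clcr_min = 25, clcr_max = 255,
                               exclude_rrt = TRUE,
                               characteristic_ranges = NULL) {
  assert_positive(clcr_min, "clcr_min")
  assert_that(clcr_min < clcr_max, "clcr_max", "must exceed clcr_min")
  if (!is.null(characteristic_ranges)) {
    ok <- vapply(characteristic_ranges,
                 function(r) length(r) == 2 && r[1] <= r[2], logical(1))
    assert_that(all(ok), "characteristic_ranges",
                "each entry must be c(low, high) with low <= high")
  }
  structure(list(clcr_min = clcr_min, clcr_max = clcr_max,
                 exclude_rrt = isTRUE(exclude_rrt),
                 characteristic_ranges = characteristic_ranges),
            class = "meropta_inclusion")
}

#' Apply inclusion criteria to a cohort
#'
#' Splits a list of patients into included and excluded sets, retaining the
#' input order and attaching one or more machine-readable exclusion reasons
#' per excluded patient (`"rrt"`, `"clcr_below_min"`, `"clcr_above_max"`,
#' `"out_of_range_<characteristic>"`).  Filtering the included set again is
#' a no-op.
#'
#' @param patients List of [patient()] objects.
#' @param criteria An [inclusion_criteria()] object.
#' @return List with elements `included` (list of patients) and
#'   `exclusion_log` (data frame with columns `id`, `reason`).
#' @export
apply_inclusion_criteria <- function(patients,
                                     criteria = inclusion_criteria()) {
  stopifnot(inherits(criteria, "meropta_inclusion"))
  reasons <- lapply(patients, function(p) {
    stopifnot(inherits(p, "meropta_patient"))
    if (is.null(p$clcr) || is.na(p$clcr)) {
      stop("patient '", p$id, "' has no resolvable clcr", call. = FALSE)
    }
    r <- character(0)
    if (criteria$exclude_rrt && p$rrt) r <- c(r, "rrt")
    if (p$clcr < criteria$clcr_min) r <- c(r, "clcr_below_min")
    if (p$clcr > criteria$clcr_max) r <- c(r, "clcr_above_max")
    for (ch in names(criteria$characteristic_ranges)) {
      v <- p[[ch]]
      rng <- criteria$characteristic_ranges[[ch]]
      if (!is.null(v) && !is.na(v) && (v < rng[1] || v > rng[2])) {
        r <- c(r, paste0("out_of_range_", ch))
      }
    }
    r
  })
  keep <- lengths(reasons) == 0
  log <- data.frame(
    id = rep(vapply(patients, function(p) as.character(p$id), character(1)),
             lengths(reasons)),
    reason = unlist(reasons, use.names = FALSE) %||% character(0),
    stringsAsFactors = FALSE)
  list(included = patients[keep], exclusion_log = log)
}

#' Read a patient table from CSV
#'
#' Expected columns: `id, sex, age_years, weight_kg, scr_mg_dl` and
#' optionally `albumin_g_dl, rrt, clcr_ml_min`.  Unknown columns trigger a
#' warning only; missing mandatory columns are an error (a column may be
#' omitted entirely when `clcr_ml_min` is given for every row).
#'
#' @param path CSV file path.
#' @return List of [patient()] objects.
#' @export
read_patients_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  known <- c("id", "sex", "age_years", "weight_kg", "scr_mg_dl",
             "albumin_g_dl", "rrt", "clcr_ml_min")
  extra <- setdiff(names(df), known)
  if (length(extra)) {
    warning("ignoring unknown columns: ", paste(extra, collapse = ", "))
  }
  if (!"id" %in% names(df)) stop("patient CSV must contain an `id` column")
  has_clcr <- "clcr_ml_min" %in% names(df)
  need <- c("sex", "age_years", "weight_kg", "scr_mg_dl")
  if (!has_clcr && !all(need %in% names(df))) {
    stop("patient CSV needs either `clcr_ml_min` or all of: ",
         paste(need, collapse = ", "))
  }
  get <- function(col, default = NA) {
    if (col %in% names(df)) df[[col]] else rep(default, nrow(df))
  }
  lapply(seq_len(nrow(df)), function(i) {
    patient(id = df$id[i],
            sex = get("sex")[i],
            age = get("age_years")[i],
            weight = get("weight_kg")[i],
            serum_creatinine = get("scr_mg_dl")[i],
            serum_albumin = get("albumin_g_dl")[i],
            rrt = isTRUE(as.logical(get("rrt", FALSE)[i])),
            clcr = if (has_clcr && !is.na(df$clcr_ml_min[i]))
              df$clcr_ml_min[i] else NULL)
  })
}

#' Write a patient table to CSV
#'
#' Inverse of [read_patients_csv()].
#'
#' @param patients List of [patient()] objects.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_patients_csv <- function(patients, path) {
  df <- patients_to_df(patients)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

patients_to_df <- function(patients) {
  data.frame(
    id = vapply(patients, function(p) as.character(p$id), character(1)),
    sex = vapply(patients, function(p) as.character(p$sex), character(1)),
    age_years = vapply(patients, function(p) as.numeric(p$age), numeric(1)),
    weight_kg = vapply(patients, function(p) as.numeric(p$weight), numeric(1)),
    scr_mg_dl = vapply(patients, function(p)
      as.numeric(p$serum_creatinine), numeric(1)),
    albumin_g_dl = vapply(patients, function(p)
      as.numeric(p$serum_albumin), numeric(1)),
    rrt = vapply(patients, function(p) p$rrt, logical(1)),
    clcr_ml_min = vapply(patients, function(p) as.numeric(p$clcr), numeric(1)),
    stringsAsFactors = FALSE)
}
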