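test_that("Lin's CCC matches hand-derived values", {
  expect_equal(lins_ccc(c(1, 2, 3), c(2, 4, 6)), 8 / 22)
  x <- c(0.2, 0.5, 0.9, 1.4)
  expect_equal(lins_ccc(x, x), 1)
  # reversal about the mean gives negative concordance
  expect_lt(lins_ccc(x, -x + 2 * mean(x)), 0)
  # degenerate cases
  expect_equal(lins_ccc(c(2, 2), c(2, 2)), 1)
  expect_equal(lins_ccc(c(2, 2), c(3, 3)), 0)
  expect_error(lins_ccc(1, 1), "at least 2")
  expect_error(lins_ccc(c(1, NA), c(1, 2)), "finite")
})

test_that("CCC is symmetric and penalizes scale/location shifts", {
  set.seed(21)
  x <- rnorm(40)
  y <- x + rnorm(40, sd = 0.3)
  expect_equal(lins_ccc(x, y), lins_ccc(y, x))
  o <- sample(40)
  expect_equal(lins_ccc(x[o], y[o]), lins_ccc(x, y))
  # scaling or shifting a perfectly correlated copy drops CCC below 1
  expect_lt(lins_ccc(x, 2 * x), 1)
  expect_lt(lins_ccc(x, x + 1), 1)
  # |CCC| <= |Pearson r| on random pairs
  for (i in 1:200) {
    a <- rnorm(10); b <- rnorm(10) + 0.5 * a
    expect_lte(abs(lins_ccc(a, b)), abs(cor(a, b)) + 1e-12)
  }
})

test_that("CCC confidence limits are ordered and consistent", {
  set.seed(5)
  x <- rnorm(50); y <- x + rnorm(50, sd = 0.4)
  ci <- ccc_with_ci(x, y)
  expect_lt(ci$lower, ci$ccc)
  expect_gt(ci$upper, ci$ccc)
  expect_lt(ci$lower_one_sided, ci$ccc)
  expect_gt(ci$lower_one_sided, ci$lower)  # one-sided limit is tighter
  # limits shrink to the point estimate as n grows
  ci_small <- ccc_confidence(0.9, n = 20)
  ci_big <- ccc_confidence(0.9, n = 20000)
  expect_lt(diff(ci_big), diff(ci_small))
  expect_equal(unname(ci_big[1]), 0.9, tolerance = 0.01)
  expect_warning(deg <- ccc_confidence(1, n = 50), "degenerate")
  expect_equal(unname(deg), c(1, 1))
})

test_that("CCC interval has near-nominal coverage on bivariate normal pairs", {
  # Monte-Carlo oracle: simulate pairs with known population CCC and count
  # two-sided coverage
  set.seed(61)
  rho <- 0.8
  n <- 50
  # equal means/variances: population CCC = Pearson rho
  reps <- 1000
  covered <- logical(reps)
  for (i in seq_len(reps)) {
    z1 <- rnorm(n)
    z2 <- rho * z1 + sqrt(1 - rho^2) * rnorm(n)
    ci <- ccc_with_ci(z1, z2)
    covered[i] <- ci$lower <= rho && rho <= ci$upper
  }
  expect_equal(mean(covered), 0.95, tolerance = 0.025)
})

test_that("McBride grades honor the printed boundaries", {
  expect_equal(as.character(mcbride_grade(c(0.50, 0.899999))),
               c("poor", "poor"))
  expect_equal(as.character(mcbride_grade(0.90)), "moderate")
  expect_equal(as.character(mcbride_grade(0.95)), "substantial")
  expect_equal(as.character(mcbride_grade(0.983)), "substantial")
  expect_equal(as.character(mcbride_grade(0.99)), "substantial")
  expect_equal(as.character(mcbride_grade(0.999)), "almost_perfect")
})

test_that("prediction errors recover hand-computed bias and quartiles", {
  # bypass simulation: deterministic PK model means predicted is exact
  m0 <- deterministic_pk()
  p <- toy_patient()
  reg <- dosing_regimen(n_doses = 2L)
  det <- concentration(individual_parameters(m0, p), reg, c(6, 14))
  tdm <- meropta:::as_tdm(data.frame(
    patient_id = "P1", dose_mg = 1000, tinf_h = 0.5,
    dose_time_h = c(0, 8), sample_time_h = c(6, 14),
    conc_mg_l = det, stringsAsFactors = FALSE))
  rep0 <- prediction_errors(tdm, list(p), m0, n_replicates = 10, seed = 1)
  expect_equal(rep0$bias_abs, 0, tolerance = 1e-10)
  expect_equal(unname(rep0$pe_interval_50), c(0, 0), tolerance = 1e-10)
  # hand computation: observed (10, 8) vs predicted (12, 7) under the
  # observed-minus-predicted convention gives PEs (-2, +1), median -0.5
  pe <- c(10, 8) - c(12, 7)
  expect_equal(median(pe), -0.5)
  # sign convention: overprediction (pred > obs) gives positive PE under
  # the default predicted-minus-observed convention, so underprediction
  # yields negative bias
  tdm3 <- tdm
  tdm3$conc_mg_l <- det + 2  # observed above prediction = underprediction
  rep3 <- prediction_errors(tdm3, list(p), m0, n_replicates = 10, seed = 1)
  expect_lt(rep3$bias_abs, 0)
  rep4 <- prediction_errors(tdm3, list(p), m0, n_replicates = 10, seed = 1,
                            sign_convention = "observed_minus_predicted")
  expect_gt(rep4$bias_abs, 0)
  expect_equal(rep4$bias_abs, -rep3$bias_abs)
})

test_that("prediction errors are invariant to observation order", {
  set.seed(8)
  pats <- suppressWarnings(
    generate_patients(cohort_spec(n_patients = 4), seed = 8))
  tdm <- generate_tdm(pats, pk_model = default_poppk_model(), seed = 9)
  r1 <- prediction_errors(tdm, pats, default_poppk_model(),
                          n_replicates = 200, seed = 10)
  shuffled <- tdm[rev(seq_len(nrow(tdm))), ]
  r2 <- prediction_errors(shuffled, pats, default_poppk_model(),
                          n_replicates = 200, seed = 10)
  expect_equal(r1$bias_abs, r2$bias_abs)
  expect_equal(r1$pe_interval_50, r2$pe_interval_50)
})

test_that("TDM reader validates schema and derives time after last dose", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("patient_id,dose_mg,tinf_h,dose_time_h,sample_time_h,conc_mg_l",
               "A,1000,0.5,0,6.2,9.0",
               "A,1000,0.5,8,14.5,7.5"), f)
  tdm <- read_tdm_csv(f)
  expect_equal(tdm$time_after_last_dose_h, c(6.2, 6.5))
  f2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("patient_id,conc_mg_l", "A,9.0"), f2)
  expect_error(read_tdm_csv(f2), "must contain columns")
})

test_that("self-agreement gives CCC 1 and offsets degrade it monotonically", {
  pats <- lapply(1:12, function(i) toy_patient(id = i, clcr = 40 + 15 * i))
  m <- toy_regression()
  risks <- unlist(lapply(pats, function(p)
    risk_regression(m, p$clcr, default_mic_grid())))
  expect_equal(lins_ccc(risks, risks), 1)
  cc <- vapply(c(0.02, 0.05, 0.10), function(off) {
    lins_ccc(risks, pmin(risks + off, 1))
  }, numeric(1))
  expect_true(all(cc < 1))
  expect_true(all(diff(cc) < 0))
})

test_that("compare_risk_methods produces a coherent agreement report", {
  set.seed(14)
  pats <- suppressWarnings(
    generate_patients(cohort_spec(n_patients = 30), seed = 14,
                      screen = TRUE))
  rep <- compare_risk_methods(pats, default_regression_model(),
                              default_poppk_model(),
                              n_replicates = 300, seed = 15)
  expect_equal(nrow(rep$paired), 30 * 8)
  expect_true(all(rep$paired$risk_regression >= 0 &
                    rep$paired$risk_regression <= 1))
  expect_true(all(rep$paired$risk_pk >= 0 & rep$paired$risk_pk <= 1))
  tab <- rep$ccc_table
  expect_true(all(c("all", "clcr_gt_50") %in% tab$stratum))
  expect_true(all(tab$ccc >= -1 & tab$ccc <= 1))
  expect_true(all(tab$lower <= tab$ccc & tab$ccc <= tab$upper))
  # pooled row concatenates all patient-by-MIC pairs
  pooled <- tab[tab$stratum == "all" & tab$pooled, ]
  expect_equal(pooled$n, 30 * 8)
  expect_identical(success_criterion(rep),
                   pooled$lower_one_sided > 0.95)
})

test_that("success rule is strict at the 0.95 boundary", {
  fake <- structure(list(ccc_table = data.frame(
    stratum = "all", mic = "0.125-16", pooled = TRUE, ccc = 0.97,
    lower = 0.94, upper = 0.99, lower_one_sided = 0.95, n = 100,
    grade = "moderate", stringsAsFactors = FALSE)),
    class = "meropta_agreement")
  expect_false(success_criterion(fake))
  fake$ccc_table$lower_one_sided <- 0.98
  expect_true(success_criterion(fake))
  fake$ccc_table$pooled <- FALSE
  expect_error(success_criterion(fake), "pooled")
})
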