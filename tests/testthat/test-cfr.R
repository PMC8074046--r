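test_that("the default reporting grid is the 8 doubling dilutions", {
  expect_equal(default_mic_grid(), c(0.125, 0.25, 0.5, 1, 2, 4, 8, 16))
})

test_that("pta_curve evaluates the bound risk function pointwise", {
  m <- toy_regression()
  rf <- function(mic) risk_regression(m, 90, mic)
  curve <- pta_curve(rf)
  expect_equal(nrow(curve), 8)
  expect_equal(curve$risk, rf(default_mic_grid()))
  expect_equal(curve$pta, 1 - curve$risk)
  expect_true(all(diff(curve$risk) >= 0))
  const <- pta_curve(function(m) rep(0.3, length(m)))
  expect_equal(const$risk, rep(0.3, 8))
  expect_error(pta_curve(rf, numeric(0)), "mic_grid")
})

test_that("MIC distribution validates its grid and provenance", {
  expect_error(mic_distribution("x", c(1, 2, 1.5), c(1, 1, 1), "src"),
               "strictly increasing")
  expect_error(mic_distribution("x", c(1, 3), c(1, 1), "src"),
               "doubling")
  expect_error(mic_distribution("x", c(1, 2), c(0, 0), "src"), "count")
  expect_error(mic_distribution("x", c(1, 2), c(1, 1), ""), "source_label")
  # gaps on the doubling grid are allowed
  d <- mic_distribution("x", c(0.25, 1, 8), c(1, 2, 1), "src")
  expect_equal(sum(d$frequency), 1)
})

test_that("cfr_risk reproduces hand-computed weighted averages", {
  # all mass in one bin: equals the single-MIC risk
  m <- toy_regression()
  rf <- function(mic) risk_regression(m, 90, mic)
  single <- mic_distribution("one-bin", 2, 100, "src")
  expect_equal(as.numeric(cfr_risk(rf, single)), rf(2))
  # hand example: risks 0.10 and 0.40 at equal weight -> 0.25
  d <- mic_distribution("two-bin", c(1, 2), c(50, 50), "src")
  lookup <- c(`1` = 0.10, `2` = 0.40)
  expect_equal(as.numeric(cfr_risk(lookup, d)), 0.25)
  # perfect attainment (PTA = 1 means risk 0 everywhere)
  expect_equal(as.numeric(cfr_risk(function(m) rep(0, length(m)), d)), 0)
  # provenance label travels with the result
  expect_equal(attr(cfr_risk(rf, d), "source_label"), "src")
})

test_that("cfr_risk errors on unmapped bins and warns on censored tops", {
  d <- mic_distribution("x", c(1, 2, 4), c(1, 1, 1), "src")
  expect_error(cfr_risk(c(`1` = 0.1, `2` = 0.2), d), "no risk value")
  dc <- mic_distribution("x", c(1, 2), c(1, 1), "src", top_censored = TRUE)
  expect_warning(cfr_risk(function(m) rep(0.2, length(m)), dc),
                 "conservative")
})

test_that("cfr_risk is a convex combination and respects dominance", {
  m <- toy_regression()
  rf <- function(mic) risk_regression(m, 90, mic)
  set.seed(17)
  for (i in 1:100) {
    mics <- 2^sort(sample(-3:5, 4))
    counts <- rmultinom(1, 200, runif(4) + 0.05)[, 1]
    if (sum(counts) == 0) counts[1] <- 1
    d <- mic_distribution("a", mics, counts, "src")
    r <- as.numeric(cfr_risk(rf, d))
    risks <- rf(mics)
    expect_gte(r + 1e-12, min(risks))
    expect_lte(r - 1e-12, max(risks))
    # shifting mass one bin upward can never decrease the risk
    if (length(mics) >= 2 && counts[1] > 0) {
      shifted <- counts
      shifted[1] <- shifted[1] - 1
      shifted[2] <- shifted[2] + 1
      d2 <- mic_distribution("b", mics, shifted, "src")
      expect_gte(as.numeric(cfr_risk(rf, d2)) + 1e-12, r)
    }
  }
})

test_that("a distribution below the grid floor is no riskier than the floor breakpoint", {
  m <- toy_regression()
  rf <- function(mic) risk_regression(m, 90, mic)
  low <- mic_distribution("low", c(0.015625, 0.03125, 0.0625),
                          c(5, 10, 5), "src")
  expect_lte(as.numeric(cfr_risk(rf, low)), breakpoint_risk(rf, 0.125))
})

test_that("breakpoint mode is the single-MIC risk at the chosen breakpoint", {
  m <- toy_regression()
  rf <- function(mic) risk_regression(m, 90, mic)
  expect_equal(breakpoint_risk(rf, 2), rf(2))
  expect_lte(breakpoint_risk(rf, 2), breakpoint_risk(rf, 8))
  expect_error(breakpoint_risk(rf, -2), "breakpoint_mic")
  m0 <- toy_regression(residual_sd = 0)
  rf0 <- function(mic) risk_regression(m0, 90, mic)
  pred <- predict_c8h(m0, 90)
  expect_equal(breakpoint_risk(rf0, pred / 2), 0)
  expect_equal(breakpoint_risk(rf0, pred * 2), 1)
})

test_that("colour classification uses the printed boundaries", {
  expect_equal(as.character(classify_risk(c(0, 0.10, 0.100001, 0.50,
                                            0.5000001, 1))),
               c("green", "green", "orange", "orange", "red", "red"))
  expect_error(classify_risk(1.2), "risk")
})

test_that("assess resolves modes with MIC > pathogen > breakpoint precedence", {
  dists <- list(`Pseudomonas aeruginosa` =
                  mic_distribution("Pseudomonas aeruginosa",
                                   c(0.25, 0.5, 1, 2, 4), c(5, 20, 30, 20, 5),
                                   "synthetic test distribution"))
  p <- toy_patient(clcr = 100)
  res_path <- assess(p, pathogen = "Pseudomonas aeruginosa",
                     distributions = dists)
  expect_equal(res_path$mode, "pathogen_cfr")
  expect_equal(res_path$inputs_echo$source, "synthetic test distribution")
  res_mic <- assess(p, mic = 2, pathogen = "Pseudomonas aeruginosa",
                    distributions = dists)
  expect_equal(res_mic$mode, "mic")
  res_bp <- assess(p, breakpoint = 8)
  expect_equal(res_bp$mode, "breakpoint")
  expect_error(assess(p), "no resolvable input mode")
  expect_error(assess(toy_patient(clcr = 300), mic = 2),
               "range of applicability")
  # category consistent with the risk thresholds
  expect_equal(res_mic$category,
               as.character(classify_risk(res_mic$risk)))
})

test_that("assess raises the low-clearance high-MIC disclaimer", {
  p_low <- toy_patient(clcr = 40)
  res <- assess(p_low, mic = 8)
  expect_true("clcr_below_50_with_high_mic" %in% res$disclaimer_flags)
  res_ok <- assess(p_low, mic = 2)
  expect_false("clcr_below_50_with_high_mic" %in% res_ok$disclaimer_flags)
  res_high <- assess(toy_patient(clcr = 90), mic = 8)
  expect_false("clcr_below_50_with_high_mic" %in% res_high$disclaimer_flags)
})

test_that("cohort summary recovers engineered band medians", {
  # three synthetic pathogens whose cohort median risks land near
  # 0.05 / 0.30 / 0.70: constant risk functions make medians exact
  pats <- lapply(1:5, function(i) toy_patient(id = i, clcr = 80 + 5 * i))
  dists <- list(
    low = mic_distribution("low", 1, 10, "src"),
    mid = mic_distribution("mid", 2, 10, "src"),
    high = mic_distribution("high", 4, 10, "src"))
  factory <- function(p) {
    function(mic) ifelse(mic <= 1, 0.05, ifelse(mic <= 2, 0.30, 0.70))
  }
  summ <- cohort_pathogen_summary(pats, dists, factory)
  expect_equal(summ$per_pathogen$median_risk, c(0.05, 0.30, 0.70))
  expect_equal(unname(summ$band_fractions),
               c(1 / 3, 1 / 3, 1 / 3))
  expect_equal(sum(summ$band_fractions), 1)
  # single patient, single pathogen: median is that patient's CFR risk
  one <- cohort_pathogen_summary(pats[1], dists["mid"], factory)
  expect_equal(one$per_pathogen$median_risk, 0.30)
})

test_that("cohort banding differs from per-patient colours at the 10% edge", {
  pats <- list(toy_patient())
  dists <- list(edge = mic_distribution("edge", 1, 10, "src"))
  factory <- function(p) function(mic) rep(0.10, length(mic))
  summ <- cohort_pathogen_summary(pats, dists, factory)
  # 10% exactly: cohort band counts it in 10-50, colour rule says green
  expect_equal(summ$per_pathogen$band, "10_to_50")
  expect_equal(summ$per_pathogen$category, "green")
})

test_that("MIC distribution CSV reader round-trips the shipped fixture", {
  f <- system.file("extdata", "mic_distributions_synthetic.csv",
                   package = "meropta")
  dists <- read_mic_distributions_csv(f, "synthetic fixture v1")
  expect_true("Pseudomonas aeruginosa" %in% names(dists))
  expect_true(all(vapply(dists, function(d)
    abs(sum(d$frequency) - 1) < 1e-12, logical(1))))
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_mic_distributions_csv(dists, f2)
  back <- read_mic_distributions_csv(f2, "synthetic fixture v1")
  expect_equal(back[["Escherichia coli"]]$count,
               dists[["Escherichia coli"]]$count)
})
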