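# Shared fixtures built in code.

# a regression model with transparent hand-checkable coefficients
toy_regression <- function(intercept = log(10), slope = -1,
                           residual_sd = 0.3, n_train = 100,
                           mean_ln_x = log(90), sxx = 40,
                           clcr_range = c(25, 255)) {
  suppressWarnings(regression_model(intercept, slope, residual_sd, n_train,
                                    mean_ln_x, sxx, clcr_range))
}

# a PK model without any random components
deterministic_pk <- function(...) {
  poppk_model(omega = c(cl = 0, v1 = 0, q = 0, v2 = 0),
              residual_prop_sd = 0, residual_add_sd = 0, ...)
}

toy_patient <- function(id = "P1", clcr = 100, weight = 73, albumin = 2.5) {
  patient(id = id, clcr = clcr, weight = weight, serum_albumin = albumin,
          sex = NA, age = NA, serum_creatinine = NA)
}

# numerical ODE oracle for the two-compartment infusion model (deSolve)
ode_conc_oracle <- function(cl, v1, q, v2, regimen, times) {
  rhs <- function(t, y, p) {
    doses_running <- sum(
      t >= (seq_len(regimen$n_doses) - 1) * regimen$interval &
        t < (seq_len(regimen$n_doses) - 1) * regimen$interval +
          regimen$infusion_duration)
    rate <- doses_running * regimen$dose / regimen$infusion_duration
    k10 <- cl / v1; k12 <- q / v1; k21 <- q / v2
    dA1 <- rate - (k10 + k12) * y[1] + k21 * y[2]
    dA2 <- k12 * y[1] - k21 * y[2]
    list(c(dA1, dA2))
  }
  # break integration at every infusion start/stop so the step integrator
  # never smooths over the rate discontinuities
  breaks <- sort(unique(c(
    times, (seq_len(regimen$n_doses) - 1) * regimen$interval,
    (seq_len(regimen$n_doses) - 1) * regimen$interval +
      regimen$infusion_duration)))
  sol <- deSolve::lsoda(c(0, 0), sort(unique(c(0, breaks))), rhs, NULL,
                        rtol = 1e-10, atol = 1e-12)
  approx(sol[, 1], sol[, 2] / v1, xout = times)$y
}
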