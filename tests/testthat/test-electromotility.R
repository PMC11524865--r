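test_that("Boltzmann length change hits its landmarks", {
  p <- boltzmann_params(Lmax = 1, alpha = 0.03, Vhalf = -50)
  expect_equal(boltzmann_length(-50, p), 0.5)
  expect_equal(boltzmann_length(-1e4, p), 0, tolerance = 1e-12)
  expect_equal(boltzmann_length(1e4, p), 1, tolerance = 1e-12)
  expect_equal(boltzmann_length(-50 + log(3) / 0.03, p), 0.75)
  V <- seq(-150, 100, 5)
  expect_true(all(diff(boltzmann_length(V, p)) > 0))
})

test_that("parameter container enforces the slope-factor convention", {
  p1 <- boltzmann_params(Qmax = 1135, slope_factor = 27, Vhalf = -54,
                         Clin = 7.9)
  p2 <- boltzmann_params(Qmax = 1135, alpha = 1 / 27, Vhalf = -54,
                         Clin = 7.9)
  expect_equal(p1$alpha, p2$alpha)
  expect_error(boltzmann_params(Qmax = 1, Vhalf = 0), "exactly one")
  expect_error(boltzmann_params(Qmax = 1, alpha = 0.03,
                                slope_factor = 30, Vhalf = 0), "exactly one")
  expect_error(boltzmann_params(Qmax = -1, alpha = 0.03, Vhalf = 0), "Qmax")
})

test_that("NLC bell peaks at Vhalf, decays to Clin and integrates to Qmax", {
  p <- fig8_params()
  expect_equal(nlc_curve(p$Vhalf, p), p$Qmax * p$alpha / 4 + p$Clin)
  far <- nlc_curve(p$Vhalf + 200 / p$alpha, p)
  expect_lt(abs(far - p$Clin), 1e-3 * p$Qmax * p$alpha)
  # symmetric about Vhalf
  dv <- c(10, 25, 60)
  expect_equal(nlc_curve(p$Vhalf + dv, p), nlc_curve(p$Vhalf - dv, p))
  # quadrature oracle: area of the nonlinear component equals Qmax
  V <- seq(p$Vhalf - 300 / p$alpha, p$Vhalf + 300 / p$alpha, length.out = 2e4)
  area <- trapz(V, nlc_curve(V, p) - p$Clin)
  expect_equal(area, p$Qmax, tolerance = 1e-3)
})

test_that("noiseless NLC fits invert the curve to 1e-6 relative", {
  truth <- fig8_params()
  rec <- recording(seq(-120, 60, 4),
                   capacitance = nlc_curve(seq(-120, 60, 4), truth))
  fit <- fit_nlc(rec)
  expect_true(fit$converged)
  expect_equal(fit$params$Vhalf, -54, tolerance = 1e-6)
  expect_equal(fit$params$Clin, 7.9, tolerance = 1e-6)
  expect_equal(fit$params$Qmax, 1135, tolerance = 1e-6)
  expect_equal(fit$params$alpha, 1 / 27, tolerance = 1e-6)
})

test_that("fit-then-generate is the identity across physiological ranges", {
  set.seed(51)
  V <- seq(-120, 60, 4)
  for (i in 1:100) {
    truth <- boltzmann_params(Qmax = runif(1, 100, 2000),
                              slope_factor = runif(1, 20, 40),
                              Vhalf = runif(1, -100, 0),
                              Clin = runif(1, 3, 12))
    fit <- fit_nlc(recording(V, capacitance = nlc_curve(V, truth)))
    expect_true(fit$converged)
    for (f in c("Qmax", "alpha", "Vhalf", "Clin")) {
      expect_equal(fit$params[[f]], truth[[f]],
                   tolerance = 1e-6 * max(1, abs(truth[[f]])))
    }
  }
})

test_that("constant capacitance is flagged, not force-fitted", {
  rec <- recording(seq(-120, 60, 4), capacitance = rep(7, 46))
  fit <- fit_nlc(rec)
  expect_false(fit$converged)
  expect_true(fit$flat)
  expect_match(fit$message, "no voltage dependence")
})

test_that("noisy NLC fits recover truth within reported standard errors", {
  truth <- fig8_params()
  V <- seq(-120, 60, 4)
  set.seed(52)
  n_ok <- 0L; n_par <- 0L
  for (i in 1:20) {
    cm <- nlc_curve(V, truth) + rnorm(length(V), 0, 0.05)
    fit <- fit_nlc(recording(V, capacitance = cm))
    expect_true(fit$converged)
    est <- c(fit$params$Qmax, fit$params$alpha, fit$params$Vhalf,
             fit$params$Clin)
    tru <- c(truth$Qmax, truth$alpha, truth$Vhalf, truth$Clin)
    se <- fit$se[c("Qmax", "alpha", "Vhalf", "Clin")]
    ok <- abs(est - tru) <= 3 * se
    n_ok <- n_ok + sum(ok); n_par <- n_par + length(ok)
  }
  expect_gte(n_ok / n_par, 0.9)
})

test_that("motility fits recover the logistic and expose its slope", {
  truth <- boltzmann_params(Lmax = 0.8, slope_factor = 30, Vhalf = -45)
  V <- seq(-130, 50, 4)
  fit <- fit_motility(recording(V, displacement = boltzmann_length(V, truth)))
  expect_true(fit$converged)
  expect_equal(fit$params$Lmax, 0.8, tolerance = 1e-6)
  expect_equal(fit$params$Vhalf, -45, tolerance = 1e-6)
  # slope function equals the analytic derivative of the fitted curve
  h <- 1e-4
  vgrid <- c(-80, -45, -10)
  numeric_slope <- (boltzmann_length(vgrid + h, fit$params) -
                      boltzmann_length(vgrid - h, fit$params)) / (2 * h)
  expect_equal(fit$slope(vgrid), numeric_slope, tolerance = 1e-6)

  flat <- fit_motility(recording(V, displacement = rep(0.1, length(V))))
  expect_true(flat$flat)
})

test_that("dual-sine estimator matches the reduced pure-RC closed form", {
  Rm <- 200e6; Cm <- 8e-12
  tr <- circuit_traces(Rs = 0, Rm = Rm, Cm = Cm, n = 1024)
  est <- two_sine_capacitance(tr$current, tr$voltage, fs = 1e5)
  # closed-form single-frequency solution for the parallel RC:
  # Y = 1/Rm + i w Cm, so Cm = Im(Y)/w at either frequency
  w1 <- 2 * pi * 390.625
  Y1 <- (1 / Rm) + 1i * w1 * Cm
  expect_equal(est$Cm, Im(Y1) / w1, tolerance = 1e-6)
  expect_equal(est$Rs, 0, tolerance = 1e-3 * Rm)
  expect_equal(est$Rm, Rm, tolerance = 1e-6 * Rm)
})

test_that("dual-sine estimator recovers Rs, Rm, Cm over a parameter grid", {
  for (Rs in c(5e6, 10e6, 20e6)) {
    for (Rm in c(100e6, 500e6, 1e9)) {
      for (Cm in c(5e-12, 10e-12, 20e-12)) {
        tr <- circuit_traces(Rs, Rm, Cm, n = 1024)
        est <- two_sine_capacitance(tr$current, tr$voltage, fs = 1e5)
        expect_true(est$ok)
        expect_equal(est$Cm, Cm, tolerance = 1e-3 * Cm)
        expect_equal(est$Rs, Rs, tolerance = 1e-3 * Rs)
        expect_equal(est$Rm, Rm, tolerance = 1e-3 * Rm)
      }
    }
  }
})

test_that("misaligned frequencies and flat responses are refused", {
  tr <- circuit_traces(10e6, 500e6, 10e-12, n = 1000)  # 1000 not bin-aligned
  expect_error(two_sine_capacitance(tr$current, tr$voltage, fs = 1e5),
               "record length")
  # a pure resistor gives identical admittance at both frequencies
  t <- seq_len(1024) / 1e5
  v <- 0.01 * (sin(2 * pi * 390.625 * t) + sin(2 * pi * 781.25 * t))
  i <- v / 10e6
  est <- two_sine_capacitance(i, v, fs = 1e5)
  expect_false(est$ok)
  expect_match(est$message, "ill-conditioned")
})

test_that("series-resistance correction subtracts the I*Rs drop", {
  expect_equal(correct_series_resistance(-54, 0.5, 10), -59)
})

test_that("voltage-dependence detection separates bell from flat", {
  set.seed(53)
  V <- seq(-120, 60, 4)
  ohc <- recording(V, capacitance = nlc_curve(V, fig8_params()) +
                     rnorm(length(V), 0, 0.1))
  expect_true(detect_voltage_dependence(ohc)$voltage_dependent)
  flat <- recording(V, capacitance = 7 + rnorm(length(V), 0, 0.1))
  expect_false(detect_voltage_dependence(flat)$voltage_dependent)
})

test_that("false-positive rate on flat traces stays near the nominal level", {
  set.seed(54)
  V <- seq(-120, 60, 4)
  n_null <- 150
  fp <- vapply(seq_len(n_null), function(i) {
    rec <- recording(V, capacitance = 7 + rnorm(length(V), 0, 0.1))
    detect_voltage_dependence(rec)$voltage_dependent
  }, logical(1))
  rate <- mean(fp)
  mc_se <- sqrt(0.05 * 0.95 / n_null)
  expect_lte(rate, 0.05 + 2 * mc_se)
})

test_that("detection rate rises monotonically with gating charge", {
  set.seed(55)
  V <- seq(-120, 60, 4)
  rate_at <- vapply(c(5, 40, 1135), function(qmax) {
    p <- boltzmann_params(Qmax = qmax, slope_factor = 27, Vhalf = -54,
                          Clin = 7.9)
    mean(vapply(1:40, function(i) {
      rec <- recording(V, capacitance = nlc_curve(V, p) +
                         rnorm(length(V), 0, 0.1))
      detect_voltage_dependence(rec)$voltage_dependent
    }, logical(1)))
  }, numeric(1))
  expect_true(all(diff(rate_at) >= 0))
  expect_lt(rate_at[1], 0.5)
  expect_equal(rate_at[3], 1)
})
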