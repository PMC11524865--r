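#' Boltzmann parameter set for motility and NLC models
#'
#' Stores the parameters of the two-state Boltzmann models: `Lmax` (maximal
#' somatic length change, um) for motility or `Qmax` (maximal nonlinear
#' gating charge, fC) for NLC, the voltage sensitivity `alpha` (mV^-1), the
#' half-maximal voltage `Vhalf` (mV), and the linear voltage-independent
#' capacitance `Clin` (pF, NLC only). Voltage sensitivity may be supplied
#' either as `alpha` (mV^-1) or as its reciprocal `slope_factor` (mV) —
#' published values appear in both conventions — but exactly one must be
#' given; internally `alpha` in mV^-1 is stored, as the exponent
#' `alpha * (V - Vhalf)` requires.
#'
#' With `Qmax` in fC and voltages in mV, the NLC comes out in fC/mV = pF
#' with no further conversion.
#'
#' @param Qmax maximal nonlinear charge, fC (NLC model), or `NA`.
#' @param Lmax maximal length change, um (motility model), or `NA`.
#' @param alpha voltage sensitivity, mV^-1 (exclusive with `slope_factor`).
#' @param slope_factor reciprocal voltage sensitivity `1/alpha`, mV.
#' @param Vhalf half-maximal voltage, mV.
#' @param Clin linear capacitance, pF; default 0.
#' @return List of class `"boltzmann_params"` with elements `Qmax`, `Lmax`,
#'   `alpha`, `Vhalf`, `Clin`.
#' @export
#' @examples
#' boltzmann_params(Qmax = 1135, slope_factor = 27, Vhalf = -54, Clin = 7.9)
boltzmann_params <- function(Qmax = NA_real_, Lmax = NA_real_, alpha = NULL,
                             slope_factor = NULL, Vhalf, Clin = 0) {
  if (is.null(alpha) == is.null(slope_factor)) {
    stop("supply exactly one of alpha (mV^-1) or slope_factor (mV)",
         call. = FALSE)
  }
  if (is.null(alpha)) {
    if (slope_factor <= 0) stop("slope_factor must be > 0", call. = FALSE)
    alpha <- 1 / slope_factor
  }
  if (alpha <= 0) stop("alpha must be > 0", call. = FALSE)
  if (!is.na(Qmax) && Qmax < 0) stop("Qmax must be >= 0", call. = FALSE)
  if (!is.na(Lmax) && Lmax < 0) stop("Lmax must be >= 0", call. = FALSE)
  if (Clin < 0) stop("Clin must be >= 0", call. = FALSE)
  structure(list(Qmax = Qmax, Lmax = Lmax, alpha = alpha,
                 Vhalf = Vhalf, Clin = Clin),
            class = "boltzmann_params")
}

#' Voltage-clamp recording container
#'
#' Holds per-step traces of a staircase voltage-clamp protocol: command
#' voltage (mV), measured membrane capacitance (pF), and optionally somatic
#' displacement (um). Voltages must be strictly monotone within the sweep.
#'
#' @param voltage numeric vector, mV.
#' @param capacitance optional numeric vector, pF, same length.
#' @param displacement optional numeric vector, um, same length.
#' @param metadata optional list (sampling interval, stimulus frequencies,
#'   ...).
#' @return List of class `"recording"`.
#' @export
recording <- function(voltage, capacitance = NULL, displacement = NULL,
                      metadata = list()) {
  voltage <- as.numeric(voltage)
  d <- diff(voltage)
  if (length(voltage) < 2 || !(all(d > 0) || all(d < 0))) {
    stop("voltage must be strictly monotone within a sweep", call. = FALSE)
  }
  for (tr in list(capacitance, displacement)) {
    if (!is.null(tr) && length(tr) != length(voltage)) {
      stop("trace lengths must match voltage", call. = FALSE)
    }
  }
  structure(list(voltage = voltage, capacitance = capacitance,
                 displacement = displacement, metadata = metadata),
            class = "recording")
}

#' Two-state Boltzmann length change
#'
#' `L(V) = Lmax / (1 + exp(-alpha * (V - Vhalf)))`: strictly increasing in
#' `V`, 0 at very negative potentials, `Lmax` at very positive ones, and
#' `Lmax / 2` at `Vhalf`.
#'
#' @param V membrane potential, mV (vectorized).
#' @param params a [boltzmann_params()] with `Lmax` set.
#' @return Displacement, um.
#' @export
boltzmann_length <- function(V, params) {
  params$Lmax / (1 + exp(-params$alpha * (V - params$Vhalf)))
}

#' Slope of the Boltzmann length change
#'
#' Analytic derivative `dL/dV = Lmax * alpha * e / (1 + e)^2` with
#' `e = exp(-alpha * (V - Vhalf))`, i.e. the voltage sensitivity function of
#' the motile response (um/mV).
#'
#' @inheritParams boltzmann_length
#' @return Slope, um/mV.
#' @export
boltzmann_slope <- function(V, params) {
  e <- exp(-params$alpha * (V - params$Vhalf))
  params$Lmax * params$alpha * e / (1 + e)^2
}

#' Derivative-of-Boltzmann nonlinear capacitance
#'
#' `Cm(V) = Qmax * alpha * e / (1 + e)^2 + Clin` with
#' `e = exp(-alpha * (V - Vhalf))`: the first derivative of the two-state
#' Boltzmann charge-voltage relation plus the linear capacitance. The bell
#' is symmetric about `Vhalf`, peaks there at `Qmax * alpha / 4 + Clin`,
#' decays to `Clin` far from `Vhalf`, and the area under the nonlinear
#' component equals `Qmax`.
#'
#' @inheritParams boltzmann_length
#' @param params a [boltzmann_params()] with `Qmax` set (fC).
#' @return Capacitance, pF.
#' @export
nlc_curve <- function(V, params) {
  e <- exp(-params$alpha * (V - params$Vhalf))
  params$Qmax * params$alpha * e / (1 + e)^2 + params$Clin
}

# Shared initialization + nlsLM fit for both bell (NLC) and logistic
# (motility) models. Returns list(params, se, residual_sd, converged,
# flat, message).
fit_boltzmann_core <- function(V, y, model = c("nlc", "motility")) {
  model <- match.arg(model)
  n <- length(V)
  if (n < 8) stop("need at least 8 voltage points", call. = FALSE)
  if (diff(range(V)) < 60) {
    stop("voltage span must be at least 60 mV", call. = FALSE)
  }
  if (sd(y) == 0) {
    return(list(params = NULL, se = NULL, residual_sd = 0, converged = FALSE,
                flat = TRUE, message = "no voltage dependence: constant trace"))
  }
  a0 <- 2 / diff(range(V))
  if (model == "nlc") {
    c0 <- min(y)
    v0 <- V[which.max(y)]
    q0 <- 4 * (max(y) - c0) / a0
    form <- y ~ Qmax * alpha * exp(-alpha * (V - Vhalf)) /
      (1 + exp(-alpha * (V - Vhalf)))^2 + Clin
    start <- list(Qmax = q0, alpha = a0, Vhalf = v0, Clin = c0)
    npar <- 4L
  } else {
    v0 <- V[which.min(abs(y - (min(y) + max(y)) / 2))]
    l0 <- max(y) - min(y)
    form <- y ~ Lmax / (1 + exp(-alpha * (V - Vhalf)))
    start <- list(Lmax = l0, alpha = a0, Vhalf = v0)
    npar <- 3L
  }
  fit <- tryCatch(
    minpack.lm::nlsLM(form, data = data.frame(V = V, y = y), start = start,
                      control = minpack.lm::nls.lm.control(
                        ftol = 1e-15, ptol = 1e-15, maxiter = 1024)),
    error = function(e) e
  )
  if (inherits(fit, "error")) {
    return(list(params = NULL, se = NULL, residual_sd = sd(y),
                converged = FALSE, flat = FALSE,
                message = paste("fit failed:", conditionMessage(fit))))
  }
  est <- coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) rep(NA_real_, npar))
  rsd <- sqrt(sum(residuals(fit)^2) / max(1, n - npar))
  if (model == "nlc") {
    params <- boltzmann_params(Qmax = abs(est[["Qmax"]]),
                               alpha = abs(est[["alpha"]]),
                               Vhalf = est[["Vhalf"]],
                               Clin = max(0, est[["Clin"]]))
  } else {
    params <- boltzmann_params(Lmax = abs(est[["Lmax"]]),
                               alpha = abs(est[["alpha"]]),
                               Vhalf = est[["Vhalf"]])
  }
  list(params = params, se = se, residual_sd = rsd, converged = TRUE,
       flat = FALSE, message = "converged")
}

#' Fit the NLC model to a capacitance-voltage recording
#'
#' Least-squares fit of [nlc_curve()] to the capacitance trace.
#' Initialization: `Clin` from the minimum capacitance, `Vhalf` from the
#' voltage at the peak, `alpha0 = 2 / span`, and
#' `Qmax0 = 4 * (peak - Clin0) / alpha0`; Levenberg-Marquardt iterations run
#' to a relative residual tolerance of 1e-15. A constant trace is returned
#' flagged (`flat = TRUE`) rather than force-fitted, and non-convergence is
#' reported in the result, never silently defaulted.
#'
#' @param rec a [recording()] with `capacitance` set, or a list/data frame
#'   with `voltage` and `capacitance`.
#' @return List with `params` ([boltzmann_params()]), `se` (parameter
#'   standard errors), `residual_sd`, `converged`, `flat`, `message`.
#' @export
fit_nlc <- function(rec) {
  if (is.null(rec$capacitance)) stop("capacitance trace required",
                                     call. = FALSE)
  fit_boltzmann_core(rec$voltage, rec$capacitance, "nlc")
}

#' Fit the two-state Boltzmann motility model
#'
#' Least-squares fit of [boltzmann_length()] to the displacement trace; the
#' returned `slope` element is the analytic derivative of the fitted curve
#' (a function of voltage, um/mV). A flat displacement trace is flagged
#' non-motile.
#'
#' @param rec a [recording()] with `displacement` set.
#' @return As [fit_nlc()], plus `slope`, a function `V -> dL/dV` (`NULL`
#'   when the fit is flagged).
#' @export
fit_motility <- function(rec) {
  if (is.null(rec$displacement)) stop("displacement trace required",
                                      call. = FALSE)
  out <- fit_boltzmann_core(rec$voltage, rec$displacement, "motility")
  out$slope <- if (!is.null(out$params)) {
    p <- out$params
    function(V) boltzmann_slope(V, p)
  }
  out
}

#' Membrane capacitance from a dual-sine admittance measurement
#'
#' Implements the two-sine estimation technique: the command voltage is the
#' sum of two sinusoids (canonically 390.625 and 781.25 Hz, printed as
#' 390.6/781.2 in rounded form, both 10 mV) riding on a holding step; the
#' complex admittance `Y = I(f)/V(f)` is extracted at exactly the two
#' stimulus bins of the discrete Fourier transform, and the three elements
#' of the patch circuit — series resistance `Rs`, membrane resistance `Rm`,
#' membrane capacitance `Cm` in series-Rs / parallel-(Rm, Cm) topology —
#' are solved in closed form from the two complex impedances
#' `Z(w) = Rs + Rm / (1 + i w Rm Cm)`.
#'
#' The record must contain an integer number of periods of both frequencies
#' (bin alignment); otherwise an error asks for a record-length adjustment.
#' When the two admittances are too close to separate the circuit (flat
#' frequency response), the result is flagged ill-conditioned.
#'
#' @param current current trace, amperes.
#' @param voltage command-voltage trace, volts, same length.
#' @param fs sampling rate, Hz.
#' @param f1,f2 stimulus frequencies, Hz; defaults 390.625 and 781.25.
#' @param tol relative admittance-separation tolerance below which the
#'   solve is flagged; default 1e-9.
#' @return List with `Cm_pF`, `Rm_MOhm`, `Rs_MOhm` (and the SI values `Cm`,
#'   `Rm`, `Rs`), plus `ok` and `message`.
#' @export
two_sine_capacitance <- function(current, voltage, fs,
                                 f1 = 390.625, f2 = 781.25, tol = 1e-9) {
  n <- length(current)
  if (length(voltage) != n) stop("current and voltage lengths differ",
                                 call. = FALSE)
  k1 <- f1 * n / fs
  k2 <- f2 * n / fs
  if (abs(k1 - round(k1)) > 1e-6 || abs(k2 - round(k2)) > 1e-6) {
    stop("stimulus frequencies are not aligned to DFT bins; adjust the ",
         "record length to an integer number of periods of both frequencies",
         call. = FALSE)
  }
  k1 <- as.integer(round(k1)); k2 <- as.integer(round(k2))
  if (fs < 10 * f2) stop("sampling rate must be at least 10x f2",
                         call. = FALSE)
  Iw <- fft(current); Vw <- fft(voltage)
  Y1 <- Iw[k1 + 1] / Vw[k1 + 1]
  Y2 <- Iw[k2 + 1] / Vw[k2 + 1]
  if (Mod(Y1 - Y2) < tol * max(Mod(Y1), Mod(Y2))) {
    return(list(Cm = NA_real_, Rm = NA_real_, Rs = NA_real_,
                Cm_pF = NA_real_, Rm_MOhm = NA_real_, Rs_MOhm = NA_real_,
                ok = FALSE,
                message = "ill-conditioned: admittances indistinguishable"))
  }
  w1 <- 2 * pi * f1; w2 <- 2 * pi * f2
  Z1 <- 1 / Y1; Z2 <- 1 / Y2
  b1 <- Im(Z1); b2 <- Im(Z2)
  # Z(w) = Rs + Rm/(1 + i w tau), tau = Rm Cm:
  #   Im Z = -Rm w tau / (1 + w^2 tau^2); the imaginary-part ratio isolates
  #   tau, then Rm, Cm, Rs follow.
  r <- b1 / b2
  tau2 <- (w1 / w2 - r) / (r * w1^2 - w1 * w2)
  if (!is.finite(tau2) || tau2 <= 0) {
    return(list(Cm = NA_real_, Rm = NA_real_, Rs = NA_real_,
                Cm_pF = NA_real_, Rm_MOhm = NA_real_, Rs_MOhm = NA_real_,
                ok = FALSE, message = "ill-conditioned: no positive tau^2"))
  }
  tau <- sqrt(tau2)
  Rm <- -b1 * (1 + w1^2 * tau2) / (w1 * tau)
  Cm <- tau / Rm
  Rs <- Re(Z1) - Rm / (1 + w1^2 * tau2)
  list(Cm = Cm, Rm = Rm, Rs = Rs,
       Cm_pF = Cm * 1e12, Rm_MOhm = Rm / 1e6, Rs_MOhm = Rs / 1e6,
       ok = TRUE, message = "ok")
}

#' Correct command voltages for series-resistance error
#'
#' Offline series-resistance compensation: `V_corrected = V_command - I * Rs`
#' with the solved series resistance.
#'
#' @param v_command command voltage, mV.
#' @param current membrane current at the step, nA.
#' @param Rs_MOhm series resistance, MOhm.
#' @return Corrected voltage, mV (nA x MOhm = mV).
#' @export
correct_series_resistance <- function(v_command, current, Rs_MOhm) {
  v_command - current * Rs_MOhm
}

#' Classify a capacitance-voltage recording as voltage dependent or flat
#'
#' Nested-model F-test of the constant-capacitance fit against the
#' derivative-of-Boltzmann fit. The recording is called voltage dependent
#' when the F-test rejects at `alpha_level` AND the fitted bell amplitude
#' (`peak - Clin = Qmax * alpha / 4`) exceeds three residual standard
#' deviations — the amplitude clause keeps statistically significant but
#' physiologically negligible wiggles classified as flat, matching how
#' non-electromotile hair cells present.
#'
#' @param rec a [recording()] with `capacitance`.
#' @param alpha_level significance level; default 0.05.
#' @return List with `voltage_dependent` (logical), `F`, `p`, `amplitude`
#'   (pF), `residual_sd` (pF), `fit` (the [fit_nlc()] result).
#' @export
detect_voltage_dependence <- function(rec, alpha_level = 0.05) {
  if (length(rec$voltage) < 8) stop("need at least 8 points", call. = FALSE)
  y <- rec$capacitance
  fit <- fit_nlc(rec)
  if (!fit$converged) {
    return(list(voltage_dependent = FALSE, F = NA_real_, p = 1,
                amplitude = 0, residual_sd = fit$residual_sd, fit = fit))
  }
  n <- length(y)
  rss0 <- sum((y - mean(y))^2)
  pred <- nlc_curve(rec$voltage, fit$params)
  rss1 <- sum((y - pred)^2)
  df1 <- 3; df2 <- n - 4
  Fstat <- ((rss0 - rss1) / df1) / (rss1 / df2)
  pval <- pf(Fstat, df1, df2, lower.tail = FALSE)
  amplitude <- fit$params$Qmax * fit$params$alpha / 4
  vd <- is.finite(Fstat) && pval < alpha_level &&
    amplitude > 3 * fit$residual_sd
  list(voltage_dependent = vd, F = Fstat, p = pval, amplitude = amplitude,
       residual_sd = fit$residual_sd, fit = fit)
}
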