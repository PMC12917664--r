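#' Boltzmann constant (J/K)
#' @keywords internal
.kB <- 1.380649e-23

#' Dynamic viscosity of water
#'
#' Linear interpolation of tabulated water viscosity (Pa s) against
#' temperature; covers 273.15-373.15 K.
#'
#' @param temperature Temperature in K.
#' @return Viscosity in Pa s.
#' @export
water_viscosity <- function(temperature) {
  tK <- c(273.15, 278.15, 283.15, 288.15, 293.15, 298.15, 303.15,
          308.15, 313.15, 323.15, 333.15, 353.15, 373.15)
  eta <- c(1.792e-3, 1.519e-3, 1.307e-3, 1.138e-3, 1.002e-3, 0.890e-3,
           0.798e-3, 0.719e-3, 0.653e-3, 0.547e-3, 0.467e-3, 0.355e-3,
           0.282e-3)
  if (any(temperature < min(tK) | temperature > max(tK)))
    stop("temperature outside the tabulated viscosity range")
  stats::approx(tK, eta, xout = temperature)$y
}

#' DLS autocorrelation trace
#'
#' Container for a baseline-subtracted intensity autocorrelation trace
#' `g2(tau) - 1` plus the instrument parameters needed to convert its decay
#' rate to a particle size. Defaults reflect a 90-degree, 633 nm instrument
#' measuring an aqueous sample.
#'
#' @param lag_times Lag times in s, strictly increasing, > 0.
#' @param g2_minus_1 Autocorrelation minus baseline, same length, finite.
#' @param temperature Sample temperature in K.
#' @param viscosity Solvent viscosity in Pa s; default from
#'   [water_viscosity()] at `temperature`.
#' @param refractive_index Solvent refractive index.
#' @param wavelength Laser wavelength in m.
#' @param scattering_angle Scattering angle in degrees.
#' @return An object of class `dls_trace`.
#' @export
dls_trace <- function(lag_times, g2_minus_1, temperature = 293.15,
                      viscosity = NULL, refractive_index = 1.33,
                      wavelength = 633e-9, scattering_angle = 90) {
  lag_times <- as.numeric(lag_times)
  g2_minus_1 <- as.numeric(g2_minus_1)
  if (length(lag_times) != length(g2_minus_1)) stop("lag/g2 length mismatch")
  if (any(lag_times <= 0) || any(diff(lag_times) <= 0))
    stop("lag times must be positive and strictly increasing")
  if (any(!is.finite(g2_minus_1))) stop("non-finite autocorrelation values")
  if (is.null(viscosity)) viscosity <- water_viscosity(temperature)
  structure(list(lag_times = lag_times, g2_minus_1 = g2_minus_1,
                 temperature = temperature, viscosity = viscosity,
                 refractive_index = refractive_index,
                 wavelength = wavelength,
                 scattering_angle = scattering_angle),
            class = "dls_trace")
}

#' Scattering vector magnitude
#'
#' `q = (4 pi n / lambda) * sin(angle/2)`.
#'
#' @param n Solvent refractive index.
#' @param wavelength Laser wavelength in m (> 0).
#' @param angle Scattering angle in degrees, in (0, 180].
#' @return q in 1/m.
#' @export
scattering_vector <- function(n, wavelength, angle) {
  if (wavelength <= 0) stop("wavelength must be positive")
  if (angle <= 0 || angle > 180) stop("scattering angle must be in (0, 180]")
  (4 * pi * n / wavelength) * sin(angle * pi / 360)
}

#' Cumulant fit of a DLS trace
#'
#' Fits the logarithm of the field correlation function obtained through
#' the Siegert relation, `ln sqrt(g2 - 1) = ln sqrt(beta) - Gamma tau`
#' (plus `mu2 tau^2 / 2` at order 2), by least squares over the lags where
#' the signal is above a fraction of the zero-lag intercept (default 1% of
#' beta), avoiding the log of the noise-dominated tail.
#'
#' @param trace A [dls_trace()].
#' @param order 1 (single exponential) or 2 (adds the polydispersity term).
#' @param signal_floor Fraction of beta below which points are dropped.
#' @return List with `gamma` (decay rate, 1/s), `beta` (intercept),
#'   `mu2` (order 2 only), `pdi` (polydispersity index, `mu2/gamma^2`),
#'   `r_squared`, `n_points`.
#' @export
cumulant_fit <- function(trace, order = 1, signal_floor = 0.01) {
  stopifnot(inherits(trace, "dls_trace"), order %in% c(1, 2))
  tau <- trace$lag_times
  g <- trace$g2_minus_1
  pos <- g > 0
  if (sum(pos) < 5L) stop("degenerate trace: < 5 positive correlation points")
  beta0 <- max(g[pos])
  keep <- pos & g > signal_floor * beta0
  if (sum(keep) < 5L) stop("degenerate trace: too few points above the noise floor")
  x <- tau[keep]
  y <- 0.5 * log(g[keep])   # ln sqrt(g2-1) = ln |g1| + ln sqrt(beta)
  # additive noise on g2-1 has variance ~const, so var(ln g) ~ 1/g^2:
  # weighting by g^2 restores homoscedasticity and removes the tail bias
  w <- g[keep]^2
  fit <- if (order == 1) stats::lm(y ~ x, weights = w)
         else stats::lm(y ~ x + I(x^2), weights = w)
  cf <- stats::coef(fit)
  gamma <- -unname(cf[2])
  # require an appreciable decay across the fitted window, not just a
  # numerically positive slope
  if (!is.finite(gamma) || gamma * (max(x) - min(x)) <= 1e-6)
    stop("degenerate trace: no measurable decay")
  mu2 <- if (order == 2) 2 * unname(cf[3]) else NA_real_
  list(gamma = gamma, beta = exp(2 * unname(cf[1])), mu2 = mu2,
       pdi = if (order == 2) mu2 / gamma^2 else NA_real_,
       r_squared = suppressWarnings(summary(fit))$r.squared, n_points = sum(keep))
}

#' Hydrodynamic diameter from the Stokes-Einstein relation
#'
#' `d_H = kB T / (3 pi eta D)` for a sphere with translational diffusion
#' coefficient D.
#'
#' @param diffusion Diffusion coefficient in m^2/s (> 0).
#' @param temperature Temperature in K (> 0).
#' @param viscosity Solvent viscosity in Pa s (> 0).
#' @return Hydrodynamic diameter in m.
#' @export
stokes_einstein_diameter <- function(diffusion, temperature, viscosity) {
  if (any(diffusion <= 0) || any(temperature <= 0) || any(viscosity <= 0))
    stop("diffusion, temperature and viscosity must all be positive")
  .kB * temperature / (3 * pi * viscosity * diffusion)
}

#' Full DLS trace analysis
#'
#' Chains the scattering vector, the cumulant fit, the conversion
#' `D = Gamma / q^2`, and the Stokes-Einstein relation into a hydrodynamic
#' diameter.
#'
#' @param trace A [dls_trace()] or a list of replicate traces.
#' @param order Cumulant order, see [cumulant_fit()].
#' @return For one trace, an object of class `hydro_result` with `q`,
#'   `gamma`, `diffusion`, `d_h` (m), `d_h_nm`, `pdi`, `fit_quality`.
#'   For a list of traces, a list with per-replicate results plus
#'   `mean_d_h_nm` and `sd_d_h_nm`.
#' @export
analyze_trace <- function(trace, order = 1) {
  if (is.list(trace) && !inherits(trace, "dls_trace")) {
    res <- lapply(trace, analyze_trace, order = order)
    dh <- vapply(res, function(r) r$d_h_nm, numeric(1))
    return(list(replicates = res, mean_d_h_nm = mean(dh),
                sd_d_h_nm = stats::sd(dh)))
  }
  q <- scattering_vector(trace$refractive_index, trace$wavelength,
                         trace$scattering_angle)
  cum <- cumulant_fit(trace, order = order)
  diffusion <- cum$gamma / q^2
  d_h <- stokes_einstein_diameter(diffusion, trace$temperature,
                                  trace$viscosity)
  structure(list(q = q, gamma = cum$gamma, diffusion = diffusion,
                 d_h = d_h, d_h_nm = d_h * 1e9, pdi = cum$pdi,
                 fit_quality = cum$r_squared),
            class = "hydro_result")
}

#' @export
print.hydro_result <- function(x, ...) {
  cat("DLS cumulant analysis\n")
  cat(sprintf("  q     : %.4g 1/m   Gamma : %.4g 1/s\n", x$q, x$gamma))
  cat(sprintf("  D     : %.4g m^2/s\n", x$diffusion))
  cat(sprintf("  d_H   : %.3f nm   (fit R^2 %.6f)\n", x$d_h_nm, x$fit_quality))
  invisible(x)
}
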