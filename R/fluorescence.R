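#' Emission spectrum for one titration point
#'
#' Container for a single fluorescence emission spectrum recorded after a
#' ligand addition, together with the metadata needed for downstream
#' corrections: the cumulative titrant volume (dilution correction) and the
#' ligand absorbances at the excitation and analysis-emission wavelengths
#' (inner-filter correction).
#'
#' @param wavelengths Numeric vector of emission wavelengths in nm, strictly
#'   increasing.
#' @param intensities Numeric vector of fluorescence intensities (arbitrary
#'   units), same length as `wavelengths`, all non-negative.
#' @param temperature Temperature in K.
#' @param ligand_total Total ligand concentration in the cuvette after this
#'   addition (mol/L). The reference spectrum has `ligand_total = 0`.
#' @param added_volume Cumulative titrant volume added so far (L).
#' @param absorbance_ex Ligand absorbance at the excitation wavelength
#'   (dimensionless, >= 0).
#' @param absorbance_em Ligand absorbance at the analysis emission wavelength
#'   (dimensionless, >= 0).
#' @return An object of class `emission_spectrum`.
#' @export
emission_spectrum <- function(wavelengths, intensities, temperature,
                              ligand_total = 0, added_volume = 0,
                              absorbance_ex = 0, absorbance_em = 0) {
  wavelengths <- as.numeric(wavelengths)
  intensities <- as.numeric(intensities)
  if (length(wavelengths) != length(intensities))
    stop("wavelengths and intensities must have the same length")
  if (length(wavelengths) < 1L) stop("empty spectrum")
  if (any(diff(wavelengths) <= 0)) stop("wavelengths must be strictly increasing")
  if (any(intensities < 0)) stop("intensities must be non-negative")
  if (absorbance_ex < 0 || absorbance_em < 0)
    stop("absorbances must be non-negative")
  if (added_volume < 0) stop("added_volume must be non-negative")
  structure(list(wavelengths = wavelengths, intensities = intensities,
                 temperature = temperature, ligand_total = ligand_total,
                 added_volume = added_volume, absorbance_ex = absorbance_ex,
                 absorbance_em = absorbance_em),
            class = "emission_spectrum")
}

#' Fluorescence titration series
#'
#' An ordered set of emission spectra recorded along a ligand titration at
#' one temperature and pH. The first spectrum must be the zero-ligand
#' reference (the F0 spectrum); all spectra share a wavelength grid and a
#' temperature.
#'
#' @param spectra List of [emission_spectrum()] objects with nondecreasing
#'   `ligand_total`, the first having `ligand_total = 0`.
#' @param protein_total Total protein concentration before titration (mol/L).
#' @param ph Solution pH.
#' @param initial_volume Cuvette volume before the first addition (L).
#' @param excitation_wavelength Excitation wavelength in nm.
#' @param label Optional condition label.
#' @return An object of class `titration_series`.
#' @export
titration_series <- function(spectra, protein_total, ph, initial_volume,
                             excitation_wavelength = 290, label = NULL) {
  if (length(spectra) < 2L) stop("a titration series needs >= 2 spectra")
  if (!all(vapply(spectra, inherits, logical(1), "emission_spectrum")))
    stop("spectra must be emission_spectrum objects")
  lig <- vapply(spectra, `[[`, numeric(1), "ligand_total")
  if (lig[1] != 0) stop("first spectrum must be the zero-ligand reference")
  if (any(diff(lig) < 0)) stop("ligand_total must be nondecreasing")
  grids <- vapply(spectra, function(s) paste(signif(s$wavelengths, 10),
                                             collapse = ","), character(1))
  if (length(unique(grids)) != 1L)
    stop("all spectra must share one wavelength grid")
  temps <- vapply(spectra, `[[`, numeric(1), "temperature")
  if (diff(range(temps)) > 1e-9)
    stop("all spectra in a series must share one temperature")
  if (initial_volume <= 0) stop("initial_volume must be positive")
  structure(list(spectra = spectra, protein_total = protein_total, ph = ph,
                 initial_volume = initial_volume,
                 excitation_wavelength = excitation_wavelength,
                 temperature = temps[1], label = label),
            class = "titration_series")
}

#' Inner-filter effect correction
#'
#' Corrects an observed fluorescence intensity for attenuation by ligand
#' absorbance at the excitation and emission wavelengths:
#' `F_corrected = F_observed * 10^((A_ex + A_em)/2)`.
#'
#' @param f_obs Observed intensity (>= 0).
#' @param a_ex Ligand absorbance at the excitation wavelength (>= 0).
#' @param a_em Ligand absorbance at the analysis emission wavelength (>= 0).
#' @return Corrected intensity. Equals `f_obs` when both absorbances are 0.
#' @export
correct_inner_filter <- function(f_obs, a_ex, a_em) {
  if (any(f_obs < 0)) stop("intensity must be non-negative")
  if (any(a_ex < 0) || any(a_em < 0)) stop("absorbances must be non-negative")
  f_obs * 10^((a_ex + a_em) / 2)
}

#' Scalar intensity metric of an emission spectrum
#'
#' Reduces a spectrum to the single intensity used in the quenching
#' analysis. Three metrics are supported: the peak maximum (`"peak"`), the
#' intensity at a fixed wavelength (`"at-wavelength"`, linearly
#' interpolated), or the trapezoidal integral over a window (`"area"`).
#'
#' @param spectrum An [emission_spectrum()].
#' @param mode One of `"peak"`, `"at-wavelength"`, `"area"`.
#' @param wavelength Analysis wavelength in nm (for `"at-wavelength"`).
#' @param window Length-2 numeric, integration window in nm (for `"area"`;
#'   defaults to the full spectral span).
#' @return A single intensity value.
#' @export
spectrum_intensity <- function(spectrum,
                               mode = c("peak", "at-wavelength", "area"),
                               wavelength = NULL, window = NULL) {
  mode <- match.arg(mode)
  wl <- spectrum$wavelengths
  fi <- spectrum$intensities
  switch(mode,
    "peak" = max(fi),
    "at-wavelength" = {
      if (is.null(wavelength)) stop("wavelength required for at-wavelength mode")
      if (wavelength < wl[1] || wavelength > wl[length(wl)])
        stop("wavelength outside the spectral span")
      stats::approx(wl, fi, xout = wavelength)$y
    },
    "area" = {
      if (is.null(window)) window <- range(wl)
      keep <- wl >= window[1] & wl <= window[2]
      if (sum(keep) < 2L) stop("empty or degenerate integration window")
      x <- wl[keep]; y <- fi[keep]
      sum(diff(x) * (y[-1] + y[-length(y)]) / 2)
    })
}

#' Fractional fluorescence quenching
#'
#' The fraction of the reference fluorescence suppressed by the ligand,
#' `theta = (F0 - F)/F0`, used as the fractional occupancy of the binding
#' sites. Values outside (0, 1) can arise from noise and are handled at the
#' fitting stage, not here.
#'
#' @param f0 Reference (zero-ligand) corrected intensity, > 0.
#' @param f Corrected intensity in the presence of ligand, >= 0.
#' @return The quenching fraction.
#' @export
quenching_fraction <- function(f0, f) {
  if (any(f0 <= 0)) stop("reference intensity must be positive")
  if (any(f < 0)) stop("intensity must be non-negative")
  (f0 - f) / f0
}

#' Ligand concentrations along a titration
#'
#' Mass-balance ligand concentration after each cumulative addition of stock
#' titrant, accounting for dilution:
#' `[L]_i = stock * V_added_i / (V0 + V_added_i)`. Also returns the dilution
#' factor `V0 / (V0 + V_added_i)` by which the protein (and hence its
#' fluorescence) is diluted at each point.
#'
#' @param added_volumes Cumulative added volumes (L), nondecreasing, >= 0.
#' @param initial_volume Initial cuvette volume V0 (L), > 0.
#' @param stock_conc Titrant stock concentration (mol/L), > 0.
#' @return A data.frame with columns `added_volume`, `ligand_conc`,
#'   `dilution_factor`.
#' @export
ligand_concentrations <- function(added_volumes, initial_volume, stock_conc) {
  if (any(added_volumes < 0)) stop("added volumes must be non-negative")
  if (any(diff(added_volumes) < 0)) stop("cumulative volumes must be nondecreasing")
  if (stock_conc <= 0) stop("stock concentration must be positive")
  if (initial_volume <= 0) stop("initial volume must be positive")
  vt <- initial_volume + added_volumes
  data.frame(added_volume = added_volumes,
             ligand_conc = stock_conc * added_volumes / vt,
             dilution_factor = initial_volume / vt)
}

#' Double-log Hill fit of quenching data
#'
#' Ordinary least-squares regression of `log10(theta/(1-theta))` on
#' `log10([L])`. Under the Hill binding isotherm
#' `theta = [L]^n / ([L]^n + Kd)` this plot is exactly linear: the slope is
#' the Hill coefficient `n` and the intercept is `-log10(Kd)`, so the
#' association constant is `Ka = 1/Kd`. Points with `theta` outside (0, 1)
#' have undefined log-odds and are excluded (recorded in `excluded`), never
#' clamped.
#'
#' @param ligand_conc Ligand concentrations (mol/L), > 0.
#' @param theta Quenching fractions, same length.
#' @return An object of class `hill_fit` with elements `n`, `kd`, `ka`,
#'   `intercept`, `r_squared`, `stderr_n`, `stderr_log_kd`, `points_used`,
#'   `excluded`, and the fitted `model`.
#' @export
hill_double_log_fit <- function(ligand_conc, theta) {
  if (length(ligand_conc) != length(theta))
    stop("ligand_conc and theta must have the same length")
  ok <- is.finite(theta) & theta > 0 & theta < 1 & ligand_conc > 0
  if (!any(is.finite(theta) & theta > 0 & theta < 1))
    stop("degenerate data: no theta value inside (0, 1)")
  if (sum(ok) < 3L)
    stop("insufficient data: need >= 3 points with 0 < theta < 1")
  x <- log10(ligand_conc[ok])
  y <- log10(theta[ok] / (1 - theta[ok]))
  fit <- stats::lm(y ~ x)
  cf <- stats::coef(fit)
  se <- sqrt(diag(suppressWarnings(stats::vcov(fit))))
  n <- unname(cf["x"])
  intercept <- unname(cf["(Intercept)"])
  kd <- 10^(-intercept)
  structure(list(n = n, kd = kd, ka = 1 / kd, intercept = intercept,
                 r_squared = suppressWarnings(summary(fit))$r.squared,
                 stderr_n = unname(se["x"]),
                 stderr_log_kd = unname(se["(Intercept)"]),
                 points_used = sum(ok), excluded = which(!ok),
                 model = fit),
            class = "hill_fit")
}

#' @export
print.hill_fit <- function(x, ...) {
  cat("Hill double-log fit\n")
  cat(sprintf("  n (Hill slope) : %.4f (se %.4f)\n", x$n, x$stderr_n))
  cat(sprintf("  Kd             : %.4g M\n", x$kd))
  cat(sprintf("  Ka             : %.4g 1/M\n", x$ka))
  cat(sprintf("  R-squared      : %.6f   points used: %d (excluded %d)\n",
              x$r_squared, x$points_used, length(x$excluded)))
  invisible(x)
}

#' Full titration analysis: spectra to Hill fit
#'
#' Chains the per-point processing of a titration series: inner-filter
#' correction of each spectrum's intensity metric, division by the dilution
#' factor (a ~1-3% volume increase otherwise masquerades as quenching),
#' computation of the quenching fraction against the corrected reference,
#' and the double-log Hill regression against the total ligand
#' concentration.
#'
#' @param series A [titration_series()].
#' @param stock_conc Titrant stock concentration (mol/L). When `NULL` the
#'   `ligand_total` stored in each spectrum is used directly and the dilution
#'   factor is computed from the recorded volumes.
#' @param metric Intensity metric passed to [spectrum_intensity()].
#' @param wavelength,window Passed to [spectrum_intensity()].
#' @return A `hill_fit` with an extra element `points`: the per-point
#'   data.frame of ligand concentration, corrected F0/F and theta.
#' @export
fit_titration <- function(series, stock_conc = NULL,
                          metric = c("peak", "at-wavelength", "area"),
                          wavelength = NULL, window = NULL) {
  metric <- match.arg(metric)
  if (!inherits(series, "titration_series")) stop("series must be a titration_series")
  sp <- series$spectra
  vols <- vapply(sp, `[[`, numeric(1), "added_volume")
  if (!is.null(stock_conc)) {
    conc <- ligand_concentrations(vols, series$initial_volume, stock_conc)
  } else {
    conc <- data.frame(
      added_volume = vols,
      ligand_conc = vapply(sp, `[[`, numeric(1), "ligand_total"),
      dilution_factor = series$initial_volume / (series$initial_volume + vols))
  }
  raw <- vapply(sp, spectrum_intensity, numeric(1), mode = metric,
                wavelength = wavelength, window = window)
  corrected <- mapply(function(f, s) correct_inner_filter(f, s$absorbance_ex,
                                                          s$absorbance_em),
                      raw, sp)
  corrected <- corrected / conc$dilution_factor
  f0 <- corrected[1]
  if (!is.finite(f0) || f0 <= 0)
    stop("fit_titration: invalid reference (zero-ligand) intensity")
  theta <- quenching_fraction(f0, corrected)
  pts <- data.frame(ligand_conc = conc$ligand_conc, f0 = f0, f = corrected,
                    theta = theta,
                    dilution_factor = conc$dilution_factor)
  keep <- pts$ligand_conc > 0
  fit <- tryCatch(
    hill_double_log_fit(pts$ligand_conc[keep], pts$theta[keep]),
    error = function(e) stop("fit_titration (Hill regression stage): ",
                             conditionMessage(e)))
  fit$points <- pts
  fit$temperature <- series$temperature
  fit$ph <- series$ph
  fit
}
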