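#' Gas constant
#'
#' @param units `"kcal"` (kcal/(mol K), default, matching the energy units
#'   used for reported binding thermodynamics) or `"kJ"` (kJ/(mol K)).
#' @return R in the requested units.
#' @export
gas_constant <- function(units = c("kcal", "kJ")) {
  units <- match.arg(units)
  if (units == "kcal") 1.987204e-3 else 8.314462e-3
}

#' van't Hoff analysis of temperature-dependent association constants
#'
#' Linear regression of `ln(Ka)` on `1/T`. Under the van't Hoff relation
#' `ln(Ka) = -dH/(R T) + dS/R` the slope is `-dH/R` and the intercept is
#' `dS/R`, so the binding enthalpy and entropy follow directly from the
#' regression coefficients. Replicate Ka values at a temperature are
#' averaged before fitting.
#'
#' @param temperature Temperatures in K (> 0), >= 2 distinct values.
#' @param ka Association constants (1/M, > 0), same length.
#' @param units Energy unit system for R, see [gas_constant()].
#' @return An object of class `vant_hoff_fit` with `delta_h` (kcal/mol or
#'   kJ/mol), `delta_s` (same energy unit per K), `r_squared`, standard
#'   errors, and the unit label.
#' @export
vant_hoff_fit <- function(temperature, ka, units = c("kcal", "kJ")) {
  units <- match.arg(units)
  if (length(temperature) != length(ka)) stop("temperature and ka lengths differ")
  if (any(ka <= 0)) stop("association constants must be positive")
  if (any(temperature <= 0)) stop("temperatures must be positive (K)")
  tavg <- tapply(ka, temperature, mean)
  tt <- as.numeric(names(tavg))
  if (length(tt) < 2L) stop("insufficient data: >= 2 distinct temperatures required")
  r <- gas_constant(units)
  x <- 1 / tt
  y <- log(as.numeric(tavg))
  fit <- stats::lm(y ~ x)
  cf <- stats::coef(fit)
  se <- sqrt(diag(suppressWarnings(stats::vcov(fit))))
  rsq <- if (length(tt) > 2L) suppressWarnings(summary(fit))$r.squared else 1
  structure(list(delta_h = -r * unname(cf["x"]),
                 delta_s = r * unname(cf["(Intercept)"]),
                 stderr_delta_h = r * unname(se["x"]),
                 r_squared = rsq, units = units,
                 temperatures = tt, ka = as.numeric(tavg)),
            class = "vant_hoff_fit")
}

#' @export
print.vant_hoff_fit <- function(x, ...) {
  u <- x$units
  cat("van't Hoff fit\n")
  cat(sprintf("  dH : %.3f %s/mol\n", x$delta_h, u))
  cat(sprintf("  dS : %.5f %s/(mol K)   TdS(%g K) = %.3f %s/mol\n",
              x$delta_s, u, x$temperatures[1],
              x$temperatures[1] * x$delta_s, u))
  invisible(x)
}

#' Gibbs free energy from enthalpy and entropy
#'
#' `dG = dH - T * dS`.
#'
#' @param delta_h Enthalpy change (energy/mol).
#' @param temperature Temperature in K (> 0).
#' @param delta_s Entropy change (energy/(mol K)).
#' @return Gibbs free energy change, same energy units as the inputs.
#' @export
gibbs_free_energy <- function(delta_h, temperature, delta_s) {
  if (any(temperature <= 0)) stop("temperature must be positive")
  delta_h - temperature * delta_s
}

#' Gibbs free energy from an association constant
#'
#' Standard-state relation `dG = -R T ln(Ka)`.
#'
#' @param ka Association constant (1/M, > 0).
#' @param temperature Temperature in K (> 0).
#' @param units Energy unit system, see [gas_constant()].
#' @return dG in the requested units per mol.
#' @export
gibbs_from_ka <- function(ka, temperature, units = c("kcal", "kJ")) {
  if (any(ka <= 0)) stop("association constant must be positive")
  if (any(temperature <= 0)) stop("temperature must be positive")
  -gas_constant(units) * temperature * log(ka)
}

#' Condition summary row (per-pH thermodynamic table)
#'
#' Collapses per-temperature Hill fits plus a van't Hoff analysis into one
#' summary row: mean Ka, mean Hill coefficient, dH from the van't Hoff fit,
#' and per-temperature and mean TdS and dG (with dG = dH - T dS at each
#' temperature). Averages are unweighted arithmetic means over temperatures;
#' dispersions are standard deviations.
#'
#' @param fits List of `hill_fit` objects, one per temperature, each with a
#'   `temperature` element (as returned by [fit_titration()]).
#' @param units Energy unit system.
#' @param label Optional condition label (e.g. a pH).
#' @return An object of class `thermo_result`: a list with `mean_ka`,
#'   `sd_ka`, `mean_n`, `sd_n`, `delta_h`, `delta_s`, `t_delta_s`,
#'   `delta_g`, `mean_t_delta_s`, `mean_delta_g`, `sd_delta_g`,
#'   `temperatures`, `r_squared`, `label`.
#' @export
condition_summary <- function(fits, units = c("kcal", "kJ"), label = NULL) {
  units <- match.arg(units)
  if (length(fits) < 1L) stop("need >= 1 per-temperature fit")
  temps <- vapply(fits, function(f) f$temperature, numeric(1))
  kas <- vapply(fits, function(f) f$ka, numeric(1))
  ns <- vapply(fits, function(f) f$n, numeric(1))
  res <- list(mean_ka = mean(kas), sd_ka = stats::sd(kas),
              mean_n = mean(ns), sd_n = stats::sd(ns),
              temperatures = temps, ka = kas, n = ns,
              units = units, label = label)
  if (length(unique(temps)) >= 2L) {
    vh <- vant_hoff_fit(temps, kas, units = units)
    res$delta_h <- vh$delta_h
    res$delta_s <- vh$delta_s
    res$r_squared <- vh$r_squared
    res$t_delta_s <- temps * vh$delta_s
    res$delta_g <- gibbs_free_energy(vh$delta_h, temps, vh$delta_s)
    res$mean_t_delta_s <- mean(res$t_delta_s)
    res$mean_delta_g <- mean(res$delta_g)
    res$sd_delta_g <- stats::sd(res$delta_g)
  } else {
    warning("single temperature: thermodynamic parameters not computed")
    res$delta_g <- gibbs_from_ka(kas, temps, units = units)
    res$mean_delta_g <- mean(res$delta_g)
  }
  structure(res, class = "thermo_result")
}

#' @export
print.thermo_result <- function(x, ...) {
  cat("Condition summary", if (!is.null(x$label)) paste0("(", x$label, ")"), "\n")
  cat(sprintf("  <Ka> : %.3g 1/M   <n> : %.3g\n", x$mean_ka, x$mean_n))
  if (!is.null(x$delta_h)) {
    cat(sprintf("  dH   : %.2f %s/mol   <TdS> : %.2f   <dG> : %.2f\n",
                x$delta_h, x$units, x$mean_t_delta_s, x$mean_delta_g))
  }
  invisible(x)
}

#' Percent reduction in binding affinity
#'
#' `100 * (ka_ref - ka_alt) / ka_ref`; e.g. the affinity loss of a
#' binding-site mutant relative to the wild type.
#'
#' @param ka_ref Reference association constant (> 0).
#' @param ka_alt Alternative (e.g. mutant) association constant.
#' @return Percent reduction (negative if `ka_alt > ka_ref`).
#' @export
affinity_reduction <- function(ka_ref, ka_alt) {
  if (any(ka_ref <= 0)) stop("reference Ka must be positive")
  100 * (ka_ref - ka_alt) / ka_ref
}
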