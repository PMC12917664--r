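#' Write a titration series to disk
#'
#' Long-format CSV (`point_index`, `wavelength_nm`, `intensity`) plus a YAML
#' sidecar with the series metadata (temperature, pH, concentrations,
#' cumulative volumes and per-point absorbances) — the same layout
#' [read_titration()] consumes.
#'
#' @param series A [titration_series()].
#' @param csv_path Path for the spectra CSV.
#' @param sidecar_path Path for the YAML sidecar (default: csv path with
#'   `.yaml` extension).
#' @return Invisibly, the two paths.
#' @export
write_titration <- function(series, csv_path,
                            sidecar_path = sub("\\.csv$", ".yaml", csv_path)) {
  sp <- series$spectra
  long <- do.call(rbind, lapply(seq_along(sp), function(i)
    data.frame(point_index = i - 1L, wavelength_nm = sp[[i]]$wavelengths,
               intensity = sp[[i]]$intensities)))
  utils::write.csv(long, csv_path, row.names = FALSE)
  meta <- list(temperature_K = series$temperature, pH = series$ph,
               protein_M = series$protein_total,
               initial_volume_L = series$initial_volume,
               excitation_nm = series$excitation_wavelength,
               ligand_M = vapply(sp, `[[`, numeric(1), "ligand_total"),
               added_volume_L = vapply(sp, `[[`, numeric(1), "added_volume"),
               A_ex = vapply(sp, `[[`, numeric(1), "absorbance_ex"),
               A_em = vapply(sp, `[[`, numeric(1), "absorbance_em"))
  yaml::write_yaml(meta, sidecar_path, precision = 15)
  invisible(c(csv_path, sidecar_path))
}

#' Read a titration series from disk
#'
#' Inverse of [write_titration()]: long-format spectra CSV plus YAML
#' metadata sidecar.
#'
#' @param csv_path Spectra CSV path.
#' @param sidecar_path YAML sidecar path.
#' @return A [titration_series()].
#' @export
read_titration <- function(csv_path,
                           sidecar_path = sub("\\.csv$", ".yaml", csv_path)) {
  if (!file.exists(csv_path)) stop("spectra file not found: ", csv_path)
  if (!file.exists(sidecar_path)) stop("metadata sidecar not found: ", sidecar_path)
  long <- utils::read.csv(csv_path)
  need <- c("point_index", "wavelength_nm", "intensity")
  if (!all(need %in% names(long)))
    stop("spectra CSV must have columns: ", paste(need, collapse = ", "))
  meta <- yaml::read_yaml(sidecar_path)
  idx <- sort(unique(long$point_index))
  spectra <- lapply(seq_along(idx), function(i) {
    d <- long[long$point_index == idx[i], ]
    d <- d[order(d$wavelength_nm), ]
    emission_spectrum(d$wavelength_nm, d$intensity,
                      temperature = meta$temperature_K,
                      ligand_total = meta$ligand_M[i],
                      added_volume = meta$added_volume_L[i],
                      absorbance_ex = meta$A_ex[i],
                      absorbance_em = meta$A_em[i])
  })
  titration_series(spectra, protein_total = meta$protein_M, ph = meta$pH,
                   initial_volume = meta$initial_volume_L,
                   excitation_wavelength = meta$excitation_nm)
}

#' Read an STD peak table
#'
#' CSV with columns `proton`, optionally `shift_ppm`, and intensities
#' among `i_off`, `i_on`, `i_std`.
#'
#' @param path CSV path.
#' @return data.frame suitable for [epitope_from_peaks()].
#' @export
read_std_table <- function(path) {
  if (!file.exists(path)) stop("STD table not found: ", path)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"proton" %in% names(d)) stop("STD table needs a 'proton' column")
  d$proton <- as.character(d$proton)
  d
}

#' Read a DLS trace
#'
#' CSV of (`lag_s`, `g2_minus_1`) plus a YAML sidecar with instrument
#' parameters (`temperature_K`, optional `viscosity_Pa_s`,
#' `refractive_index`, `wavelength_m`, `scattering_angle_deg`).
#'
#' @param csv_path Trace CSV path.
#' @param sidecar_path YAML sidecar path.
#' @return A [dls_trace()].
#' @export
read_dls_trace <- function(csv_path,
                           sidecar_path = sub("\\.csv$", ".yaml", csv_path)) {
  if (!file.exists(csv_path)) stop("DLS trace not found: ", csv_path)
  d <- utils::read.csv(csv_path)
  meta <- if (file.exists(sidecar_path)) yaml::read_yaml(sidecar_path) else list()
  dls_trace(d$lag_s, d$g2_minus_1,
            temperature = meta$temperature_K %||% 293.15,
            viscosity = meta$viscosity_Pa_s,
            refractive_index = meta$refractive_index %||% 1.33,
            wavelength = meta$wavelength_m %||% 633e-9,
            scattering_angle = meta$scattering_angle_deg %||% 90)
}

#' Write a DLS trace to disk
#'
#' @param trace A [dls_trace()].
#' @param csv_path Trace CSV path.
#' @param sidecar_path YAML sidecar path.
#' @return Invisibly, the two paths.
#' @export
write_dls_trace <- function(trace, csv_path,
                            sidecar_path = sub("\\.csv$", ".yaml", csv_path)) {
  utils::write.csv(data.frame(lag_s = trace$lag_times,
                              g2_minus_1 = trace$g2_minus_1),
                   csv_path, row.names = FALSE)
  yaml::write_yaml(list(temperature_K = trace$temperature,
                        viscosity_Pa_s = trace$viscosity,
                        refractive_index = trace$refractive_index,
                        wavelength_m = trace$wavelength,
                        scattering_angle_deg = trace$scattering_angle),
                   sidecar_path, precision = 15)
  invisible(c(csv_path, sidecar_path))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Export a Hill fit and its quenching points
#'
#' @param fit A `hill_fit` from [fit_titration()].
#' @param csv_path Path for the per-point table.
#' @param json_path Optional path for the fit parameters as JSON.
#' @return Invisibly, the paths written.
#' @export
write_hill_fit <- function(fit, csv_path, json_path = NULL) {
  utils::write.csv(fit$points, csv_path, row.names = FALSE)
  if (!is.null(json_path)) {
    jsonlite::write_json(list(n = fit$n, kd = fit$kd, ka = fit$ka,
                              intercept = fit$intercept,
                              r_squared = fit$r_squared,
                              stderr_n = fit$stderr_n,
                              stderr_log_kd = fit$stderr_log_kd,
                              points_used = fit$points_used),
                         json_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(c(csv_path, json_path))
}
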