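# Run code under a local RNG seed, restoring global RNG state afterwards.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Generate synthetic fluorescence titration series with known truth
#'
#' Emulates a quenching titration: a fixed protein concentration in the
#' cuvette, equal-volume additions of a concentrated ligand stock until the
#' ligand:protein mole ratio reaches 1:1, association constants across
#' temperatures tied together by the van't Hoff relation anchored at
#' `ka_ref` and `delta_h`, occupancy from the Hill isotherm
#' `theta = [L]^n / ([L]^n + Kd(T))`, fluorescence `F = F0 (1 - theta)`
#' scaled by the dilution factor, attenuated by a linear-in-[L]
#' inner-filter absorbance, and multiplicative Gaussian noise (truncated
#' at zero). Deterministic for a fixed seed.
#'
#' @param ka_ref Association constant (1/M) at the reference temperature.
#' @param n Hill coefficient.
#' @param delta_h Binding enthalpy in kcal/mol (controls how Ka varies
#'   across temperatures; 0 gives identical Ka everywhere).
#' @param temperatures Temperatures in K (default 295, 299, 303).
#' @param t_ref Reference temperature for `ka_ref` (default 299).
#' @param protein_total Protein concentration (mol/L, default 2e-6).
#' @param stock_conc Ligand stock concentration (mol/L, default 202e-6).
#' @param initial_volume Cuvette volume (L, default 2e-3).
#' @param n_points Number of ligand additions (>= 4, default 10).
#' @param noise_sd_frac Multiplicative intensity noise SD as a fraction.
#' @param absorbance_per_molar Effective extinction for the inner-filter
#'   model `A = eps [L]`, applied at both wavelengths (1/M, default 0).
#' @param f0_scale Reference peak intensity (arbitrary units).
#' @param ph pH label carried through to the series.
#' @param schedule `"equal"` (equal-volume additions, the titration
#'   protocol emulated here) or `"log"` (log-spaced, better conditioned).
#' @param seed RNG seed.
#' @return A list with `series` (one [titration_series()] per temperature)
#'   and `truth` (all parameters plus per-temperature Ka and per-point
#'   theta and ligand concentrations).
#' @export
gen_titration <- function(ka_ref, n = 1, delta_h = 0,
                          temperatures = c(295, 299, 303), t_ref = 299,
                          protein_total = 2e-6, stock_conc = 202e-6,
                          initial_volume = 2e-3, n_points = 10,
                          noise_sd_frac = 0, absorbance_per_molar = 0,
                          f0_scale = 1e6, ph = NA,
                          schedule = c("equal", "log"), seed = 1) {
  schedule <- match.arg(schedule)
  if (n_points < 4L) stop("n_points must be >= 4")
  if (noise_sd_frac < 0) stop("noise_sd_frac must be non-negative")
  if (stock_conc <= protein_total)
    stop("infeasible schedule: stock concentration must exceed the protein concentration")
  r <- gas_constant("kcal")
  # entropy anchored so that Ka(t_ref) = ka_ref
  delta_s <- r * log(ka_ref) + delta_h / t_ref
  ka_t <- exp(-delta_h / (r * temperatures) + delta_s / r)
  # total titrant volume for a 1:1 ligand:protein mole ratio endpoint
  v_total <- protein_total * initial_volume / stock_conc
  frac <- if (schedule == "equal") seq_len(n_points) / n_points
          else 10^seq(log10(0.02), 0, length.out = n_points)
  vols <- c(0, v_total * frac)
  conc <- ligand_concentrations(vols, initial_volume, stock_conc)
  wl <- seq(300, 500, by = 2)
  shape <- exp(-(wl - 340)^2 / (2 * 30^2))
  with_seed(seed, {
    series <- vector("list", length(temperatures))
    truth_theta <- vector("list", length(temperatures))
    for (ti in seq_along(temperatures)) {
      kd <- 1 / ka_t[ti]
      theta <- ifelse(conc$ligand_conc > 0,
                      conc$ligand_conc^n / (conc$ligand_conc^n + kd), 0)
      f_true <- f0_scale * (1 - theta)
      a <- absorbance_per_molar * conc$ligand_conc
      noise <- pmax(0, 1 + stats::rnorm(length(f_true), 0, noise_sd_frac))
      f_obs <- f_true * conc$dilution_factor / 10^((a + a) / 2) * noise
      spectra <- lapply(seq_along(f_obs), function(i)
        emission_spectrum(wl, f_obs[i] * shape,
                          temperature = temperatures[ti],
                          ligand_total = conc$ligand_conc[i],
                          added_volume = conc$added_volume[i],
                          absorbance_ex = a[i], absorbance_em = a[i]))
      series[[ti]] <- titration_series(spectra, protein_total, ph,
                                       initial_volume,
                                       label = sprintf("T=%gK", temperatures[ti]))
      truth_theta[[ti]] <- data.frame(ligand_conc = conc$ligand_conc,
                                      theta = theta)
    }
    names(series) <- as.character(temperatures)
    names(truth_theta) <- as.character(temperatures)
    list(series = series,
         truth = list(ka_ref = ka_ref, n = n, delta_h = delta_h,
                      delta_s = delta_s, temperatures = temperatures,
                      ka_by_temperature = ka_t, t_ref = t_ref,
                      protein_total = protein_total, stock_conc = stock_conc,
                      initial_volume = initial_volume, n_points = n_points,
                      noise_sd_frac = noise_sd_frac,
                      absorbance_per_molar = absorbance_per_molar,
                      f0_scale = f0_scale, schedule = schedule, seed = seed,
                      points = truth_theta))
  })
}

#' Generate a synthetic STD peak table with known epitope profile
#'
#' Emits per-proton off-resonance and on-resonance intensities such that
#' the true amplification factor of proton i equals `ratios[i]`:
#' `I_off = i0_scale`, `I_on = i0_scale (1 - ratio) + noise`. The
#' noise-free table round-trips through [epitope_from_peaks()] to the
#' rescaled profile.
#'
#' @param ratios Named numeric vector of true saturation-transfer ratios,
#'   each in (0, 1); names are proton labels.
#' @param shifts Optional chemical shifts (ppm), same length.
#' @param i0_scale Off-resonance reference intensity.
#' @param noise_sd Additive Gaussian noise SD on the on-resonance
#'   intensities (absolute units).
#' @param seed RNG seed.
#' @return data.frame with columns `proton`, `shift_ppm`, `i_off`, `i_on`,
#'   `i_std`, plus a `truth` attribute holding the input profile.
#' @export
gen_std_table <- function(ratios, shifts = NA_real_, i0_scale = 1,
                          noise_sd = 0, seed = 1) {
  if (any(ratios <= 0 | ratios >= 1))
    stop("true STD ratios must lie strictly inside (0, 1)")
  labels <- if (!is.null(names(ratios))) names(ratios)
            else as.character(seq_along(ratios))
  with_seed(seed, {
    i_on <- i0_scale * (1 - ratios) +
      stats::rnorm(length(ratios), 0, noise_sd)
    d <- data.frame(proton = labels,
                    shift_ppm = rep_len(shifts, length(ratios)),
                    i_off = i0_scale, i_on = i_on,
                    i_std = i0_scale - i_on,
                    stringsAsFactors = FALSE)
    attr(d, "truth") <- ratios
    d
  })
}

#' Generate a synthetic DLS autocorrelation trace with known diameter
#'
#' Computes the diffusion coefficient of a sphere of diameter `d_h` from
#' the Stokes-Einstein relation, the decay rate `Gamma = D q^2`, and emits
#' `g2 - 1 = beta exp(-2 Gamma tau)` on a log-spaced lag grid spanning the
#' decay, plus additive Gaussian noise. The noise-free trace round-trips
#' through [analyze_trace()] to `d_h`.
#'
#' @param d_h True hydrodynamic diameter in m.
#' @param temperature Temperature in K.
#' @param viscosity Solvent viscosity in Pa s (default water at
#'   `temperature`).
#' @param refractive_index,wavelength,scattering_angle Instrument
#'   parameters (defaults: 1.33, 633 nm, 90 degrees).
#' @param beta Coherence (zero-lag) intercept.
#' @param n_lags Number of lag points.
#' @param noise_sd Additive noise SD on g2 - 1.
#' @param seed RNG seed.
#' @return A [dls_trace()] with a `truth` attribute (d_h, diffusion,
#'   gamma, q, beta, seed).
#' @export
gen_dls_trace <- function(d_h, temperature = 293.15, viscosity = NULL,
                          refractive_index = 1.33, wavelength = 633e-9,
                          scattering_angle = 90, beta = 1, n_lags = 200,
                          noise_sd = 0, seed = 1) {
  if (d_h <= 0) stop("diameter must be positive")
  if (is.null(viscosity)) viscosity <- water_viscosity(temperature)
  q <- scattering_vector(refractive_index, wavelength, scattering_angle)
  diffusion <- .kB * temperature / (3 * pi * viscosity * d_h)
  gamma <- diffusion * q^2
  tau <- 10^seq(log10(0.005 / (2 * gamma)), log10(6 / (2 * gamma)),
                length.out = n_lags)
  with_seed(seed, {
    g2 <- beta * exp(-2 * gamma * tau) +
      stats::rnorm(n_lags, 0, noise_sd)
    tr <- dls_trace(tau, g2, temperature = temperature,
                    viscosity = viscosity,
                    refractive_index = refractive_index,
                    wavelength = wavelength,
                    scattering_angle = scattering_angle)
    attr(tr, "truth") <- list(d_h = d_h, diffusion = diffusion,
                              gamma = gamma, q = q, beta = beta,
                              noise_sd = noise_sd, seed = seed)
    tr
  })
}

# Minimal rigid ligand used by gen_toy_complex: three carbons and one
# carbonyl-like oxygen, all in the z = 0 plane.
.toy_ligand <- function() {
  data.frame(name = c("C1", "C2", "C3", "O1"),
             element = c("C", "C", "C", "O"),
             x = c(0, 1.4, -1.4, 0), y = c(0, 0, 0, 1.3), z = c(0, 0, 0, 0),
             stringsAsFactors = FALSE)
}

#' Generate a toy protein-ligand complex as PDB text
#'
#' Builds a synthetic complex with full geometric control: a small rigid
#' ligand (HETATM residue `LIG`) surrounded by single-contact-atom
#' residues. Residues listed in `contact_resno` have their contact atom
#' placed exactly `contact_distance` from its nearest ligand atom; all
#' other residues are kept at least `far_distance` away. Residues listed
#' in `polar_resno` get an oxygen contact atom aimed at the ligand oxygen
#' (a hydrogen-bond geometry); the rest get carbon. Multi-model files
#' translate the ligand by `drift` Angstrom along +z per model, so contacts
#' are progressively lost.
#'
#' @param n_residues Number of protein residues (>= 1).
#' @param contact_resno Residue numbers intended as ligand contacts.
#' @param contact_distance Exact nearest-atom distance for contacts (A).
#' @param far_distance Minimum ligand distance for all other residues (A).
#' @param polar_resno Subset of `contact_resno` receiving an oxygen contact
#'   atom placed relative to the ligand oxygen.
#' @param n_models Number of models (default 1).
#' @param drift Per-model ligand translation along +z (A).
#' @param file Optional path; when given the PDB text is written there.
#' @param seed RNG seed (contact directions are jittered deterministically).
#' @return A list with `pdb_text` (character vector of lines), `file`
#'   (or NULL), and `truth` (intended contact set, polar set, per-model
#'   ligand offset).
#' @export
gen_toy_complex <- function(n_residues, contact_resno = integer(),
                            contact_distance = 3.0, far_distance = 8,
                            polar_resno = integer(), n_models = 1,
                            drift = 0, file = NULL, seed = 1) {
  if (n_residues < 1L) stop("n_residues must be >= 1")
  if (!all(contact_resno %in% seq_len(n_residues)))
    stop("infeasible pocket: contact residues outside 1..n_residues")
  if (!all(polar_resno %in% contact_resno))
    stop("infeasible pocket: polar residues must be contact residues")
  if (contact_distance >= far_distance)
    stop("infeasible pocket: contact_distance must be < far_distance")
  lig <- .toy_ligand()
  lig_xyz <- as.matrix(lig[, c("x", "y", "z")])
  ctr <- colMeans(lig_xyz)
  # one outward unit direction per residue (golden-angle spiral in the
  # xy-plane keeps z = 0, so +z ligand drift strictly increases distances)
  ang <- (seq_len(n_residues) - 1) * 2.399963
  dirs <- cbind(cos(ang), sin(ang), 0)
  res <- vector("list", n_residues)
  for (i in seq_len(n_residues)) {
    is_contact <- i %in% contact_resno
    is_polar <- i %in% polar_resno
    target <- if (is_polar) 4L else 1L + (i %% 3L)   # ligand atom index
    a0 <- lig_xyz[target, ]
    out <- a0 - ctr
    out[3] <- 0
    nrm <- sqrt(sum(out^2))
    u <- if (nrm > 1e-8) out / nrm else dirs[i, ]
    # blend the radial direction with the residue's own spiral direction,
    # staying in the xy-plane; unit length preserves exact placement
    w <- 0.7 * u + 0.5 * dirs[i, ]
    w <- w / sqrt(sum(w^2))
    d0 <- if (is_contact) contact_distance else far_distance + 1.5
    p <- a0 + d0 * w
    dmin <- min(sqrt(rowSums(sweep(lig_xyz, 2, p)^2)))
    if (is_contact && dmin < contact_distance - 1e-9) {
      # another ligand atom ended up closer; push along w until the
      # nearest-atom distance equals the requested contact distance
      f <- function(s) min(sqrt(rowSums(sweep(lig_xyz, 2, a0 + s * w)^2))) -
        contact_distance
      d0 <- stats::uniroot(f, c(contact_distance, contact_distance + 10))$root
      p <- a0 + d0 * w
    }
    if (!is_contact && dmin < far_distance)
      stop("infeasible pocket: could not place residue ", i,
           " beyond far_distance")
    cname <- if (is_polar) "OG" else "CB"
    celem <- if (is_polar) "O" else "C"
    rname <- if (is_polar) "SER" else "ALA"
    # backbone dummies strictly farther out along w than the contact atom
    bb <- rbind(p + 1.5 * w, p + 2.4 * w, p + 3.3 * w, p + 4.0 * w)
    res[[i]] <- data.frame(
      name = c(cname, "N", "CA", "C", "O"),
      element = c(celem, "N", "C", "C", "O"),
      resname = rname, resno = i, chain = "A",
      x = c(p[1], bb[, 1]), y = c(p[2], bb[, 2]), z = c(p[3], bb[, 3]),
      stringsAsFactors = FALSE)
  }
  prot <- do.call(rbind, res)
  models <- character(0)
  offsets <- (seq_len(n_models) - 1) * drift
  for (m in seq_len(n_models)) {
    lines <- character(0)
    if (n_models > 1) lines <- c(lines, sprintf("MODEL     %4d", m))
    serial <- 1L
    for (j in seq_len(nrow(prot))) {
      lines <- c(lines, .pdb_atom_line("ATOM", serial, prot$name[j],
                                       prot$resname[j], prot$chain[j],
                                       prot$resno[j], prot$x[j], prot$y[j],
                                       prot$z[j], prot$element[j]))
      serial <- serial + 1L
    }
    for (j in seq_len(nrow(lig))) {
      lines <- c(lines, .pdb_atom_line("HETATM", serial, lig$name[j], "LIG",
                                       "L", 900L, lig$x[j], lig$y[j],
                                       lig$z[j] + offsets[m], lig$element[j]))
      serial <- serial + 1L
    }
    if (n_models > 1) lines <- c(lines, "ENDMDL")
    models <- c(models, lines)
  }
  pdb_text <- c(models, "END")
  if (!is.null(file)) writeLines(pdb_text, file)
  list(pdb_text = pdb_text, file = file,
       truth = list(contact_resno = sort(contact_resno),
                    polar_resno = sort(polar_resno),
                    contact_distance = contact_distance,
                    far_distance = far_distance,
                    model_offsets = offsets))
}

.pdb_atom_line <- function(record, serial, name, resname, chain, resno,
                           x, y, z, element) {
  name4 <- if (nchar(name) < 4L) sprintf(" %-3s", name) else name
  sprintf("%-6s%5d %4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          record, serial, name4, resname, chain, resno, x, y, z, 1.0, 0.0,
          element)
}
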