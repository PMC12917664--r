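test_that("titration generator is deterministic and van't Hoff-consistent", {
  g1 <- gen_titration(4.5e5, n = 1, delta_h = 11.5, noise_sd_frac = 0.05,
                      seed = 99)
  g2 <- gen_titration(4.5e5, n = 1, delta_h = 11.5, noise_sd_frac = 0.05,
                      seed = 99)
  expect_identical(g1, g2)
  # Ka(T) honours the anchoring at the reference temperature
  expect_equal(g1$truth$ka_by_temperature[g1$truth$temperatures == 299], 4.5e5)
  r <- gas_constant("kcal")
  vh <- vant_hoff_fit(g1$truth$temperatures, g1$truth$ka_by_temperature)
  expect_equal(vh$delta_h, 11.5, tolerance = 1e-8)
  # schedule reaches a 1:1 ligand:protein mole ratio at the last point
  last <- g1$series[["299"]]$spectra[[length(g1$series[["299"]]$spectra)]]
  v0 <- g1$series[["299"]]$initial_volume
  lig_mol <- last$ligand_total * (v0 + last$added_volume)
  prot_mol <- 2e-6 * v0
  expect_equal(lig_mol / prot_mol, 1, tolerance = 1e-9)
})

test_that("noise-free intensities satisfy the isotherm algebraically", {
  g <- gen_titration(1e5, n = 1, absorbance_per_molar = 0, seed = 1)
  s <- g$series[["299"]]
  f <- vapply(s$spectra, spectrum_intensity, numeric(1), mode = "peak")
  vols <- vapply(s$spectra, `[[`, numeric(1), "added_volume")
  dil <- s$initial_volume / (s$initial_volume + vols)
  fcorr <- f / dil
  theta <- (fcorr[1] - fcorr) / fcorr[1]
  truth <- g$truth$points[["299"]]
  expect_equal(theta, truth$theta, tolerance = 1e-10)
})

test_that("estimator dispersion shrinks with the noise level", {
  ka_hat <- function(noise, seeds) vapply(seeds, function(s) {
    g <- gen_titration(4.5e5, n = 1, noise_sd_frac = noise, seed = s)
    fit_titration(g$series[["299"]], stock_conc = 202e-6)$ka
  }, numeric(1))
  seeds <- 1:25
  sd_hi <- sd(ka_hat(0.05, seeds))
  sd_lo <- sd(ka_hat(0.01, seeds))
  expect_lt(sd_lo, sd_hi)
})

test_that("infeasible titration scenarios are rejected", {
  expect_error(gen_titration(1e5, protein_total = 2e-6, stock_conc = 1e-6),
               "infeasible")
  expect_error(gen_titration(1e5, n_points = 3), "n_points")
})

test_that("STD table generator round-trips its epitope profile", {
  ratios <- c("3" = 0.12, "4" = 0.47, "5" = 0.30)
  tab <- gen_std_table(ratios, i0_scale = 2.5, noise_sd = 0)
  expect_equal(tab$i_std / tab$i_off, unname(ratios))
  m <- epitope_from_peaks(tab)
  expect_equal(m$pct, 100 * unname(ratios) / max(ratios))
  # uniform profile: every proton at 100%
  u <- epitope_from_peaks(gen_std_table(c(a = 0.3, b = 0.3, c = 0.3)))
  expect_equal(u$pct, rep(100, 3))
  # 1% intensity noise keeps the typical worst-proton deviation within a
  # few percentage points (median across seeds, Monte-Carlo derived)
  maxdev <- vapply(1:20, function(s) {
    mn <- epitope_from_peaks(gen_std_table(ratios, i0_scale = 1,
                                           noise_sd = 0.01, seed = s))
    max(abs(mn$pct - m$pct))
  }, numeric(1))
  expect_lt(median(maxdev), 3)
  expect_error(gen_std_table(c(0.5, 1.2)), "inside")
  # determinism
  expect_identical(gen_std_table(ratios, noise_sd = 0.01, seed = 3),
                   gen_std_table(ratios, noise_sd = 0.01, seed = 3))
})

test_that("DLS generator encodes the requested particle and is deterministic", {
  tr <- gen_dls_trace(6.02e-9, beta = 1)
  expect_equal(max(tr$g2_minus_1) <= 1, TRUE)
  truth <- attr(tr, "truth")
  expect_equal(truth$gamma, truth$diffusion * truth$q^2)
  expect_identical(gen_dls_trace(5e-9, noise_sd = 0.01, seed = 4),
                   gen_dls_trace(5e-9, noise_sd = 0.01, seed = 4))
  expect_error(gen_dls_trace(-1e-9), "positive")
})

test_that("generators restore the global RNG state", {
  set.seed(123)
  before <- .Random.seed
  invisible(gen_titration(1e5, noise_sd_frac = 0.05, seed = 7))
  invisible(gen_dls_trace(5e-9, noise_sd = 0.01, seed = 7))
  invisible(gen_std_table(c(a = 0.5), noise_sd = 0.01, seed = 7))
  expect_identical(.Random.seed, before)
})

test_that("toy complex construction honours its pocket specification", {
  gen <- gen_toy_complex(15, contact_resno = c(3, 7, 11),
                         contact_distance = 2.9, far_distance = 7,
                         polar_resno = 7, seed = 4)
  f <- tempfile(fileext = ".pdb")
  writeLines(gen$pdb_text, f)
  cs <- read_complex(f)
  rep34 <- contact_residues(cs, 3.4)
  expect_setequal(rep34$resno, c(3, 7, 11))
  # non-contact residues stay beyond far_distance
  all_min <- contact_residues(cs, 100)
  far <- all_min[!all_min$resno %in% c(3, 7, 11), ]
  expect_true(all(far$min_distance >= 7 - 1e-3))
  expect_error(gen_toy_complex(5, contact_resno = 9), "infeasible")
  expect_error(gen_toy_complex(5, contact_resno = 2, polar_resno = 3),
               "infeasible")
})
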