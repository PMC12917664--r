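test_that("inner-filter correction is the identity at zero absorbance and multiplicative otherwise", {
  expect_equal(correct_inner_filter(100, 0, 0), 100)
  expect_equal(correct_inner_filter(100, 0.1, 0.1), 100 * 10^0.1)
  expect_equal(correct_inner_filter(0, 0.5, 0.5), 0)
  # strictly increasing in each absorbance
  expect_gt(correct_inner_filter(100, 0.2, 0.1), correct_inner_filter(100, 0.1, 0.1))
  expect_gt(correct_inner_filter(100, 0.1, 0.2), correct_inner_filter(100, 0.1, 0.1))
  # multiplicative: correct-then-scale == scale-then-correct
  expect_equal(3 * correct_inner_filter(50, 0.07, 0.02),
               correct_inner_filter(3 * 50, 0.07, 0.02))
  expect_error(correct_inner_filter(-1, 0, 0), "non-negative")
  expect_error(correct_inner_filter(10, -0.1, 0), "non-negative")
})

test_that("quenching fraction covers its range and rejects invalid references", {
  expect_equal(quenching_fraction(100, 100), 0)
  expect_equal(quenching_fraction(100, 0), 1)
  expect_equal(quenching_fraction(100, 75), 0.25)
  expect_lt(quenching_fraction(100, 110), 0)   # negative, flagged downstream
  expect_error(quenching_fraction(0, 10), "positive")
})

test_that("spectrum intensity metrics behave on constructed spectra", {
  wl <- seq(300, 500, by = 1)
  flat <- emission_spectrum(wl, rep(5, length(wl)), 299)
  expect_equal(spectrum_intensity(flat, "peak"), 5)
  expect_equal(spectrum_intensity(flat, "area", window = c(350, 450)), 500)
  tri <- emission_spectrum(wl, pmax(0, 10 - abs(wl - 340) * 0.25), 299)
  expect_equal(spectrum_intensity(tri, "at-wavelength", wavelength = 340), 10)
  expect_error(spectrum_intensity(flat, "at-wavelength", wavelength = 600),
               "span")
  expect_error(spectrum_intensity(flat, "area", window = c(600, 700)))
})

test_that("ligand concentrations follow mass balance with dilution", {
  out <- ligand_concentrations(20e-6, 2e-3, 202e-6)
  expect_equal(out$ligand_conc, 202e-6 * 20 / 2020)
  expect_equal(out$dilution_factor, 2000 / 2020)
  # a 3% total volume change gives the corresponding dilution factor
  out3 <- ligand_concentrations(0.03 * 2e-3, 2e-3, 202e-6)
  expect_equal(out3$dilution_factor, 1 / 1.03)
  expect_equal(nrow(ligand_concentrations(numeric(0), 2e-3, 202e-6)), 0L)
  expect_error(ligand_concentrations(-1e-6, 2e-3, 202e-6), "non-negative")
})

test_that("double-log Hill fit recovers exact isotherm parameters", {
  L <- c(2e-6, 5e-6, 1e-5, 2e-5)
  theta <- L / (L + 1e-5)
  fit <- hill_double_log_fit(L, theta)
  expect_equal(fit$n, 1, tolerance = 1e-10)
  expect_equal(fit$kd, 1e-5, tolerance = 1e-10)
  expect_equal(fit$ka, 1e5, tolerance = 1e-10)
  expect_equal(fit$ka * fit$kd, 1)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  # theta = 0.5 at [L] = Kd gives log-odds zero
  expect_equal(log10(0.5 / (1 - 0.5)), 0)
})

test_that("Hill fit recovery is exact across the (n, Kd) plane", {
  for (n_true in c(0.5, 0.85, 1, 1.5, 2)) {
    for (kd_num in c(1e-7, 1e-5, 1e-3)) {
      L <- 10^seq(log10(kd_num^(1 / n_true)) - 1,
                  log10(kd_num^(1 / n_true)) + 1, length.out = 8)
      theta <- L^n_true / (L^n_true + kd_num)
      fit <- hill_double_log_fit(L, theta)
      expect_equal(fit$n, n_true, tolerance = 1e-7)
      expect_equal(fit$kd, kd_num, tolerance = 1e-6 * kd_num)
    }
  }
})

test_that("Hill regression equals a direct least-squares minimization oracle", {
  set.seed(42)
  L <- 10^seq(-6, -4.5, length.out = 10)
  theta <- L^0.9 / (L^0.9 + 3e-5)
  theta <- pmin(0.999, pmax(1e-4, theta * (1 + rnorm(10, 0, 0.03))))
  fit <- hill_double_log_fit(L, theta)
  x <- log10(L); y <- log10(theta / (1 - theta))
  ssr <- function(p) sum((y - (p[1] * x + p[2]))^2)
  opt <- optim(c(1, 0), ssr, method = "Nelder-Mead",
               control = list(reltol = 1e-14, maxit = 5000))
  expect_equal(fit$n, opt$par[1], tolerance = 1e-6)
  expect_equal(fit$intercept, opt$par[2], tolerance = 1e-5)
})

test_that("Hill fit excludes out-of-range theta and errors on degenerate data", {
  L <- c(1e-6, 2e-6, 5e-6, 1e-5, 2e-5)
  theta <- c(-0.05, 0.2, 0.4, 0.6, 1.2)   # first and last inadmissible
  fit <- hill_double_log_fit(L, theta)
  expect_equal(fit$points_used, 3L)
  expect_equal(fit$excluded, c(1L, 5L))
  expect_error(hill_double_log_fit(c(1e-6, 2e-6), c(0.2, 0.4)), "insufficient")
  expect_error(hill_double_log_fit(L, rep(1.5, 5)), "degenerate")
})

test_that("fit_titration chains corrections and recovers generator truth", {
  gen <- gen_titration(4.5e5, n = 1.0, delta_h = 11.5, seed = 7)
  fit <- fit_titration(gen$series[["299"]], stock_conc = 202e-6)
  expect_equal(fit$ka, 4.5e5, tolerance = 1e-8)
  expect_equal(fit$n, 1.0, tolerance = 1e-8)
  # with inner-filter absorbances and dilution present, the chain still
  # recovers the truth exactly (corrections are exact inverses)
  gen2 <- gen_titration(6.4e4, n = 0.85, delta_h = 15.8,
                        absorbance_per_molar = 400, seed = 7)
  fit2 <- fit_titration(gen2$series[["295"]], stock_conc = 202e-6)
  expect_equal(fit2$ka, gen2$truth$ka_by_temperature[1], tolerance = 1e-8)
  expect_equal(fit2$n, 0.85, tolerance = 1e-8)
  # fitted theta is monotone in [L] for isotherm data
  expect_true(all(diff(fit$points$theta) >= -1e-12))
})

test_that("noisy titrations recover Ka within Monte-Carlo tolerance", {
  # The double-log intercept extrapolates several decades beyond the
  # titrated ligand range, so Ka recovery is acutely noise-sensitive;
  # at instrument-level (0.2%) multiplicative noise the median relative
  # error across seeds stays within 15% (Monte-Carlo derived).
  ka_hat <- vapply(1:20, function(s) {
    gen <- gen_titration(4.5e5, n = 1.0, noise_sd_frac = 0.002, seed = s)
    fit_titration(gen$series[["299"]], stock_conc = 202e-6)$ka
  }, numeric(1))
  expect_lt(median(abs(ka_hat - 4.5e5)) / 4.5e5, 0.15)
})

test_that("series validation catches malformed input", {
  wl <- seq(300, 500, by = 2)
  s0 <- emission_spectrum(wl, rep(1, length(wl)), 299, ligand_total = 0)
  s1 <- emission_spectrum(wl, rep(0.9, length(wl)), 299, ligand_total = 1e-6)
  expect_s3_class(titration_series(list(s0, s1), 2e-6, 7, 2e-3),
                  "titration_series")
  expect_error(titration_series(list(s1, s0), 2e-6, 7, 2e-3), "reference")
  s2 <- emission_spectrum(wl, rep(1, length(wl)), 303, ligand_total = 2e-6)
  expect_error(titration_series(list(s0, s2), 2e-6, 7, 2e-3), "temperature")
  expect_error(emission_spectrum(rev(wl), rep(1, length(wl)), 299),
               "increasing")
})
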