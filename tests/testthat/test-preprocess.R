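test_that("despike leaves clean spectra untouched and is idempotent", {
  s <- single_gaussian_spectrum()
  d <- despike(s)
  expect_identical(d$intensities, s$intensities)
  noisy <- generate_spectrum(synthetic_spectrum_spec(
    data.frame(center = 1650, rel_area = 1, fwhm = 20),
    noise_sd = 0.01, seed = 11))
  d1 <- despike(noisy)
  expect_identical(despike(d1)$intensities, d1$intensities)
})

test_that("despike replaces spike points and nothing else", {
  spec <- synthetic_spectrum_spec(
    data.frame(center = 1650, rel_area = 1, fwhm = 20),
    noise_sd = 0.005, seed = 42)
  s <- generate_spectrum(spec)
  clean <- attr(s, "clean")
  noise_sd <- 0.005 * max(clean)

  for (spike_idx in list(30L, c(60L, 61L))) {  # single and adjacent pair
    y <- s$intensities
    y[spike_idx] <- y[spike_idx] + 50 * max(clean)
    spiked <- raman_spectrum(s$wavenumbers, y)
    d <- despike(spiked)
    expect_lt(max(abs(d$intensities[spike_idx] - clean[spike_idx])),
              3 * noise_sd)
    expect_identical(d$intensities[-spike_idx], y[-spike_idx])
  }

  expect_error(despike(s, preprocess_config(despike_window = 999)), "larger")
})

test_that("polynomial baseline removes its exact degree and zero input", {
  w <- seq(1590, 1710, by = 1)
  u <- (w - 1650) / 60
  cubic <- 2 + 0.5 * u - 1.2 * u^2 + 0.8 * u^3
  s <- raman_spectrum(w, cubic)
  cfg <- preprocess_config(baseline_method = "polynomial")
  out <- baseline_correct(s, cfg)
  expect_lt(max(abs(out$intensities)), 1e-6 * diff(range(cubic)))

  zero <- baseline_correct(raman_spectrum(w, rep(0, length(w))), cfg)
  expect_equal(zero$intensities, rep(0, length(w)))

  expect_error(
    baseline_correct(raman_spectrum(w[1:3], cubic[1:3]),
                     preprocess_config(baseline_method = "polynomial",
                                       baseline_order = 5L)),
    "order")
})

test_that("baseline estimators recover a known cubic under Gaussian bands", {
  # baseline estimation runs on a wide region (here 1500-1800) before the
  # amide-I crop, so the estimators see baseline-only stretches either side
  spec <- synthetic_spectrum_spec(
    data.frame(center = c(1620, 1665), rel_area = c(40, 60), fwhm = 20),
    grid = c(1500, 1800, 1),
    baseline_coeffs = c(0.01, 0.004, 0.006, -0.003))
  s <- generate_spectrum(spec)
  clean <- attr(s, "clean")
  peak <- max(clean)

  out <- baseline_correct(s, preprocess_config(baseline_method = "polynomial"))
  expect_lt(max(abs(out$intensities - clean)), 0.02 * peak)
  expect_gt(min(out$intensities), -0.02 * peak)
  expect_length(attr(out, "baseline"), length(clean))

  # the Whittaker-penalized ALS estimate resists genuine baseline curvature,
  # so it carries a larger (still bounded) bias on a strongly cubic
  # background; its corrected signal must stay near-nonnegative
  als <- baseline_correct(s, preprocess_config(als_lambda = 1e4))
  base_mag <- max(abs(attr(s, "baseline")))
  expect_lt(max(abs(als$intensities - clean)), 0.5 * base_mag)
  expect_gt(min(als$intensities), -0.05 * peak)
})

test_that("vector normalization follows the 3-4-5 contract and is idempotent", {
  s <- vector_normalize(raman_spectrum(c(1600, 1604), c(3, 4)))
  expect_equal(s$intensities, c(0.6, 0.8), tolerance = 1e-15)
  again <- vector_normalize(s)
  expect_equal(again$intensities, s$intensities, tolerance = 1e-12)

  any_s <- single_gaussian_spectrum()
  expect_equal(sqrt(sum(vector_normalize(any_s)$intensities^2)), 1,
               tolerance = 1e-12)
  expect_error(vector_normalize(raman_spectrum(c(1600, 1604), c(0, 0))),
               "all-zero")
})

test_that("averaging is the pointwise mean and commutes with scaling", {
  w <- seq(1600, 1700, by = 2)
  base <- single_gaussian_spectrum(grid = c(1600, 1700, 2))
  identical_set <- spectrum_set(rep(list(base), 30L))
  avg <- average_spectra(identical_set)
  expect_equal(avg$intensities, base$intensities)
  expect_identical(avg$meta$n_averaged, 30L)

  two <- spectrum_set(list(raman_spectrum(w, rep(0, length(w))),
                           raman_spectrum(w, rep(2, length(w)))))
  expect_equal(average_spectra(two)$intensities, rep(1, length(w)))

  # mean of 30 noisy realizations within 4*sd/sqrt(30) of the clean trace
  sd_frac <- 0.02
  reals <- lapply(1:30, function(i) {
    generate_spectrum(synthetic_spectrum_spec(
      data.frame(center = 1650, rel_area = 1, fwhm = 20),
      noise_sd = sd_frac, seed = 100 + i))
  })
  clean <- attr(reals[[1L]], "clean")
  noise_sd <- sd_frac * max(clean)
  avg30 <- average_spectra(spectrum_set(reals))
  expect_lt(max(abs(avg30$intensities - clean)), 4 * noise_sd / sqrt(30))

  scaled <- spectrum_set(lapply(reals, function(s) {
    set_int <- s
    set_int$intensities <- s$intensities * 3
    set_int
  }))
  expect_equal(average_spectra(scaled)$intensities, 3 * avg30$intensities,
               tolerance = 1e-12)

  other_grid <- raman_spectrum(w + 1, base$intensities)
  expect_error(spectrum_set(list(base, other_grid)), "resampl")
})

test_that("Savitzky-Golay smoothing reproduces polynomials and damps noise", {
  w <- seq(1600, 1700, by = 1)
  quad <- 3 + 0.1 * (w - 1650) + 0.002 * (w - 1650)^2
  out <- smooth_sg(raman_spectrum(w, quad))
  expect_equal(out$intensities, quad, tolerance = 1e-9)

  noise <- generate_spectrum(synthetic_spectrum_spec(
    data.frame(center = 1650, rel_area = 1e-12, fwhm = 20),
    noise_sd = 1, seed = 5))
  expect_lt(var(smooth_sg(noise)$intensities), var(noise$intensities))

  noisy_band <- generate_spectrum(synthetic_spectrum_spec(
    data.frame(center = 1650, rel_area = 1, fwhm = 20),
    noise_sd = 0.05, seed = 7))
  clean <- attr(noisy_band, "clean")
  rms <- function(v) sqrt(mean(v^2))
  expect_lt(rms(smooth_sg(noisy_band)$intensities - clean),
            rms(noisy_band$intensities - clean))

  irregular <- raman_spectrum(c(1600, 1601, 1603, 1604, 1606, 1607, 1609, 1610),
                              rnorm(8))
  expect_error(smooth_sg(irregular), "uniform")
})

test_that("cropping keeps the closed interval and enforces minimum size", {
  grid <- seq(200, 4000, by = 4)
  s <- raman_spectrum(grid, seq_along(grid))
  cropped <- crop_spectrum(s, 1590, 1710)
  expect_identical(length(cropped$wavenumbers),
                   sum(grid >= 1590 & grid <= 1710))  # enumeration: 30 points
  expect_identical(length(cropped$wavenumbers), 30L)
  expect_true(all(cropped$wavenumbers >= 1590 & cropped$wavenumbers <= 1710))

  full <- crop_spectrum(s, 200, 4000)
  expect_identical(full$wavenumbers, s$wavenumbers)

  low <- raman_spectrum(seq(500, 900, by = 4), rep(1, 101))
  expect_error(crop_spectrum(low, 1600, 1700), "points")
})

test_that("the chain reproduces a clean spectrum up to the normalization scalar", {
  spec <- amide_preset("control")
  s <- generate_spectrum(spec)
  clean <- attr(s, "clean")

  no_sg <- preprocess(s, preprocess_config(
    baseline_method = "none", stages = c("despike", "normalize", "crop")))
  scale <- sqrt(sum(clean^2))
  expect_lt(max(abs(no_sg$intensities - clean / scale)) / max(clean / scale),
            1e-6)

  with_sg <- preprocess(s, preprocess_config(
    baseline_method = "none",
    stages = c("despike", "normalize", "smooth", "crop")))
  expect_lt(max(abs(with_sg$intensities - clean / scale)) / max(clean / scale),
            0.02)
})

test_that("resampling puts unequal grids onto one common grid", {
  a <- single_gaussian_spectrum(grid = c(1600, 1700, 1))
  b <- single_gaussian_spectrum(grid = c(1600, 1700, 0.5))
  common <- seq(1601, 1699, by = 1)
  set <- resample_spectra(list(a, b), common)
  expect_s3_class(set, "spectrum_set")
  expect_equal(set$spectra[[1L]]$wavenumbers, common)
  expect_equal(set$spectra[[1L]]$intensities, set$spectra[[2L]]$intensities,
               tolerance = 1e-3)
  expect_error(resample_spectra(list(a), seq(1500, 1700, 1)), "extrapolate")
})
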