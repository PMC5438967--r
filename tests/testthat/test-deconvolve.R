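test_that("a single Gaussian yields one candidate at its center", {
  s <- single_gaussian_spectrum(center = 1670)
  centers <- second_derivative_bands(s)
  expect_length(centers, 1L)
  expect_lte(abs(centers - 1670), 1)  # one grid step
})

test_that("second-derivative candidates match the analytic-derivative oracle", {
  cases <- list(
    list(centers = c(1608, 1622, 1642, 1665, 1685),
         pct = c(10, 5, 10, 60, 15)),
    list(centers = c(1608, 1634, 1670), pct = c(6, 5, 89)),
    list(centers = c(1620, 1660), pct = c(50, 50))
  )
  for (cs in cases) {
    oracle <- analytic_d2_minima(cs$centers, cs$pct, fwhm = 20)
    s <- generate_spectrum(synthetic_spectrum_spec(
      data.frame(center = cs$centers, rel_area = cs$pct, fwhm = 20)))
    found <- second_derivative_bands(s, fit_config(min_band_separation = 0.5))
    expect_length(found, length(oracle))
    expect_lt(max(abs(found - oracle)), 1)
  }
})

test_that("candidates closer than the separation threshold merge to the deeper one", {
  s <- generate_spectrum(synthetic_spectrum_spec(
    data.frame(center = c(1648, 1652), rel_area = c(30, 70), fwhm = 20)))
  centers <- second_derivative_bands(s, fit_config(min_band_separation = 8))
  expect_length(centers, 1L)
  expect_lt(abs(centers - 1651), 3)
})

test_that("a noiseless single Gaussian is recovered essentially exactly", {
  s <- single_gaussian_spectrum(center = 1670, fwhm = 20)
  res <- fit_gaussians(s, centers = 1668)  # deliberately offset seed
  expect_identical(nrow(res$bands), 1L)
  expect_lt(abs(res$bands$center - 1670), 0.1)
  expect_lt(abs(res$bands$fwhm - 20), 0.2)
  expect_lt(abs(res$bands$area - 1), 0.005)
})

test_that("the reference three-band mixture recovers its relative areas", {
  truth <- group_truth$reference_ab42
  s <- generate_spectrum(synthetic_spectrum_spec(
    data.frame(center = truth$center, rel_area = truth$pct, fwhm = 20)))
  res <- fit_gaussians(s, centers = truth$center)
  rel <- 100 * res$bands$area / sum(res$bands$area)
  expect_lt(max(abs(rel - truth$pct)), 1)
})

test_that("mean recovery under 1% noise stays within 2 percent points", {
  truth <- group_truth$reference_ab42
  rel_beta <- vapply(1:20, function(seed) {
    s <- generate_spectrum(synthetic_spectrum_spec(
      data.frame(center = truth$center, rel_area = truth$pct, fwhm = 20),
      noise_sd = 0.01, seed = seed))
    res <- fit_gaussians(s, centers = truth$center)
    100 * res$bands$area[3L] / sum(res$bands$area)
  }, numeric(1))
  expect_lt(abs(mean(rel_beta) - 89), 2)
})

test_that("fits reconstruct the signal and conserve total area", {
  for (g in c("control", "d60")) {
    truth <- group_truth[[g]]
    s <- generate_spectrum(synthetic_spectrum_spec(
      data.frame(center = truth$center, rel_area = truth$pct, fwhm = 20)))
    res <- fit_gaussians(s, centers = truth$center)
    expect_gte(res$r_squared, 0.995)
    w <- s$wavenumbers
    trapz <- sum(diff(w) * (s$intensities[-1L] + s$intensities[-length(w)]) / 2)
    expect_lt(abs(sum(res$bands$area) - trapz) / trapz, 0.02)
  }
})

test_that("parameter recovery holds when centers are at least 0.7 FWHM apart", {
  truth <- group_truth$control  # minimum gap 14 = 0.7 x FWHM 20
  s <- generate_spectrum(synthetic_spectrum_spec(
    data.frame(center = truth$center, rel_area = truth$pct, fwhm = 20)))
  res <- fit_gaussians(s, centers = truth$center)
  expect_lt(max(abs(res$bands$center - truth$center)), 1)
  rel <- 100 * res$bands$area / sum(res$bands$area)
  expect_lt(max(abs(rel - truth$pct)), 2)
})

test_that("fitting is deterministic", {
  truth <- group_truth$d60
  s <- generate_spectrum(synthetic_spectrum_spec(
    data.frame(center = truth$center, rel_area = truth$pct, fwhm = 20)))
  r1 <- fit_gaussians(s, centers = truth$center)
  r2 <- fit_gaussians(s, centers = truth$center)
  expect_identical(r1$bands, r2$bands)
  expect_identical(r1$r_squared, r2$r_squared)
})

test_that("unresolvable close pairs come back as one band carrying both areas", {
  s <- generate_spectrum(synthetic_spectrum_spec(
    data.frame(center = c(1658, 1662), rel_area = c(40, 30), fwhm = 20)))
  centers <- second_derivative_bands(s)  # merge threshold 8 > separation 4
  expect_length(centers, 1L)
  res <- fit_gaussians(s, centers)
  expect_lt(abs(sum(res$bands$area) - 1) / 1, 0.03)
})

test_that("degenerate fitting inputs are rejected", {
  s <- single_gaussian_spectrum()
  expect_error(fit_gaussians(s, centers = 1500), "inside the fit region")
  tiny <- crop_spectrum(s, 1660, 1672)
  expect_error(fit_gaussians(tiny, centers = c(1662, 1666, 1670)),
               "3 points per free parameter")
})

test_that("abundances are area fractions with optional structural-only view", {
  s <- generate_spectrum(synthetic_spectrum_spec(
    data.frame(center = c(1635, 1665), rel_area = c(1, 3), fwhm = 16)))
  res <- fit_gaussians(s, centers = c(1635, 1665))
  res <- compute_abundances(res)
  expect_equal(unname(res$abundance[c("aromatic_ring", "alpha_helix")]),
               c(25, 75), tolerance = 0.1)
  expect_equal(sum(res$abundance), 100, tolerance = 0.1)

  only <- compute_abundances(res, exclude_non_structural = TRUE)
  expect_equal(unname(only$abundance["alpha_helix"]), 100, tolerance = 0.1)

  one <- fit_gaussians(single_gaussian_spectrum(center = 1665), centers = 1665)
  one <- compute_abundances(one)
  expect_equal(unname(one$abundance["alpha_helix"]), 100, tolerance = 1e-6)
})
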