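# shared fixtures: published per-group amide-I inventories (centers in 1/cm,
# relative abundances in %), used as generator truth across the suite
group_truth <- list(
  reference_ab42 = data.frame(
    center = c(1608, 1634, 1670), pct = c(6, 5, 89),
    label = c("side_chain", "aromatic_ring", "beta_sheet")),
  control = data.frame(
    center = c(1608, 1622, 1642, 1665, 1685), pct = c(10, 5, 10, 60, 15),
    label = c("side_chain", "aromatic_ring", "unordered", "alpha_helix",
              "beta_turn")),
  d7 = data.frame(
    center = c(1615, 1649, 1668, 1683), pct = c(8, 33, 47, 12),
    label = c("side_chain", "unordered", "alpha_helix", "beta_turn")),
  d15 = data.frame(
    center = c(1602, 1619, 1644, 1662, 1681), pct = c(9, 13, 16, 46, 16),
    label = c("side_chain", "aromatic_ring", "unordered", "alpha_helix",
              "beta_turn")),
  d30 = data.frame(
    center = c(1623, 1650, 1661, 1680), pct = c(6, 30, 41, 23),
    label = c("aromatic_ring", "unordered", "alpha_helix", "beta_turn")),
  d60 = data.frame(
    center = c(1609, 1630, 1652, 1671, 1690), pct = c(5, 16, 22, 52, 5),
    label = c("side_chain", "aromatic_ring", "alpha_helix", "beta_sheet",
              "beta_turn")),
  d90 = data.frame(
    center = c(1610, 1635, 1655, 1672, 1695), pct = c(15, 13, 20, 48, 4),
    label = c("side_chain", "aromatic_ring", "alpha_helix", "beta_sheet",
              "beta_turn"))
)

# a single clean Gaussian spectrum on the default grid
single_gaussian_spectrum <- function(center = 1670, fwhm = 20,
                                     grid = c(1590, 1710, 1)) {
  generate_spectrum(synthetic_spectrum_spec(
    data.frame(center = center, rel_area = 1, fwhm = fwhm), grid = grid))
}

# analytic second derivative of a Gaussian mixture with unit total area
mixture_d2 <- function(x, centers, rel_areas, fwhm) {
  areas <- rel_areas / sum(rel_areas)
  sig <- fwhm / (2 * sqrt(2 * log(2)))
  out <- numeric(length(x))
  for (i in seq_along(centers)) {
    a <- areas[i] / (sig * sqrt(2 * pi))
    u <- (x - centers[i]) / sig
    out <- out + a / sig^2 * (u^2 - 1) * exp(-u^2 / 2)
  }
  out
}

# independent oracle: minima of the analytic second derivative located by
# sign-change enumeration on a fine grid, refined with optimize()
analytic_d2_minima <- function(centers, rel_areas, fwhm,
                               lo = 1590, hi = 1710) {
  x <- seq(lo, hi, by = 0.05)
  d2 <- mixture_d2(x, centers, rel_areas, fwhm)
  i <- which(diff(sign(diff(d2))) == 2) + 1L
  i <- i[d2[i] < 0]
  vapply(i, function(j) {
    stats::optimize(function(z) mixture_d2(z, centers, rel_areas, fwhm),
                    lower = x[j] - 0.1, upper = x[j] + 0.1)$minimum
  }, numeric(1))
}

# run the noiseless round-trip pipeline for one preset group
roundtrip_group <- function(group, noise_sd = 0, seed = NULL) {
  spec <- amide_preset(group, noise_sd = noise_sd, seed = seed)
  stages <- if (noise_sd > 0) c("despike", "normalize", "smooth", "crop")
            else c("smooth", "crop")
  s <- preprocess(generate_spectrum(spec),
                  preprocess_config(baseline_method = "none", stages = stages))
  deconvolve_spectrum(s, fit_config(center_seeds = spec$meta$center_seeds),
                      overrides = default_overrides(group))
}
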