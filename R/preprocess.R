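#' Preprocessing configuration
#'
#' Bundles every tunable of the preprocessing chain
#' despike -> baseline -> vector-normalize -> average -> Savitzky-Golay
#' smooth -> crop. Each stage can be switched off individually, so the same
#' chain serves raw instrument exports (all stages on) and already
#' baseline-corrected data (baseline `"none"`).
#'
#' @param despike_z Modified z-score threshold for cosmic-ray detection
#'   (unitless, default 8).
#' @param despike_window Odd running-median window in points (default 5).
#' @param baseline_method `"asymmetric_least_squares"` (default),
#'   `"polynomial"` (iteratively clipped polynomial), or `"none"`.
#' @param baseline_order Polynomial degree for the polynomial method
#'   (default 3).
#' @param als_lambda,als_p Smoothness and asymmetry parameters of the
#'   asymmetric least-squares baseline (defaults 1e5 and 0.01).
#' @param sg_window Odd Savitzky-Golay window in points (default 5).
#' @param sg_polyorder Savitzky-Golay polynomial order, `< sg_window`
#'   (default 2).
#' @param norm Normalization; only `"vector"` (unit Euclidean norm) or
#'   `"none"`.
#' @param crop_lo,crop_hi Crop interval in 1/cm (defaults 1590 and 1710,
#'   slightly wider than the 1600-1700 amide I core so the ~1604 and
#'   ~1612 1/cm shoulder bands stay inside the fit region).
#' @param stages Character vector selecting which stages run, in fixed
#'   order; subset of
#'   `c("despike", "baseline", "normalize", "average", "smooth", "crop")`.
#' @return A list of class `preprocess_config`.
#' @export
preprocess_config <- function(despike_z = 8,
                              despike_window = 5L,
                              baseline_method = c("asymmetric_least_squares",
                                                  "polynomial", "none"),
                              baseline_order = 3L,
                              als_lambda = 1e5,
                              als_p = 0.01,
                              sg_window = 5L,
                              sg_polyorder = 2L,
                              norm = c("vector", "none"),
                              crop_lo = 1590,
                              crop_hi = 1710,
                              stages = c("despike", "baseline", "normalize",
                                         "average", "smooth", "crop")) {
  baseline_method <- match.arg(baseline_method)
  norm <- match.arg(norm)
  stages <- match.arg(stages, several.ok = TRUE)
  if (sg_window < 3L || sg_window %% 2L == 0L) {
    stop("sg_window must be odd and >= 3")
  }
  if (sg_polyorder >= sg_window) stop("sg_polyorder must be < sg_window")
  if (despike_window < 3L || despike_window %% 2L == 0L) {
    stop("despike_window must be odd and >= 3")
  }
  if (crop_lo >= crop_hi) stop("crop_lo must be < crop_hi")
  structure(
    list(despike_z = despike_z, despike_window = as.integer(despike_window),
         baseline_method = baseline_method,
         baseline_order = as.integer(baseline_order),
         als_lambda = als_lambda, als_p = als_p,
         sg_window = as.integer(sg_window),
         sg_polyorder = as.integer(sg_polyorder),
         norm = norm, crop_lo = crop_lo, crop_hi = crop_hi,
         stages = stages),
    class = "preprocess_config"
  )
}

#' Remove cosmic-ray spikes
#'
#' Cosmic rays hit the CCD as one- or two-pixel artifacts far sharper than
#' any Raman band. Points whose detail signal (intensity minus running
#' median over `despike_window`) has a modified z-score above `despike_z`
#' are replaced by the running-median value; all other points pass through
#' untouched, which makes the operation idempotent. The z-score scale is
#' floored at 1% of the intensity range: the detail signal of a smooth,
#' noise-free band never exceeds about 1% of the range (peak-curvature
#' residue of the running median), so clean spectra are never flagged,
#' while genuine cosmic-ray spikes sit orders of magnitude above the floor.
#'
#' @param s A [raman_spectrum()].
#' @param cfg A [preprocess_config()].
#' @return The despiked spectrum.
#' @export
despike <- function(s, cfg = preprocess_config()) {
  stopifnot(is_raman_spectrum(s))
  y <- s$intensities
  k <- cfg$despike_window
  if (k > length(y)) {
    stop("despike_window (", k, ") larger than spectrum (", length(y), ")")
  }
  med <- stats::runmed(y, k, endrule = "median")
  detail <- y - med
  scale <- stats::mad(detail, center = 0)
  floor_scale <- 0.01 * diff(range(y))
  scale <- max(scale, floor_scale, .Machine$double.eps)
  z <- abs(detail) / scale
  hit <- z > cfg$despike_z
  if (any(hit)) y[hit] <- med[hit]
  set_intensities(s, y, meta = list(despiked_points = sum(hit)))
}

#' Subtract a smooth baseline
#'
#' Estimates the slowly varying fluorescence background under the Raman
#' bands and subtracts it. Two estimators are provided:
#' \describe{
#'   \item{asymmetric_least_squares}{Whittaker smoother with asymmetric
#'     weights (points above the current baseline get weight `als_p`,
#'     points below `1 - als_p`), the standard choice for fluorescence
#'     backgrounds in tissue Raman.}
#'   \item{polynomial}{Iteratively clipped polynomial of degree
#'     `baseline_order`: fit, clip the signal to `min(signal, fit)`,
#'     refit until stable. Exact on inputs that are themselves polynomials
#'     of that degree.}
#' }
#' The estimated baseline is attached as attribute `"baseline"` for
#' inspection.
#'
#' @inheritParams despike
#' @return Baseline-corrected spectrum with attribute `"baseline"`.
#' @export
baseline_correct <- function(s, cfg = preprocess_config()) {
  stopifnot(is_raman_spectrum(s))
  y <- s$intensities
  base <- switch(cfg$baseline_method,
    none = rep(0, length(y)),
    polynomial = baseline_poly(s$wavenumbers, y, cfg$baseline_order),
    asymmetric_least_squares = baseline_als(y, cfg$als_lambda, cfg$als_p)
  )
  out <- set_intensities(s, y - base,
                         meta = list(baseline_method = cfg$baseline_method))
  attr(out, "baseline") <- base
  out
}

# iteratively clipped polynomial baseline. Each pass refits the polynomial
# and re-clips from the ORIGINAL signal at fit + rms(residual), so
# baseline-only stretches that an early fit undercut are recovered later
# (clipping from the previous iterate instead would corrupt them for good).
baseline_poly <- function(w, y, order, max_iter = 100L) {
  if (order >= length(y)) {
    stop("polynomial order (", order, ") must be below the number of points (",
         length(y), ")")
  }
  x <- (w - mean(w)) / max(diff(range(w)) / 2, 1)  # scale for conditioning
  X <- stats::poly(x, degree = order, raw = TRUE, simple = TRUE)
  X <- cbind(`(Intercept)` = 1, X)
  z <- y
  dev_prev <- Inf
  fit <- rep(0, length(y))
  for (i in seq_len(max_iter)) {
    co <- stats::lm.fit(X, z)$coefficients
    fit <- drop(X %*% ifelse(is.na(co), 0, co))
    dev <- sqrt(mean((z - fit)^2))
    z <- pmin(y, fit + dev)
    if (abs(dev - dev_prev) <= 1e-12 * max(abs(y), 1e-300)) break
    dev_prev <- dev
  }
  fit
}

# asymmetric least squares (Whittaker smoother with asymmetric weights)
baseline_als <- function(y, lambda = 1e5, p = 0.01, max_iter = 20L) {
  m <- length(y)
  D <- Matrix::bandSparse(m - 2L, m,
                          k = 0:2,
                          diagonals = list(rep(1, m - 2L), rep(-2, m - 2L),
                                           rep(1, m - 2L)))
  DtD <- lambda * Matrix::crossprod(D)
  w <- rep(1, m)
  z <- y
  for (i in seq_len(max_iter)) {
    W <- Matrix::Diagonal(m, w)
    z <- as.numeric(Matrix::solve(W + DtD, w * y))
    w_new <- ifelse(y > z, p, 1 - p)
    if (all(w_new == w)) break
    w <- w_new
  }
  z
}

#' Vector-normalize a spectrum
#'
#' Scales the intensity vector to unit Euclidean norm so spectra acquired
#' at different laser powers or integration times become comparable.
#'
#' @param s A [raman_spectrum()].
#' @return Spectrum with `sqrt(sum(intensities^2)) == 1`.
#' @export
vector_normalize <- function(s) {
  stopifnot(is_raman_spectrum(s))
  nrm <- sqrt(sum(s$intensities^2))
  if (nrm == 0) stop("cannot vector-normalize an all-zero spectrum")
  set_intensities(s, s$intensities / nrm)
}

#' Average the spectra of a set
#'
#' Pointwise arithmetic mean over all members of the set (e.g. the 30
#' point spectra collected across six cells of one tissue section).
#'
#' @param set A [spectrum_set()] whose members share one grid.
#' @return A single [raman_spectrum()]; `meta$n_averaged` records the count.
#' @export
average_spectra <- function(set) {
  if (is_raman_spectrum(set)) return(set)
  if (!inherits(set, "spectrum_set")) {
    stop("average_spectra needs a spectrum_set; to combine loose spectra ",
         "build a set first (mismatched grids: resample_spectra())")
  }
  ymat <- vapply(set$spectra, function(s) s$intensities,
                 numeric(length(set$spectra[[1L]]$wavenumbers)))
  mean_y <- rowMeans(as.matrix(ymat))
  meta <- set$spectra[[1L]]$meta
  meta$n_averaged <- length(set$spectra)
  meta$point_id <- NULL
  raman_spectrum(set$spectra[[1L]]$wavenumbers, mean_y, meta)
}

#' Savitzky-Golay smoothing
#'
#' Local polynomial least-squares smoothing, which preserves band height
#' and width far better than a moving average. Requires a uniform grid;
#' endpoints are handled by evaluating the edge-window polynomial fits at
#' the edge positions.
#'
#' @inheritParams despike
#' @return The smoothed spectrum.
#' @export
smooth_sg <- function(s, cfg = preprocess_config()) {
  stopifnot(is_raman_spectrum(s))
  check_uniform_grid(s$wavenumbers,
                     "smooth_sg needs a uniform grid; resample first")
  if (cfg$sg_window > length(s$intensities)) {
    stop("sg_window (", cfg$sg_window, ") larger than spectrum")
  }
  y <- signal::sgolayfilt(s$intensities, p = cfg$sg_polyorder,
                          n = cfg$sg_window, m = 0)
  set_intensities(s, y, meta = list(sg_window = cfg$sg_window,
                                    sg_polyorder = cfg$sg_polyorder))
}

#' Crop a spectrum to a wavenumber interval
#'
#' Retains the points with `lo <= wavenumber <= hi` (closed interval).
#' The default pipeline crops to 1590-1710 1/cm: the amide I band plus the
#' low-wavenumber shoulder bands that are not baseline-separated from it.
#'
#' @param s A [raman_spectrum()].
#' @param lo,hi Interval bounds in 1/cm.
#' @return The cropped spectrum.
#' @export
crop_spectrum <- function(s, lo = 1590, hi = 1710) {
  stopifnot(is_raman_spectrum(s))
  if (lo >= hi) stop("lo must be < hi")
  keep <- s$wavenumbers >= lo & s$wavenumbers <= hi
  if (sum(keep) < 8L) {
    stop("crop [", lo, ", ", hi, "] leaves ", sum(keep),
         " points (need at least 8)")
  }
  raman_spectrum(s$wavenumbers[keep], s$intensities[keep], s$meta)
}

#' Resample spectra onto a common uniform grid
#'
#' Linear interpolation onto `grid`; used when set members were acquired on
#' unequal grids. Extrapolation is refused.
#'
#' @param set A [spectrum_set()] or list of spectra.
#' @param grid Target wavenumber vector (strictly increasing).
#' @return A [spectrum_set()] on the common grid.
#' @export
resample_spectra <- function(set, grid) {
  spectra <- if (inherits(set, "spectrum_set")) set$spectra else set
  grid <- as.numeric(grid)
  if (any(diff(grid) <= 0)) stop("grid must be strictly increasing")
  out <- lapply(spectra, function(s) {
    if (min(grid) < min(s$wavenumbers) || max(grid) > max(s$wavenumbers)) {
      stop("grid extends beyond spectrum range; refusing to extrapolate")
    }
    y <- stats::approx(s$wavenumbers, s$intensities, xout = grid)$y
    raman_spectrum(grid, y, s$meta)
  })
  spectrum_set(out, group_key = if (inherits(set, "spectrum_set")) set$group_key else "")
}

#' Run the full preprocessing chain
#'
#' Applies, in fixed order, the stages selected in `cfg$stages`:
#' despike -> baseline -> vector-normalize -> average -> SG smooth -> crop.
#' Per-spectrum stages run on every member of a set before averaging.
#'
#' @param x A [raman_spectrum()] or [spectrum_set()].
#' @param cfg A [preprocess_config()].
#' @return A single preprocessed [raman_spectrum()].
#' @export
preprocess <- function(x, cfg = preprocess_config()) {
  stages <- cfg$stages
  per_spectrum <- function(s) {
    if ("despike" %in% stages) s <- despike(s, cfg)
    if ("baseline" %in% stages && cfg$baseline_method != "none") {
      s <- baseline_correct(s, cfg)
    }
    if ("normalize" %in% stages && cfg$norm == "vector") {
      s <- vector_normalize(s)
    }
    s
  }
  if (inherits(x, "spectrum_set")) {
    x <- spectrum_set(lapply(x$spectra, per_spectrum), x$group_key)
    s <- if ("average" %in% stages) average_spectra(x) else x$spectra[[1L]]
  } else {
    s <- per_spectrum(x)
  }
  if ("smooth" %in% stages) s <- smooth_sg(s, cfg)
  if ("crop" %in% stages) s <- crop_spectrum(s, cfg$crop_lo, cfg$crop_hi)
  s
}

check_uniform_grid <- function(w, msg, rel_tol = 1e-6) {
  d <- diff(w)
  if ((max(d) - min(d)) > rel_tol * mean(d)) stop(msg)
  invisible(mean(d))
}
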