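#' Construct a Raman spectrum
#'
#' A `raman_spectrum` is a single wavenumber-ordered intensity trace with a
#' free-form metadata map carried along the whole pipeline (group label,
#' exposure days, cell/point identifiers, processing provenance).
#'
#' @param wavenumbers Numeric vector of wavenumbers in 1/cm, strictly
#'   increasing. Spacing may be non-uniform.
#' @param intensities Numeric vector of intensities (arbitrary counts), same
#'   length as `wavenumbers`, all finite.
#' @param meta Named list of metadata strings/values (e.g. `group`,
#'   `exposure_days`, `cell_id`, `point_id`).
#' @return An object of class `raman_spectrum` with elements `wavenumbers`,
#'   `intensities` and `meta`.
#' @examples
#' s <- raman_spectrum(seq(1600, 1700, by = 4), rnorm(26) + 10)
#' s
#' @export
raman_spectrum <- function(wavenumbers, intensities, meta = list()) {
  wavenumbers <- as.numeric(wavenumbers)
  intensities <- as.numeric(intensities)
  if (length(wavenumbers) != length(intensities)) {
    stop("wavenumbers and intensities must have the same length (",
         length(wavenumbers), " vs ", length(intensities), ")")
  }
  if (length(wavenumbers) < 2L) {
    stop("a spectrum needs at least 2 points")
  }
  if (anyNA(wavenumbers) || any(!is.finite(wavenumbers))) {
    stop("wavenumbers must be finite")
  }
  if (any(diff(wavenumbers) <= 0)) {
    stop("wavenumbers must be strictly increasing")
  }
  bad <- which(!is.finite(intensities))
  if (length(bad)) {
    stop("non-finite intensities at rows: ",
         paste(utils::head(bad, 10L), collapse = ", "))
  }
  structure(
    list(wavenumbers = wavenumbers, intensities = intensities,
         meta = as.list(meta)),
    class = "raman_spectrum"
  )
}

#' @export
print.raman_spectrum <- function(x, ...) {
  cat(sprintf("<raman_spectrum> %d points, %.1f-%.1f cm^-1\n",
              length(x$wavenumbers), min(x$wavenumbers), max(x$wavenumbers)))
  if (length(x$meta)) {
    keep <- vapply(x$meta, function(v) is.atomic(v) && length(v) == 1L,
                   logical(1))
    if (any(keep)) {
      cat("  meta:",
          paste(names(x$meta)[keep], unlist(x$meta[keep], use.names = FALSE),
                sep = "=", collapse = ", "), "\n")
    }
  }
  invisible(x)
}

#' @export
length.raman_spectrum <- function(x) length(x$wavenumbers)

is_raman_spectrum <- function(x) inherits(x, "raman_spectrum")

#' Construct a spectrum set
#'
#' A `spectrum_set` holds several spectra acquired on one common wavenumber
#' grid (for example the 30 point spectra of one tissue section), to be
#' averaged after normalization.
#'
#' @param spectra List of [raman_spectrum()] objects sharing one grid.
#' @param group_key Character label for the set (e.g. exposure group).
#' @return An object of class `spectrum_set`.
#' @export
spectrum_set <- function(spectra, group_key = "") {
  if (!length(spectra)) stop("spectrum_set must be non-empty")
  if (!all(vapply(spectra, is_raman_spectrum, logical(1)))) {
    stop("all elements must be raman_spectrum objects")
  }
  ref <- spectra[[1L]]$wavenumbers
  same <- vapply(spectra, function(s) {
    length(s$wavenumbers) == length(ref) && all(s$wavenumbers == ref)
  }, logical(1))
  if (!all(same)) {
    stop("all member spectra must share one wavenumber grid; ",
         "resample to a common grid first (see resample_spectra())")
  }
  structure(list(spectra = spectra, group_key = as.character(group_key)),
            class = "spectrum_set")
}

#' @export
print.spectrum_set <- function(x, ...) {
  cat(sprintf("<spectrum_set> %d spectra, group '%s', %d points each\n",
              length(x$spectra), x$group_key,
              length(x$spectra[[1L]]$wavenumbers)))
  invisible(x)
}

#' @export
length.spectrum_set <- function(x) length(x$spectra)

# replace intensities, keeping grid and metadata
set_intensities <- function(s, y, meta = NULL) {
  out <- raman_spectrum(s$wavenumbers, y, s$meta)
  if (!is.null(meta)) out$meta[names(meta)] <- meta
  out
}
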