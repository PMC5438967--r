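#' Read a spectrum or a multi-spectrum table from delimited text
#'
#' Reads plain-text spectral exports: either a two-column file
#' (wavenumber, intensity) or a multi-column table (one wavenumber column
#' followed by N intensity columns, e.g. the 30 point spectra of one tissue
#' section). Comma, tab and whitespace delimiters are recognised, with an
#' optional single header line. Files stored in descending wavenumber order
#' are reordered to ascending and flagged in `meta$original_order`.
#'
#' File names following the convention `<group>_<days>d_<cell>_<point>.csv`
#' populate the `group`, `exposure_days`, `cell_id` and `point_id` metadata
#' fields; absent fields default to empty.
#'
#' @param path Path to a delimited text file.
#' @param dialect One of `"auto"` (decide from the column count),
#'   `"two_column"` or `"multi_column"`.
#' @return A [raman_spectrum()] for two-column input, a [spectrum_set()] for
#'   multi-column input.
#' @export
read_spectrum <- function(path, dialect = c("auto", "two_column", "multi_column")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty file: ", path)

  sep <- if (grepl(",", lines[[1L]])) "," else if (grepl("\t", lines[[1L]])) "\t" else ""
  split_row <- function(line) {
    if (sep == "") strsplit(trimws(line), "[[:space:]]+")[[1L]]
    else trimws(strsplit(line, sep, fixed = TRUE)[[1L]])
  }
  first <- split_row(lines[[1L]])
  has_header <- anyNA(suppressWarnings(as.numeric(first)))
  body <- if (has_header) lines[-1L] else lines
  if (!length(body)) stop("no data rows in ", path)

  cells <- lapply(body, split_row)
  ncol <- length(cells[[1L]])
  if (ncol < 2L) stop("need at least 2 columns, got ", ncol, " in ", path)
  if (any(lengths(cells) != ncol)) {
    stop("ragged rows in ", path, " (row ",
         which(lengths(cells) != ncol)[1L] + has_header, ")")
  }
  mat <- matrix(NA_real_, nrow = length(cells), ncol = ncol)
  for (i in seq_along(cells)) {
    v <- suppressWarnings(as.numeric(cells[[i]]))
    if (any(is.na(v) & !is.nan(v))) {
      j <- which(is.na(v) & !is.nan(v))[1L]
      stop("non-numeric cell at row ", i + has_header, ", column ", j,
           " of ", path, ": '", cells[[i]][j], "'")
    }
    mat[i, ] <- v
  }
  if (nrow(mat) < 8L) {
    stop("input too short: ", nrow(mat), " points in ", path,
         " (need at least 8)")
  }
  nan_rows <- which(apply(mat[, -1L, drop = FALSE], 1L,
                          function(r) any(is.nan(r) | !is.finite(r))))
  if (length(nan_rows)) {
    stop("non-finite intensities in ", path, " at rows: ",
         paste(nan_rows + has_header, collapse = ", "))
  }

  meta <- parse_spectrum_filename(path)
  w <- mat[, 1L]
  descending <- all(diff(w) < 0)
  if (descending) {
    mat <- mat[rev(seq_len(nrow(mat))), , drop = FALSE]
    w <- mat[, 1L]
    meta$original_order <- "descending"
  }
  if (any(diff(w) <= 0)) {
    stop("wavenumber column of ", path,
         " is neither strictly increasing nor strictly decreasing")
  }

  if (dialect == "auto") {
    dialect <- if (ncol == 2L) "two_column" else "multi_column"
  }
  if (dialect == "two_column") {
    if (ncol != 2L) stop("two_column dialect but ", ncol, " columns in ", path)
    raman_spectrum(w, mat[, 2L], meta)
  } else {
    spectra <- lapply(seq_len(ncol - 1L), function(j) {
      m <- meta
      m$point_id <- if (is.null(meta$point_id) || meta$point_id == "") as.character(j) else meta$point_id
      raman_spectrum(w, mat[, j + 1L], m)
    })
    spectrum_set(spectra, group_key = if (is.null(meta$group)) "" else meta$group)
  }
}

# <group>_<days>d_<cell>_<point>.csv -> metadata map; absent fields empty
parse_spectrum_filename <- function(path) {
  base <- sub("\\.[^.]*$", "", basename(path))
  parts <- strsplit(base, "_", fixed = TRUE)[[1L]]
  meta <- list(group = "", exposure_days = "", cell_id = "", point_id = "",
               source_file = basename(path))
  if (length(parts) >= 2L && grepl("^[0-9]+d$", parts[[2L]])) {
    meta$group <- parts[[1L]]
    meta$exposure_days <- sub("d$", "", parts[[2L]])
    if (length(parts) >= 3L) meta$cell_id <- parts[[3L]]
    if (length(parts) >= 4L) meta$point_id <- parts[[4L]]
  }
  meta
}

#' Write fitted sub-band results as a delimited table
#'
#' Serializes one row per fitted sub-band per group with the columns
#' `group`, `exposure_days`, `band_id`, `center_cm1`, `area`,
#' `abundance_pct`, `assignment`. Abundances are kept at full precision
#' internally and rounded only here, at serialization.
#'
#' @param results Non-empty list of `deconvolution_result` objects (see
#'   [fit_gaussians()]); `group`/`exposure_days` are taken from each result's
#'   metadata.
#' @param path Output file path (CSV).
#' @param digits Decimal places for the serialized `abundance_pct` column.
#' @return The path, invisibly.
#' @export
write_result_table <- function(results, path, digits = 2L) {
  df <- result_table(results)
  df$abundance_pct <- round(df$abundance_pct, digits)
  tryCatch(
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE),
    error = function(e) stop("cannot write result table to ", path, ": ",
                             conditionMessage(e))
  )
  invisible(path)
}

#' Assemble the per-band result table in memory
#'
#' @inheritParams write_result_table
#' @return A data.frame with one row per sub-band and the seven standard
#'   columns, abundances at full precision.
#' @export
result_table <- function(results) {
  if (!length(results)) stop("empty result list")
  if (inherits(results, "deconvolution_result")) results <- list(results)
  rows <- lapply(results, function(r) {
    if (!inherits(r, "deconvolution_result")) {
      stop("results must be deconvolution_result objects")
    }
    b <- r$bands
    total <- sum(b$area)
    data.frame(
      group = meta_chr(r$meta, "group"),
      exposure_days = meta_int(r$meta, "exposure_days"),
      band_id = seq_len(nrow(b)),
      center_cm1 = b$center,
      area = b$area,
      abundance_pct = 100 * b$area / total,
      assignment = b$label,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

#' Write a full deconvolution result as JSON
#'
#' Machine-readable dump: fitted bands (center, amplitude, fwhm, area,
#' label), fit diagnostics and the motif abundance map.
#'
#' @param result A `deconvolution_result`.
#' @param path Output path (`.json`).
#' @return The path, invisibly.
#' @export
write_result_json <- function(result, path) {
  if (!inherits(result, "deconvolution_result")) {
    stop("result must be a deconvolution_result")
  }
  payload <- list(
    bands = result$bands,
    r_squared = result$r_squared,
    residual_rms = result$residual_rms,
    fit_region = result$fit_region,
    abundance = as.list(result$abundance),
    meta = result$meta
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}

#' Write a spectrum as two-column delimited text
#'
#' @param s A [raman_spectrum()].
#' @param path Output path.
#' @param sep Field separator (default comma).
#' @return The path, invisibly.
#' @export
write_spectrum <- function(s, path, sep = ",") {
  stopifnot(is_raman_spectrum(s))
  df <- data.frame(wavenumber_cm1 = s$wavenumbers, intensity = s$intensities)
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

meta_chr <- function(meta, key) {
  v <- meta[[key]]
  if (is.null(v)) "" else as.character(v)
}

meta_int <- function(meta, key) {
  v <- meta[[key]]
  if (is.null(v) || identical(v, "")) NA_integer_
  else suppressWarnings(as.integer(v))
}
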