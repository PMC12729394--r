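#' Wavelength-by-time coefficient series
#'
#' Container for attenuation/absorption-type coefficient tables: one
#' spectrum (column) per storage time on a common wavelength grid. All
#' coefficients are natural-logarithm based and carried in cm^-1;
#' wavelengths in nm, storage times in hours.
#'
#' @param wavelengths_nm Strictly increasing wavelength grid (nm).
#' @param times_h Strictly increasing storage times (hours).
#' @param values Numeric matrix, `length(wavelengths_nm)` rows by
#'   `length(times_h)` columns, coefficients in cm^-1.
#' @param kind One of `"attenuation"`, `"absorption"`, `"scattering"`,
#'   `"difference"`, `"double_difference"`. Attenuation series must be
#'   nonnegative; difference-type series may have either sign.
#' @param path_length_cm Optical path length of the measurement cell (cm).
#'   The experiments used a 3 mm cell, hence the 0.3 default.
#' @return An object of class `spectral_series`.
#' @export
spectral_series <- function(wavelengths_nm, times_h, values,
                            kind = c("attenuation", "absorption", "scattering",
                                     "difference", "double_difference"),
                            path_length_cm = 0.3) {
  kind <- match.arg(kind)
  wavelengths_nm <- as.numeric(wavelengths_nm)
  times_h <- as.numeric(times_h)
  values <- as.matrix(values)
  if (any(!is.finite(wavelengths_nm)) || any(diff(wavelengths_nm) <= 0))
    stop("wavelengths_nm must be finite and strictly increasing")
  if (any(!is.finite(times_h)) || (length(times_h) > 1 && any(diff(times_h) <= 0)))
    stop("times_h must be finite and strictly increasing")
  if (!all(is.finite(values)))
    stop("values must be finite")
  if (nrow(values) != length(wavelengths_nm) || ncol(values) != length(times_h))
    stop(sprintf("values must be %d x %d (wavelengths x times), got %d x %d",
                 length(wavelengths_nm), length(times_h), nrow(values), ncol(values)))
  if (kind == "attenuation" && any(values < 0))
    stop("attenuation coefficients must be >= 0")
  if (!is.numeric(path_length_cm) || length(path_length_cm) != 1 || path_length_cm <= 0)
    stop("path_length_cm must be a single positive number")
  dimnames(values) <- NULL
  structure(list(wavelengths_nm = wavelengths_nm, times_h = times_h,
                 values = values, kind = kind,
                 path_length_cm = path_length_cm),
            class = "spectral_series")
}

#' @export
print.spectral_series <- function(x, ...) {
  cat(sprintf("spectral_series [%s]: %d wavelengths (%g-%g nm) x %d times (%g-%g h), l = %g cm\n",
              x$kind, length(x$wavelengths_nm), min(x$wavelengths_nm),
              max(x$wavelengths_nm), length(x$times_h), min(x$times_h),
              max(x$times_h), x$path_length_cm))
  invisible(x)
}

#' Convert transmission to attenuation coefficient
#'
#' The spectrophotometer reports transmission `T = exp(-alpha * l)`; this
#' inverts it with the natural logarithm, `alpha = -ln(T) / l`.
#'
#' @param transmission Transmission in (0, 1].
#' @param path_length_cm Optical path length (cm), > 0.
#' @return Attenuation coefficient in cm^-1.
#' @export
transmission_to_attenuation <- function(transmission, path_length_cm = 0.3) {
  if (any(!is.finite(transmission)) || any(transmission <= 0) || any(transmission > 1))
    stop("transmission must lie in (0, 1]")
  if (!is.numeric(path_length_cm) || any(path_length_cm <= 0))
    stop("path_length_cm must be > 0")
  -log(transmission) / path_length_cm
}

#' Convert attenuation coefficient to transmission
#'
#' Inverse of [transmission_to_attenuation()]: `T = exp(-alpha * l)`.
#'
#' @param alpha Attenuation coefficient (cm^-1), >= 0.
#' @param path_length_cm Optical path length (cm), > 0.
#' @return Transmission in (0, 1].
#' @export
attenuation_to_transmission <- function(alpha, path_length_cm = 0.3) {
  if (any(!is.finite(alpha)) || any(alpha < 0))
    stop("alpha must be >= 0")
  if (!is.numeric(path_length_cm) || any(path_length_cm <= 0))
    stop("path_length_cm must be > 0")
  exp(-alpha * path_length_cm)
}

#' Natural-log attenuation coefficient to decadic absorbance
#'
#' Provided for interoperability with absorbance-reporting instruments;
#' the pipeline itself works exclusively in natural-log cm^-1 units.
#'
#' @param alpha Coefficient in cm^-1 (natural-log convention).
#' @param path_length_cm Path length (cm).
#' @return Decadic absorbance (dimensionless), `alpha * l / ln(10)`.
#' @export
attenuation_to_absorbance <- function(alpha, path_length_cm = 0.3) {
  alpha * path_length_cm / log(10)
}

#' Write a spectral series to a delimited text file
#'
#' Writes a comma-separated table (first column wavelength in nm, one
#' column per storage time) preceded by `#` metadata comment lines that
#' record the series kind, path length and units, so a round trip through
#' [read_spectral_series()] is lossless.
#'
#' @param series A [spectral_series()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_spectral_series <- function(series, path) {
  stopifnot(inherits(series, "spectral_series"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# kind: %s", series$kind),
    sprintf("# path_length_cm: %s", format(series$path_length_cm, digits = 17)),
    "# units: wavelength nm, time h, coefficients cm^-1"
  ), con)
  header <- paste(c("wavelength_nm",
                    format(series$times_h, digits = 17, trim = TRUE)),
                  collapse = ",")
  writeLines(header, con)
  body <- cbind(series$wavelengths_nm, series$values)
  utils::write.table(format(body, digits = 17, trim = TRUE), con,
                     sep = ",", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read a spectral series written by [write_spectral_series()]
#'
#' @param path Input file path. The file must have `#` comment metadata,
#'   a header row of storage times, strictly increasing wavelengths in the
#'   first column and a rectangular numeric body.
#' @return A [spectral_series()].
#' @export
read_spectral_series <- function(path) {
  lines <- readLines(path)
  is_comment <- startsWith(lines, "#")
  meta <- lines[is_comment]
  kind <- sub("^# kind:\\s*", "", grep("^# kind:", meta, value = TRUE)[1])
  plc <- grep("^# path_length_cm:", meta, value = TRUE)
  path_length_cm <- if (length(plc)) as.numeric(sub("^# path_length_cm:\\s*", "", plc[1])) else 0.3
  body_lines <- lines[!is_comment & nzchar(lines)]
  if (length(body_lines) < 2)
    stop("no data rows found in ", path)
  header <- strsplit(body_lines[1], ",", fixed = TRUE)[[1]]
  times_h <- suppressWarnings(as.numeric(header[-1]))
  if (any(is.na(times_h)))
    stop("non-numeric time header in ", path)
  ncol_expected <- length(header)
  rows <- strsplit(body_lines[-1], ",", fixed = TRUE)
  for (i in seq_along(rows)) {
    if (length(rows[[i]]) != ncol_expected)
      stop(sprintf("ragged row at line %d of %s: expected %d fields, got %d",
                   which(!is_comment & nzchar(lines))[i + 1], path,
                   ncol_expected, length(rows[[i]])))
  }
  mat <- matrix(suppressWarnings(as.numeric(unlist(rows))),
                ncol = ncol_expected, byrow = TRUE)
  if (any(is.na(mat)))
    stop("non-numeric data in ", path)
  wl <- mat[, 1]
  if (any(diff(wl) <= 0)) {
    bad <- which(diff(wl) <= 0)[1] + 1
    stop(sprintf("wavelengths not strictly increasing at data row %d of %s", bad, path))
  }
  spectral_series(wl, times_h, mat[, -1, drop = FALSE],
                  kind = if (is.na(kind)) "attenuation" else kind,
                  path_length_cm = path_length_cm)
}
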