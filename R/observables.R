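#' Absorption cross-section table
#'
#' Cross-sections (cm^2) keyed by retinal species and analysis
#' wavelength, as needed to map population number densities onto the
#' eight measured coefficient series. Combinations not supplied default
#' to 0 and are flagged in the `"defaulted"` attribute.
#'
#' @param df Data frame with columns `species`, `wavelength_nm`,
#'   `sigma_cm2` (all sigma >= 0).
#' @return An object of class `cross_section_table`.
#' @export
cross_section_table <- function(df) {
  stopifnot(is.data.frame(df),
            all(c("species", "wavelength_nm", "sigma_cm2") %in% names(df)))
  if (any(df$sigma_cm2 < 0)) stop("cross-sections must be >= 0")
  if (anyDuplicated(df[c("species", "wavelength_nm")]))
    stop("duplicate (species, wavelength) entries")
  structure(list(table = df[c("species", "wavelength_nm", "sigma_cm2")]),
            class = "cross_section_table")
}

#' Look up a cross-section
#'
#' @param xsec A [cross_section_table()].
#' @param species Species name, e.g. `"Ret_500"`.
#' @param wavelength_nm Analysis wavelength (nm).
#' @param required If TRUE, a missing combination is an error naming the
#'   pair; otherwise 0 is returned.
#' @return Cross-section in cm^2.
#' @export
xsec_lookup <- function(xsec, species, wavelength_nm, required = TRUE) {
  stopifnot(inherits(xsec, "cross_section_table"))
  hit <- xsec$table$species == species &
    xsec$table$wavelength_nm == wavelength_nm
  if (!any(hit)) {
    if (required)
      stop(sprintf("cross-section missing for (%s, %g nm)", species, wavelength_nm))
    return(0)
  }
  xsec$table$sigma_cm2[which(hit)[1]]
}

#' Published cross-section table for QuasAr1
#'
#' The 14 (species, wavelength) cross-sections used in the kinetic
#' analysis of QuasAr1, in cm^2.
#'
#' @return A [cross_section_table()].
#' @export
quasar_cross_sections <- function() {
  cross_section_table(data.frame(
    species = c("Ret_580",
                "Ret_500", "Ret_500", "Ret_500", "Ret_500",
                "Ret_460", "Ret_460", "Ret_460", "Ret_460",
                "Ret_405", "Ret_405", "Ret_405",
                "Ret_340"),
    wavelength_nm = c(580,
                      500, 460, 405, 340,
                      500, 460, 405, 340,
                      460, 405, 340,
                      340),
    sigma_cm2 = c(1.593e-16,
                  1.25e-16, 1.0e-16, 5.47e-17, 5.85e-17,
                  2.64e-17, 1.0e-16, 5.34e-17, 4.40e-17,
                  1.60e-18, 8.5e-17, 3.72e-17,
                  1.8e-16)))
}

#' Predict the eight measured coefficient series from populations
#'
#' Linear Beer-Lambert combinations of the species number densities with
#' fixed cross-sections:
#' \itemize{
#'   \item `a580`: total Ret_580 absorption at 580 nm;
#'   \item `d500`, `d460`, `d405`, `d340`: difference-spectrum series at
#'     the four product-band wavelengths (Ret_500 + Ret_460 + Ret_405 +
#'     Ret_340 contributions as applicable);
#'   \item `dd460`, `dd405`, `dd340`: double-difference series with the
#'     Ret_500 contribution removed.
#' }
#'
#' @param traj A `population_trajectory` from [solve_populations()].
#' @param xsec A [cross_section_table()]; must contain the 14 required
#'   (species, wavelength) combinations.
#' @return An object of class `observable_series`: list with `times_h`
#'   and the eight numeric series (cm^-1).
#' @export
predict_observables <- function(traj, xsec) {
  stopifnot(inherits(traj, "population_trajectory"),
            inherits(xsec, "cross_section_table"))
  N <- traj$N
  s <- function(sp, wl) xsec_lookup(xsec, sp, wl, required = TRUE)
  a580 <- (N[, "Ret_580_I"] + N[, "Ret_580_II"]) * s("Ret_580", 580)
  d500 <- N[, "Ret_500"] * s("Ret_500", 500) + N[, "Ret_460"] * s("Ret_460", 500)
  d460 <- N[, "Ret_500"] * s("Ret_500", 460) + N[, "Ret_460"] * s("Ret_460", 460) +
    N[, "Ret_405"] * s("Ret_405", 460)
  d405 <- N[, "Ret_500"] * s("Ret_500", 405) + N[, "Ret_460"] * s("Ret_460", 405) +
    N[, "Ret_405"] * s("Ret_405", 405)
  d340 <- N[, "Ret_500"] * s("Ret_500", 340) + N[, "Ret_460"] * s("Ret_460", 340) +
    N[, "Ret_405"] * s("Ret_405", 340) + N[, "Ret_340"] * s("Ret_340", 340)
  dd460 <- N[, "Ret_460"] * s("Ret_460", 460) + N[, "Ret_405"] * s("Ret_405", 460)
  dd405 <- N[, "Ret_460"] * s("Ret_460", 405) + N[, "Ret_405"] * s("Ret_405", 405)
  dd340 <- N[, "Ret_460"] * s("Ret_460", 340) + N[, "Ret_405"] * s("Ret_405", 340) +
    N[, "Ret_340"] * s("Ret_340", 340)
  structure(list(times_h = traj$times_h,
                 a580 = unname(a580), d500 = unname(d500),
                 d460 = unname(d460), d405 = unname(d405),
                 d340 = unname(d340), dd460 = unname(dd460),
                 dd405 = unname(dd405), dd340 = unname(dd340)),
            class = "observable_series")
}

OBSERVABLE_NAMES <- c("a580", "d500", "d460", "d405", "d340",
                      "dd460", "dd405", "dd340")

#' Convert an observable series to a data frame
#'
#' @param x An `observable_series`.
#' @param row.names,optional,... Passed through for S3 compatibility.
#' @return Data frame with `t_h` and the eight series columns (cm^-1).
#' @export
as.data.frame.observable_series <- function(x, row.names = NULL,
                                            optional = FALSE, ...) {
  cbind(data.frame(t_h = x$times_h),
        as.data.frame(x[OBSERVABLE_NAMES]))
}
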