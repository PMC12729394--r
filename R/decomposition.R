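#' Component spectra for difference-spectrum decomposition
#'
#' The fixed spectral shapes needed to strip the initial-state
#' contributions from absorption spectra: the Ret_580 and Ret_500
#' cross-section spectra (cm^2, shape-invariant over storage time) and
#' the static residual-retinal and apoprotein absorption spectra at
#' t = 0 (cm^-1).
#'
#' @param wavelengths_nm Wavelength grid (nm), strictly increasing.
#' @param sigma_Ret_580_cm2,sigma_Ret_500_cm2 Cross-section spectra on
#'   the grid (cm^2, >= 0).
#' @param residual_cm1,apoprotein_cm1 Static absorption spectra at t = 0
#'   (cm^-1, >= 0).
#' @return An object of class `component_spectra`.
#' @export
component_spectra <- function(wavelengths_nm, sigma_Ret_580_cm2,
                              sigma_Ret_500_cm2, residual_cm1,
                              apoprotein_cm1) {
  n <- length(wavelengths_nm)
  comps <- list(sigma_Ret_580_cm2 = sigma_Ret_580_cm2,
                sigma_Ret_500_cm2 = sigma_Ret_500_cm2,
                residual_cm1 = residual_cm1,
                apoprotein_cm1 = apoprotein_cm1)
  for (nm in names(comps)) {
    if (length(comps[[nm]]) != n)
      stop(nm, " must match the wavelength grid length")
    if (any(comps[[nm]] < 0)) stop(nm, " must be >= 0")
  }
  structure(c(list(wavelengths_nm = as.numeric(wavelengths_nm)), comps),
            class = "component_spectra")
}

.check_grids <- function(series, comp, traj) {
  if (length(series$wavelengths_nm) != length(comp$wavelengths_nm) ||
      any(series$wavelengths_nm != comp$wavelengths_nm))
    stop("series and component spectra are on different wavelength grids")
  if (length(series$times_h) != length(traj$times_h) ||
      any(series$times_h != traj$times_h))
    stop("series and trajectory are on different time grids")
}

#' Difference spectra: strip the initial-state contributions
#'
#' `Delta alpha_a(lambda, t) = alpha_a(lambda, t)
#'   - sigma_Ret580(lambda) * [N_580I(t) + N_580II(t)]
#'   - alpha_residual(lambda) - alpha_apoprotein(lambda)`,
#' leaving the absorption of the isomerization/deprotonation products.
#' The Ret_580 term is the t = 0 band shape scaled by the surviving
#' Ret_580 population (shape-invariant band assumption).
#'
#' @param absorption [spectral_series()] of kind `"absorption"`.
#' @param comp A [component_spectra()] on the same wavelength grid.
#' @param traj A `population_trajectory` on the same time grid.
#' @return [spectral_series()] of kind `"difference"`.
#' @export
difference_spectra <- function(absorption, comp, traj) {
  stopifnot(inherits(absorption, "spectral_series"),
            inherits(comp, "component_spectra"),
            inherits(traj, "population_trajectory"))
  .check_grids(absorption, comp, traj)
  N580 <- traj$N[, "Ret_580_I"] + traj$N[, "Ret_580_II"]
  vals <- absorption$values -
    outer(comp$sigma_Ret_580_cm2, N580) -
    comp$residual_cm1 - comp$apoprotein_cm1
  spectral_series(absorption$wavelengths_nm, absorption$times_h, vals,
                  kind = "difference",
                  path_length_cm = absorption$path_length_cm)
}

#' Double-difference spectra: additionally strip the Ret_500 band
#'
#' `DeltaDelta alpha_a(lambda, t) = Delta alpha_a(lambda, t)
#'   - sigma_Ret500(lambda) * N_500(t)`, isolating Ret_460, Ret_405 and
#' Ret_340.
#'
#' @param diff [spectral_series()] of kind `"difference"`.
#' @param comp A [component_spectra()] on the same wavelength grid.
#' @param traj A `population_trajectory` on the same time grid.
#' @return [spectral_series()] of kind `"double_difference"`.
#' @export
double_difference_spectra <- function(diff, comp, traj) {
  stopifnot(inherits(diff, "spectral_series"),
            inherits(comp, "component_spectra"),
            inherits(traj, "population_trajectory"))
  .check_grids(diff, comp, traj)
  vals <- diff$values - outer(comp$sigma_Ret_500_cm2, traj$N[, "Ret_500"])
  spectral_series(diff$wavelengths_nm, diff$times_h, vals,
                  kind = "double_difference",
                  path_length_cm = diff$path_length_cm)
}

#' Extract the eight analysis time series from decomposed spectra
#'
#' Samples the absorption, difference and double-difference series at
#' the five analysis wavelengths to form the eight observables used for
#' kinetic fitting. The 580 nm series is the Ret_580 contribution alone
#' (total absorption minus the product contributions and the static
#' backgrounds at 580 nm).
#'
#' @param absorption [spectral_series()] of kind `"absorption"`.
#' @param comp A [component_spectra()].
#' @param traj A `population_trajectory` (supplies the Ret_580 and
#'   Ret_500 population scalings for the subtractions).
#' @return An `observable_series` (see [predict_observables()]).
#' @export
extract_observables <- function(absorption, comp, traj) {
  d <- difference_spectra(absorption, comp, traj)
  dd <- double_difference_spectra(d, comp, traj)
  at <- function(series, wl) as.numeric(sample_series(series, wl))
  i580 <- match(580, comp$wavelengths_nm)
  if (is.na(i580)) stop("wavelength grid must contain 580 nm")
  static580 <- comp$residual_cm1[i580] + comp$apoprotein_cm1[i580]
  structure(list(times_h = absorption$times_h,
                 a580 = at(absorption, 580) - at(d, 580) - static580,
                 d500 = at(d, 500), d460 = at(d, 460),
                 d405 = at(d, 405), d340 = at(d, 340),
                 dd460 = at(dd, 460), dd405 = at(dd, 405),
                 dd340 = at(dd, 340)),
            class = "observable_series")
}

#' Sample a spectral series at given wavelengths
#'
#' Exact grid lookup (no interpolation); each requested wavelength must
#' be on the series grid.
#'
#' @param series A [spectral_series()].
#' @param wavelengths_nm Wavelengths to extract (nm).
#' @return Matrix, `length(wavelengths_nm)` x `length(times_h)`.
#' @export
sample_series <- function(series, wavelengths_nm) {
  stopifnot(inherits(series, "spectral_series"))
  idx <- match(wavelengths_nm, series$wavelengths_nm)
  if (anyNA(idx))
    stop("wavelength(s) not on the series grid: ",
         paste(wavelengths_nm[is.na(idx)], collapse = ", "))
  out <- series$values[idx, , drop = FALSE]
  rownames(out) <- wavelengths_nm
  out
}
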