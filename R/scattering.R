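#' Empirical power-law scattering model
#'
#' Aggregation of the protein into Mie-sized particles adds a smooth
#' scattering background to the attenuation spectra. In the transparency
#' window it is well described per measurement time by
#' `alpha_s(lambda, t) = alpha_s(lambda0, t) * (lambda0 / lambda)^gamma(t)`,
#' with a power factor gamma at or below the Rayleigh value 4.
#'
#' @param times_h Storage times (h) at which the model is defined.
#' @param amplitude_series Scattering coefficient at the reference
#'   wavelength per time, `alpha_s(lambda0, t)` (cm^-1, >= 0).
#' @param gamma_series Power factor gamma(t), in (0, 4].
#' @param lambda0_nm Reference wavelength (nm), default 900.
#' @return An object of class `scattering_model`.
#' @export
scattering_model <- function(times_h, amplitude_series, gamma_series,
                             lambda0_nm = 900) {
  times_h <- as.numeric(times_h)
  amplitude_series <- as.numeric(amplitude_series)
  gamma_series <- as.numeric(gamma_series)
  if (length(amplitude_series) != length(times_h) ||
      length(gamma_series) != length(times_h))
    stop("amplitude_series and gamma_series must match times_h in length")
  if (any(!is.finite(amplitude_series)) || any(amplitude_series < 0))
    stop("amplitudes must be finite and >= 0")
  if (any(!is.finite(gamma_series)) || any(gamma_series <= 0) || any(gamma_series > 4))
    stop("gamma must lie in (0, 4]")
  if (!is.finite(lambda0_nm) || lambda0_nm <= 0)
    stop("lambda0_nm must be > 0")
  structure(list(times_h = times_h, amplitude_series = amplitude_series,
                 gamma_series = gamma_series, lambda0_nm = lambda0_nm),
            class = "scattering_model")
}

# nearest-time index lookup; the model is defined per measurement, no
# temporal interpolation
.nearest_time <- function(model, t_h) {
  vapply(t_h, function(t) which.min(abs(model$times_h - t)), integer(1))
}

#' Evaluate the power-law scattering coefficient
#'
#' @param model A [scattering_model()].
#' @param lambda_nm Wavelength(s), nm, > 0.
#' @param t_h Storage time (h); the nearest model time is used.
#' @return Scattering coefficient(s) alpha_s(lambda, t) in cm^-1.
#' @export
eval_scattering <- function(model, lambda_nm, t_h) {
  stopifnot(inherits(model, "scattering_model"))
  if (any(lambda_nm <= 0)) stop("lambda_nm must be > 0")
  i <- .nearest_time(model, t_h)
  if (length(t_h) == 1) {
    model$amplitude_series[i] * (model$lambda0_nm / lambda_nm)^model$gamma_series[i]
  } else {
    mapply(function(ii, l) model$amplitude_series[ii] *
             (model$lambda0_nm / l)^model$gamma_series[ii],
           i, lambda_nm)
  }
}

#' Subtract the scattering background from attenuation spectra
#'
#' `alpha_a(lambda, t) = alpha(lambda, t) - alpha_s(lambda, t)`.
#' By default the raw (unclipped) difference is returned so residuals
#' remain unbiased for fitting; with `clip = TRUE` negative values
#' (noise in the transparency region) are set to 0 and counted in the
#' `"n_clipped"` attribute.
#'
#' @param attenuation [spectral_series()] of kind `"attenuation"`.
#' @param model A [scattering_model()] defined on the same time grid.
#' @param clip Clip negative post-subtraction values at 0 (default FALSE).
#' @return [spectral_series()] of kind `"absorption"`.
#' @export
subtract_scattering <- function(attenuation, model, clip = FALSE) {
  stopifnot(inherits(attenuation, "spectral_series"),
            inherits(model, "scattering_model"))
  if (length(model$times_h) != length(attenuation$times_h) ||
      any(model$times_h != attenuation$times_h))
    stop("scattering model and attenuation series must share the time grid")
  sc <- outer(attenuation$wavelengths_nm, seq_along(model$times_h),
              function(l, j) model$amplitude_series[j] *
                (model$lambda0_nm / l)^model$gamma_series[j])
  vals <- attenuation$values - sc
  n_clipped <- 0L
  if (clip) {
    n_clipped <- sum(vals < 0)
    vals[vals < 0] <- 0
  }
  out <- spectral_series(attenuation$wavelengths_nm, attenuation$times_h,
                         vals, kind = "absorption",
                         path_length_cm = attenuation$path_length_cm)
  attr(out, "n_clipped") <- n_clipped
  out
}

#' Fit the power-law scattering model in the transparency window
#'
#' Estimates `gamma(t)` and the reference-wavelength amplitude per time
#' point by ordinary least squares of `ln alpha` on `ln(lambda0/lambda)`
#' over a wavelength window where the protein does not absorb
#' (default 710-900 nm). Times where the whole window is at or below the
#' noise floor get amplitude 0 and gamma stored as 4.
#'
#' @param attenuation [spectral_series()] of kind `"attenuation"`.
#' @param window Length-2 wavelength window (nm), default `c(710, 900)`.
#' @param lambda0_nm Reference wavelength (nm), default 900.
#' @param noise_floor Values at or below this (cm^-1) are treated as
#'   no-scattering; default 1e-12.
#' @return A [scattering_model()] on the attenuation time grid.
#' @export
fit_scattering_window <- function(attenuation, window = c(710, 900),
                                  lambda0_nm = 900, noise_floor = 1e-12) {
  stopifnot(inherits(attenuation, "spectral_series"))
  sel <- attenuation$wavelengths_nm >= window[1] &
    attenuation$wavelengths_nm <= window[2]
  if (sum(sel) < 3)
    stop("scattering window must contain at least 3 wavelengths")
  lam <- attenuation$wavelengths_nm[sel]
  nt <- length(attenuation$times_h)
  amp <- numeric(nt)
  gam <- rep(4, nt)
  x <- log(lambda0_nm / lam)
  for (j in seq_len(nt)) {
    y <- attenuation$values[sel, j]
    pos <- y > noise_floor
    if (sum(pos) < 3) next  # amplitude 0, gamma kept at 4
    fit <- stats::lm.fit(cbind(1, x[pos]), log(y[pos]))
    g <- fit$coefficients[2]
    amp[j] <- exp(fit$coefficients[1])
    gam[j] <- min(max(g, 1e-6), 4)
  }
  scattering_model(attenuation$times_h, amp, gam, lambda0_nm = lambda0_nm)
}

#' Aggregation diagnostics from the scattering amplitude
#'
#' The scattering enhancement factor compares the measured scattering
#' coefficient with the level expected for a purely monomeric Rayleigh
#' scatterer: `M_sca(t) = alpha_s(lambda0, t) / (N_monomer * sigma_R_monomer)`.
#' In the Rayleigh coherent-scattering limit the mean number of monomers
#' per aggregate (degree of aggregation) equals `M_sca`, so `beta_m` is
#' reported as a Rayleigh-limit lower bound on the true degree of
#' aggregation of the larger (Mie-sized) particles.
#'
#' @param amplitude_series Scattering coefficient at the reference
#'   wavelength per time (cm^-1).
#' @param times_h Storage times (h) matching `amplitude_series`.
#' @param N_monomer_cm3 Monomer number density (cm^-3), > 0.
#' @param sigma_R_monomer_cm2 Monomer Rayleigh cross-section at the
#'   reference wavelength (cm^2), > 0.
#' @return List of class `aggregation_report` with `times_h`, `M_sca`,
#'   `beta_m` (flagged `rayleigh_limit_lower_bound`), and the inputs.
#' @export
aggregation_enhancement <- function(amplitude_series, times_h,
                                    N_monomer_cm3, sigma_R_monomer_cm2) {
  if (!is.finite(N_monomer_cm3) || N_monomer_cm3 <= 0)
    stop("N_monomer_cm3 must be > 0")
  if (!is.finite(sigma_R_monomer_cm2) || sigma_R_monomer_cm2 <= 0)
    stop("sigma_R_monomer_cm2 must be > 0")
  if (any(amplitude_series < 0)) stop("amplitudes must be >= 0")
  M <- amplitude_series / (N_monomer_cm3 * sigma_R_monomer_cm2)
  structure(list(times_h = times_h, M_sca = M, beta_m = M,
                 rayleigh_limit_lower_bound = TRUE,
                 N_monomer_cm3 = N_monomer_cm3,
                 sigma_R_monomer_cm2 = sigma_R_monomer_cm2),
            class = "aggregation_report")
}

#' Rayleigh scattering cross-section of a dielectric sphere
#'
#' Standard small-particle (Rayleigh) result,
#' `sigma = (128 pi^5 / 3) * a^6 / lambda_med^4 * ((m^2-1)/(m^2+2))^2`
#' with relative index `m = n_particle / n_medium` and in-medium
#' wavelength `lambda_med = lambda / n_medium`. Provided for consistency
#' exploration of the aggregation diagnostics.
#'
#' @param a_nm Particle radius (nm), > 0.
#' @param lambda_nm Vacuum wavelength (nm), > 0.
#' @param n_particle,n_medium Refractive indices.
#' @return Cross-section in cm^2.
#' @export
rayleigh_cross_section <- function(a_nm, lambda_nm, n_particle, n_medium) {
  if (any(a_nm <= 0) || any(lambda_nm <= 0)) stop("a_nm and lambda_nm must be > 0")
  if (any(n_particle <= 0) || any(n_medium <= 0)) stop("indices must be > 0")
  a_cm <- a_nm * 1e-7
  lam_med_cm <- (lambda_nm / n_medium) * 1e-7
  m2 <- (n_particle / n_medium)^2
  (128 * pi^5 / 3) * a_cm^6 / lam_med_cm^4 * ((m2 - 1) / (m2 + 2))^2
}
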