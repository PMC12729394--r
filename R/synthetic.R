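#' Bi-Gaussian-in-wavenumber absorption band model
#'
#' Retinal protein absorption bands are well approximated by sums of
#' Gaussian-like components in the wavenumber domain, with a steeper
#' long-wavelength (red) edge than short-wavelength (blue) edge. A band
#' here is a sum of 1-3 bi-Gaussian components
#' `sigma(nu) = sum_j p_j exp(-((nu - nu_j)/w_j)^2)` with `nu = 1/lambda`
#' and a separate 1/e half-width `w_j` on each side of the component
#' center (narrow on the red side, free on the blue side). Amplitudes
#' and widths are least-squares matched to a set of anchor
#' cross-sections at the analysis wavelengths.
#'
#' @param species Species label, e.g. `"Ret_500"`.
#' @param anchors Data frame with `wavelength_nm`, `sigma_cm2`: the
#'   cross-sections the band must reproduce (each within 2%).
#' @param centers Component center wavelengths (nm), 1-3 values. Default:
#'   the anchor wavelength of maximum sigma, plus blue-side satellites
#'   when more anchors must be matched.
#' @return An object of class `band_model` with `species`, `centers_nm`,
#'   `peaks_cm2`, `widths_blue_invnm`, `widths_red_invnm` and the anchors.
#' @export
build_band <- function(species, anchors, centers = NULL) {
  stopifnot(is.data.frame(anchors),
            all(c("wavelength_nm", "sigma_cm2") %in% names(anchors)),
            nrow(anchors) >= 1, all(anchors$sigma_cm2 > 0))
  if (is.null(centers)) {
    main <- anchors$wavelength_nm[which.max(anchors$sigma_cm2)]
    others <- sort(setdiff(anchors$wavelength_nm, main))
    n_extra <- min(2, max(0, nrow(anchors) - 1))
    centers <- c(main, others[seq_len(min(n_extra, length(others)))])
  }
  if (length(centers) < 1 || length(centers) > 3)
    stop("1 to 3 band components are supported")
  nu_a <- 1 / anchors$wavelength_nm
  sig_a <- anchors$sigma_cm2
  scale <- max(sig_a)
  # defaults: ~1.2e-4 nm^-1 1/e half-width on the red edge (steep, keeps
  # the transparency window clean), ~1.8e-4 on the blue edge
  wr0 <- 1.0e-4; wb0 <- 1.8e-4
  k <- length(centers)
  make_band <- function(p, wb, wr) {
    structure(list(species = species, centers_nm = centers,
                   peaks_cm2 = p, widths_blue_invnm = wb,
                   widths_red_invnm = wr, anchors = anchors),
              class = "band_model")
  }
  if (nrow(anchors) == 1 && k == 1 &&
      isTRUE(all.equal(centers[1], anchors$wavelength_nm[1]))) {
    band <- make_band(sig_a[1], wb0, wr0)
  } else {
    # theta = (log p / scale, log wb / wb0, log wr / wr0) per component
    unpack <- function(theta) {
      list(p = exp(theta[seq_len(k)]) * scale,
           wb = exp(theta[k + seq_len(k)]) * wb0,
           wr = exp(theta[2 * k + seq_len(k)]) * wr0)
    }
    obj <- function(theta) {
      u <- unpack(theta)
      pred <- eval_band(make_band(u$p, u$wb, u$wr), anchors$wavelength_nm)
      sum(((pred - sig_a) / sig_a)^2) + 1e-5 * sum(theta[-seq_len(k)]^2)
    }
    p0 <- sig_a[match(centers, anchors$wavelength_nm)] / scale
    p0[is.na(p0)] <- 0.4
    theta0 <- c(log(pmax(p0, 0.05)), rep(0, 2 * k))
    lower <- c(rep(log(1e-3), k), rep(log(1 / 3), k), rep(log(0.5), k))
    upper <- c(rep(log(2), k), rep(log(2.5), k), rep(log(1.6), k))
    best <- NULL
    for (s in c(1, 0.6, 1.6)) {  # restarts against local minima in widths
      th <- theta0; th[k + seq_len(k)] <- log(s)
      fit <- stats::nlminb(th, obj, lower = lower, upper = upper,
                           control = list(iter.max = 1000))
      if (is.null(best) || fit$objective < best$objective) best <- fit
    }
    u <- unpack(best$par)
    band <- make_band(u$p, u$wb, u$wr)
  }
  err <- abs(eval_band(band, anchors$wavelength_nm) - sig_a) / sig_a
  if (any(err > 0.02))
    stop(sprintf("band for %s misses anchors by up to %.1f%% (> 2%%); supply different centers",
                 species, 100 * max(err)))
  band
}

#' Evaluate a band model on a wavelength grid
#'
#' @param band A [build_band()] model.
#' @param lambda_nm Wavelengths (nm), > 0.
#' @return Cross-section spectrum sigma(lambda) in cm^2.
#' @export
eval_band <- function(band, lambda_nm) {
  stopifnot(inherits(band, "band_model"))
  if (any(lambda_nm <= 0)) stop("lambda_nm must be > 0")
  nu <- 1 / lambda_nm
  out <- numeric(length(nu))
  for (j in seq_along(band$peaks_cm2)) {
    nu_c <- 1 / band$centers_nm[j]
    w <- ifelse(nu >= nu_c, band$widths_blue_invnm[j],
                band$widths_red_invnm[j])
    out <- out + band$peaks_cm2[j] * exp(-((nu - nu_c) / w)^2)
  }
  out
}

#' Default band models anchored to the published cross-sections
#'
#' Builds the five retinal species bands from the published
#' (species, wavelength, sigma) anchors; every anchor is reproduced
#' within 2%.
#'
#' @param xsec A [cross_section_table()]; default [quasar_cross_sections()].
#' @return Named list of [build_band()] models.
#' @export
default_bands <- function(xsec = quasar_cross_sections()) {
  tab <- xsec$table
  anchors_of <- function(sp) {
    a <- tab[tab$species == sp, c("wavelength_nm", "sigma_cm2")]
    a[order(-a$sigma_cm2), ]
  }
  centers <- list(Ret_580 = 580,
                  Ret_500 = c(500, 448, 352),
                  Ret_460 = c(460, 402, 344),
                  Ret_405 = c(405, 343),
                  Ret_340 = 340)
  out <- lapply(names(centers), function(sp)
    build_band(sp, anchors_of(sp), centers[[sp]]))
  names(out) <- names(centers)
  out
}

# static background spectra: weak residual-retinal shoulder below 450 nm
# and the apoprotein band peaking near 280 nm (cm^-1, Gaussians in
# wavenumber like the retinal bands)
.gauss_nm <- function(lambda_nm, center_nm, width_invnm, peak) {
  peak * exp(-((1 / lambda_nm - 1 / center_nm) / width_invnm)^2)
}

residual_retinal_spectrum <- function(lambda_nm, peak_cm1 = 0.08) {
  .gauss_nm(lambda_nm, 380, 2.5e-4, peak_cm1)
}

apoprotein_spectrum <- function(lambda_nm, peak_cm1 = 3.0) {
  .gauss_nm(lambda_nm, 280, 1.5e-4, peak_cm1)
}

#' Synthetic measurement scenario configuration
#'
#' Collects everything needed to generate an attenuation-spectra movie
#' with the statistical structure of the dark-storage experiment:
#' the kinetic parameters, the species band models, static
#' residual-retinal and apoprotein backgrounds, the aggregation
#' scattering schedule (zero before 6 h, logistic rise centered at 15 h
#' to a 0.105 cm^-1 plateau at 750 nm, level to 456 h, then linear
#' decline to 0.05 cm^-1 at 2424 h), the scattering power factor, the
#' grids, the additive noise level and the seed.
#'
#' @param params [kinetic_parameters()]; default [quasar_parameters()].
#' @param bands Named list of band models; default [default_bands()].
#' @param apoprotein_peak_cm1 Peak apoprotein absorption at 280 nm (cm^-1).
#' @param residual_peak_cm1 Peak residual-retinal absorption (cm^-1).
#' @param scattering_plateau_cm1 Plateau scattering coefficient at 750 nm.
#' @param scattering_final_cm1 Scattering coefficient at 750 nm at the
#'   final measurement time.
#' @param gamma Mie power factor gamma(t); single value or one per time
#'   point, in (0, 4].
#' @param lambda0_nm Reference wavelength for the scattering model (nm).
#' @param noise_sd_cm1 Additive Gaussian noise standard deviation (cm^-1).
#' @param times_h Measurement time grid (h).
#' @param wavelengths_nm Wavelength grid (nm).
#' @param seed Integer seed; fixed seed gives bitwise-identical output.
#' @return An object of class `scenario_config`.
#' @export
scenario_config <- function(params = quasar_parameters(),
                            bands = default_bands(),
                            apoprotein_peak_cm1 = 3.0,
                            residual_peak_cm1 = 0.08,
                            scattering_plateau_cm1 = 0.105,
                            scattering_final_cm1 = 0.05,
                            gamma = 2.5,
                            lambda0_nm = 900,
                            noise_sd_cm1 = 0.005,
                            times_h = c(0, 6, 10, 24, 48, 95, 117, 168, 240,
                                        336, 456, 600, 800, 1000, 1200, 1600,
                                        2000, 2424),
                            wavelengths_nm = 250:900,
                            seed = 1L) {
  stopifnot(inherits(params, "kinetic_parameters"))
  if (any(gamma <= 0) || any(gamma > 4)) stop("gamma must lie in (0, 4]")
  if (!(length(gamma) %in% c(1, length(times_h))))
    stop("gamma must be scalar or one value per time point")
  if (noise_sd_cm1 < 0) stop("noise_sd_cm1 must be >= 0")
  structure(list(params = params, bands = bands,
                 apoprotein_peak_cm1 = apoprotein_peak_cm1,
                 residual_peak_cm1 = residual_peak_cm1,
                 scattering_plateau_cm1 = scattering_plateau_cm1,
                 scattering_final_cm1 = scattering_final_cm1,
                 gamma = gamma, lambda0_nm = lambda0_nm,
                 noise_sd_cm1 = noise_sd_cm1,
                 times_h = as.numeric(times_h),
                 wavelengths_nm = as.numeric(wavelengths_nm),
                 seed = as.integer(seed)),
            class = "scenario_config")
}

# scattering amplitude schedule at 750 nm: exactly zero through 6 h,
# logistic rise (center 15 h, scale 2.5 h) to the plateau, level to
# 456 h, linear decline to the final value at 2424 h
scattering_amplitude_750 <- function(t_h, plateau = 0.105, final = 0.05) {
  level <- ifelse(t_h <= 456, plateau,
                  plateau + (final - plateau) * pmin((t_h - 456) / (2424 - 456), 1))
  rise <- 1 / (1 + exp(-(t_h - 15) / 2.5))
  ifelse(t_h <= 6, 0, level * rise)
}

#' Generate a synthetic attenuation-spectra movie with ground truth
#'
#' Builds `alpha(lambda, t)` as the sum of the five species band
#' contributions (populations from the kinetic model), the static
#' residual-retinal and apoprotein backgrounds, the power-law
#' scattering background, and additive Gaussian noise. Noise can push
#' near-zero attenuation values below zero; those are clamped at 0 to
#' keep the series physical.
#'
#' @param config A [scenario_config()].
#' @return List with `attenuation` ([spectral_series()]), and ground
#'   truth: `trajectory`, `scattering` ([scattering_model()] at the
#'   reference wavelength), `components` ([component_spectra()]),
#'   `observables` (noiseless [predict_observables()] output), `params`
#'   and `config`.
#' @export
generate_scenario <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  lam <- config$wavelengths_nm
  tt <- config$times_h
  traj <- solve_populations(config$params, tt)
  sig <- vapply(SPECIES_BAND, function(sp) eval_band(config$bands[[sp]], lam),
                numeric(length(lam)))
  # map the two Ret_580 branches onto the single Ret_580 band
  Nmat <- cbind(Ret_580 = traj$N[, "Ret_580_I"] + traj$N[, "Ret_580_II"],
                traj$N[, c("Ret_500", "Ret_460", "Ret_405", "Ret_340")])
  absorption <- sig %*% t(Nmat[, SPECIES_BAND])
  residual <- residual_retinal_spectrum(lam, config$residual_peak_cm1)
  apo <- apoprotein_spectrum(lam, config$apoprotein_peak_cm1)
  static <- residual + apo
  gamma_t <- rep(config$gamma, length.out = length(tt))
  amp750 <- scattering_amplitude_750(tt, config$scattering_plateau_cm1,
                                     config$scattering_final_cm1)
  amp0 <- amp750 * (750 / config$lambda0_nm)^gamma_t
  scat_model <- scattering_model(tt, amp0, gamma_t,
                                 lambda0_nm = config$lambda0_nm)
  scat <- outer(lam, seq_along(tt),
                function(l, j) amp0[j] * (config$lambda0_nm / l)^gamma_t[j])
  vals <- absorption + static + scat
  if (config$noise_sd_cm1 > 0) {
    old <- .Random.seed_save()
    set.seed(config$seed)
    vals <- vals + matrix(stats::rnorm(length(vals), 0, config$noise_sd_cm1),
                          nrow = nrow(vals))
    .Random.seed_restore(old)
    vals[vals < 0] <- 0
  }
  attenuation <- spectral_series(lam, tt, vals, kind = "attenuation")
  comp <- component_spectra(
    wavelengths_nm = lam,
    sigma_Ret_580_cm2 = sig[, "Ret_580"],
    sigma_Ret_500_cm2 = sig[, "Ret_500"],
    residual_cm1 = residual,
    apoprotein_cm1 = apo)
  list(attenuation = attenuation, trajectory = traj,
       scattering = scat_model, components = comp,
       observables = predict_observables(traj, quasar_cross_sections()),
       params = config$params, config = config)
}

SPECIES_BAND <- c("Ret_580", "Ret_500", "Ret_460", "Ret_405", "Ret_340")

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}
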