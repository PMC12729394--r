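test_that("difference spectra strip exactly the initial-state components", {
  g <- cached_noiseless_scenario()
  cfg <- g$config
  # exact scattering subtraction using the generating model
  aa <- subtract_scattering(g$attenuation, g$scattering)
  d <- difference_spectra(aa, g$components, g$trajectory)
  expect_identical(d$kind, "difference")
  # at t = 0 nothing but the initial components is present
  expect_lt(max(abs(d$values[, 1])), 1e-8)
  # construct-and-compare: the residue is the summed product-band
  # contributions
  lam <- cfg$wavelengths_nm
  bands <- cfg$bands
  prod <- eval_band(bands$Ret_500, lam) %o% g$trajectory$N[, "Ret_500"] +
    eval_band(bands$Ret_460, lam) %o% g$trajectory$N[, "Ret_460"] +
    eval_band(bands$Ret_405, lam) %o% g$trajectory$N[, "Ret_405"] +
    eval_band(bands$Ret_340, lam) %o% g$trajectory$N[, "Ret_340"]
  expect_equal(d$values, prod, tolerance = 1e-7)
})

test_that("double differences remove the Ret_500 band", {
  g <- cached_noiseless_scenario()
  aa <- subtract_scattering(g$attenuation, g$scattering)
  d <- difference_spectra(aa, g$components, g$trajectory)
  dd <- double_difference_spectra(d, g$components, g$trajectory)
  expect_identical(dd$kind, "double_difference")
  expect_lt(max(abs(dd$values[, 1])), 1e-8)
  # with no Ret_500 population the double difference equals the difference
  tr0 <- g$trajectory
  tr0$N[, "Ret_500"] <- 0
  expect_equal(double_difference_spectra(d, g$components, tr0)$values,
               d$values)
  # cross-module consistency at 460 nm with the Beer-Lambert combination
  xs <- quasar_cross_sections()
  eq21 <- g$trajectory$N[, "Ret_460"] * xsec_lookup(xs, "Ret_460", 460) +
    g$trajectory$N[, "Ret_405"] * xsec_lookup(xs, "Ret_405", 460)
  expect_equal(as.numeric(sample_series(dd, 460)), eq21, tolerance = 1e-3)
})

test_that("sampled decomposition matches the equation-level observables", {
  # agreement is limited only by band overlap outside the anchored
  # combinations (the analysis equations truncate those cross terms)
  g <- cached_noiseless_scenario()
  aa <- subtract_scattering(g$attenuation, g$scattering)
  ext <- extract_observables(aa, g$components, g$trajectory)
  for (nm in c("a580", "d500", "d460", "d405", "d340",
               "dd460", "dd405", "dd340")) {
    expect_lt(max(abs(ext[[nm]] - g$observables[[nm]])), 2e-3)
  }
  # the 580 nm extraction removes product-band leakage exactly
  expect_equal(ext$a580, g$observables$a580, tolerance = 1e-7)
})

test_that("early-time difference development has the Ret_500 band shape", {
  g <- cached_noiseless_scenario()
  cfg <- g$config
  aa <- subtract_scattering(g$attenuation, fit_scattering_window(g$attenuation))
  d <- difference_spectra(aa, g$components, g$trajectory)
  i95 <- match(95, cfg$times_h); i24 <- match(24, cfg$times_h)
  sel <- cfg$wavelengths_nm > 300
  v <- d$values[sel, i95] - d$values[sel, i24]
  ref <- g$components$sigma_Ret_500_cm2[sel]
  cosine <- sum(v * ref) / sqrt(sum(v^2) * sum(ref^2))
  expect_gt(cosine, 0.99)
})

test_that("grid mismatches are shape errors", {
  g <- cached_noiseless_scenario()
  aa <- subtract_scattering(g$attenuation, g$scattering)
  comp_bad <- g$components
  comp_bad$wavelengths_nm <- comp_bad$wavelengths_nm + 1
  expect_error(difference_spectra(aa, comp_bad, g$trajectory),
               "wavelength grids")
  tr_bad <- g$trajectory
  tr_bad$times_h <- tr_bad$times_h + 1
  expect_error(difference_spectra(aa, g$components, tr_bad), "time grids")
  expect_error(sample_series(aa, 123.4), "not on the series grid")
})
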