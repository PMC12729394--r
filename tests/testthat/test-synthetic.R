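test_that("band models reproduce every anchor cross-section within 2%", {
  bands <- cached_bands()
  expect_setequal(names(bands),
                  c("Ret_580", "Ret_500", "Ret_460", "Ret_405", "Ret_340"))
  for (sp in names(bands)) {
    a <- bands[[sp]]$anchors
    pred <- eval_band(bands[[sp]], a$wavelength_nm)
    expect_lt(max(abs(pred - a$sigma_cm2) / a$sigma_cm2), 0.02)
  }
  # single-anchor band peaks exactly at its anchor
  b340 <- build_band("Ret_340",
                     data.frame(wavelength_nm = 340, sigma_cm2 = 1.8e-16))
  expect_equal(eval_band(b340, 340), 1.8e-16)
  expect_equal(b340$centers_nm, 340)
  # bands die off in the transparency window so the scattering fit
  # window stays clean
  for (sp in names(bands))
    expect_lt(max(eval_band(bands[[sp]], seq(710, 900, 10))), 2e-20)
})

test_that("infeasible anchor sets are rejected", {
  # a single component cannot be lower between two equal anchors
  bad <- data.frame(wavelength_nm = c(400, 450, 500),
                    sigma_cm2 = c(1e-16, 1e-18, 1e-16))
  expect_error(build_band("impossible", bad, centers = 450), "misses anchors")
})

test_that("generation is deterministic per seed and seed-sensitive", {
  cfg <- scenario_config(bands = cached_bands(), seed = 5,
                         wavelengths_nm = seq(250, 900, 5))
  g1 <- generate_scenario(cfg)
  g2 <- generate_scenario(cfg)
  expect_identical(g1$attenuation$values, g2$attenuation$values)
  cfg2 <- scenario_config(bands = cached_bands(), seed = 6,
                          wavelengths_nm = seq(250, 900, 5))
  expect_false(identical(generate_scenario(cfg2)$attenuation$values,
                         g1$attenuation$values))
})

test_that("noiseless, scatter-free output is the pure absorption model", {
  cfg <- scenario_config(bands = cached_bands(), noise_sd_cm1 = 0,
                         scattering_plateau_cm1 = 0,
                         scattering_final_cm1 = 0,
                         wavelengths_nm = seq(250, 900, 5))
  g <- generate_scenario(cfg)
  lam <- cfg$wavelengths_nm
  N <- g$trajectory$N
  manual <- eval_band(cfg$bands$Ret_580, lam) %o%
    (N[, "Ret_580_I"] + N[, "Ret_580_II"]) +
    eval_band(cfg$bands$Ret_500, lam) %o% N[, "Ret_500"] +
    eval_band(cfg$bands$Ret_460, lam) %o% N[, "Ret_460"] +
    eval_band(cfg$bands$Ret_405, lam) %o% N[, "Ret_405"] +
    eval_band(cfg$bands$Ret_340, lam) %o% N[, "Ret_340"] +
    g$components$residual_cm1 + g$components$apoprotein_cm1
  expect_equal(g$attenuation$values, manual, tolerance = 1e-12)
  # zero-amplitude scattering model leaves it untouched
  out <- subtract_scattering(g$attenuation, g$scattering)
  expect_equal(out$values, g$attenuation$values)
})

test_that("default scenario reproduces the measured anchor points", {
  g <- cached_noiseless_scenario()
  # initial 580 nm absorption: the printed worked value
  expect_equal(unname(sample_series(g$attenuation, 580)[1, 1]), 2.20,
               tolerance = 1e-3)
  # transparency-window trace: nothing before 6 h, plateau near
  # 0.105 1/cm between 24 h and 456 h, decline toward 0.05 1/cm
  tr750 <- as.numeric(sample_series(g$attenuation, 750))
  tt <- g$config$times_h
  expect_true(all(tr750[tt <= 6] < 0.005))
  plateau <- tr750[tt >= 24 & tt <= 456]
  expect_true(all(abs(plateau - 0.105) < 0.015))
  expect_lt(tr750[length(tt)], 0.07)
  expect_gt(tr750[length(tt)], 0.03)
})
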