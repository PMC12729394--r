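test_that("power-law evaluation matches the defining relation", {
  m <- scattering_model(c(0, 24), c(0.02, 0.105), c(3, 2), lambda0_nm = 900)
  # at the reference wavelength the amplitude is returned unchanged
  expect_equal(eval_scattering(m, 900, 24), 0.105)
  # hand evaluation: amplitude 0.105, gamma 2, lambda = lambda0/2
  m2 <- scattering_model(0, 0.105, 2, lambda0_nm = 900)
  expect_equal(eval_scattering(m2, 450, 0), 0.105 * 4)
  m4 <- scattering_model(0, 0.07, 4, lambda0_nm = 900)
  expect_equal(eval_scattering(m4, 450, 0), 16 * 0.07)
  expect_error(eval_scattering(m, -500, 0), "> 0")
  # strictly decreasing in wavelength for gamma > 0
  lam <- seq(300, 900, by = 50)
  expect_true(all(diff(eval_scattering(m, lam, 24)) < 0))
})

test_that("window fit inverts noiseless power-law scattering", {
  lam <- 250:900
  set.seed(11)
  for (rep in 1:10) {
    gam <- runif(1, 0.5, 4)
    amp <- runif(1, 0.01, 0.2)
    truth <- scattering_model(0, amp, gam, 900)
    vals <- matrix(eval_scattering(truth, lam, 0), ncol = 1)
    att <- spectral_series(lam, 0, vals, kind = "attenuation")
    fit <- fit_scattering_window(att)
    expect_equal(fit$amplitude_series, amp, tolerance = 1e-8)
    expect_equal(fit$gamma_series, gam, tolerance = 1e-8)
  }
  # reference example gamma 2.5, amplitude 0.08
  truth <- scattering_model(0, 0.08, 2.5, 900)
  att <- spectral_series(lam, 0,
                         matrix(eval_scattering(truth, lam, 0), ncol = 1),
                         kind = "attenuation")
  fit <- fit_scattering_window(att)
  expect_equal(fit$gamma_series, 2.5, tolerance = 1e-10)
  expect_equal(fit$amplitude_series, 0.08, tolerance = 1e-10)
  # all-zero window gives the no-scattering path
  att0 <- spectral_series(lam, 0, matrix(0, length(lam), 1),
                          kind = "attenuation")
  fit0 <- fit_scattering_window(att0)
  expect_identical(fit0$amplitude_series, 0)
})

test_that("scattering subtraction recovers a known absorption matrix", {
  lam <- seq(300, 900, by = 2)
  tt <- c(0, 24, 456)
  absorption <- outer(exp(-((lam - 500) / 60)^2), c(1, 0.6, 0.2))
  model <- scattering_model(tt, c(0, 0.08, 0.05), c(4, 2.6, 2.2), 900)
  scat <- outer(lam, 1:3, function(l, j)
    model$amplitude_series[j] * (900 / l)^model$gamma_series[j])
  att <- spectral_series(lam, tt, absorption + scat, kind = "attenuation")
  out <- subtract_scattering(att, model)
  expect_identical(out$kind, "absorption")
  expect_equal(out$values, absorption, tolerance = 1e-12)
  # t = 0 column had zero scattering amplitude: unchanged
  expect_equal(out$values[, 1], att$values[, 1])
  # zero model is the identity
  zero <- scattering_model(tt, c(0, 0, 0), c(4, 4, 4), 900)
  expect_equal(subtract_scattering(att, zero)$values, att$values)
  # mismatched time grids are a shape error
  bad <- scattering_model(c(0, 24), c(0, 0.08), c(4, 2.6), 900)
  expect_error(subtract_scattering(att, bad), "time grid")
  # clipping counts negatives
  deep <- scattering_model(tt, c(1, 1, 1), c(0.5, 0.5, 0.5), 900)
  clipped <- subtract_scattering(att, deep, clip = TRUE)
  expect_true(attr(clipped, "n_clipped") > 0)
  expect_true(all(clipped$values >= 0))
})

test_that("aggregation enhancement reproduces the published bound", {
  rep <- aggregation_enhancement(0.105, 24, 1.381e16, 5e-22)
  expect_equal(rep$M_sca, 0.105 / (1.381e16 * 5e-22), tolerance = 1e-12)
  expect_gt(rep$M_sca, 14000)
  expect_equal(rep$beta_m, rep$M_sca)
  expect_true(rep$rayleigh_limit_lower_bound)
  expect_equal(aggregation_enhancement(1.381e16 * 5e-22, 0, 1.381e16, 5e-22)$M_sca, 1)
  expect_equal(aggregation_enhancement(0, 0, 1.381e16, 5e-22)$M_sca, 0)
  expect_error(aggregation_enhancement(0.1, 0, -1, 5e-22), "> 0")
  expect_error(aggregation_enhancement(0.1, 0, 1e16, 0), "> 0")
})

test_that("Rayleigh cross-section obeys the size and wavelength power laws", {
  s1 <- rayleigh_cross_section(10, 750, 1.6, 1.33)
  expect_equal(rayleigh_cross_section(20, 750, 1.6, 1.33) / s1, 64,
               tolerance = 1e-12)
  expect_equal(s1 / rayleigh_cross_section(10, 1500, 1.6, 1.33), 16,
               tolerance = 1e-12)
  expect_equal(rayleigh_cross_section(10, 750, 1.33, 1.33), 0)
  expect_gt(s1, 0)
})
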