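test_that("time-constant schedule relaxes exponentially between its endpoints", {
  s <- rate_schedule(450, 80, 13)
  expect_equal(tau_of_t(s, 0), 450)
  expect_equal(tau_of_t(s, 13), (450 - 80) / exp(1) + 80, tolerance = 1e-12)
  expect_equal(tau_of_t(s, 1e6), 80, tolerance = 1e-9)
  const <- rate_schedule(200, 200, 50)
  expect_equal(tau_of_t(const, c(0, 10, 1000)), rep(200, 3))
  expect_error(tau_of_t(s, -1), ">= 0")
  expect_error(rate_schedule(450, -80, 13), "> 0")
})

test_that("closed-form survival matches brute-force quadrature", {
  quad_survival <- function(s, t) {
    exp(-stats::integrate(function(u) 1 / tau_of_t(s, u), 0, t,
                          rel.tol = 1e-13)$value)
  }
  s <- rate_schedule(450, 80, 13)
  expect_equal(survival_fraction(s, 0), 1)
  expect_equal(survival_fraction(s, 13), quad_survival(s, 13),
               tolerance = 1e-9)
  expect_equal(survival_fraction(s, 13), 0.9576, tolerance = 1e-4)
  set.seed(4)
  for (rep in 1:20) {
    sr <- rate_schedule(runif(1, 100, 6000), runif(1, 50, 3000),
                        runif(1, 5, 2000))
    for (t in c(1, 13, 95, 456, 2425))
      expect_equal(survival_fraction(sr, t), quad_survival(sr, t),
                   tolerance = 1e-9)
    # monotone nonincreasing
    tt <- seq(0, 2425, length.out = 40)
    expect_true(all(diff(survival_fraction(sr, tt)) <= 0))
  }
  # degenerate schedule reduces to a constant rate
  d <- rate_schedule(300, 300, 10)
  expect_equal(survival_fraction(d, c(10, 300, 900)),
               exp(-c(10, 300, 900) / 300), tolerance = 1e-12)
})

test_that("population ODE honours initial conditions and conservation", {
  p <- quasar_parameters()
  tr <- solve_populations(p, default_time_grid())
  expect_equal(unname(tr$N[1, ]),
               c(0.43, 0.57, 0, 0, 0, 0) * p$N0_cm3)
  expect_lt(max(abs(rowSums(tr$N) - p$N0_cm3)) / p$N0_cm3, 1e-7)
  # branch decays match the closed-form survival
  expect_equal(tr$N[, "Ret_580_I"] / (0.43 * p$N0_cm3),
               survival_fraction(p$scheduleI, tr$times_h), tolerance = 1e-7)
  expect_equal(tr$N[, "Ret_580_II"] / (0.57 * p$N0_cm3),
               survival_fraction(p$scheduleII, tr$times_h), tolerance = 1e-7)
  # monotonicity of sources and sinks
  expect_true(all(diff(tr$N[, "Ret_580_I"]) <= 0))
  expect_true(all(diff(tr$N[, "Ret_580_II"]) <= 0))
  expect_true(all(diff(tr$N[, "Ret_405"]) >= 0))
  expect_true(all(diff(tr$N[, "Ret_340"]) >= 0))
  # Ret_460 is drained faster than it forms
  expect_lt(max(tr$N[, "Ret_460"]), max(tr$N[, "Ret_500"]))
})

test_that("conservation holds across random parameter draws", {
  set.seed(9)
  for (rep in 1:50) {
    k <- runif(1, 0.05, 0.95)
    p <- kinetic_parameters(
      kappaI = k,
      scheduleI = rate_schedule(runif(1, 50, 3000), runif(1, 20, 2000),
                                runif(1, 5, 1500)),
      scheduleII = rate_schedule(runif(1, 50, 6000), runif(1, 20, 3000),
                                 runif(1, 5, 1500)),
      tau_Ret500_h = runif(1, 100, 3000), tau_Ret460_h = runif(1, 100, 3000),
      N0_cm3 = 1.381e16)
    tr <- solve_populations(p, c(0, 10, 100, 1000, 2425))
    expect_lt(max(abs(rowSums(tr$N) - p$N0_cm3)) / p$N0_cm3, 1e-7)
    expect_true(all(tr$N > -1e-7 * p$N0_cm3))
  }
})

test_that("long-time populations split into the branch fractions", {
  p <- quasar_parameters()
  tr <- solve_populations(p, c(0, 1e5))
  expect_equal(unname(tr$N[2, "Ret_405"]) / p$N0_cm3, 0.43, tolerance = 1e-5)
  expect_equal(unname(tr$N[2, "Ret_340"]) / p$N0_cm3, 0.57, tolerance = 1e-5)
})

test_that("constant-rate limit reduces to the textbook two-step cascade", {
  # with tau0 = tauInf the branch is A -> B -> C with constant rates
  tauA <- 500; tauB <- 1000
  p <- kinetic_parameters(
    kappaI = 1 - 1e-9, kappaII = 1e-9,
    scheduleI = rate_schedule(tauA, tauA, 100),
    scheduleII = rate_schedule(5000, 5000, 100),
    tau_Ret500_h = tauB, tau_Ret460_h = 400, N0_cm3 = 1)
  tt <- c(0, 50, 200, 800, 2425)
  tr <- solve_populations(p, tt)
  la <- 1 / tauA; lb <- 1 / tauB
  B_exact <- la / (lb - la) * (exp(-la * tt) - exp(-lb * tt))
  expect_equal(tr$N[, "Ret_580_I"], exp(-la * tt), tolerance = 1e-8)
  expect_equal(tr$N[, "Ret_500"], B_exact, tolerance = 1e-7)
  expect_equal(tr$N[, "Ret_405"], 1 - exp(-la * tt) - B_exact,
               tolerance = 1e-7)
})

test_that("initial density is the Beer-Lambert quotient", {
  expect_equal(initial_density(2.20, 1.593e-16), 1.381e16, tolerance = 1e-3)
  expect_equal(initial_density(0, 1.593e-16), 0)
  expect_equal(initial_density(1.593e-16, 1.593e-16), 1)
  expect_error(initial_density(1, 0), "> 0")
  expect_error(initial_density(-1, 1e-16), ">= 0")
})

test_that("parameter container validates the branch split", {
  expect_error(kinetic_parameters(0.43, 0.5,
                                  rate_schedule(450, 80, 13),
                                  rate_schedule(5000, 1700, 1000),
                                  1000, 400, 1e16),
               "must equal 1")
  expect_error(kinetic_parameters(1.2, -0.2,
                                  rate_schedule(450, 80, 13),
                                  rate_schedule(5000, 1700, 1000),
                                  1000, 400, 1e16),
               "kappaI")
  expect_error(solve_populations(quasar_parameters(), c(10, 5)),
               "strictly increasing")
})
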