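# shared fixtures, built once per test run

default_time_grid <- function() {
  c(0, 6, 10, 24, 48, 95, 117, 168, 240, 336, 456, 600, 800, 1000, 1200,
    1600, 2000, 2424)
}

# published parameter values with their printed uncertainties, used as
# recovery tolerances
table1_tolerances <- function() {
  list(kappaI = 0.02, tau0_I = 50, tauInf_I = 10, delta_I = 1,
       tau0_II = 300, tauInf_II = 100, delta_II = 50,
       tau_Ret500 = 50, tau_Ret460 = 30)
}

.fixture_env <- new.env()

cached_bands <- function() {
  if (is.null(.fixture_env$bands)) .fixture_env$bands <- default_bands()
  .fixture_env$bands
}

cached_noiseless_scenario <- function() {
  if (is.null(.fixture_env$noiseless)) {
    .fixture_env$noiseless <- generate_scenario(
      scenario_config(bands = cached_bands(), noise_sd_cm1 = 0))
  }
  .fixture_env$noiseless
}

# flat named vector of the nine free kinetic parameters
param_vector <- function(p) {
  c(kappaI = p$kappaI,
    tau0_I = p$scheduleI$tau0_h, tauInf_I = p$scheduleI$tauInf_h,
    delta_I = p$scheduleI$delta_h,
    tau0_II = p$scheduleII$tau0_h, tauInf_II = p$scheduleII$tauInf_h,
    delta_II = p$scheduleII$delta_h,
    tau_Ret500 = p$tau_Ret500_h, tau_Ret460 = p$tau_Ret460_h)
}

# multiplicative x[0.5, 2] perturbation of a parameter set (time
# constants jittered in log space, kappa_I reset off-truth)
perturbed_start <- function(p, seed) {
  set.seed(seed)
  per <- function(x) x * exp(stats::runif(1, log(0.5), log(2)))
  kinetic_parameters(
    kappaI = 0.5,
    scheduleI = rate_schedule(per(p$scheduleI$tau0_h),
                              per(p$scheduleI$tauInf_h),
                              per(p$scheduleI$delta_h)),
    scheduleII = rate_schedule(per(p$scheduleII$tau0_h),
                               per(p$scheduleII$tauInf_h),
                               per(p$scheduleII$delta_h)),
    tau_Ret500_h = per(p$tau_Ret500_h), tau_Ret460_h = per(p$tau_Ret460_h),
    N0_cm3 = p$N0_cm3)
}

# hand-built population trajectory (for linearity/consistency tests)
manual_trajectory <- function(times_h, N, N0 = sum(N[1, ])) {
  colnames(N) <- c("Ret_580_I", "Ret_580_II", "Ret_500", "Ret_460",
                   "Ret_405", "Ret_340")
  structure(list(times_h = times_h, N = N, N0_cm3 = N0),
            class = "population_trajectory")
}
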