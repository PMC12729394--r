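#!/usr/bin/env Rscript
# Stage 4: global kinetic parameter estimation.
#
# Fits the ten-parameter two-branch isomerization/deprotonation model to
# the eight observable series extracted from the scattering-corrected,
# decomposed spectra (stage 3), by multi-start Levenberg-Marquardt
# weighted least squares, and compares the estimates with the
# generating values.

suppressPackageStartupMessages(library(quasarkin))

out_dir <- "results/fit"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

obs_df <- utils::read.csv("results/decomposition/observables.csv")
obs <- structure(c(list(times_h = obs_df$t_h),
                   as.list(obs_df[, -1])), class = "observable_series")

xsec <- quasar_cross_sections()
truth <- quasar_parameters()

# start from the published values perturbed x[0.5, 2]; the multi-start
# machinery jitters further around this start
set.seed(404)
perturb <- function(x) x * exp(stats::runif(1, log(0.5), log(2)))
start <- kinetic_parameters(
  kappaI = 0.5,
  scheduleI = rate_schedule(perturb(450), perturb(80), perturb(13)),
  scheduleII = rate_schedule(perturb(5000), perturb(1700), perturb(1000)),
  tau_Ret500_h = perturb(1000), tau_Ret460_h = perturb(400),
  N0_cm3 = truth$N0_cm3)

fit <- fit_kinetics(obs, xsec, start, n_starts = 8, seed = 404)
est <- fit$params

flat <- function(p) c(kappa_I = p$kappaI, kappa_II = p$kappaII,
                      tau0_I_h = p$scheduleI$tau0_h,
                      tauInf_I_h = p$scheduleI$tauInf_h,
                      delta_I_h = p$scheduleI$delta_h,
                      tau0_II_h = p$scheduleII$tau0_h,
                      tauInf_II_h = p$scheduleII$tauInf_h,
                      delta_II_h = p$scheduleII$delta_h,
                      tau_Ret500_h = p$tau_Ret500_h,
                      tau_Ret460_h = p$tau_Ret460_h)
tab <- data.frame(parameter = names(flat(truth)),
                  truth = unname(flat(truth)),
                  estimate = unname(flat(est)))
tab$rel_error_pct <- 100 * (tab$estimate - tab$truth) / tab$truth
utils::write.csv(tab, file.path(out_dir, "estimates.csv"), row.names = FALSE)
print(tab, digits = 4)
message(sprintf("objective %.3e after %d LM iterations over %d starts; converged: %s",
                fit$objective, fit$n_evaluations, fit$n_starts, fit$converged))
message(paste("note: under measurement noise the branch fractions and the",
              "deprotonation time constants are recovered tightly, while the",
              "relaxing isomerization schedules (especially branch II) are",
              "weakly identified on a 0-2425 h window; see stage 5 for the",
              "noiseless closure"))

jsonlite::write_json(list(stage = "fit", seed = 404, n_starts = fit$n_starts,
                          objective = fit$objective,
                          converged = fit$converged,
                          estimates = as.list(stats::setNames(tab$estimate,
                                                              tab$parameter)),
                          outputs = list.files(out_dir)),
                     file.path(out_dir, "manifest.json"),
                     auto_unbox = TRUE, pretty = TRUE)
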