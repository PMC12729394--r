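# internal parameter transform: the nine free quantities are optimized
# as logit(kappaI) plus the logs of the eight time constants (they span
# 13-5000 h; log space keeps the problem well conditioned). kappaII is
# always 1 - kappaI.
.theta_names <- c("kappaI", "tau0_I", "tauInf_I", "delta_I",
                  "tau0_II", "tauInf_II", "delta_II",
                  "tau_Ret500", "tau_Ret460")

.params_to_theta <- function(params) {
  c(stats::qlogis(params$kappaI),
    log(c(params$scheduleI$tau0_h, params$scheduleI$tauInf_h,
          params$scheduleI$delta_h,
          params$scheduleII$tau0_h, params$scheduleII$tauInf_h,
          params$scheduleII$delta_h,
          params$tau_Ret500_h, params$tau_Ret460_h)))
}

.theta_to_params <- function(theta, N0_cm3) {
  k <- stats::plogis(theta[1])
  tc <- exp(theta[-1])
  kinetic_parameters(
    kappaI = k, kappaII = 1 - k,
    scheduleI = rate_schedule(tc[1], tc[2], tc[3]),
    scheduleII = rate_schedule(tc[4], tc[5], tc[6]),
    tau_Ret500_h = tc[7], tau_Ret460_h = tc[8],
    N0_cm3 = N0_cm3)
}

.default_weights <- function(observed) {
  w <- vapply(OBSERVABLE_NAMES,
              function(nm) 1 / max(abs(observed[[nm]]))^2, numeric(1))
  if (any(!is.finite(w))) stop("a series is identically zero; supply weights")
  w
}

.predict_from_theta <- function(theta, times_h, xsec, N0_cm3,
                                rtol = 1e-8) {
  params <- .theta_to_params(theta, N0_cm3)
  traj <- solve_populations(params, times_h, rtol = rtol,
                            atol = 1e-10 * N0_cm3)
  predict_observables(traj, xsec)
}

.weighted_residuals <- function(theta, observed, xsec, weights, N0_cm3) {
  pred <- .predict_from_theta(theta, observed$times_h, xsec, N0_cm3)
  unlist(lapply(OBSERVABLE_NAMES, function(nm)
    sqrt(weights[[nm]]) * (pred[[nm]] - observed[[nm]])), use.names = FALSE)
}

#' Weighted least-squares objective for the kinetic model
#'
#' `sum_s w_s sum_t (pred_s(t) - obs_s(t))^2` over the eight observable
#' series. Default weights normalize each series by its maximum
#' magnitude so the small double-difference series are not swamped by
#' the large 580 nm series. Parameter sets violating the model
#' invariants return a large penalty value (with attribute
#' `invalid = TRUE`) rather than raising, so optimizers can traverse.
#'
#' @param params A [kinetic_parameters()] (or a list attempting to be one).
#' @param observed An `observable_series` (the data).
#' @param xsec A [cross_section_table()].
#' @param weights Named per-series weights; default `1/max(|obs_s|)^2`.
#' @return Nonnegative scalar objective value.
#' @export
kinetic_objective <- function(params, observed, xsec, weights = NULL) {
  if (is.null(weights)) weights <- .default_weights(observed)
  ok <- tryCatch({
    if (!inherits(params, "kinetic_parameters"))
      params <- do.call(kinetic_parameters, params)
    TRUE
  }, error = function(e) FALSE)
  if (!ok)
    return(structure(1e12, invalid = TRUE))
  theta <- .params_to_theta(params)
  r <- .weighted_residuals(theta, observed, xsec, weights, params$N0_cm3)
  sum(r^2)
}

#' Global multi-start fit of the ten kinetic parameters
#'
#' Levenberg-Marquardt weighted least squares of the eight observable
#' series over (kappa_I, the two three-parameter isomerization
#' schedules, and the two deprotonation time constants); kappa_II is
#' parameterized as 1 - kappa_I throughout, and N0 and the
#' cross-section table are held fixed (they are inputs). The best of
#' `n_starts` local optimizations is returned; start points are the
#' supplied start with log-uniform x[0.5, 2] jitter of the time
#' constants and uniform +/-0.1 jitter of kappa_I. Deterministic for a
#' fixed seed.
#'
#' @param observed An `observable_series`.
#' @param xsec A [cross_section_table()].
#' @param start A [kinetic_parameters()] start point (also fixes N0).
#' @param lower,upper Optional named bounds on the natural scale for
#'   `kappaI` and the eight time constants; defaults are kappa_I in
#'   (0.01, 0.99) and each time constant within a factor 20 of its
#'   start.
#' @param n_starts Number of local optimizations (default 8).
#' @param seed Integer seed for the start-point jitter.
#' @param weights Optional per-series weights (see [kinetic_objective()]).
#' @return An object of class `fit_result`: `params` (best-fit
#'   [kinetic_parameters()]), `objective`, `residual_norms` (per
#'   series), `converged`, `n_evaluations`, `seed`, and
#'   `start_objectives` for all local runs.
#' @export
fit_kinetics <- function(observed, xsec, start, lower = NULL, upper = NULL,
                         n_starts = 8, seed = 1L, weights = NULL) {
  stopifnot(inherits(observed, "observable_series"),
            inherits(xsec, "cross_section_table"),
            inherits(start, "kinetic_parameters"))
  if (is.null(weights)) weights <- .default_weights(observed)
  N0 <- start$N0_cm3
  theta0 <- .params_to_theta(start)
  tc0 <- exp(theta0[-1])
  lo <- c(stats::qlogis(if (is.null(lower$kappaI)) 0.01 else lower$kappaI),
          log(tc0 / 20))
  hi <- c(stats::qlogis(if (is.null(upper$kappaI)) 0.99 else upper$kappaI),
          log(tc0 * 20))
  for (nm in setdiff(names(lower), "kappaI"))
    lo[match(nm, .theta_names)] <- log(lower[[nm]])
  for (nm in setdiff(names(upper), "kappaI"))
    hi[match(nm, .theta_names)] <- log(upper[[nm]])
  if (any(theta0 < lo | theta0 > hi))
    stop("bounds must bracket the start point")

  old <- .Random.seed_save()
  set.seed(as.integer(seed))
  starts <- vector("list", n_starts)
  starts[[1]] <- theta0
  if (n_starts > 1) {
    for (j in 2:n_starts) {
      th <- theta0
      th[-1] <- th[-1] + stats::runif(8, log(0.5), log(2))
      k <- stats::plogis(th[1]) + stats::runif(1, -0.1, 0.1)
      th[1] <- stats::qlogis(min(max(k, 0.02), 0.98))
      starts[[j]] <- pmin(pmax(th, lo), hi)
    }
  }
  .Random.seed_restore(old)

  resfun <- function(th) .weighted_residuals(th, observed, xsec, weights, N0)
  best <- NULL
  start_obj <- numeric(n_starts)
  nfev <- 0L
  any_conv <- FALSE
  for (j in seq_len(n_starts)) {
    run <- tryCatch(
      minpack.lm::nls.lm(par = starts[[j]], fn = resfun,
                         lower = lo, upper = hi,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 300, ftol = 1e-13, ptol = 1e-13)),
      error = function(e) NULL)
    if (is.null(run)) { start_obj[j] <- NA_real_; next }
    obj <- sum(run$fvec^2)
    start_obj[j] <- obj
    nfev <- nfev + run$niter
    conv <- run$info %in% 1:4
    any_conv <- any_conv || conv
    if (is.null(best) || obj < best$obj)
      best <- list(par = run$par, obj = obj, conv = conv)
  }
  if (is.null(best))
    stop("all local optimizations failed")
  params_hat <- .theta_to_params(best$par, N0)
  pred <- .predict_from_theta(best$par, observed$times_h, xsec, N0)
  rn <- vapply(OBSERVABLE_NAMES, function(nm)
    sqrt(sum((pred[[nm]] - observed[[nm]])^2)), numeric(1))
  structure(list(params = params_hat, objective = best$obj,
                 residual_norms = rn, converged = any_conv && best$conv,
                 n_evaluations = nfev, seed = as.integer(seed),
                 n_starts = n_starts, start_objectives = start_obj),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("fit_result: objective = %.3e, converged = %s, %d LM iterations over %d starts (seed %d)\n",
              x$objective, x$converged, x$n_evaluations, x$n_starts, x$seed))
  print(x$params)
  invisible(x)
}
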