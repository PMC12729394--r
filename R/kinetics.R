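#' Exponentially relaxing isomerization time-constant schedule
#'
#' The isomerization of the protonated Schiff base speeds up (or slows
#' down) with storage time, presumably through slow structural change of
#' the apoprotein. The time constant relaxes exponentially from an
#' initial to a final value:
#' `tau(t) = (tau0 - tauInf) * exp(-t / delta) + tauInf`.
#'
#' @param tau0_h Initial time constant (h), > 0.
#' @param tauInf_h Final time constant (h), > 0.
#' @param delta_h Change-over time constant (h), > 0.
#' @return An object of class `rate_schedule`.
#' @export
rate_schedule <- function(tau0_h, tauInf_h, delta_h) {
  vals <- c(tau0_h = tau0_h, tauInf_h = tauInf_h, delta_h = delta_h)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("rate_schedule components must be finite and > 0")
  structure(as.list(vals), class = "rate_schedule")
}

#' Evaluate a rate schedule at a storage time
#'
#' @param schedule A [rate_schedule()].
#' @param t_h Storage time(s) in hours, >= 0.
#' @return Time constant tau(t) in hours.
#' @export
tau_of_t <- function(schedule, t_h) {
  stopifnot(inherits(schedule, "rate_schedule"))
  if (any(t_h < 0)) stop("t_h must be >= 0")
  (schedule$tau0_h - schedule$tauInf_h) * exp(-t_h / schedule$delta_h) +
    schedule$tauInf_h
}

#' Closed-form survival fraction under a relaxing time constant
#'
#' For a species decaying as `dN/dt = -N / tau(t)` with the schedule of
#' [rate_schedule()], the survival fraction has the closed form
#' `S(t) = exp(-t/tauInf) * [((tau0 - tauInf) e^{-t/delta} + tauInf) / tau0]^(-delta/tauInf)`,
#' obtained by integrating `1/tau(s)` analytically. Used as an
#' independent cross-check of the numerical ODE solution.
#'
#' @param schedule A [rate_schedule()].
#' @param t_h Storage time(s) in hours, >= 0.
#' @return Dimensionless survival fraction in (0, 1].
#' @export
survival_fraction <- function(schedule, t_h) {
  stopifnot(inherits(schedule, "rate_schedule"))
  if (any(t_h < 0)) stop("t_h must be >= 0")
  A <- schedule$tau0_h - schedule$tauInf_h
  B <- schedule$tauInf_h
  d <- schedule$delta_h
  # integral of 1/tau from 0 to t: t/B + (d/B) * log((A e^{-t/d} + B) / (A + B))
  exp(-(t_h / B) - (d / B) * log((A * exp(-t_h / d) + B) / (A + B)))
}

#' Kinetic parameter set for the two-branch degradation scheme
#'
#' The initially present protonated retinal Schiff base Ret_580 splits
#' into two fractions: branch I (fraction `kappaI`) isomerizes to Ret_500
#' which deprotonates to Ret_405; branch II (fraction `kappaII`)
#' isomerizes to Ret_460 which deprotonates to Ret_340. Both
#' isomerizations follow relaxing time-constant schedules; the
#' deprotonations have fixed time constants.
#'
#' @param kappaI Initial fraction of Ret_580 in branch I (dimensionless).
#' @param kappaII Initial fraction in branch II; must equal `1 - kappaI`
#'   to within 1e-9.
#' @param scheduleI,scheduleII [rate_schedule()] for the branch I / II
#'   isomerization time constants.
#' @param tau_Ret500_h Deprotonation time constant of Ret_500 (h).
#' @param tau_Ret460_h Deprotonation time constant of Ret_460 (h).
#' @param N0_cm3 Initial Ret_580 number density (cm^-3).
#' @return An object of class `kinetic_parameters`.
#' @export
kinetic_parameters <- function(kappaI, kappaII = 1 - kappaI,
                               scheduleI, scheduleII,
                               tau_Ret500_h, tau_Ret460_h, N0_cm3) {
  if (!is.finite(kappaI) || kappaI < 0 || kappaI > 1)
    stop("kappaI must lie in [0, 1]")
  if (abs(kappaI + kappaII - 1) > 1e-9)
    stop("kappaI + kappaII must equal 1 (to 1e-9)")
  stopifnot(inherits(scheduleI, "rate_schedule"),
            inherits(scheduleII, "rate_schedule"))
  if (!is.finite(tau_Ret500_h) || tau_Ret500_h <= 0)
    stop("tau_Ret500_h must be > 0")
  if (!is.finite(tau_Ret460_h) || tau_Ret460_h <= 0)
    stop("tau_Ret460_h must be > 0")
  if (!is.finite(N0_cm3) || N0_cm3 <= 0)
    stop("N0_cm3 must be > 0")
  structure(list(kappaI = kappaI, kappaII = kappaII,
                 scheduleI = scheduleI, scheduleII = scheduleII,
                 tau_Ret500_h = tau_Ret500_h, tau_Ret460_h = tau_Ret460_h,
                 N0_cm3 = N0_cm3),
            class = "kinetic_parameters")
}

#' @export
print.kinetic_parameters <- function(x, ...) {
  cat(sprintf(paste0(
    "kinetic_parameters:\n",
    "  kappa_I = %.4g, kappa_II = %.4g\n",
    "  branch I : tau0 = %.4g h, tauInf = %.4g h, delta = %.4g h\n",
    "  branch II: tau0 = %.4g h, tauInf = %.4g h, delta = %.4g h\n",
    "  tau_Ret500 = %.4g h, tau_Ret460 = %.4g h, N0 = %.4g cm^-3\n"),
    x$kappaI, x$kappaII,
    x$scheduleI$tau0_h, x$scheduleI$tauInf_h, x$scheduleI$delta_h,
    x$scheduleII$tau0_h, x$scheduleII$tauInf_h, x$scheduleII$delta_h,
    x$tau_Ret500_h, x$tau_Ret460_h, x$N0_cm3))
  invisible(x)
}

#' Published kinetic parameter values for QuasAr1
#'
#' The best-fit parameter set for QuasAr1 in pH 8 Tris buffer at room
#' temperature in the dark: kappa_I = 0.43, kappa_II = 0.57; branch I
#' schedule (450, 80, 13) h; branch II schedule (5000, 1700, 1000) h;
#' deprotonation time constants 1000 h (Ret_500) and 400 h (Ret_460);
#' initial density 1.381e16 cm^-3.
#'
#' @return A [kinetic_parameters()] object.
#' @export
quasar_parameters <- function() {
  kinetic_parameters(
    kappaI = 0.43, kappaII = 0.57,
    scheduleI = rate_schedule(450, 80, 13),
    scheduleII = rate_schedule(5000, 1700, 1000),
    tau_Ret500_h = 1000, tau_Ret460_h = 400,
    N0_cm3 = 1.381e16)
}

#' Initial chromophore number density from the Beer-Lambert relation
#'
#' `N0 = alpha_a(580 nm, 0) / sigma_a,Ret580(580 nm)`.
#'
#' @param alpha0 Initial absorption coefficient (cm^-1), >= 0.
#' @param sigma Absorption cross-section (cm^2), > 0.
#' @return Number density in cm^-3.
#' @export
initial_density <- function(alpha0, sigma) {
  if (any(alpha0 < 0)) stop("alpha0 must be >= 0")
  if (any(sigma <= 0)) stop("sigma must be > 0")
  alpha0 / sigma
}

SPECIES <- c("Ret_580_I", "Ret_580_II", "Ret_500", "Ret_460",
             "Ret_405", "Ret_340")

#' Solve the six-species population ODE system
#'
#' Integrates the irreversible reaction network
#' Ret_580_I -> Ret_500 -> Ret_405 and Ret_580_II -> Ret_460 -> Ret_340,
#' with time-dependent isomerization rates `1/tau(t)` from the branch
#' schedules, using a stiff-capable adaptive integrator (lsoda) with
#' dense output at the requested times. Total population is conserved.
#'
#' @param params A [kinetic_parameters()].
#' @param times_h Sorted output time grid (h), `times_h[1] >= 0`.
#' @param rtol,atol Solver tolerances. Defaults satisfy the package's
#'   conservation contract (relative error below 1e-7 of N0).
#' @return An object of class `population_trajectory`: list with
#'   `times_h` and matrix `N` (times x 6 species, cm^-3).
#' @export
solve_populations <- function(params, times_h,
                              rtol = 1e-10, atol = 1e-12 * params$N0_cm3) {
  stopifnot(inherits(params, "kinetic_parameters"))
  times_h <- as.numeric(times_h)
  if (is.unsorted(times_h, strictly = TRUE)) stop("times_h must be strictly increasing")
  if (times_h[1] < 0) stop("times_h must be >= 0")
  y0 <- c(params$kappaI * params$N0_cm3, params$kappaII * params$N0_cm3,
          0, 0, 0, 0)
  names(y0) <- SPECIES
  sI <- params$scheduleI; sII <- params$scheduleII
  t500 <- params$tau_Ret500_h; t460 <- params$tau_Ret460_h
  rhs <- function(t, y, parms) {
    kI <- 1 / ((sI$tau0_h - sI$tauInf_h) * exp(-t / sI$delta_h) + sI$tauInf_h)
    kII <- 1 / ((sII$tau0_h - sII$tauInf_h) * exp(-t / sII$delta_h) + sII$tauInf_h)
    list(c(-y[1] * kI,
           -y[2] * kII,
           y[1] * kI - y[3] / t500,
           y[2] * kII - y[4] / t460,
           y[3] / t500,
           y[4] / t460))
  }
  tt <- times_h
  prepend0 <- tt[1] > 0
  if (prepend0) tt <- c(0, tt)
  sol <- deSolve::lsoda(y0, tt, rhs, parms = NULL, rtol = rtol, atol = atol)
  if (attr(sol, "istate")[1] < 0)
    stop("ODE solver failed to converge; istate = ", attr(sol, "istate")[1])
  N <- unname(sol[, -1, drop = FALSE])
  if (prepend0) N <- N[-1, , drop = FALSE]
  colnames(N) <- SPECIES
  structure(list(times_h = times_h, N = N, N0_cm3 = params$N0_cm3),
            class = "population_trajectory")
}

#' @export
print.population_trajectory <- function(x, ...) {
  cat(sprintf("population_trajectory: %d times (%g-%g h), N0 = %.4g cm^-3\n",
              length(x$times_h), min(x$times_h), max(x$times_h), x$N0_cm3))
  invisible(x)
}

#' Export a population trajectory as a data frame
#'
#' @param x A `population_trajectory`.
#' @param row.names,optional,... Passed through for S3 compatibility.
#' @return Data frame with `t_h` and one column per species (cm^-3).
#' @export
as.data.frame.population_trajectory <- function(x, row.names = NULL,
                                                optional = FALSE, ...) {
  data.frame(t_h = x$times_h, as.data.frame(x$N), check.names = FALSE)
}
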