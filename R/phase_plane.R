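#' Numerical separatrix of the deterministic phasic model
#'
#' For each recovery value `w` on a grid, bisects on the initial membrane
#' value `v` between a non-spiking and a spiking initial condition. The
#' classifier integrates the deterministic system ([integrate_deterministic()])
#' from `(v, w)` and asks whether [detect_spikes()] at the variant's `w_c`
#' reports an excursion. The returned curve `v*(w)` separates initial
#' conditions that relax straight back to rest from those that take a spike
#' excursion first.
#'
#' @param params deterministic [fn_params()] (`D = 0`, `A = 0` required).
#' @param w_range range of `w` covered by the grid. The spike branch of the
#'   separatrix only exists below the cubic's fold maximum (w ~ 0.12): above
#'   it no initial `v` can produce an excursion, so the default grid stops
#'   at 0.1.
#' @param n_w number of grid points.
#' @param tol bisection convergence tolerance on `v`.
#' @param v_bracket initial bracket on `v` (non-spiking left endpoint: the
#'   rest basin interior; strongly negative `v` rebounds into a spike);
#'   widened once (by 1 on each side)
#'   if its endpoints classify identically, after which failure signals.
#' @param t_end classification horizon (ms); long enough that non-spiking
#'   paths demonstrably decay back to rest.
#' @param dt RK4 step used by the classifier.
#' @return Object of class `"separatrix"`: `w`, `v_star`, `tol`, plus the
#'   classification settings.
#' @export
compute_separatrix <- function(params, w_range = c(-0.05, 0.1), n_w = 31,
                               tol = 1e-5, v_bracket = c(0, 1.5),
                               t_end = 150, dt = 0.005) {
  stopifnot(inherits(params, "fn_params"))
  if (params$D != 0 || params$A != 0)
    stop("separatrix is a deterministic construction: set D = 0 and A = 0")
  w_grid <- seq(w_range[1], w_range[2], length.out = n_w)
  spikes_from <- function(v0, w0) {
    traj <- integrate_deterministic(params, c(v0, w0), t_end, dt)
    length(detect_spikes(traj, params$w_c)[[1]]$times) > 0
  }
  v_star <- vapply(w_grid, function(w0) {
    lo <- v_bracket[1]; hi <- v_bracket[2]
    if (spikes_from(lo, w0) || !spikes_from(hi, w0)) {
      lo <- lo - 1; hi <- hi + 1          # one widening attempt
      if (spikes_from(lo, w0) || !spikes_from(hi, w0))
        stop(sprintf("bracket endpoints classify identically at w = %g", w0))
    }
    while (hi - lo > tol) {
      mid <- (lo + hi) / 2
      if (spikes_from(mid, w0)) hi <- mid else lo <- mid
    }
    (lo + hi) / 2
  }, 1)
  structure(list(w = w_grid, v_star = v_star, tol = tol, t_end = t_end,
                 dt = dt, params = params),
            class = "separatrix")
}

#' @export
print.separatrix <- function(x, ...) {
  cat(sprintf("separatrix: %d points on w in [%g, %g], tol = %g\n",
              length(x$w), min(x$w), max(x$w), x$tol))
  invisible(x)
}

#' Distance-to-threshold trace along a deterministic trajectory
#'
#' Integrates the deterministic system from `ic` and reports
#' \eqn{\Delta U(t) = v^*(w(t)) - v(t)}: the horizontal (v-direction)
#' distance from the trajectory point to the separatrix at the same `w`.
#' A transient dip of \eqn{\Delta U(t)} below its rest value is the
#' phase-plane signature of hyperpolarization lowering the effective spike
#' threshold.
#'
#' @param params deterministic [fn_params()].
#' @param ic initial condition `c(v0, w0)`.
#' @param separatrix a [compute_separatrix()] result covering the
#'   trajectory's `w` range; leaving the covered range signals an error with
#'   the exit time.
#' @param t_end,dt integration horizon and step.
#' @return Object of class `"distance_trace"`: `t`, `dU`, and the rest
#'   distance `dU_rest = v*(0)`.
#' @export
threshold_distance_trace <- function(params, ic, separatrix,
                                     t_end = 100, dt = 0.005) {
  stopifnot(inherits(separatrix, "separatrix"))
  if (params$D != 0 || params$A != 0)
    stop("distance trace is a deterministic construction: set D = 0, A = 0")
  traj <- integrate_deterministic(params, ic, t_end, dt)
  w <- traj$w[, 1]
  out_of_range <- w < min(separatrix$w) | w > max(separatrix$w)
  if (any(out_of_range))
    stop(sprintf("trajectory leaves the separatrix w-grid at t = %g ms",
                 traj$t[which(out_of_range)[1]]))
  v_star_w <- approx(separatrix$w, separatrix$v_star, xout = w)$y
  dU_rest <- approx(separatrix$w, separatrix$v_star, xout = 0)$y
  structure(list(t = traj$t, dU = v_star_w - traj$v[, 1],
                 dU_rest = dU_rest),
            class = "distance_trace")
}

#' @export
print.distance_trace <- function(x, ...) {
  cat(sprintf(
    "distance trace: %d samples, min dU = %.4f (rest %.4f)\n",
    length(x$t), min(x$dU), x$dU_rest))
  invisible(x)
}
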