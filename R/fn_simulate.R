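#' Spike train container
#'
#' @param times strictly increasing spike times in `[0, duration)` (ms).
#' @param duration observation window (ms).
#' @param cell_id ensemble index of the originating cell.
#' @return Object of class `"spike_train"`.
#' @export
spike_train <- function(times, duration, cell_id = 1L) {
  times <- as.numeric(times)
  stopifnot(
    "duration must be > 0" = duration > 0,
    "spike times must lie in [0, duration)" =
      length(times) == 0 || (min(times) >= 0 && max(times) < duration),
    "spike times must be strictly increasing" =
      length(times) < 2 || all(diff(times) > 0)
  )
  structure(list(times = times, duration = duration,
                 cell_id = as.integer(cell_id)),
            class = "spike_train")
}

#' @export
print.spike_train <- function(x, ...) {
  cat(sprintf("spike train: %d spikes in %g ms (cell %d)\n",
              length(x$times), x$duration, x$cell_id))
  invisible(x)
}

#' Simulate the stochastic FitzHugh-Nagumo ensemble
#'
#' Integrates an ensemble of uncoupled cells with the Euler-Maruyama scheme.
#' The noise increment applied to the `v`-equation at each step has mean 0
#' and variance `2 * D * dt / tau_v^2`; the sinusoidal drive
#' `A * sin(2*pi*phi*t)` enters the `v`-drift. With `D = 0` the scheme
#' reduces to deterministic Euler and the path from rest stays at rest.
#' Spikes are detected online as upward crossings of `w` through
#' `params$w_c` (previous sample strictly below), linearly interpolated
#' between the bracketing samples.
#'
#' @param params an [fn_params()] object.
#' @param record_trajectory keep the full `(t, v, w)` paths. Only sensible
#'   for small runs; refused beyond 2e7 stored samples per variable.
#' @param record_noise keep the sampled noise path, stored as per-step
#'   increments divided by `sqrt(dt)` (an estimate of the white-noise
#'   process `xi`). Same size guard as `record_trajectory`.
#' @param sta_window optional numeric pair `c(pre_ms, post_ms)`: accumulate
#'   the spike-triggered average of the noise online, without storing the
#'   noise path. See [spike_triggered_average()].
#' @param init initial condition `c(v, w)` shared by all cells.
#' @return Object of class `"fn_sim"`: the parameters, a list of
#'   [spike_train()]s (one per cell), and optionally `trajectory` (class
#'   `"fn_trajectory"` with `t`, matrices `v`, `w`, and `noise`) and `sta`
#'   (class `"sta_result"`).
#' @examples
#' sim <- simulate_fn(fn_params(D = 0.03, duration = 2000, n_cells = 2))
#' firing_rate(sim$trains)
#' @export
simulate_fn <- function(params, record_trajectory = FALSE,
                        record_noise = FALSE, sta_window = NULL,
                        init = c(0, 0)) {
  stopifnot(inherits(params, "fn_params"))
  n_steps <- round(params$duration / params$dt)
  if ((record_trajectory || record_noise) &&
      n_steps * params$n_cells > 2e7)
    stop("trajectory/noise recording refused for ", n_steps * params$n_cells,
         " samples per variable; shorten the run or drop the recording")
  do_sta <- !is.null(sta_window)
  if (do_sta) {
    stopifnot(length(sta_window) == 2, all(sta_window >= 0))
    if (sta_window[1] + sta_window[2] >= params$duration)
      stop("sta_window exceeds the simulated duration")
  }
  raw <- fn_simulate_cpp(fn_par_cpp(params), record_trajectory, record_noise,
                         do_sta,
                         if (do_sta) sta_window[1] else 0,
                         if (do_sta) sta_window[2] else 0,
                         init[1], init[2])
  trains <- lapply(seq_len(params$n_cells), function(c)
    spike_train(raw$spikes[[c]], params$duration, c))
  out <- list(params = params, trains = trains)
  if (record_trajectory || record_noise) {
    out$trajectory <- structure(
      list(t = seq(0, by = params$dt, length.out = raw$n_steps + 1),
           v = if (record_trajectory) raw$v else NULL,
           w = if (record_trajectory) raw$w else NULL,
           noise = if (record_noise) raw$noise else NULL,
           dt = params$dt),
      class = "fn_trajectory")
  }
  if (do_sta) {
    dt <- params$dt
    n_pre <- round(sta_window[1] / dt)
    n_post <- round(sta_window[2] / dt)
    out$sta <- new_sta_result(
      lag = seq(-n_pre, n_post) * dt,
      average = if (raw$sta_count > 0) raw$sta_sum / raw$sta_count
                else rep(NA_real_, n_pre + n_post + 1),
      n_spikes = raw$sta_count)
  }
  class(out) <- "fn_sim"
  out
}

#' @export
print.fn_sim <- function(x, ...) {
  n <- sum(vapply(x$trains, function(tr) length(tr$times), 1L))
  cat(sprintf("FN simulation: %d cells x %g ms, %d spikes (nu = %.4g /ms)\n",
              x$params$n_cells, x$params$duration, n,
              n / (x$params$n_cells * x$params$duration)))
  invisible(x)
}

#' Deterministic integration of the FitzHugh-Nagumo model
#'
#' Fixed-step 4th-order Runge-Kutta path of the noise-free system
#' (`D = 0` semantics regardless of `params$D`; the sinusoidal drive in
#' `params` is retained). Used by the phase-plane module, where classified
#' spiking/non-spiking trajectories feed the separatrix bisection.
#'
#' @param params an [fn_params()] object (its `D` is ignored).
#' @param ic initial condition `c(v0, w0)`.
#' @param t_end integration horizon (ms).
#' @param dt RK4 step (ms); the default 0.005 changes the path by well under
#'   1e-8 compared with half the step.
#' @return `"fn_trajectory"` object with single-column `v`, `w`.
#' @export
integrate_deterministic <- function(params, ic, t_end, dt = 0.005) {
  stopifnot(inherits(params, "fn_params"), t_end > 0, dt > 0,
            length(ic) == 2)
  raw <- fn_rk4_cpp(fn_par_cpp(params), ic[1], ic[2], t_end, dt)
  structure(list(t = raw$t, v = matrix(raw$v, ncol = 1),
                 w = matrix(raw$w, ncol = 1), noise = NULL, dt = dt),
            class = "fn_trajectory")
}

#' Detect spikes on a recorded trajectory
#'
#' Upward crossings of the recovery variable `w` through `w_c`, located by
#' linear interpolation between the bracketing samples. A sample exactly at
#' `w_c` counts as a crossing only when the previous sample is strictly
#' below, which also enforces at least one sub-threshold sample between
#' consecutive spikes.
#'
#' @param traj an `"fn_trajectory"` (from [simulate_fn()] with
#'   `record_trajectory = TRUE`, or [integrate_deterministic()]).
#' @param w_c detection threshold.
#' @return List of [spike_train()] objects, one per cell. Cells without
#'   crossings yield empty trains.
#' @export
detect_spikes <- function(traj, w_c) {
  stopifnot(inherits(traj, "fn_trajectory"),
            "trajectory has no recorded w" = !is.null(traj$w))
  dt <- traj$dt
  duration <- traj$t[length(traj$t)]
  lapply(seq_len(ncol(traj$w)), function(c) {
    w <- traj$w[, c]
    i <- which(w[-length(w)] < w_c & w[-1] >= w_c)
    times <- traj$t[i] + dt * (w_c - w[i]) / (w[i + 1] - w[i])
    # crossings interpolated into the final sample can touch t = duration
    spike_train(times[times < duration], duration, c)
  })
}
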