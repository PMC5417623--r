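#' Parameters of the augmented FitzHugh-Nagumo model
#'
#' Bundles every constant of the stochastic phasic neuron model
#' \deqn{\tau_v \dot v = v(0.1 - v)(v - 1) - w + A\sin(2\pi\varphi t)
#'       + \sqrt{2D}\,\xi(t), \qquad \dot w = \varepsilon(v)\, v,}
#' together with the integration and ensemble settings. Two variants are
#' supported: the constant-timescale model (\code{eps_mode = "constant"},
#' \eqn{\varepsilon = } \code{eps_const}) and the voltage-dependent model
#' (\code{eps_mode = "voltage_dependent"}), in which the recovery rate is the
#' decreasing sigmoid
#' \deqn{\varepsilon(v) = \frac{\varepsilon_{hi} + \varepsilon_{lo}
#'   e^{(v - v_{1/2})/k}}{1 + e^{(v - v_{1/2})/k}},}
#' so the negative feedback is faster (larger \eqn{\varepsilon}) when the cell
#' is hyperpolarized. Spikes are upward crossings of the recovery variable
#' \code{w} through the detection threshold \code{w_c}.
#'
#' @param eps_mode recovery-timescale variant, \code{"voltage_dependent"} or
#'   \code{"constant"}.
#' @param tau_v membrane time constant (ms). Its value is not pinned down by
#'   the model's published constants; the default is 1 ms and it is exposed
#'   here as a calibration knob (see the methods vignette).
#' @param eps_const recovery rate of the constant-\eqn{\varepsilon} model
#'   (1/ms).
#' @param eps_lo,eps_hi plateau recovery rates of the sigmoid for strongly
#'   depolarized / hyperpolarized \code{v}; must satisfy
#'   \code{eps_lo < eps_hi}.
#' @param v_half,v_slope midpoint and width of the sigmoid.
#' @param D noise intensity (>= 0).
#' @param A amplitude of the sinusoidal drive (>= 0).
#' @param phi frequency of the sinusoidal drive (cycles/ms, >= 0).
#' @param w_c spike-detection threshold on \code{w}, in (0, 1). Defaults to
#'   0.14 for the voltage-dependent model and 0.15 for the constant model.
#' @param dt Euler-Maruyama step (ms).
#' @param duration simulated time per cell (ms).
#' @param n_cells ensemble size (uncoupled cells).
#' @param seed master random seed; each cell draws from an independent
#'   stream derived from \code{(seed, cell_id)} so ensembles are
#'   order-independent.
#'
#' @return An object of class \code{"fn_params"}.
#' @seealso [simulate_fn()], [epsilon_of_v()]
#' @examples
#' p <- fn_params(D = 0.03, duration = 1000)
#' epsilon_of_v(0.15, p)   # sigmoid midpoint: (0.1 + 0.03)/2
#' @export
fn_params <- function(eps_mode = c("voltage_dependent", "constant"),
                      tau_v = 1, eps_const = 0.03,
                      eps_lo = 0.03, eps_hi = 0.1,
                      v_half = 0.15, v_slope = 0.03,
                      D = 0, A = 0, phi = 0, w_c = NULL,
                      dt = 0.01, duration = 1000, n_cells = 1, seed = 1) {
  eps_mode <- match.arg(eps_mode)
  if (is.null(w_c)) w_c <- if (eps_mode == "voltage_dependent") 0.14 else 0.15
  stopifnot(
    "tau_v must be > 0" = is.numeric(tau_v) && tau_v > 0,
    "dt must be > 0" = is.numeric(dt) && dt > 0,
    "duration must be > 0" = is.numeric(duration) && duration > 0,
    "n_cells must be >= 1" = n_cells >= 1,
    "D must be >= 0" = is.numeric(D) && D >= 0,
    "A must be >= 0" = is.numeric(A) && A >= 0,
    "phi must be >= 0" = is.numeric(phi) && phi >= 0,
    "eps_lo must be < eps_hi" = eps_lo < eps_hi,
    "w_c must lie in (0, 1)" = w_c > 0 && w_c < 1,
    "v_slope must be > 0" = v_slope > 0,
    "eps_const must be > 0" = eps_const > 0,
    "seed must be a non-negative integer" = seed >= 0
  )
  if (A > 0 && phi <= 0)
    stop("a sinusoidal drive (A > 0) requires phi > 0")
  structure(
    list(eps_mode = eps_mode, tau_v = tau_v, eps_const = eps_const,
         eps_lo = eps_lo, eps_hi = eps_hi, v_half = v_half,
         v_slope = v_slope, D = D, A = A, phi = phi, w_c = w_c,
         dt = dt, duration = duration, n_cells = as.integer(n_cells),
         seed = seed),
    class = "fn_params")
}

#' @export
print.fn_params <- function(x, ...) {
  cat("FitzHugh-Nagumo parameters (", x$eps_mode, " epsilon)\n", sep = "")
  cat(sprintf("  tau_v = %g ms, D = %g, A = %g, phi = %g /ms, w_c = %g\n",
              x$tau_v, x$D, x$A, x$phi, x$w_c))
  cat(sprintf("  dt = %g ms, duration = %g ms, n_cells = %d, seed = %g\n",
              x$dt, x$duration, x$n_cells, x$seed))
  invisible(x)
}

#' Voltage-dependent recovery rate
#'
#' Evaluates the sigmoid \eqn{\varepsilon(v)} of the voltage-dependent model.
#' The computation uses the logistic form
#' \code{eps_lo + (eps_hi - eps_lo) * plogis(-(v - v_half)/v_slope)}, which is
#' overflow-free for arbitrarily large \code{|v|}.
#'
#' @param v membrane-variable value(s).
#' @param params an [fn_params()] object in \code{"voltage_dependent"} mode.
#' @return Rate value(s) strictly between \code{eps_lo} and \code{eps_hi},
#'   non-increasing in \code{v}.
#' @export
epsilon_of_v <- function(v, params) {
  stopifnot(inherits(params, "fn_params"))
  if (params$eps_mode != "voltage_dependent")
    stop("epsilon_of_v() called for a constant-epsilon model; ",
         "the recovery rate is eps_const = ", params$eps_const)
  params$eps_lo + (params$eps_hi - params$eps_lo) *
    plogis(-(v - params$v_half) / params$v_slope)
}

# internal: flat list handed to the C++ integrators
fn_par_cpp <- function(params) {
  list(tau_v = params$tau_v,
       vdep = params$eps_mode == "voltage_dependent",
       eps_const = params$eps_const, eps_lo = params$eps_lo,
       eps_hi = params$eps_hi, v_half = params$v_half,
       v_slope = params$v_slope, D = params$D, A = params$A,
       phi = params$phi, w_c = params$w_c, dt = params$dt,
       duration = params$duration, n_cells = params$n_cells,
       seed = as.double(params$seed))
}
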