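#' Two-barrier phenomenological model specification
#'
#' The reduced description of phasic spiking: an overdamped particle in a
#' potential well whose large fluctuations either cross a static left
#' barrier of height `dU_L` (recruiting the subthreshold negative feedback)
#' or a right barrier (firing a spike). Crossing rates follow the
#' Arrhenius-type hazard \eqn{H(\Delta U, D) = \gamma
#' e^{-\beta \Delta U^{p}/D}}. After a reset the right barrier relaxes along
#' the damped oscillation
#' \deqn{\Delta U_R(t) = v_R - a\,\frac{\sin(\omega (t + s_1))}
#'   {e^{\lambda (t + s_2)}},}
#' which transiently dips below its asymptote `v_R`, mimicking the lowered
#' spike threshold after a hyperpolarizing excursion of the full
#' FitzHugh-Nagumo phasic model.
#'
#' Three variants are compared: \describe{
#'   \item{`"phasic"`}{left barrier active; both left crossings and spikes
#'     reset the moving right barrier.}
#'   \item{`"right_moving"`}{no left barrier; the right barrier moves and is
#'     reset by spikes only.}
#'   \item{`"classic"`}{no left barrier and a constant right barrier `v_R`
#'     (classical stochastic resonance setup); only the sinusoid modulates
#'     it.}}
#'
#' A weak slow sinusoid (`A`, `phi`) modulates both barrier heights
#' quasi-statically: `dU - A*sin(2*pi*phi*(t + psi0))`.
#'
#' @param variant model variant, see Details.
#' @param gamma hazard prefactor (maximum escape rate).
#' @param beta,p_exp exponent scale and barrier power of the hazard.
#' @param dU_L left (feedback-recruiting) barrier height.
#' @param v_R asymptotic right (spike) barrier height.
#' @param mb_amp,mb_freq,mb_shift1,mb_decay,mb_shift2 constants of the
#'   moving-barrier transient.
#' @param D noise intensity, > 0.
#' @param A sinusoid amplitude (>= 0, must stay below every barrier height).
#' @param phi sinusoid frequency (> 0 whenever `A > 0`).
#' @return Object of class `"barrier_spec"`.
#' @examples
#' sp <- barrier_spec("phasic", D = 1)
#' hazard(1.5, sp)          # asymptotic spike hazard
#' moving_barrier(0.475, sp)  # near the transient's minimum
#' @export
barrier_spec <- function(variant = c("phasic", "right_moving", "classic"),
                         gamma = 5, beta = 3, p_exp = 1.5,
                         dU_L = 0.9, v_R = 1.5,
                         mb_amp = 1.4, mb_freq = 0.8 * pi,
                         mb_shift1 = 0.15, mb_decay = 0.8, mb_shift2 = 0.25,
                         D, A = 0, phi = 0) {
  variant <- match.arg(variant)
  stopifnot(
    "D must be > 0" = is.numeric(D) && D > 0,
    "A must be >= 0" = A >= 0,
    gamma > 0, beta > 0, p_exp > 0, dU_L > 0, v_R > 0
  )
  if (A > 0 && phi <= 0) stop("a sinusoid (A > 0) requires phi > 0")
  spec <- structure(
    list(variant = variant, gamma = gamma, beta = beta, p_exp = p_exp,
         dU_L = dU_L, v_R = v_R, mb_amp = mb_amp, mb_freq = mb_freq,
         mb_shift1 = mb_shift1, mb_decay = mb_decay, mb_shift2 = mb_shift2,
         D = D, A = A, phi = phi),
    class = "barrier_spec")
  # barrier positivity over the whole reset transient and signal cycle
  if (variant != "classic") {
    mb_min <- min(moving_barrier_min(spec)$height, v_R)
    if (mb_min - A <= 0)
      stop(sprintf("right barrier collapses: min height %.3f <= A = %g",
                   mb_min, A))
  } else if (v_R - A <= 0) {
    stop("right barrier collapses: v_R <= A")
  }
  if (variant == "phasic" && dU_L - A <= 0)
    stop("left barrier collapses: dU_L <= A")
  spec
}

#' @export
print.barrier_spec <- function(x, ...) {
  cat(sprintf(
    "barrier model '%s': H(dU) = %g exp(-%g dU^%g / D), D = %g, A = %g, phi = %g\n",
    x$variant, x$gamma, x$beta, x$p_exp, x$D, x$A, x$phi))
  invisible(x)
}

#' Arrhenius-type escape hazard
#'
#' \eqn{H(\Delta U, D) = \gamma e^{-\beta \Delta U^{p}/D}}: monotone
#' decreasing in the barrier height, increasing in the noise intensity, and
#' bounded above by `gamma` (attained at `dU = 0`).
#'
#' @param dU barrier height(s), >= 0.
#' @param spec a [barrier_spec()].
#' @param D optional noise-intensity override (defaults to `spec$D`).
#' @return Escape rate(s).
#' @export
hazard <- function(dU, spec, D = spec$D) {
  stopifnot(inherits(spec, "barrier_spec"))
  if (any(dU < 0))
    stop("negative barrier height: the barrier has collapsed (A too large?)")
  spec$gamma * exp(-spec$beta * dU^spec$p_exp / D)
}

#' Moving right-barrier height
#'
#' Height of the spike barrier at time `t` since the last reset: the damped
#' oscillatory transient for the `"phasic"` and `"right_moving"` variants,
#' or the constant `v_R` for `"classic"`. The transient dips to a global
#' minimum (~0.716 for the default constants, near t ~ 0.475) before
#' settling back to `v_R`.
#'
#' @param t time(s) since the last reset, >= 0.
#' @param spec a [barrier_spec()].
#' @return Barrier height(s).
#' @export
moving_barrier <- function(t, spec) {
  stopifnot(inherits(spec, "barrier_spec"), all(t >= 0))
  if (spec$variant == "classic") return(rep(spec$v_R, length(t)))
  spec$v_R - spec$mb_amp * sin(spec$mb_freq * (t + spec$mb_shift1)) *
    exp(-spec$mb_decay * (t + spec$mb_shift2))
}

# global minimum of the moving-barrier transient: coarse grid scan (the
# transient is oscillatory, so a bare 1-D optimizer can land in the wrong
# trough) followed by local refinement
moving_barrier_min <- function(spec) {
  horizon <- max(6 * pi / spec$mb_freq, 10 / spec$mb_decay)
  tg <- seq(0, horizon, length.out = 2048)
  i <- which.min(moving_barrier(tg, spec))
  lo <- tg[max(i - 1, 1)]
  hi <- tg[min(i + 1, length(tg))]
  opt <- optimize(function(t) moving_barrier(t, spec), c(lo, hi))
  list(t = opt$minimum, height = opt$objective)
}

# internal: flat list for the C++ thinning simulator
barrier_spec_cpp <- function(spec) {
  list(variant_code = match(spec$variant,
                            c("phasic", "right_moving", "classic")) - 1L,
       gamma = spec$gamma, beta = spec$beta, p_exp = spec$p_exp,
       dU_L = spec$dU_L, v_R = spec$v_R, mb_amp = spec$mb_amp,
       mb_freq = spec$mb_freq, mb_shift1 = spec$mb_shift1,
       mb_decay = spec$mb_decay, mb_shift2 = spec$mb_shift2,
       D = spec$D, A = spec$A, phi = spec$phi)
}
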