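#' Computational grid for the renewal theory
#'
#' Builds the time, Fourier and starting-phase grids on which the
#' interspike-interval (ISI) density is solved. `t_max` starts from the
#' kernel-survivor rule (total integrated hazard > ~14, i.e. survivor mass
#' below 1e-6) and is then doubled until the solved ISI density itself
#' carries less than `1e-8` mass near the end of the grid -- the phasic
#' variant's ISI density decays much more slowly than its exit kernels, and
#' because the FFT solve is circular, a too-short grid would silently alias
#' the tail rather than lose mass. `dt` is chosen to resolve the
#' moving-barrier oscillation and (when present) the sinusoid period; `n_t`
#' is a power of two between 2^14 and 2^22. The wrap-sum truncation `k_max`
#' covers the full grid, so further terms are identically zero.
#'
#' @param spec a [barrier_spec()].
#' @param n_psi starting-phase grid size (ignored when `A = 0`/`phi = 0`).
#' @param tol_norm admissible normalization defect of solved densities.
#' @param n_t_min,n_t_max power-of-two bounds on the time grid.
#' @return Object of class `"barrier_grid"`: `t`, `dt`, `n_t`, `t_max`,
#'   `psi`, `n_psi`, `k_max`, `tol_norm`.
#' @export
barrier_grid <- function(spec, n_psi = 128, tol_norm = 1e-3,
                         n_t_min = 2^14, n_t_max = 2^22) {
  stopifnot(inherits(spec, "barrier_spec"))
  # slowest rate the exit kernels can settle to: asymptotic right barrier
  # raised by the signal trough, plus the left hazard for the phasic variant
  h_floor <- hazard(spec$v_R + spec$A, spec)
  if (spec$variant == "phasic") h_floor <- h_floor + hazard(spec$dU_L + spec$A, spec)
  t_max <- 20 / h_floor

  # step fine enough for every feature of the kernels: the moving-barrier
  # oscillation, the sinusoid period, and the fastest escape transient
  h_fast <- if (spec$variant == "classic") hazard(spec$v_R - spec$A, spec)
  else hazard(max(moving_barrier_min(spec)$height, 0) - spec$A, spec)
  if (spec$variant == "phasic")
    h_fast <- h_fast + hazard(spec$dU_L - spec$A, spec)
  dt <- 0.02 / h_fast
  if (spec$variant != "classic" && spec$mb_amp != 0)
    dt <- min(dt, (2 * pi / spec$mb_freq) / 64)
  if (spec$phi > 0) dt <- min(dt, (1 / spec$phi) / 64)

  make <- function(t_max) {
    n_t <- 2^min(max(ceiling(log2(t_max / dt)), log2(n_t_min)), log2(n_t_max))
    g <- structure(
      list(t = seq(0, by = t_max / n_t, length.out = n_t),
           dt = t_max / n_t, n_t = n_t, t_max = t_max,
           # bin centers: the kernel column at psi0 stands for the whole
           # bin, so midpoint evaluation keeps the phase chain O(dpsi^2)
           psi = if (spec$phi > 0)
             (seq_len(n_psi) - 0.5) / (spec$phi * n_psi)
           else numeric(0),
           n_psi = n_psi,
           k_max = if (spec$phi > 0) ceiling(t_max * spec$phi) else 0L,
           tol_norm = tol_norm),
      class = "barrier_grid")
    g
  }
  g <- make(t_max)
  # grow until the solved density's own tail is negligible
  repeat {
    f <- isi_density_endogenous(spec, g, psi0 = 0)
    tail_mass <- sum(f$f[g$t > 0.9 * g$t_max]) * g$dt
    if (tail_mass < 1e-8 || g$n_t >= n_t_max) break
    g <- make(2 * g$t_max)
  }
  g
}

#' @export
print.barrier_grid <- function(x, ...) {
  cat(sprintf(
    "barrier grid: n_t = %d, dt = %.4g, t_max = %.4g, n_psi = %d, k_max = %d\n",
    x$n_t, x$dt, x$t_max, x$n_psi, x$k_max))
  invisible(x)
}

#' Exit kernels of the two-barrier process
#'
#' The sub-densities of leaving through either barrier first, measured from
#' the last reset: `J_R(t) = H_R(t) * S(t)` (fire without having crossed the
#' left barrier) and `J_L(t) = H_L * S(t)` (recruit the feedback without
#' having fired), with `S(t) = exp(-int_0^t (H_L + H_R))` the joint survivor.
#' A sinusoid of starting phase `psi0` modulates both barrier heights
#' quasi-statically. Variants without a left barrier have `J_L` identically
#' zero.
#'
#' @param spec a [barrier_spec()].
#' @param grid a [barrier_grid()].
#' @param psi0 starting phase of the sinusoid (time units, ignored if
#'   `A = 0`).
#' @return List with `t`, `H_L`, `H_R`, `J_L`, `J_R`, `survivor`.
#' @export
exit_kernels <- function(spec, grid, psi0 = 0) {
  stopifnot(inherits(spec, "barrier_spec"), inherits(grid, "barrier_grid"))
  t <- grid$t
  sig <- if (spec$A > 0)
    spec$A * sin(2 * pi * spec$phi * (t + psi0)) else 0
  bR <- moving_barrier(t, spec) - sig
  if (any(bR < 0)) stop("right barrier collapses on the grid; reduce A")
  H_R <- hazard(bR, spec)
  if (spec$variant == "phasic") {
    bL <- spec$dU_L - sig
    if (any(bL < 0)) stop("left barrier collapses on the grid; reduce A")
    H_L <- hazard(bL, spec)
    if (length(H_L) == 1) H_L <- rep(H_L, length(t))
  } else {
    H_L <- rep(0, length(t))
  }
  S <- exp(-cumtrapz_uniform(H_L + H_R, grid$dt))
  list(t = t, H_L = H_L, H_R = H_R, J_L = H_L * S, J_R = H_R * S,
       survivor = S)
}

# cumulative trapezoid on a uniform grid, first element 0
cumtrapz_uniform <- function(y, dt) {
  n <- length(y)
  c(0, cumsum((y[-1] + y[-n]) / 2)) * dt
}

trapz_uniform <- function(y, dt) {
  n <- length(y)
  (sum(y) - (y[1] + y[n]) / 2) * dt
}

# Fourier-domain renewal solve: f-hat = J_R-hat / (1 - J_L-hat), with
# trapezoid-corrected transforms (right endpoint negligible by grid
# construction). The t = 0 sample is repaired to the exact boundary value
# f(0) = J_R(0).
solve_renewal_fft <- function(J_R, J_L, dt) {
  n <- length(J_R)
  JRh <- dt * (fft(J_R) - J_R[1] / 2)
  JLh <- dt * (fft(J_L) - J_L[1] / 2)
  denom <- 1 - JLh
  if (any(Mod(denom) < 1e-8))
    stop("renewal solve ill-conditioned: |1 - J_L-hat| ~ 0; enlarge the grid")
  f <- Re(fft(JRh / denom, inverse = TRUE)) / (n * dt)
  f[1] <- J_R[1]
  f
}

new_isi_density <- function(t, f, dt, tol_norm) {
  fmax <- max(f)
  if (min(f) < -1e-6 * fmax)
    stop(sprintf("ISI density has negativity %.3g * max(f); grid too coarse",
                 -min(f) / fmax))
  clipped <- -sum(f[f < 0]) * dt
  f[f < 0] <- 0
  mass <- trapz_uniform(f, dt)
  defect <- abs(mass - 1)
  if (defect > tol_norm)
    stop(sprintf("ISI density normalization defect %.3g exceeds %.1g",
                 defect, tol_norm))
  structure(list(t = t, f = f, dt = dt, norm_defect = defect,
                 clipped_mass = clipped),
            class = "isi_density")
}

#' @export
print.isi_density <- function(x, ...) {
  cat(sprintf(
    "ISI density: %d points, dt = %.4g, norm defect %.2g, mean ISI %.4g\n",
    length(x$t), x$dt, x$norm_defect, trapz_uniform(x$t * x$f, x$dt)))
  invisible(x)
}

#' Semi-analytic ISI density (endogenous sinusoid)
#'
#' Solves the renewal convolution equation
#' `f(t) = J_R(t) + int_0^t J_L(t - t') f(t') dt'` in the Fourier domain:
#' `f-hat = J_R-hat / (1 - J_L-hat)`, inverted back to the time grid.
#' "Endogenous" means the sinusoid restarts at phase offset `psi0` after
#' every reset, which is what makes the kernels stationary in
#' time-since-reset and the convolution theorem applicable. For variants
#' without a left barrier the solution is `J_R` itself.
#'
#' @inheritParams exit_kernels
#' @return An `"isi_density"`: `t`, `f` (>= 0, tiny FFT ringing clipped and
#'   reported as `clipped_mass`), `norm_defect`.
#' @export
isi_density_endogenous <- function(spec, grid, psi0 = 0) {
  k <- exit_kernels(spec, grid, psi0)
  f <- if (spec$variant == "phasic")
    solve_renewal_fft(k$J_R, k$J_L, grid$dt)
  else k$J_R
  new_isi_density(grid$t, f, grid$dt, grid$tol_norm)
}

# Direct summation of the renewal series (n-fold convolutions of J_L with
# J_R), by time-domain trapezoid convolution. Independent oracle for the
# Fourier solver; truncation mass beyond n_terms is reported.
isi_density_series <- function(spec, grid, psi0 = 0, n_terms = 8) {
  k <- exit_kernels(spec, grid, psi0)
  dt <- grid$dt
  n <- grid$n_t
  term <- k$J_R
  f <- term
  for (m in seq_len(n_terms)) {
    term <- conv_trapz(k$J_L, term, dt)[1:n]
    f <- f + term
  }
  b <- trapz_uniform(k$J_L, dt)   # P(left exit first)
  a <- trapz_uniform(k$J_R, dt)
  list(t = grid$t, f = f,
       truncation_mass = a * b^(n_terms + 1) / (1 - b))
}

# linear convolution with trapezoid endpoint weights
conv_trapz <- function(x, y, dt) {
  n <- length(x)
  xx <- c(x, rep(0, n))
  yy <- c(y, rep(0, n))
  full <- Re(fft(fft(xx) * fft(yy), inverse = TRUE)) / (2 * n)
  idx <- seq_len(n)
  # half-weight the endpoint products to turn the Riemann sum into trapezoid
  (full[idx] - (x[1] * y[idx] + x[idx] * y[1]) / 2) * dt
}

#' Firing rate from an ISI density
#'
#' Reciprocal mean interval, `nu = 1 / int t f(t) dt` (trapezoid
#' quadrature). The residual tail mass beyond the grid is bounded by the
#' reported normalization defect; a defect above the grid's tolerance
#' signals an error.
#'
#' @param f an `"isi_density"`.
#' @param tol_norm normalization tolerance (defaults to 1e-3).
#' @return Firing rate (events per time unit).
#' @export
firing_rate_from_density <- function(f, tol_norm = 1e-3) {
  stopifnot(inherits(f, "isi_density"))
  if (f$norm_defect > tol_norm)
    stop(sprintf("normalization defect %.3g exceeds %.1g",
                 f$norm_defect, tol_norm))
  mass <- trapz_uniform(f$f, f$dt)
  1 / (trapz_uniform(f$t * f$f, f$dt) / mass)
}

#' Spike-phase transition kernel
#'
#' Probability density `g(psi | psi0)` of firing at sinusoid phase `psi`
#' given the interval started at phase `psi0`: the ISI density conditioned
#' on `psi0`, wrapped onto one period,
#' `g(psi|psi0) ~ sum_{k=0}^{k_max} f(k T + psi - psi0 | psi0)`, with each
#' column renormalized to integrate to one (the stated property of the
#' kernel; the wrap-sum prefactor is fixed by this normalization). The
#' wrapped sum is evaluated by aggregating the ISI density's mass into phase
#' bins on its own fine time grid, so the kernel is the bin-averaged density
#' and each column's mass equals the density's total mass by construction.
#' `k_max` spans the whole time grid; the mass carried beyond `k_max`
#' periods is checked against the grid tolerance.
#'
#' @inheritParams exit_kernels
#' @return Object of class `"phase_kernel"`: `psi`, matrix `G`
#'   (`psi` by `psi0`), `phi`, per-column pre-normalization defects, and the
#'   per-column mean ISIs `col_mean_isi` (used for the exogenous rate).
#' @export
phase_kernel <- function(spec, grid) {
  stopifnot(spec$phi > 0)
  T_per <- 1 / spec$phi
  psi <- grid$psi
  n_psi <- grid$n_psi
  dpsi <- T_per / n_psi
  G <- matrix(0, n_psi, n_psi)
  col_mass <- col_mean <- numeric(n_psi)
  f0 <- if (spec$A == 0) isi_density_endogenous(spec, grid, 0) else NULL
  keep <- grid$t < grid$k_max * T_per
  for (j in seq_len(n_psi)) {
    fj <- if (is.null(f0)) isi_density_endogenous(spec, grid, psi[j]) else f0
    col_mean[j] <- trapz_uniform(fj$t * fj$f, fj$dt)
    beyond <- sum(fj$f[!keep]) * fj$dt
    if (beyond > grid$tol_norm)
      stop(sprintf(
        "ISI mass %.3g survives beyond k_max = %d periods; enlarge k_max",
        beyond, grid$k_max))
    # spike phase of every t sample, folded onto one period; trapezoid
    # end-weights so the column mass matches the density's integral
    wts <- rep(fj$dt, grid$n_t)
    wts[c(1, grid$n_t)] <- fj$dt / 2
    bin <- pmin(floor(((psi[j] + grid$t[keep]) %% T_per) / dpsi) + 1, n_psi)
    m <- numeric(n_psi)
    agg <- rowsum(fj$f[keep] * wts[keep], bin)
    m[as.integer(rownames(agg))] <- agg
    col_mass[j] <- sum(m)
    G[, j] <- m / (dpsi * col_mass[j])
  }
  structure(list(psi = psi, G = G, phi = spec$phi,
                 col_norm_defect = abs(col_mass - 1),
                 col_mean_isi = col_mean, k_max = grid$k_max),
            class = "phase_kernel")
}

#' Stationary phase density of spikes
#'
#' Fixed point of the phase map `p_n = L p_{n-1}`, where `L` integrates the
#' spike-phase kernel over the previous spike's phase. Solved by power
#' iteration from the uniform density; every iterate is renormalized, and
#' the returned residual is the L1 distance `||p - Lp||_1`.
#'
#' @param g a [phase_kernel()].
#' @param tol L1 convergence tolerance.
#' @param max_iter iteration cap; non-convergence signals an error carrying
#'   the residual history.
#' @return Object of class `"phase_density"`: `psi`, `p`, `phi`, `residual`,
#'   `n_iter`.
#' @export
phase_density_fixed_point <- function(g, tol = 1e-10, max_iter = 1000) {
  stopifnot(inherits(g, "phase_kernel"))
  n <- length(g$psi)
  T_per <- 1 / g$phi
  dpsi <- T_per / n
  p <- rep(1 / T_per, n)
  res_hist <- numeric(0)
  for (i in seq_len(max_iter)) {
    p_new <- as.vector(g$G %*% p) * dpsi
    p_new <- p_new / (sum(p_new) * dpsi)
    res <- sum(abs(p_new - p)) * dpsi
    res_hist <- c(res_hist, res)
    p <- p_new
    if (res < tol) break
  }
  if (res >= tol)
    stop("phase-density fixed point did not converge; residuals: ",
         paste(signif(utils::tail(res_hist, 5), 3), collapse = " "))
  structure(list(psi = g$psi, p = p, phi = g$phi, residual = res,
                 n_iter = i),
            class = "phase_density")
}

#' @export
print.phase_density <- function(x, ...) {
  cat(sprintf(
    "phase density on [0, %g): %d points, residual %.2g after %d iterations\n",
    1 / x$phi, length(x$psi), x$residual, x$n_iter))
  invisible(x)
}

#' Conditioned ISI density family
#'
#' The family `f(t | psi0)` over the starting-phase grid, as a
#' `n_t x n_psi` matrix. Refused for very large grids (use
#' [theory_metrics()], which streams over columns instead).
#'
#' @inheritParams exit_kernels
#' @return List with `t`, `psi`, matrix `f` (`t` by `psi0`).
#' @export
isi_family <- function(spec, grid) {
  stopifnot(spec$phi > 0)
  if (grid$n_t * grid$n_psi > 2^25)
    stop("family too large to store; use theory_metrics()")
  f <- vapply(grid$psi,
              function(p0) isi_density_endogenous(spec, grid, p0)$f,
              numeric(grid$n_t))
  list(t = grid$t, psi = grid$psi, f = f)
}

#' Exogenous ISI density
#'
#' Mixture of the conditioned family over the stationary spike-phase
#' density: `f(t) = int_0^T f(t|psi) p(psi) dpsi`. This is the ISI density
#' of the process driven by a free-running (exogenous) sinusoid under the
#' quasi-static renewal approximation.
#'
#' @param f_family result of [isi_family()].
#' @param p a [phase_density_fixed_point()] result on the same `psi` grid.
#' @param tol_norm normalization tolerance.
#' @return An `"isi_density"`.
#' @export
isi_density_exogenous <- function(f_family, p, tol_norm = 1e-3) {
  stopifnot(inherits(p, "phase_density"))
  if (length(f_family$psi) != length(p$psi) ||
      max(abs(f_family$psi - p$psi)) > 1e-12)
    stop("psi grids of the family and the phase density do not match")
  dpsi <- (1 / p$phi) / length(p$psi)
  f <- as.vector(f_family$f %*% (p$p * dpsi))
  new_isi_density(f_family$t, f, f_family$t[2] - f_family$t[1], tol_norm)
}

#' Semi-analytic firing rate, vector strength and coding measure
#'
#' Full theory pipeline for one model specification: exit kernels for each
#' starting phase, conditioned ISI densities, spike-phase kernel, stationary
#' phase density, then `r` (vector strength of the phase density), `nu`
#' (reciprocal mean of the exogenous ISI density) and `q = nu * r`. With no
#' sinusoid (`phi = 0`) the endogenous density alone is used and `r = 0`.
#'
#' @param spec a [barrier_spec()].
#' @param grid optional [barrier_grid()]; built automatically if missing.
#' @return List with `nu`, `r`, `q`, and diagnostics (`phase_density`,
#'   `grid`, `residual`).
#' @examples
#' \donttest{
#' th <- theory_metrics(barrier_spec("classic", D = 1, A = 0.1, phi = 0.1))
#' th$nu   # near the constant-barrier rate 5 exp(-3 * 1.5^1.5 / D)
#' }
#' @export
theory_metrics <- function(spec, grid = NULL) {
  stopifnot(inherits(spec, "barrier_spec"))
  if (is.null(grid)) grid <- barrier_grid(spec)
  if (spec$phi <= 0) {
    f <- isi_density_endogenous(spec, grid)
    nu <- firing_rate_from_density(f, grid$tol_norm)
    return(list(nu = nu, r = 0, q = 0, phase_density = NULL, grid = grid))
  }
  g <- phase_kernel(spec, grid)
  p <- phase_density_fixed_point(g)
  r <- vector_strength(p)
  dpsi <- (1 / spec$phi) / grid$n_psi
  mean_isi <- sum(p$p * g$col_mean_isi) * dpsi   # mixture mean, Eq-level identity
  nu <- 1 / mean_isi
  list(nu = nu, r = r, q = nu * r, phase_density = p, grid = grid,
       residual = p$residual)
}
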