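test_that("hazard follows the Arrhenius form with its bounds", {
  sp <- barrier_spec("phasic", D = 1)
  expect_equal(hazard(0, sp), 5)
  expect_equal(hazard(1.5, sp), 5 * exp(-3 * 1.5^1.5), tolerance = 1e-12)
  expect_equal(hazard(1.5, sp), 0.0202, tolerance = 1e-2)
  dU <- seq(0, 6, by = 0.1)
  expect_true(all(diff(hazard(dU, sp)) < 0))
  expect_lt(hazard(50, sp), 1e-12)
  expect_true(all(hazard(dU[-1], sp, D = 2) > hazard(dU[-1], sp, D = 1)))
  expect_error(hazard(-0.1, sp), "collapsed")
})

test_that("moving barrier matches the printed transient", {
  sp <- barrier_spec("phasic", D = 1)
  expect_equal(moving_barrier(0, sp),
               1.5 - 1.4 * sin(0.8 * pi * 0.15) / exp(0.8 * 0.25))
  expect_equal(moving_barrier(0, sp), 1.078, tolerance = 1e-3)
  expect_equal(moving_barrier(30, sp), 1.5, tolerance = 1e-6)
  # global minimum of the printed formula, found by independent optimization
  ref <- optimize(function(t)
    1.5 - 1.4 * sin(0.8 * pi * (t + 0.15)) * exp(-0.8 * (t + 0.25)),
    c(0.2, 0.6))
  mm <- phasic:::moving_barrier_min(sp)
  expect_equal(mm$height, ref$objective, tolerance = 1e-6)
  expect_equal(mm$t, ref$minimum, tolerance = 1e-3)
  # classic variant: constant barrier
  spc <- barrier_spec("classic", D = 1)
  expect_equal(moving_barrier(c(0, 1, 10), spc), rep(1.5, 3))
})

test_that("exit kernels obey the closed forms and telescoping identities", {
  spc <- barrier_spec("classic", D = 1)
  g <- barrier_grid(spc)
  k <- exit_kernels(spc, g)
  H <- hazard(1.5, spc)
  expect_equal(k$J_R, H * exp(-H * g$t), tolerance = 1e-12)
  expect_true(all(k$J_L == 0))
  # phasic: total exit probability reaches 1 and J_L/J_R = H_L/H_R pointwise
  spp <- barrier_spec("phasic", D = 1)
  gp <- barrier_grid(spp)
  kp <- exit_kernels(spp, gp)
  total <- phasic:::trapz_uniform(kp$J_L + kp$J_R, gp$dt)
  expect_equal(total, 1, tolerance = 1e-5)
  nz <- kp$J_R > 1e-300
  expect_equal(kp$J_L[nz] / kp$J_R[nz], kp$H_L[nz] / kp$H_R[nz],
               tolerance = 1e-12)
})

test_that("constant right barrier: left crossings are invisible in f", {
  # with a flat moving barrier the solved density must equal H_R e^{-H_R t}
  # whatever the left hazard is
  for (dU_L in c(0.6, 1.2)) {
    sp <- barrier_spec("phasic", D = 1, dU_L = dU_L, mb_amp = 0)
    g <- barrier_grid(sp, n_t_min = 2^21)
    f <- isi_density_endogenous(sp, g)
    H_R <- hazard(sp$v_R, sp)
    err <- max(abs(f$f - H_R * exp(-H_R * g$t))) / H_R
    expect_lt(err, 1e-6)
  }
})

test_that("direct convolution series reproduces the Fourier solution", {
  sp <- barrier_spec("phasic", D = 1)
  g <- barrier_grid(sp)
  f_fft <- isi_density_endogenous(sp, g)
  f_ser <- phasic:::isi_density_series(sp, g, n_terms = 8)
  l1 <- sum(abs(f_fft$f - f_ser$f)) * g$dt
  # the series is truncated: the gap must match its own truncation bound
  expect_lt(l1, f_ser$truncation_mass + 1e-3)
  expect_gt(l1, f_ser$truncation_mass - 1e-3)
})

test_that("solved densities are normalized and the rate inverts the mean", {
  spp <- barrier_spec("phasic", D = 1)
  gp <- barrier_grid(spp)
  f <- isi_density_endogenous(spp, gp)
  expect_lt(f$norm_defect, 1e-3)
  expect_true(all(f$f >= 0))
  # exponential density: nu = lambda
  lam <- 0.3
  t <- seq(0, 120, length.out = 2^14)
  fe <- phasic:::new_isi_density(t, lam * exp(-lam * t), t[2], 1e-3)
  expect_equal(firing_rate_from_density(fe), lam, tolerance = 1e-4)
  # equal mixture of exponentials: nu = 1 / mean of the two means
  l1 <- 0.2; l2 <- 1
  fm <- phasic:::new_isi_density(
    t, 0.5 * l1 * exp(-l1 * t) + 0.5 * l2 * exp(-l2 * t), t[2], 1e-3)
  expect_equal(firing_rate_from_density(fm), 1 / (0.5 * (1 / l1 + 1 / l2)),
               tolerance = 1e-4)
  # narrow peak at t0: nu -> 1/t0
  t0 <- 7
  fp <- exp(-(t - t0)^2 / (2 * 0.05^2)); fp <- fp / (sum(fp) * t[2])
  fpk <- phasic:::new_isi_density(t, fp, t[2], 1e-3)
  expect_equal(firing_rate_from_density(fpk), 1 / t0, tolerance = 1e-3)
})

test_that("phase kernel columns are normalized and shift-invariant at A = 0", {
  sp <- barrier_spec("phasic", D = 1, A = 0, phi = 0.1)
  g <- barrier_grid(sp)
  gk <- phase_kernel(sp, g)
  dpsi <- (1 / sp$phi) / g$n_psi
  expect_lt(max(abs(colSums(gk$G) * dpsi - 1)), 1e-12)
  expect_lt(max(gk$col_norm_defect), 1e-3)
  # no signal: g depends only on (psi - psi0) mod T, i.e. column j is
  # column 1 rotated down by j - 1 bins
  n <- g$n_psi
  for (j in c(2, 17, 64)) {
    shifted <- c(gk$G[(n - j + 2):n, 1], gk$G[1:(n - j + 1), 1])
    expect_equal(gk$G[, j], shifted, tolerance = 1e-10)
  }
  # enlarging k_max adds only empty mass
  g2 <- g
  g2$k_max <- 2 * g$k_max
  gk2 <- phase_kernel(sp, g2)
  expect_equal(gk$G, gk2$G, tolerance = 1e-12)
})

test_that("the phase map fixes the uniform density when A = 0", {
  sp <- barrier_spec("phasic", D = 1, A = 0, phi = 0.1)
  g <- barrier_grid(sp)
  gk <- phase_kernel(sp, g)
  p <- phase_density_fixed_point(gk)
  expect_lt(max(abs(p$p - sp$phi)), 1e-10)     # uniform density = phi = 1/T
  expect_lt(p$residual, 1e-10)
  dpsi <- (1 / sp$phi) / g$n_psi
  expect_equal(sum(p$p) * dpsi, 1, tolerance = 1e-12)
  # one more application of L stays put
  p2 <- as.vector(gk$G %*% p$p) * dpsi
  expect_lt(sum(abs(p2 - p$p)) * dpsi, 1e-9)
})

test_that("exogenous mixture reduces to the endogenous density at A = 0", {
  sp <- barrier_spec("phasic", D = 1, A = 0, phi = 0.1)
  g <- barrier_grid(sp)
  fam <- isi_family(sp, g)
  p <- phase_density_fixed_point(phase_kernel(sp, g))
  fx <- isi_density_exogenous(fam, p)
  f0 <- isi_density_endogenous(sp, g)
  expect_lt(max(abs(fx$f - f0$f)), 1e-9)
  expect_lt(fx$norm_defect, 1e-3)
})

test_that("full pipeline: classic rate limit and noise monotonicity", {
  # A -> 0: classic variant rate approaches the constant-barrier closed form
  for (D in c(0.8, 1.5)) {
    sp <- barrier_spec("classic", D = D, A = 1e-6, phi = 0.1)
    th <- theory_metrics(sp)
    expect_equal(th$nu, 5 * exp(-3 * 1.5^1.5 / D), tolerance = 1e-3)
  }
  # increasing D increases nu for all three variants
  for (v in c("phasic", "right_moving", "classic")) {
    nus <- vapply(c(0.7, 1, 1.6), function(D)
      theory_metrics(barrier_spec(v, D = D, A = 0.1, phi = 0.1))$nu, 1)
    expect_true(all(diff(nus) > 0))
  }
})
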