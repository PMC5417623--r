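test_that("rest is an equilibrium: D = 0, A = 0 stays at (0, 0) forever", {
  p <- epsv_params(D = 0, duration = 500, n_cells = 2)
  sim <- simulate_fn(p, record_trajectory = TRUE)
  expect_equal(max(abs(sim$trajectory$v)), 0)
  expect_equal(max(abs(sim$trajectory$w)), 0)
  expect_equal(n_spikes(sim), 0)
})

test_that("identical (params, seed) reproduce trajectories bit-for-bit", {
  p <- epsv_params(D = 0.05, duration = 200, n_cells = 3, seed = 99)
  s1 <- simulate_fn(p, record_trajectory = TRUE, record_noise = TRUE)
  s2 <- simulate_fn(p, record_trajectory = TRUE, record_noise = TRUE)
  expect_identical(s1$trajectory$v, s2$trajectory$v)
  expect_identical(s1$trajectory$noise, s2$trajectory$noise)
  expect_identical(lapply(s1$trains, `[[`, "times"),
                   lapply(s2$trains, `[[`, "times"))
  # distinct cells draw from distinct streams
  expect_false(identical(s1$trajectory$v[, 1], s1$trajectory$v[, 2]))
})

test_that("noise increments have the Euler-Maruyama variance 2 D dt / tau^2", {
  p <- epsv_params(D = 0.2, tau_v = 2, duration = 500, n_cells = 1, seed = 5)
  sim <- simulate_fn(p, record_noise = TRUE)
  xi <- sim$trajectory$noise[, 1]          # stored as increments / sqrt(dt)
  expect_lt(abs(mean(xi)), 4 / sqrt(p$dt) / sqrt(length(xi)))
  expect_equal(var(xi) * p$dt, 1, tolerance = 0.02)  # xi ~ N(0, 1/dt)
})

test_that("a suprathreshold initial condition fires exactly one spike", {
  p <- epsv_params(D = 0, duration = 200)
  sim <- simulate_fn(p, init = c(0.3, 0), record_trajectory = TRUE)
  expect_equal(n_spikes(sim), 1)
  # and the trajectory returns to rest afterwards
  expect_lt(abs(sim$trajectory$v[length(sim$trajectory$t), 1]), 1e-4)
})

test_that("spike detection finds interpolated upward crossings", {
  traj <- structure(
    list(t = seq(0, 0.04, by = 0.01),
         v = matrix(0, 5), w = matrix(c(0, 0.10, 0.16, 0.10, 0.20), 5),
         noise = NULL, dt = 0.01),
    class = "fn_trajectory")
  tr <- detect_spikes(traj, 0.14)[[1]]
  expect_length(tr$times, 2)
  expect_equal(tr$times, c(0.01 + 0.01 * 0.04 / 0.06, 0.03 + 0.01 * 0.04 / 0.10))
  # everywhere below threshold: empty train
  traj$w <- matrix(c(0, 0.05, 0.1, 0.05, 0), 5)
  expect_length(detect_spikes(traj, 0.14)[[1]]$times, 0)
  # a tie at w_c counts only when the previous sample is strictly below
  traj$w <- matrix(c(0.14, 0.2, 0.1, 0.14, 0.2), 5)
  expect_length(detect_spikes(traj, 0.14)[[1]]$times, 1)
})

test_that("online C++ spike detection matches the R detector", {
  p <- epsv_params(D = 0.05, duration = 2000, n_cells = 2, seed = 3)
  sim <- simulate_fn(p, record_trajectory = TRUE)
  redetected <- detect_spikes(sim$trajectory, p$w_c)
  for (c in 1:2)
    expect_equal(sim$trains[[c]]$times, redetected[[c]]$times,
                 tolerance = 1e-12)
})

test_that("ensemble firing rate is weakly insensitive to halving dt", {
  p1 <- epsv_params(D = 0.03, duration = 20000, n_cells = 8, seed = 21)
  p2 <- epsv_params(D = 0.03, duration = 20000, n_cells = 8, seed = 22,
                    dt = 0.005)
  nu1 <- firing_rate(simulate_fn(p1)$trains)
  nu2 <- firing_rate(simulate_fn(p2)$trains)
  expect_lt(abs(nu1 - nu2) / nu1, 0.08)   # ~4000 spikes each, MC error ~2%
})

test_that("deterministic RK4 path converges under step halving", {
  p <- epsv_params(D = 0)
  t1 <- integrate_deterministic(p, c(-0.2, 0), 100, dt = 0.01)
  t2 <- integrate_deterministic(p, c(-0.2, 0), 100, dt = 0.005)
  expect_lt(max(abs(t1$v[seq(1, 10001, 1)] - t2$v[seq(1, 20001, 2)])), 1e-8)
  # rest is preserved; hyperpolarized start relaxes back to rest (the
  # subthreshold focus has eigenvalue ~ -0.05/ms, so allow a few hundred ms)
  t0 <- integrate_deterministic(p, c(0, 0), 50, dt = 0.01)
  expect_equal(max(abs(t0$v)), 0)
  t3 <- integrate_deterministic(p, c(-0.2, 0), 300, dt = 0.01)
  expect_lt(abs(t3$v[length(t3$v)]) + abs(t3$w[length(t3$w)]), 1e-4)
})

test_that("firing rate is non-decreasing in D for both variants", {
  Ds <- c(0.005, 0.02, 0.08)
  rate_at <- function(D, mode) {
    p <- fn_params(eps_mode = mode, D = D, duration = 10000, n_cells = 4,
                   seed = 17)
    firing_rate(simulate_fn(p)$trains)
  }
  for (mode in c("voltage_dependent", "constant")) {
    nus <- vapply(Ds, rate_at, 1, mode = mode)
    expect_true(all(diff(nus) > 0))
  }
})
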