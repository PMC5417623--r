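test_that("firing rate is total count over total time", {
  expect_equal(firing_rate(spike_train(seq(50, 950, length.out = 10), 1000)),
               0.01)
  expect_equal(firing_rate(spike_train(numeric(0), 1000)), 0)
  trains <- lapply(1:3, function(c)
    spike_train(seq(1, 999, length.out = 15), 1000, c))
  expect_equal(firing_rate(trains), 0.015)
  expect_error(firing_rate(list()), "zero total")
})

test_that("phase histogram is a normalized density on [0, T)", {
  phi <- 0.01   # T = 100 ms
  # spikes at exact multiples of the period: all mass in the first bin
  tr <- spike_train(seq(0, 900, by = 100), 1000)
  h <- empirical_phase_density(tr, phi, n_bins = 20)
  expect_equal(h$counts[1], 10)
  expect_equal(sum(h$counts[-1]), 0)
  expect_equal(sum(h$density * diff(h$bin_edges)), 1)
  # uniform spikes: flat within multinomial error
  set.seed(4)
  tru <- spike_train(sort(runif(20000, 0, 1000)), 1000)
  hu <- empirical_phase_density(tru, phi, n_bins = 10)
  expect_lt(max(abs(hu$counts - 2000)) / 2000, 5 * sqrt(0.9 / 2000))
  expect_equal(sum(hu$density * diff(hu$bin_edges)), 1)
  # zero spikes: flagged empty
  he <- empirical_phase_density(spike_train(numeric(0), 100), phi)
  expect_true(he$empty)
})

test_that("vector strength reproduces closed-form values", {
  phi <- 0.1
  T_per <- 1 / phi
  # perfect locking: all spikes at one phase
  expect_equal(vector_strength(spike_train(seq(2, 92, by = 10), 100), phi), 1)
  # uniform density: orthogonality gives 0
  psi <- (0:511 + 0.5) * T_per / 512
  expect_equal(vector_strength(rep(phi, 512), phi = phi, psi = psi), 0)
  # raised-cosine density integrates to r = 1/2
  p <- (1 + cos(2 * pi * phi * psi)) * phi
  expect_equal(vector_strength(p, phi = phi, psi = psi), 0.5,
               tolerance = 1e-10)
  expect_error(vector_strength(2 * p, phi = phi, psi = psi), "normalized")
})

test_that("vector strength is invariant to a uniform phase shift", {
  set.seed(8)
  phi <- 0.02
  times <- sort(runif(500, 0, 400)) + cumsum(rep(0.3, 500))
  r0 <- vector_strength(spike_train(times, 1e4), phi)
  for (shift in c(3.7, 12.5, 49.9)) {
    r1 <- vector_strength(spike_train(times + shift, 1e4), phi)
    expect_equal(r1, r0, tolerance = 1e-12)
  }
})

test_that("q weights locking by rate and is monotone in both arguments", {
  expect_equal(q_value(0.01, 0.5), 0.005)
  expect_equal(q_value(0.7, 0), 0)
  expect_equal(q_value(0.0045, 1), 0.0045)
  nus <- seq(0, 0.1, by = 0.02)
  rs <- seq(0, 1, by = 0.2)
  expect_true(all(diff(vapply(nus, q_value, 1, r = 0.4)) > 0))
  expect_true(all(diff(vapply(rs, q_value, 1, nu = 0.05)) >= 0))
})

test_that("STA of a single spike is that spike's noise segment", {
  set.seed(12)
  dt <- 0.1
  noise <- matrix(rnorm(1000), ncol = 1)
  tr <- list(spike_train(50.23, 100))
  sta <- spike_triggered_average(noise, tr, window = c(2, 1), dt = dt)
  j <- floor(50.23 / dt) + 1
  expect_equal(sta$average, noise[(j - 20):(j + 10), 1])
  expect_equal(sta$n_spikes, 1L)
})

test_that("STA of spikes independent of the noise is flat", {
  set.seed(13)
  dt <- 0.1
  n <- 2e5
  noise <- matrix(rnorm(n, sd = 1 / sqrt(dt)), ncol = 1)
  times <- sort(runif(3000, 5, n * dt - 5))
  times <- times[c(TRUE, diff(times) > dt)]
  sta <- spike_triggered_average(noise, list(spike_train(times, n * dt)),
                                 window = c(3, 1), dt = dt)
  band <- 5 * (1 / sqrt(dt)) / sqrt(sta$n_spikes)
  expect_lt(max(abs(sta$average)), band)
  # unqualifying spikes are flagged
  sta0 <- spike_triggered_average(noise, list(spike_train(0.05, n * dt)),
                                  window = c(3, 1), dt = dt)
  expect_true(sta0$empty)
})

test_that("Welch spectrum finds a tone and satisfies Parseval", {
  dt <- 0.1
  t <- seq(0, 5000 - dt, by = dt)
  x <- sin(2 * pi * 0.5 * t)
  sp <- power_spectrum_v(x, segment_length = 1024, dt = dt)
  expect_equal(sp$freq[which.max(sp$power)], 0.5, tolerance = 0.01)
  expect_equal(sum(sp$power) * sp$df, var(x), tolerance = 0.01)
  expect_true(all(sp$power >= 0))
  # white noise: flat across halves, Parseval again
  set.seed(14)
  xw <- rnorm(5e4)
  spw <- power_spectrum_v(xw, segment_length = 512, dt = dt)
  lo <- mean(spw$power[spw$freq < 2.5 & spw$freq > 0])
  hi <- mean(spw$power[spw$freq >= 2.5])
  expect_equal(lo / hi, 1, tolerance = 0.1)
  expect_equal(sum(spw$power) * spw$df, var(xw), tolerance = 0.01)
  expect_error(power_spectrum_v(xw[1:100], segment_length = 512, dt = dt),
               "segment_length")
})

test_that("pseudo-Gaussian smoother preserves constants and mass", {
  expect_equal(smooth_signal(rep(3.2, 100), 9), rep(3.2, 100))
  # impulse response: symmetric, sums to 1
  x <- numeric(201); x[101] <- 1
  k <- smooth_signal(x, 15)
  expect_equal(sum(k), 1, tolerance = 1e-12)
  expect_equal(k, rev(k))
  # variance reduction on white noise
  set.seed(15)
  z <- rnorm(5000)
  expect_lt(var(smooth_signal(z, 11)), var(z) / 5)
  expect_error(smooth_signal(z[1:5], 100), "width")
})
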