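test_that("constant-hazard variant reproduces the exponential closed form", {
  sp <- barrier_spec("classic", D = 1.5)
  H <- hazard(1.5, sp)
  rec <- simulate_barrier_process(sp, 1.2e4 / H, seed = 2)
  isi <- diff(rec$spike_times)
  expect_gt(length(isi), 1e4)
  se <- sd(isi) / sqrt(length(isi))
  expect_lt(abs(mean(isi) - 1 / H), 3 * se)
  expect_length(rec$left_times, 0)
})

test_that("an insurmountable left barrier yields no left crossings", {
  sp <- barrier_spec("phasic", D = 1, dU_L = 30)
  rec <- simulate_barrier_process(sp, 2e4, seed = 4)
  expect_length(rec$left_times, 0)
  expect_gt(length(rec$spike_times), 0)
})

test_that("event records are reproducible by seed and strictly ordered", {
  sp <- barrier_spec("phasic", D = 1, A = 0.1, phi = 0.1)
  r1 <- simulate_barrier_process(sp, 5e3, seed = 7, "per_reset")
  r2 <- simulate_barrier_process(sp, 5e3, seed = 7, "per_reset")
  expect_identical(r1$spike_times, r2$spike_times)
  expect_identical(r1$left_times, r2$left_times)
  r3 <- simulate_barrier_process(sp, 5e3, seed = 8, "per_reset")
  expect_false(identical(r1$spike_times, r3$spike_times))
  merged <- sort(c(r1$spike_times, r1$left_times))
  expect_true(all(diff(merged) > 0))
})

test_that("MC firing rate matches the renewal theory without a signal", {
  sp <- barrier_spec("phasic", D = 1)
  nu_th <- firing_rate_from_density(
    isi_density_endogenous(sp, barrier_grid(sp)))
  rec <- simulate_barrier_process(sp, 6e4, seed = 3)
  mc <- mc_metrics(rec)
  expect_gt(mc$n_spikes, 1e4)
  expect_lt(abs(nu_th - mc$nu), 3 * mc$nu_se)
})

test_that("thinning is exact for a time-varying, motion-free hazard", {
  # classic variant with a sinusoid under the endogenous clock: every ISI is
  # an independent draw from the solved density f(t | psi0)
  sp <- barrier_spec("classic", D = 1.5, A = 0.1, phi = 0.1)
  psi0 <- 3.3
  rec <- simulate_barrier_process(sp, 3e4, seed = 6, "endogenous",
                                  psi0 = psi0)
  isi <- diff(rec$spike_times)
  g <- barrier_grid(sp)
  f <- isi_density_endogenous(sp, g, psi0 = psi0)
  cdf_vals <- cumsum(f$f) * f$dt
  cdf <- approxfun(g$t, cdf_vals / cdf_vals[length(cdf_vals)],
                   yleft = 0, yright = 1)
  ks <- suppressWarnings(stats::ks.test(isi, cdf))
  expect_gt(length(isi), 3000)
  expect_gt(ks$p.value, 0.01)
})

test_that("right-moving variant diverges from phasic at small D and converges at large D", {
  ratio <- vapply(c(0.5, 1, 2), function(D) {
    nu_ph <- theory_metrics(barrier_spec("phasic", D = D))$nu
    nu_rm <- theory_metrics(barrier_spec("right_moving", D = D))$nu
    nu_ph / nu_rm
  }, 1)
  expect_gt(ratio[1], 5)        # very different when left resets dominate
  expect_lt(ratio[3], 2.5)      # responses approach one another
  expect_true(all(diff(ratio) < 0))
})
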