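test_that("blocked randomization balances every block and reproduces from seed", {
  expect_identical(randomize_operations(0), character(0))
  a4 <- randomize_operations(4, 4, seed = 1)
  expect_equal(sum(a4 == "with_ses"), 2)
  expect_error(randomize_operations(10, 3), "even")
  expect_identical(randomize_operations(20, 4, seed = 9),
                   randomize_operations(20, 4, seed = 9))
  a100 <- randomize_operations(100, 4, seed = 5)
  blocks <- matrix(a100 == "with_ses", nrow = 4)
  expect_true(all(colSums(blocks) == 2))
})

test_that("assignment shows no positional bias across seeds", {
  # within-block position should be with_ses half the time, every position
  hits <- rowSums(vapply(1:1000, function(s) {
    randomize_operations(4, 4, seed = s) == "with_ses"
  }, logical(4)))
  p <- chisq.test(cbind(hits, 1000 - hits))$p.value
  expect_gt(p, 0.001)
})

test_that("the plume model obeys its closed forms", {
  # no sources, no background, no noise: operation segment is exactly zero
  cfg0 <- tiny_config(noise = 0, event_rate = 0)
  d <- tiny_design()
  sim <- simulate_operation(d, cfg0, seed = 1)
  idx <- sim$series$time >= 120 & sim$series$time < 240
  expect_true(all(sim$series$conc[idx, ] == 0))

  # single event: concentration 1/k after the event is A * f * exp(-1)
  k <- 0.05
  sig <- orsmoke:::plume_signal(t = c(10, 10 + 1 / k), ev_times = 10,
                                amps = matrix(8, 1, 1), k = k)
  expect_equal(sig[1, 1], 8)
  expect_equal(sig[2, 1], 8 * exp(-1))

  # design factors multiply: with_ses * room_air * open
  cfg <- tiny_config()
  d2 <- tiny_design(ses = "with_ses", location = "room_air", approach = "open")
  expect_equal(orsmoke:::design_factor(d2, cfg),
               cfg$ses_attenuation * cfg$room_dilution * cfg$open_vs_mis_factor)
})

test_that("identical design, config and seed give bit-identical output", {
  cfg <- tiny_config()
  d <- tiny_design()
  s1 <- simulate_operation(d, cfg, seed = 33)
  s2 <- simulate_operation(d, cfg, seed = 33)
  expect_identical(s1$series$conc, s2$series$conc)
  expect_identical(s1$truth$event_times, s2$truth$event_times)
})

test_that("doubling emission amplitudes doubles the plume exactly", {
  d <- tiny_design()
  c1 <- tiny_config(noise = 0, background_ppb = 0)
  c2 <- tiny_config(emission = 2 * c(A = 30, B = 10), noise = 0,
                    background_ppb = 0)
  s1 <- simulate_operation(d, c1, seed = 11)
  s2 <- simulate_operation(d, c2, seed = 11)
  idx <- s1$series$time >= 120 & s1$series$time < 240
  expect_equal(s2$series$conc[idx, ], 2 * s1$series$conc[idx, ])
  expect_equal(s2$truth$expected_mean_ppb, 2 * s1$truth$expected_mean_ppb)
})

test_that("noise-free series sits on background and peaks at an event time", {
  cfg <- tiny_config(noise = 0, background_ppb = 3)
  d <- tiny_design()
  sim <- simulate_operation(d, cfg, seed = 21)
  expect_gte(length(sim$truth$event_times), 1)
  idx <- sim$series$time >= 120 & sim$series$time < 240
  op <- sim$series$conc[idx, , drop = FALSE]
  expect_true(all(op >= 3 - 1e-12))
  # the maximum lies within one sample of a realized event time
  tmax <- sim$series$time[idx][apply(op, 2, which.max)]
  gap <- vapply(tmax, function(tt) min(abs(tt - sim$truth$event_times)), 0)
  expect_true(all(gap <= cfg$sample_period))
})

test_that("SES attenuation halves mean concentrations as expected", {
  cfg <- tiny_config(emission = c(A = 30), noise = 0.2)
  d_with <- tiny_design(ses = "with_ses", duration = 120)
  d_without <- tiny_design(ses = "without_ses", duration = 120)
  means <- vapply(1:200, function(s) {
    m1 <- simulate_operation(d_with, cfg, seed = 1000 + s)
    m0 <- simulate_operation(d_without, cfg, seed = 5000 + s)
    idx <- m1$series$time >= 120 & m1$series$time < 240
    c(mean(m1$series$conc[idx, "A"]), mean(m0$series$conc[idx, "A"]))
  }, numeric(2))
  ratio <- mean(means[1, ]) / mean(means[2, ])
  # Monte-Carlo standard error of the ratio via the delta method
  se <- ratio * sqrt(var(means[1, ]) / (200 * mean(means[1, ])^2) +
                     var(means[2, ]) / (200 * mean(means[2, ])^2))
  expect_lt(abs(ratio - 0.5), 3 * se)
})

test_that("breath pairs encode the requested uptake", {
  cfg <- tiny_config(emission = c(A = 50), noise = 0)
  bp0 <- simulate_breath_pair(cfg, 0, seed = 2)
  expect_equal(bp0$inhale$conc, bp0$exhale$conc)
  bp1 <- simulate_breath_pair(cfg, 1, seed = 2)
  expect_true(all(bp1$exhale$conc == 0))
  expect_error(simulate_breath_pair(cfg, 1.2, seed = 2), "parameter error")

  cfgn <- tiny_config(emission = c(A = 50), noise = 0.5)
  est <- vapply(1:200, function(s) {
    bp <- simulate_breath_pair(cfgn, 0.4, seed = 100 + s)
    uptake_fraction(bp$inhale, bp$exhale, "A")$uptake_fraction
  }, numeric(1))
  expect_lt(abs(mean(est) - 0.40), 0.02)
})
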