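test_that("blank subtraction removes constant offsets and preserves segments", {
  s <- constant_series(c(A = 5, B = 2))
  out <- subtract_blank(s)
  expect_true(all(out$conc == 0))
  expect_identical(out$segments, s$segments)

  # blank mean zero leaves the series unchanged
  s0 <- s
  s0$conc[s0$time < 30, ] <- 0
  expect_equal(subtract_blank(s0)$conc[s0$time >= 30, ],
               s0$conc[s0$time >= 30, ])

  s_no <- ion_series("x", 0:9, matrix(1, 10, 1, dimnames = list(NULL, "A")),
                     list(operation = c(0, 10)))
  expect_error(subtract_blank(s_no), "op_id|blank_pre|segment")
})

test_that("blank subtraction centres the closing blank near zero", {
  cfg <- tiny_config(emission = c(A = 20), noise = 0.1, background_ppb = 3)
  d <- tiny_design(duration = 60)
  post_means <- vapply(1:100, function(s) {
    sim <- simulate_operation(d, cfg, seed = 300 + s)
    out <- subtract_blank(sim$series)
    idx <- out$time >= 180  # closing blank window
    mean(out$conc[idx, "A"])
  }, numeric(1))
  se <- sd(post_means) / sqrt(100)
  expect_lt(abs(mean(post_means)), 3 * se + 1e-12)
})

test_that("single-point calibration scales to the standard", {
  s <- constant_series(c(A = 5))
  out <- calibrate(s, c(A = 5))           # calib mean already equals standard
  expect_equal(out$conc, s$conc)
  expect_equal(unname(attr(out, "calib_factor")), 1)

  out2 <- calibrate(s, c(A = 10))         # calib mean = standard / 2
  expect_equal(out2$conc, 2 * s$conc)

  expect_error(calibrate(s, c(Z = 5)), "unknown channel")
  expect_error(calibrate(s, c(A = -1)), "> 0")
  neg <- s
  neg$conc[] <- -1
  expect_error(calibrate(neg, c(A = 5)), "non-positive")
})

test_that("calibration recovers a simulated sensitivity error within 2%", {
  cfg <- tiny_config(emission = c(A = 20), noise = 0.2,
                     calib_true_factor = 0.8, calib_standard_ppb = 100)
  d <- tiny_design(duration = 60)
  factors <- vapply(1:50, function(s) {
    sim <- simulate_operation(d, cfg, seed = 600 + s)
    attr(calibrate(sim$series, c(A = 100)), "calib_factor")[["A"]]
  }, numeric(1))
  expect_lt(abs(mean(factors) - 1 / 0.8), 0.02 * (1 / 0.8))
})

test_that("total VOC is the pointwise channel sum", {
  s <- constant_series(c(A = 5, B = 2))
  one <- total_voc(s, "A")
  expect_equal(unname(one$conc[, 1]), unname(s$conc[, "A"]))
  both <- total_voc(s, c("A", "B"))
  expect_equal(unname(both$conc[, 1]), unname(s$conc[, "A"] + s$conc[, "B"]))
  expect_error(total_voc(s, "Z"), "lookup error")
})

test_that("summing the panel averages reproduces the recorded harmful total", {
  reg <- load_registry()
  s <- constant_series(setNames(reg$avg_ppb_paper, reg$name))
  tot <- total_voc(s, reg$name, name = "harmful_total")
  m <- summarize_operation(tot)$channel_stats$mean_ppb
  expect_lt(abs(m - 272.69), 0.02 + 1e-9)
})

test_that("blank subtraction and totalling commute", {
  cfg <- tiny_config()
  sim <- simulate_operation(tiny_design(duration = 60), cfg, seed = 4)
  a <- total_voc(subtract_blank(sim$series))
  b <- subtract_blank(total_voc(sim$series))
  expect_equal(a$conc, b$conc)
})

test_that("operation summaries use the operation segment with earliest-tie argmax", {
  s <- constant_series(c(A = 7))
  sm <- summarize_operation(s)
  expect_equal(sm$channel_stats$mean_ppb, 7)
  expect_equal(sm$channel_stats$max_ppb, 7)
  expect_equal(sm$channel_stats$argmax_time_fraction, 0)  # earliest tie

  # linear ramp: maximum at the final sample
  t <- 0:119
  ramp <- ion_series("ramp", t,
                     matrix(t, ncol = 1, dimnames = list(NULL, "A")),
                     list(blank_pre = c(0, 20), operation = c(20, 120)))
  smr <- summarize_operation(ramp)
  expect_gte(smr$channel_stats$argmax_time_fraction, 1 - 1 / 100)

  # single plume event placed 25% into the segment
  op_t <- 0:399
  ev <- 100  # 25% of a 400 s segment
  sig <- orsmoke:::plume_signal(op_t, ev, matrix(10, 1, 1), k = 0.02)
  single <- ion_series("one", c(-10:-1, op_t),
                       matrix(c(rep(0, 10), sig), ncol = 1,
                              dimnames = list(NULL, "A")),
                       list(blank_pre = c(-10, 0), operation = c(0, 400)))
  expect_equal(summarize_operation(single)$channel_stats$argmax_time_fraction,
               0.25, tolerance = 1 / 400)
})

test_that("summaries are invariant to channel order and bound by channel maxima", {
  reg <- load_registry()
  cfg <- sim_config_from_registry(reg)
  sim <- simulate_operation(tiny_design(duration = 60), cfg, seed = 8)
  s <- sim$series
  perm <- s
  ord <- rev(seq_len(ncol(s$conc)))
  perm$conc <- perm$conc[, ord]
  a <- summarize_operation(s, registry = reg)
  b <- summarize_operation(perm, registry = reg)
  expect_equal(a$harmful_total_mean_ppb, b$harmful_total_mean_ppb)
  expect_equal(a$total_voc_max_ppb, b$total_voc_max_ppb)
  expect_equal(a$channel_stats[order(a$channel_stats$channel), ],
               b$channel_stats[order(b$channel_stats$channel), ],
               ignore_attr = TRUE)
  # max of sum <= sum of maxima over the panel
  panel <- intersect(reg$name, colnames(s$conc))
  expect_lte(a$harmful_total_max_ppb,
             sum(a$channel_stats$max_ppb[a$channel_stats$channel %in% panel]))
})

test_that("series survive a write/read round trip with their sidecar", {
  cfg <- tiny_config()
  d <- tiny_design(duration = 60, ses = "with_ses")
  sim <- simulate_operation(d, cfg, seed = 12)
  path <- withr::local_tempfile(fileext = ".csv")
  write_ion_series(sim$series, path, design = d)
  back <- read_ion_series(path)
  expect_equal(back$conc, sim$series$conc, tolerance = 1e-6)
  expect_equal(back$segments, sim$series$segments)
  expect_equal(attr(back, "design")$ses, "with_ses")
})
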