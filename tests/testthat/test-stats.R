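test_that("two-group comparison handles identical groups and swaps symmetrically", {
  sums <- c(lapply(1:3, function(i) make_summary(paste0("a", i), ses = "with_ses",
                                                 response = 100)),
            lapply(1:3, function(i) make_summary(paste0("b", i), ses = "without_ses",
                                                 response = 100)))
  res <- compare_groups(sums, "ses")
  expect_equal(res$mean_difference, 0)
  expect_equal(res$p_value, 1)

  set.seed(1)
  y1 <- rnorm(8, 100, 10)
  y2 <- rnorm(8, 80, 20)
  mk <- function(y, lev) {
    lapply(seq_along(y), function(i) {
      make_summary(paste0(lev, i), ses = lev, response = y[i])
    })
  }
  fwd <- compare_groups(c(mk(y1, "with_ses"), mk(y2, "without_ses")), "ses")
  rev <- compare_groups(c(mk(y2, "with_ses"), mk(y1, "without_ses")), "ses")
  expect_equal(fwd$mean_difference, -rev$mean_difference)
  expect_equal(fwd$p_value, rev$p_value)
  # and it agrees with a direct Welch test
  direct <- t.test(y1, y2)
  expect_equal(fwd$p_value, direct$p.value)

  expect_error(compare_groups(mk(y1, "with_ses"), "ses"), "grouping error")
})

test_that("effect decomposition inverts a noise-free linear model exactly", {
  grid <- expand.grid(ses = c("with_ses", "without_ses"),
                      approach = c("open", "minimally_invasive"),
                      location = c("surgeon_level", "room_air"),
                      rep = 1:2, stringsAsFactors = FALSE)
  y <- 200 - 100 * (grid$ses == "with_ses") + 50 * (grid$approach == "open") +
    20 * (grid$location == "surgeon_level")
  sums <- lapply(seq_len(nrow(grid)), function(i) {
    make_summary(paste0("op", i), ses = grid$ses[i], approach = grid$approach[i],
                 location = grid$location[i], response = y[i])
  })
  dec <- suppressWarnings(effect_decomposition(sums))  # exact fit warns in lm
  expect_equal(unname(dec$coefficients["ses"]), -100)
  expect_equal(unname(dec$coefficients["open"]), 50)
  expect_equal(unname(dec$coefficients["surgeon_level"]), 20)
  expect_equal(dec$intercept, 200)
  expect_equal(dec$R, 1)
})

test_that("a single varying factor reproduces the difference of group means", {
  set.seed(7)
  y <- rnorm(12, 300, 40)
  ses <- rep(c("with_ses", "without_ses"), each = 6)
  sums <- lapply(1:12, function(i) {
    make_summary(paste0("op", i), ses = ses[i], response = y[i])
  })
  dec <- effect_decomposition(sums)
  expect_equal(unname(dec$coefficients["ses"]),
               mean(y[1:6]) - mean(y[7:12]))
})

test_that("rank-deficient factor codings are reported as errors", {
  # ses and approach perfectly aliased
  sums <- lapply(1:8, function(i) {
    lev <- if (i <= 4) c("with_ses", "open") else c("without_ses", "minimally_invasive")
    make_summary(paste0("op", i), ses = lev[1], approach = lev[2],
                 response = rnorm(1, 100, 10))
  })
  expect_error(effect_decomposition(sums), "decomposition error")
})

test_that("R shrinks toward zero when the response ignores the factors", {
  set.seed(42)
  Rs <- vapply(1:60, function(r) {
    ses <- rep(c("with_ses", "without_ses"), 50)
    appr <- rep(c("open", "open", "minimally_invasive", "minimally_invasive"), 25)
    sums <- lapply(1:100, function(i) {
      make_summary(paste0("op", i), ses = ses[i], approach = appr[i],
                   location = if (i <= 50) "surgeon_level" else "room_air",
                   response = rnorm(1, 400, 150))
    })
    effect_decomposition(sums)$R
  }, numeric(1))
  # with 3 indicators and n = 100 the null R concentrates near sqrt(3/99)
  expect_lt(median(Rs), 0.3)
  expect_gt(mean(Rs < 0.35), 0.9)
})

test_that("time-of-maximum pooling caps at K and ignores labels and padding", {
  one <- make_summary("op1", argmax_fractions = c(0.1, 0.5, 0.9),
                      max_ppb = c(5, 4, 3))
  res <- max_time_distribution(list(one), K = 100)
  expect_equal(res$n, 3)

  # only the top-K channels enter the pool
  two <- make_summary("op2", argmax_fractions = c(0.2, 0.4, 0.6, 0.8),
                      max_ppb = c(10, 9, 1, 2))
  res2 <- max_time_distribution(list(two), K = 2)
  expect_setequal(res2$fractions, c(0.2, 0.4))

  # appending zero-max channels beyond rank K changes nothing
  padded <- make_summary("op3", argmax_fractions = c(0.2, 0.4, 0.99, 0.99),
                         max_ppb = c(10, 9, 0, 0))
  res3 <- max_time_distribution(list(padded), K = 2)
  expect_equal(sort(res3$fractions), sort(res2$fractions))
  expect_equal(res3$ks_statistic, res2$ks_statistic)
})

test_that("early-clustered maxima reject uniformity decisively", {
  set.seed(3)
  sums <- lapply(1:30, function(i) {
    make_summary(paste0("op", i), argmax_fractions = runif(100, 0, 0.1),
                 max_ppb = runif(100, 1, 10))
  })
  res <- max_time_distribution(sums, K = 100)
  expect_lt(res$p_value, 1e-6)
})

test_that("sample size mapping matches the design's power target", {
  expect_equal(sample_size_two_group(1.22, 1, 0.05, 0.90), 15)
  expect_equal(sample_size_two_group(100, 1), 2)      # floor at n = 2
  n1 <- sample_size_two_group(1, 1)
  n2 <- sample_size_two_group(0.5, 1)
  expect_gt(n2 / n1, 3.3)                             # ~ 1/d^2 scaling
  expect_lt(n2 / n1, 4.7)
  # effect/sd scaling equivalence
  expect_equal(sample_size_two_group(12.2, 10), sample_size_two_group(1.22, 1))
  expect_error(sample_size_two_group(0, 1), "parameter error")
})

test_that("the returned sample size is consistent with brute-force power", {
  # simulate the two-sample t-test at the returned n for d = 1.22
  n <- sample_size_two_group(1.22, 1, 0.05, 0.90)
  set.seed(11)
  rej <- mean(vapply(1:2000, function(r) {
    t.test(rnorm(n, 1.22), rnorm(n, 0))$p.value < 0.05
  }, logical(1)))
  expect_lt(abs(rej - 0.90), 0.03)
  # two groups fewer would undershoot the target clearly
  rej_low <- mean(vapply(1:2000, function(r) {
    t.test(rnorm(n - 2, 1.22), rnorm(n - 2, 0))$p.value < 0.05
  }, logical(1)))
  expect_lt(rej_low, 0.90)
})
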