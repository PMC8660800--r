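test_that("marker calibration interpolates fragment length monotonically", {
  # two markers: position 10 -> 27 nt, position 50 -> 7 nt; midpoint maps to 17
  cal <- calibrate(data.frame(position = c(10, 50), tail_nt = c(27, 7)))
  expect_equal(cal$map(30), 17)
  # identity at marker positions
  expect_equal(cal$map(c(10, 50)), c(27, 7))
  # extrapolation clamped to marker range
  expect_equal(cal$map(c(0, 99)), c(27, 7))
  # random monotone marker sets equal an independent two-point oracle
  set.seed(2)
  for (i in 1:10) {
    pos <- sort(runif(5, 0, 100))
    len <- sort(runif(5, 5, 40), decreasing = TRUE)
    cal <- calibrate(data.frame(position = pos, tail_nt = len))
    x0 <- runif(20, min(pos), max(pos))
    expect_equal(cal$map(x0),
                 vapply(x0, function(x) oracle_interp(pos, len, x), 0),
                 tolerance = 1e-12)
  }
  expect_error(calibrate(data.frame(position = c(1, 2, 3),
                                    tail_nt = c(10, 12, 11))), "monotone")
  expect_error(calibrate(data.frame(position = 1, tail_nt = 10)), ">= 2")
})

test_that("most abundant tail is the calibrated argmax with longer-tail ties", {
  grid <- seq(0, 100, 0.5)
  cal <- calibrate(data.frame(position = c(19, 79), tail_nt = c(27, 7)))
  # single Gaussian band at the A20 position (27 nt total) -> 20 As
  lane <- data.frame(position = grid,
                     intensity = exp(-(grid - 19)^2 / 2))
  expect_equal(most_abundant_tail(lane, cal, bg_window = 0), 20)
  # two equal-height bands -> tie broken toward the longer tail
  pos15 <- 79 - 3 * 15   # total 22 nt -> 15 As
  pos5 <- 79 - 3 * 5     # total 12 nt -> 5 As
  lane2 <- data.frame(position = grid, intensity = 0)
  lane2$intensity[grid == pos15] <- 1
  lane2$intensity[grid == pos5] <- 1
  expect_equal(most_abundant_tail(lane2, cal, bg_window = 0), 15)
  expect_error(most_abundant_tail(
    data.frame(position = grid, intensity = rep(0, length(grid))), cal),
    "all zero")
})

test_that("noisy simulated lanes recover the true modal tail", {
  sim <- simulate_lane_profiles(0.625, seq(0, 24, 4), tail0 = 20,
                                noise_sd = 0.05, seed = 6)
  cal <- calibrate(sim$markers)
  tails <- vapply(sim$lanes, most_abundant_tail, 0, cal = cal)
  expect_equal(tails, sim$truth$tail_As)
})

test_that("rate estimation is exact on the linear ladder and clamps at zero", {
  # tails 20/15/10/5 at 0/8/16/24 min -> 0.625 As/min, R2 = 1
  est <- estimate_rate(data.frame(time_min = c(0, 8, 16, 24),
                                  tail_As = c(20, 15, 10, 5)))
  expect_equal(est$rate_As_per_min, 0.625, tolerance = 1e-12)
  expect_equal(est$r2, 1, tolerance = 1e-12)
  # constant tails -> rate 0
  est0 <- estimate_rate(data.frame(time_min = c(0, 8, 16, 24),
                                   tail_As = rep(12, 4)))
  expect_equal(est0$rate_As_per_min, 0)
  # increasing tails cannot happen physically: clamped with a warning
  expect_warning(
    estr <- estimate_rate(data.frame(time_min = c(0, 8, 16, 24),
                                     tail_As = c(5, 6, 8, 9))),
    "positive")
  expect_equal(estr$rate_As_per_min, 0)
  expect_error(estimate_rate(data.frame(time_min = c(0, 8),
                                        tail_As = c(20, 10))), ">= 3")
})

test_that("plateau lanes are excluded from the regression window", {
  # fully deadenylated lanes after 16 min would flatten the slope
  ser <- data.frame(time_min = c(0, 4, 8, 12, 16, 24, 32),
                    tail_As = c(20, 15, 10, 5, 0, 0, 0))
  est <- estimate_rate(ser)
  expect_equal(est$rate_As_per_min, 1.25, tolerance = 1e-12)
  expect_identical(est$n_points, 5L)
  # appending post-plateau lanes never increases bias vs the no-plateau fit
  pre <- estimate_rate(ser[1:4, ])
  expect_lte(abs(est$rate_As_per_min - 1.25), abs(pre$rate_As_per_min - 1.25) + 1e-12)
})

test_that("fold inhibition is the rate ratio with propagated uncertainty", {
  expect_equal(fold_inhibition(1.0, 0.25)$fold, 4.0)
  expect_equal(fold_inhibition(0.8, 0.8)$fold, 1.0)
  # independent ratio-of-fits oracle with SE propagation
  s1 <- simulate_lane_profiles(1.2, seq(0, 16, 2), seed = 5)
  s2 <- simulate_lane_profiles(0.35, seq(0, 32, 4), seed = 6)
  r1 <- quantify_deadenylation(s1$lanes, s1$markers)$rate
  r2 <- quantify_deadenylation(s2$lanes, s2$markers)$rate
  f <- fold_inhibition(r1, r2)
  expect_equal(f$fold, r1$rate_As_per_min / r2$rate_As_per_min)
  expect_equal(f$se, f$fold * sqrt((r1$se / r1$rate_As_per_min)^2 +
                                     (r2$se / r2$rate_As_per_min)^2),
               tolerance = 1e-12)
  expect_lt(abs(f$fold / (1.2 / 0.35) - 1), 0.1)
  # a dead enzyme gives a bound, not infinity
  z <- structure(list(rate_As_per_min = 0, se = 0.05), class = "rate_estimate")
  fb <- fold_inhibition(r1, z)
  expect_true(fb$bound)
  expect_equal(fb$fold, r1$rate_As_per_min / 0.05)
})

test_that("reported tail is monotone in band position under any calibration", {
  set.seed(8)
  grid <- seq(0, 100, 0.5)
  for (i in 1:5) {
    pos <- sort(runif(4, 5, 95))
    len <- sort(runif(4, 7, 40), decreasing = TRUE)
    cal <- calibrate(data.frame(position = pos, tail_nt = len))
    centres <- sort(runif(6, min(pos), max(pos)))
    tails <- vapply(centres, function(cc) {
      lane <- data.frame(position = grid,
                         intensity = exp(-(grid - cc)^2 / 2))
      most_abundant_tail(lane, cal, body_nt = 0, bg_window = 0)
    }, 0)
    expect_true(all(diff(tails) <= 0))
  }
})
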