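test_that("chase simulation is deterministic under a fixed seed", {
  cfg <- chase_sim_config(n_genes = 100, library_depth = 1e6,
                          n_spikeins = 10, seed = 11)
  a <- simulate_chase(cfg)
  b <- simulate_chase(cfg)
  expect_identical(a$matrix$counts, b$matrix$counts)
  expect_identical(a$truth, b$truth)
})

test_that("in the Poisson limit, normalized mean counts track exp(-k m t)", {
  cfg <- chase_sim_config(n_genes = 40, timepoints_h = c(0, 2, 4, 6),
                          n_replicates = 40, conditions = c(parental = 1, KO = 1.3),
                          library_depth = 2e7, nb_dispersion = Inf,
                          n_spikeins = 20, seed = 4)
  sim <- simulate_chase(cfg)
  norm <- normalize_to_spikeins(sim$matrix)
  sheet <- norm$samples
  for (cond in c("parental", "KO")) {
    tr <- sim$truth[sim$truth$condition == cond, ]
    for (t in c(2, 4, 6)) {
      sel0 <- sheet$condition == cond & sheet$time_h == 0
      selt <- sheet$condition == cond & sheet$time_h == t
      ratio <- rowMeans(norm$values[tr$gene, selt, drop = FALSE]) /
        rowMeans(norm$values[tr$gene, sel0, drop = FALSE])
      expect_true(all(abs(ratio / exp(-tr$k_per_h * t) - 1) < 0.01))
    }
  }
})

test_that("generated true half-lives follow the configured log-normal", {
  cfg <- chase_sim_config(n_genes = 2000, library_depth = 5e6, seed = 8)
  sim <- simulate_chase(cfg)
  med <- median(sim$truth$halflife_h[sim$truth$condition == "parental"])
  set.seed(999)  # independent draw-and-sort oracle over the same law
  oracle_med <- median(sort(rlnorm(2e5, log(4.9), 0.5)))
  expect_lt(abs(med / oracle_med - 1), 0.05)
  expect_lt(abs(med / 4.9 - 1), 0.05)
})

test_that("truth table satisfies t1/2 * k = ln 2 to machine precision", {
  sim <- small_chase(seed = 2)
  expect_equal(sim$truth$halflife_h * sim$truth$k_per_h,
               rep(log(2), nrow(sim$truth)), tolerance = 1e-14)
})

test_that("chase config rejects invalid designs", {
  expect_error(chase_sim_config(timepoints_h = c(0, 2, 2, 6)), "increasing")
  expect_error(chase_sim_config(timepoints_h = c(1, 2, 3)), "include 0")
  expect_error(chase_sim_config(conditions = c(a = 1, b = -2)), "positive")
  expect_error(chase_sim_config(spikein_fraction = 1.2), "spikein_fraction")
  expect_error(chase_sim_config(library_depth = 100, n_spikeins = 92,
                                spikein_fraction = 0.05), "too small")
})

test_that("lane profile generator walks the modal band down the ladder", {
  # direct arithmetic: rate 0.625, t = 0/8/16/24, tail0 = 20 -> 20/15/10/5
  sim <- simulate_lane_profiles(0.625, c(0, 8, 16, 24), tail0 = 20, seed = 1)
  expect_equal(sim$truth$tail_As, c(20, 15, 10, 5))
  # rate 0: modal tail constant
  sim0 <- simulate_lane_profiles(0, c(0, 8, 16, 24), tail0 = 20, seed = 1)
  expect_equal(sim0$truth$tail_As, rep(20, 4))
  # noiseless narrow bands: argmax maps back to the true tail exactly
  simn <- simulate_lane_profiles(0.625, c(0, 8, 16, 24), tail0 = 20,
                                 band_sigma = 0.5, noise_sd = 0, seed = 1)
  cal <- calibrate(simn$markers)
  tails <- vapply(simn$lanes, most_abundant_tail, 0, cal = cal)
  expect_equal(tails, simn$truth$tail_As)
  expect_error(simulate_lane_profiles(-1, 0:3), "rate")
  expect_error(simulate_lane_profiles(1, 0:3, band_sigma = -1), "band_sigma")
})

test_that("qPCR series generator is exact when noiseless and deterministic", {
  q <- simulate_qpcr_series(1, timepoints_h = 0:3, noise_cv = 0)
  expect_equal(q$target / q$reference_signal, c(1, 0.5, 0.25, 0.125))
  expect_identical(simulate_qpcr_series(2, seed = 5),
                   simulate_qpcr_series(2, seed = 5))
  # near-noiseless series is recovered by the targeted fit within 2%
  qn <- simulate_qpcr_series(3, timepoints_h = 0:4, noise_cv = 0.01, seed = 3)
  expect_lt(abs(fit_series(qn)$halflife_h / 3 - 1), 0.02)
})

test_that("AP-MS generator plants bait-exclusive members and is deterministic", {
  ap <- simulate_apms(missing_rate = 0, seed = 9)
  ctrl <- ap$samples$sample[ap$samples$label == "control"]
  members <- ap$truth$protein[ap$truth$complex_member]
  expect_true(all(is.na(ap$intensities[members, ctrl])))
  # with no missingness every unflagged protein passes the presence filter
  fl <- filter_table(ap, min_present = 3)
  expect_setequal(rownames(fl$intensities),
                  ap$flags$protein[!(ap$flags$contaminant | ap$flags$reverse |
                                       ap$flags$site_only)])
  expect_identical(simulate_apms(seed = 2)$intensities,
                   simulate_apms(seed = 2)$intensities)
})

test_that("a strongly regulated SILAC protein is detected in >95% of seeds", {
  # power oracle by direct simulation at the generator's distribution:
  # true log2 ratio -1.0, replicate sd 0.05, n = 4
  hits <- vapply(1:1000, function(s) {
    ap <- simulate_apms(n_background = 2, silac_regulated = c(RNF219 = -1),
                        silac_sd = 0.05, n_replicates = 4, seed = s)
    silac_test(ap$silac["RNF219", ])$p_value < 0.05
  }, TRUE)
  expect_gt(mean(hits), 0.95)
})
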