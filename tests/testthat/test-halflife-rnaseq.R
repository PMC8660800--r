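make_matrix <- function(counts, times, spikeins, conditions = "c1",
                        replicates = 1L) {
  sheet <- data.frame(sample = colnames(counts),
                      condition = rep(conditions, length.out = ncol(counts)),
                      replicate = rep(replicates, length.out = ncol(counts)),
                      time_h = times)
  chase_matrix(counts, sheet, spikeins)
}

test_that("normalization divides by the spike-in sum of each sample", {
  counts <- rbind(gene1 = c(100L, 100L, 100L),
                  `ERCC-1` = c(1e6L, 2e6L, 1e6L))
  colnames(counts) <- c("s1", "s2", "s3")
  m <- make_matrix(counts, c(0, 2, 4), "ERCC-1")
  norm <- normalize_to_spikeins(m)
  # spike sums 1e6 and 2e6, equal raw counts -> normalized values in ratio 2:1
  expect_equal(norm$values["gene1", "s1"] / norm$values["gene1", "s2"], 2)
  # independent elementwise division oracle on a random matrix
  set.seed(1)
  counts <- matrix(rpois(50 * 6, 500), nrow = 50,
                   dimnames = list(c(sprintf("g%02d", 1:45),
                                     sprintf("ERCC-%d", 1:5)),
                                   sprintf("s%d", 1:6)))
  m <- make_matrix(counts, rep(c(0, 3, 6), 2), sprintf("ERCC-%d", 1:5),
                   replicates = rep(1:2, each = 3))
  norm <- normalize_to_spikeins(m)
  ssum <- colSums(counts[46:50, ])
  oracle <- t(t(counts) / ssum) * 2^round(log2(median(ssum)))
  expect_equal(norm$values, oracle, tolerance = 1e-15)
})

test_that("normalization refuses samples without spike-in reads", {
  counts <- rbind(gene1 = c(5L, 5L, 5L), `ERCC-1` = c(10L, 0L, 3L))
  colnames(counts) <- c("s1", "s2", "s3")
  m <- make_matrix(counts, c(0, 2, 4), "ERCC-1")
  expect_error(normalize_to_spikeins(m), "s2")
})

test_that("fit_decay matches first-order arithmetic and the OLS oracle", {
  # exact two-fold decay per hour
  f <- fit_decay(c(0, 1, 2, 3), c(100, 50, 25, 12.5))
  expect_equal(f$slope, -log(2), tolerance = 1e-12)
  expect_equal(f$halflife_h, 1, tolerance = 1e-12)
  expect_equal(f$r2, 1, tolerance = 1e-12)
  # constant series: no decay, infinite half-life
  fc <- fit_decay(c(0, 2, 4, 6), rep(7, 4))
  expect_equal(fc$slope, 0)
  expect_identical(fc$halflife_h, Inf)
  # closed-form fit equals lm on seeded noisy series
  set.seed(42)
  for (i in 1:20) {
    t <- rep(c(0, 2, 4, 6), 2)
    v <- exp(rnorm(8, mean = 5 - 0.2 * t, sd = 0.2))
    f <- fit_decay(t, v)
    o <- oracle_lm_fit(t, v)
    expect_equal(f$slope, o$slope, tolerance = 1e-10)
    expect_equal(f$intercept, o$intercept, tolerance = 1e-10)
    expect_equal(f$r2, o$r2, tolerance = 1e-10)
  }
})

test_that("zero values are dropped and sparse genes marked failed", {
  f <- fit_decay(c(0, 1, 2, 3), c(10, 5, 0, 0))
  expect_identical(f$status, "too_few_points")
  expect_identical(f$n_dropped, 2L)
  f2 <- fit_decay(c(0, 1, 2, 3), c(8, 4, 2, 0))
  expect_identical(f2$status, "ok")
  expect_identical(f2$n_points, 3L)
  expect_equal(f2$halflife_h, 1, tolerance = 1e-12)
})

test_that("reliability filter applies the three rules strictly", {
  fits <- data.frame(
    gene = rep(c("g1", "g2", "g3", "g4"), each = 2),
    condition = rep(c("a", "b"), 4),
    status = "ok",
    slope = c(-0.2, -0.2,   -0.2, -0.2,   -0.2, 0.1,   -0.2, -0.2),
    r2 = c(0.9, 0.9,   0.9, 0.5,   0.9, 0.99,   0.9, 0.51),
    stringsAsFactors = FALSE)
  fits$halflife_h <- halflife_from_slope(fits$slope)
  fits$n_points <- 4L
  fits$intercept <- 1
  fits$n_dropped <- 0L
  fits$is_spikein <- FALSE
  ht <- filter_reliable(fits, r2_min = 0.5)
  # g2 has R2 exactly 0.5 in one condition: excluded (strict inequality);
  # g3 has a positive slope despite R2 0.99: excluded
  expect_setequal(ht$table$gene, c("g1", "g4"))
  expect_identical(ht$flags$outcome[ht$flags$gene == "g2"], "filtered")
})

test_that("reliability filter equals the row-scan oracle on a synthetic run", {
  sim <- small_chase(seed = 3)
  fits <- fit_decay_all(normalize_to_spikeins(sim$matrix))
  ht <- filter_reliable(fits)
  expect_identical(sort(ht$table$gene), oracle_filter(fits))
  expect_error(filter_reliable(fits[fits$gene != "gene_00001" |
                                      fits$condition != "KO", ]),
               "universe")
})

test_that("half-lives are bit-identical under per-sample library rescaling", {
  sim <- small_chase(seed = 6)
  run0 <- run_halflife_pipeline(sim$matrix)
  for (j in c(1, 5)) {
    m2 <- sim$matrix
    m2$counts[, j] <- m2$counts[, j] * 7L
    run2 <- run_halflife_pipeline(m2)
    expect_identical(run0$table$table, run2$table$table)
    expect_identical(run0$fits$slope, run2$fits$slope)
    expect_identical(run0$fits$r2, run2$fits$r2)
  }
})

test_that("pipeline recovers true half-lives at low counting noise", {
  # low noise: near-Poisson dispersion, 4 replicates, every gene deeply covered
  sim <- simulate_chase(chase_sim_config(
    n_genes = 60, n_replicates = 4, library_depth = 5e6, nb_dispersion = 1e4,
    halflife_sdlog = 0.4, n_spikeins = 20, seed = 5))
  run <- run_halflife_pipeline(sim$matrix)
  long <- merge(halflife_long(run), sim$truth[, c("gene", "condition", "halflife_h")])
  mean_count <- rowMeans(sim$matrix$counts)[long$gene]
  sel <- mean_count >= 50 & long$halflife_h <= 12
  expect_gt(sum(sel), 50)
  expect_true(all(abs(long$est[sel] / long$halflife_h[sel] - 1) < 0.15))
})

test_that("pipeline recovery error and retention behave at study scale", {
  sim <- simulate_chase(chase_sim_config(seed = 1))   # 2000 genes, depth 5e6
  run <- run_halflife_pipeline(sim$matrix)
  long <- merge(halflife_long(run), sim$truth[, c("gene", "condition", "halflife_h")])
  mare <- median(abs(long$est - long$halflife_h) / long$halflife_h)
  expect_lt(mare, 0.10)
  expect_gt(run$summary$n_retained, 1500)
})

test_that("a larger decay multiplier strictly lowers the recovered median", {
  sim <- simulate_chase(chase_sim_config(
    n_genes = 800, conditions = c(a = 1.0, b = 1.2, c = 1.5),
    library_depth = 2e6, n_spikeins = 30, seed = 10))
  run <- run_halflife_pipeline(sim$matrix)
  med <- run$summary$median_halflife_h
  expect_true(med[["a"]] > med[["b"]] && med[["b"]] > med[["c"]])
})

test_that("per-replicate fitting mode agrees with pooled fits at low noise", {
  sim <- simulate_chase(chase_sim_config(
    n_genes = 100, library_depth = 2e6, nb_dispersion = 1e4,
    n_spikeins = 20, seed = 12))
  norm <- normalize_to_spikeins(sim$matrix)
  pooled <- fit_decay_all(norm)
  perrep <- fit_decay_all(norm, per_replicate = TRUE)
  ok <- pooled$status == "ok" & perrep$status == "ok" & pooled$slope < -0.05
  expect_gt(mean(abs(perrep$slope[ok] / pooled$slope[ok] - 1) < 0.1), 0.95)
})

test_that("degenerate inputs raise errors", {
  counts <- matrix(integer(0), nrow = 0, ncol = 0)
  expect_error(chase_matrix(counts, data.frame(), character()))
  sim <- small_chase(seed = 1, n_genes = 10)
  only_spikes <- sim$matrix
  only_spikes$counts <- only_spikes$counts[only_spikes$spikeins, ]
  expect_error(run_halflife_pipeline(only_spikes), "no genes")
})
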