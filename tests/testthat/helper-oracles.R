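# Independent oracles used across the suite. Each recomputes a quantity by a
# route disjoint from the implementation under test.

# Exact two-sided signed-rank p by full enumeration of all 2^n sign
# assignments (average ranks for tied magnitudes).
oracle_signed_rank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  wall <- as.vector(signs %*% r)
  min(1, 2 * min(mean(wall <= w), mean(wall >= w)))
}

# Log-linear OLS via stats::lm, the reference route for the closed-form fits.
oracle_lm_fit <- function(time, value) {
  fit <- lm(log(value) ~ time)
  s <- summary(fit)
  list(intercept = unname(coef(fit)[1]), slope = unname(coef(fit)[2]),
       r2 = s$r.squared)
}

# Row-scan reliability filter: apply the three retention rules literally.
oracle_filter <- function(fits, r2_min = 0.5) {
  fits <- fits[!fits$is_spikein, ]
  keep <- vapply(unique(fits$gene), function(g) {
    f <- fits[fits$gene == g, ]
    all(f$status == "ok") && all(f$slope < 0) &&
      all(!is.na(f$r2) & f$r2 > r2_min)
  }, TRUE)
  sort(unique(fits$gene)[keep])
}

# Piecewise-linear interpolation by the two-point formula, independent of
# stats::approx.
oracle_interp <- function(xs, ys, x0) {
  stopifnot(length(xs) == length(ys))
  o <- order(xs)
  xs <- xs[o]; ys <- ys[o]
  if (x0 <= xs[1]) return(ys[1])
  if (x0 >= xs[length(xs)]) return(ys[length(ys)])
  i <- max(which(xs <= x0))
  ys[i] + (ys[i + 1] - ys[i]) * (x0 - xs[i]) / (xs[i + 1] - xs[i])
}

# One-sample t test from the t distribution directly.
oracle_t_test <- function(x) {
  n <- length(x)
  tstat <- mean(x) / (sd(x) / sqrt(n))
  list(t = tstat, p = 2 * pt(-abs(tstat), df = n - 1))
}

# Small chase simulation used by several tests.
small_chase <- function(seed = 1, n_genes = 200, ...) {
  simulate_chase(chase_sim_config(n_genes = n_genes, library_depth = 1e6,
                                  n_spikeins = 20, seed = seed, ...))
}

# Long-format (gene, condition, est) view of a retained half-life table.
halflife_long <- function(run) {
  tab <- run$table$table
  do.call(rbind, lapply(run$table$conditions, function(cn)
    data.frame(gene = tab$gene, condition = cn, est = tab[[cn]],
               stringsAsFactors = FALSE)))
}
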