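# Transcriptome-wide half-life estimation: spike-in normalization, per-gene
# log-linear first-order decay regression, reliability filtering.

#' Normalize a chase count matrix to spike-in totals
#'
#' Divides every count by the sample's total spike-in reads. Because the
#' spike-in mass per sample is fixed while cellular mRNA decays after
#' transcription shut-off, this anchors abundances on an absolute scale and
#' makes slopes insensitive to library size. A cosmetic rescale keeps values
#' in a count-like range: the power of two nearest the median spike-in total,
#' so that the rescale is exact in floating point and every downstream slope,
#' R2 and half-life is bit-reproducible under per-sample library-size
#' changes.
#'
#' @param x A [chase_matrix()]. Every sample must have at least one spike-in
#'   read.
#' @return A list of class `normalized_chase` with `values` (real matrix,
#'   spike-in rows retained), `samples`, `spikeins`, `spikein_sums` and
#'   `scale`.
#' @export
normalize_to_spikeins <- function(x) {
  stopifnot(inherits(x, "chase_matrix"))
  ssum <- colSums(x$counts[x$spikeins, , drop = FALSE])
  if (any(ssum <= 0))
    stop("zero spike-in reads in sample(s): ",
         paste(names(ssum)[ssum <= 0], collapse = ", "))
  scale <- 2^round(log2(median(ssum)))
  values <- sweep(x$counts, 2, ssum, "/") * scale
  structure(list(values = values, samples = x$samples, spikeins = x$spikeins,
                 spikein_sums = ssum, scale = scale),
            class = "normalized_chase")
}

#' Fit first-order decay to one gene's normalized time series
#'
#' Ordinary least squares of natural-log normalized abundance on time,
#' pooling all points supplied (typically both replicates of one condition).
#' Zero values cannot be log-transformed and are dropped; at least 3 positive
#' points must remain or the fit is marked failed rather than raising an
#' error, so that sparse genes flow into the exclusion log.
#'
#' @param time_h Time in hours.
#' @param value Normalized abundance (>= 0; zeros are dropped).
#' @return A list of class `decay_fit`: `status` ("ok" or "too_few_points"),
#'   `intercept` (log abundance at t = 0), `slope` (per hour), `r2`,
#'   `halflife_h` (`Inf` when `slope >= 0`), `n_points`, `n_dropped`.
#' @export
fit_decay <- function(time_h, value) {
  stopifnot(length(time_h) == length(value))
  keep <- value > 0
  n_dropped <- sum(!keep)
  t <- time_h[keep]
  v <- value[keep]
  if (length(v) < 3L || length(unique(t)) < 2L) {
    return(structure(list(status = "too_few_points", intercept = NA_real_,
                          slope = NA_real_, r2 = NA_real_,
                          halflife_h = NA_real_, n_points = length(v),
                          n_dropped = n_dropped),
                     class = "decay_fit"))
  }
  fit <- ols_fit(t, log(v))
  structure(list(status = "ok", intercept = fit$intercept, slope = fit$slope,
                 r2 = fit$r2, halflife_h = halflife_from_slope(fit$slope),
                 n_points = fit$n, n_dropped = n_dropped),
            class = "decay_fit")
}

#' Fit decay for every gene in every condition
#'
#' @param norm A `normalized_chase` from [normalize_to_spikeins()].
#' @param per_replicate If `TRUE`, fit each replicate separately and average
#'   the replicate slopes (half-life from the mean slope); the default pools
#'   all replicate points of a condition into one regression, which gains
#'   degrees of freedom and yields the single R2 the reliability filter
#'   applies.
#' @return Data frame with one row per feature x condition: `gene`,
#'   `condition`, `status`, `intercept`, `slope`, `r2`, `halflife_h`,
#'   `n_points`, `n_dropped`, `is_spikein`.
#' @export
fit_decay_all <- function(norm, per_replicate = FALSE) {
  stopifnot(inherits(norm, "normalized_chase"))
  conds <- unique(norm$samples$condition)
  feats <- rownames(norm$values)
  out <- vector("list", length(conds))
  for (ci in seq_along(conds)) {
    sel <- norm$samples$condition == conds[ci]
    tt <- norm$samples$time_h[sel]
    vv <- norm$values[, sel, drop = FALSE]
    reps <- norm$samples$replicate[sel]
    fits <- lapply(seq_along(feats), function(i) {
      if (!per_replicate) return(fit_decay(tt, vv[i, ]))
      rf <- lapply(unique(reps), function(r)
        fit_decay(tt[reps == r], vv[i, reps == r]))
      ok <- vapply(rf, function(f) f$status == "ok", TRUE)
      if (!all(ok))
        return(structure(list(status = "too_few_points", intercept = NA_real_,
                              slope = NA_real_, r2 = NA_real_,
                              halflife_h = NA_real_,
                              n_points = sum(vapply(rf, `[[`, 0, "n_points")),
                              n_dropped = sum(vapply(rf, `[[`, 0, "n_dropped"))),
                         class = "decay_fit"))
      slope <- mean(vapply(rf, `[[`, 0, "slope"))
      structure(list(status = "ok",
                     intercept = mean(vapply(rf, `[[`, 0, "intercept")),
                     slope = slope,
                     r2 = mean(vapply(rf, `[[`, 0, "r2")),
                     halflife_h = halflife_from_slope(slope),
                     n_points = sum(vapply(rf, `[[`, 0, "n_points")),
                     n_dropped = sum(vapply(rf, `[[`, 0, "n_dropped"))),
                class = "decay_fit")
    })
    out[[ci]] <- data.frame(
      gene = feats, condition = conds[ci],
      status = vapply(fits, `[[`, "", "status"),
      intercept = vapply(fits, `[[`, 0, "intercept"),
      slope = vapply(fits, `[[`, 0, "slope"),
      r2 = vapply(fits, `[[`, 0, "r2"),
      halflife_h = vapply(fits, `[[`, 0, "halflife_h"),
      n_points = vapply(fits, function(f) as.integer(f$n_points), 0L),
      n_dropped = vapply(fits, function(f) as.integer(f$n_dropped), 0L),
      is_spikein = feats %in% norm$spikeins,
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Apply the reliability filter and build the half-life table
#'
#' A gene is retained only if, in every condition, its fit succeeded, its
#' slope is negative (positive finite half-life) and its coefficient of
#' determination exceeds `r2_min` strictly. Spike-in features are always
#' excluded. Genes with no positive counts anywhere are reported as
#' "not_quantified", distinct from genes that were fit but "filtered".
#'
#' @param fits Output of [fit_decay_all()]; every condition must cover the
#'   same gene universe.
#' @param r2_min Strict lower bound on R2 (default 0.5).
#' @return A list of class `halflife_table`: `table`, a wide data frame
#'   (`gene` plus one half-life column per condition, plus per-condition R2
#'   and n columns), `conditions`, `r2_min`, and `flags`, a per-gene outcome
#'   (`retained`, `filtered`, `not_quantified`).
#' @export
filter_reliable <- function(fits, r2_min = 0.5) {
  conds <- unique(fits$condition)
  fits <- fits[!fits$is_spikein, , drop = FALSE]
  universes <- split(fits$gene, fits$condition)
  for (u in universes[-1])
    if (!identical(sort(u), sort(universes[[1]])))
      stop("conditions cover different gene universes")
  genes <- unique(fits$gene)

  wide_of <- function(col) {
    m <- matrix(NA_real_, nrow = length(genes), ncol = length(conds),
                dimnames = list(genes, conds))
    m[cbind(match(fits$gene, genes), match(fits$condition, conds))] <- fits[[col]]
    m
  }
  hl <- wide_of("halflife_h")
  r2 <- wide_of("r2")
  np <- wide_of("n_points")
  slope <- wide_of("slope")
  ok_status <- matrix(FALSE, nrow = length(genes), ncol = length(conds),
                      dimnames = list(genes, conds))
  ok_status[cbind(match(fits$gene, genes), match(fits$condition, conds))] <-
    fits$status == "ok"

  pass <- ok_status & !is.na(slope) & slope < 0 &
    !is.na(r2) & r2 > r2_min
  retained <- rowSums(pass) == length(conds)
  quantified <- rowSums(ok_status) > 0 | rowSums(np > 0, na.rm = TRUE) > 0

  flags <- data.frame(gene = genes,
                      outcome = ifelse(retained, "retained",
                                       ifelse(quantified, "filtered",
                                              "not_quantified")),
                      stringsAsFactors = FALSE)

  tab <- data.frame(gene = genes[retained], stringsAsFactors = FALSE)
  for (cn in conds) {
    tab[[cn]] <- hl[retained, cn]
    tab[[paste0("r2_", cn)]] <- r2[retained, cn]
    tab[[paste0("n_", cn)]] <- as.integer(np[retained, cn])
  }
  rownames(tab) <- NULL
  structure(list(table = tab, conditions = conds, r2_min = r2_min,
                 flags = flags),
            class = "halflife_table")
}

#' @export
print.halflife_table <- function(x, ...) {
  cat(sprintf("Half-life table: %d genes retained (R2 > %g in all %d conditions)\n",
              nrow(x$table), x$r2_min, length(x$conditions)))
  for (cn in x$conditions)
    cat(sprintf("  median t1/2 %-12s %.2f h\n", cn, median(x$table[[cn]])))
  invisible(x)
}

#' Run the full half-life pipeline on a chase count matrix
#'
#' Composition normalize -> per-gene fits -> reliability filter, with a run
#' summary (median half-life per condition, retention counts and exclusion
#' reasons).
#'
#' @param x A [chase_matrix()].
#' @param r2_min Strict R2 threshold for [filter_reliable()].
#' @param per_replicate Passed to [fit_decay_all()].
#' @return A list of class `halflife_run`: `table` (a `halflife_table`),
#'   `fits` (full per-gene report) and `summary`.
#' @export
run_halflife_pipeline <- function(x, r2_min = 0.5, per_replicate = FALSE) {
  stopifnot(inherits(x, "chase_matrix"))
  if (length(chase_genes(x)) == 0) stop("count matrix contains no genes")
  norm <- normalize_to_spikeins(x)
  fits <- fit_decay_all(norm, per_replicate = per_replicate)
  ht <- filter_reliable(fits, r2_min = r2_min)
  med <- vapply(ht$conditions, function(cn) median(ht$table[[cn]]), 0)
  summary <- list(
    n_genes = length(chase_genes(x)),
    n_retained = nrow(ht$table),
    exclusions = table(ht$flags$outcome),
    median_halflife_h = med)
  structure(list(table = ht, fits = fits, summary = summary),
            class = "halflife_run")
}

#' @export
print.halflife_run <- function(x, ...) {
  cat(sprintf("Half-life pipeline: %d/%d genes retained\n",
              x$summary$n_retained, x$summary$n_genes))
  for (cn in names(x$summary$median_halflife_h))
    cat(sprintf("  median t1/2 %-12s %.2f h\n", cn,
                x$summary$median_halflife_h[[cn]]))
  invisible(x)
}
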