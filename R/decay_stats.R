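# Comparative statistics over half-life tables: paired Wilcoxon signed-rank
# tests between conditions, half-life binning, and gene-set subgroups.

as_halflife_df <- function(table) {
  if (inherits(table, "halflife_run")) table <- table$table
  if (inherits(table, "halflife_table")) table <- table$table
  as.data.frame(table)
}

paired_values <- function(table, cond_a, cond_b) {
  df <- as_halflife_df(table)
  for (cn in c(cond_a, cond_b))
    if (!cn %in% names(df)) stop("condition not in table: ", cn)
  keep <- is.finite(df[[cond_a]]) & is.finite(df[[cond_b]])
  list(gene = df$gene[keep], a = df[[cond_a]][keep], b = df[[cond_b]][keep])
}

#' Paired comparison of half-lives between two conditions
#'
#' Two-sided Wilcoxon signed-rank test on per-gene half-life pairs over the
#' genes quantified in both conditions. Zero differences are dropped before
#' ranking (Wilcoxon's original treatment). The null distribution is exact
#' for n <= `exact_max` untied pairs and a normal approximation with
#' continuity correction above. An unpaired Mann-Whitney variant
#' (`paired = FALSE`) is available for sensitivity analysis.
#'
#' @param table A half-life table (from [filter_reliable()] /
#'   [run_halflife_pipeline()], or any data frame with a `gene` column and
#'   one numeric column per condition).
#' @param cond_a,cond_b Condition column names; direction is reported for
#'   `cond_b` relative to `cond_a`.
#' @param exact_max Largest n for which the exact null is used (default 25).
#' @param paired Use the signed-rank test (default) or Mann-Whitney.
#' @return A list of class `comparison_result`: `cond_a`, `cond_b`, `n`
#'   (pairs after dropping zeros), `median_a`, `median_b`, `statistic`,
#'   `p_value`, `direction` (`"stabilized"`, `"destabilized"` or `"none"`).
#' @export
compare_paired <- function(table, cond_a, cond_b, exact_max = 25,
                           paired = TRUE) {
  pv <- paired_values(table, cond_a, cond_b)
  if (length(pv$a) < 6) stop("need >= 6 genes shared between conditions")
  if (paired) {
    d <- pv$b - pv$a
    d <- d[d != 0]
    n <- length(d)
    if (n == 0) {
      # all pairs identical: no evidence against the null
      return(structure(list(cond_a = cond_a, cond_b = cond_b, n = 0L,
                            median_a = median(pv$a), median_b = median(pv$b),
                            statistic = NA_real_, p_value = 1,
                            direction = "none"),
                       class = "comparison_result"))
    }
    ties <- any(duplicated(abs(d)))
    if (n <= exact_max && ties && n <= 14) {
      # exact null with average ranks, by full sign enumeration
      # (psignrank assumes untied ranks)
      r <- rank(abs(d))
      w <- sum(r[d > 0])
      signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
      wall <- as.vector(signs %*% r)
      p <- min(1, 2 * min(mean(wall <= w), mean(wall >= w)))
      ht <- list(statistic = c(V = w), p.value = p)
    } else {
      ht <- wilcox.test(d, exact = n <= exact_max && !ties, correct = TRUE)
    }
  } else {
    n <- length(pv$a)
    ht <- wilcox.test(pv$b, pv$a, exact = n <= exact_max, correct = TRUE)
    d <- pv$b - pv$a
  }
  med_shift <- median(d)
  direction <- if (n == 0 || med_shift == 0) "none"
               else if (med_shift > 0) "stabilized" else "destabilized"
  structure(list(cond_a = cond_a, cond_b = cond_b, n = n,
                 median_a = median(pv$a), median_b = median(pv$b),
                 statistic = unname(ht$statistic), p_value = ht$p.value,
                 direction = direction),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("%s vs %s: median %.2f vs %.2f h, %s (n = %d, p = %.3g)\n",
              x$cond_a, x$cond_b, x$median_a, x$median_b, x$direction,
              x$n, x$p_value))
  invisible(x)
}

#' Bin genes by half-life and compare conditions within bins
#'
#' Genes are assigned to half-open intervals `(lo, hi]` of their half-life in
#' the reference condition (so a gene at exactly 6 h with an edge at 6 falls
#' in the (3,6] bin), then each bin is compared between `cond_a` and
#' `cond_b`. Default edges 0/3/6/9/12/Inf h. Empty or too-small bins are
#' reported with `NA` statistics rather than dropped.
#'
#' @param table Half-life table.
#' @param cond_a Reference condition used for binning and comparison.
#' @param cond_b Optional second condition; when `NULL` only bin assignments
#'   and per-bin medians of `cond_a` are returned.
#' @param edges Increasing bin edges in hours (first edge exclusive).
#' @param min_n Minimum genes per bin for a test (default 6).
#' @return A list of class `binned_halflives`: `edges`, `assignments`
#'   (`gene`, `bin`, reference half-life) and `results` (per-bin `n`,
#'   medians, `p_value`, `direction`, `median_ratio` = median_b / median_a).
#' @export
bin_halflives <- function(table, cond_a, cond_b = NULL,
                          edges = c(0, 3, 6, 9, 12, Inf), min_n = 6) {
  if (is.unsorted(edges, strictly = TRUE)) stop("edges must be increasing")
  df <- as_halflife_df(table)
  if (!cond_a %in% names(df)) stop("condition not in table: ", cond_a)
  bin <- cut(df[[cond_a]], breaks = edges, right = TRUE,
             include.lowest = FALSE)
  assignments <- data.frame(gene = df$gene, bin = bin,
                            ref_halflife_h = df[[cond_a]],
                            stringsAsFactors = FALSE)
  lv <- levels(bin)
  res <- data.frame(bin = lv, n = as.integer(table(bin)[lv]),
                    median_a = NA_real_, median_b = NA_real_,
                    p_value = NA_real_, direction = NA_character_,
                    median_ratio = NA_real_, stringsAsFactors = FALSE)
  for (i in seq_along(lv)) {
    sub <- df[!is.na(bin) & bin == lv[i], , drop = FALSE]
    if (nrow(sub) == 0) next
    res$median_a[i] <- median(sub[[cond_a]])
    if (is.null(cond_b)) next
    res$median_b[i] <- median(sub[[cond_b]])
    res$median_ratio[i] <- res$median_b[i] / res$median_a[i]
    if (nrow(sub) >= min_n) {
      cmp <- compare_paired(sub, cond_a, cond_b)
      res$p_value[i] <- cmp$p_value
      res$direction[i] <- cmp$direction
    }
  }
  structure(list(edges = edges, assignments = assignments, results = res,
                 cond_a = cond_a, cond_b = cond_b),
            class = "binned_halflives")
}

#' @export
print.binned_halflives <- function(x, ...) {
  cat(sprintf("Half-life bins on %s (h):\n", x$cond_a))
  print(x$results, row.names = FALSE)
  invisible(x)
}

#' Gene-set subgroup comparisons
#'
#' Restricts [compare_paired()] to each gene set (e.g. IEG, YTHDF2-, TTP- or
#' Roquin-bound mRNAs). Sets with fewer than `min_n` quantified genes are
#' skipped with a warning.
#'
#' @param table Half-life table.
#' @param genesets Named list of gene-ID character vectors (see
#'   [read_gmt()]).
#' @param cond_a,cond_b Conditions to compare.
#' @param min_n Minimum quantified genes per set (default 6).
#' @return Data frame: `set`, `n_set`, `n_quantified`, medians, `p_value`,
#'   `direction`, `median_ratio`.
#' @export
subgroup_analysis <- function(table, genesets, cond_a, cond_b, min_n = 6) {
  df <- as_halflife_df(table)
  rows <- lapply(names(genesets), function(nm) {
    ids <- unique(genesets[[nm]])
    sub <- df[df$gene %in% ids, , drop = FALSE]
    if (nrow(sub) < min_n) {
      warning("gene set `", nm, "` has < ", min_n,
              " quantified genes; skipped")
      return(NULL)
    }
    cmp <- compare_paired(sub, cond_a, cond_b)
    data.frame(set = nm, n_set = length(ids), n_quantified = nrow(sub),
               median_a = cmp$median_a, median_b = cmp$median_b,
               p_value = cmp$p_value, direction = cmp$direction,
               median_ratio = cmp$median_b / cmp$median_a,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(set = character(), n_set = integer(),
                      n_quantified = integer(), median_a = numeric(),
                      median_b = numeric(), p_value = numeric(),
                      direction = character(), median_ratio = numeric())
  rownames(out) <- NULL
  out
}

#' Median half-life of one condition
#'
#' Sample median (midpoint rule for even n) over genes quantified in the
#' condition.
#'
#' @param table Half-life table.
#' @param condition Condition column name.
#' @return Median half-life in hours.
#' @export
median_halflife <- function(table, condition) {
  df <- as_halflife_df(table)
  if (!condition %in% names(df)) stop("condition not in table: ", condition)
  v <- df[[condition]]
  v <- v[is.finite(v)]
  if (length(v) == 0) stop("no finite half-lives for condition ", condition)
  median(v)
}
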