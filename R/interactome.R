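# AP-MS interactome analytics: confidence filtering, bait-exclusive
# enrichment calling, SILAC regulation testing, and glycerol-gradient
# profile normalization.

#' Filter an AP-MS proteomics table for confidently identified proteins
#'
#' Removes contaminant-, decoy- and site-only-flagged rows, then retains
#' proteins whose LFQ intensity is present (non-missing) in at least
#' `min_present` samples. By default presence is counted across the bait
#' pull-down replicates only; `count_in = "all"` counts across every sample.
#' Missing intensities are treated as absent, never imputed, because the
#' downstream exclusivity logic is presence/absence-based.
#'
#' @param table A `proteomics_table` (see [simulate_apms()] or
#'   [read_protein_groups()]).
#' @param min_present Minimum number of non-missing intensities (default 3).
#' @param count_in `"bait"` (default) or `"all"`.
#' @return The filtered `proteomics_table`.
#' @export
filter_table <- function(table, min_present = 3, count_in = c("bait", "all")) {
  stopifnot(inherits(table, "proteomics_table"))
  count_in <- match.arg(count_in)
  cols <- if (count_in == "bait")
    table$samples$sample[table$samples$label == "bait"]
  else table$samples$sample
  if (min_present > length(cols))
    stop("min_present exceeds the number of samples counted (",
         length(cols), ")")
  fl <- table$flags
  clean <- !(fl$contaminant | fl$reverse | fl$site_only)
  present <- rowSums(!is.na(table$intensities[, cols, drop = FALSE])) >= min_present
  keep <- clean & present[fl$protein]
  out <- table
  out$intensities <- table$intensities[keep, , drop = FALSE]
  out$flags <- fl[keep, , drop = FALSE]
  if (!is.null(table$silac))
    out$silac <- table$silac[rownames(table$silac) %in% fl$protein[keep], ,
                             drop = FALSE]
  if (!is.null(table$truth))
    out$truth <- table$truth[keep, , drop = FALSE]
  out
}

#' Bait-versus-control enrichment and exclusive identification
#'
#' Computes per-protein means of log2 LFQ intensities in bait and control
#' pull-downs and flags proteins identified exclusively in the bait samples
#' (no intensity in any control run), the criterion by which core complex
#' subunits and candidate interactors are called.
#'
#' @param table A filtered `proteomics_table` containing both bait and
#'   control samples.
#' @return Data frame: `protein`, `mean_bait`, `mean_control` (`NA` when
#'   never identified in controls), `log2_enrichment`, `exclusive`.
#' @export
enrich <- function(table) {
  stopifnot(inherits(table, "proteomics_table"))
  bait_cols <- table$samples$sample[table$samples$label == "bait"]
  ctrl_cols <- table$samples$sample[table$samples$label == "control"]
  if (length(bait_cols) == 0 || length(ctrl_cols) == 0)
    stop("table must contain both bait and control samples")
  bi <- table$intensities[, bait_cols, drop = FALSE]
  ci <- table$intensities[, ctrl_cols, drop = FALSE]
  mean_bait <- rowMeans(bi, na.rm = TRUE)
  mean_bait[is.nan(mean_bait)] <- NA_real_
  mean_ctrl <- rowMeans(ci, na.rm = TRUE)
  mean_ctrl[is.nan(mean_ctrl)] <- NA_real_
  exclusive <- !is.na(mean_bait) & rowSums(!is.na(ci)) == 0
  data.frame(protein = rownames(table$intensities),
             mean_bait = mean_bait, mean_control = mean_ctrl,
             log2_enrichment = mean_bait - mean_ctrl,
             exclusive = exclusive,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' One-sample test of SILAC regulation
#'
#' Two-sided one-sample t test of per-replicate log2 SILAC ratios against 0
#' (equivalently, of linear ratios against 1, read on the log scale where
#' ratio distributions are symmetric). With a single replicate only the mean
#' is reported; with zero replicate variance the p value is floored at the
#' smallest positive double with a warning instead of failing.
#'
#' @param ratios Numeric vector of log2 ratios for one protein (>= 1 value).
#' @return A list of class `silac_result`: `n`, `mean_log2`, `mean_ratio`
#'   (linear scale), `t`, `df`, `p_value`.
#' @export
silac_test <- function(ratios) {
  ratios <- ratios[!is.na(ratios)]
  n <- length(ratios)
  if (n == 0) stop("no ratios supplied")
  m <- mean(ratios)
  if (n == 1)
    return(structure(list(n = 1L, mean_log2 = m, mean_ratio = 2^m,
                          t = NA_real_, df = NA_real_, p_value = NA_real_),
                     class = "silac_result"))
  if (sd(ratios) == 0) {
    warning("zero variance across replicate ratios; p value floored")
    return(structure(list(n = n, mean_log2 = m, mean_ratio = 2^m,
                          t = sign(m) * Inf, df = n - 1L,
                          p_value = if (m == 0) 1 else .Machine$double.xmin),
                     class = "silac_result"))
  }
  ht <- t.test(ratios, mu = 0)
  structure(list(n = n, mean_log2 = m, mean_ratio = 2^m,
                 t = unname(ht$statistic), df = unname(ht$parameter),
                 p_value = ht$p.value),
            class = "silac_result")
}

#' @export
print.silac_result <- function(x, ...) {
  cat(sprintf("SILAC ratio %.3g (log2 %.3g), t = %.3g, p = %.3g (n = %d)\n",
              x$mean_ratio, x$mean_log2, x$t, x$p_value, x$n))
  invisible(x)
}

#' Test every protein of a SILAC ratio matrix
#'
#' @param silac Protein x replicate matrix of log2 ratios (`NA` allowed).
#' @return Data frame: `protein`, `n`, `mean_log2`, `mean_ratio`, `t`,
#'   `p_value`.
#' @export
silac_test_all <- function(silac) {
  rows <- lapply(rownames(silac), function(p) {
    r <- suppressWarnings(silac_test(silac[p, ]))
    data.frame(protein = p, n = r$n, mean_log2 = r$mean_log2,
               mean_ratio = r$mean_ratio, t = r$t, p_value = r$p_value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Normalize a gradient sedimentation profile to a relative distribution
#'
#' Divides each protein's band intensity by its total across fractions, so
#' every profile sums to 1 and co-sedimentation of proteins quantified on
#' different absolute scales can be compared.
#'
#' @param profile Numeric vector (one protein) or matrix (proteins in rows)
#'   of non-negative band intensities per gradient fraction.
#' @return Same shape as `profile`, rows summing to 1.
#' @export
normalize_gradient <- function(profile) {
  if (is.matrix(profile)) {
    if (any(profile < 0)) stop("intensities must be >= 0")
    tot <- rowSums(profile)
    if (any(tot <= 0)) stop("total intensity must be > 0 for every protein")
    return(profile / tot)
  }
  if (any(profile < 0)) stop("intensities must be >= 0")
  tot <- sum(profile)
  if (tot <= 0) stop("total intensity must be > 0")
  profile / tot
}
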