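#' Actinomycin-D chase count matrix
#'
#' Container for a gene-level count matrix from a transcription shut-off
#' (actinomycin D) time course, together with its sample sheet and the set of
#' ERCC spike-in feature IDs used for normalization.
#'
#' @param counts Integer matrix, genes in rows (rownames = gene IDs), samples
#'   in columns (colnames = sample IDs). Counts must be non-negative.
#' @param samples Data frame with one row per column of `counts` and columns
#'   `sample`, `condition`, `replicate`, `time_h`. Each condition must cover
#'   at least 3 distinct time points for half-life fitting to be possible.
#' @param spikeins Character vector of spike-in feature IDs; must be a subset
#'   of `rownames(counts)`.
#' @return An object of class `chase_matrix`.
#' @export
chase_matrix <- function(counts, samples, spikeins) {
  if (!is.matrix(counts) || is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("`counts` must be a matrix with gene rownames and sample colnames")
  if (any(counts < 0)) stop("counts must be non-negative")
  req <- c("sample", "condition", "replicate", "time_h")
  if (!all(req %in% names(samples)))
    stop("sample sheet needs columns: ", paste(req, collapse = ", "))
  samples <- as.data.frame(samples)
  if (!setequal(samples$sample, colnames(counts)) ||
      nrow(samples) != ncol(counts))
    stop("sample sheet rows must match count matrix columns one-to-one")
  samples <- samples[match(colnames(counts), samples$sample), , drop = FALSE]
  rownames(samples) <- NULL
  if (!all(spikeins %in% rownames(counts)))
    stop("spike-in IDs absent from count matrix: ",
         paste(utils::head(setdiff(spikeins, rownames(counts)), 3), collapse = ", "))
  ntp <- tapply(samples$time_h, samples$condition, function(t) length(unique(t)))
  if (any(ntp < 3))
    stop("each condition needs >= 3 distinct timepoints; violated by: ",
         paste(names(ntp)[ntp < 3], collapse = ", "))
  structure(list(counts = counts, samples = samples,
                 spikeins = as.character(spikeins)),
            class = "chase_matrix")
}

#' @export
print.chase_matrix <- function(x, ...) {
  cat("Actinomycin-D chase count matrix\n")
  cat(sprintf("  %d features (%d spike-ins), %d samples\n",
              nrow(x$counts), length(x$spikeins), ncol(x$counts)))
  for (cond in unique(x$samples$condition)) {
    s <- x$samples[x$samples$condition == cond, ]
    cat(sprintf("  condition %-12s t = %s h, n = %d replicates\n", cond,
                paste(sort(unique(s$time_h)), collapse = "/"),
                length(unique(s$replicate))))
  }
  invisible(x)
}

#' Genes (non-spike-in features) of a chase matrix
#' @param x A `chase_matrix`.
#' @return Character vector of gene IDs excluding spike-ins.
#' @export
chase_genes <- function(x) {
  setdiff(rownames(x$counts), x$spikeins)
}
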