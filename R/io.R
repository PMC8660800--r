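# Readers and writers for the plain-text formats the pipeline consumes and
# emits: featureCounts-style count matrices, sample sheets, spike-in ID
# lists, GMT gene sets, lane-profile and marker CSVs, MaxQuant-style
# proteinGroups tables, and result CSV/JSON.

#' Read a featureCounts-style count matrix
#'
#' Accepts either the 7-column featureCounts dialect (Geneid, Chr, Start,
#' End, Strand, Length, then one column per sample) or a bare matrix with
#' gene IDs in the first column. Comment lines starting with `#` are
#' skipped.
#'
#' @param path Tab-separated counts file.
#' @return Integer matrix, genes x samples.
#' @export
read_counts <- function(path) {
  df <- read.delim(path, comment.char = "#", check.names = FALSE,
                   stringsAsFactors = FALSE)
  fc_cols <- c("Chr", "Start", "End", "Strand", "Length")
  if (all(fc_cols %in% names(df)))
    df <- df[, !(names(df) %in% fc_cols), drop = FALSE]
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- df[[1]]
  m
}

#' Read a chase sample sheet
#'
#' @param path CSV with columns `sample`, `condition`, `replicate`,
#'   `time_h`.
#' @return Data frame.
#' @export
read_sample_sheet <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  req <- c("sample", "condition", "replicate", "time_h")
  if (!all(req %in% names(df)))
    stop("sample sheet needs columns: ", paste(req, collapse = ", "))
  df
}

#' Read a spike-in ID list (one ID per line)
#' @param path Text file of feature IDs (typically `ERCC-` prefixed).
#' @return Character vector.
#' @export
read_spikein_ids <- function(path) {
  ids <- readLines(path)
  ids[nzchar(trimws(ids))]
}

#' Read a chase experiment from its three files
#'
#' @param counts_path,samples_path,spikeins_path Paths to the count matrix,
#'   sample sheet and spike-in list.
#' @return A [chase_matrix()].
#' @export
read_chase_experiment <- function(counts_path, samples_path, spikeins_path) {
  chase_matrix(read_counts(counts_path), read_sample_sheet(samples_path),
               read_spikein_ids(spikeins_path))
}

#' Write a chase experiment to disk
#'
#' Writes the count matrix as tab-separated text (first column `Geneid`),
#' the sample sheet as CSV and the spike-in list as plain text.
#'
#' @param x A [chase_matrix()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_chase_experiment <- function(x, dir) {
  stopifnot(inherits(x, "chase_matrix"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("counts.tsv", "samples.csv", "spikeins.txt"))
  df <- data.frame(Geneid = rownames(x$counts), x$counts,
                   check.names = FALSE)
  write.table(df, paths[1], sep = "\t", quote = FALSE, row.names = FALSE)
  write.csv(x$samples, paths[2], row.names = FALSE, quote = FALSE)
  writeLines(x$spikeins, paths[3])
  invisible(paths)
}

#' Read gene sets in GMT format
#'
#' @param path GMT file: one set per line, tab-separated
#'   `name <tab> description <tab> gene1 <tab> gene2 ...`.
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  sets <- lapply(lines, function(l) {
    parts <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3) stop("malformed GMT line: ", substr(l, 1, 40))
    unique(parts[-(1:2)])
  })
  names(sets) <- vapply(lines, function(l)
    strsplit(l, "\t", fixed = TRUE)[[1]][1], "")
  sets
}

#' Write gene sets in GMT format
#' @param genesets Named list of gene-ID vectors.
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_gmt <- function(genesets, path) {
  lines <- vapply(names(genesets), function(nm)
    paste(c(nm, nm, genesets[[nm]]), collapse = "\t"), "")
  writeLines(lines, path)
  invisible(path)
}

#' Write a half-life table as CSV
#' @param ht A `halflife_table` or `halflife_run`.
#' @param path Output CSV.
#' @return Invisibly, `path`.
#' @export
write_halflife_table <- function(ht, path) {
  write.csv(as_halflife_df(ht), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a pipeline run summary as JSON
#' @param run A `halflife_run`.
#' @param path Output JSON file.
#' @return Invisibly, `path`.
#' @export
write_run_summary <- function(run, path) {
  stopifnot(inherits(run, "halflife_run"))
  s <- run$summary
  jsonlite::write_json(
    list(n_genes = s$n_genes, n_retained = s$n_retained,
         exclusions = as.list(s$exclusions),
         median_halflife_h = as.list(s$median_halflife_h)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read gel lane profiles from a long-format CSV
#'
#' @param path CSV with columns `lane`, `position`, `intensity` and
#'   optionally `time_min`.
#' @return List of lane data frames (`position`, `intensity`) with
#'   `time_min` attributes when available.
#' @export
read_lane_profiles <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  req <- c("lane", "position", "intensity")
  if (!all(req %in% names(df)))
    stop("lane profile CSV needs columns: ", paste(req, collapse = ", "))
  lapply(split(df, df$lane), function(d) {
    d <- d[order(d$position), ]
    lane <- data.frame(position = d$position, intensity = d$intensity)
    if ("time_min" %in% names(d)) attr(lane, "time_min") <- d$time_min[1]
    lane
  })
}

#' Write gel lane profiles to a long-format CSV
#' @param lanes List of lane data frames (see [simulate_lane_profiles()]).
#' @param path Output CSV.
#' @return Invisibly, `path`.
#' @export
write_lane_profiles <- function(lanes, path) {
  df <- do.call(rbind, lapply(seq_along(lanes), function(i)
    data.frame(lane = i, time_min = attr(lanes[[i]], "time_min"),
               position = lanes[[i]]$position,
               intensity = lanes[[i]]$intensity)))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a gel marker table
#' @param path CSV with columns `position`, `tail_nt`.
#' @return Data frame suitable for [calibrate()].
#' @export
read_marker_table <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("position", "tail_nt") %in% names(df)))
    stop("marker table CSV needs columns `position` and `tail_nt`")
  df
}

#' Read a MaxQuant proteinGroups-style table
#'
#' Parses the tab-separated proteinGroups dialect: a protein ID column,
#' `LFQ intensity <sample>` columns (zero means not identified), and the
#' `Reverse` / `Potential contaminant` / `Only identified by site` marker
#' columns (`+` = flagged).
#'
#' @param path Tab-separated proteinGroups file.
#' @param bait_pattern Regular expression identifying bait sample names;
#'   all other samples are labelled control.
#' @return A `proteomics_table` (no SILAC component).
#' @export
read_protein_groups <- function(path, bait_pattern = "bait") {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  id_col <- intersect(c("Majority protein IDs", "Protein IDs", "protein"),
                      names(df))[1]
  if (is.na(id_col)) stop("no protein ID column found")
  lfq_cols <- grep("^LFQ intensity ", names(df), value = TRUE)
  if (length(lfq_cols) == 0) stop("no `LFQ intensity` columns found")
  sample_names <- sub("^LFQ intensity ", "", lfq_cols)
  intens <- as.matrix(df[, lfq_cols, drop = FALSE])
  intens[intens == 0] <- NA_real_
  intens <- log2(intens)
  dimnames(intens) <- list(df[[id_col]], sample_names)
  marker <- function(col) if (col %in% names(df))
    !is.na(df[[col]]) & df[[col]] == "+" else rep(FALSE, nrow(df))
  flags <- data.frame(protein = df[[id_col]],
                      contaminant = marker("Potential contaminant"),
                      reverse = marker("Reverse"),
                      site_only = marker("Only identified by site"),
                      stringsAsFactors = FALSE)
  samples <- data.frame(
    sample = sample_names,
    label = ifelse(grepl(bait_pattern, sample_names), "bait", "control"),
    replicate = seq_along(sample_names),
    stringsAsFactors = FALSE)
  structure(list(intensities = intens, samples = samples, flags = flags,
                 silac = NULL, truth = NULL),
            class = "proteomics_table")
}
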