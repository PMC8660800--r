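# Synthetic-data generators. Every downstream module is exercised against
# data from here, with ground truth returned alongside, so the whole pipeline
# is testable without the original sequencing/MS/gel raw data.

#' Configuration for a simulated actinomycin-D chase experiment
#'
#' Defines the study design and noise model for [simulate_chase()]. Defaults
#' emulate a HeLa transcription shut-off experiment read out by RNA-seq:
#' four time points (0/2/4/6 h), two biological replicates, a log-normal
#' half-life distribution with median 4.9 h, ERCC-style spike-ins at a fixed
#' fraction of the t = 0 library, and negative-binomial counting noise.
#'
#' @param n_genes Number of (non-spike-in) genes.
#' @param timepoints_h Chase time points in hours; strictly increasing and
#'   including 0. The alternative three-point design `c(0, 3, 6)` is also
#'   supported.
#' @param n_replicates Biological replicates per condition.
#' @param conditions Named numeric vector of global decay multipliers, one
#'   per condition (all > 0). A multiplier m scales every gene's decay rate
#'   k in that condition, so a knockout that accelerates global turnover from
#'   a median half-life of 4.9 h to 4.0 h has m = 4.9/4.0.
#' @param halflife_meanlog,halflife_sdlog Parameters of the log-normal
#'   distribution of true baseline half-lives (hours); the default meanlog
#'   `log(4.9)` puts the median at 4.9 h.
#' @param library_depth Expected total reads per sample at t = 0.
#' @param nb_dispersion Negative-binomial size parameter shared by all
#'   features (`Inf` gives the Poisson limit).
#' @param spikein_fraction Fraction of the t = 0 library arising from
#'   spike-ins; in (0, 1).
#' @param n_spikeins Number of spike-in species (the ERCC mix has 92).
#' @param genesets Optional named list defining destabilization-prone gene
#'   sets (e.g. an IEG-like labile subset). Each element is a list with
#'   `size` (number of member genes) and optionally `multipliers`, a named
#'   numeric vector of extra per-condition decay multipliers. Membership is
#'   assigned as consecutive gene-index blocks (recorded in the truth table)
#'   so subgroup analyses are reproducible.
#' @param stability_effects Optional list of extra effects conditional on a
#'   gene's baseline stability; each element is a list with `condition`,
#'   `min_halflife_h` and `multiplier`: genes whose true baseline half-life
#'   exceeds the threshold get the extra decay multiplier in that condition.
#'   This encodes effects confined to long-lived mRNAs, such as a rescue
#'   construct that restores stability of short-lived but not long-lived
#'   transcripts.
#' @param seed Integer seed; identical configs and seeds give byte-identical
#'   output.
#' @return A list of class `chase_sim_config`.
#' @export
chase_sim_config <- function(n_genes = 2000,
                             timepoints_h = c(0, 2, 4, 6),
                             n_replicates = 2,
                             conditions = c(parental = 1.0, KO = 4.9 / 4.0),
                             halflife_meanlog = log(4.9),
                             halflife_sdlog = 0.5,
                             library_depth = 5e6,
                             nb_dispersion = 50,
                             spikein_fraction = 0.05,
                             n_spikeins = 92,
                             genesets = NULL,
                             stability_effects = NULL,
                             seed = 1L) {
  if (is.unsorted(timepoints_h, strictly = TRUE))
    stop("timepoints_h must be strictly increasing")
  if (timepoints_h[1] != 0) stop("timepoints_h must include 0")
  if (is.null(names(conditions)) || any(conditions <= 0))
    stop("conditions must be a named vector of positive decay multipliers")
  if (spikein_fraction <= 0 || spikein_fraction >= 1)
    stop("spikein_fraction must be in (0, 1)")
  if (n_genes < 1 || n_replicates < 1 || n_spikeins < 1)
    stop("n_genes, n_replicates and n_spikeins must all be >= 1")
  if (spikein_fraction * library_depth < n_spikeins)
    stop("library_depth too small to allot >= 1 expected read per spike-in")
  if (!is.null(genesets) && sum(vapply(genesets, `[[`, 0, "size")) > n_genes)
    stop("gene sets exceed n_genes")
  structure(list(n_genes = as.integer(n_genes), timepoints_h = timepoints_h,
                 n_replicates = as.integer(n_replicates),
                 conditions = conditions,
                 halflife_meanlog = halflife_meanlog,
                 halflife_sdlog = halflife_sdlog,
                 library_depth = library_depth,
                 nb_dispersion = nb_dispersion,
                 spikein_fraction = spikein_fraction,
                 n_spikeins = as.integer(n_spikeins),
                 genesets = genesets,
                 stability_effects = stability_effects,
                 seed = as.integer(seed)),
            class = "chase_sim_config")
}

# draw counts around expectations; size = Inf is the Poisson limit
rcounts <- function(mu, size) {
  if (is.infinite(size)) rpois(length(mu), lambda = mu)
  else rnbinom(length(mu), mu = mu, size = size)
}

#' Simulate an actinomycin-D chase RNA-seq experiment
#'
#' Draws per-gene true half-lives from the configured log-normal, applies the
#' condition-specific global decay multiplier (plus any gene-set or
#' stability-conditional extra multipliers), and samples gene-level counts.
#' Gene g in condition c has expected normalized abundance
#' `a0_g * exp(-k_g * m_c * t)`; spike-ins have time-constant expected
#' abundance. Expected counts are scaled so spike-ins take `spikein_fraction`
#' of the library at t = 0; because mRNA decays while the spike-in mass is
#' fixed, total expected reads decline over the chase, exactly the situation
#' spike-in normalization is designed for.
#'
#' @param config A [chase_sim_config()].
#' @return A list with `matrix` (a [chase_matrix()]) and `truth`, a data
#'   frame with one row per gene x condition: `gene`, `condition`,
#'   `halflife_h`, `k_per_h` (= ln 2 / t1/2 after all multipliers), `a0`
#'   (relative abundance at t = 0), and `geneset` membership.
#' @export
simulate_chase <- function(config) {
  stopifnot(inherits(config, "chase_sim_config"))
  set.seed(config$seed)
  ng <- config$n_genes
  genes <- sprintf("gene_%05d", seq_len(ng))
  spikes <- sprintf("ERCC-%05d", seq_len(config$n_spikeins))

  t_half0 <- rlnorm(ng, config$halflife_meanlog, config$halflife_sdlog)
  k0 <- log(2) / t_half0
  a0 <- rlnorm(ng, meanlog = 0, sdlog = 1)          # relative abundance scale
  spike_ab <- rlnorm(config$n_spikeins, meanlog = 0, sdlog = 1)

  geneset <- rep(NA_character_, ng)                  # consecutive index blocks
  offset <- 0L
  for (nm in names(config$genesets)) {
    sz <- config$genesets[[nm]]$size
    geneset[(offset + 1L):(offset + sz)] <- nm
    offset <- offset + sz
  }

  conds <- names(config$conditions)
  # effective decay rate per gene x condition
  k_eff <- outer(k0, config$conditions)
  colnames(k_eff) <- conds
  for (nm in names(config$genesets)) {
    mult <- config$genesets[[nm]]$multipliers
    if (is.null(mult)) next
    memb <- which(geneset == nm)
    for (cn in names(mult)) k_eff[memb, cn] <- k_eff[memb, cn] * mult[[cn]]
  }
  for (eff in config$stability_effects) {
    memb <- which(t_half0 > eff$min_halflife_h)
    k_eff[memb, eff$condition] <- k_eff[memb, eff$condition] * eff$multiplier
  }

  f <- config$spikein_fraction
  gene_scale <- (1 - f) * config$library_depth / sum(a0)
  spike_scale <- f * config$library_depth / sum(spike_ab)
  mu_spike <- spike_scale * spike_ab

  sheet <- expand.grid(time_h = config$timepoints_h,
                       replicate = seq_len(config$n_replicates),
                       condition = conds,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  sheet$sample <- sprintf("%s_r%d_t%g", sheet$condition, sheet$replicate,
                          sheet$time_h)
  sheet <- sheet[, c("sample", "condition", "replicate", "time_h")]

  counts <- matrix(0L, nrow = ng + config$n_spikeins, ncol = nrow(sheet),
                   dimnames = list(c(genes, spikes), sheet$sample))
  for (j in seq_len(nrow(sheet))) {
    mu_gene <- gene_scale * a0 * exp(-k_eff[, sheet$condition[j]] * sheet$time_h[j])
    counts[, j] <- as.integer(rcounts(c(mu_gene, mu_spike), config$nb_dispersion))
  }

  truth <- data.frame(
    gene = rep(genes, times = length(conds)),
    condition = rep(conds, each = ng),
    k_per_h = as.vector(k_eff),
    a0 = rep(a0, times = length(conds)),
    geneset = rep(geneset, times = length(conds)),
    stringsAsFactors = FALSE)
  truth$halflife_h <- log(2) / truth$k_per_h

  list(matrix = chase_matrix(counts, sheet, spikes), truth = truth)
}

#' Simulate gel lane densitometry profiles for a deadenylation assay
#'
#' Emulates line scans of a denaturing polyacrylamide gel resolving the
#' products of an in vitro deadenylation reaction on a short RNA body
#' carrying a poly(A) tail. The most abundant intermediate walks down the
#' poly(A) ladder at `rate_As_per_min`; each lane is a Gaussian band centred
#' at the migration position of the current modal species plus additive
#' noise. Migration position is linear in total fragment length (shorter
#' fragments migrate further), a local approximation the downstream
#' calibration never assumes.
#'
#' @param rate_As_per_min True deadenylation rate, adenosines removed per
#'   minute (>= 0).
#' @param timepoints_min Reaction time points in minutes.
#' @param tail0 Initial poly(A) tail length in adenosines.
#' @param band_sigma Gaussian band width in position units.
#' @param noise_sd Additive intensity noise (peak height is 1).
#' @param marker_tails Tail lengths (As) of the RNA size-marker bands.
#' @param body_nt Length of the RNA body in nucleotides (7-mer by default).
#' @param seed Integer seed.
#' @return A list with `lanes` (list of `data.frame(position, intensity)`,
#'   each with a `time_min` attribute), `markers`
#'   (`data.frame(position, tail_nt)` of total fragment length per marker
#'   band), and `truth` (`data.frame(time_min, tail_As)`).
#' @export
simulate_lane_profiles <- function(rate_As_per_min, timepoints_min,
                                   tail0 = 20L, band_sigma = 1.5,
                                   noise_sd = 0.02,
                                   marker_tails = c(0, 5, 10, 15, 20),
                                   body_nt = 7L, seed = 1L) {
  if (rate_As_per_min < 0) stop("rate must be >= 0")
  if (tail0 < 0) stop("tail0 must be >= 0")
  if (band_sigma <= 0) stop("band_sigma must be > 0")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  set.seed(seed)
  pos_of_len <- function(len_nt) 100 - 3 * len_nt   # monotone: shorter runs further
  grid <- seq(0, 100, by = 0.25)

  true_tail <- pmax(0, round(tail0 - rate_As_per_min * timepoints_min))
  lanes <- lapply(seq_along(timepoints_min), function(i) {
    centre <- pos_of_len(body_nt + true_tail[i])
    intensity <- exp(-(grid - centre)^2 / (2 * band_sigma^2)) +
      rnorm(length(grid), sd = noise_sd)
    lane <- data.frame(position = grid, intensity = intensity)
    attr(lane, "time_min") <- timepoints_min[i]
    lane
  })
  markers <- data.frame(position = pos_of_len(body_nt + marker_tails),
                        tail_nt = body_nt + marker_tails)
  markers <- markers[order(markers$position), ]
  rownames(markers) <- NULL
  list(lanes = lanes, markers = markers,
       truth = data.frame(time_min = timepoints_min, tail_As = true_tail))
}

#' Simulate a qPCR-style targeted decay time series
#'
#' First-order decay of a target feature measured against a stable reference
#' (18S-like), with multiplicative log-normal measurement noise of the given
#' coefficient of variation on both channels.
#'
#' @param t_half_h True half-life in hours.
#' @param timepoints_h Chase time points in hours.
#' @param noise_cv Coefficient of variation of the measurement noise.
#' @param feature,reference Feature names for the output table.
#' @param seed Integer seed.
#' @return A data frame with columns `feature`, `reference`, `time_h`,
#'   `target`, `reference_signal`.
#' @export
simulate_qpcr_series <- function(t_half_h, timepoints_h = c(0, 1, 2, 3),
                                 noise_cv = 0.02, feature = "target",
                                 reference = "18S", seed = 1L) {
  if (t_half_h <= 0) stop("t_half_h must be > 0")
  if (noise_cv < 0) stop("noise_cv must be >= 0")
  set.seed(seed)
  k <- log(2) / t_half_h
  n <- length(timepoints_h)
  sdlog <- sqrt(log(1 + noise_cv^2))
  data.frame(feature = feature, reference = reference,
             time_h = timepoints_h,
             target = exp(-k * timepoints_h) * rlnorm(n, -sdlog^2 / 2, sdlog),
             reference_signal = rlnorm(n, -sdlog^2 / 2, sdlog),
             stringsAsFactors = FALSE)
}

#' Simulate an AP-MS bait-versus-control proteomics experiment
#'
#' Generates a label-free quantification (LFQ) table in which planted complex
#' members are detected only in bait pull-downs (the basis of
#' exclusive-identification calling), background proteins appear in both bait
#' and control runs, intensities are missing at random, and, optionally,
#' per-replicate SILAC log2 ratios encode treatment-regulated association.
#' A few contaminant/decoy-flagged rows are always included to exercise the
#' upstream exclusion rules.
#'
#' @param n_background Number of background proteins present in bait and
#'   control runs.
#' @param complex_members Character vector of planted bait-complex proteins
#'   (bait-exclusive).
#' @param bait_enrichment_log2 Mean log2-intensity increment of complex
#'   members over background.
#' @param silac_regulated Named numeric vector: true mean log2 SILAC ratio of
#'   regulated proteins (unnamed proteins are centred at 0).
#' @param silac_sd Replicate-to-replicate SD of log2 SILAC ratios.
#' @param missing_rate Probability a measured intensity is missing, per
#'   protein x sample.
#' @param n_replicates Biological replicates per group.
#' @param n_flagged Contaminant/decoy/site-only rows to plant.
#' @param seed Integer seed.
#' @return A list of class `proteomics_table` with `intensities` (protein x
#'   sample matrix of log2 LFQ values, `NA` = not identified), `samples`
#'   (sample sheet with `label` bait/control), `flags` (logical columns
#'   `contaminant`, `reverse`, `site_only`), `silac` (protein x replicate
#'   matrix of log2 ratios, complex members only), and `truth` (planted
#'   membership and regulation).
#' @export
simulate_apms <- function(n_background = 300,
                          complex_members = c("CNOT1", "CNOT2", "CNOT3",
                                              "CNOT9", "RNF219"),
                          bait_enrichment_log2 = 4,
                          silac_regulated = c(RNF219 = -1.0),
                          silac_sd = 0.2,
                          missing_rate = 0.1,
                          n_replicates = 4,
                          n_flagged = 6,
                          seed = 1L) {
  if (missing_rate < 0 || missing_rate >= 1) stop("missing_rate must be in [0, 1)")
  if (n_replicates < 2) stop("n_replicates must be >= 2")
  set.seed(seed)
  bg <- sprintf("BG_%04d", seq_len(n_background))
  flagged <- sprintf("FLAG_%02d", seq_len(n_flagged))
  proteins <- c(complex_members, bg, flagged)
  np <- length(proteins)

  samples <- data.frame(
    sample = c(sprintf("bait_r%d", seq_len(n_replicates)),
               sprintf("control_r%d", seq_len(n_replicates))),
    label = rep(c("bait", "control"), each = n_replicates),
    replicate = rep(seq_len(n_replicates), 2),
    stringsAsFactors = FALSE)

  base <- rnorm(np, mean = 25, sd = 2)
  base[seq_along(complex_members)] <- base[seq_along(complex_members)] +
    bait_enrichment_log2
  intens <- matrix(rnorm(np * nrow(samples), sd = 0.3), nrow = np,
                   dimnames = list(proteins, samples$sample)) + base
  # complex members never identified in control pull-downs
  intens[seq_along(complex_members), samples$label == "control"] <- NA_real_
  if (missing_rate > 0) {
    drop <- matrix(stats::runif(np * nrow(samples)) < missing_rate, nrow = np)
    intens[drop] <- NA_real_
  }

  flags <- data.frame(
    protein = proteins,
    contaminant = c(rep(FALSE, np - n_flagged),
                    rep(c(TRUE, FALSE, FALSE), length.out = n_flagged)),
    reverse = c(rep(FALSE, np - n_flagged),
                rep(c(FALSE, TRUE, FALSE), length.out = n_flagged)),
    site_only = c(rep(FALSE, np - n_flagged),
                  rep(c(FALSE, FALSE, TRUE), length.out = n_flagged)),
    stringsAsFactors = FALSE)

  silac_mu <- setNames(rep(0, length(complex_members)), complex_members)
  silac_mu[names(silac_regulated)] <- silac_regulated
  silac <- matrix(rnorm(length(complex_members) * n_replicates,
                        mean = silac_mu, sd = silac_sd),
                  nrow = length(complex_members),
                  dimnames = list(complex_members,
                                  sprintf("ratio_r%d", seq_len(n_replicates))))

  truth <- data.frame(protein = proteins,
                      complex_member = proteins %in% complex_members,
                      silac_log2 = unname(silac_mu[match(proteins, names(silac_mu))]),
                      stringsAsFactors = FALSE)

  structure(list(intensities = intens, samples = samples, flags = flags,
                 silac = silac, truth = truth),
            class = "proteomics_table")
}
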