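#!/usr/bin/env Rscript
# Comparative decay statistics on the half-life table: paired Wilcoxon
# signed-rank tests between cell lines, half-life binning on the parental
# estimates, and the IEG subgroup.

suppressPackageStartupMessages(library(decaykit))

tab <- read.csv("results/halflife_table.csv")
sets <- read_gmt("results/data/genesets.gmt")
conds <- c("KO", "WT", "RINGmut")

cat("== global paired comparisons vs parental ==\n")
global <- do.call(rbind, lapply(conds, function(cb) {
  cmp <- compare_paired(tab, "parental", cb)
  print(cmp)
  data.frame(comparison = paste0("parental_vs_", cb), n = cmp$n,
             median_parental = cmp$median_a, median_other = cmp$median_b,
             p_value = cmp$p_value, direction = cmp$direction)
}))
write.csv(global, "results/comparisons_global.csv", row.names = FALSE)

cat("\n== per-bin median ratios (bins on parental t1/2, h) ==\n")
binned <- do.call(rbind, lapply(conds, function(cb) {
  b <- bin_halflives(tab, "parental", cb)$results
  b$comparison <- paste0("parental_vs_", cb)
  b
}))
print(binned[, c("comparison", "bin", "n", "median_ratio", "p_value")],
      row.names = FALSE, digits = 3)
write.csv(binned, "results/comparisons_binned.csv", row.names = FALSE)

cat("\n== IEG subgroup ==\n")
sub <- do.call(rbind, lapply(conds, function(cb) {
  s <- subgroup_analysis(tab, sets, "parental", cb)
  s$comparison <- paste0("parental_vs_", cb)
  s
}))
print(sub[, c("comparison", "set", "n_quantified", "median_ratio", "p_value")],
      row.names = FALSE, digits = 3)
write.csv(sub, "results/comparisons_subgroups.csv", row.names = FALSE)

ko_bins <- binned[binned$comparison == "parental_vs_KO", ]
rm_bins <- binned[binned$comparison == "parental_vs_RINGmut", ]
cat(sprintf("\nKO destabilizes every bin (max ratio %.2f); RINGmut rescues
bins <= 6 h (ratios %s) but not > 9 h (ratios %s).\n",
            max(ko_bins$median_ratio),
            paste(sprintf("%.2f", rm_bins$median_ratio[1:2]), collapse = "/"),
            paste(sprintf("%.2f", rm_bins$median_ratio[4:5]), collapse = "/")))
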