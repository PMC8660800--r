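#!/usr/bin/env Rscript
# In vitro deadenylation kinetics: simulate gel line scans of a 7-mer-A20
# substrate deadenylated by a reconstituted CCR4-NOT complex, with and
# without an RNF219-like inhibitor, then quantify apparent rates (As/min)
# from the most abundant intermediate per time point and the fold
# inhibition.

suppressPackageStartupMessages(library(decaykit))

seed <- 219
dir.create("results", showWarnings = FALSE)

ctl <- simulate_lane_profiles(1.225, timepoints_min = seq(0, 14, 2),
                              seed = seed)
inh <- simulate_lane_profiles(0.35, timepoints_min = seq(0, 32, 4),
                              seed = seed + 1)
write_lane_profiles(ctl$lanes, "results/lanes_control.csv")
write_lane_profiles(inh$lanes, "results/lanes_inhibited.csv")

qc <- quantify_deadenylation(ctl$lanes, ctl$markers)
qi <- quantify_deadenylation(inh$lanes, inh$markers)
cat("control (CCR4-NOT alone):   "); print(qc$rate)
cat("inhibited (+ RNF219-like):  "); print(qi$rate)
fold <- fold_inhibition(qc$rate, qi$rate)
print(fold)

out <- rbind(
  data.frame(assay = "control", qc$series, check.names = FALSE),
  data.frame(assay = "inhibited", qi$series, check.names = FALSE))
write.csv(out, "results/deadenylation_tail_series.csv", row.names = FALSE)
write.csv(data.frame(assay = c("control", "inhibited"),
                     rate_As_per_min = c(qc$rate$rate_As_per_min,
                                         qi$rate$rate_As_per_min),
                     se = c(qc$rate$se, qi$rate$se),
                     r2 = c(qc$rate$r2, qi$rate$r2),
                     fold_inhibition = c(NA, fold$fold)),
          "results/deadenylation_rates.csv", row.names = FALSE)
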