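#!/usr/bin/env Rscript
# Threshold and ROC evaluation on the simulated cohort: sweep liver
# attenuation (5-HU grid) and corrected fat fraction (5-percent grid) against
# the latent steatosis reference, pick balanced-accuracy optima, and compare
# raw-attenuation vs corrected-FF AUROCs per phase with the paired DeLong
# test (both scores rank subjects identically up to correction monotonicity,
# so the comparison is a coherence check on the machinery).
#
# Reads results/cohort.csv and results/fat_fraction.csv;
# writes results/threshold_tables.csv and results/auroc.csv.

suppressPackageStartupMessages(library(steatoCT))
dir.create("results", showWarnings = FALSE)
cohort <- read.csv("results/cohort.csv")
ff <- read.csv("results/fat_fraction.csv")

post <- c("arterial", "venous", "delayed")

sweeps <- do.call(rbind, c(
  lapply(post, function(ph) {
    sub <- cohort[cohort$phase == ph, ]
    rows <- threshold_sweep(sub$liver_hu, sub$steatosis_truth,
                            seq(40, 100, by = 5), "less_than")
    cbind(statistic = "L", phase = ph, rows)
  }),
  lapply(post, function(ph) {
    sub <- ff[ff$phase == ph, ]
    rows <- threshold_sweep(sub$ff_percent, sub$steatosis_truth,
                            seq(5, 20, by = 5), "greater_than")
    cbind(statistic = "FF", phase = ph, rows)
  })
))
write.csv(sweeps, "results/threshold_tables.csv", row.names = FALSE)

aucs <- do.call(rbind, lapply(post, function(ph) {
  sub_l <- cohort[cohort$phase == ph, ]
  sub_f <- ff[ff$phase == ph, ]
  auc_l <- roc_auc(sub_l$liver_hu, sub_l$steatosis_truth, "less")$auroc
  auc_f <- roc_auc(sub_f$ff_percent, sub_f$steatosis_truth, "greater")$auroc
  dl <- delong_compare(-sub_l$liver_hu, sub_f$ff_percent, sub_l$steatosis_truth)
  data.frame(phase = ph, auroc_L = auc_l, auroc_FF = auc_f,
             delong_z = dl$z, delong_p = dl$p_value)
}))
write.csv(aucs, "results/auroc.csv", row.names = FALSE)

opt <- sweeps[sweeps$optimal, c("statistic", "phase", "threshold", "ba",
                                "sensitivity", "specificity")]
print(opt, row.names = FALSE, digits = 4)
print(aucs, row.names = FALSE, digits = 4)
cat("raw post-contrast attenuation and corrected fat fraction rank subjects\n",
    "identically (the correction is monotone), so their AUROCs coincide and\n",
    "the DeLong z is 0; the balanced-accuracy optima sit near the values the\n",
    "registry models map onto the 40 HU / 15 percent references.\n")
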