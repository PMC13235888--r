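#!/usr/bin/env Rscript
# Step 6 — notch-centered feature battery and group comparison.
#
# Extracts the 63 segment/derivative/statistic features per pulse from
# the simulated cohort, removes outliers by the 1.5 IQR rule, applies
# the Shapiro-Wilk-gated t/U test per feature, and runs the
# point-by-point comparison of aligned peak-to-offset pulses.

suppressPackageStartupMessages(library(abpwave))

dir.create("results", showWarnings = FALSE)
recs <- synth_cohort(preset_cohort("default", n_patients = 120,
                                   event_prevalence = 0.5,
                                   duration = 60, seed = 17))
feats <- cohort_feature_table(recs)
res <- compare_groups(feats)
write.csv(res, "results/feature_tests.csv", row.names = FALSE)

named <- c("P2N_d1_mean", "N2D_d1_min", "D2O_d1_min", "P2N_d2_area")
cat("Group comparison over", nrow(res), "testable features;",
    sum(res$significant), "significant at p < 0.05.\n\n")
cat("Key diastolic-runoff features:\n")
print(res[match(named, res$feature),
          c("feature", "test_used", "p_value", "direction")],
      digits = 3, row.names = FALSE)

ap <- aligned_pulses(recs, max_pulses = 30)
pw <- pointwise_compare(ap$pulses, ap$patient_id, ap$label)
write.csv(data.frame(position = seq_along(pw$p_values),
                     p_value = pw$p_values),
          "results/pointwise_p.csv", row.names = FALSE)
dn_mean <- mean(ap$notch_pos)
cat(sprintf("\nPoint-by-point: %d of 300 aligned positions significant;",
            length(pw$significant)))
cat(sprintf(" %.0f%% lie beyond the mean notch position (%.0f).\n",
            100 * mean(pw$significant >= dn_mean), dn_mean))
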