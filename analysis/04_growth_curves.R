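#!/usr/bin/env Rscript
# Population growth: windowed log-linear doubling times per well
# (OD 0.0625-0.125, R^2 >= 0.99) and the two-strain comparison.

suppressPackageStartupMessages({library(poleage); library(jsonlite)})
od <- read_od_series("results/data/od_plate.csv")

est <- estimate_plate(od)
utils::write.csv(est, "results/doubling_times.csv", row.names = FALSE)
cat(sprintf("%d of %d wells accepted (R^2 >= 0.99)\n",
            sum(est$accepted), nrow(est)))

cmp <- compare_strains(est, "csrA_like", "wt_like")
cat(sprintf("%s: %.1f +/- %.1f min (mean +/- SE, n = %d)\n",
            cmp$strains[1], cmp$mean[1], cmp$se[1], cmp$n[1]))
cat(sprintf("%s: %.1f +/- %.1f min (mean +/- SE, n = %d)\n",
            cmp$strains[2], cmp$mean[2], cmp$se[2], cmp$n[2]))
cat(sprintf("Difference %.2f min, 95%% CI [%.2f, %.2f], Welch p = %.2f\n",
            cmp$difference, cmp$conf_int[1], cmp$conf_int[2], cmp$p_value))

write_json(cmp, "results/strain_comparison.json", auto_unbox = TRUE,
           digits = NA, pretty = TRUE)
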