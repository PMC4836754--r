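#!/usr/bin/env Rscript
# Replicative-lifespan analysis: rebuild the pole-age lineage from the
# tracking table, classify fates with the stop-of-division criterion, and
# compute the stop curve, median stop ages, the hazard trend, the predictors
# of last divisions, birth-state correlations and post-arrest elongation.

suppressPackageStartupMessages({library(poleage); library(jsonlite)})
data_dir <- "results/data"
dir.create("results", showWarnings = FALSE)

tab <- read_tracking_table(file.path(data_dir, "tracking.csv"))
asg <- assign_pole_ages(build_lineage(tab), "discard_root_use_last_daughter")
fates <- assign_fates(asg$individuals, experiment_end = 2000, stop_criterion())

curve <- stop_curve(fates)
utils::write.csv(curve, "results/stop_curve.csv", row.names = FALSE)
cat("Stop curve over", nrow(curve), "pole ages;",
    sum(curve$n_events), "stops among",
    curve$n_at_risk[1], "classifiable individuals\n")
cat(sprintf("Median stop pole age: %d (discrete), %.2f (interpolated)\n",
            median_stop_age(curve), median_stop_age(curve, "interpolated")))

trend <- hazard_trend_test(fates)
cat(sprintf("Hazard trend: slope %.3f log-odds/age, p = %.3g\n",
            trend$slope, trend$p_value))

rec <- division_records(asg, fates)
pred <- last_division_predictors(rec)
print(pred)

br <- birth_records(asg, fates)
pot <- birth_state_vs_potential(br)
print(pot)

ivc <- tryCatch(interdivision_comparison(fates),
                poleage_insufficient_data = function(e) NULL)
if (!is.null(ivc)) {
  cat(sprintf("Mother vs last-daughter first intervals: %.1f vs %.1f min (p = %.2f, n = %d)\n",
              ivc$mean_focal, ivc$mean_daughter, ivc$p_value, ivc$n_pairs))
}

el <- elongation_after_stop(asg, fates)
cat(sprintf("Post-last-division elongation over 25 min: mean %.1f%% (sd %.1f%%, n = %d)\n",
            mean(el$percent_elongation, na.rm = TRUE),
            stats::sd(el$percent_elongation, na.rm = TRUE),
            sum(!is.na(el$percent_elongation))))

write_individuals(fates, "results/individuals.csv")
write_json(list(
  median_discrete = median_stop_age(curve),
  median_interpolated = median_stop_age(curve, "interpolated"),
  hazard_trend = trend[c("slope", "se", "p_value", "n_opportunities")],
  last_division_predictors = pred,
  birth_state_vs_potential = pot,
  interdivision_comparison = ivc,
  elongation_mean_percent = mean(el$percent_elongation, na.rm = TRUE)
), "results/lifespan_report.json", auto_unbox = TRUE, digits = NA, pretty = TRUE)
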