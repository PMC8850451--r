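#!/usr/bin/env Rscript
# Stage 3: functional classification of ROIs.
#
# z-scores the traces, regresses every ROI on the archetype and per-fish
# motor regressors (r2 thresholds 0.3 and 0.2, strict), merges the strong
# subtypes, flags over-contributing fish, and writes assignments, proportion
# tables, behavior correlations and the motor-association selection.

library(loomnet)

data_dir <- "results/data"
out <- "results/classification"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

for (tag in c("f20_wt", "f60_wt", "s20short_wt", "s20short_fmr1")) {
  co <- read_cohort(file.path(data_dir, tag))
  zs <- zscore_traces(co$traces)
  regs <- archetype_regressors(co$train, sampling_rate = co$sampling_rate)
  mr <- lapply(co$motor_events, motor_regressor, n_timepoints = ncol(zs),
               sampling_rate = co$sampling_rate)
  frames <- if (mean(co$train$isi_values) > 40) {
    loom_trim_frames(co$train, co$sampling_rate)
  } else NULL
  asg <- classify_rois(zs, regs, fish_id = co$rois$fish_id,
                       motor_regressors = mr, frames = frames)
  asg$region <- co$rois$region
  write.csv(asg[, c("roi_id", "fish_id", "label", "best_r2")],
            file.path(out, paste0(tag, "_assignments.csv")), row.names = FALSE)
  acc <- mean(asg$label == co$rois$true_archetype)
  outliers <- flag_outlier_fish(asg)
  message(sprintf("%s: archetype agreement %.1f%%; outlier fish: %s",
                  tag, 100 * acc,
                  if (length(outliers)) paste(outliers, collapse = ", ")
                  else "none"))

  tabs <- proportion_tables(asg)
  write.csv(tabs$cluster_by_region,
            file.path(out, paste0(tag, "_cluster_by_region.csv")))
  write.csv(tabs$cluster_within_region,
            file.path(out, paste0(tag, "_cluster_within_region.csv")))
}

message("neural-behavior correlation, f20")
co <- read_cohort(file.path(data_dir, "f20_wt"))
zs <- zscore_traces(co$traces)
regs <- archetype_regressors(co$train, sampling_rate = co$sampling_rate)
mr <- lapply(co$motor_events, motor_regressor, n_timepoints = ncol(zs),
             sampling_rate = co$sampling_rate)
asg <- classify_rois(zs, regs, fish_id = co$rois$fish_id,
                     motor_regressors = mr)
asg$region <- co$rois$region
norm <- normalized_loom_responses(zs, co$train, co$sampling_rate)
tracks <- read_behavior_tracks(file.path(data_dir, "behavior_f20.csv"))
prob <- response_probability(escape_matrix(tracks))
nb <- neural_behavior_correlation(norm[, seq_along(prob), drop = FALSE],
                                  asg, prob)
write.csv(nb, file.path(out, "f20_neural_behavior_correlation.csv"),
          row.names = FALSE)
top <- nb[order(-nb$mean_r), ]
top <- top[!is.na(top$mean_r), ]
message("strongest behavior correlate: ", top$cluster[1], " in ",
        top$region[1], sprintf(" (mean r = %.2f)", top$mean_r[1]))

message("motor-associated subset of the strong cluster")
strong_rows <- which(asg$label == "strong")
rho <- vapply(strong_rows, function(i) {
  suppressWarnings(stats::cor(zs[i, ], mr[[co$rois$fish_id[i]]],
                              method = "spearman"))
}, numeric(1))
ok <- is.finite(rho)
sel <- motor_association_selection(rho[ok], co$rois$region[strong_rows][ok])
write.csv(data.frame(region = names(sel$proportions),
                     proportion_selected = sel$proportions),
          file.path(out, "f20_motor_association.csv"), row.names = FALSE)
message(sprintf("Spearman threshold (mean + 1 SD) = %.4f; %.1f%% selected",
                sel$threshold, 100 * mean(sel$selected)))
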