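#!/usr/bin/env Rscript
# Stage 1: generate the synthetic cohorts every later stage analyzes.
#
# Produces, under results/data/:
#   - a wild-type f20 imaging cohort (6 larvae) and an f60 companion,
#   - a WT / fmr1 pair on the two-block s20 train sharing the WT's node frame,
#   - free-swimming behavior cohorts (36 larvae) for f20, f60 and the
#     genotype comparison on the short s20 train.

library(loomnet)

seed <- 7L
out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

message("imaging cohorts")
for (spec in list(list(paradigm = "f20", genotype = "WT", tag = "f20_wt"),
                  list(paradigm = "f60", genotype = "WT", tag = "f60_wt"),
                  list(paradigm = "s20-short", genotype = "WT", tag = "s20short_wt"),
                  list(paradigm = "s20-short", genotype = "fmr1", tag = "s20short_fmr1"))) {
  cc <- cohort_config(spec$paradigm, n_fish = 6, genotype = spec$genotype,
                      roi_counts = default_roi_counts(0.8))
  co <- simulate_cohort(cc, seed = loomnet:::mix_seed(seed, spec$tag))
  write_cohort(co, file.path(out, spec$tag))
  message(sprintf("  %s: %d ROIs, %d timepoints, %d looms",
                  spec$tag, nrow(co$rois), ncol(co$traces),
                  length(co$train$loom_onsets)))
}

message("behavior cohorts (36 larvae each)")
for (spec in list(list(paradigm = "f20", genotype = "WT", tag = "behavior_f20"),
                  list(paradigm = "f60", genotype = "WT", tag = "behavior_f60"),
                  list(paradigm = "s20-short", genotype = "WT", tag = "behavior_s20short_wt"),
                  list(paradigm = "s20-short", genotype = "het", tag = "behavior_s20short_het"),
                  list(paradigm = "s20-short", genotype = "fmr1", tag = "behavior_s20short_fmr1"))) {
  tr <- build_stimulus_train(spec$paradigm, seed = loomnet:::mix_seed(seed, spec$paradigm))
  tracks <- simulate_behavior_cohort(36, tr, genotype = spec$genotype,
                                     seed = loomnet:::mix_seed(seed, spec$tag))
  write_behavior_tracks(tracks, file.path(out, paste0(spec$tag, ".csv")))
  save_stimulus_train(tr, file.path(out, paste0(spec$tag, "_train.json")))
  message("  ", spec$tag, ": ", length(tracks), " tracks")
}

message("done; cohorts under ", out)
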