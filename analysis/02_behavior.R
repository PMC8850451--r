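#!/usr/bin/env Rscript
# Stage 2: free-swimming habituation.
#
# Escape detection (>30 mm/s inside the loom window), per-loom response
# probabilities, one-phase decay fits of the first block, and one-sided
# binomial tests of the mutant and heterozygote groups against the WT
# response proportions with the Bonferroni cutoff for 2 contrasts x 20 looms.

library(loomnet)

data_dir <- "results/data"
out <- "results/behavior"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

prob_tab <- list()
fit_tab <- list()
for (tag in c("behavior_f20", "behavior_f60")) {
  tracks <- read_behavior_tracks(file.path(data_dir, paste0(tag, ".csv")))
  prob <- response_probability(escape_matrix(tracks))
  fit <- fit_one_phase_decay(prob[1:10])
  paradigm <- sub("behavior_", "", tag)
  prob_tab[[tag]] <- data.frame(paradigm = paradigm,
                                loom = seq_along(prob), probability = prob)
  fit_tab[[tag]] <- data.frame(paradigm = paradigm, Y0 = fit$Y0, K = fit$K,
                               plateau = fit$plateau, sse = fit$sse,
                               converged = fit$converged)
  message(sprintf("%s: K = %.3f, plateau = %.3f, recovery (11th-10th) = %.3f",
                  paradigm, fit$K, fit$plateau, prob[11] - prob[10]))
}
write.csv(do.call(rbind, prob_tab), file.path(out, "response_probability.csv"),
          row.names = FALSE)
write.csv(do.call(rbind, fit_tab), file.path(out, "decay_fits.csv"),
          row.names = FALSE)

message("genotype contrast on the two-block s20 train")
esc <- lapply(c(WT = "behavior_s20short_wt", het = "behavior_s20short_het",
                fmr1 = "behavior_s20short_fmr1"), function(tag) {
  escape_matrix(read_behavior_tracks(file.path(data_dir, paste0(tag, ".csv"))))
})
tests <- do.call(rbind, lapply(c("fmr1", "het"), function(g) {
  d <- per_loom_binomial_tests(esc[[g]], esc$WT, alpha = 0.05, n_contrasts = 2)
  d$contrast <- paste0(g, "_vs_WT")
  d
}))
write.csv(tests, file.path(out, "binomial_tests.csv"), row.names = FALSE)
message(sprintf("significant looms at the %.5f cutoff: %d of %d",
                tests$cutoff[1], sum(tests$significant), nrow(tests)))
message("mutant responds more at early looms: fmr1 p-values, looms 2-4: ",
        paste(signif(tests$p_value[tests$contrast == "fmr1_vs_WT"][2:4], 3),
              collapse = ", "))
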