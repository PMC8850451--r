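test_that("z-scoring uses the population SD and flags constant rows", {
  m <- rbind(c(1, 2, 3), c(5, 5, 5), c(-1, 0, 1))
  zs <- zscore_traces(m)
  expect_equal(zs[1, ], c(-1, 0, 1) / sqrt(2 / 3), tolerance = 1e-12)
  expect_equal(zs[1, 1], -1.2247, tolerance = 1e-4)
  expect_equal(attr(zs, "zero_variance"), 2L)
  expect_equal(zs[2, ], c(0, 0, 0))
  # idempotence
  expect_equal(unname(zscore_traces(zs)[1, ]), unname(zs[1, ]),
               tolerance = 1e-12)
  expect_error(zscore_traces(m[, 1, drop = FALSE]), "2 timepoints")
})

test_that("r-squared equals the squared sample correlation", {
  set.seed(1)
  reg <- rnorm(100)
  expect_equal(regress_roi(2 * reg + 1, reg), 1, tolerance = 1e-12)
  y <- 0.4 * reg + rnorm(100)
  expect_equal(regress_roi(y, reg), cor(y, reg)^2, tolerance = 1e-12)
  expect_true(is.na(regress_roi(rep(1, 100), reg)))
  expect_true(is.na(regress_roi(y, rep(0, 100))))
  expect_error(regress_roi(y, reg[1:50]), "length mismatch")
  # vectorized path agrees with the scalar one
  tr <- rbind(y, 2 * reg, rnorm(100))
  r2v <- loomnet:::regress_rows(tr, reg)
  expect_equal(r2v, apply(tr, 1, regress_roi, regressor = reg),
               tolerance = 1e-12)
})

test_that("cityblock k-means separates planted groups with median centers", {
  set.seed(5)
  a <- matrix(rnorm(40 * 6, 0), 40, 6)
  b <- matrix(rnorm(40 * 6, 8), 40, 6)
  km <- kmeans_cityblock(rbind(a, b), k = 2, replicates = 3, seed = 1)
  expect_equal(length(unique(km$cluster[1:40])), 1)
  expect_equal(length(unique(km$cluster[41:80])), 1)
  expect_false(km$cluster[1] == km$cluster[41])

  km1 <- kmeans_cityblock(rbind(a, b), k = 1, replicates = 1, seed = 1)
  expect_equal(km1$centers[1, ], apply(rbind(a, b), 2, median),
               tolerance = 1e-12)

  km_a <- kmeans_cityblock(a, k = 3, replicates = 2, seed = 9)
  km_b <- kmeans_cityblock(a, k = 3, replicates = 2, seed = 9)
  expect_identical(km_a$cluster, km_b$cluster)
  expect_error(kmeans_cityblock(a, k = 100), "exceeds")
})

test_that("cluster selection applies the two representation tiers", {
  presence <- rbind(
    data.frame(dataset = c("f20", "f60", "s20", "s60"), cluster = "m",
               frac_fish = c(9 / 11, 7 / 8, 9 / 10, 9 / 10), responds = TRUE),
    data.frame(dataset = c("f20", "f60", "s20", "s60"), cluster = "single",
               frac_fish = c(1 / 11, 0, 0, 0), responds = TRUE),
    data.frame(dataset = c("f20", "s20"), cluster = "aud",
               frac_fish = c(0.95, 0.92), responds = TRUE),
    data.frame(dataset = c("f20", "f60", "s20", "s60"), cluster = "artifact",
               frac_fish = 1, responds = FALSE)
  )
  sel <- select_loom_clusters(presence)
  expect_equal(sel$tier[sel$cluster == "m"], "primary")
  expect_equal(sel$tier[sel$cluster == "aud"], "secondary")
  expect_false("single" %in% sel$cluster)
  expect_false("artifact" %in% sel$cluster)
  expect_warning(
    empty <- select_loom_clusters(presence[presence$cluster == "single", ]),
    "no cluster"
  )
  expect_equal(nrow(empty), 0)
})

test_that("classification thresholds are strict and ties break by precedence", {
  set.seed(2)
  reg_a <- rnorm(200)
  reg_b <- rnorm(200)
  regs <- list(strong1 = reg_a, moderate = reg_b)
  # trace equal to reg_b: r2 = 1 for moderate
  tr <- rbind(reg_b + rnorm(200, 0, 0.05), rnorm(200))
  asg <- classify_rois(tr, regs)
  expect_equal(asg$label, c("moderate", "none"))

  # exact tie: identical regressors under two names -> first in precedence
  regs_tie <- list(moderate = reg_a, strong1 = reg_a)
  asg_tie <- classify_rois(rbind(reg_a), regs_tie)
  expect_equal(asg_tie$label, "strong")   # strong precedes moderate

  # r2 exactly at the threshold is not selected (strict >)
  reg <- c(rep(1, 50), rep(0, 50))
  y <- c(rep(1, 25), rep(0, 75))          # r2 = 1/3 vs threshold 1/3
  r2 <- regress_roi(y, reg)
  asg_eq <- classify_rois(rbind(y), list(moderate = reg), r2_threshold = r2)
  expect_equal(asg_eq$label, "none")
})

test_that("motor classification needs events and strict r2 > 0.2", {
  co <- tiny_cohort()
  zs <- zscore_traces(co$traces)
  regs <- archetype_regressors(co$train)
  mr <- lapply(co$motor_events, motor_regressor, n_timepoints = ncol(zs))
  asg <- classify_rois(zs, regs, fish_id = co$rois$fish_id,
                       motor_regressors = mr)
  truth_motor <- co$rois$true_archetype == "motor"
  expect_gt(mean(asg$label[truth_motor] == "motor"), 0.9)

  # no movement events -> all-zero regressor -> no motor labels
  mr0 <- lapply(mr, function(x) x * 0)
  asg0 <- classify_rois(zs[truth_motor, , drop = FALSE],
                        regs, fish_id = co$rois$fish_id[truth_motor],
                        motor_regressors = mr0)
  expect_false(any(asg0$label == "motor"))
  expect_equal(motor_regressor(numeric(0), 100), rep(0, 100))
})

test_that("over-contributing fish are flagged by the 50 percent rule", {
  asg <- data.frame(
    fish_id = c(rep("f1", 51), rep("f2", 49), rep("f3", 30)),
    label = c(rep("strong", 100), rep("weak", 30))
  )
  expect_equal(flag_outlier_fish(asg), c("f1", "f3"))
  balanced <- data.frame(fish_id = rep(c("a", "b", "c"), each = 10),
                         label = "moderate")
  expect_length(flag_outlier_fish(balanced), 0)
  single <- data.frame(fish_id = "only", label = rep("strong", 5))
  expect_equal(flag_outlier_fish(single), "only")
})

test_that("normalized loom responses divide baseline-adjusted maxima by loom 1", {
  tr <- build_stimulus_train("s20-short", seed = 1)
  k <- calcium_kernel(sampling_rate = 2)
  dur <- tr$record_duration
  amps <- c(1, 0.5, rep(0.25, 18))
  trace <- convolve_calcium(amps, tr$loom_onsets + 1, dur, kernel = k)
  norm <- normalized_loom_responses(rbind(trace, trace), tr)
  expect_equal(norm[1, 1], 1)
  expect_equal(norm[1, 2], 0.5, tolerance = 1e-9)
  expect_equal(norm[1, 3], 0.25, tolerance = 1e-9)
  # constant offset cancels through the baseline adjustment
  norm_shift <- normalized_loom_responses(rbind(trace + 3), tr)
  expect_equal(norm_shift[1, ], norm[1, ], tolerance = 1e-9)
  # non-positive first-loom response is flagged
  flat <- normalized_loom_responses(rbind(rep(0, length(trace))), tr)
  expect_equal(attr(flat, "flagged"), 1L)
  expect_true(all(is.na(flat[1, ])))
})

test_that("proportion tables satisfy their sum-to-one constraints", {
  set.seed(4)
  asg <- data.frame(
    fish_id = rep(paste0("f", 1:4), each = 50),
    label = sample(c("strong", "moderate", "weak"), 200, replace = TRUE),
    region = sample(c("tectum", "hindbrain", "pallium"), 200, replace = TRUE),
    dataset = rep(c("f20", "s20"), each = 100)
  )
  tabs <- proportion_tables(asg, clusters = c("strong", "moderate", "weak"),
                            regions = c("tectum", "hindbrain", "pallium"))
  expect_equal(unname(rowSums(tabs$cluster_by_region)), rep(1, 3),
               tolerance = 1e-9)
  expect_equal(unname(colSums(tabs$cluster_within_region)), rep(1, 3),
               tolerance = 1e-9)

  one_region <- proportion_tables(
    data.frame(fish_id = "f1", label = rep("strong", 10), region = "tectum"),
    clusters = "strong", regions = "tectum"
  )
  expect_equal(one_region$cluster_by_region[1, 1], 1)
})

test_that("neural-behavior correlations respect the three-fish rule", {
  prob <- c(1, 0.8, 0.5, 0.4, 0.3)
  resp <- rbind(prob * 2, prob * 3, prob * 1.5, -prob, 2 - prob)
  asg <- data.frame(fish_id = c("f1", "f2", "f3", "f4", "f5"),
                    region = c(rep("tectum", 3), "pallium", "pallium"),
                    label = c(rep("moderate", 3), "weak", "weak"))
  out <- neural_behavior_correlation(resp, asg, prob)
  tect <- out[out$region == "tectum", ]
  expect_equal(tect$n_fish, 3)
  expect_equal(tect$mean_r, 1, tolerance = 1e-12)
  pall <- out[out$region == "pallium", ]
  expect_true(is.na(pall$mean_r))        # only two contributing fish
  # anti-phase responses correlate at -1
  out_neg <- neural_behavior_correlation(rbind(-prob, -prob * 2, 1 - prob),
                                         data.frame(fish_id = c("a", "b", "c"),
                                                    region = "tectum",
                                                    label = "strong"),
                                         prob)
  expect_equal(out_neg$mean_r, -1, tolerance = 1e-12)
})

test_that("motor-association threshold is the data-derived mean plus one SD", {
  set.seed(6)
  rho <- as.numeric(scale(rnorm(200))) * 0.1544 + 0.1522
  sel <- motor_association_selection(rho)
  expect_equal(sel$threshold, 0.3066, tolerance = 1e-12)
  expect_equal(sel$selected, rho > 0.3066)
  # permutation invariance
  perm <- sample(length(rho))
  expect_equal(motor_association_selection(rho[perm])$threshold,
               sel$threshold)
  # degenerate: zero SD means an empty strict selection
  sel0 <- motor_association_selection(rep(0.25, 10))
  expect_equal(sel0$threshold, 0.25)
  expect_false(any(sel0$selected))
  # regional proportions
  regions <- rep(c("tectum", "hindbrain"), each = 100)
  selr <- motor_association_selection(rho, regions)
  expect_equal(selr$proportions[["tectum"]],
               mean(rho[regions == "tectum"] > sel$threshold))
})
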