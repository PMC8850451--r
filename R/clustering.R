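#' Row-wise z-scoring of fluorescence traces
#'
#' Centers and scales each ROI trace to mean 0, SD 1, using the population
#' (N-denominator) standard deviation. Zero-variance rows are left as zeros
#' and flagged; downstream regression skips them.
#'
#' @param traces ROI x timepoint matrix.
#' @return Matrix of the same shape with attributes `zscored = TRUE` and
#'   `zero_variance` (row indices of flagged constant traces).
#' @export
zscore_traces <- function(traces) {
  if (ncol(traces) < 2) stop("need at least 2 timepoints")
  mu <- rowMeans(traces)
  sd_pop <- sqrt(rowMeans((traces - mu)^2))
  flagged <- which(sd_pop == 0)
  sd_pop[flagged] <- 1
  out <- (traces - mu) / sd_pop
  out[flagged, ] <- 0
  attr(out, "zscored") <- TRUE
  attr(out, "zero_variance") <- flagged
  out
}

#' Coefficient of determination of a trace on a regressor
#'
#' Ordinary least squares of the trace on the regressor with slope and
#' intercept; returns the r-squared. Zero-variance input makes the r-squared
#' undefined (`NA`), and such ROIs are excluded from classification.
#'
#' @param trace,regressor Equal-length numeric vectors.
#' @return r-squared in `[0, 1]`, or `NA`.
#' @export
regress_roi <- function(trace, regressor) {
  if (length(trace) != length(regressor)) stop("length mismatch")
  xc <- regressor - mean(regressor)
  yc <- trace - mean(trace)
  sxx <- sum(xc^2)
  syy <- sum(yc^2)
  if (sxx == 0 || syy == 0) return(NA_real_)
  beta <- sum(xc * yc) / sxx
  sse <- sum((yc - beta * xc)^2)
  1 - sse / syy
}

# vectorized r^2 of every row of `traces` against one regressor
regress_rows <- function(traces, regressor) {
  xc <- regressor - mean(regressor)
  sxx <- sum(xc^2)
  yc <- traces - rowMeans(traces)
  syy <- rowSums(yc^2)
  sxy <- as.numeric(yc %*% xc)
  r2 <- (sxy^2) / (sxx * syy)
  r2[syy == 0 | sxx == 0] <- NA_real_
  r2
}

#' k-means clustering of traces under the cityblock metric
#'
#' Lloyd-type iteration with L1 (cityblock) assignment and elementwise-median
#' centers (the cityblock-optimal centroid), k-means++-style farthest-point
#' seeding, and best-of-replicates selection by total within-cluster L1 cost.
#'
#' @param x Observation x feature matrix.
#' @param k Number of clusters.
#' @param replicates Independent seeded restarts; the lowest-cost one wins.
#' @param seed Integer seed.
#' @param max_iter Iteration cap per replicate.
#' @return List: `centers` (k x feature), `cluster` (assignment per row),
#'   `cost` (total L1 cost), `sizes`.
#' @export
kmeans_cityblock <- function(x, k = 50, replicates = 5, seed = 1L,
                             max_iter = 50) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (k > n) stop("k exceeds the number of observations")
  best <- NULL
  for (rep in seq_len(replicates)) {
    set.seed(mix_seed(seed, rep))
    centers <- kmpp_init_l1(x, k)
    cl <- rep(1L, n)
    for (it in seq_len(max_iter)) {
      d <- l1_dist_to_centers(x, centers)
      new_cl <- max.col(-d, ties.method = "first")
      # re-seed empty clusters to the worst-fit points
      empty <- setdiff(seq_len(k), unique(new_cl))
      if (length(empty)) {
        far <- order(d[cbind(seq_len(n), new_cl)], decreasing = TRUE)
        for (j in seq_along(empty)) {
          centers[empty[j], ] <- x[far[j], ]
          new_cl[far[j]] <- empty[j]
        }
        d <- l1_dist_to_centers(x, centers)
        new_cl <- max.col(-d, ties.method = "first")
      }
      converged <- all(new_cl == cl) && it > 1
      cl <- new_cl
      for (j in seq_len(k)) {
        centers[j, ] <- apply(x[cl == j, , drop = FALSE], 2, stats::median)
      }
      if (converged) break
    }
    cost <- sum(l1_dist_to_centers(x, centers)[cbind(seq_len(n), cl)])
    if (is.null(best) || cost < best$cost) {
      best <- list(centers = centers, cluster = cl, cost = cost,
                   sizes = tabulate(cl, k))
    }
  }
  best
}

l1_dist_to_centers <- function(x, centers) {
  d <- matrix(0, nrow(x), nrow(centers))
  for (j in seq_len(nrow(centers))) {
    d[, j] <- rowSums(abs(x - matrix(centers[j, ], nrow(x), ncol(x), byrow = TRUE)))
  }
  d
}

kmpp_init_l1 <- function(x, k) {
  n <- nrow(x)
  idx <- integer(k)
  idx[1] <- sample.int(n, 1)
  d2 <- rowSums(abs(x - matrix(x[idx[1], ], n, ncol(x), byrow = TRUE)))
  if (k > 1) for (j in 2:k) {
    prob <- d2 / sum(d2)
    if (all(d2 == 0)) prob <- rep(1 / n, n)
    idx[j] <- sample.int(n, 1, prob = prob)
    dj <- rowSums(abs(x - matrix(x[idx[j], ], n, ncol(x), byrow = TRUE)))
    d2 <- pmin(d2, dj)
  }
  x[idx, , drop = FALSE]
}

#' Select loom-locked clusters across data sets
#'
#' Primary tier: clusters responsive at the first loom, present in every data
#' set, and represented in more than 80% of fish in each. Secondary tier
#' (admits the inhibited and auditory classes): responsive clusters present in
#' more than 90% of fish in at least `secondary_min_datasets` data sets.
#'
#' @param presence Data frame with columns `dataset`, `cluster`,
#'   `frac_fish` (fraction of that data set's fish containing the cluster)
#'   and `responds` (logical, loom- or tone-locked response at first
#'   presentation).
#' @param primary_fraction,secondary_fraction Strict fish-representation
#'   thresholds for the two tiers.
#' @param secondary_min_datasets Minimum qualifying data sets for tier 2.
#' @return Data frame `cluster`, `tier` (`"primary"`/`"secondary"`); zero rows
#'   (with a warning) when nothing qualifies.
#' @export
select_loom_clusters <- function(presence, primary_fraction = 0.8,
                                 secondary_fraction = 0.9,
                                 secondary_min_datasets = 2) {
  n_datasets <- length(unique(presence$dataset))
  out <- lapply(split(presence, presence$cluster), function(d) {
    if (!all(d$responds)) return(NULL)
    if (nrow(d) == n_datasets && all(d$frac_fish > primary_fraction)) {
      return(data.frame(cluster = d$cluster[1], tier = "primary"))
    }
    if (sum(d$frac_fish > secondary_fraction) >= secondary_min_datasets) {
      return(data.frame(cluster = d$cluster[1], tier = "secondary"))
    }
    NULL
  })
  res <- do.call(rbind, out)
  if (is.null(res)) {
    warning("no cluster passed the selection criteria")
    res <- data.frame(cluster = character(0), tier = character(0))
  }
  rownames(res) <- NULL
  res
}

#' Build a motor regressor from swim-bout times
#'
#' Inserts a unit calcium kernel at each movement event. A fish with no
#' events yields an all-zero regressor, which produces no motor labels.
#'
#' @param event_times Bout times, seconds.
#' @param n_timepoints Length of the recording in frames.
#' @param sampling_rate Hz.
#' @param kernel Calcium kernel ([calcium_kernel()]).
#' @return Numeric regressor of length `n_timepoints`.
#' @export
motor_regressor <- function(event_times, n_timepoints, sampling_rate = 2,
                            kernel = calcium_kernel(sampling_rate = sampling_rate)) {
  if (length(event_times) == 0) return(numeric(n_timepoints))
  convolve_calcium(rep(1, length(event_times)), event_times,
                   n_timepoints / sampling_rate, kernel = kernel,
                   sampling_rate = sampling_rate, noise_sd = 0)
}

#' Classify ROIs by regression against template regressors
#'
#' Each ROI is labeled by the regressor giving the highest r-squared among
#' those exceeding their threshold (strictly): 0.3 for the loom regressors
#' and 0.2 for the per-fish motor regressor. Strongly habituating
#' sub-regressors (names starting `strong`) are merged into one `strong`
#' label. Ties break by a fixed precedence order. ROIs with no qualifying
#' regressor are labeled `none`.
#'
#' @param traces z-scored ROI x timepoint matrix.
#' @param regressors Named list of loom regressors (full-length traces).
#' @param fish_id Per-ROI fish label (needed for motor regressors).
#' @param motor_regressors Named list (by fish) of motor regressors, or NULL.
#' @param r2_threshold Strict threshold for loom regressors.
#' @param motor_threshold Strict threshold for the motor regressor.
#' @param precedence Tie-break order of merged labels.
#' @param frames Optional frame indices to restrict the regression to (used
#'   to trim long-ISI recordings around the looms).
#' @return Data frame `roi_id`, `fish_id`, `label`, `best_r2`, with the full
#'   r-squared matrix as attribute `r2`.
#' @export
classify_rois <- function(traces, regressors, fish_id = NULL,
                          motor_regressors = NULL, r2_threshold = 0.3,
                          motor_threshold = 0.2,
                          precedence = c("strong", "moderate", "weak",
                                         "inhibited", "motor", "auditory"),
                          frames = NULL) {
  roi_ids <- if (!is.null(rownames(traces))) rownames(traces) else
    seq_len(nrow(traces))
  if (!is.null(frames)) {
    traces <- traces[, frames, drop = FALSE]
    regressors <- lapply(regressors, `[`, frames)
    if (!is.null(motor_regressors)) {
      motor_regressors <- lapply(motor_regressors, `[`, frames)
    }
  }
  n <- nrow(traces)
  r2 <- vapply(regressors, function(rg) regress_rows(traces, rg), numeric(n))
  if (!is.matrix(r2)) r2 <- matrix(r2, nrow = n)
  colnames(r2) <- names(regressors)
  thr <- rep(r2_threshold, ncol(r2))
  if (!is.null(motor_regressors)) {
    stopifnot(!is.null(fish_id))
    motor_r2 <- rep(NA_real_, n)
    for (f in names(motor_regressors)) {
      rows <- which(fish_id == f)
      if (!length(rows)) next
      rg <- motor_regressors[[f]]
      if (all(rg == 0)) next
      motor_r2[rows] <- regress_rows(traces[rows, , drop = FALSE], rg)
    }
    r2 <- cbind(r2, motor = motor_r2)
    thr <- c(thr, motor_threshold)
  }
  merged <- ifelse(grepl("^strong", colnames(r2)), "strong", colnames(r2))
  prec_rank <- match(merged, precedence)
  prec_rank[is.na(prec_rank)] <- length(precedence) + seq_len(sum(is.na(prec_rank)))
  labels <- rep("none", n)
  best_r2 <- rep(NA_real_, n)
  qual <- sweep(r2, 2, thr, `>`)
  qual[is.na(qual)] <- FALSE
  for (i in seq_len(n)) {
    j <- which(qual[i, ])
    if (!length(j)) next
    jbest <- j[order(-r2[i, j], prec_rank[j])][1]
    labels[i] <- merged[jbest]
    best_r2[i] <- r2[i, jbest]
  }
  out <- data.frame(
    roi_id = roi_ids,
    fish_id = if (is.null(fish_id)) NA_character_ else fish_id,
    label = labels, best_r2 = best_r2
  )
  attr(out, "r2") <- r2
  out
}

#' Flag over-contributing fish
#'
#' A fish is excluded when its ROIs make up more than half of any habituating
#' cluster, marking it an outlier in responsiveness.
#'
#' @param assignments Data frame with `fish_id` and `label`.
#' @param habituating_labels Clusters the rule applies to.
#' @return Character vector of excluded fish ids.
#' @export
flag_outlier_fish <- function(assignments,
                              habituating_labels = c("strong", "moderate", "weak")) {
  excluded <- character(0)
  for (lab in habituating_labels) {
    d <- assignments[assignments$label == lab, ]
    if (!nrow(d)) next
    share <- table(d$fish_id) / nrow(d)
    excluded <- union(excluded, names(share)[share > 0.5])
  }
  sort(excluded)
}

#' Baseline-adjusted per-loom response maxima, normalized to loom 1
#'
#' For each ROI and loom: the maximum z-score inside the response window minus
#' the mean of the 4-s baseline immediately before onset, divided by the same
#' quantity at the first loom. ROIs whose first-loom value is not positive are
#' flagged and return `NA`.
#'
#' @param traces z-scored ROI x timepoint matrix.
#' @param train A `stimulus_train`.
#' @param sampling_rate Hz.
#' @param baseline_s Baseline window length before onset, seconds.
#' @param windows Response windows; default [response_frame_windows()].
#' @return ROI x loom matrix of normalized responses, with attribute
#'   `flagged` (rows with non-positive first-loom response).
#' @export
normalized_loom_responses <- function(traces, train, sampling_rate = 2,
                                      baseline_s = 4, windows = NULL) {
  if (is.null(windows)) windows <- response_frame_windows(train, sampling_rate)
  nb <- round(baseline_s * sampling_rate)
  raw <- vapply(windows, function(w) {
    b <- seq.int(max(1L, w[1] - nb), w[1] - 1L)
    apply(traces[, w, drop = FALSE], 1, max) -
      rowMeans(traces[, b, drop = FALSE])
  }, numeric(nrow(traces)))
  if (!is.matrix(raw)) raw <- matrix(raw, nrow = nrow(traces))
  colnames(raw) <- names(windows)
  flagged <- which(unname(raw[, 1] <= 0))
  out <- raw / raw[, 1]
  out[flagged, ] <- NA_real_
  attr(out, "flagged") <- flagged
  out
}

#' Proportion tables of functional clusters across brain regions
#'
#' Table 1 (`cluster_by_region`): for each cluster, the proportion of its
#' ROIs in each region (rows sum to 1). Table 2 (`cluster_within_region`):
#' for each region, the proportion of its loom-responsive ROIs belonging to
#' each cluster (columns sum to 1). Both are computed per fish, averaged per
#' data set, then across data sets.
#'
#' @param assignments Data frame with `fish_id`, `label`, `region` and
#'   optionally `dataset` (defaults to a single data set).
#' @param clusters Cluster labels to tabulate.
#' @param regions Region vocabulary.
#' @return List of two cluster x region matrices.
#' @export
proportion_tables <- function(assignments,
                              clusters = c("strong", "moderate", "weak", "inhibited"),
                              regions = brain_regions) {
  if (is.null(assignments$dataset)) assignments$dataset <- "all"
  d <- assignments[assignments$label %in% clusters, ]
  per_dataset <- function(dd) {
    fish <- unique(dd$fish_id)
    t1 <- array(NA_real_, c(length(clusters), length(regions), length(fish)))
    t2 <- array(NA_real_, c(length(clusters), length(regions), length(fish)))
    for (k in seq_along(fish)) {
      df <- dd[dd$fish_id == fish[k], ]
      cnt <- table(factor(df$label, clusters), factor(df$region, regions))
      rs <- rowSums(cnt)
      cs <- colSums(cnt)
      t1[, , k] <- sweep(cnt, 1, ifelse(rs == 0, NA, rs), `/`)
      t2[, , k] <- sweep(cnt, 2, ifelse(cs == 0, NA, cs), `/`)
    }
    list(t1 = apply(t1, c(1, 2), mean, na.rm = TRUE),
         t2 = apply(t2, c(1, 2), mean, na.rm = TRUE))
  }
  by_ds <- lapply(split(d, d$dataset), per_dataset)
  avg <- function(which) {
    m <- Reduce(`+`, lapply(by_ds, function(z) {
      x <- z[[which]]; x[is.nan(x)] <- NA; ifelse(is.na(x), 0, x)
    })) / Reduce(`+`, lapply(by_ds, function(z) !is.na(z[[which]]) & !is.nan(z[[which]])))
    dimnames(m) <- list(clusters, regions)
    m
  }
  list(cluster_by_region = avg("t1"), cluster_within_region = avg("t2"))
}

#' Correlation between neural habituation and free-swimming behavior
#'
#' Pearson correlation, per fish, between the fish's mean normalized loom
#' responses (per region x cluster) and the free-swimming response-probability
#' curve of the matching group; averaged over fish only where at least
#' `min_fish` fish contribute.
#'
#' @param norm_responses ROI x loom matrix ([normalized_loom_responses()]).
#' @param assignments Data frame with per-ROI `fish_id`, `region`, `label`.
#' @param behavior_prob Per-loom response probability of the matching group.
#' @param min_fish Minimum contributing fish per combination.
#' @return Data frame `region`, `cluster`, `n_fish`, `mean_r` (`NA` when
#'   fewer than `min_fish` fish contribute).
#' @export
neural_behavior_correlation <- function(norm_responses, assignments,
                                        behavior_prob, min_fish = 3) {
  stopifnot(ncol(norm_responses) == length(behavior_prob))
  combos <- unique(assignments[assignments$label != "none",
                               c("region", "label")])
  out <- lapply(seq_len(nrow(combos)), function(i) {
    sel <- assignments$region == combos$region[i] &
      assignments$label == combos$label[i]
    rs <- numeric(0)
    for (f in unique(assignments$fish_id[sel])) {
      rows <- which(sel & assignments$fish_id == f)
      m <- colMeans(norm_responses[rows, , drop = FALSE], na.rm = TRUE)
      if (all(is.finite(m)) && stats::sd(m) > 0) {
        rs <- c(rs, stats::cor(m, behavior_prob))
      }
    }
    data.frame(region = combos$region[i], cluster = combos$label[i],
               n_fish = length(rs),
               mean_r = if (length(rs) >= min_fish) mean(rs) else NA_real_)
  })
  do.call(rbind, out)
}

#' Motor-associated subset of a functional cluster
#'
#' Selects ROIs whose Spearman correlation with their fish's motor regressor
#' strictly exceeds the data-derived threshold mean + 1 SD of the coefficient
#' distribution.
#'
#' @param rho Spearman coefficients, one per ROI.
#' @param regions Optional per-ROI region labels for the regional breakdown.
#' @return List: `threshold`, `selected` (logical), and `proportions`
#'   (selected share of the cluster per region) when regions are given.
#' @export
motor_association_selection <- function(rho, regions = NULL) {
  threshold <- mean(rho) + stats::sd(rho)
  if (is.na(threshold)) threshold <- mean(rho)
  selected <- rho > threshold
  out <- list(threshold = threshold, selected = selected)
  if (!is.null(regions)) {
    tot <- table(regions)
    sel <- table(factor(regions[selected], names(tot)))
    out$proportions <- as.numeric(sel) / as.numeric(tot)
    names(out$proportions) <- names(tot)
  }
  out
}
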