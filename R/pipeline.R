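#' Run configuration for the end-to-end pipeline
#'
#' Collects every tunable of the analysis with explicit seeds for each
#' stochastic stage (all derived from one master seed). Round-trips
#' losslessly through JSON ([save_run_config()] / [load_run_config()]).
#'
#' @param paradigm Stimulus paradigm.
#' @param n_fish Imaging cohort size.
#' @param n_behavior_fish Behavior cohort size.
#' @param genotype Genotype label (single or per-fish).
#' @param roi_scale Multiplier on the default per-fish ROI counts.
#' @param noise_sd Trace white-noise SD.
#' @param r2_threshold,motor_threshold Classification thresholds.
#' @param edge_cutoff Correlation threshold for graph metrics.
#' @param node_thresholds Node-count rule boundaries; defaults to the
#'   full-scale table divided by 10 to suit desk-scale synthetic cohorts.
#' @param gamma_grid,omega_grid Community-detection sweep grids.
#' @param sweep_reps Louvain repetitions per sweep cell.
#' @param max_looms_analyzed Loom layers used in graph stages (pre + this).
#' @param seed Master seed; per-stage seeds derive from it.
#' @return A `run_config` list.
#' @export
run_config <- function(paradigm = "f20", n_fish = 6, n_behavior_fish = 36,
                       genotype = "WT", roi_scale = 1, noise_sd = 0.1,
                       r2_threshold = 0.3, motor_threshold = 0.2,
                       edge_cutoff = 0.75,
                       node_thresholds = c(20, 50, 100, 300),
                       gamma_grid = c(0.5, 1, 1.5), omega_grid = c(0.25, 0.75),
                       sweep_reps = 10, max_looms_analyzed = 11, seed = 1L) {
  cfg <- list(paradigm = paradigm, n_fish = n_fish,
              n_behavior_fish = n_behavior_fish, genotype = genotype,
              roi_scale = roi_scale, noise_sd = noise_sd,
              r2_threshold = r2_threshold, motor_threshold = motor_threshold,
              edge_cutoff = edge_cutoff, node_thresholds = node_thresholds,
              gamma_grid = gamma_grid, omega_grid = omega_grid,
              sweep_reps = sweep_reps, max_looms_analyzed = max_looms_analyzed,
              seed = as.integer(seed))
  validate_run_config(cfg)
  cfg
}

validate_run_config <- function(cfg) {
  required <- c("paradigm", "n_fish", "seed", "edge_cutoff", "node_thresholds")
  missing <- setdiff(required, names(cfg))
  if (length(missing)) {
    stop("run config is missing field(s): ", paste(missing, collapse = ", "))
  }
  if (length(cfg$seed) != 1 || !is.finite(cfg$seed)) {
    stop("run config must carry an explicit seed")
  }
  paradigm_spec(cfg$paradigm)
  invisible(TRUE)
}

stage_seed <- function(cfg, stage) {
  offsets <- c(simulate = 1L, behavior = 2L, cluster = 3L, graph = 4L,
               nulls = 5L, communities = 6L, topology = 7L)
  cfg$seed * 101L + offsets[[stage]]
}

#' Archetype regressors for a cohort
#'
#' Noise-free template traces built from the archetype amplitude model and
#' the calcium kernel: three strongly habituating subtypes (the fast cluster
#' appeared as several k-means subclusters in the source analysis), moderate,
#' weak, a sign-inverted loom regressor for the inhibited class, and (when
#' the train carries a tone) an auditory regressor.
#'
#' @param train A `stimulus_train`.
#' @param archetypes Named list of [archetype_params()].
#' @param sampling_rate Hz.
#' @return Named list of regressor traces.
#' @export
archetype_regressors <- function(train, archetypes = default_archetypes(),
                                 sampling_rate = 2) {
  dur <- train$record_duration
  kern <- calcium_kernel(sampling_rate = sampling_rate)
  onsets <- train$loom_onsets + train$pre_duration
  esc_p <- habituation_amplitudes(default_escape_params(), train)
  make <- function(p, k_scale = 1, escape_gated = FALSE, gate_floor = 0.3) {
    p2 <- p
    p2$K <- p$K * k_scale
    amp <- habituation_amplitudes(p2, train, jitter = FALSE)
    # the strong class is escape-associated; its expected response carries
    # the escape-probability attenuation
    if (escape_gated) amp <- amp * (esc_p + (1 - esc_p) * gate_floor)
    convolve_calcium(p$sign * amp, onsets, dur, kernel = kern,
                     sampling_rate = sampling_rate, noise_sd = 0)
  }
  regs <- list(
    strong1 = make(archetypes$strong, 1, escape_gated = TRUE),
    strong2 = make(archetypes$strong, 1.4, escape_gated = TRUE),
    strong3 = make(archetypes$strong, 0.8, escape_gated = TRUE),
    moderate = make(archetypes$moderate),
    weak = make(archetypes$weak),
    inhibited = make(archetypes$inhibited)
  )
  if (length(train$tone_times)) {
    regs$auditory <- convolve_calcium(rep(1, length(train$tone_times)),
                                      train$tone_times, dur, kernel = kern,
                                      sampling_rate = sampling_rate,
                                      noise_sd = 0)
  }
  regs
}

#' Graph-stage analysis of a classified cohort
#'
#' Builds (or reuses) nodes, computes per-fish per-loom correlation matrices,
#' group averages, and the standard graph metrics per analyzed loom: strong
#' edge counts, density and mean participation over the functional-cluster
#' partition, plus the recovery matrix match.
#'
#' @param cohort [simulate_cohort()] output.
#' @param assignments [classify_rois()] output for the cohort.
#' @param cfg A [run_config()].
#' @param nodes Optional reference node table (reused via
#'   [assign_to_existing_nodes()]); built from this cohort when NULL.
#' @return List: nodes, membership, tensor (node x node x window x fish),
#'   avg (node x node x window), metrics data frame, match (recovery match),
#'   windows.
#' @export
graph_stage <- function(cohort, assignments, cfg, nodes = NULL) {
  zs <- zscore_traces(cohort$traces)
  if (is.null(nodes)) {
    nb <- build_nodes(cohort$rois, assignments$label,
                      thresholds = cfg$node_thresholds,
                      seed = stage_seed(cfg, "graph"))
    nodes <- nb$nodes
    membership <- nb$membership
  } else {
    membership <- assign_to_existing_nodes(cohort$rois, assignments$label,
                                           nodes)
  }
  nt <- node_mean_traces(zs, membership, nodes, cohort$rois$fish_id)
  windows <- loom_frame_windows(cohort$train, cohort$sampling_rate,
                                include_pre = TRUE)
  n_keep <- min(length(windows), cfg$max_looms_analyzed + 1)
  windows <- windows[seq_len(n_keep)]
  tensor <- per_loom_matrices(nt, windows)
  avg <- average_matrices(tensor)
  looms <- seq_len(dim(avg)[3])
  metrics <- do.call(rbind, lapply(looms, function(w) {
    m <- avg[, , w]
    g <- threshold_graph(m, cfg$edge_cutoff)
    data.frame(
      window = dimnames(avg)[[3]][w],
      edges_gt_cutoff = count_strong_edges(m, cfg$edge_cutoff),
      density = graph_density(g),
      mean_participation = mean(participation_coefficients(g, nodes$cluster))
    )
  }))
  loom_idx <- which(dimnames(avg)[[3]] != "pre")
  match <- if (length(loom_idx) >= 11) {
    match_recovery_matrix(avg[, , loom_idx[1:10]], avg[, , loom_idx[11]])
  } else NULL
  list(nodes = nodes, membership = membership, tensor = tensor, avg = avg,
       metrics = metrics, match = match, windows = windows)
}

#' Dynamic-community stage
#'
#' Runs the gamma/omega sweep on the averaged per-loom matrices (pre-loom
#' layer first) and computes flexibility, cohesion and promiscuity per node
#' from the consensus partitions of the selected (or best-scoring) cells.
#'
#' @param avg node x node x window array from [graph_stage()].
#' @param cfg A [run_config()].
#' @return List: `sweep`, `metrics` (per node x selected cell: data frame
#'   node, gamma, omega, flexibility, cohesion, promiscuity), `layers`.
#' @export
communities_stage <- function(avg, cfg) {
  layers <- lapply(seq_len(dim(avg)[3]), function(w) avg[, , w])
  sw <- sweep_gamma_omega(layers, cfg$gamma_grid, cfg$omega_grid,
                          reps = cfg$sweep_reps,
                          seed = stage_seed(cfg, "communities"))
  sel <- which(sw$grid$selected)
  if (!length(sel)) sel <- which.max(sw$grid$score)
  metrics <- do.call(rbind, lapply(sel, function(ci) {
    lab <- sw$consensus[[ci]]
    data.frame(node = seq_len(nrow(lab)), gamma = sw$grid$gamma[ci],
               omega = sw$grid$omega[ci], flexibility = flexibility(lab),
               cohesion = cohesion(lab)$strength,
               promiscuity = promiscuity(lab))
  }))
  list(sweep = sw, metrics = metrics, layers = layers)
}

#' Run the full analysis pipeline on synthetic cohorts
#'
#' simulate -> behavior -> classification -> graph -> surrogate nulls ->
#' dynamic communities -> topology. Each stage's tabular outputs are written
#' under `out_dir` and recorded in a manifest with MD5 hashes, so identical
#' configurations reproduce identical manifests.
#'
#' @param cfg A [run_config()].
#' @param out_dir Output directory (created); `NULL` for a session temporary
#'   directory.
#' @param max_dim Homology dimension cap for the topology stage.
#' @param topology_looms Windows analyzed in the topology stage.
#' @return List with per-stage results and `manifest` (stage, file, md5,
#'   seconds).
#' @export
run_pipeline <- function(cfg, out_dir = NULL, max_dim = 1,
                         topology_looms = c("pre", "loom1", "loom10", "loom11")) {
  validate_run_config(cfg)
  if (is.null(out_dir)) out_dir <- tempfile("loomnet_run_")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list()
  note <- function(stage, file, t0) {
    manifest[[length(manifest) + 1]] <<- data.frame(
      stage = stage, file = basename(file),
      md5 = unname(tools::md5sum(file)),
      seconds = round(as.numeric(Sys.time()) - t0, 2)
    )
  }
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", stage, "' failed (outputs under ", out_dir,
           "): ", conditionMessage(e), call. = FALSE)
    })
  }

  # --- simulate ---
  t0 <- as.numeric(Sys.time())
  cohort <- run_stage("simulate", {
    cc <- cohort_config(cfg$paradigm, cfg$n_fish, cfg$genotype,
                        roi_counts = default_roi_counts(cfg$roi_scale),
                        archetypes = default_archetypes(cfg$noise_sd))
    simulate_cohort(cc, seed = stage_seed(cfg, "simulate"))
  })
  f <- file.path(out_dir, "rois.csv")
  utils::write.csv(cohort$rois, f, row.names = FALSE)
  note("simulate", f, t0)

  # --- behavior ---
  t0 <- as.numeric(Sys.time())
  behavior <- run_stage("behavior", {
    tracks <- simulate_behavior_cohort(cfg$n_behavior_fish, cohort$train,
                                       genotype = cfg$genotype,
                                       seed = stage_seed(cfg, "behavior"))
    esc <- escape_matrix(tracks)
    prob <- response_probability(esc)
    npb <- cohort$train$looms_per_block
    fit <- fit_one_phase_decay(prob[seq_len(npb)], plateau_fixed = FALSE)
    list(tracks = tracks, escapes = esc, probability = prob, decay_fit = fit)
  })
  f <- file.path(out_dir, "behavior_probability.csv")
  utils::write.csv(data.frame(loom = seq_along(behavior$probability),
                              probability = behavior$probability),
                   f, row.names = FALSE)
  note("behavior", f, t0)

  # --- classification ---
  t0 <- as.numeric(Sys.time())
  classified <- run_stage("cluster", {
    zs <- zscore_traces(cohort$traces)
    regs <- archetype_regressors(cohort$train, sampling_rate = cohort$sampling_rate)
    motor_regs <- lapply(cohort$motor_events, motor_regressor,
                         n_timepoints = ncol(zs),
                         sampling_rate = cohort$sampling_rate)
    frames <- if (mean(cohort$train$isi_values) > 40) {
      loom_trim_frames(cohort$train, cohort$sampling_rate)
    } else NULL
    asg <- classify_rois(zs, regs, fish_id = cohort$rois$fish_id,
                         motor_regressors = motor_regs,
                         r2_threshold = cfg$r2_threshold,
                         motor_threshold = cfg$motor_threshold,
                         frames = frames)
    asg$region <- cohort$rois$region
    asg
  })
  f <- file.path(out_dir, "assignments.csv")
  utils::write.csv(classified[, c("roi_id", "fish_id", "label", "best_r2")],
                   f, row.names = FALSE)
  note("cluster", f, t0)

  # --- graph ---
  t0 <- as.numeric(Sys.time())
  graph <- run_stage("graph", graph_stage(cohort, classified, cfg))
  f <- file.path(out_dir, "graph_metrics.csv")
  utils::write.csv(graph$metrics, f, row.names = FALSE)
  note("graph", f, t0)

  # --- surrogate nulls ---
  t0 <- as.numeric(Sys.time())
  nulls <- run_stage("nulls", {
    nt <- node_mean_traces(zscore_traces(cohort$traces), graph$membership,
                           graph$nodes, cohort$rois$fish_id)
    avg_ts <- Reduce(`+`, lapply(nt, function(m) {
      m[is.na(m)] <- 0
      m
    })) / length(nt)
    sseed <- stage_seed(cfg, "nulls")
    sur <- t(vapply(seq_len(nrow(avg_ts)), function(i) {
      aaft_surrogate(avg_ts[i, ], seed = sseed + i)
    }, numeric(ncol(avg_ts))))
    sur_mats <- per_loom_matrices(list(all = sur), graph$windows)
    true_mats <- per_loom_matrices(list(all = avg_ts), graph$windows)
    list(surrogate_loom1 = sur_mats[, , "loom1", 1],
         true_loom1 = true_mats[, , "loom1", 1])
  })
  f <- file.path(out_dir, "null_summary.csv")
  utils::write.csv(data.frame(
    quantity = c("true_density_loom1", "surrogate_density_loom1"),
    value = c(graph_density(threshold_graph(nulls$true_loom1, cfg$edge_cutoff)),
              graph_density(threshold_graph(nulls$surrogate_loom1, cfg$edge_cutoff)))
  ), f, row.names = FALSE)
  note("nulls", f, t0)

  # --- dynamic communities ---
  t0 <- as.numeric(Sys.time())
  communities <- run_stage("communities", communities_stage(graph$avg, cfg))
  f <- file.path(out_dir, "community_metrics.csv")
  utils::write.csv(communities$metrics, f, row.names = FALSE)
  note("communities", f, t0)

  # --- topology ---
  t0 <- as.numeric(Sys.time())
  topology <- run_stage("topology", {
    wanted <- intersect(topology_looms, dimnames(graph$avg)[[3]])
    out <- lapply(stats::setNames(wanted, wanted), function(w) {
      persistent_homology(graph$avg[, , w], max_dim = max_dim)
    })
    sums <- do.call(rbind, lapply(names(out), function(w) {
      data.frame(window = w, dimension = 0:max_dim,
                 lifetime_sum = vapply(0:max_dim, lifetime_sum,
                                       numeric(1), barcode = out[[w]]))
    }))
    list(barcodes = out, lifetime_sums = sums)
  })
  f <- file.path(out_dir, "lifetime_sums.csv")
  utils::write.csv(topology$lifetime_sums, f, row.names = FALSE)
  note("topology", f, t0)

  manifest <- do.call(rbind, manifest)
  f <- file.path(out_dir, "manifest.csv")
  utils::write.csv(manifest, f, row.names = FALSE)
  list(config = cfg, cohort = cohort, behavior = behavior,
       assignments = classified, graph = graph, nulls = nulls,
       communities = communities, topology = topology,
       manifest = manifest, out_dir = out_dir)
}
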