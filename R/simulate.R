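#' Response-archetype parameters
#'
#' Phenomenological description of one functional response class: a per-block
#' one-phase decay of loom-response amplitude with partial recovery after each
#' rest. Defaults for the six archetypes (three habituation speeds, an
#' inhibited class, a motor class driven by swim bouts, and an auditory class
#' driven by the tone) are returned by [default_archetypes()].
#'
#' @param archetype Label.
#' @param initial_amplitude Peak response to the first loom, in raw trace
#'   units; against the default noise SD of 0.1 this is roughly the peak
#'   z-score of the neuron. Archetype ROIs represent neurons that pass a
#'   responsiveness selection, so defaults are several times the noise floor.
#' @param K Habituation rate constant per loom (>= 0).
#' @param plateau Asymptotic amplitude as a fraction of the initial (0-1).
#' @param recovery_fraction Fraction of the habituated deficit recovered over
#'   a rest period (0-1).
#' @param sign +1, or -1 for the inhibited class.
#' @param noise_sd Additive white-noise SD on the trace.
#' @param loom_jitter_sd SD of the multiplicative log-normal per-loom
#'   amplitude jitter (0 disables).
#' @export
archetype_params <- function(archetype, initial_amplitude = 1, K = 1,
                             plateau = 0.2, recovery_fraction = 0.5,
                             sign = 1, noise_sd = 0.1, loom_jitter_sd = 0.15) {
  stopifnot(K >= 0, plateau >= 0, plateau <= 1,
            recovery_fraction >= 0, recovery_fraction <= 1)
  structure(list(
    archetype = archetype, initial_amplitude = initial_amplitude, K = K,
    plateau = plateau, recovery_fraction = recovery_fraction, sign = sign,
    noise_sd = noise_sd, loom_jitter_sd = loom_jitter_sd
  ), class = "archetype_params")
}

#' Default archetype set
#'
#' Rate constants and plateaus are anchored to the fitted one-phase decay of
#' moderately habituating tectal responses under 20-s ISIs (K near 1, plateau
#' near 0.19), with faster/slower classes spread around it.
#' @param noise_sd White-noise SD applied to every archetype.
#' @return Named list of [archetype_params()].
#' @export
default_archetypes <- function(noise_sd = 0.1) {
  list(
    strong = archetype_params("strong", 8, K = 1.8, plateau = 0.05,
                              recovery_fraction = 0.2, noise_sd = noise_sd),
    moderate = archetype_params("moderate", 4.5, K = 1.0, plateau = 0.19,
                                recovery_fraction = 0.65, noise_sd = noise_sd),
    weak = archetype_params("weak", 4, K = 0.25, plateau = 0.60,
                            recovery_fraction = 0.9, noise_sd = noise_sd),
    inhibited = archetype_params("inhibited", 3.5, K = 0.8, plateau = 0.30,
                                 recovery_fraction = 0.5, sign = -1,
                                 noise_sd = noise_sd),
    motor = archetype_params("motor", 4, K = 0, plateau = 1,
                             recovery_fraction = 1, noise_sd = noise_sd),
    auditory = archetype_params("auditory", 4, K = 0, plateau = 1,
                                recovery_fraction = 1, noise_sd = noise_sd)
  )
}

#' Genotype modifiers of habituation dynamics
#'
#' The mutant genotype slows habituation (scales K down), strengthens
#' post-rest recovery, and increases the shared network drive that couples
#' ROIs within a fish; heterozygotes are intermediate.
#' @param genotype `"WT"`, `"het"` or `"fmr1"`.
#' @return List with `k_scale`, `recovery_scale`, `shared_scale`.
#' @export
genotype_modifier <- function(genotype) {
  switch(genotype,
    WT = list(k_scale = 1, recovery_scale = 1, shared_scale = 1),
    het = list(k_scale = 0.8, recovery_scale = 1.25, shared_scale = 1.5),
    fmr1 = list(k_scale = 0.6, recovery_scale = 1.5, shared_scale = 2),
    stop("unknown genotype '", genotype, "'")
  )
}

#' Per-loom response amplitudes under block-wise one-phase decay
#'
#' Within each block, amplitude at loom n follows
#' `plateau + (start - plateau) * exp(-K * (n - 1))` where `start` is 1 for
#' the first block and, after each rest, recovers toward 1 by
#' `recovery_fraction` of the habituated deficit. The sequence is scaled by
#' `initial_amplitude` and clipped to `[0, initial_amplitude]`.
#'
#' @param params An [archetype_params()].
#' @param train A `stimulus_train`.
#' @param genotype_modifier List with `k_scale` and `recovery_scale`
#'   (see [genotype_modifier()]).
#' @param seed Seed for the per-loom jitter (unused when `loom_jitter_sd` is 0).
#' @param jitter Apply the archetype's multiplicative per-loom jitter.
#' @return Numeric vector, one amplitude per loom.
#' @export
habituation_amplitudes <- function(params, train,
                                   genotype_modifier = list(k_scale = 1, recovery_scale = 1),
                                   seed = 1L, jitter = FALSE) {
  K <- params$K * genotype_modifier$k_scale
  rec <- min(1, params$recovery_fraction * genotype_modifier$recovery_scale)
  npb <- train$looms_per_block
  amp <- numeric(train$n_blocks * npb)
  start <- 1
  for (b in seq_len(train$n_blocks)) {
    n <- seq_len(npb)
    a <- params$plateau + (start - params$plateau) * exp(-K * (n - 1))
    amp[(b - 1) * npb + n] <- a
    start <- a[npb] + rec * (1 - a[npb])
  }
  if (jitter && params$loom_jitter_sd > 0) {
    set.seed(as.integer(seed))
    amp <- amp * exp(stats::rnorm(length(amp), 0, params$loom_jitter_sd) -
                       params$loom_jitter_sd^2 / 2)
  }
  pmin(pmax(amp * params$initial_amplitude, 0), params$initial_amplitude)
}

#' Calcium-indicator impulse kernel
#'
#' Difference of exponentials, `exp(-t/decay) - exp(-t/rise)`, normalized to
#' unit peak. Defaults (rise 0.5 s, decay 3.5 s) approximate a slow
#' nuclear-targeted GCaMP6s response.
#' @param duration_s Kernel support, seconds.
#' @param sampling_rate Hz.
#' @param rise,decay Time constants, seconds.
#' @return Numeric vector sampled at `sampling_rate`.
#' @export
calcium_kernel <- function(duration_s = 20, sampling_rate = 2,
                           rise = 0.5, decay = 3.5) {
  stopifnot(decay > rise, rise > 0)
  t <- seq(0, duration_s, by = 1 / sampling_rate)
  k <- exp(-t / decay) - exp(-t / rise)
  k / max(k)
}

#' Synthesize a fluorescence trace from event amplitudes
#'
#' Superposes amplitude-scaled copies of a calcium kernel at the given onsets
#' and adds white Gaussian noise.
#'
#' @param amplitudes Per-event amplitudes (may be negative).
#' @param onsets Event times, seconds; must lie within the record.
#' @param duration_s Record duration, seconds.
#' @param kernel Kernel vector as from [calcium_kernel()].
#' @param sampling_rate Hz.
#' @param noise_sd Gaussian noise SD (>= 0).
#' @param seed Seed for the noise draw.
#' @return Numeric trace of length `round(duration_s * sampling_rate)`.
#' @export
convolve_calcium <- function(amplitudes, onsets, duration_s,
                             kernel = calcium_kernel(sampling_rate = sampling_rate),
                             sampling_rate = 2, noise_sd = 0, seed = 1L) {
  stopifnot(length(amplitudes) == length(onsets))
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  if (length(onsets) && (min(onsets) < 0 || max(onsets) > duration_s)) {
    stop("onsets must lie within the record")
  }
  n <- round(duration_s * sampling_rate)
  trace <- numeric(n)
  for (e in seq_along(onsets)) {
    i0 <- floor(onsets[e] * sampling_rate) + 1L
    idx <- i0:min(n, i0 + length(kernel) - 1L)
    trace[idx] <- trace[idx] + amplitudes[e] * kernel[seq_along(idx)]
  }
  if (noise_sd > 0) {
    set.seed(as.integer(seed))
    trace <- trace + stats::rnorm(n, 0, noise_sd)
  }
  trace
}

# escape-probability curve of the WT reference under 20-s ISIs
default_escape_params <- function() {
  archetype_params("escape", 0.9, K = 1, plateau = 0.15,
                   recovery_fraction = 0.6, noise_sd = 0)
}

brain_regions <- c("pallium", "subpallium", "thalamus", "habenula",
                   "pretectum", "tectum", "tegmentum", "cerebellum",
                   "hindbrain")

# Axis-aligned bounding boxes (micrometres) in a common reference frame.
# x: medio-lateral (0-500, midline at 250), y: rostro-caudal, z: dorso-ventral.
region_boxes <- function() {
  b <- rbind(
    pallium    = c(100, 400,   0, 150,  80, 250),
    subpallium = c(150, 350,  60, 180,  20, 120),
    thalamus   = c(150, 350, 180, 280,  60, 200),
    habenula   = c(180, 320, 160, 230, 180, 260),
    pretectum  = c(120, 380, 240, 330, 120, 240),
    tectum     = c( 50, 450, 280, 480, 120, 300),
    tegmentum  = c(150, 350, 320, 440,  40, 160),
    cerebellum = c( 80, 420, 460, 560, 120, 260),
    hindbrain  = c( 80, 420, 520, 900,  20, 220)
  )
  colnames(b) <- c("x0", "x1", "y0", "y1", "z0", "z1")
  b
}

#' Default per-fish ROI counts by region and archetype
#'
#' Echoes the study's anatomical distribution: moderately habituating ROIs
#' concentrated in the tectum, motor ROIs in cerebellum/hindbrain, inhibited
#' ROIs rare.
#' @param scale Multiplier on all counts.
#' @param n_noise Unresponsive (pure-noise) ROIs per region per fish.
#' @return Data frame with `region`, `archetype`, `n`.
#' @export
default_roi_counts <- function(scale = 1, n_noise = 4) {
  counts <- list(
    strong = c(pallium = 6, subpallium = 4, thalamus = 8, habenula = 2,
               pretectum = 10, tectum = 20, tegmentum = 6, cerebellum = 5,
               hindbrain = 10),
    moderate = c(pallium = 5, thalamus = 8, pretectum = 12, tectum = 40,
                 tegmentum = 5, cerebellum = 4, hindbrain = 8),
    weak = c(pallium = 4, thalamus = 6, habenula = 3, pretectum = 8,
             tectum = 25, hindbrain = 6),
    inhibited = c(pallium = 4, thalamus = 3, tectum = 6, hindbrain = 3),
    motor = c(tegmentum = 8, cerebellum = 15, hindbrain = 25),
    auditory = c(thalamus = 3, cerebellum = 5, hindbrain = 12)
  )
  df <- do.call(rbind, lapply(names(counts), function(a) {
    data.frame(region = names(counts[[a]]), archetype = a,
               n = unname(counts[[a]]))
  }))
  if (n_noise > 0) {
    df <- rbind(df, data.frame(region = brain_regions, archetype = "none",
                               n = n_noise))
  }
  df$n <- round(df$n * scale)
  df[df$n > 0, ]
}

#' Cohort configuration
#'
#' @param paradigm Stimulus paradigm label.
#' @param n_fish Number of larvae.
#' @param genotype Single label or per-fish vector (`WT`, `het`, `fmr1`).
#' @param roi_counts Per-fish ROI counts ([default_roi_counts()]).
#' @param archetypes Named list of [archetype_params()].
#' @param shared_drive_sd Weight scale of the slow per-fish common signal
#'   added to every ROI (models brain-wide covariability; scaled up by the
#'   mutant genotype).
#' @param group_noise_sd SD of the white noise shared within spatially
#'   contiguous ~25-ROI microcircuits of one region x archetype group (noise
#'   that does not average out in node means, so node correlations decay as
#'   responses habituate).
#' @param escape_gate_floor Fraction of the strongly habituating response
#'   retained on looms where the fish does not escape (the strong class is
#'   escape-associated).
#' @param sampling_rate Hz.
#' @param spont_bout_rate Spontaneous swim-bout rate, events per second.
#' @export
cohort_config <- function(paradigm = "f20", n_fish = 11, genotype = "WT",
                          roi_counts = default_roi_counts(),
                          archetypes = default_archetypes(),
                          shared_drive_sd = 0.2, group_noise_sd = 0.3,
                          escape_gate_floor = 0.3, sampling_rate = 2,
                          spont_bout_rate = 0.04) {
  bad <- setdiff(roi_counts$region, brain_regions)
  if (length(bad)) stop("unknown region(s): ", paste(bad, collapse = ", "))
  genotype <- rep_len(genotype, n_fish)
  list(paradigm = paradigm, n_fish = n_fish, genotype = genotype,
       roi_counts = roi_counts, archetypes = archetypes,
       shared_drive_sd = shared_drive_sd, group_noise_sd = group_noise_sd,
       escape_gate_floor = escape_gate_floor, sampling_rate = sampling_rate,
       spont_bout_rate = spont_bout_rate)
}

smoothed_noise <- function(n, smooth_frames = 4) {
  x <- stats::rnorm(n + smooth_frames)
  x <- stats::filter(x, rep(1 / smooth_frames, smooth_frames), sides = 1)
  x <- x[!is.na(x)][seq_len(n)]
  as.numeric(scale(x))
}

#' Simulate an imaging cohort
#'
#' Generates, per fish, an ROI table (coordinates inside region bounding
#' boxes, archetype ground truth) and fluorescence traces: archetype-specific
#' loom responses (one-phase decay with post-rest recovery, per-loom jitter,
#' per-ROI amplitude variability), motor responses locked to simulated swim
#' bouts, auditory responses locked to the tone, a slow shared within-fish
#' drive, and white noise. Deterministic given the seed.
#'
#' @param config A [cohort_config()].
#' @param seed Integer master seed.
#' @return List with `rois` (data frame: roi_id, fish_id, genotype, x, y, z,
#'   region, true_archetype), `traces` (ROI x timepoint matrix, raw units),
#'   `train` (the `stimulus_train`), `motor_events` (per-fish bout times, s),
#'   `sampling_rate`.
#' @export
simulate_cohort <- function(config, seed = 1L) {
  train <- build_stimulus_train(config$paradigm, seed = seed)
  sr <- config$sampling_rate
  dur <- train$record_duration
  n_t <- round(dur * sr)
  boxes <- region_boxes()
  kern <- calcium_kernel(sampling_rate = sr)

  roi_list <- list()
  trace_list <- list()
  motor_events <- vector("list", config$n_fish)
  names(motor_events) <- paste0("fish", seq_len(config$n_fish))
  roi_counter <- 0L

  for (f in seq_len(config$n_fish)) {
    set.seed(mix_seed(seed, f))
    gm <- genotype_modifier(config$genotype[f])
    shared <- smoothed_noise(n_t)
    # swim bouts: spontaneous Poisson train plus escape-locked bouts whose
    # probability habituates like the behavioral escape curve
    n_spont <- stats::rpois(1, config$spont_bout_rate * dur)
    bouts <- sort(stats::runif(n_spont, 0, dur - 10))
    esc_p <- habituation_amplitudes(default_escape_params(), train, gm,
                                    jitter = FALSE)
    escapes <- stats::runif(length(esc_p)) < esc_p
    bouts <- sort(c(bouts, train$loom_onsets[escapes] + train$pre_duration + 0.5))
    motor_events[[f]] <- bouts

    counts <- config$roi_counts
    if (length(train$tone_times) == 0) {
      counts <- counts[counts$archetype != "auditory", ]
    }
    n_roi <- sum(counts$n)
    if (n_roi == 0) {
      roi_list[[f]] <- data.frame(
        roi_id = integer(0), fish_id = character(0), genotype = character(0),
        x = numeric(0), y = numeric(0), z = numeric(0),
        region = character(0), true_archetype = character(0)
      )
      trace_list[[f]] <- matrix(0, 0, n_t)
      next
    }
    rows <- counts[rep(seq_len(nrow(counts)), counts$n), c("region", "archetype")]
    xyz <- t(vapply(rows$region, function(rg) {
      b <- boxes[rg, ]
      c(stats::runif(1, b["x0"], b["x1"]), stats::runif(1, b["y0"], b["y1"]),
        stats::runif(1, b["z0"], b["z1"]))
    }, numeric(3)))
    # spatially contiguous microcircuits (~25 ROIs) within each
    # region x archetype group share a trial-noise trace
    micro <- rep(0L, n_roi)
    grp <- paste(rows$region, rows$archetype)
    n_micro <- 0L
    for (g in unique(grp[rows$archetype != "none"])) {
      idx <- which(grp == g)
      k_sub <- max(1L, ceiling(length(idx) / 25))
      sub <- if (k_sub == 1 || length(idx) <= k_sub) rep(1L, length(idx)) else {
        stats::kmeans(xyz[idx, , drop = FALSE], centers = k_sub,
                      nstart = 2, iter.max = 30)$cluster
      }
      micro[idx] <- n_micro + sub
      n_micro <- n_micro + max(sub)
    }
    micro_noise <- if (n_micro > 0) {
      matrix(stats::rnorm(n_micro * n_t, 0, config$group_noise_sd), n_micro, n_t)
    } else matrix(0, 0, n_t)
    tr <- matrix(0, n_roi, n_t)
    for (i in seq_len(n_roi)) {
      a <- rows$archetype[i]
      if (a == "none") {
        base <- numeric(n_t)
        noise_sd <- 0.8
      } else {
        p <- config$archetypes[[a]]
        noise_sd <- p$noise_sd
        roi_gain <- exp(stats::rnorm(1, 0, 0.2))
        if (a == "motor") {
          ev <- bouts
          amp <- rep(p$initial_amplitude * roi_gain, length(ev))
        } else if (a == "auditory") {
          ev <- train$tone_times
          amp <- rep(p$initial_amplitude * roi_gain, length(ev))
        } else {
          ev <- train$loom_onsets + train$pre_duration
          amp <- habituation_amplitudes(p, train, gm,
                                        seed = mix_seed(seed, f, i),
                                        jitter = TRUE) * roi_gain
          if (a == "strong") {
            # the strongly habituating class is escape-associated: its loom
            # response collapses toward a subthreshold visual component on
            # trials where the fish does not escape
            amp <- amp * ifelse(escapes, 1, config$escape_gate_floor)
          }
        }
        base <- convolve_calcium(p$sign * amp, ev, dur, kernel = kern,
                                 sampling_rate = sr, noise_sd = 0)
      }
      w_shared <- abs(stats::rnorm(1, config$shared_drive_sd * gm$shared_scale,
                                   config$shared_drive_sd * gm$shared_scale / 3))
      tr[i, ] <- base + w_shared * shared + stats::rnorm(n_t, 0, noise_sd)
      if (micro[i] > 0) tr[i, ] <- tr[i, ] + micro_noise[micro[i], ]
    }
    rois <- data.frame(
      roi_id = roi_counter + seq_len(n_roi),
      fish_id = paste0("fish", f),
      genotype = config$genotype[f],
      x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
      region = rows$region,
      true_archetype = rows$archetype,
      row.names = NULL
    )
    roi_counter <- roi_counter + n_roi
    roi_list[[f]] <- rois
    trace_list[[f]] <- tr
  }
  rois <- do.call(rbind, roi_list)
  traces <- do.call(rbind, trace_list)
  rownames(traces) <- rois$roi_id
  list(rois = rois, traces = traces, train = train,
       motor_events = motor_events, sampling_rate = sr)
}

#' Simulate a free-swimming behavior cohort
#'
#' Per fish, draws an escape (Bernoulli) at each loom from a genotype- and
#' paradigm-dependent one-phase-decay probability curve, and emits a 1-s
#' binned speed track: escapes insert a burst bin above 30 mm/s inside the
#' loom window; all other bins stay below 30 mm/s (slow background movement
#' with occasional routine bouts).
#'
#' @param n_fish Number of larvae.
#' @param train A `stimulus_train`.
#' @param genotype Single label or per-fish vector.
#' @param escape_params [archetype_params()]-style curve for the escape
#'   probability of the WT reference (defaults depend on the paradigm's ISI:
#'   60-s trains habituate more slowly and recover less).
#' @param seed Integer seed.
#' @return List of behavior tracks; each has `fish_id`, `genotype`, `speeds`
#'   (mm/s per 1-s bin) and `loom_windows` (list of bin-index ranges covering
#'   dot appearance through end of expansion).
#' @export
simulate_behavior_cohort <- function(n_fish, train, genotype = "WT",
                                     escape_params = NULL, seed = 1L) {
  genotype <- rep_len(genotype, n_fish)
  if (is.null(escape_params)) {
    slow_isi <- mean(train$isi_values) > 40
    escape_params <- archetype_params(
      "escape", initial_amplitude = 0.95,
      K = if (slow_isi) 0.8 else 1.0,
      plateau = if (slow_isi) 0.20 else 0.10,
      recovery_fraction = if (slow_isi) 0.25 else 0.6,
      noise_sd = 0
    )
  }
  n_bins <- ceiling(train$record_duration)
  win_len <- train$pre_duration + train$expansion_duration
  windows <- lapply(train$loom_onsets, function(on) {
    seq.int(floor(on) + 1L, min(n_bins, floor(on + win_len) + 1L))
  })
  lapply(seq_len(n_fish), function(f) {
    set.seed(mix_seed(seed, 7, f))
    gm <- genotype_modifier(genotype[f])
    p <- habituation_amplitudes(escape_params, train, gm, jitter = FALSE)
    speeds <- stats::runif(n_bins, 0, 5)
    bout <- stats::runif(n_bins) < 0.08
    speeds[bout] <- stats::runif(sum(bout), 5, 25)
    escaped <- stats::runif(length(p)) < p
    for (l in which(escaped)) {
      b <- sample(windows[[l]], 1)
      speeds[b] <- stats::runif(1, 35, 80)
    }
    structure(list(fish_id = paste0("fish", f), genotype = genotype[f],
                   speeds = speeds, loom_windows = windows),
              class = "behavior_track")
  })
}
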