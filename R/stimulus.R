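#' Loom stimulus trains
#'
#' A loom epoch is a dark disc that appears as a static dot for 1 s, expands
#' over 2 s (fast) or 4 s (slow), holds full size for 2 s, and fades back to
#' white over 9 s. Looms are delivered in blocks of 10 separated by 300 s of
#' rest, with a jittered white-screen inter-stimulus interval (ISI) between
#' consecutive looms: 18/20/22 s for the 20-s paradigms and 54/60/66 s for the
#' 60-s paradigms. Recording starts 30 s before the first onset.
#'
#' @param paradigm One of `"f20"`, `"f60"`, `"s20"`, `"s60"`, `"s20-short"`.
#'   The `f`/`s` prefix selects fast (2 s) or slow (4 s) expansion; the suffix
#'   selects the mean ISI. `"s20-short"` is the two-block (20 loom) variant
#'   used for mutant cohorts.
#' @param seed Integer seed controlling the ISI jitter draw.
#' @return An object of class `stimulus_train`: a list with the paradigm,
#'   block structure, loom onsets (s), per-loom epoch timing, the drawn ISI
#'   values, tone times (s; empty for two-block trains) and the total record
#'   duration implied by the train.
#' @examples
#' tr <- build_stimulus_train("f20", seed = 1)
#' length(tr$loom_onsets)  # 30
#' @export
build_stimulus_train <- function(paradigm, seed = 1L) {
  spec <- paradigm_spec(paradigm)
  set.seed(as.integer(seed))
  n_looms <- spec$n_blocks * spec$looms_per_block
  # ISI = white-screen gap between fade end and the next onset (within block)
  isi <- sample(spec$isi_set, n_looms, replace = TRUE)
  epoch <- spec$pre_duration + spec$expansion_duration +
    spec$hold_duration + spec$fade_duration
  onsets <- numeric(n_looms)
  t <- spec$baseline_duration
  for (i in seq_len(n_looms)) {
    onsets[i] <- t
    gap <- if (i %% spec$looms_per_block == 0) spec$rest_duration else isi[i]
    t <- t + epoch + gap
  }
  # auditory tone: 3 x 1 s pulses, 1 s apart, first one 25 s before loom 21
  tones <- if (spec$n_blocks >= 3) onsets[21] - 25 + c(0, 2, 4) else numeric(0)
  structure(list(
    paradigm = paradigm,
    n_blocks = spec$n_blocks,
    looms_per_block = spec$looms_per_block,
    loom_onsets = onsets,
    pre_duration = spec$pre_duration,
    expansion_duration = spec$expansion_duration,
    hold_duration = spec$hold_duration,
    fade_duration = spec$fade_duration,
    isi_values = isi[seq_len(n_looms - 1)][seq_len(n_looms - 1) %% spec$looms_per_block != 0],
    rest_duration = spec$rest_duration,
    baseline_duration = spec$baseline_duration,
    tone_times = tones,
    record_duration = onsets[n_looms] + epoch + 20
  ), class = "stimulus_train")
}

paradigm_spec <- function(paradigm) {
  base <- list(
    looms_per_block = 10L, pre_duration = 1, hold_duration = 2,
    fade_duration = 9, rest_duration = 300, baseline_duration = 30
  )
  tab <- list(
    "f20" = list(n_blocks = 3L, expansion_duration = 2, isi_set = c(18, 20, 22)),
    "f60" = list(n_blocks = 3L, expansion_duration = 2, isi_set = c(54, 60, 66)),
    "s20" = list(n_blocks = 3L, expansion_duration = 4, isi_set = c(18, 20, 22)),
    "s60" = list(n_blocks = 3L, expansion_duration = 4, isi_set = c(54, 60, 66)),
    "s20-short" = list(n_blocks = 2L, expansion_duration = 4, isi_set = c(18, 20, 22))
  )
  if (!paradigm %in% names(tab)) {
    stop("unknown paradigm '", paradigm, "'; supported: ",
         paste(names(tab), collapse = ", "))
  }
  c(base, tab[[paradigm]])
}

#' Loom epoch duration (dot appearance through end of fade), in seconds
#' @param train A `stimulus_train`.
#' @export
loom_epoch_duration <- function(train) {
  train$pre_duration + train$expansion_duration + train$hold_duration +
    train$fade_duration
}

#' Visual angle of a loom over time
#'
#' The disc subtends a constant minimum angle while static, grows linearly to
#' the maximum angle over the expansion, and stays at the maximum during the
#' hold (and fade, when only luminance changes). The angular range differs
#' between the free-swimming arena (11-90 degrees) and the imaging setup
#' (10-82 degrees).
#'
#' @param train A `stimulus_train`.
#' @param loom_index Loom number within the train.
#' @param context `"behavior"` or `"imaging"`.
#' @param dt Sampling step of the returned curve, seconds.
#' @return Data frame with `time_s` (relative to dot appearance) and
#'   `angle_deg`, covering dot, expansion and hold.
#' @export
loom_angle_profile <- function(train, loom_index, context = c("behavior", "imaging"),
                               dt = 0.1) {
  context <- match.arg(context)
  if (loom_index < 1 || loom_index > length(train$loom_onsets)) {
    stop("loom_index out of range")
  }
  rng <- if (context == "behavior") c(11, 90) else c(10, 82)
  t_end <- train$pre_duration + train$expansion_duration + train$hold_duration
  time_s <- seq(0, t_end, by = dt)
  frac <- pmin(1, pmax(0, (time_s - train$pre_duration) / train$expansion_duration))
  data.frame(time_s = time_s, angle_deg = rng[1] + frac * (rng[2] - rng[1]))
}

#' Per-loom sample windows of a stimulus train
#'
#' Frame index ranges (1-based, inclusive) used to window node traces for the
#' per-loom correlation matrices: from loom onset to 2 s after fade onset.
#' Optionally prepends a pre-loom window of the same length ending immediately
#' before the first onset.
#'
#' @param train A `stimulus_train`.
#' @param sampling_rate Hz.
#' @param include_pre Prepend a baseline window before loom 1.
#' @param window_s Window length in seconds; default onset to fade onset + 2 s.
#' @return List of integer vectors of frame indices, one per (pre-)loom.
#' @export
loom_frame_windows <- function(train, sampling_rate = 2, include_pre = FALSE,
                               window_s = NULL) {
  if (is.null(window_s)) {
    window_s <- train$pre_duration + train$expansion_duration +
      train$hold_duration + 2
  }
  len <- round(window_s * sampling_rate)
  win <- lapply(train$loom_onsets, function(on) {
    start <- floor(on * sampling_rate) + 1L
    seq.int(start, start + len - 1L)
  })
  names(win) <- paste0("loom", seq_along(win))
  if (include_pre) {
    first <- floor(train$loom_onsets[1] * sampling_rate)
    pre <- seq.int(max(1L, first - len + 1L), first)
    win <- c(list(pre = pre), win)
  }
  win
}

#' Per-loom response-scoring windows, onset to end of hold
#' @inheritParams loom_frame_windows
#' @return List of integer frame-index vectors, one per loom.
#' @export
response_frame_windows <- function(train, sampling_rate = 2) {
  loom_frame_windows(
    train, sampling_rate,
    window_s = train$pre_duration + train$expansion_duration + train$hold_duration
  )
}

#' Frames around the looms for regression on long-ISI recordings
#'
#' For 60-s ISI trains most of the record is rest; restricting the ROI
#' regressions to frames around the looms (and the tone) keeps the
#' classification comparable across paradigms.
#'
#' @param train A `stimulus_train`.
#' @param sampling_rate Hz.
#' @param pre_s,post_s Seconds kept before each onset and after the end of
#'   each loom epoch.
#' @return Sorted integer vector of frame indices.
#' @export
loom_trim_frames <- function(train, sampling_rate = 2, pre_s = 6, post_s = 12) {
  n_t <- round(train$record_duration * sampling_rate)
  epoch <- loom_epoch_duration(train)
  events <- c(train$loom_onsets, train$tone_times)
  idx <- unlist(lapply(events, function(on) {
    seq.int(max(1L, floor((on - pre_s) * sampling_rate)),
            min(n_t, ceiling((on + epoch + post_s) * sampling_rate)))
  }))
  sort(unique(c(seq_len(round(train$baseline_duration * sampling_rate)), idx)))
}
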