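#' Save and load the pipeline's data containers
#'
#' All containers round-trip through plain-text formats: ROI tables, traces
#' (flat wide CSV, one row per ROI), behavior tracks (long CSV), stimulus
#' trains and run configurations (JSON), correlation tensors (long CSV with
#' labeled node/loom/fish axes). Reloading reproduces the numeric content
#' exactly up to the 15-significant-digit text representation used on write.
#'
#' @name loomnet-io
NULL

fmt <- function(x) formatC(x, digits = 15, format = "g")

#' @rdname loomnet-io
#' @param cohort A [simulate_cohort()] result.
#' @param dir Directory to write into (created if needed).
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(cohort$rois, file.path(dir, "rois.csv"), row.names = FALSE)
  tr <- data.frame(roi_id = cohort$rois$roi_id,
                   fish_id = cohort$rois$fish_id, cohort$traces,
                   check.names = FALSE)
  names(tr) <- c("roi_id", "fish_id", paste0("t", seq_len(ncol(cohort$traces))))
  utils::write.csv(tr, file.path(dir, "traces.csv"), row.names = FALSE)
  save_stimulus_train(cohort$train, file.path(dir, "train.json"))
  ev <- do.call(rbind, lapply(names(cohort$motor_events), function(f) {
    t <- cohort$motor_events[[f]]
    if (!length(t)) return(NULL)
    data.frame(fish_id = f, time_s = t)
  }))
  if (is.null(ev)) ev <- data.frame(fish_id = character(0), time_s = numeric(0))
  utils::write.csv(ev, file.path(dir, "motor_events.csv"), row.names = FALSE)
  utils::write.csv(data.frame(sampling_rate = cohort$sampling_rate),
                   file.path(dir, "meta.csv"), row.names = FALSE)
  invisible(dir)
}

#' @rdname loomnet-io
#' @export
read_cohort <- function(dir) {
  rois <- utils::read.csv(file.path(dir, "rois.csv"))
  require_columns(rois, c("roi_id", "fish_id", "region"), "rois.csv")
  tr <- utils::read.csv(file.path(dir, "traces.csv"), check.names = FALSE)
  require_columns(tr, c("roi_id", "fish_id"), "traces.csv")
  traces <- as.matrix(tr[, grep("^t\\d+$", names(tr)), drop = FALSE])
  dimnames(traces) <- list(tr$roi_id, NULL)
  ev <- utils::read.csv(file.path(dir, "motor_events.csv"))
  motor_events <- lapply(split(ev$time_s, factor(ev$fish_id, unique(rois$fish_id))),
                         as.numeric)
  meta <- utils::read.csv(file.path(dir, "meta.csv"))
  list(rois = rois, traces = traces,
       train = load_stimulus_train(file.path(dir, "train.json")),
       motor_events = motor_events, sampling_rate = meta$sampling_rate)
}

require_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    stop(what, " is missing column(s): ", paste(missing, collapse = ", "))
  }
  invisible(TRUE)
}

#' @rdname loomnet-io
#' @param train A `stimulus_train`.
#' @param path File path.
#' @export
save_stimulus_train <- function(train, path) {
  jsonlite::write_json(unclass(train), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname loomnet-io
#' @export
load_stimulus_train <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$tone_times <- as.numeric(x$tone_times)
  structure(x, class = "stimulus_train")
}

#' @rdname loomnet-io
#' @param tracks List of `behavior_track`s.
#' @export
write_behavior_tracks <- function(tracks, path) {
  long <- do.call(rbind, lapply(tracks, function(tk) {
    data.frame(fish_id = tk$fish_id, genotype = tk$genotype,
               bin = seq_along(tk$speeds), speed_mm_s = tk$speeds)
  }))
  utils::write.csv(long, path, row.names = FALSE)
  wins <- do.call(rbind, lapply(tracks[[1]]$loom_windows, range))
  utils::write.csv(data.frame(loom = seq_len(nrow(wins)),
                              first_bin = wins[, 1], last_bin = wins[, 2]),
                   sub("\\.csv$", "_windows.csv", path), row.names = FALSE)
  invisible(path)
}

#' @rdname loomnet-io
#' @export
read_behavior_tracks <- function(path) {
  long <- utils::read.csv(path)
  require_columns(long, c("fish_id", "bin", "speed_mm_s"), basename(path))
  wins <- utils::read.csv(sub("\\.csv$", "_windows.csv", path))
  windows <- lapply(seq_len(nrow(wins)), function(l) {
    seq.int(wins$first_bin[l], wins$last_bin[l])
  })
  tracks <- lapply(split(long, factor(long$fish_id, unique(long$fish_id))), function(d) {
    structure(list(fish_id = d$fish_id[1], genotype = d$genotype[1],
                   speeds = d$speed_mm_s, loom_windows = windows),
              class = "behavior_track")
  })
  unname(tracks)
}

#' @rdname loomnet-io
#' @param tensor node x node x loom (x fish) correlation array.
#' @export
write_correlation_tensor <- function(tensor, path) {
  dn <- dimnames(tensor)
  if (length(dim(tensor)) == 3) {
    tensor <- array(tensor, c(dim(tensor), 1),
                    dimnames = c(dn, list("all")))
    dn <- dimnames(tensor)
  }
  d <- dim(tensor)
  idx <- which(slice.index(tensor, 1) < slice.index(tensor, 2))
  coords <- arrayInd(idx, d)
  long <- data.frame(
    node_i = dn[[1]][coords[, 1]], node_j = dn[[2]][coords[, 2]],
    window = dn[[3]][coords[, 3]], fish = dn[[4]][coords[, 4]],
    r = tensor[idx]
  )
  utils::write.csv(long[is.finite(tensor[idx]), ], path, row.names = FALSE)
  invisible(path)
}

#' @rdname loomnet-io
#' @export
read_correlation_tensor <- function(path) {
  long <- utils::read.csv(path)
  require_columns(long, c("node_i", "node_j", "window", "r"), basename(path))
  nodes <- sort(unique(c(long$node_i, long$node_j)))
  wins <- unique(long$window)
  fish <- unique(long$fish)
  out <- array(NA_real_, c(length(nodes), length(nodes), length(wins),
                           length(fish)),
               dimnames = list(nodes, nodes, wins, fish))
  i <- match(long$node_i, nodes)
  j <- match(long$node_j, nodes)
  w <- match(long$window, wins)
  f <- match(long$fish, fish)
  out[cbind(i, j, w, f)] <- long$r
  out[cbind(j, i, w, f)] <- long$r
  for (wi in seq_along(wins)) for (fi in seq_along(fish)) {
    diag(out[, , wi, fi]) <- 1
  }
  out
}

#' @rdname loomnet-io
#' @param cfg A [run_config()].
#' @export
save_run_config <- function(cfg, path) {
  jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname loomnet-io
#' @export
load_run_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg$seed <- as.integer(cfg$seed)
  validate_run_config(cfg)
  cfg
}

#' @rdname loomnet-io
#' @param barcode A [persistent_homology()] barcode.
#' @export
write_barcode <- function(barcode, path) {
  utils::write.csv(as.data.frame(barcode), path, row.names = FALSE)
  # companion persistence-diagram text format: "dim birth death" per line
  writeLines(sprintf("%d %s %s", barcode$dimension, fmt(barcode$birth),
                     fmt(barcode$death)),
             sub("\\.csv$", ".dgm", path))
  invisible(path)
}
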