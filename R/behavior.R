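#' Detect escape responses on a speed track
#'
#' An escape is scored for a loom when at least one 1-s bin inside its window
#' strictly exceeds the speed threshold (30 mm/s, the tracker's burst-swim
#' category boundary).
#'
#' @param track A `behavior_track` (fish_id, speeds, loom_windows).
#' @param threshold_mm_s Speed threshold, strict inequality.
#' @return Logical vector, one element per loom.
#' @export
detect_escapes <- function(track, threshold_mm_s = 30) {
  vapply(track$loom_windows, function(w) {
    if (length(w) == 0) stop("empty loom window")
    if (max(w) > length(track$speeds)) stop("loom window outside track")
    any(track$speeds[w] > threshold_mm_s)
  }, logical(1))
}

#' Escape matrix for a behavior cohort
#' @param tracks List of `behavior_track`s.
#' @param threshold_mm_s Passed to [detect_escapes()].
#' @return Fish x loom logical matrix with a `genotype` attribute.
#' @export
escape_matrix <- function(tracks, threshold_mm_s = 30) {
  m <- t(vapply(tracks, detect_escapes, threshold_mm_s = threshold_mm_s,
                logical(length(tracks[[1]]$loom_windows))))
  rownames(m) <- vapply(tracks, `[[`, character(1), "fish_id")
  attr(m, "genotype") <- vapply(tracks, `[[`, character(1), "genotype")
  m
}

#' Per-loom response probability
#'
#' Number of responding fish divided by the total number of fish, per loom.
#' @param escapes Fish x loom logical matrix.
#' @return Numeric vector in `[0, 1]`, one value per loom.
#' @export
response_probability <- function(escapes) {
  if (is.null(dim(escapes)) || nrow(escapes) < 1) stop("need at least one fish")
  colMeans(escapes)
}

#' Constrained one-phase exponential decay fit
#'
#' Least-squares fit of `y = plateau + (Y0 - plateau) * exp(-K * (x - 1))`
#' with the rate constant constrained positive and, optionally, the plateau
#' fixed to zero. Fitting starts at the first loom of a block (x = 1).
#'
#' @param y Per-loom response values (>= 3 points, finite).
#' @param x Loom indices (default `1..length(y)`).
#' @param plateau_fixed Fix the plateau to 0.
#' @return Object of class `decay_fit`: `Y0`, `K`, `plateau`, `plateau_fixed`,
#'   `sse`, `converged`, `fitted`. Non-convergence is flagged, not silent.
#' @export
fit_one_phase_decay <- function(y, x = seq_along(y), plateau_fixed = FALSE) {
  if (any(!is.finite(y))) stop("non-finite response values")
  if (length(y) < 3) stop("need at least 3 points")
  model_sse <- function(p) {
    f <- p[["plateau"]] + (p[["Y0"]] - p[["plateau"]]) * exp(-p[["K"]] * (x - 1))
    sum((y - f)^2)
  }
  k_starts <- c(0.05, 0.2, 0.5, 1, 2)
  best <- NULL
  for (k0 in k_starts) {
    fit <- tryCatch({
      if (plateau_fixed) {
        minpack.lm::nlsLM(
          y ~ Y0 * exp(-K * (x - 1)),
          start = list(Y0 = y[1], K = k0),
          lower = c(Y0 = -Inf, K = 1e-9),
          control = minpack.lm::nls.lm.control(maxiter = 200)
        )
      } else {
        minpack.lm::nlsLM(
          y ~ plateau + (Y0 - plateau) * exp(-K * (x - 1)),
          start = list(plateau = min(y), Y0 = y[1], K = k0),
          lower = c(plateau = -Inf, Y0 = -Inf, K = 1e-9),
          control = minpack.lm::nls.lm.control(maxiter = 200)
        )
      }
    }, error = function(e) NULL)
    if (is.null(fit)) next
    cf <- stats::coef(fit)
    p <- list(Y0 = cf[["Y0"]], K = cf[["K"]],
              plateau = if (plateau_fixed) 0 else cf[["plateau"]])
    sse <- model_sse(p)
    if (is.null(best) || sse < best$sse - 1e-12) {
      best <- c(p, list(sse = sse, converged = fit$convInfo$isConv))
    }
  }
  if (is.null(best)) {
    best <- list(Y0 = y[1], K = 1e-9, plateau = if (plateau_fixed) 0 else mean(y),
                 sse = model_sse(list(Y0 = y[1], K = 1e-9,
                                      plateau = if (plateau_fixed) 0 else mean(y))),
                 converged = FALSE)
  }
  fitted <- best$plateau + (best$Y0 - best$plateau) * exp(-best$K * (x - 1))
  structure(list(Y0 = best$Y0, K = best$K, plateau = best$plateau,
                 plateau_fixed = plateau_fixed, sse = best$sse,
                 converged = isTRUE(best$converged), at_K_bound = best$K <= 1e-8,
                 fitted = fitted, x = x, y = y),
            class = "decay_fit")
}

#' @export
print.decay_fit <- function(x, ...) {
  cat(sprintf("One-phase decay fit: Y0 = %.4f, K = %.4f, plateau = %.4f%s (SSE %.4g)%s\n",
              x$Y0, x$K, x$plateau, if (x$plateau_fixed) " [fixed]" else "",
              x$sse, if (x$converged) "" else " [not converged]"))
  invisible(x)
}

#' One-sided exact binomial tests of escape counts against a reference group
#'
#' For each loom, tests the test group's responder count against the observed
#' response proportion of the reference group, treated as a fixed null
#' probability. Significance flags use a Bonferroni cutoff
#' `alpha / (n_contrasts * n_looms)`.
#'
#' @param escapes_test,escapes_ref Fish x loom logical matrices with equal
#'   loom counts.
#' @param alternative `"greater"` (test group hyper-responsive) or `"less"`.
#' @param alpha Family-wise error rate.
#' @param n_contrasts Number of group contrasts sharing the correction.
#' @return Data frame: loom, x (test responders), n, p_ref, p_value,
#'   cutoff, significant.
#' @export
per_loom_binomial_tests <- function(escapes_test, escapes_ref,
                                    alternative = c("greater", "less"),
                                    alpha = 0.05, n_contrasts = 1) {
  alternative <- match.arg(alternative)
  if (ncol(escapes_test) != ncol(escapes_ref)) {
    stop("loom counts differ between groups")
  }
  n_looms <- ncol(escapes_test)
  n <- nrow(escapes_test)
  p_ref <- colMeans(escapes_ref)
  x <- colSums(escapes_test)
  pv <- vapply(seq_len(n_looms), function(l) {
    binom_onesided(x[l], n, p_ref[l], alternative)
  }, numeric(1))
  cutoff <- bonferroni_cutoff(alpha, n_contrasts * n_looms)
  data.frame(loom = seq_len(n_looms), x = x, n = n, p_ref = p_ref,
             p_value = pv, cutoff = cutoff, significant = pv < cutoff)
}

# exact one-sided binomial tail, with degenerate null probabilities handled
binom_onesided <- function(x, n, p0, alternative) {
  if (p0 <= 0) {
    if (alternative == "greater") return(if (x == 0) 1 else 0)
    return(1)
  }
  if (p0 >= 1) {
    if (alternative == "greater") return(1)
    return(if (x == n) 1 else 0)
  }
  if (alternative == "greater") {
    stats::pbinom(x - 1, n, p0, lower.tail = FALSE)
  } else {
    stats::pbinom(x, n, p0)
  }
}

#' Bonferroni-corrected significance cutoff
#' @param alpha Family-wise error rate.
#' @param m Number of tests.
#' @return `alpha / m`.
#' @export
bonferroni_cutoff <- function(alpha = 0.05, m) {
  stopifnot(m >= 1)
  alpha / m
}
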