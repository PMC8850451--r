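#' Amplitude-adjusted Fourier transform surrogate
#'
#' Classic three-step AAFT: (1) Gaussianize the series by rank remapping onto
#' sorted Gaussian deviates, (2) randomize Fourier phases of the Gaussian
#' series while enforcing conjugate symmetry (DC kept; for even lengths the
#' Nyquist bin keeps a real coefficient), (3) remap the original sorted values
#' onto the ranks of the phase-randomized series. The surrogate's sorted
#' values therefore equal the original's exactly, while the power spectrum is
#' approximately preserved and phase structure is destroyed.
#'
#' @param x Numeric series (length >= 4). A constant series is returned
#'   unchanged.
#' @param seed Integer seed for the phase draw.
#' @return Surrogate series of the same length.
#' @export
aaft_surrogate <- function(x, seed = 1L) {
  n <- length(x)
  if (stats::sd(x) == 0) return(x)
  if (n < 4) stop("series too short for a surrogate")
  set.seed(as.integer(seed))
  rk <- rank(x, ties.method = "first")
  g <- sort(stats::rnorm(n))[rk]
  gs <- phase_randomize(g)
  sort(x)[rank(gs, ties.method = "first")]
}

phase_randomize <- function(g) {
  n <- length(g)
  fx <- stats::fft(g)
  half <- floor((n - 1) / 2)           # bins with a free phase
  phases <- stats::runif(half, 0, 2 * pi)
  rot <- rep(1 + 0i, n)
  if (half > 0) {
    rot[2:(half + 1)] <- exp(1i * phases)
    rot[n:(n - half + 1)] <- Conj(rot[2:(half + 1)])
  }
  # DC (bin 1) untouched; even n leaves the Nyquist bin (n/2 + 1) untouched
  Re(stats::fft(fx * rot, inverse = TRUE)) / n
}

#' Window-restricted AAFT surrogate
#'
#' Applies [aaft_surrogate()] independently inside each window; samples
#' outside every window are returned unchanged.
#'
#' @param x Numeric series.
#' @param windows List of index vectors.
#' @param seed Integer seed; each window uses a derived sub-seed.
#' @return Surrogate series.
#' @export
windowed_aaft <- function(x, windows, seed = 1L) {
  out <- x
  for (w in seq_along(windows)) {
    idx <- windows[[w]]
    out[idx] <- aaft_surrogate(x[idx], seed = mix_seed(seed, w))
  }
  out
}

#' Temporal null model: permuted layer order
#'
#' Uniformly permutes the order of the layers of a multilayer graph, leaving
#' each layer's content untouched.
#'
#' @param layers List of per-layer matrices (or any list).
#' @param seed Integer seed.
#' @return The list in permuted order, with the permutation as attribute
#'   `perm`.
#' @export
temporal_null <- function(layers, seed = 1L) {
  set.seed(as.integer(seed))
  perm <- sample(length(layers))
  out <- layers[perm]
  attr(out, "perm") <- perm
  out
}
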