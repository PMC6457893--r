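# Shared numerical helpers: the 20 kHz time grid, seeded evaluation, and
# FFT-based convolution/correlation used throughout the package.

#' Simulation time step (ms)
#'
#' All simulations and synthetic recordings use a uniform 0.05 ms grid
#' (20 kHz), matching the digitization rate of the recordings the model
#' emulates. Spike times are snapped to this grid.
#' @export
GRID_DT <- 0.05

#' @keywords internal
snap_to_grid <- function(t, dt = GRID_DT) round(t / dt) * dt

#' @keywords internal
time_to_index <- function(t, dt = GRID_DT) as.integer(round(t / dt)) + 1L

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so that seeded generators are pure
#' functions of their arguments and do not disturb the caller's RNG stream.
#' @param seed integer seed
#' @param expr expression to evaluate
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("`seed` must be a single integer", call. = FALSE)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Derive a stream-specific sub-seed from a master seed
#'
#' Keeps derived seeds inside the 32-bit integer range.
#' @keywords internal
derive_seed <- function(seed, k) {
  as.integer((as.double(seed) * 7919 + as.double(k) * 104729) %% 2147483647)
}

#' Causal convolution of a sampled signal with a kernel
#'
#' Computes `(x * k)[n] = sum_j x[n - j + 1] k[j]` (kernel index starting at
#' lag zero) via FFT, truncated to `length(x)`.
#' @keywords internal
conv_causal <- function(x, k) {
  n <- length(x) + length(k) - 1L
  nfft <- stats::nextn(n, 2)
  xf <- stats::fft(c(x, numeric(nfft - length(x))))
  kf <- stats::fft(c(k, numeric(nfft - length(k))))
  out <- Re(stats::fft(xf * kf, inverse = TRUE)) / nfft
  out[seq_along(x)]
}

#' Correlate a signal with a kernel anchored at each sample
#'
#' Returns `c[m] = sum_j x[m + j - 1] k[j]` for `m = 1..length(x)` (samples
#' of x beyond its end treated as zero). Used for the associative-depression
#' integral of the plasticity rule.
#' @keywords internal
corr_with_kernel <- function(x, k) {
  out <- conv_causal(c(x, numeric(length(k))), rev(k))
  out[seq(length(k), length.out = length(x))]
}

#' @keywords internal
stopifnot_scalar_pos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x <= 0)
    stop(sprintf("`%s` must be a positive scalar", name), call. = FALSE)
}
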