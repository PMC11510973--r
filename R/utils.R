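#' Pink (1/f) noise
#'
#' Generates 1/f-amplitude-shaped Gaussian noise by spectral shaping:
#' white Gaussian noise is transformed to the frequency domain, scaled by
#' 1/sqrt(f), and transformed back. Output is normalized to unit standard
#' deviation.
#'
#' @param n Number of samples.
#' @return Numeric vector of length `n` with sd 1.
#' @export
pink_noise <- function(n) {
  stopifnot(n >= 2)
  x <- stats::rnorm(n)
  X <- stats::fft(x)
  # frequency index magnitude, DC treated like the first bin to avoid 1/0
  k <- c(seq_len(floor(n / 2) + 1) - 1, rev(seq_len(ceiling(n / 2) - 1)))
  k[1] <- 1
  X <- X / sqrt(k)
  out <- Re(stats::fft(X, inverse = TRUE)) / n
  out / stats::sd(out)
}

#' Fractional-sample delay
#'
#' Delays a signal by `tau` seconds using frequency-domain phase rotation
#' (circular boundary). Exact for band-limited stationary signals and used
#' to impose constant phase lags on narrow-band oscillators.
#'
#' @param x Numeric vector.
#' @param tau Delay in seconds (positive delays the signal).
#' @param fs Sampling rate in Hz.
#' @return Delayed signal, same length.
#' @export
frac_delay <- function(x, tau, fs) {
  n <- length(x)
  f <- c(0:floor(n / 2), -(ceiling(n / 2) - 1):-1) / n * fs
  if (n %% 2 == 0) f[n / 2 + 1] <- abs(f[n / 2 + 1])
  Re(stats::fft(stats::fft(x) * exp(-2i * pi * f * tau), inverse = TRUE) / n)
}

#' Fraction of signal power inside a frequency band
#'
#' Periodogram-based band power fraction, used for spectral-placement
#' checks and the relative-band-power node feature.
#'
#' @param x Numeric vector.
#' @param fs Sampling rate in Hz.
#' @param low,high Band edges in Hz.
#' @return Scalar in `[0, 1]`.
#' @export
band_power_fraction <- function(x, fs, low, high) {
  n <- length(x)
  P <- Mod(stats::fft(x - mean(x)))^2
  half <- floor(n / 2)
  freqs <- (0:half) / n * fs
  P <- P[1:(half + 1)]
  tot <- sum(P)
  if (tot <= 0) return(0)
  sum(P[freqs >= low & freqs <= high]) / tot
}

# Total power (variance about the mean) of a signal restricted to a band,
# computed from the one-sided periodogram.
band_power <- function(x, fs, low, high) {
  n <- length(x)
  P <- Mod(stats::fft(x - mean(x)))^2 / n^2
  half <- floor(n / 2)
  freqs <- (0:half) / n * fs
  # fold negative frequencies onto positive ones
  w <- rep(2, half + 1)
  w[1] <- 1
  if (n %% 2 == 0) w[half + 1] <- 1
  sum((w * P[1:(half + 1)])[freqs >= low & freqs <= high])
}

# Evaluate an expression with a temporary RNG seed, restoring (or
# removing) the global seed afterwards so callers' RNG streams are not
# perturbed.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Deterministic child seed derived from a parent seed and a label; keeps
# results below 2^31 so they remain valid R integer seeds.
derive_seed <- function(seed, label) {
  h <- sum(utf8ToInt(paste0(label)) * seq_along(utf8ToInt(paste0(label))))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483587) + 1L
}

# Sample kurtosis (excess) and skewness with the zero-variance convention:
# a constant signal has no shape, both are defined as 0.
safe_kurtosis <- function(x) {
  if (stats::var(x) < .Machine$double.eps) return(0)
  e1071::kurtosis(x, type = 2)
}

safe_skewness <- function(x) {
  if (stats::var(x) < .Machine$double.eps) return(0)
  e1071::skewness(x, type = 2)
}
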