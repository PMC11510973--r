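#' Analytic signal via the Hilbert transform
#'
#' FFT-based analytic signal: negative frequencies are zeroed, positive
#' frequencies doubled, DC and Nyquist kept.
#'
#' @param x Numeric vector.
#' @return Complex vector, same length.
#' @export
analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  h[1] <- 1
  if (n %% 2 == 0) {
    h[n / 2 + 1] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

#' Instantaneous cross-spectrum of two band-limited series
#'
#' S(t) = a_x(t) * conj(a_y(t)), where a is the analytic signal. The
#' leading and trailing 5% of samples are trimmed to suppress Hilbert
#' edge effects.
#'
#' @param x,y Numeric vectors of equal length (>= 64 samples).
#' @param trim Fraction trimmed from each end (default 0.05).
#' @return Complex vector of the retained samples.
#' @export
cross_spectrum_series <- function(x, y, trim = 0.05) {
  if (length(x) != length(y))
    stop("series lengths differ: ", length(x), " vs ", length(y))
  n <- length(x)
  if (n < 64) stop("need at least 64 samples, got ", n)
  S <- analytic_signal(x) * Conj(analytic_signal(y))
  k <- max(1, round(trim * n))
  S[(k + 1):(n - k)]
}

#' Weighted phase lag index of two series
#'
#' WPLI = |mean(Im S(t))| / mean(|Im S(t)|) over the instantaneous
#' cross-spectrum of one segment. Values lie in `[0, 1]`; 1 means the
#' imaginary cross-spectrum keeps a constant sign (consistent non-zero
#' phase lag), 0 means no lag evidence. When mean(|Im S|) < 1e-12 (e.g.
#' identical inputs, whose cross-spectrum is purely real) the index is
#' defined as 0.
#'
#' @param x,y Numeric vectors of equal length.
#' @param n_epochs If > 1, the series are split into that many
#'   non-overlapping epochs, the analytic signal is computed per epoch,
#'   and the expectation runs over all retained epoch samples.
#' @param trim Edge-trim fraction per (epoch) series.
#' @return Scalar in `[0, 1]`.
#' @export
wpli <- function(x, y, n_epochs = 1, trim = 0.05) {
  if (n_epochs > 1) {
    n <- length(x)
    bounds <- floor(seq(0, n, length.out = n_epochs + 1))
    im <- unlist(lapply(seq_len(n_epochs), function(e) {
      idx <- (bounds[e] + 1):bounds[e + 1]
      Im(cross_spectrum_series(x[idx], y[idx], trim = trim))
    }))
  } else {
    im <- Im(cross_spectrum_series(x, y, trim = trim))
  }
  denom <- mean(abs(im))
  if (denom < 1e-12) return(0)
  abs(mean(im)) / denom
}

#' Connectivity matrix
#'
#' Symmetric matrix of pairwise connectivity values in `[0, 1]` with zero
#' diagonal, tagged with channel names, band, and segment id.
#'
#' @param values Symmetric numeric matrix.
#' @param channel_names Channel names (rows/cols of `values`).
#' @param band Band label (`"delta"`..`"beta"`, or `"coe"`).
#' @param segment_id Optional segment identifier.
#' @return A `connectivity_matrix`.
#' @export
connectivity_matrix <- function(values, channel_names, band = NA_character_,
                                segment_id = NA_character_) {
  values <- as.matrix(values)
  if (nrow(values) != ncol(values)) stop("connectivity matrix must be square")
  if (max(abs(values - t(values))) > 1e-12) stop("matrix must be symmetric")
  if (any(diag(values) != 0)) stop("diagonal must be exactly 0")
  if (any(values < 0 | values > 1)) stop("entries must lie in [0, 1]")
  dimnames(values) <- list(channel_names, channel_names)
  structure(list(values = values, channel_names = channel_names,
                 band = band, segment_id = segment_id),
            class = "connectivity_matrix")
}

#' @export
print.connectivity_matrix <- function(x, ...) {
  cat(sprintf("<connectivity_matrix> %d channels, band %s, segment %s\n",
              nrow(x$values), x$band, x$segment_id))
  print(round(x$values, 3))
  invisible(x)
}

#' All-pairs WPLI matrix of a multichannel recording
#'
#' Computes the WPLI for every channel pair of a band-limited recording.
#' The result is symmetric with an exactly zero diagonal (self-coupling is
#' excluded by convention).
#'
#' @param rec A band-limited `recording` with >= 2 channels.
#' @param band Band label stored in the result.
#' @param segment_id Segment identifier stored in the result.
#' @param n_epochs,trim Passed to [wpli()].
#' @return A `connectivity_matrix`.
#' @export
wpli_matrix <- function(rec, band = NA_character_, segment_id = NA_character_,
                        n_epochs = 1, trim = 0.05) {
  N <- nrow(rec$samples)
  if (N < 2) stop("need at least 2 channels")
  n <- ncol(rec$samples)
  k <- max(1, round(trim * n))
  keep <- (k + 1):(n - k)
  a <- t(apply(rec$samples, 1, analytic_signal))
  vals <- matrix(0, N, N)
  for (i in 1:(N - 1)) {
    for (j in (i + 1):N) {
      if (n_epochs > 1) {
        w <- wpli(rec$samples[i, ], rec$samples[j, ], n_epochs = n_epochs,
                  trim = trim)
      } else {
        im <- Im(a[i, keep] * Conj(a[j, keep]))
        denom <- mean(abs(im))
        w <- if (denom < 1e-12) 0 else abs(mean(im)) / denom
      }
      vals[i, j] <- vals[j, i] <- w
    }
  }
  connectivity_matrix(vals, rec$channel_names, band = band,
                      segment_id = segment_id)
}
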