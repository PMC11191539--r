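#' Frequency band definition
#'
#' @param name band name.
#' @param low,high band edges in Hz, `0 < low < high`.
#' @return A `band_definition` list.
#' @export
band_def <- function(name, low, high) {
  if (!(low > 0 && high > low)) stop("band requires 0 < low < high")
  structure(list(name = name, low = low, high = high),
            class = "band_definition")
}

#' Standard analysis bands
#'
#' The four filtering bands used for the connectivity analysis: delta
#' (0.5-4 Hz), theta (4-8 Hz), alpha (8-13 Hz), beta (13-30 Hz).
#'
#' @return Named list of [band_def()]s.
#' @export
default_bands <- function() {
  list(delta = band_def("delta", 0.5, 4), theta = band_def("theta", 4, 8),
       alpha = band_def("alpha", 8, 13), beta = band_def("beta", 13, 30))
}

#' Spectral summary bands
#'
#' Finer tiling used for relative-power time courses: delta, theta, alpha1
#' (8-10 Hz), alpha2 (10-13 Hz), beta, gamma (30-48 Hz; the gamma range is a
#' configuration default, not a published value).
#'
#' @return Named list of [band_def()]s tiling 0.5-48 Hz.
#' @export
spectral_bands <- function() {
  list(delta = band_def("delta", 0.5, 4), theta = band_def("theta", 4, 8),
       alpha1 = band_def("alpha1", 8, 10), alpha2 = band_def("alpha2", 10, 13),
       beta = band_def("beta", 13, 30), gamma = band_def("gamma", 30, 48))
}

#' Zero-phase band-pass filter
#'
#' Frequency-domain masking: the FFT is multiplied by a symmetric mask that
#' is 1 inside `[low, high]`, 0 outside, with one-bin raised-cosine edges,
#' then inverted. Deterministic, exactly zero-phase, no filter-order choice;
#' in-band sinusoids pass with unit gain and out-of-band components are
#' suppressed to numerical zero.
#'
#' @param x numeric series (length >= 64) or channels-by-samples matrix.
#' @param band a [band_def()] (or `low`/`high` given separately).
#' @param fs sample rate, Hz.
#' @param low,high band edges, Hz (alternative to `band`).
#' @return Filtered series (or matrix), same shape as `x`.
#' @export
bandpass <- function(x, band = NULL, fs, low = band$low, high = band$high) {
  if (is.matrix(x))
    return(t(apply(x, 1L, bandpass, fs = fs, low = low, high = high)))
  n <- length(x)
  if (n < 64L) stop("series too short to filter (need >= 64 samples)")
  if (high >= fs / 2) stop("band outside Nyquist range")
  f <- (seq_len(n) - 1) * fs / n
  f <- pmin(f, fs - f)  # two-sided |frequency|
  df <- fs / n
  mask <- numeric(n)
  mask[f >= low & f <= high] <- 1
  lo_edge <- f >= low - df & f < low
  mask[lo_edge] <- 0.5 * (1 + cos(pi * (low - f[lo_edge]) / df))
  hi_edge <- f > high & f <= high + df
  mask[hi_edge] <- 0.5 * (1 + cos(pi * (f[hi_edge] - high) / df))
  Re(stats::fft(stats::fft(x) * mask, inverse = TRUE)) / n
}

#' Analytic signal via the Hilbert transform
#'
#' One-sided-spectrum construction: Fourier transform, zero the negative
#' frequencies (doubling the positive ones), inverse transform. Returns the
#' analytic signal `z = x + i*H(x) = A exp(i*phi)` decomposed into real and
#' imaginary parts, instantaneous phase (radians, in (-pi, pi]) and
#' amplitude envelope.
#'
#' @param x real-valued numeric series.
#' @return An `analytic_signal` list: `real`, `imag`, `phase`, `envelope`,
#'   plus the complex series `z`.
#' @export
analytic_signal <- function(x) {
  n <- length(x)
  if (stats::sd(x) == 0)
    stop("constant series: instantaneous phase undefined")
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1L] <- 1; h[2:(n / 2)] <- 2; h[n / 2 + 1L] <- 1
  } else {
    h[1L] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  z <- stats::fft(X * h, inverse = TRUE) / n
  structure(list(real = Re(z), imag = Im(z),
                 phase = atan2(Im(z), Re(z)), envelope = Mod(z), z = z),
            class = "analytic_signal")
}

# one-sided periodogram; x vector or channels-by-samples matrix (averaged)
periodogram <- function(x, fs) {
  if (is.matrix(x)) {
    per <- NULL
    for (i in seq_len(nrow(x))) {
      p <- periodogram(x[i, ], fs)
      per <- if (is.null(per)) p$power else per + p$power
    }
    return(list(freq = p$freq, power = per / nrow(x)))
  }
  n <- length(x)
  P <- Mod(stats::fft(x))^2 / n
  k <- seq_len(floor(n / 2) + 1L)
  list(freq = (k - 1) * fs / n, power = P[k])
}

#' Relative band power
#'
#' Fraction of periodogram power in each band relative to the total power in
#' `total_range`, with bins assigned to half-open intervals `(low, high]` so
#' that bands tiling the range partition the bins exactly.
#'
#' @param x numeric series or channels-by-samples matrix (channel-averaged
#'   spectrum).
#' @param fs sample rate, Hz.
#' @param bands list of [band_def()]s (default [spectral_bands()]).
#' @param total_range numeric `c(f_lo, f_hi)` normalization range, Hz.
#' @return Named numeric vector of band fractions.
#' @export
relative_band_power <- function(x, fs, bands = spectral_bands(),
                                total_range = c(0.5, 48)) {
  per <- periodogram(x, fs)
  in_tot <- per$freq > total_range[1L] & per$freq <= total_range[2L]
  tot <- sum(per$power[in_tot])
  if (tot <= 0) stop("zero total power in range")
  out <- vapply(bands, function(b) {
    if (b$low < total_range[1L] - 1e-9 || b$high > total_range[2L] + 1e-9)
      stop("band ", b$name, " outside total_range")
    sum(per$power[per$freq > b$low & per$freq <= b$high]) / tot
  }, numeric(1))
  names(out) <- vapply(bands, `[[`, character(1), "name")
  out
}

#' Median (and peak) frequency
#'
#' Frequency below which half of the in-range periodogram power lies, with
#' linear interpolation of the cumulative power between bin centers (the
#' cumulative value at a bin center counts half that bin's power, so a pure
#' tone returns its own bin frequency).
#'
#' @param x numeric series or channels-by-samples matrix.
#' @param fs sample rate, Hz.
#' @param range numeric `c(f_lo, f_hi)`, Hz.
#' @return Median frequency in Hz; the spectral peak frequency is attached
#'   as attribute `"peak"`.
#' @export
median_frequency <- function(x, fs, range = c(0.5, 48)) {
  per <- periodogram(x, fs)
  sel <- per$freq > range[1L] & per$freq <= range[2L]
  f <- per$freq[sel]
  p <- per$power[sel]
  tot <- sum(p)
  if (tot <= 0) stop("zero power in range")
  cum <- (cumsum(p) - p / 2) / tot  # midpoint convention
  nz <- which(p > max(p) * 1e-12)   # interpolate through power-carrying bins
  med <- if (length(nz) == 1L) f[nz] else
    stats::approx(cum[nz], f[nz], xout = 0.5, rule = 2, ties = "ordered")$y
  structure(med, peak = f[which.max(p)])
}
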