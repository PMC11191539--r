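#' Amplitude envelope correlation (AEC / AECc)
#'
#' Pearson correlation of the Hilbert amplitude envelopes of two
#' band-filtered series. With `corrected = TRUE` (AECc) the series are
#' pairwise orthogonalized first: the instantaneous least-squares projection
#' of one signal on the other is removed before the envelope of the residual
#' is correlated with the envelope of the reference, the two directions are
#' averaged. A numerically null residual (pure volume conduction,
#' `y = a*x`) contributes 0 by convention.
#'
#' @param x,y equal-length band-filtered numeric series.
#' @param corrected logical; leakage-corrected variant.
#' @return Correlation value in `[-1, 1]`.
#' @export
aec <- function(x, y, corrected = FALSE) {
  stopifnot(length(x) == length(y))
  zx <- analytic_signal(x)$z
  zy <- analytic_signal(y)$z
  if (!corrected) {
    ex <- Mod(zx); ey <- Mod(zy)
    if (stats::sd(ex) == 0 || stats::sd(ey) == 0)
      stop("zero-variance envelope")
    return(stats::cor(ex, ey))
  }
  one_dir <- function(zx, zy, x, y) {
    beta <- sum(x * y) / sum(x * x)
    res <- zy - beta * zx  # Hilbert transform is linear
    if (sum(Re(res)^2) < 1e-20 * sum(y^2)) return(0)
    r <- stats::cor(Mod(zx), Mod(res))
    if (is.na(r)) 0 else r
  }
  (one_dir(zx, zy, x, y) + one_dir(zy, zx, y, x)) / 2
}

#' Phase lag index (PLI)
#'
#' Absolute time average of the sign of the sine of the instantaneous phase
#' difference; `sign(0)` contributes 0 (neither lead nor lag), so zero-lag
#' (volume-conducted) coupling yields 0 and a constant nonzero lag yields 1.
#'
#' @param phase_x,phase_y instantaneous phase series (radians) from the same
#'   band and epoch.
#' @return Value in `[0, 1]`.
#' @export
pli <- function(phase_x, phase_y) {
  stopifnot(length(phase_x) == length(phase_y))
  abs(mean(sign_eps(sin(phase_x - phase_y))))
}

# signum with a numerical dead zone: |s| below 1e-12 (phase differences at
# floating-point rounding level, e.g. exact scale copies) counts as zero lag
sign_eps <- function(s, eps = 1e-12) {
  (s > eps) - (s < -eps)
}

#' Phase lag time (PLT)
#'
#' Persistence of phase lead/lag relations: sign changes of
#' `sin(phase_x - phase_y)` across consecutive samples are detected (zero
#' samples carry the preceding nonzero sign), `T` is the mean duration in
#' seconds of the intervals they delimit - boundary-truncated intervals at
#' the epoch edges included, so a series with no sign change gives `T` equal
#' to the full epoch duration - and `PLT = 1 - exp(-T)`. An identically
#' zero phase difference (volume conduction) returns 0.
#'
#' @param phase_x,phase_y instantaneous phase series (radians).
#' @param fs sample rate, Hz.
#' @param boundary `"truncated"` (default) counts the partial first/last
#'   intervals; `"complete"` averages only full intervals (falling back to
#'   the epoch duration when there are fewer than two sign changes).
#' @return Value in `[0, 1)`.
#' @export
plt <- function(phase_x, phase_y, fs,
                boundary = c("truncated", "complete")) {
  boundary <- match.arg(boundary)
  stopifnot(length(phase_x) == length(phase_y))
  s <- sign_eps(sin(phase_x - phase_y))
  nz <- s[s != 0]
  if (length(nz) == 0L) return(0)
  changes <- sum(diff(nz) != 0)
  m <- length(s)
  Tbar <- if (boundary == "truncated" || changes < 2L) {
    (m / fs) / (changes + 1L)
  } else {
    pos <- which(s != 0)[c(FALSE, diff(nz) != 0)]  # sample after each change
    mean(diff(pos)) / fs
  }
  1 - exp(-Tbar)
}

# lexicographic list of all permutations of 1..n
perm_table <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- perm_table(n - 1L)
  out <- NULL
  for (k in seq_len(n)) {
    blk <- cbind(k, sub + (sub >= k))
    out <- rbind(out, blk)
  }
  unname(out)
}

# map each time point to its ordinal pattern code (1..n!), ranking the n
# lagged amplitudes from highest (rank 1) to lowest (rank n); ties broken
# in favour of the earlier sample (equivalent to rank(-v, ties = "first")).
# Ranks are computed by vectorized pairwise comparison across all windows.
ordinal_codes <- function(x, n = 4L, tau = 1L) {
  m <- length(x) - (n - 1L) * tau
  if (m < 1L) stop("series too short for pattern length ", n, " at lag ", tau)
  lagmat <- sapply(seq_len(n) - 1L, function(k) x[seq_len(m) + k * tau])
  if (m == 1L) lagmat <- matrix(lagmat, 1L)
  key_w <- n^(seq_len(n) - 1)
  acc <- numeric(m)  # positional key of the rank vector, built column-wise
  for (i in seq_len(n)) {
    r <- rep(0, m)  # rank_i - 1
    for (j in seq_len(n)) {
      if (j == i) next
      r <- r + (lagmat[, j] > lagmat[, i]) +
        (j < i) * (lagmat[, j] == lagmat[, i])
    }
    acc <- acc + r * key_w[i]
  }
  perms <- perm_table(n)
  key <- (perms - 1) %*% key_w
  as.integer(match(acc, key))
}

# code of the amplitude-reversed pattern (ranks r -> n+1-r) for each code
reversal_map <- function(n = 4L) {
  perms <- perm_table(n)
  key <- (perms - 1) %*% (n^(seq_len(n) - 1))
  rev <- n + 1L - perms
  as.integer(match((rev - 1) %*% (n^(seq_len(n) - 1)), key))
}

#' Joint permutation entropy (JPE)
#'
#' Both series are mapped to ordinal patterns of length `n` at lag `tau`
#' (amplitudes ranked from highest = 1 to lowest = n). The joint histogram
#' of co-occurring pattern pairs is formed, excluding symmetric
#' (`pattern_x == pattern_y`) and anti-symmetric (`pattern_y` equal to the
#' amplitude reversal of `pattern_x`) pairs to suppress volume-conduction
#' artifacts. `H` is the Shannon entropy (natural log) of the remaining
#' histogram and the returned value is `1 - H / log((n! - 1)^2)`, so the
#' measure increases with coupling strength. `literal = TRUE` returns the
#' raw sign convention `-H / log((n! - 1)^2)` instead.
#'
#' @param x,y equal-length numeric series (band-filtered amplitudes).
#' @param n pattern length (default 4).
#' @param tau time lag in samples (default 1).
#' @param literal logical; printed-formula sign convention.
#' @return Value in `[0, 1]` (default convention). If every pattern pair is
#'   excluded (e.g. `y` identical to `x`), returns 1 with attribute
#'   `degenerate = TRUE`.
#' @export
jpe <- function(x, y, n = 4L, tau = 1L, literal = FALSE) {
  stopifnot(length(x) == length(y), n >= 2L, tau >= 1L)
  cx <- ordinal_codes(x, n, tau)
  cy <- ordinal_codes(y, n, tau)
  rmap <- reversal_map(n)
  keep <- cy != cx & cy != rmap[cx]
  hmax <- jpe_norm_constant(n)
  if (!any(keep)) return(structure(1, degenerate = TRUE))
  npat <- factorial(n)
  counts <- tabulate((cx[keep] - 1L) * npat + cy[keep], nbins = npat^2)
  p <- counts[counts > 0] / sum(counts)
  H <- -sum(p * log(p))
  if (literal) -H / hmax else 1 - H / hmax
}

#' JPE normalization constant
#'
#' `log((n! - 1)^2)`, the entropy maximum used to normalize the joint
#' permutation entropy (`log 529` for `n = 4`).
#'
#' @param n pattern length.
#' @return Natural-log normalization constant.
#' @export
jpe_norm_constant <- function(n = 4L) {
  log((factorial(n) - 1)^2)
}

#' Pairwise functional connectivity matrix for one epoch
#'
#' Band-filters the multichannel signals, derives the analytic signal where
#' needed, trims `trim` of the samples at each epoch edge (Hilbert edge
#' artifacts), and evaluates the requested measure on all unordered channel
#' pairs. The heavy pairwise loops run in compiled code; `use_cpp = FALSE`
#' selects the plain-R per-pair path ([aec()], [pli()], [plt()], [jpe()]),
#' which the compiled path matches exactly.
#'
#' @param signals channels-by-samples numeric matrix (>= 2 channels).
#' @param measure one of `"AEC"`, `"AECc"`, `"PLI"`, `"PLT"`, `"JPE"`.
#' @param band a [band_def()].
#' @param fs sample rate, Hz.
#' @param epoch_index epoch number carried in the result.
#' @param trim fraction of samples discarded at each edge after filtering
#'   (default 0.01).
#' @param jpe_n,jpe_tau ordinal-pattern configuration for JPE.
#' @param labels optional channel labels.
#' @param use_cpp use the compiled pairwise kernels.
#' @return An `fc_matrix` object: `values` (`N x N` symmetric, zero
#'   diagonal), `measure`, `band`, `epoch_index`, `labels`.
#' @export
fc_matrix <- function(signals, measure = c("AECc", "AEC", "PLI", "PLT", "JPE"),
                      band, fs, epoch_index = 1L, trim = 0.01,
                      jpe_n = 4L, jpe_tau = 1L, labels = NULL,
                      use_cpp = TRUE) {
  measure <- match.arg(measure)
  if (!is.matrix(signals) || nrow(signals) < 2L)
    stop("need a channels-by-samples matrix with >= 2 channels")
  n <- nrow(signals)
  if (is.null(labels)) labels <- rownames(signals)
  if (is.null(labels)) labels <- paste0("ROI_", seq_len(n))
  filt <- bandpass(signals, fs = fs, low = band$low, high = band$high)
  ntrim <- floor(trim * ncol(filt))
  keep <- seq.int(ntrim + 1L, ncol(filt) - ntrim)
  vals <- if (measure == "JPE") {
    fx <- filt[, keep, drop = FALSE]
    if (use_cpp) {
      codes <- t(apply(fx, 1L, ordinal_codes, n = jpe_n, tau = jpe_tau))
      jpe_all_pairs_cpp(codes, reversal_map(jpe_n), factorial(jpe_n),
                        jpe_norm_constant(jpe_n), FALSE)
    } else pairwise(fx, function(a, b) jpe(a, b, jpe_n, jpe_tau))
  } else {
    zs <- lapply(seq_len(n), function(i) analytic_signal(filt[i, ])$z[keep])
    if (measure %in% c("AEC", "AECc")) {
      zr <- do.call(rbind, lapply(zs, Re))
      zi <- do.call(rbind, lapply(zs, Im))
      if (use_cpp) aec_all_pairs_cpp(zr, zi, measure == "AECc")
      else pairwise_z(zr, zi, function(x, y, zx, zy)
        aec_on_analytic(zx, zy, x, y, measure == "AECc"))
    } else {
      ph <- do.call(rbind, lapply(zs, function(z) atan2(Im(z), Re(z))))
      if (use_cpp) {
        pp <- pli_plt_all_pairs_cpp(ph, fs)
        if (measure == "PLI") pp$pli else pp$plt
      } else if (measure == "PLI") {
        pairwise(ph, pli)
      } else {
        pairwise(ph, function(a, b) plt(a, b, fs))
      }
    }
  }
  dimnames(vals) <- list(labels, labels)
  diag(vals) <- 0
  structure(list(values = vals, measure = measure, band = band,
                 epoch_index = epoch_index, labels = labels),
            class = "fc_matrix")
}

# apply f to all unordered row pairs of m; returns symmetric matrix
pairwise <- function(m, f) {
  n <- nrow(m)
  out <- matrix(0, n, n)
  for (i in seq_len(n - 1L))
    for (j in seq.int(i + 1L, n)) {
      v <- f(m[i, ], m[j, ])
      out[i, j] <- out[j, i] <- as.numeric(v)
    }
  out
}

pairwise_z <- function(zr, zi, f) {
  n <- nrow(zr)
  out <- matrix(0, n, n)
  for (i in seq_len(n - 1L))
    for (j in seq.int(i + 1L, n)) {
      v <- f(zr[i, ], zr[j, ], complex(real = zr[i, ], imaginary = zi[i, ]),
             complex(real = zr[j, ], imaginary = zi[j, ]))
      out[i, j] <- out[j, i] <- as.numeric(v)
    }
  out
}

# AEC/AECc on precomputed analytic signals (shared by the R fallback path)
aec_on_analytic <- function(zx, zy, x, y, corrected) {
  if (!corrected) return(stats::cor(Mod(zx), Mod(zy)))
  one_dir <- function(zx, zy, x, y) {
    beta <- sum(x * y) / sum(x * x)
    res <- zy - beta * zx
    if (sum(Re(res)^2) < 1e-20 * sum(y^2)) return(0)
    r <- stats::cor(Mod(zx), Mod(res))
    if (is.na(r)) 0 else r
  }
  (one_dir(zx, zy, x, y) + one_dir(zy, zx, y, x)) / 2
}

#' @export
print.fc_matrix <- function(x, ...) {
  cat(sprintf("<fc_matrix> %s, %s band (%g-%g Hz), epoch %d, %d x %d\n",
              x$measure, x$band$name, x$band$low, x$band$high,
              x$epoch_index, nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Per-ROI mean connectivity
#'
#' Mean of each row's off-diagonal entries of an FC matrix.
#'
#' @param m an [fc_matrix()] or plain symmetric matrix.
#' @return Named numeric vector, one value per ROI.
#' @export
roi_means <- function(m) {
  v <- if (inherits(m, "fc_matrix")) m$values else m
  n <- nrow(v)
  (rowSums(v) - diag(v)) / (n - 1)
}

#' Whole-brain mean connectivity
#'
#' Mean over all off-diagonal entries (equivalently, the mean of the per-ROI
#' means).
#'
#' @param m an [fc_matrix()] or plain symmetric matrix.
#' @return Scalar mean.
#' @export
whole_brain_mean <- function(m) {
  v <- if (inherits(m, "fc_matrix")) m$values else m
  mean(v[upper.tri(v)])
}
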