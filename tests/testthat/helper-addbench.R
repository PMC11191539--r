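# Shared fixtures and independent oracles. Oracles are deliberately naive
# (per-sample loops, textbook formulas) and never call the code paths they
# check.

tiny_net <- function(n = 6L, seed = 3L, density = 0.5) {
  generate_surrogate(n, density, "erdos_renyi", seed = seed)
}

fast_params <- function(...) {
  nm_params(epoch_len = 256, transient_len = 200, ...)
}

# --- signal fixtures -------------------------------------------------------

sine <- function(freq, fs = 500, n = 4096, phase = 0, amp = 1) {
  amp * cos(2 * pi * freq * (seq_len(n) - 1) / fs + phase)
}

# --- oracles ---------------------------------------------------------------

# discrete Hilbert transform by brute-force DFT phase shift: -i for
# positive frequencies, +i for negative, 0 at DC/Nyquist
oracle_analytic <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  k <- 0:(n - 1)
  mult <- ifelse(k == 0 | (n %% 2 == 0 & k == n / 2), 0 + 0i,
                 ifelse(k < n / 2, 0 - 1i, 0 + 1i))
  xt <- Re(stats::fft(X * mult, inverse = TRUE) / n)
  complex(real = x, imaginary = xt)
}

# per-sample loop PLI
oracle_pli <- function(px, py) {
  s <- 0
  for (k in seq_along(px)) {
    d <- sin(px[k] - py[k])
    s <- s + if (d > 1e-12) 1 else if (d < -1e-12) -1 else 0
  }
  abs(s / length(px))
}

# per-sample loop PLT (truncated-interval convention)
oracle_plt <- function(px, py, fs) {
  sg <- integer(0)
  for (k in seq_along(px)) {
    d <- sin(px[k] - py[k])
    sg <- c(sg, if (d > 1e-12) 1L else if (d < -1e-12) -1L else 0L)
  }
  nz <- sg[sg != 0L]
  if (length(nz) == 0L) return(0)
  ch <- 0L
  for (k in seq_along(nz)[-1]) if (nz[k] != nz[k - 1]) ch <- ch + 1L
  Tbar <- (length(sg) / fs) / (ch + 1L)
  1 - exp(-Tbar)
}

# ordinal pattern of one window, rank 1 = highest, ties to earlier sample
oracle_pattern <- function(v) rank(-v, ties.method = "first")

# joint permutation entropy by explicit window loops
oracle_jpe <- function(x, y, n = 4L, tau = 1L) {
  m <- length(x) - (n - 1L) * tau
  tab <- list()
  for (t in seq_len(m)) {
    ix <- x[t + (0:(n - 1)) * tau]
    iy <- y[t + (0:(n - 1)) * tau]
    rx <- oracle_pattern(ix)
    ry <- oracle_pattern(iy)
    if (identical(rx, ry)) next                  # symmetric
    if (identical(as.integer(n + 1 - rx), as.integer(ry))) next  # anti
    key <- paste(c(rx, ry), collapse = ",")
    tab[[key]] <- (tab[[key]] %||% 0) + 1
  }
  cnt <- unlist(tab)
  if (is.null(cnt)) return(structure(1, degenerate = TRUE))
  p <- cnt / sum(cnt)
  1 - (-sum(p * log(p))) / log((factorial(n) - 1)^2)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# AEC by independent construction (envelopes via oracle_analytic)
oracle_aec <- function(x, y, corrected = FALSE) {
  if (!corrected)
    return(stats::cor(Mod(oracle_analytic(x)), Mod(oracle_analytic(y))))
  dir1 <- {
    res <- y - sum(x * y) / sum(x * x) * x
    if (sum(res^2) < 1e-20 * sum(y^2)) 0
    else stats::cor(Mod(oracle_analytic(x)), Mod(oracle_analytic(res)))
  }
  dir2 <- {
    res <- x - sum(x * y) / sum(y * y) * y
    if (sum(res^2) < 1e-20 * sum(x^2)) 0
    else stats::cor(Mod(oracle_analytic(y)), Mod(oracle_analytic(res)))
  }
  (dir1 + dir2) / 2
}

# two coupled noisy oscillators for coupling-sweep properties: y mixes a
# lagged copy of x's narrowband driver, weight = coupling
coupled_pair <- function(coupling, n = 2048, fs = 500, seed = 1) {
  set.seed(seed)
  drv <- sine(10, fs, n + 8) + 0.3 * rnorm(n + 8)
  x <- drv[1:n] + 0.5 * rnorm(n)
  y <- coupling * drv[5:(n + 4)] + 0.5 * rnorm(n)
  list(x = x, y = y)
}
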