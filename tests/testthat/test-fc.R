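# band-filtered noise fixture shared across measure tests
filtered_noise <- function(n = 1024, fs = 500, low = 8, high = 13,
                           seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  bandpass(rnorm(n), fs = fs, low = low, high = high)
}

test_that("AEC analytic cases: self-correlation and volume-conduction null", {
  x <- filtered_noise(seed = 1)
  expect_equal(aec(x, x), 1)
  expect_equal(aec(x, 0.5 * x, corrected = TRUE), 0)  # orthogonalized null
  # independent series: AECc near zero within a Monte-Carlo band (broadband
  # noise; narrowband envelopes have far fewer effective samples)
  vals <- sapply(1:20, function(k) {
    aec(filtered_noise(low = 1, high = 240, seed = 100 + k),
        filtered_noise(low = 1, high = 240, seed = 200 + k),
        corrected = TRUE)
  })
  expect_lt(max(abs(vals)), 3 * 3 / sqrt(1024))
  expect_lt(abs(mean(vals)), 0.02)
})

test_that("AEC and AECc match the brute-force oracle to 1e-10", {
  for (k in 1:5) {
    x <- filtered_noise(seed = 300 + k)
    y <- 0.4 * x + filtered_noise(seed = 400 + k)
    expect_equal(aec(x, y), oracle_aec(x, y), tolerance = 1e-10)
    expect_equal(aec(x, y, corrected = TRUE),
                 oracle_aec(x, y, corrected = TRUE), tolerance = 1e-10)
  }
})

test_that("PLI analytic cases and oracle equality", {
  n <- 1024
  ph <- runif(n, -pi, pi)
  expect_equal(pli(ph + pi / 2, ph), 1)       # constant lag
  expect_equal(pli(ph, ph), 0)                # identical phases, sign(0)=0
  set.seed(10)
  for (k in 1:5) {
    px <- runif(n, -pi, pi)
    py <- runif(n, -pi, pi)
    expect_identical(pli(px, py), oracle_pli(px, py))
  }
  # independent phases: near 0 with SD ~ 1/sqrt(n)
  set.seed(11)
  v <- replicate(50, pli(runif(4096, -pi, pi), runif(4096, -pi, pi)))
  expect_lt(abs(mean(v)) , 0.02)
  expect_equal(sd(v), 1 / sqrt(4096), tolerance = 0.4)
})

test_that("PLT closed forms, volume-conduction zero, and oracle equality", {
  fs <- 500
  n <- 4096  # 8.192 s epoch
  ph <- cumsum(rep(0.1, n))
  expect_equal(plt(ph + pi / 4, ph, fs), 1 - exp(-8.192))  # no sign change
  expect_equal(plt(ph, ph, fs), 0)                          # identical
  alt <- ph + rep(c(0.1, -0.1), n / 2)                      # flips each sample
  expect_equal(plt(alt, ph, fs), 1 - exp(-0.002))
  set.seed(12)
  for (k in 1:5) {
    px <- cumsum(rnorm(n, 0.05, 0.2))
    py <- cumsum(rnorm(n, 0.05, 0.2))
    expect_equal(plt(px, py, fs), oracle_plt(px, py, fs))
  }
  # complete-interval convention falls back gracefully and stays in [0,1)
  expect_gte(plt(px, py, fs, boundary = "complete"), 0)
  expect_lt(plt(px, py, fs, boundary = "complete"), 1)
})

test_that("JPE normalization, degenerate case, noise floor, coupling", {
  expect_equal(jpe_norm_constant(4), log(529))
  x <- filtered_noise(4096, seed = 20)
  d <- jpe(x, x)
  expect_equal(as.numeric(d), 1)
  expect_true(attr(d, "degenerate"))
  # anti-symmetric (sign-flipped) channel is also fully excluded
  expect_equal(as.numeric(jpe(x, -x)), 1)
  # independent white noise: entropy near maximum, JPE < 0.05
  set.seed(21)
  v <- replicate(10, jpe(rnorm(4096), rnorm(4096)))
  expect_lt(max(v), 0.05)
  expect_gt(min(v), 0)
  # a lagged copy is detected as coupling
  set.seed(22)
  a <- rnorm(4096)
  b <- c(a[-1], rnorm(1))
  expect_gt(jpe(a, b), max(v))
  # literal printed convention is the negative-sign variant
  expect_equal(jpe(a, b, literal = TRUE), (jpe(a, b) - 1))
})

test_that("JPE matches the window-loop oracle exactly", {
  set.seed(23)
  for (k in 1:4) {
    x <- rnorm(400)
    y <- 0.6 * c(x[-(1:2)], rnorm(2)) + 0.4 * rnorm(400)
    expect_equal(jpe(x, y), oracle_jpe(x, y), tolerance = 1e-12)
    expect_equal(jpe(x, y, n = 3, tau = 2), oracle_jpe(x, y, n = 3, tau = 2),
                 tolerance = 1e-12)
  }
})

test_that("all measures are symmetric under channel swap", {
  set.seed(24)
  x <- filtered_noise(2048, seed = 30)
  y <- 0.5 * x + filtered_noise(2048, seed = 31)
  px <- analytic_signal(x)$phase
  py <- analytic_signal(y)$phase
  expect_equal(aec(x, y, corrected = TRUE), aec(y, x, corrected = TRUE))
  expect_identical(pli(px, py), pli(py, px))
  expect_identical(plt(px, py, 500), plt(py, px, 500))
  expect_equal(jpe(x, y), jpe(y, x), tolerance = 1e-12)
})

test_that("volume-conduction null holds for y = a*x + b", {
  x <- filtered_noise(2048, seed = 33)
  y <- 2.3 * x  # filtered signals are zero-mean; scale-only copy
  px <- analytic_signal(x)$phase
  py <- analytic_signal(y)$phase
  expect_equal(pli(px, py), 0)
  expect_equal(plt(px, py, 500), 0)
  expect_equal(aec(x, y, corrected = TRUE), 0)
  expect_equal(as.numeric(jpe(x, y)), 1)  # all pairs excluded
})

test_that("PLI, PLT, JPE increase with coupling strength", {
  cs <- c(0, 0.25, 0.5, 0.75, 1)
  res <- sapply(cs, function(cc) {
    vals <- sapply(1:8, function(s) {
      p <- coupled_pair(cc, seed = 500 + s)
      fx <- bandpass(p$x, fs = 500, low = 8, high = 13)
      fy <- bandpass(p$y, fs = 500, low = 8, high = 13)
      px <- analytic_signal(fx)$phase
      py <- analytic_signal(fy)$phase
      c(pli = pli(px, py), plt = plt(px, py, 500),
        jpe = as.numeric(jpe(fx, fy)))
    })
    rowMeans(vals)
  })
  for (msr in rownames(res)) {
    expect_gt(res[msr, 5], res[msr, 1])
    expect_gt(cor(cs, res[msr, ], method = "spearman"), 0.8)
  }
})

test_that("fc_matrix equals the looped pairwise oracle on a 5-channel fixture", {
  set.seed(40)
  sig <- matrix(rnorm(5 * 1200), 5)
  sig[3, ] <- 0.6 * sig[1, ] + 0.4 * sig[3, ]
  theta <- band_def("theta", 4, 8)
  for (msr in c("AEC", "AECc", "PLI", "PLT", "JPE")) {
    fast <- fc_matrix(sig, msr, theta, 500, use_cpp = TRUE)
    slow <- fc_matrix(sig, msr, theta, 500, use_cpp = FALSE)
    expect_equal(fast$values, slow$values, tolerance = 1e-12)
    expect_true(isSymmetric(fast$values))
    expect_true(all(diag(fast$values) == 0))
    if (msr %in% c("PLI", "PLT", "JPE"))
      expect_true(all(fast$values >= 0 & fast$values <= 1))
  }
  # permutation equivariance
  perm <- c(3, 1, 5, 2, 4)
  m1 <- fc_matrix(sig, "PLI", theta, 500)$values
  m2 <- fc_matrix(sig[perm, ], "PLI", theta, 500)$values
  expect_equal(m2, m1[perm, perm], ignore_attr = TRUE)
})

test_that("roi_means and whole_brain_mean obey the averaging identity", {
  m <- matrix(0.7, 4, 4); diag(m) <- 0
  expect_equal(unname(roi_means(m)), rep(0.7, 4))
  expect_equal(whole_brain_mean(m), 0.7)
  m3 <- matrix(0, 3, 3)
  m3[1, 2] <- m3[2, 1] <- 0.2
  m3[1, 3] <- m3[3, 1] <- 0.4
  m3[2, 3] <- m3[3, 2] <- 0.6
  expect_equal(whole_brain_mean(m3), 0.4)
  set.seed(41)
  r <- matrix(runif(36), 6); r <- (r + t(r)) / 2; diag(r) <- 0
  expect_equal(mean(roi_means(r)), whole_brain_mean(r))
})
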