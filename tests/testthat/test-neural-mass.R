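test_that("psp_filter matches the closed-form biexponential", {
  f <- psp_filter(1.6, 55, 605, 500, normalize = "peak")
  # impulse response starts at 0 (e^0 - e^0)
  h <- impulse_response(f, 100)
  expect_equal(h[1], 0)
  # continuous-time peak location ln(b/a)/(b-a) = 4.36 ms for the EPSP
  expect_equal(f$t_peak, log(605 / 55) / (605 - 55))
  expect_equal(f$t_peak, 0.004360, tolerance = 1e-3)
  # discrete peak within 2% of amp at 500 Hz
  expect_lt(abs(max(h) - 1.6) / 1.6, 0.02)
  # raw convention multiplies the biexponential directly
  fr <- psp_filter(1.6, 55, 605, 500, normalize = "raw")
  m <- 0:9
  expect_equal(impulse_response(fr, 10),
               1.6 * (exp(-55 * m / 500) - exp(-605 * m / 500)))
  expect_error(psp_filter(1, 100, 50, 500), "b > a")
})

test_that("filter_apply equals direct convolution and has the right DC gain", {
  f <- psp_filter(32, 27.5, 55, 500, normalize = "raw")
  set.seed(1)
  x <- rnorm(300)
  h <- impulse_response(f, 300)
  direct <- stats::convolve(x, rev(h), type = "open")[1:300] / 500
  expect_equal(filter_apply(f, x), direct, tolerance = 1e-10)
  # sustained input approaches the continuous DC gain K*(1/a - 1/b)
  y <- filter_apply(f, rep(10, 3000))
  expect_equal(tail(y, 1), 10 * 32 * (1 / 27.5 - 1 / 55), tolerance = 0.06)
})

test_that("sigmoid rate function hits threshold, saturation, and plug-in", {
  expect_equal(potential_to_rate(7, 25, 0.34, 7), 25)
  expect_equal(potential_to_rate(-1e4, 25, 0.34, 7), 0)
  expect_equal(potential_to_rate(1e4, 25, 0.34, 7), 50)
  # 5 mV above threshold: 50/(1+e^(-1.7)) = 42.3 spikes/s
  expect_equal(potential_to_rate(12, 25, 0.34, 7), 50 / (1 + exp(-1.7)))
  expect_equal(round(potential_to_rate(12, 25, 0.34, 7), 1), 42.3)
  V <- seq(-30, 40, by = 0.5)
  expect_true(all(diff(potential_to_rate(V, 25, 0.34, 7)) > 0))
})

test_that("compiled engine matches the R reference stepper exactly", {
  net <- tiny_net(4, seed = 5)
  p <- nm_params(epoch_len = 40, transient_len = 20, substeps = 2)
  model <- nm_model(p, net, add_enabled = FALSE)
  set.seed(77)
  rec <- run_epoch(model)$record

  set.seed(77)
  st <- NULL
  syn <- synaptic_state(4)
  sig <- matrix(NA_real_, 4, 40)
  er <- matrix(NA_real_, 4, 40)
  for (t in 1:60) {
    st <- step_network(st, p, net, syn, rnorm(4))
    if (t > 20) {
      sig[, t - 20] <- st$Ve
      er[, t - 20] <- st$E
    }
  }
  expect_equal(rec$signals, sig, tolerance = 1e-12)
  expect_equal(rec$e_rates, er, tolerance = 1e-12)
})

test_that("engine with ADD matches R stepper + explicit degeneration ops", {
  net <- tiny_net(3, seed = 8)
  p <- nm_params(epoch_len = 30, transient_len = 10, substeps = 1,
                 kappa = 50)  # fast decay so the test exercises real losses
  model <- nm_model(p, net, add_enabled = TRUE)
  set.seed(9)
  rec <- run_epoch(model)$record

  set.seed(9)
  st <- NULL
  syn <- synaptic_state(3)
  hist <- matrix(numeric(0), 3, 0)
  for (t in 1:40) {
    st <- step_network(st, p, net, syn, rnorm(3))
    hist <- cbind(hist, st$E)[, max(1, ncol(hist) - 18):(ncol(hist) + 1),
                              drop = FALSE]
    maxact <- apply(hist, 1L, max_activity)
    syn <- apply_degeneration(syn, loss_factor(maxact, p$d_eff),
                              floor = p$strength_floor)
  }
  expect_equal(rec$synaptic_strengths[, "s_ei"], syn$s_ei,
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_lt(max(syn$s_ei), 1)  # losses actually happened
})

test_that("quiescent and deterministic limits of the stepper", {
  net <- tiny_net(3, seed = 8)
  # no input at all: potentials stay at 0, rates at the sigmoid rest value
  # (single substep: with more, within-sample inhibition already acts)
  p0 <- nm_params(Pt = 0, noiselevel = 0, S = 0, substeps = 1)
  st <- NULL
  syn <- synaptic_state(3)
  st <- step_network(st, p0, net, syn, rnorm(3))
  rest <- potential_to_rate(0, p0$g, p0$q, p0$Vd1)
  expect_equal(st$Ve, rep(0, 3))
  expect_equal(st$E, rep(rest, 3))
  # rates stay bounded by the saturation 2g for strong input
  p1 <- nm_params(Pt = 5000)
  for (t in 1:50) st <- step_network(st, p1, net, syn, rnorm(3))
  expect_true(all(st$E >= 0 & st$E <= 2 * p1$g))
  expect_true(all(st$I >= 0 & st$I <= 2 * p1$g))
})

test_that("run_epoch produces epoch-shaped records and simulate_run is seeded", {
  net <- tiny_net()
  p <- fast_params()
  run <- simulate_run(p, net, 3, seed = 21, add_enabled = FALSE)
  rec <- run$records[["2"]]
  expect_equal(dim(rec$signals), c(6, 256))
  expect_equal(p$transient_len + p$epoch_len, 456)  # steps per epoch
  expect_false(any(!is.finite(rec$signals)))
  expect_true(all(rec$synaptic_strengths == 1))  # control freezes synapses

  run2 <- simulate_run(p, net, 3, seed = 21, add_enabled = FALSE)
  expect_identical(run$records[["3"]]$signals, run2$records[["3"]]$signals)
  run3 <- simulate_run(p, net, 3, seed = 22, add_enabled = FALSE)
  expect_false(identical(run$records[["3"]]$signals,
                         run3$records[["3"]]$signals))
})

test_that("ADD runs have non-increasing strengths; control has no trend", {
  net <- tiny_net()
  p <- fast_params(kappa = 2000)
  run <- simulate_run(p, net, 6, seed = 31, add_enabled = TRUE,
                      keep_signals = FALSE)
  s <- run$rate_summary$mean_strength
  expect_true(all(diff(s) <= 0))
  expect_lt(s[6], s[1])

  # control: per-epoch mean E shows no trend (slope CI includes 0)
  con <- simulate_run(nm_params(epoch_len = 512, transient_len = 200), net,
                      20, seed = 31, add_enabled = FALSE,
                      keep_signals = FALSE)
  fit <- stats::lm(mean_E ~ epoch, data = con$rate_summary)
  ci <- stats::confint(fit)["epoch", ]
  expect_true(ci[1] < 0 && ci[2] > 0)
})

test_that("default 78-node model oscillates in the alpha band", {
  net <- generate_surrogate(78, 0.10, "modular", seed = 1)
  p <- nm_params()
  run <- simulate_run(p, net, 1, seed = 5, add_enabled = FALSE)
  sp <- epoch_spectral_summary(run$records[["1"]]$signals, p$fs)
  expect_gt(sp[["alpha1"]], sp[["delta"]])
  expect_gt(sp[["alpha1"]], sp[["beta"]])
  expect_gt(sp[["peak_freq"]], 8)
  expect_lt(sp[["peak_freq"]], 10)
})

test_that("doubling integration substeps changes band powers < 5%", {
  net <- tiny_net(10, seed = 6, density = 0.3)
  bp <- function(substeps) {
    p <- nm_params(substeps = substeps, transient_len = 1000)
    run <- simulate_run(p, net, 8, seed = 77, add_enabled = FALSE,
                        keep_signals = FALSE, on_epoch = function(rec)
                          relative_band_power(rec$signals -
                                                rowMeans(rec$signals), p$fs))
    rowMeans(sapply(run$epoch_summaries, identity))
  }
  b8 <- bp(8)   # default resolution
  b16 <- bp(16)
  main <- b8 > 0.05  # compare bands that carry real power
  expect_lt(max(abs(b16[main] - b8[main]) / b8[main]), 0.05)
})
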