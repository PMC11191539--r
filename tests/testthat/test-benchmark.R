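test_that("permutation test: exact enumeration oracle and edge cases", {
  expect_equal(permutation_test(c(1, 2, 3), c(10, 11, 12)), 2 / choose(6, 3))
  expect_equal(permutation_test(c(5, 5), c(5, 5)), 1)
  # label-swap invariance
  set.seed(1)
  a <- rnorm(5); b <- rnorm(5) + 1
  expect_identical(permutation_test(a, b), permutation_test(b, a))
  # Monte Carlo path agrees with exact enumeration within its own error
  p_mc <- permutation_test(a, b, n_perm = 4000, seed = 3, exact_limit = 1)
  p_ex <- permutation_test(a, b)
  expect_lt(abs(p_mc - p_ex), 4 * sqrt(p_ex * (1 - p_ex) / 4000) + 1e-3)
})

test_that("permutation p-values are uniform under the null", {
  set.seed(2)
  ps <- replicate(400, permutation_test(rnorm(4), rnorm(4)))
  # exact p on C(8,4)=70 relabelings: discrete-uniform; KS at alpha=0.01
  ks <- suppressWarnings(stats::ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
  expect_lt(abs(mean(ps < 0.25) - 0.25), 0.07)
})

test_that("BH-FDR matches the hand-computed step-up and stats::p.adjust", {
  expect_equal(fdr_bh(0.03)$adjusted, 0.03)
  out <- fdr_bh(c(0.01, 0.02, 0.03, 0.04))
  expect_equal(out$adjusted, rep(0.04, 4))  # p * 4 / rank, cummin enforced
  expect_true(all(out$reject))
  expect_false(any(fdr_bh(rep(1, 6))$reject))
  set.seed(3)
  for (k in 1:10) {
    p <- runif(sample(3:40, 1))^sample(1:3, 1)
    expect_equal(fdr_bh(p)$adjusted, stats::p.adjust(p, "BH"))
  }
  expect_error(fdr_bh(c(0.1, 1.2)), "0, 1")
})

test_that("BH-FDR controls the false-rejection rate on uniform p-values", {
  set.seed(4)
  fp <- replicate(300, mean(fdr_bh(runif(20), q = 0.05)$reject))
  expect_lte(mean(fp), 0.05 + 2 * sd(fp) / sqrt(300) + 0.01)
})

test_that("ROC: perfect separation, hand case, Mann-Whitney equivalence", {
  r <- roc_analysis(c(4, 5, 6), c(1, 2, 3))
  expect_equal(r$auc, 1)
  expect_equal(r$accuracy, 1)
  expect_equal(r$sensitivity, 1)
  expect_equal(r$specificity, 1)
  # interleaved groups: U = 1 of 4 pairs unflipped; auto-orientation folds
  expect_equal(roc_analysis(c(1, 3), c(2, 4), orientation = "ADD-high")$auc,
               0.25)
  expect_equal(roc_analysis(c(1, 3), c(2, 4))$auc, 0.75)
  set.seed(5)
  for (k in 1:100) {
    pos <- rnorm(sample(3:12, 1), mean = runif(1, 0, 2))
    neg <- rnorm(sample(3:12, 1))
    r <- roc_analysis(pos, neg)
    sp <- if (r$orientation == "ADD-low") -1 else 1
    u <- sum(outer(sp * pos, sp * neg, ">")) +
      0.5 * sum(outer(pos, neg, "=="))
    expect_equal(r$auc, u / (length(pos) * length(neg)), tolerance = 1e-12)
    expect_true(r$accuracy >= 0.5 - 1e-12)
    # reported operating point is consistent with its own counts
    expect_equal(r$accuracy,
                 (r$sensitivity * length(pos) + r$specificity * length(neg)) /
                   (length(pos) + length(neg)))
  }
})

test_that("ROC under label permutation concentrates at AUC 0.5", {
  set.seed(6)
  pool <- rnorm(20)
  aucs <- replicate(200, {
    idx <- sample(20, 10)
    roc_analysis(pool[idx], pool[-idx], orientation = "ADD-high")$auc
  })
  expect_lt(abs(mean(aucs) - 0.5), 0.05)
})

test_that("ROC auto-orientation handles ADD-low measures", {
  r <- roc_analysis(c(1, 2, 3), c(7, 8, 9))
  expect_equal(r$orientation, "ADD-low")
  expect_equal(r$auc, 1)
})

# build synthetic measured-run tables: per run a long data.frame
fake_measured <- function(run_seed, shift = 0, n_roi = 10, timesteps = 1:3,
                          measures = c("PLI", "JPE"), band = "theta") {
  set.seed(run_seed)
  do.call(rbind, lapply(timesteps, function(ts) {
    do.call(rbind, lapply(measures, function(m) {
      data.frame(timestep = ts, measure = m, band = band,
                 roi = seq_len(n_roi),
                 value = rnorm(n_roi, mean = 0.3 + shift * ts / 3, sd = 0.05))
    }))
  }))
}

test_that("timecourse benchmark: null control and shaped output", {
  con <- lapply(1:6, function(k) fake_measured(1000 + k))
  con2 <- lapply(7:12, function(k) fake_measured(1000 + k))
  out <- timecourse_benchmark(con, con2, n_perm = 500, seed = 9,
                              theta_ref = FALSE)
  expect_equal(nrow(out), 2 * 1 * 3)  # measures x bands x timesteps
  expect_false(any(out$significant))

  # an injected effect is detected and FDR columns are coherent
  add <- lapply(1:6, function(k) fake_measured(2000 + k, shift = 0.4))
  out2 <- timecourse_benchmark(add, con, n_perm = 500, seed = 9,
                               theta_ref = FALSE)
  expect_true(any(out2$significant))
  expect_true(all(out2$p_fdr >= out2$p - 1e-12))
})

test_that("rel_theta reference curve is replicated into every band family", {
  mk <- function(seed) {
    rbind(fake_measured(seed, measures = "PLI", band = "theta"),
          fake_measured(seed + 1, measures = "PLI", band = "alpha"),
          fake_measured(seed + 2, measures = "rel_theta", band = "theta"))
  }
  add <- lapply(c(1, 10, 20), mk)
  con <- lapply(c(30, 40, 50), mk)
  out <- timecourse_benchmark(add, con, n_perm = 200, seed = 2)
  expect_setequal(unique(out$measure), c("PLI", "rel_theta"))
  expect_setequal(unique(out$band[out$measure == "rel_theta"]),
                  c("theta", "alpha"))
})

test_that("roi_profile_comparison: nulls, shape, and synthetic recovery", {
  con <- lapply(1:6, function(k) fake_measured(3000 + k, n_roi = 78))
  con2 <- lapply(7:12, function(k) fake_measured(3000 + k, n_roi = 78))
  prof <- roi_profile_comparison(con, con2, "PLI", "theta", 2,
                                 n_perm = 300, seed = 4)
  expect_equal(nrow(prof), 78)
  expect_false(any(prof$significant))  # identical groups

  # a 6-SEM shift in 10 of 78 ROIs is recovered (a 3-SEM shift gives a
  # between-group z of only 3/sqrt(2) and cannot clear BH over 78 ROIs)
  hit <- 1:10
  shift_one <- function(df, rois, delta) {
    sel <- df$roi %in% rois & df$measure == "PLI"
    df$value[sel] <- df$value[sel] + delta
    df
  }
  sem <- 0.05 / sqrt(6)
  recovered <- sapply(1:5, function(s) {
    add <- lapply(1:6, function(k)
      shift_one(fake_measured(4000 + 10 * s + k, n_roi = 78), hit, 6 * sem))
    con <- lapply(1:6, function(k) fake_measured(6000 + 10 * s + k, n_roi = 78))
    p <- roi_profile_comparison(add, con, "PLI", "theta", 2, n_perm = 300,
                                seed = s)
    sig <- p$roi[p$significant]
    c(inside = sum(sig %in% hit), outside = sum(!sig %in% hit))
  })
  expect_gte(stats::median(recovered["inside", ]), 8)
  expect_lt(mean(recovered["outside", ]), 2)
})
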