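#' Two-sided permutation test for a difference of group means
#'
#' Exact enumeration of all group relabelings when the number of
#' combinations is at most `exact_limit` (the p-value is then the fraction
#' of relabelings with `|difference| >= |observed|`, identity included);
#' otherwise Monte Carlo with the add-one estimator
#' `p = (1 + #extreme) / (1 + n_perm)`.
#'
#' @param a,b numeric vectors (each length >= 2).
#' @param n_perm Monte Carlo permutations (default 5000).
#' @param seed optional seed for the Monte Carlo draw (caller RNG state
#'   preserved).
#' @param exact_limit enumeration threshold on `choose(na+nb, na)`.
#' @return p-value in (0, 1].
#' @export
permutation_test <- function(a, b, n_perm = 5000L, seed = NULL,
                             exact_limit = 20000) {
  stopifnot(length(a) >= 2L, length(b) >= 2L)
  pooled <- c(a, b)
  na <- length(a)
  if (max(pooled) - min(pooled) == 0) return(1)
  obs <- abs(mean(a) - mean(b))
  eps <- 1e-12 * max(1, obs)
  stat <- function(idx) {
    abs(mean(pooled[idx]) - mean(pooled[-idx]))
  }
  if (choose(length(pooled), na) <= exact_limit) {
    combs <- utils::combn(length(pooled), na)
    extreme <- sum(apply(combs, 2L, stat) >= obs - eps)
    return(extreme / ncol(combs))
  }
  draw <- function() {
    hits <- 0L
    for (k in seq_len(n_perm))
      if (stat(sample.int(length(pooled), na)) >= obs - eps) hits <- hits + 1L
    (1 + hits) / (1 + n_perm)
  }
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

#' Benjamini-Hochberg false-discovery-rate correction
#'
#' Step-up adjustment: `adj_(i) = min_{j >= i} p_(j) m / j`, capped at 1,
#' with rejection at `adj <= q`.
#'
#' @param pvals numeric vector of p-values in `[0, 1]`.
#' @param q FDR level (default 0.05).
#' @return List with `adjusted` (same order as input) and `reject` (logical
#'   mask).
#' @export
fdr_bh <- function(pvals, q = 0.05) {
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  m <- length(pvals)
  o <- order(pvals)
  adj <- pvals[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(1, adj)
  out <- numeric(m)
  out[o] <- adj
  list(adjusted = out, reject = out <= q)
}

#' ROC analysis of a scalar biomarker
#'
#' Builds the ROC of positive (ADD) versus negative (control) scores. The
#' orientation is chosen automatically so that the positive class has the
#' higher group mean (`"ADD-high"`); otherwise scores are negated
#' internally and the orientation is reported as `"ADD-low"` (cutoffs are
#' reported on the original scale, with positives at or below the cutoff).
#' AUC is the trapezoidal area over all thresholds (equal to the
#' Mann-Whitney statistic `U/(n1 n2)` with ties counted half). The optimal
#' cutoff maximizes accuracy; ties prefer higher sensitivity, then the less
#' extreme threshold.
#'
#' @param scores_pos,scores_neg numeric scores of the two groups.
#' @param orientation `"auto"` (default) picks the direction from the group
#'   means; `"ADD-high"` / `"ADD-low"` force it (useful for calibration
#'   studies where auto-selection would fold the null AUC distribution
#'   above 0.5).
#' @return An object of class `roc_result`: `auc`, `optimal_cutoff`,
#'   `sensitivity`, `specificity`, `accuracy`, `orientation`, and the full
#'   `curve` data.frame.
#' @export
roc_analysis <- function(scores_pos, scores_neg,
                         orientation = c("auto", "ADD-high", "ADD-low")) {
  orientation <- match.arg(orientation)
  stopifnot(length(scores_pos) >= 1L, length(scores_neg) >= 1L)
  flip <- if (orientation == "auto") mean(scores_pos) < mean(scores_neg)
          else orientation == "ADD-low"
  orientation <- if (flip) "ADD-low" else "ADD-high"
  sp <- if (flip) -scores_pos else scores_pos
  sn <- if (flip) -scores_neg else scores_neg
  thr <- sort(unique(c(sp, sn)))
  thr <- c(thr, Inf)  # classify score >= threshold as positive
  np <- length(sp); nn <- length(sn)
  sens <- vapply(thr, function(t) mean(sp >= t), numeric(1))
  spec <- vapply(thr, function(t) mean(sn < t), numeric(1))
  acc <- (sens * np + spec * nn) / (np + nn)
  # trapezoid over the ROC polyline (points ordered by decreasing threshold)
  fpr <- 1 - spec
  ord <- order(fpr, sens)
  auc <- sum(diff(fpr[ord]) * (utils::head(sens[ord], -1) +
                                 utils::tail(sens[ord], -1)) / 2)
  best <- which(acc == max(acc))
  if (length(best) > 1L) best <- best[sens[best] == max(sens[best])]
  if (length(best) > 1L) best <- best[1L]  # lowest threshold among ties
  cutoff <- thr[best]
  if (flip) cutoff <- -cutoff
  structure(list(auc = auc, optimal_cutoff = cutoff,
                 sensitivity = sens[best], specificity = spec[best],
                 accuracy = acc[best], orientation = orientation,
                 curve = data.frame(threshold = if (flip) -thr else thr,
                                    sensitivity = sens,
                                    specificity = spec, accuracy = acc)),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf(paste0("<roc_result> AUC %.3f (%s), cutoff %.4g: ",
                     "sens %.3f spec %.3f acc %.3f\n"),
              x$auc, x$orientation, x$optimal_cutoff, x$sensitivity,
              x$specificity, x$accuracy))
  invisible(x)
}

# bind per-run measurement tables, tagging condition and run id
bind_measured <- function(add_runs, con_runs) {
  lab <- function(lst, cond) {
    do.call(rbind, lapply(seq_along(lst), function(k) {
      df <- lst[[k]]
      df$condition <- cond
      df$run_id <- paste0(cond, "_", k)
      df
    }))
  }
  rbind(lab(add_runs, "ADD"), lab(con_runs, "Con"))
}

# per-run whole-brain means for one (measure, band, timestep) cell
cell_scores <- function(df, msr, bnd, ts) {
  sub <- df[df$measure == msr & df$band == bnd & df$timestep == ts, ]
  if (nrow(sub) == 0L) stop("missing timestep ", ts, " for ", msr, "/", bnd)
  agg <- stats::aggregate(value ~ run_id + condition, sub, mean)
  agg
}

#' Significance time courses of biomarkers (ADD vs control)
#'
#' For each measure, band and timestep, computes the permutation p-value of
#' the ADD-versus-control difference in per-run whole-brain means, then
#' applies Benjamini-Hochberg FDR across the timesteps within each
#' (measure, band) family. When `theta_ref = TRUE` and a `"rel_theta"`
#' measure is present in the measurement tables, its (band-independent)
#' curve is replicated into every band family as the reference biomarker.
#'
#' @param add_runs,con_runs lists of per-run measurement data.frames as
#'   returned by [measure_run()] (columns `timestep`, `measure`, `band`,
#'   `roi`, `value`).
#' @param measures,bands,timesteps character/character/integer vectors
#'   selecting the benchmark grid (defaults: everything present).
#' @param n_perm,q permutation count and FDR level.
#' @param seed optional seed for the Monte Carlo permutations.
#' @param theta_ref replicate the relative-theta-power curve into each band.
#' @return data.frame with one row per (measure, band, timestep): group
#'   means, `p`, `p_fdr`, `significant`.
#' @export
timecourse_benchmark <- function(add_runs, con_runs, measures = NULL,
                                 bands = NULL, timesteps = NULL,
                                 n_perm = 5000L, q = 0.05, seed = NULL,
                                 theta_ref = TRUE) {
  df <- bind_measured(add_runs, con_runs)
  if (is.null(measures)) measures <- setdiff(unique(df$measure), "rel_theta")
  if (is.null(bands)) bands <- unique(df$band)
  if (is.null(timesteps)) timesteps <- sort(unique(df$timestep))
  if (theta_ref && "rel_theta" %in% df$measure) {
    ref <- df[df$measure == "rel_theta", ]
    df <- df[df$measure != "rel_theta", ]
    for (b in bands) {
      rb <- ref
      rb$band <- b
      df <- rbind(df, rb)
    }
    measures <- c(measures, "rel_theta")
  }
  grid <- expand.grid(measure = measures, band = bands,
                      timestep = timesteps, stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(r) {
    g <- grid[r, ]
    agg <- cell_scores(df, g$measure, g$band, g$timestep)
    aval <- agg$value[agg$condition == "ADD"]
    cval <- agg$value[agg$condition == "Con"]
    if (length(aval) < 2L || length(cval) < 2L)
      stop("need >= 2 runs per condition")
    s <- if (is.null(seed)) NULL else
      (seed + 7L * r) %% .Machine$integer.max
    data.frame(measure = g$measure, band = g$band, timestep = g$timestep,
               mean_add = mean(aval), mean_con = mean(cval),
               p = permutation_test(aval, cval, n_perm = n_perm, seed = s))
  })
  out <- do.call(rbind, rows)
  out$p_fdr <- NA_real_
  out$significant <- NA
  for (msr in unique(out$measure))
    for (bnd in unique(out$band)) {
      sel <- out$measure == msr & out$band == bnd
      fdr <- fdr_bh(out$p[sel], q = q)
      out$p_fdr[sel] <- fdr$adjusted
      out$significant[sel] <- fdr$reject
    }
  rownames(out) <- NULL
  out
}

#' Per-ROI group comparison at one timestep
#'
#' Group means and standard errors per ROI, permutation p-values, and
#' Benjamini-Hochberg FDR across the ROIs, with the direction of each
#' difference.
#'
#' @inheritParams timecourse_benchmark
#' @param measure,band,timestep the benchmark cell to profile.
#' @return data.frame with one row per ROI: `roi`, `mean_add`, `sem_add`,
#'   `mean_con`, `sem_con`, `direction`, `p`, `p_fdr`, `significant`.
#' @export
roi_profile_comparison <- function(add_runs, con_runs, measure, band,
                                   timestep, n_perm = 5000L, q = 0.05,
                                   seed = NULL) {
  df <- bind_measured(add_runs, con_runs)
  sub <- df[df$measure == measure & df$band == band &
              df$timestep == timestep, ]
  if (nrow(sub) == 0L) stop("no data for requested cell")
  rois <- unique(sub$roi)
  sem <- function(v) stats::sd(v) / sqrt(length(v))
  rows <- lapply(seq_along(rois), function(k) {
    rr <- sub[sub$roi == rois[k], ]
    aval <- rr$value[rr$condition == "ADD"]
    cval <- rr$value[rr$condition == "Con"]
    s <- if (is.null(seed)) NULL else
      (seed + 13L * k) %% .Machine$integer.max
    data.frame(roi = rois[k], mean_add = mean(aval), sem_add = sem(aval),
               mean_con = mean(cval), sem_con = sem(cval),
               direction = if (mean(aval) >= mean(cval)) "ADD>Con"
                           else "ADD<Con",
               p = permutation_test(aval, cval, n_perm = n_perm, seed = s),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  fdr <- fdr_bh(out$p, q = q)
  out$p_fdr <- fdr$adjusted
  out$significant <- fdr$reject
  rownames(out) <- NULL
  out
}
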