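#' Measure functional connectivity and spectral biomarkers on a run
#'
#' Applies the selected FC measures in the selected bands to each retained
#' epoch of a simulated (or externally loaded) run, plus the relative theta
#' power reference, and returns a long table of per-ROI values ready for
#' [timecourse_benchmark()] / [roi_profile_comparison()].
#'
#' FC rows hold the per-ROI mean connectivity of the epoch's FC matrix;
#' `rel_theta` rows hold each channel's relative theta power (band column
#' `"theta"`).
#'
#' @param run an [simulate_run()] result with kept signals, or a plain list
#'   of channels-by-samples matrices named by timestep.
#' @param measures subset of `c("AECc","AEC","PLI","PLT","JPE")`; the
#'   reference `"rel_theta"` may be included (default: the benchmark four
#'   plus the reference).
#' @param bands list of [band_def()]s (default [default_bands()]).
#' @param timesteps epochs to measure (default: all kept).
#' @param fs sample rate (taken from the run if available).
#' @param trim edge-trim fraction passed to [fc_matrix()].
#' @param total_range normalization range for relative power.
#' @return data.frame with columns `timestep`, `measure`, `band`, `roi`,
#'   `value`.
#' @export
measure_run <- function(run, measures = c("AECc", "PLI", "JPE", "PLT",
                                          "rel_theta"),
                        bands = default_bands(), timesteps = NULL,
                        fs = NULL, trim = 0.01, total_range = c(0.5, 48)) {
  known <- c("AECc", "AEC", "PLI", "PLT", "JPE", "rel_theta")
  if (!all(measures %in% known))
    stop("unknown measure(s): ",
         paste(setdiff(measures, known), collapse = ", "))
  if (inherits(run, "add_run")) {
    sigs <- lapply(run$records, `[[`, "signals")
    names(sigs) <- names(run$records)
    if (is.null(fs)) fs <- run$params$fs
  } else {
    sigs <- run
    if (is.null(fs)) stop("fs required for plain signal lists")
  }
  if (is.null(timesteps)) timesteps <- as.integer(names(sigs))
  fc_measures <- setdiff(measures, "rel_theta")
  theta <- band_def("theta", 4, 8)
  rows <- list()
  for (ts in timesteps) {
    sig <- sigs[[as.character(ts)]]
    if (is.null(sig)) stop("no retained signals for timestep ", ts)
    nroi <- nrow(sig)
    for (msr in fc_measures)
      for (b in bands) {
        m <- fc_matrix(sig, msr, b, fs, epoch_index = ts, trim = trim)
        rows[[length(rows) + 1L]] <-
          data.frame(timestep = ts, measure = msr, band = b$name,
                     roi = seq_len(nroi), value = unname(roi_means(m)))
      }
    if ("rel_theta" %in% measures) {
      rt <- apply(sig, 1L, function(ch)
        relative_band_power(ch, fs, bands = list(theta),
                            total_range = total_range))
      rows[[length(rows) + 1L]] <-
        data.frame(timestep = ts, measure = "rel_theta", band = "theta",
                   roi = seq_len(nroi), value = as.numeric(rt))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Spectral summary of one epoch
#'
#' Channel-averaged relative band power ([spectral_bands()] tiling by
#' default), median frequency and spectral peak frequency of an epoch's
#' signals.
#'
#' @param signals channels-by-samples matrix.
#' @param fs sample rate, Hz.
#' @param bands list of [band_def()]s.
#' @param total_range normalization range, Hz.
#' @return Named numeric vector: one entry per band plus `median_freq` and
#'   `peak_freq`.
#' @export
epoch_spectral_summary <- function(signals, fs, bands = spectral_bands(),
                                   total_range = c(0.5, 48)) {
  # remove per-channel mean so DC leakage does not pollute the delta band
  sig <- signals - rowMeans(signals)
  rp <- relative_band_power(sig, fs, bands = bands,
                            total_range = total_range)
  mf <- median_frequency(sig, fs, range = total_range)
  c(rp, median_freq = as.numeric(mf), peak_freq = attr(mf, "peak"))
}
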