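#' Biexponential postsynaptic-potential filter
#'
#' Discrete realization (impulse invariance at rate `fs`) of the
#' postsynaptic-potential kernel `h(t) = K (exp(-a t) - exp(-b t))`, the
#' linear "memory" that converts an incoming spike density into a membrane
#' potential deflection. With `normalize = "peak"` the kernel is rescaled so
#' its peak value equals `amp` (the peak sits at `t* = log(b/a)/(b-a)`);
#' with `normalize = "raw"` the amplitude parameter multiplies the
#' biexponential directly (the classical alpha-rhythm model convention used
#' by the simulator, see [nm_params()]).
#'
#' @param amp amplitude parameter, mV.
#' @param a,b shape rates, 1/s, with `b > a > 0`.
#' @param fs sample rate, Hz.
#' @param normalize `"peak"` or `"raw"`.
#' @return An object of class `psp_filter` with the recursion coefficients;
#'   see [impulse_response()] and [filter_apply()].
#' @examples
#' f <- psp_filter(1.6, 55, 605, 500)
#' max(impulse_response(f, 50))  # close to 1.6 mV
#' @export
psp_filter <- function(amp, a, b, fs, normalize = c("peak", "raw")) {
  normalize <- match.arg(normalize)
  if (a <= 0 || b <= a) stop("psp_filter requires b > a > 0 (non-causal shape)")
  tstar <- log(b / a) / (b - a)
  peak <- exp(-a * tstar) - exp(-b * tstar)
  K <- if (normalize == "peak") amp / peak else amp
  structure(list(amp = amp, a = a, b = b, fs = fs, normalize = normalize,
                 K = K, da = exp(-a / fs), db = exp(-b / fs),
                 t_peak = tstar),
            class = "psp_filter")
}

#' Sampled impulse response of a PSP filter
#'
#' Response to a unit discrete impulse: `h[m] = K (exp(-a m/fs) -
#' exp(-b m/fs))`, `m = 0..n-1`. For a peak-normalized filter the maximum is
#' `amp` up to sampling of the continuous peak.
#'
#' @param f a [psp_filter()].
#' @param n number of samples.
#' @return Numeric vector of length `n` (mV).
#' @export
impulse_response <- function(f, n) {
  m <- seq_len(n) - 1
  f$K * (exp(-f$a * m / f$fs) - exp(-f$b * m / f$fs))
}

#' Apply a PSP filter to a spike-density series
#'
#' Convolves the sampled kernel with the input by two exact first-order
#' recursions, scaled by the sample time so that `x` is interpreted as a
#' spike density in spikes/s (a sustained density `X` produces the
#' continuous-time DC response `K X (1/a - 1/b)`).
#'
#' @param f a [psp_filter()].
#' @param x numeric series, spikes/s.
#' @return Filtered series, mV.
#' @export
filter_apply <- function(f, x) {
  u <- as.numeric(stats::filter(x, f$da, method = "recursive"))
  v <- as.numeric(stats::filter(x, f$db, method = "recursive"))
  f$K / f$fs * (u - v)
}

#' Sigmoidal membrane-potential to firing-rate function
#'
#' `f(V) = 2 g / (1 + exp(q (Vd - V)))`: monotone, bounded by the saturation
#' `2 g`, equal to `g` at the threshold `Vd`. This form uses exactly the
#' published parameter triplet (`g`, `q`, `Vd`); see the methods vignette for
#' the calibration caveat on initial inhibitory rates.
#'
#' @param V membrane potential, mV (vectorized).
#' @param g rate scale, spikes/s.
#' @param q steepness, 1/mV.
#' @param Vd threshold, mV.
#' @return Spike density, spikes/s.
#' @examples
#' potential_to_rate(7, 25, 0.34, 7)  # g = 25 at threshold
#' @export
potential_to_rate <- function(V, g, q, Vd) {
  2 * g / (1 + exp(q * (Vd - V)))
}

#' Initial synaptic state
#'
#' Per-mass multiplicative synapse strengths, all 1 in the healthy state:
#' `s_ei` scales the excitatory-to-inhibitory gain `C1`, `s_ie` the
#' inhibitory-to-excitatory gain `C2`, `s_thal` the thalamic drive, and
#' `s_edge` the receiving-side strength of every incident inter-mass
#' connection (an edge's effective strength is the product of its two
#' endpoint-side multipliers). `rate_history` holds the last up-to-20
#' excitatory spike-density samples per mass, the window over which the
#' degeneration rule takes its peak activity.
#'
#' @param n_nodes number of masses.
#' @return An object of class `synaptic_state`.
#' @export
synaptic_state <- function(n_nodes) {
  structure(list(s_ei = rep(1, n_nodes), s_ie = rep(1, n_nodes),
                 s_thal = rep(1, n_nodes), s_edge = rep(1, n_nodes),
                 rate_history = matrix(numeric(0), nrow = n_nodes, ncol = 0)),
            class = "synaptic_state")
}

#' Effective inter-mass edge strengths
#'
#' @param net a [structural_network()].
#' @param synapses a [synaptic_state()].
#' @return `N x N` matrix `A_ij * s_edge_i * s_edge_j`.
#' @export
effective_edge_strengths <- function(net, synapses) {
  net$adjacency * outer(synapses$s_edge, synapses$s_edge)
}

# zeroed filter/rate state for an N-mass network
nm_state_init <- function(n) {
  list(u1 = rep(0, n), v1 = rep(0, n), u2 = rep(0, n), v2 = rep(0, n),
       u3 = rep(0, n), v3 = rep(0, n), E = rep(0, n), I = rep(0, n),
       Ve = rep(0, n), Vi = rep(0, n))
}

# internal: engine coefficient list shared by the R and C++ steppers
engine_coefs <- function(params) {
  f1 <- psp_filter(params$Amp1, params$a1, params$b1,
                   params$fs * params$substeps, params$psp_normalize)
  f2 <- psp_filter(params$Amp2, params$a2, params$b2,
                   params$fs * params$substeps, params$psp_normalize)
  list(K1 = f1$K, K2 = f2$K, d1a = f1$da, d1b = f1$db, d2a = f2$da,
       d2b = f2$db, h = params$dt / params$substeps)
}

#' Advance the network by one 2-ms sample (reference stepper)
#'
#' Pure-R single-sample update of all masses, the readable reference for the
#' compiled engine used by [run_epoch()] (the two are asserted equal in the
#' test suite). Each mass's excitatory population integrates thalamic input,
#' `S`-weighted excitatory spike densities of adjacent masses (both through
#' the EPSP kernel) minus `C2`-weighted inhibitory feedback (IPSP kernel);
#' the inhibitory population integrates `C1`-weighted excitatory drive; both
#' potentials pass through the rate sigmoid. All gains are scaled by the
#' current synaptic multipliers. Substeps of `dt/substeps` are taken with the
#' noise draw held fixed.
#'
#' @param state list as produced by previous calls (filter states, `E`, `I`,
#'   `Ve`, `Vi` per mass); pass `NULL` to start from rest.
#' @param params an [nm_params()].
#' @param network a [structural_network()].
#' @param synapses a [synaptic_state()].
#' @param noise_draw per-mass standard-normal draw for this sample.
#' @return Updated state list.
#' @export
step_network <- function(state, params, network, synapses, noise_draw) {
  n <- network$n_nodes
  if (is.null(state)) state <- nm_state_init(n)
  co <- engine_coefs(params)
  P <- pmax(0, params$Pt + params$noiselevel * params$sigma0 * noise_draw)
  A <- network$adjacency
  for (s in seq_len(params$substeps)) {
    xe <- synapses$s_thal * P +
      params$S * synapses$s_edge * as.numeric(A %*% (synapses$s_edge * state$E))
    state$u1 <- co$d1a * state$u1 + xe
    state$v1 <- co$d1b * state$v1 + xe
    xh <- params$C2 * synapses$s_ie * state$I
    state$u2 <- co$d2a * state$u2 + xh
    state$v2 <- co$d2b * state$v2 + xh
    xi <- params$C1 * synapses$s_ei * state$E
    state$u3 <- co$d1a * state$u3 + xi
    state$v3 <- co$d1b * state$v3 + xi
    state$Ve <- co$K1 * co$h * (state$u1 - state$v1) -
      co$K2 * co$h * (state$u2 - state$v2)
    state$Vi <- co$K1 * co$h * (state$u3 - state$v3)
    if (any(!is.finite(state$Ve)) || any(!is.finite(state$Vi)))
      stop("numeric overflow in mass ",
           which(!is.finite(state$Ve) | !is.finite(state$Vi))[1L])
    state$E <- potential_to_rate(state$Ve, params$g, params$q, params$Vd1)
    state$I <- potential_to_rate(state$Vi, params$g, params$q, params$Vd2)
  }
  state
}

#' Create a simulation model object
#'
#' Bundles parameters, network, dynamic state and synaptic state; epochs are
#' advanced with [run_epoch()], which returns an updated model (epochs are
#' consecutive: state carries over, as in the published protocol).
#'
#' @param params an [nm_params()].
#' @param network a [structural_network()].
#' @param add_enabled logical; `FALSE` freezes all synaptic strengths at 1
#'   (control condition).
#' @return An object of class `nm_model`.
#' @export
nm_model <- function(params, network, add_enabled = TRUE) {
  stopifnot(inherits(params, "nm_params"),
            inherits(network, "structural_network"))
  structure(list(params = params, network = network,
                 state = nm_state_init(network$n_nodes),
                 synapses = synaptic_state(network$n_nodes),
                 add_enabled = isTRUE(add_enabled), epoch_index = 0L),
            class = "nm_model")
}

#' Run one epoch of the simulation
#'
#' Advances the model by `transient_len` settling samples plus `epoch_len`
#' retained samples (degeneration, when enabled, acts throughout) and
#' returns the retained traces. Draws from the current R random number
#' stream; seed at the run level (see [simulate_run()]).
#'
#' @param model an [nm_model()].
#' @return List with elements `model` (advanced) and `record`, an
#'   `epoch_record`: `signals` (`N x epoch_len` excitatory membrane
#'   potentials, mV), `e_rates`, `i_rates` (spike densities),
#'   `synaptic_strengths` (`N x 4` matrix, columns `s_ei`, `s_ie`, `s_thal`,
#'   `s_edge`, at epoch end) and `epoch_index`.
#' @export
run_epoch <- function(model) {
  p <- model$params
  co <- engine_coefs(p)
  res <- run_epoch_cpp(model$network$adjacency, p, co, model$state,
                       model$synapses, model$add_enabled)
  model$state <- res$state
  model$synapses <- structure(res$synapses, class = "synaptic_state")
  model$epoch_index <- model$epoch_index + 1L
  syn <- cbind(s_ei = res$synapses$s_ei, s_ie = res$synapses$s_ie,
               s_thal = res$synapses$s_thal, s_edge = res$synapses$s_edge)
  rownames(syn) <- model$network$labels
  record <- structure(list(signals = res$signals, e_rates = res$e_rates,
                           i_rates = res$i_rates, synaptic_strengths = syn,
                           epoch_index = model$epoch_index),
                      class = "epoch_record")
  list(model = model, record = record)
}

#' Simulate a run of consecutive epochs
#'
#' Seeded, reproducible multi-epoch simulation. Retained signals can be kept
#' for all epochs, a subset, or none (per-epoch firing-rate summaries and
#' synaptic strengths are always kept, so long runs need not hold all
#' signals in memory); an `on_epoch` callback can compute per-epoch
#' summaries (e.g. spectra) before signals are discarded.
#'
#' @param params an [nm_params()].
#' @param network a [structural_network()].
#' @param n_epochs number of epochs (>= 1).
#' @param seed integer seed; the caller's RNG state is preserved.
#' @param add_enabled `FALSE` for the control condition (all strengths 1).
#' @param keep_signals `TRUE`, `FALSE`, or an integer vector of epoch
#'   indices whose full records are retained.
#' @param on_epoch optional `function(record)` whose value is stored in the
#'   run's `epoch_summaries`.
#' @return An object of class `add_run`: list with `records` (kept
#'   `epoch_record`s, named by epoch), `rate_summary` (per-epoch mean `E`,
#'   mean `I`, mean synaptic strength), `epoch_summaries`, `params`,
#'   `network`, `seed`, `add_enabled`, `n_epochs`.
#' @export
simulate_run <- function(params, network, n_epochs, seed = NULL,
                         add_enabled = TRUE, keep_signals = TRUE,
                         on_epoch = NULL) {
  stopifnot(n_epochs >= 1)
  keep <- if (isTRUE(keep_signals)) seq_len(n_epochs)
          else if (isFALSE(keep_signals)) integer(0)
          else as.integer(keep_signals)
  body <- function() {
    model <- nm_model(params, network, add_enabled = add_enabled)
    records <- list()
    summaries <- list()
    rs <- matrix(NA_real_, n_epochs, 5L,
                 dimnames = list(NULL, c("epoch", "mean_E", "mean_I",
                                         "EI_balance", "mean_strength")))
    for (k in seq_len(n_epochs)) {
      out <- run_epoch(model)
      model <- out$model
      rec <- out$record
      rs[k, ] <- c(k, mean(rec$e_rates), mean(rec$i_rates),
                   ei_balance(rowMeans(rec$e_rates), rowMeans(rec$i_rates)),
                   mean(rec$synaptic_strengths))
      if (!is.null(on_epoch)) summaries[[k]] <- on_epoch(rec)
      if (k %in% keep) records[[as.character(k)]] <- rec
    }
    structure(list(records = records, rate_summary = as.data.frame(rs),
                   epoch_summaries = summaries, params = params,
                   network = network, seed = seed,
                   add_enabled = isTRUE(add_enabled), n_epochs = n_epochs),
              class = "add_run")
  }
  if (is.null(seed)) body() else with_seed(seed, body())
}

#' @export
print.add_run <- function(x, ...) {
  cat(sprintf("<add_run> %d epochs, %d masses, ADD %s, seed %s\n",
              x$n_epochs, x$network$n_nodes,
              if (x$add_enabled) "enabled" else "disabled (control)",
              if (is.null(x$seed)) "none" else x$seed))
  invisible(x)
}
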