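#' Peak recent excitatory activity
#'
#' Maximum excitatory spike density over the most recent (up to) 20 samples
#' of 2 ms, the activity term of the degeneration rule.
#'
#' @param rate_history numeric vector of spike densities, most recent last.
#' @return `maxAct`, spikes/s.
#' @export
max_activity <- function(rate_history) {
  if (length(rate_history) == 0L) stop("empty rate history")
  max(utils::tail(rate_history, 20L))
}

#' Degeneration loss factor
#'
#' `loss = exp(-d_eff * maxAct)`: the multiplicative synaptic weakening per
#' sample. `loss` is in (0, 1] and equals 1 only when the effective rate or
#' the activity is zero.
#'
#' @param maxAct peak recent excitatory spike density, spikes/s (>= 0).
#' @param d_eff effective per-sample degeneration rate (>= 0); see
#'   [nm_params()] for the `d / kappa` calibration.
#' @return Loss factor(s), dimensionless.
#' @export
loss_factor <- function(maxAct, d_eff) {
  if (any(maxAct < 0) || any(d_eff < 0)) stop("negative inputs")
  exp(-d_eff * maxAct)
}

#' Apply one degeneration step to the synaptic state
#'
#' Multiplies every synaptic multiplier of mass `i` (E-to-I, I-to-E,
#' thalamic, and the receiving side of its inter-mass connections) by
#' `loss_per_mass[i]`, clipping at the configured floor. An inter-mass
#' edge's effective strength therefore decays by the product of both
#' endpoint-side updates.
#'
#' @param synapses a [synaptic_state()].
#' @param loss_per_mass vector of per-mass loss factors in (0, 1].
#' @param floor lower clip for the multipliers.
#' @return Updated [synaptic_state()].
#' @export
apply_degeneration <- function(synapses, loss_per_mass, floor = 1e-6) {
  if (any(loss_per_mass <= 0) || any(loss_per_mass > 1))
    stop("loss values must be in (0, 1]")
  for (f in c("s_ei", "s_ie", "s_thal", "s_edge"))
    synapses[[f]] <- pmax(floor, synapses[[f]] * loss_per_mass)
  synapses
}

#' Excitation/inhibition balance
#'
#' `E / (E + I)` on epoch-averaged per-mass firing rates, averaged over
#' masses; normalized to (0, 1), rising as inhibition degrades.
#'
#' @param e_rates per-mass mean excitatory spike densities (or a scalar).
#' @param i_rates per-mass mean inhibitory spike densities.
#' @return Balance value in (0, 1).
#' @export
ei_balance <- function(e_rates, i_rates) {
  tot <- e_rates + i_rates
  if (any(tot <= 0)) stop("zero total rate")
  mean(e_rates / tot)
}

#' Per-epoch degeneration time course
#'
#' Tidy per-epoch summary of a simulated run: mean excitatory and inhibitory
#' firing rates, E/I balance, and mean synaptic strength.
#'
#' @param run an [simulate_run()] result.
#' @return data.frame with columns `epoch`, `mean_E`, `mean_I`,
#'   `EI_balance` (mean over masses of per-mass `E/(E+I)` on epoch-averaged
#'   rates), `mean_strength`.
#' @export
degeneration_timecourse <- function(run) {
  rs <- run$rate_summary
  data.frame(epoch = rs$epoch, mean_E = rs$mean_E, mean_I = rs$mean_I,
             EI_balance = rs$EI_balance, mean_strength = rs$mean_strength)
}
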