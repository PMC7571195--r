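# Dynamic evolving SNN readout: one output neuron per sample, connected to
# every reservoir neuron, initialised by rank-order coding on the first
# spikes and made dynamic by a per-step drift.

#' Readout parameters
#'
#' @param alpha Rank-order learning parameter (default 1).
#' @param mod Order modulation factor in (0, 1]; how quickly the initial
#'   weight decays with the first-spike rank (default 0.8).
#' @param drift Per-step weight increment/decrement applied after a synapse
#'   is initialised (default 0.005).
#' @return An object of class `readout_params`.
#' @export
readout_params <- function(alpha = 1, mod = 0.8, drift = 0.005) {
  check_number(alpha, "alpha", lower = 0, strict_lower = TRUE)
  check_number(mod, "mod", lower = 0, upper = 1, strict_lower = TRUE)
  check_number(drift, "drift", lower = 0)
  structure(list(alpha = alpha, mod = mod, drift = drift),
            class = "readout_params")
}

#' Rank-order initial weights from first-spike times
#'
#' Reservoir neurons are ranked by their first firing step (ascending, ties
#' broken by neuron index); the synapse from the neuron with rank `k`
#' (`k = 0` for the earliest spike) is initialised to `alpha * mod^k`.
#' Neurons that never spike contribute weight 0.
#'
#' @param first_spike_steps Integer vector of first firing steps per
#'   reservoir neuron, `NA` for silent neurons.
#' @param params A [readout_params()].
#' @return Numeric weight vector of the same length.
#' @export
rank_order_init <- function(first_spike_steps, params = readout_params()) {
  w <- numeric(length(first_spike_steps))
  spiking <- which(!is.na(first_spike_steps))
  if (length(spiking)) {
    ord <- spiking[order(first_spike_steps[spiking], spiking)]
    w[ord] <- params$alpha * params$mod^(seq_along(ord) - 1L)
  }
  w
}

#' Drift dynamics over a propagation record
#'
#' Once a synapse is initialised by its neuron's first spike it becomes
#' dynamic: at every later time step its weight gains `drift` if the neuron
#' fired at that step and loses `drift` otherwise. Synapses of silent
#' neurons stay at 0.
#'
#' @param weights Initial weight vector (from [rank_order_init()]).
#' @param firings List of firing-step vectors per reservoir neuron
#'   (0-based steps).
#' @param horizon Number of simulation steps (default 129).
#' @param params A [readout_params()].
#' @return Updated weight vector: for a neuron first firing at step `f` with
#'   `m` later firings, `w + drift * (m - (horizon - 1 - f - m))`.
#' @export
drift_update <- function(weights, firings, horizon = 129L,
                         params = readout_params()) {
  stopifnot(length(weights) == length(firings))
  first <- vapply(firings, function(v)
    if (length(v)) v[1L] else NA_integer_, integer(1))
  fires_after <- vapply(firings, function(v)
    if (length(v)) length(v) - 1L else 0L, integer(1))
  steps_after <- (horizon - 1L) - first
  silences <- steps_after - fires_after
  delta <- params$drift * (fires_after - silences)
  delta[is.na(first)] <- 0
  unname(weights + delta)
}

#' Create an output neuron for one sample
#'
#' Propagates the sample's raster through the frozen reservoir and builds
#' the output neuron's weight vector by rank-order initialisation followed
#' by drift dynamics.
#'
#' @param net A trained [reservoir_net].
#' @param raster The sample's `spike_raster`.
#' @param label Class label (`"low"`/`"high"`) or `NULL` for a test neuron.
#' @param params A [readout_params()].
#' @param subject_id,trial_id Source identifiers carried on the neuron.
#' @return An object of class `output_neuron` with fields `weights` (length
#'   = reservoir size), `label`, `subject_id`, `trial_id`.
#' @export
create_output_neuron <- function(net, raster, label = NULL,
                                 params = readout_params(),
                                 subject_id = NA_character_,
                                 trial_id = NA_character_) {
  rec <- propagate(net, raster, plasticity = FALSE)$record
  w0 <- rank_order_init(rec$first_spike, params)
  w <- drift_update(w0, rec$firings, horizon = rec$n_steps, params = params)
  structure(list(weights = w, label = label, subject_id = subject_id,
                 trial_id = trial_id), class = "output_neuron")
}
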