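# Integrate-and-fire simulation of granule cells. The inner loop lives in
# src/if_sim.cpp and advances the linear membrane + dual-exponential
# synapse system with the exact per-step closed form on the 20 kHz grid.

#' Closed-form subthreshold EPSP shape
#'
#' Membrane-filtered response (relative to the leak potential) to a single
#' input spike at t = 0 through a dual-exponential synaptic current:
#' each component contributes
#' `w/(tau_c - tau_m) * (exp(-t/tau_c) - exp(-t/tau_m))`.
#'
#' @param t times since the spike (ms)
#' @param tau_m membrane time constant (ms)
#' @param syn a [synapse_params()]
#' @return voltage deviation from rest (mV)
#' @export
epsp_shape <- function(t, tau_m, syn) {
  comp <- function(w, tau_c) {
    if (abs(tau_c - tau_m) < 1e-9) tau_c <- tau_c + 1e-6
    w / (tau_c - tau_m) * (exp(-t / tau_c) - exp(-t / tau_m))
  }
  out <- comp(syn$w_fast, syn$tau_fast) + comp(syn$w_slow, syn$tau_slow)
  out[t < 0] <- 0
  out
}

#' Unjittered single-EPSP peak on the simulation grid
#' @inheritParams epsp_shape
#' @export
epsp_peak <- function(tau_m, syn) {
  t <- seq(0, 10 * syn$tau_slow, by = GRID_DT)
  max(epsp_shape(t, tau_m, syn))
}

#' Simulate a granule cell's response to input spike trains
#'
#' Advances the integrate-and-fire equation
#' `tau_m dV/dt = E_l - V + sum_sites E(t - t_spike)` on the 0.05 ms grid.
#' Each input spike's EPSP peak is perturbed by an additive draw from
#' `Normal(0, epsp_jitter_sd)` (trial-to-trial variability of recorded
#' EPSPs), implemented by jointly scaling that spike's fast and slow
#' weights so the peak shifts by the drawn amount. With
#' `subthreshold_only = TRUE` the threshold is disabled (used for voltage
#' statistics and fitting fixtures).
#'
#' @param spec a [granule_cell_spec()]
#' @param input_spikes list of spike-time vectors (ms), one per input site
#'   (at most 3; silent sites may be empty)
#' @param t_end simulation length (ms); default last spike + 100 ms
#' @param subthreshold_only disable threshold/reset?
#' @param seed integer seed for the EPSP jitter; `NULL` disables jitter
#' @return object of class `granule_response` with `sample_times`,
#'   `voltage`, `spike_times`
#' @export
simulate_granule <- function(spec, input_spikes, t_end = NULL,
                             subthreshold_only = FALSE, seed = NULL) {
  if (!is.list(input_spikes)) input_spikes <- list(input_spikes)
  if (length(input_spikes) > 3L)
    stop("at most 3 input sites", call. = FALSE)
  for (s in input_spikes) {
    if (length(s) && any(diff(s) < 0))
      stop("input spike trains must be sorted", call. = FALSE)
    if (length(s) && any(s < 0))
      stop("input spike times must be >= 0", call. = FALSE)
  }
  all_last <- suppressWarnings(max(c(0, unlist(input_spikes))))
  if (is.null(t_end)) t_end <- all_last + 100
  n_steps <- time_to_index(t_end)

  site_of <- integer(0)
  times <- numeric(0)
  for (k in seq_along(input_spikes)) {
    times <- c(times, input_spikes[[k]])
    site_of <- c(site_of, rep(k - 1L, length(input_spikes[[k]])))
  }
  ord <- order(times)
  times <- snap_to_grid(times[ord])
  site_of <- site_of[ord]
  idx <- as.integer(round(times / GRID_DT))

  ns <- max(1L, length(input_spikes))
  site_syn <- if (!is.null(spec$syn_sites)) spec$syn_sites
              else rep(list(spec$syn), ns)
  if (length(site_syn) < ns)
    stop("`syn_sites` must cover every input site", call. = FALSE)

  scale <- rep(1, length(times))
  if (!is.null(seed) && spec$epsp_jitter_sd > 0 && length(times)) {
    pk <- vapply(site_syn[seq_len(ns)], function(sy)
      epsp_peak(spec$tau_m, sy), numeric(1))
    delta <- with_seed(seed, rnorm(length(times),
                                   sd = spec$epsp_jitter_sd))
    scale <- 1 + delta / pk[site_of + 1L]
  }

  out <- cpp_simulate_if(GRID_DT, n_steps, spec$tau_m, spec$E_l,
                         spec$theta, spec$v_reset, spec$t_ref,
                         idx, site_of, scale,
                         vapply(site_syn[seq_len(ns)], `[[`, numeric(1),
                                "tau_fast"),
                         vapply(site_syn[seq_len(ns)], `[[`, numeric(1),
                                "w_fast"),
                         vapply(site_syn[seq_len(ns)], `[[`, numeric(1),
                                "tau_slow"),
                         vapply(site_syn[seq_len(ns)], `[[`, numeric(1),
                                "w_slow"),
                         subthreshold_only)
  structure(list(sample_times = (seq_len(n_steps) - 1) * GRID_DT,
                 voltage = out$voltage, spike_times = out$spike_times),
            class = "granule_response")
}

#' Expand a population's mossy-fiber inputs over a command sequence
#'
#' Expands every template of the library that the population uses (once per
#' fiber, shared across the granule cells it contacts, as in the circuit)
#' and returns per-cell per-site spike trains.
#'
#' @param population list of [granule_cell_spec()]
#' @param template_library the library the population was sampled from
#' @param seq a [command_sequence()]
#' @param variant `"original"` or `"revised"`
#' @param seed integer seed (stochastic fiber classes)
#' @param t_end span for tonic/pause fibers (ms)
#' @return list (per cell) of lists (per site) of spike-time vectors
#' @export
expand_population_inputs <- function(population, template_library, seq,
                                     variant = c("original", "revised"),
                                     seed = 1, t_end = NULL) {
  variant <- match.arg(variant)
  if (is.null(t_end)) t_end <- max(seq$command_times) + 200
  cache <- new.env(parent = emptyenv())
  get_expansion <- function(cl, i) {
    key <- paste0(cl, i)
    if (is.null(cache[[key]])) {
      tmpl <- template_library[[cl]][[i]]
      cache[[key]] <- expand_template(
        tmpl, seq, variant,
        seed = derive_seed(seed, match(cl, MOSSY_CLASSES) * 10000 + i),
        t_end = t_end)$spike_times
    }
    cache[[key]]
  }
  lapply(population, function(spec) {
    lapply(spec$sites, function(site) {
      if (site$class == "none") numeric(0)
      else get_expansion(site$class, site$template)
    })
  })
}

#' Simulate a whole granule population over a command sequence
#'
#' Convenience wrapper: expands inputs and simulates every cell. Returns
#' spike trains (and optionally voltages) per cell.
#'
#' @inheritParams expand_population_inputs
#' @param subthreshold_only disable thresholds (voltage statistics)?
#' @param keep_voltage return voltage traces (memory-heavy for large
#'   populations)?
#' @param jitter_seed base seed for the per-spike EPSP jitter
#' @return list with `spike_trains` (list of numeric vectors) and, if
#'   requested, `voltages`
#' @export
simulate_population <- function(population, template_library, seq,
                                variant = c("original", "revised"),
                                seed = 1, t_end = NULL,
                                subthreshold_only = FALSE,
                                keep_voltage = FALSE, jitter_seed = 1) {
  variant <- match.arg(variant)
  if (is.null(t_end)) t_end <- max(seq$command_times) + 200
  inputs <- expand_population_inputs(population, template_library, seq,
                                     variant, seed = seed, t_end = t_end)
  spikes <- vector("list", length(population))
  volts <- if (keep_voltage) vector("list", length(population)) else NULL
  for (i in seq_along(population)) {
    r <- simulate_granule(population[[i]], inputs[[i]], t_end = t_end,
                          subthreshold_only = subthreshold_only,
                          seed = derive_seed(jitter_seed, i))
    spikes[[i]] <- r$spike_times
    if (keep_voltage) volts[[i]] <- r$voltage
  }
  out <- list(spike_trains = spikes, t_end = t_end,
              n_samples = time_to_index(t_end))
  if (keep_voltage) out$voltages <- volts
  out
}
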