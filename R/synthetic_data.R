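# Synthetic inputs: EOD command sequences, the linear electroreceptor model
# (damped-oscillation impulse kernel convolved with mimic times), sensory
# traces for the ELL neuron, and synthetic granule-cell voltage recordings
# used to validate the fitting module.

#' EOD command sequence
#'
#' An ordered train of EOD motor-command times, optionally paired with EOD
#' mimic times at a fixed delay after each command. In the paralyzed
#' preparation the fish's actual discharge is blocked; the mimic is the
#' experimentally delivered electrosensory pulse. Pairing delay defaults to
#' 4.5 ms, the delay at which the EOD would normally occur.
#'
#' @param command_times strictly increasing times (ms), first command at 0
#' @param nominal_rate commands per second
#' @param paired logical; attach mimic times at `mimic_delay` after each
#'   command
#' @param mimic_delay ms
#' @return object of class `command_sequence`
#' @export
command_sequence <- function(command_times, nominal_rate, paired = FALSE,
                             mimic_delay = 4.5) {
  command_times <- as.numeric(command_times)
  if (length(command_times) < 1L || any(diff(command_times) <= 0))
    stop("`command_times` must be non-empty and strictly increasing",
         call. = FALSE)
  stopifnot_scalar_pos(nominal_rate, "nominal_rate")
  structure(list(
    command_times = command_times,
    nominal_rate = nominal_rate,
    mimic_times = if (paired) command_times + mimic_delay else NULL,
    mimic_delay = mimic_delay
  ), class = "command_sequence")
}

#' Generate a regular EOD command train
#'
#' Equally spaced commands at the given rate, emulating microstimulation
#' trains of (by default) 25 commands at 1-60 Hz.
#'
#' @param rate commands per second, in `[1, 60]`
#' @param n_commands number of commands
#' @param paired attach EOD mimic times (`command + mimic_delay`)?
#' @param seed unused for the regular train; accepted for interface symmetry
#'   with the stochastic generators
#' @param mimic_delay ms, default 4.5
#' @return a [command_sequence()]
#' @export
gen_command_sequence <- function(rate, n_commands, paired = FALSE,
                                 seed = NULL, mimic_delay = 4.5) {
  stopifnot_scalar_pos(rate, "rate")
  if (rate < 1 || rate > 60)
    stop("`rate` must be in [1, 60] commands/s", call. = FALSE)
  if (!is.numeric(n_commands) || n_commands < 1)
    stop("`n_commands` must be >= 1", call. = FALSE)
  times <- (seq_len(n_commands) - 1) * 1000 / rate
  command_sequence(times, rate, paired = paired, mimic_delay = mimic_delay)
}

#' @export
print.command_sequence <- function(x, ...) {
  cat(sprintf("<command_sequence> %d commands @ %.3g Hz, span %.1f ms%s\n",
              length(x$command_times), x$nominal_rate,
              diff(range(x$command_times)),
              if (!is.null(x$mimic_times))
                sprintf(", paired (mimic +%.2g ms)", x$mimic_delay) else ""))
  invisible(x)
}

#' Event times driving the sensory pathway
#'
#' Mimic times when the sequence is paired, command times otherwise.
#' @keywords internal
sensory_event_times <- function(seq) {
  if (!is.null(seq$mimic_times)) seq$mimic_times else seq$command_times
}

#' Damped-oscillation impulse-response kernel
#'
#' Electroreceptor afferents respond to an isolated EOD with a ringing,
#' damped-oscillation firing-rate deviation lasting ~200 ms. The synthetic
#' kernel is `peak_rate * exp(-t/decay_tau) * cos(2*pi*frequency*t/1000)`,
#' first lobe positive (excitatory). The oscillation frequency and decay are
#' stand-ins for unreported afferent parameters and are fully configurable.
#'
#' @param peak_rate spikes/s at t = 0
#' @param frequency oscillation frequency (Hz)
#' @param decay_tau envelope decay constant (ms)
#' @param duration kernel support (ms); must be at least `3 * decay_tau`
#' @param baseline_rate afferent baseline rate (spikes/s), metadata only
#' @return object of class `impulse_kernel` with fields `sample_times`,
#'   `values`, `baseline_rate`, `dt`
#' @export
gen_damped_oscillation_kernel <- function(peak_rate = 100, frequency = 10,
                                          decay_tau = 50, duration = 250,
                                          baseline_rate = 50) {
  stopifnot_scalar_pos(peak_rate, "peak_rate")
  stopifnot_scalar_pos(decay_tau, "decay_tau")
  if (duration < 3 * decay_tau)
    stop("`duration` must be >= 3 * decay_tau for the kernel to decay out",
         call. = FALSE)
  t <- seq(0, duration, by = GRID_DT)
  v <- peak_rate * exp(-t / decay_tau) * cos(2 * pi * frequency * t / 1000)
  structure(list(sample_times = t, values = v,
                 baseline_rate = baseline_rate, dt = GRID_DT),
            class = "impulse_kernel")
}

#' Linear prediction of afferent responses to a pulse train
#'
#' Superposition of the impulse kernel at every mimic time (command times if
#' unpaired): `L(t) = sum_i K(t - t_i)`, evaluated on the uniform grid from
#' t = 0 to the last pulse plus the kernel support.
#'
#' @param kernel an [gen_damped_oscillation_kernel()] object
#' @param seq a [command_sequence()]
#' @return object of class `linear_prediction` (`sample_times`, `values`)
#' @export
predict_linear_response <- function(kernel, seq) {
  if (!inherits(seq, "command_sequence") ||
      length(seq$command_times) == 0L)
    stop("`seq` must be a non-empty command_sequence", call. = FALSE)
  events <- snap_to_grid(sensory_event_times(seq))
  n <- time_to_index(max(events)) + length(kernel$values) - 1L
  imp <- numeric(n)
  idx <- time_to_index(events)
  imp[idx] <- imp[idx] + 1
  vals <- conv_causal(imp, kernel$values)
  structure(list(sample_times = (seq_len(n) - 1) * GRID_DT, values = vals),
            class = "linear_prediction")
}

#' Synthetic sensory input s(t) for the model ELL neuron
#'
#' The command-locked electrosensory drive onto the ELL neuron during
#' pairing, built from the linear afferent model and rescaled so that an
#' isolated mimic peaks at `amplitude` (arbitrary input units of the
#' current-based ELL neuron; polarity excitatory).
#'
#' @param kernel impulse kernel
#' @param seq paired [command_sequence()]
#' @param amplitude peak response to an isolated mimic (input units)
#' @return object of class `sensory_trace` (`sample_times`, `values`,
#'   `amplitude`)
#' @export
gen_sensory_trace <- function(kernel, seq, amplitude = 1) {
  if (is.null(seq$mimic_times))
    stop("sensory trace requires a paired sequence (mimic on)", call. = FALSE)
  stopifnot_scalar_pos(amplitude, "amplitude")
  lp <- predict_linear_response(kernel, seq)
  scale <- amplitude / max(abs(kernel$values))
  structure(list(sample_times = lp$sample_times,
                 values = lp$values * scale, amplitude = amplitude),
            class = "sensory_trace")
}

#' Synthetic granule-cell voltage recording
#'
#' Forward-simulates a granule cell (subthreshold unless `spiking = TRUE`)
#' from known input spike times, then adds recording noise and, optionally,
#' brief command-locked stimulus artifacts. The generating parameters and
#' input times are stored alongside the trace, so fitting-module tests can
#' score recovery against ground truth. Artifacts are 0.3 ms rectangular
#' deflections of +/-20 mV at command times, large enough that the
#' 1.8 mV/ms gradient criterion always catches them.
#'
#' Recording noise is an Ornstein-Uhlenbeck process with correlation time
#' `noise_tau` (default 5 ms) and stationary standard deviation
#' `noise_sd`: intracellular voltage noise is dominated by synaptic
#' background filtered by the ~10 ms membrane, so white noise at 20 kHz
#' would be unrealistically broadband; 5 ms is a conservative
#' (whiter-than-membrane) choice. The artifact-removal gradient criterion
#' presumes recordings whose synaptic rise slopes and noise gradients stay
#' below its 1.8 mV/ms threshold, so fixtures should combine kinetics and
#' noise accordingly.
#'
#' @param spec a [granule_cell_spec()]
#' @param seq a [command_sequence()] (only used for artifact times; may be
#'   NULL with `artifacts = FALSE`)
#' @param input_times list of numeric vectors, one per input site (ms)
#' @param noise_sd stationary noise SD (mV), >= 0; the default 0.05 mV
#'   reflects the low-noise whole-cell granule recordings the fitting
#'   procedure targets
#' @param seed integer seed
#' @param t_end trace duration (ms); default covers the last event + 100 ms
#' @param artifacts inject stimulus artifacts at command times?
#' @param spiking simulate with threshold enabled (for spike-removal tests)?
#' @param jitter apply the per-spike EPSP peak variability? Disable for
#'   exact parameter-recovery fixtures
#' @param noise_tau correlation time of the recording noise (ms)
#' @return object of class `synthetic_voltage_recording`
#' @export
gen_synthetic_voltage_recording <- function(spec, seq = NULL,
                                            input_times = list(numeric(0)),
                                            noise_sd = 0.05, seed = 1,
                                            t_end = NULL, artifacts = FALSE,
                                            spiking = FALSE, jitter = TRUE,
                                            noise_tau = 5) {
  if (noise_sd < 0) stop("`noise_sd` must be >= 0", call. = FALSE)
  last_event <- suppressWarnings(max(c(0, unlist(input_times),
                                       if (!is.null(seq)) seq$command_times)))
  if (is.null(t_end)) t_end <- last_event + 100
  sim <- simulate_granule(spec, input_times, t_end = t_end,
                          subthreshold_only = !spiking,
                          seed = if (jitter) derive_seed(seed, 1))
  v <- sim$voltage
  n <- length(v)
  if (noise_sd > 0) {
    rho <- exp(-GRID_DT / noise_tau)
    eps <- with_seed(derive_seed(seed, 2),
                     rnorm(n, sd = noise_sd * sqrt(1 - rho^2)))
    noise <- as.numeric(stats::filter(eps, rho, method = "recursive"))
    v <- v + noise
  }
  artifact_times <- numeric(0)
  if (artifacts && !is.null(seq)) {
    artifact_times <- snap_to_grid(seq$command_times)
    signs <- with_seed(derive_seed(seed, 3),
                       sample(c(-1, 1), length(artifact_times),
                              replace = TRUE))
    wid <- max(1L, as.integer(round(0.3 / GRID_DT)))
    for (a in seq_along(artifact_times)) {
      i0 <- time_to_index(artifact_times[a])
      ii <- i0:min(n, i0 + wid - 1L)
      v[ii] <- v[ii] + signs[a] * 20
    }
  }
  structure(list(sample_times = sim$sample_times, voltage = v,
                 true_input_times = input_times, true_params = spec,
                 true_spike_times = sim$spike_times,
                 artifact_times = artifact_times, noise_sd = noise_sd,
                 dt = GRID_DT),
            class = "synthetic_voltage_recording")
}
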