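# Expansion of single-command mossy-fiber templates into responses to full
# EOD command sequences, under the original and revised input models.
# Medium, late and pause fibers are treated identically in the two models;
# early and tonic fibers differ:
#   original - early fibers repeat the exact same burst after every command;
#              tonic fibers fire command-independent gamma-ISI trains.
#   revised  - early fibers drop spikes as a function of recent command
#              history (retained fraction f with tau_f df/dt = 1 - f and
#              f -> alpha f after each command, alpha = 0.72, tau_f = 80 ms);
#              tonic fibers are thinned by a retention probability that
#              falls linearly from 1 at <=10 Hz to 0.6 at 60 Hz of the
#              trailing-100-ms command rate.

EARLY_ALPHA <- 0.72
EARLY_TAU_F <- 80

#' Early-fiber spike-retention state
#'
#' @param f retained-spike fraction in (0, 1]
#' @param tau_f relaxation time constant (ms)
#' @param alpha multiplicative reduction per command
#' @return object of class `early_drop_state`
#' @export
early_drop_state <- function(f = 1, tau_f = EARLY_TAU_F,
                             alpha = EARLY_ALPHA) {
  if (alpha <= 0 || alpha > 1) stop("`alpha` must be in (0, 1]",
                                    call. = FALSE)
  if (f <= 0 || f > 1) stop("`f` must be in (0, 1]", call. = FALSE)
  structure(list(f = f, tau_f = tau_f, alpha = alpha),
            class = "early_drop_state")
}

#' Advance the early-fiber retention fraction through one command
#'
#' Relaxes `f` toward 1 over the inter-command interval
#' (`f <- 1 - (1 - f) exp(-dt/tau_f)`), then applies the per-command
#' reduction `f <- alpha * f`. A rested fiber (f = 1) therefore holds
#' f = alpha immediately after a command.
#'
#' @param state an [early_drop_state()]
#' @param dt_since_last_command ms, >= 0 (use `Inf` for a fully rested
#'   fiber)
#' @return updated `early_drop_state`
#' @export
step_early_drop <- function(state, dt_since_last_command) {
  if (dt_since_last_command < 0)
    stop("`dt_since_last_command` must be >= 0", call. = FALSE)
  relax <- 1 - (1 - state$f) * exp(-dt_since_last_command / state$tau_f)
  state$f <- state$alpha * relax
  state
}

#' @keywords internal
new_sequence_response <- function(spike_times, fiber_class, variant) {
  structure(list(spike_times = sort(spike_times),
                 fiber_class = fiber_class, variant = variant),
            class = "mossy_sequence_response")
}

#' @keywords internal
check_class <- function(template, wanted) {
  if (!identical(template$fiber_class, wanted))
    stop(sprintf("template is of class '%s', expected '%s'",
                 template$fiber_class, wanted), call. = FALSE)
}

#' Expand an early-fiber template over a command sequence
#'
#' Original model: the full burst is copied after every command. Revised
#' model: before the k-th command's burst is emitted, the retention
#' fraction is relaxed over the preceding interval; `round(f * n)` spikes
#' are kept, dropping from the end of the burst first (late burst spikes
#' disappear first at high rates), and the alpha reduction is then applied.
#' An isolated command always emits the full burst.
#'
#' @param template early-class [mossy_template()]
#' @param seq [command_sequence()]
#' @param variant `"original"` or `"revised"`
#' @return `mossy_sequence_response`
#' @export
expand_early <- function(template, seq, variant = c("original", "revised")) {
  check_class(template, "early")
  variant <- match.arg(variant)
  burst <- template$burst_times
  cmds <- seq$command_times
  if (variant == "original") {
    spikes <- as.vector(outer(burst, cmds, `+`))
    return(new_sequence_response(spikes, "early", variant))
  }
  f <- 1
  prev <- -Inf
  spikes <- vector("list", length(cmds))
  for (k in seq_along(cmds)) {
    relax <- 1 - (1 - f) * exp(-(cmds[k] - prev) / EARLY_TAU_F)
    n_keep <- round(relax * length(burst))
    if (n_keep > 0) spikes[[k]] <- cmds[k] + burst[seq_len(n_keep)]
    f <- EARLY_ALPHA * relax
    prev <- cmds[k]
  }
  new_sequence_response(unlist(spikes), "early", variant)
}

#' Expand a medium-fiber template over a command sequence
#'
#' The identical spike set is appended after every command; spikes from
#' successive commands may overlap. Spikes closer than a 1 ms absolute
#' refractory period are merged (the later spike dropped), bounding the
#' fiber's instantaneous rate.
#'
#' @inheritParams expand_early
#' @param refractory merge window (ms)
#' @export
expand_medium <- function(template, seq, refractory = 1) {
  check_class(template, "medium")
  spikes <- sort(as.vector(outer(template$burst_times, seq$command_times,
                                 `+`)))
  if (length(spikes) > 1) {
    keep <- logical(length(spikes))
    keep[1] <- TRUE
    last <- spikes[1]
    for (i in 2:length(spikes)) {
      if (spikes[i] - last >= refractory) {
        keep[i] <- TRUE
        last <- spikes[i]
      }
    }
    spikes <- spikes[keep]
  }
  new_sequence_response(spikes, "medium", "both")
}

#' Expand a late-fiber template over a command sequence
#'
#' Firing delays accumulate: walking the commands in order, each command
#' opens a silent window of `late_delay` ms that deletes pending spikes
#' from earlier commands; the command's own burst is appended after its
#' window. At short inter-command intervals earlier bursts are suppressed
#' entirely.
#'
#' @inheritParams expand_early
#' @export
expand_late <- function(template, seq) {
  check_class(template, "late")
  pending <- numeric(0)
  for (cmd in seq$command_times) {
    pending <- pending[pending <= cmd | pending > cmd + template$late_delay]
    pending <- c(pending, cmd + template$late_burst)
  }
  new_sequence_response(pending, "late", "both")
}

#' Expand a pause-fiber template over a command sequence
#'
#' A tonic gamma-ISI train is laid down over the whole span; every spike in
#' `(command, command + pause_duration]` is deleted. When inter-command
#' intervals are shorter than the pause, the pauses tile the train and
#' firing ceases for its duration.
#'
#' @inheritParams expand_early
#' @param seed integer seed for the tonic background
#' @param t_end span to populate (ms); default last command + 200 ms
#' @export
expand_pause <- function(template, seq, seed, t_end = NULL) {
  check_class(template, "pause")
  if (is.null(t_end)) t_end <- max(seq$command_times) + 200
  spikes <- with_seed(seed, sample_isi_train(template$isi_law, t_end))
  for (cmd in seq$command_times)
    spikes <- spikes[spikes <= cmd | spikes > cmd + template$pause_duration]
  new_sequence_response(spikes, "pause", "both")
}

#' Linear tonic-fiber retention probability
#'
#' Retention of tonic mossy-fiber spikes as a function of the recent EOD
#' command rate: 1 at or below 10 Hz, falling linearly to 0.6 at 60 Hz,
#' clamped to `[0.6, 1]` outside the measured 10-60 Hz range.
#'
#' @param rate_hz command rate (commands/s), vectorized
#' @return retention probability in `[0.6, 1]`
#' @export
tonic_retention <- function(rate_hz) {
  pmin(1, pmax(0.6, 1 - 0.4 * (rate_hz - 10) / 50))
}

#' Expand a tonic-fiber template over a command sequence
#'
#' Original model: a command-independent gamma-ISI train. Revised model:
#' each spike of that train is retained with probability
#' [tonic_retention()] of the trailing-100-ms command rate (command count
#' in the last 100 ms times 10).
#'
#' @inheritParams expand_pause
#' @param variant `"original"` or `"revised"`
#' @export
expand_tonic <- function(template, seq, variant = c("original", "revised"),
                         seed, t_end = NULL) {
  check_class(template, "tonic")
  variant <- match.arg(variant)
  if (is.null(t_end)) t_end <- max(seq$command_times) + 200
  spikes <- with_seed(derive_seed(seed, 1),
                      sample_isi_train(template$isi_law, t_end))
  if (variant == "revised" && length(spikes)) {
    cmds <- seq$command_times
    n_recent <- vapply(spikes, function(s)
      sum(cmds > s - 100 & cmds <= s), numeric(1))
    p <- tonic_retention(n_recent * 10)
    keep <- with_seed(derive_seed(seed, 2), runif(length(spikes)) < p)
    spikes <- spikes[keep]
  }
  new_sequence_response(spikes, "tonic", variant)
}

#' Expand any template over a command sequence
#'
#' Dispatches on the template's fiber class. Stochastic classes (pause,
#' tonic) require a seed; deterministic classes ignore it.
#'
#' @inheritParams expand_tonic
#' @param template any [mossy_template()]
#' @export
expand_template <- function(template, seq,
                            variant = c("original", "revised"),
                            seed = 1, t_end = NULL) {
  variant <- match.arg(variant)
  switch(template$fiber_class,
         early = expand_early(template, seq, variant),
         medium = expand_medium(template, seq),
         late = expand_late(template, seq),
         pause = expand_pause(template, seq, seed = seed, t_end = t_end),
         tonic = expand_tonic(template, seq, variant, seed = seed,
                              t_end = t_end))
}
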