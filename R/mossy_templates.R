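# Mossy-fiber single-command response templates. Five functional classes of
# corollary-discharge input to granule cells: early (precisely timed burst
# ~12 ms long at short latency), medium (spikes at intermediate delays),
# late (delayed firing after a silent period), pause (tonic firing
# interrupted after each command), and tonic (high-rate, command-independent
# firing; includes unipolar-brush-cell-like input).

MOSSY_CLASSES <- c("early", "medium", "late", "pause", "tonic")

#' Mossy-fiber single-command response template
#'
#' Describes how one fiber of one class responds to an isolated EOD command.
#' Burst times are relative to the command (ms). Tonic and pause fibers
#' carry an inter-spike-interval law (gamma ISIs) instead of / in addition
#' to burst structure.
#'
#' @param fiber_class one of `"early"`, `"medium"`, `"late"`, `"pause"`,
#'   `"tonic"`
#' @param burst_times spike times relative to the command (ms); early and
#'   medium classes
#' @param late_delay silent delay after the command (ms); late class
#' @param late_burst spike times relative to the command, all
#'   `> late_delay`; late class
#' @param pause_duration pause length after each command (ms); pause class
#' @param isi_law list with `shape` and `mean_isi` (ms); tonic and pause
#'   classes
#' @return object of class `mossy_template`
#' @export
mossy_template <- function(fiber_class, burst_times = NULL,
                           late_delay = NULL, late_burst = NULL,
                           pause_duration = NULL, isi_law = NULL) {
  fiber_class <- match.arg(fiber_class, MOSSY_CLASSES)
  if (fiber_class %in% c("early", "medium")) {
    if (is.null(burst_times) || length(burst_times) == 0)
      stop(fiber_class, " template needs `burst_times`", call. = FALSE)
    burst_times <- sort(as.numeric(burst_times))
    if (any(burst_times < 0))
      stop("`burst_times` must be non-negative", call. = FALSE)
  }
  if (fiber_class == "late") {
    if (is.null(late_delay) || is.null(late_burst))
      stop("late template needs `late_delay` and `late_burst`",
           call. = FALSE)
    late_burst <- sort(as.numeric(late_burst))
    if (any(late_burst <= late_delay))
      stop("`late_burst` spikes must fall after `late_delay`", call. = FALSE)
  }
  if (fiber_class == "pause") {
    if (is.null(pause_duration) || pause_duration <= 0)
      stop("pause template needs `pause_duration` > 0", call. = FALSE)
    if (is.null(isi_law)) stop("pause template needs `isi_law`",
                               call. = FALSE)
  }
  if (fiber_class == "tonic" && is.null(isi_law))
    stop("tonic template needs `isi_law`", call. = FALSE)
  structure(list(fiber_class = fiber_class, burst_times = burst_times,
                 late_delay = late_delay, late_burst = late_burst,
                 pause_duration = pause_duration, isi_law = isi_law),
            class = "mossy_template")
}

#' Sample a stationary gamma-ISI spike train
#'
#' ISIs are gamma with the law's shape and mean; the train is started one
#' random ISI fraction before zero so spiking is (approximately) stationary
#' over `[0, t_end]`.
#' @keywords internal
sample_isi_train <- function(isi_law, t_end) {
  mean_isi <- isi_law$mean_isi
  shape <- isi_law$shape
  n_guess <- max(16L, as.integer(ceiling(1.5 * t_end / mean_isi)) + 8L)
  isis <- rgamma(n_guess, shape = shape, scale = mean_isi / shape)
  t0 <- -runif(1) * mean_isi
  s <- t0 + cumsum(isis)
  while (length(s) && s[length(s)] < t_end) {
    extra <- rgamma(n_guess, shape = shape, scale = mean_isi / shape)
    s <- c(s, s[length(s)] + cumsum(extra))
  }
  s[s >= 0 & s <= t_end]
}

#' Generate a synthetic mossy-fiber template library
#'
#' Randomized per-fiber templates emulating the statistics of recorded
#' single-command responses: early bursts of 3-6 spikes spanning ~12 ms at
#' 2-6 ms latency; medium spikes at 15-50 ms; late bursts after a 30-60 ms
#' silent delay; pause fibers with 20-60 ms pauses over gamma-ISI tonic
#' firing; tonic fibers with gamma ISIs (shape 4) at 20-80 spikes/s.
#'
#' @param n_per_class fibers per class
#' @param seed integer seed
#' @return object of class `template_library`: list of template lists by
#'   class
#' @export
gen_template_library <- function(n_per_class = 40, seed = 1) {
  lib <- with_seed(seed, {
    lapply_named <- function(cls, f)
      stats::setNames(lapply(seq_len(n_per_class), f), NULL)
    list(
      early = lapply_named("early", function(i) {
        n <- sample(3:6, 1)
        delay <- runif(1, 2, 6)
        span <- runif(1, 10, 12)
        mossy_template("early",
                       burst_times = delay + span * seq(0, 1,
                                                        length.out = n))
      }),
      medium = lapply_named("medium", function(i) {
        n <- sample(2:5, 1)
        mossy_template("medium", burst_times = sort(runif(n, 15, 50)))
      }),
      late = lapply_named("late", function(i) {
        delay <- runif(1, 30, 60)
        n <- sample(3:8, 1)
        span <- runif(1, 15, 30)
        mossy_template("late", late_delay = delay,
                       late_burst = delay + span * seq_len(n) / n)
      }),
      pause = lapply_named("pause", function(i) {
        rate <- runif(1, 20, 80)
        mossy_template("pause", pause_duration = runif(1, 20, 60),
                       isi_law = list(shape = 4, mean_isi = 1000 / rate))
      }),
      tonic = lapply_named("tonic", function(i) {
        rate <- runif(1, 20, 80)
        mossy_template("tonic",
                       isi_law = list(shape = 4, mean_isi = 1000 / rate))
      })
    )
  })
  structure(lib, class = "template_library")
}
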