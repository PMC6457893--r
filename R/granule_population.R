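# Model granule-cell populations built by random mixing of mossy-fiber
# inputs. Each granule cell has three input sites; each site independently
# receives early / medium / late / pause / tonic / no input with fixed
# probabilities, and then a uniformly chosen fiber of that class from the
# template library. Synapse kernel parameters (fast and slow time constants
# and weights of the dual-exponential EPSC) are drawn per cell from gamma
# distributions and shared across the cell's inputs.

#' Default input-class probabilities
#'
#' Per-site probabilities of receiving early, medium, late, pause, tonic or
#' no input, as estimated from fits to recorded granule cells.
#' @export
DEFAULT_CLASS_PROBS <- c(early = 0.425, medium = 0.075, late = 0.05,
                         pause = 0.05, tonic = 0.157, none = 0.243)

#' Default gamma hyperparameters for synapse kernel parameters
#'
#' Means and shapes of the gamma distributions from which `tau_fast`,
#' `w_fast`, `tau_slow` and `w_slow` are drawn (one independent draw each,
#' per cell). The means are stand-ins chosen so that a mean-parameter
#' single EPSP peaks near 8 mV with a 10 ms membrane; the fitted values of
#' the recorded cells are not tabulated, so these are configurable
#' defaults, not reconstructions.
#' @export
DEFAULT_SYNAPSE_HYPER <- list(
  tau_fast = list(mean = 2, shape = 4),
  w_fast = list(mean = 100, shape = 4),
  tau_slow = list(mean = 20, shape = 4),
  w_slow = list(mean = 80, shape = 4)
)

#' Dual-exponential synapse kernel parameters
#'
#' `E(t) = (w_fast/tau_fast) exp(-t/tau_fast) +
#'         (w_slow/tau_slow) exp(-t/tau_slow)` (mV.ms weights; the kernel
#' enters the membrane equation as a current in voltage units).
#'
#' @param tau_fast,w_fast,tau_slow,w_slow positive; `tau_fast < tau_slow`
#' @return object of class `synapse_params`
#' @export
synapse_params <- function(tau_fast, w_fast, tau_slow, w_slow) {
  for (nm in c("tau_fast", "w_fast", "tau_slow", "w_slow"))
    stopifnot_scalar_pos(get(nm), nm)
  if (tau_fast >= tau_slow)
    stop("`tau_fast` must be < `tau_slow`", call. = FALSE)
  structure(list(tau_fast = tau_fast, w_fast = w_fast,
                 tau_slow = tau_slow, w_slow = w_slow),
            class = "synapse_params")
}

#' Draw synapse kernel parameters from their gamma hyperpriors
#'
#' Four independent gamma draws (always positive); one parameter set is
#' shared by all inputs to a given cell. Draws where the fast time constant
#' would exceed the slow one are resampled.
#'
#' @param seed integer seed
#' @param hyper hyperparameter list, see [DEFAULT_SYNAPSE_HYPER]
#' @return a [synapse_params()]
#' @export
sample_synapse_params <- function(seed, hyper = DEFAULT_SYNAPSE_HYPER) {
  with_seed(seed, {
    draw <- function(h) rgamma(1, shape = h$shape,
                               scale = h$mean / h$shape)
    repeat {
      tf <- draw(hyper$tau_fast)
      ts <- draw(hyper$tau_slow)
      if (tf < ts) break
    }
    synapse_params(tf, draw(hyper$w_fast), ts, draw(hyper$w_slow))
  })
}

#' Integrate-and-fire granule-cell specification
#'
#' Membrane parameters plus the three input-site assignments. Threshold,
#' reset and refractory period are not constrained by the recorded-cell
#' fits and default to `theta = E_l + 10` mV (so single early EPSPs of
#' ~8 mV are usually subthreshold and spikes require summation),
#' `v_reset = E_l`, `t_ref = 1` ms.
#'
#' @param tau_m membrane time constant (ms)
#' @param E_l leak / resting potential (mV)
#' @param theta spike threshold (mV), `> E_l`
#' @param v_reset post-spike reset (mV)
#' @param t_ref absolute refractory period (ms)
#' @param sites list of exactly 3 site assignments; each either
#'   `list(class = "none")` or `list(class = <fiber class>, template = i)`
#' @param syn a [synapse_params()] shared by the cell's inputs (the
#'   population model draws one parameter set per cell)
#' @param syn_sites optional list of per-site [synapse_params()],
#'   overriding `syn` (used for two-input fitting fixtures where the
#'   command-locked and tonic channels have different kinetics)
#' @param epsp_jitter_sd SD of the per-spike EPSP peak-height perturbation
#'   (mV); trial-to-trial variability of recorded single EPSPs
#' @return object of class `granule_cell_spec`
#' @export
granule_cell_spec <- function(tau_m = 10, E_l = -65, theta = E_l + 10,
                              v_reset = E_l, t_ref = 1,
                              sites = rep(list(list(class = "none")), 3),
                              syn = synapse_params(2, 100, 20, 80),
                              syn_sites = NULL,
                              epsp_jitter_sd = 0.224) {
  if (theta <= E_l) stop("`theta` must exceed `E_l`", call. = FALSE)
  if (length(sites) != 3L)
    stop("a granule cell has exactly 3 input sites", call. = FALSE)
  structure(list(tau_m = tau_m, E_l = E_l, theta = theta,
                 v_reset = v_reset, t_ref = t_ref, sites = sites,
                 syn = syn, syn_sites = syn_sites,
                 epsp_jitter_sd = epsp_jitter_sd),
            class = "granule_cell_spec")
}

#' Sample a model granule-cell population
#'
#' Each of the three sites of each cell is independently assigned an input
#' class with probabilities `class_probs`, then a uniformly chosen template
#' of that class from the library. Synapse parameters are drawn per cell.
#'
#' @param n_cells population size
#' @param class_probs named probabilities over
#'   `c("early","medium","late","pause","tonic","none")`, summing to 1
#' @param template_library a [gen_template_library()] object
#' @param seed integer seed
#' @param hyper synapse hyperparameters
#' @param ... membrane parameter overrides passed to [granule_cell_spec()]
#' @return list of `granule_cell_spec`
#' @export
sample_population <- function(n_cells, class_probs = DEFAULT_CLASS_PROBS,
                              template_library, seed,
                              hyper = DEFAULT_SYNAPSE_HYPER, ...) {
  if (abs(sum(class_probs) - 1) > 1e-9)
    stop("`class_probs` must sum to 1", call. = FALSE)
  classes <- names(class_probs)
  n_avail <- vapply(classes, function(cl)
    if (cl == "none") 1L else length(template_library[[cl]]), integer(1))
  if (any(n_avail == 0L & class_probs > 0))
    stop("template library has an empty class with nonzero probability",
         call. = FALSE)
  with_seed(seed, {
    lapply(seq_len(n_cells), function(i) {
      sites <- lapply(1:3, function(s) {
        cl <- sample(classes, 1, prob = class_probs)
        if (cl == "none") list(class = "none")
        else list(class = cl,
                  template = sample.int(length(template_library[[cl]]), 1))
      })
      draw <- function(h) rgamma(1, shape = h$shape,
                                 scale = h$mean / h$shape)
      repeat {
        tf <- draw(hyper$tau_fast)
        ts <- draw(hyper$tau_slow)
        if (tf < ts) break
      }
      syn <- synapse_params(tf, draw(hyper$w_fast), ts, draw(hyper$w_slow))
      granule_cell_spec(sites = sites, syn = syn, ...)
    })
  })
}

#' Fractional increase in maximum membrane voltage, 10 Hz to 60 Hz
#'
#' `(max depolarization at 60 Hz - max at 10 Hz) / max at 10 Hz`, measured
#' on subthreshold (spike-free) traces relative to the leak potential. The
#' experimental reference value is 0.006 (fractional scale).
#'
#' @param resp_10,resp_60 `granule_response` objects from the same cell
#' @param E_l leak potential used as baseline (mV)
#' @return dimensionless fraction
#' @export
stat_percent_increase <- function(resp_10, resp_60, E_l) {
  m10 <- max(resp_10$voltage - E_l)
  m60 <- max(resp_60$voltage - E_l)
  if (m10 <= 0) stop("10 Hz maximum depolarization is zero; statistic undefined",
                     call. = FALSE)
  (m60 - m10) / m10
}

#' Best-fit slope of membrane voltage across a train (mV/s)
#'
#' Ordinary least-squares slope of the subthreshold voltage against time
#' over the train window. The experimental reference value for 60 Hz trains
#' is -0.43 mV/s.
#'
#' @param resp a `granule_response` (subthreshold trace)
#' @param window `c(t_start, t_end)` in ms; default the full trace
#' @return slope in mV/s
#' @export
stat_slope_60hz <- function(resp, window = NULL) {
  t <- resp$sample_times
  v <- resp$voltage
  if (!is.null(window)) {
    sel <- t >= window[1] & t <= window[2]
    t <- t[sel]; v <- v[sel]
  }
  if (length(t) < 2) stop("window shorter than 2 samples", call. = FALSE)
  1000 * stats::cov(t, v) / stats::var(t)  # mV/ms -> mV/s
}

#' Bootstrap distribution of sample-size-matched medians
#'
#' Draws `n_draws` sets of `set_size` cells (with replacement) from the
#' model population's per-cell statistics, computes each set's median, and
#' reports a two-sided tail probability of a reference value relative to
#' the bootstrap median. The two-sided floor of the 1000-draw resolution is
#' 2/1000, reported via `p_floor`.
#'
#' @param population_values per-cell statistic values
#' @param reference reference (experimental) value
#' @param n_draws bootstrap draws
#' @param set_size cells per draw (28 matches the recorded sample)
#' @param seed integer seed
#' @return list with `bootstrap_medians`, `p_value`, `p_floor`
#' @export
bootstrap_stat <- function(population_values, reference, n_draws = 1000,
                           set_size = 28, seed = 1) {
  if (length(population_values) < set_size)
    stop("population smaller than `set_size`", call. = FALSE)
  meds <- with_seed(seed, vapply(seq_len(n_draws), function(i)
    stats::median(sample(population_values, set_size, replace = TRUE)),
    numeric(1)))
  p <- 2 * min(mean(meds <= reference), mean(meds >= reference))
  floor_p <- 2 / n_draws
  list(bootstrap_medians = meds,
       p_value = min(1, max(p, floor_p)),
       p_floor = p < floor_p)
}
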