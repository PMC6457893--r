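# End-to-end model experiments: generalization (learn at 10 Hz, probe
# across rates), training at all rates, and population-statistics
# comparisons between the original and revised input models. A single
# seeded config fixes the template library, granule population, sensory
# kernel and protocol, so whole reports are reproducible.

#' Experiment configuration
#'
#' @param variant mossy-fiber input model, `"original"` or `"revised"`
#' @param regularization `"minimal"` (1/lambda = 1000 s, weights start and
#'   decay toward 0) or `"full"` (1/lambda = 10 s, weights start at and
#'   decay toward the baseline `w_c` matched to the sensory input)
#' @param protocol a [pairing_protocol()]
#' @param n_cells granule population size (the reference model uses
#'   20,000; the desk-scale default is 2,000 with the plasticity rates
#'   rescaled to matched drive)
#' @param n_per_class template-library fibers per class
#' @param kernel sensory impulse kernel
#' @param sensory_amplitude peak s(t) for an isolated mimic (input units)
#' @param delta_plus,delta_minus reference-size plasticity rates (rescaled
#'   internally by `20000 / n_cells`)
#' @param seed master seed
#' @return object of class `experiment_config`
#' @export
experiment_config <- function(variant = c("revised", "original"),
                              regularization = c("full", "minimal"),
                              protocol = pairing_protocol(),
                              n_cells = 2000, n_per_class = 40,
                              kernel = gen_damped_oscillation_kernel(),
                              sensory_amplitude = 1,
                              delta_plus = 4e-6, delta_minus = 0.02,
                              seed = 1) {
  structure(list(variant = match.arg(variant),
                 regularization = match.arg(regularization),
                 protocol = protocol, n_cells = n_cells,
                 n_per_class = n_per_class, kernel = kernel,
                 sensory_amplitude = sensory_amplitude,
                 delta_plus = delta_plus, delta_minus = delta_minus,
                 seed = seed),
            class = "experiment_config")
}

#' Prepare the shared inputs of an experiment
#'
#' Builds the template library and granule population, simulates granule
#' spike responses (threshold on) to a 25-command paired sequence at every
#' rate the protocol touches, and computes the sensory trace per rate.
#' Returns everything [run_pairing_experiment()] needs, plus the baseline
#' weight and initial state for the configured regularization mode.
#'
#' @param config an [experiment_config()]
#' @return list with `inputs_by_rate`, `state`, `rule`, `population`,
#'   `library`, `w_c`
#' @export
setup_experiment <- function(config) {
  proto <- config$protocol
  rates <- sort(unique(c(proto$learn_rates, proto$probe_rates)))
  lib <- gen_template_library(config$n_per_class,
                              seed = derive_seed(config$seed, 1))
  pop <- sample_population(config$n_cells, template_library = lib,
                           seed = derive_seed(config$seed, 2))
  epsp <- synapse_params(2, 0.5, 15, 0.5)
  inputs_by_rate <- list()
  for (r in rates) {
    seq_r <- gen_command_sequence(r, proto$commands_per_block,
                                  paired = TRUE)
    span <- max(seq_r$command_times)
    t_end <- span + 300
    simr <- simulate_population(pop, lib, seq_r, config$variant,
                                seed = derive_seed(config$seed, 100 + r),
                                t_end = t_end,
                                jitter_seed = derive_seed(config$seed,
                                                          200 + r))
    s <- gen_sensory_trace(config$kernel, seq_r,
                           amplitude = config$sensory_amplitude)
    n_samples <- simr$n_samples
    sv <- c(s$values, numeric(max(0, n_samples - length(s$values))))
    sv <- sv[1:n_samples]
    inputs_by_rate[[as.character(r)]] <-
      list(spike_trains = simr$spike_trains, s = sv,
           n_samples = n_samples, window = c(0, t_end),
           rate = r, n_commands = proto$commands_per_block)
  }
  rule <- scale_rule(plasticity_rule(config$delta_plus,
                                     config$delta_minus),
                     n_inputs = config$n_cells)
  rule$lambda <- if (config$regularization == "full") 1 / 10 else 1 / 1000
  first <- inputs_by_rate[[as.character(proto$learn_rates[1])]]
  state0 <- ell_state(rep(0, config$n_cells), epsp = epsp)
  w_c <- set_baseline_weights(state0, first$s, first$spike_trains)
  if (config$regularization == "full") {
    rule$w_c <- w_c
    state0$weights <- rep(w_c, config$n_cells)
  } else {
    rule$w_c <- 0
  }
  list(inputs_by_rate = inputs_by_rate, state = state0, rule = rule,
       population = pop, library = lib, w_c = w_c)
}

#' Run the generalization experiment
#'
#' Pairing (learning) at the protocol's learn rates only (10 Hz by
#' default), probing across all probe rates pre and post with plasticity
#' frozen, plus command-alone probes for the negative image.
#'
#' @param config an [experiment_config()]
#' @param prepared optional result of [setup_experiment()] to reuse
#' @return list (`experiment_report`): `cancellation` per rate,
#'   `per_block_C`, `weight_variance`, `negative_image`, `state`, `w_c`,
#'   `config`
#' @export
run_generalization <- function(config, prepared = NULL) {
  if (is.null(prepared)) prepared <- setup_experiment(config)
  res <- run_pairing_experiment(config$protocol, prepared$state,
                                prepared$rule, prepared$inputs_by_rate)
  res$weight_variance <- stats::var(res$state$weights)
  res$w_c <- prepared$w_c
  res$config <- config
  res$C_table <- data.frame(
    rate = as.numeric(names(res$cancellation)),
    C = vapply(res$cancellation, `[[`, numeric(1),
               "residual_power_ratio"))
  res
}

#' Run the train-at-all-rates benchmark
#'
#' Identical to [run_generalization()] except that learning blocks cycle
#' through every probe rate, so no generalization is required.
#'
#' @inheritParams run_generalization
#' @export
run_train_all_rates <- function(config, prepared = NULL) {
  config$protocol$learn_rates <- config$protocol$probe_rates
  run_generalization(config, prepared = prepared)
}

#' Per-cell voltage statistics of a granule population
#'
#' Simulates every cell subthreshold at 10 Hz and 60 Hz 25-command trains
#' and returns the per-cell fractional max-voltage increase and the 60 Hz
#' voltage slope (over the train window).
#'
#' @param population,template_library,variant,seed as in
#'   [simulate_population()]
#' @param n_commands commands per train
#' @return data.frame with `pct_increase` and `slope_60`
#' @export
population_voltage_stats <- function(population, template_library,
                                     variant = c("original", "revised"),
                                     seed = 1, n_commands = 25) {
  variant <- match.arg(variant)
  seq10 <- gen_command_sequence(10, n_commands)
  seq60 <- gen_command_sequence(60, n_commands)
  span60 <- max(seq60$command_times)
  in10 <- expand_population_inputs(population, template_library, seq10,
                                   variant, seed = derive_seed(seed, 10),
                                   t_end = max(seq10$command_times) + 200)
  in60 <- expand_population_inputs(population, template_library, seq60,
                                   variant, seed = derive_seed(seed, 60),
                                   t_end = span60 + 200)
  pct <- slope <- rep(NA_real_, length(population))
  for (i in seq_along(population)) {
    spec <- population[[i]]
    r10 <- simulate_granule(spec, in10[[i]],
                            t_end = max(seq10$command_times) + 200,
                            subthreshold_only = TRUE,
                            seed = derive_seed(seed, 1000 + i))
    r60 <- simulate_granule(spec, in60[[i]], t_end = span60 + 200,
                            subthreshold_only = TRUE,
                            seed = derive_seed(seed, 2000 + i))
    m10 <- max(r10$voltage - spec$E_l)
    if (m10 > 1e-9) {
      pct[i] <- stat_percent_increase(r10, r60, spec$E_l)
      slope[i] <- stat_slope_60hz(r60, window = c(0, span60 + 20))
    }
  }
  data.frame(pct_increase = pct, slope_60 = slope)
}

#' Compare population statistics of the two input models
#'
#' Simulates matched populations (same cells, same seeds) under the
#' original and revised input models, computes per-cell statistics, and
#' bootstraps sample-size-matched medians against the experimental
#' reference values (fractional max-voltage increase 0.006; 60 Hz slope
#' -0.43 mV/s).
#'
#' @param config an [experiment_config()] (variant field ignored)
#' @param reference_pct,reference_slope experimental reference values
#' @return list with per-variant statistic tables and bootstrap summaries
#' @export
run_population_comparison <- function(config, reference_pct = 0.006,
                                      reference_slope = -0.43) {
  lib <- gen_template_library(config$n_per_class,
                              seed = derive_seed(config$seed, 1))
  pop <- sample_population(config$n_cells, template_library = lib,
                           seed = derive_seed(config$seed, 2))
  out <- list(config = config)
  for (variant in c("original", "revised")) {
    st <- population_voltage_stats(pop, lib, variant,
                                   seed = derive_seed(config$seed, 3))
    st <- st[stats::complete.cases(st), ]
    out[[variant]] <- list(
      stats = st,
      boot_pct = bootstrap_stat(st$pct_increase, reference_pct,
                                seed = derive_seed(config$seed, 4)),
      boot_slope = bootstrap_stat(st$slope_60, reference_slope,
                                  seed = derive_seed(config$seed, 5)))
  }
  out
}
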