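# Shared, lazily computed experiment runs for the acceptance-level tests.
# The two canonical model configurations (minimally regularized original
# model; fully regularized revised model) are each run once per session at
# the desk-scale population size and reused across the convergence,
# generalization, weight-variance and negative-image checks.

acc_cache <- new.env(parent = emptyenv())

acc_protocol <- function()
  pairing_protocol(learn_rates = 10, probe_rates = c(10, 40, 60),
                   n_learning_blocks = 100)

acc_run <- function(variant, regularization) {
  key <- paste(variant, regularization, sep = "_")
  if (is.null(acc_cache[[key]])) {
    cfg <- experiment_config(variant, regularization,
                             protocol = acc_protocol(),
                             n_cells = 2000, seed = 1)
    prep_key <- paste0("prep_", variant)
    if (is.null(acc_cache[[prep_key]]))
      acc_cache[[prep_key]] <- setup_experiment(cfg)
    prep <- acc_cache[[prep_key]]
    # regularization mode determines rule/initial state; rebuild them for
    # this config while reusing the prepared inputs
    rule <- scale_rule(plasticity_rule(cfg$delta_plus, cfg$delta_minus),
                       n_inputs = cfg$n_cells)
    rule$lambda <- if (regularization == "full") 1 / 10 else 1 / 1000
    state0 <- ell_state(rep(0, cfg$n_cells))
    if (regularization == "full") {
      rule$w_c <- prep$w_c
      state0$weights <- rep(prep$w_c, cfg$n_cells)
    }
    prep2 <- prep
    prep2$rule <- rule
    prep2$state <- state0
    acc_cache[[key]] <- run_generalization(cfg, prep2)
    acc_cache[[paste0("inputs_", variant)]] <- prep$inputs_by_rate
  }
  acc_cache[[key]]
}

acc_inputs <- function(variant) {
  acc_run(variant, if (variant == "original") "minimal" else "full")
  acc_cache[[paste0("inputs_", variant)]]
}
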