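# Fixture kinetics: the EPSP onset slope (w_fast/tau_fast + w_slow/tau_slow)
# / tau_m = 1.13 mV/ms stays well below the 1.8 mV/ms artifact threshold
# even with noise-gradient fluctuations on top, as in the recordings the
# cleaning rule was designed for.
fit_spec <- function() granule_cell_spec(tau_m = 12, E_l = -66,
                                         syn = synapse_params(3.5, 36,
                                                              18, 60))

test_that("gradient-threshold cleaning preserves smooth traces", {
  spec <- fit_spec()
  rec <- gen_synthetic_voltage_recording(spec, NULL, list(c(50, 150)),
                                         noise_sd = 0, seed = 1,
                                         t_end = 300, jitter = FALSE)
  cl <- clean_trace(rec$voltage)
  expect_equal(nrow(cl$removed_intervals), 0)
  expect_equal(cl$voltage, rec$voltage)
  expect_error(clean_trace(c(1)), "2 samples")
})

test_that("cleaning excises every injected artifact and action potential", {
  spec <- fit_spec()
  sq <- gen_command_sequence(10, 5, paired = TRUE)
  rec <- gen_synthetic_voltage_recording(spec, sq, list(c(50, 250, 380)),
                                         noise_sd = 0.05, seed = 2,
                                         artifacts = TRUE)
  cl <- clean_trace(rec$voltage)
  expect_gte(nrow(cl$removed_intervals), length(rec$artifact_times))
  for (a in rec$artifact_times) {
    hit <- any(cl$removed_intervals[, 1] <= a + 0.3 &
               cl$removed_intervals[, 2] >= a)
    expect_true(hit, label = sprintf("artifact at %.1f ms excised", a))
  }
  # the cleaned trace respects the gradient bound away from the edges
  grad <- diff(cl$voltage) / GRID_DT
  expect_lt(max(abs(grad)), 1.8 + 1e-6)

  # a spiking cell: action potentials excised, EPSP feet preserved
  spiky <- granule_cell_spec(theta = -60, v_reset = -70,
                             syn = fit_spec()$syn)
  rec2 <- gen_synthetic_voltage_recording(spiky, NULL,
                                          list(c(100, 102, 104)),
                                          noise_sd = 0, seed = 3,
                                          t_end = 300, spiking = TRUE)
  expect_gt(length(rec2$true_spike_times), 0)
  cl2 <- clean_trace(rec2$voltage)
  sp <- rec2$true_spike_times[1]
  expect_true(any(cl2$removed_intervals[, 1] <= sp &
                  cl2$removed_intervals[, 2] >= sp))
})

test_that("wavelet detection finds separated EPSPs and nothing in noise", {
  spec <- fit_spec()
  # noise-only fixture: no candidates at the default threshold
  flat <- gen_synthetic_voltage_recording(spec, NULL, list(numeric(0)),
                                          noise_sd = 0.05, seed = 4,
                                          t_end = 1000)
  cand0 <- detect_epsps(clean_trace(flat$voltage))
  expect_length(cand0$times, 0)

  # three separated EPSPs recovered within 0.5 ms
  truth <- c(100, 300, 520)
  rec <- gen_synthetic_voltage_recording(spec, NULL, list(truth),
                                         noise_sd = 0.05, seed = 5,
                                         t_end = 700)
  cand <- detect_epsps(clean_trace(rec$voltage))
  expect_length(cand$times, 3)
  expect_true(all(abs(cand$times - truth) <= 0.5))

  # two inputs 0.3 ms apart merge into one candidate (known limitation)
  rec2 <- gen_synthetic_voltage_recording(spec, NULL, list(c(100, 100.3)),
                                          noise_sd = 0.05, seed = 6,
                                          t_end = 300)
  cand2 <- detect_epsps(clean_trace(rec2$voltage))
  expect_length(cand2$times, 1)
  # candidate separation invariant
  expect_true(all(diff(cand$times) >= 0.5))
})

test_that("detection is translation-equivariant", {
  spec <- fit_spec()
  truth <- c(80, 230)
  rec <- gen_synthetic_voltage_recording(spec, NULL, list(truth),
                                         noise_sd = 0.05, seed = 7,
                                         t_end = 400)
  v <- rec$voltage
  shift <- 400L  # 20 ms
  v_shift <- c(rep(v[1], shift), v[1:(length(v) - shift)])
  c1 <- detect_epsps(v)
  c2 <- detect_epsps(v_shift)
  # sub-sample tolerance: the padding changes the noise-adaptive
  # thresholds slightly, which can move a support-weighted mean by a
  # fraction of a sample
  expect_equal(c2$times, c1$times + shift * GRID_DT,
               tolerance = GRID_DT / 2)
})

test_that("channel assignment splits command-locked from tonic candidates", {
  cmds <- c(0, 100, 200)
  out <- assign_channels(c(5, 60, 105, 214.9, 250), cmds, n_channels = 2)
  expect_equal(out[[1]], c(5, 105, 214.9))
  expect_equal(out[[2]], c(60, 250))
  expect_equal(assign_channels(c(1, 2), cmds, n_channels = 1),
               list(c(1, 2)))
})

test_that("least squares recovers the response function on clean fixtures", {
  # With a single input channel the membrane and synaptic time constants
  # of the three-exponential subthreshold response admit an exactly
  # equivalent relabeling, so the function (trace, EPSP shape) is the
  # recoverable object; tau_m itself is pinned down by two-channel cells
  # (next test).
  spec <- fit_spec()
  truth <- list(c(60, 200, 340, 480))
  rec <- gen_synthetic_voltage_recording(spec, NULL, truth, noise_sd = 0,
                                         seed = 8, t_end = 600,
                                         jitter = FALSE)
  fit <- fit_least_squares(clean_trace(rec$voltage), truth, seed = 1)
  expect_true(fit$converged)
  expect_lt(fit$residual / length(rec$voltage), 1e-8)  # mean sq error
  expect_lt(abs(fit$params$E_l - spec$E_l), 0.05)
  pk_true <- epsp_peak(spec$tau_m, spec$syn)
  pk_fit <- epsp_peak(fit$params$tau_m,
                      c(fit$params$syn[[1]], class = "synapse_params"))
  expect_lt(abs(pk_fit - pk_true) / pk_true, 0.02)
  # all synaptic weights positive
  expect_gt(fit$params$syn[[1]]$w_fast, 0)
  expect_gt(fit$params$syn[[1]]$w_slow, 0)
})

test_that("two-channel fixtures pin down the shared membrane time constant", {
  spec <- granule_cell_spec(
    tau_m = 12, E_l = -66,
    syn_sites = list(synapse_params(3, 48, 18, 70),
                     synapse_params(1, 10, 30, 25),
                     synapse_params(2, 100, 20, 80)))
  truth <- list(c(60, 200, 340, 480), c(120, 260, 420))
  rec <- gen_synthetic_voltage_recording(spec, NULL, truth, noise_sd = 0,
                                         seed = 12, t_end = 600,
                                         jitter = FALSE)
  fit <- fit_least_squares(clean_trace(rec$voltage), truth,
                           n_starts = 12, seed = 3)
  expect_lt(abs(fit$params$tau_m - 12) / 12, 0.02)
  expect_lt(abs(fit$params$E_l + 66), 0.05)
})

test_that("a pure-leak trace fits to its resting potential with ~0 residual", {
  v <- rep(-65, 4000)
  fit <- fit_least_squares(v, list(numeric(0)), n_starts = 2, seed = 2)
  expect_lt(abs(fit$params$E_l - (-65)), 1e-3)
  expect_lt(fit$residual, 1e-4)
})

test_that("MCMC chains are deterministic and concentrate on clean fixtures", {
  spec <- fit_spec()
  truth <- list(c(60, 180, 300))
  rec <- gen_synthetic_voltage_recording(spec, NULL, truth, noise_sd = 0,
                                         seed = 9, t_end = 420,
                                         jitter = FALSE)
  cl <- clean_trace(rec$voltage)
  f1 <- fit_mcmc(cl, truth, n_sweeps = 150, burn = 100, thin = 5,
                 seed = 11)
  f2 <- fit_mcmc(cl, truth, n_sweeps = 150, burn = 100, thin = 5,
                 seed = 11)
  expect_identical(f1$posterior_mean, f2$posterior_mean)
  # spike count stays at the truth on a noise-free fixture
  expect_equal(lengths(f1$input_times), lengths(truth))
  expect_lt(f1$acceptance[["remove"]], 0.05)
})

test_that("the MCMC add-move recovers an EPSP missing from the init", {
  spec <- fit_spec()
  truth <- c(60, 150, 240)
  rec <- gen_synthetic_voltage_recording(spec, NULL, list(truth),
                                         noise_sd = 0.05, seed = 10,
                                         t_end = 350)
  cl <- clean_trace(rec$voltage)
  hits <- 0
  n_chain <- 5
  for (k in seq_len(n_chain)) {
    fit <- fit_mcmc(cl, list(truth[-2]), n_sweeps = 400, burn = 500,
                    thin = 10, seed = 20 + k)
    got <- fit$input_times[[1]]
    if (any(abs(got - truth[2]) <= 0.5)) hits <- hits + 1
  }
  expect_gte(hits, n_chain - 1)
})
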