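make_toy_inputs <- function(n_inputs = 20, t_end = 500, seed = 1) {
  with_seed(seed, lapply(seq_len(n_inputs), function(i)
    sort(round(runif(rpois(1, 8), 0, t_end - 50) / GRID_DT) * GRID_DT)))
}

test_that("the ELL readout reduces to its parts", {
  st <- ell_state(rep(0, 5))
  spikes <- rep(list(numeric(0)), 5)
  n <- 2000
  s <- c(numeric(200), rep(1, 400), numeric(n - 600))
  # all weights 0: V is the membrane-filtered sensory input alone
  V <- simulate_ell_block(st, spikes, s, n)
  em <- exp(-GRID_DT / st$tau_m)
  expect_equal(V, as.numeric(stats::filter(s * (1 - em), em,
                                           method = "recursive")))
  # single unit-weight input, s = 0: the membrane-filtered EPSP train
  st2 <- ell_state(c(1, rep(0, 4)))
  spikes2 <- spikes; spikes2[[1]] <- c(10, 60)
  V2 <- simulate_ell_block(st2, spikes2, NULL, n)
  expect_gt(max(V2), 0)
  expect_true(all(abs(V2[1:time_to_index(9.9)]) < 1e-12))
})

test_that("plasticity updates match hand evaluation in the degenerate cases", {
  st <- ell_state(c(0.4, 0.1))
  rule <- plasticity_rule(delta_plus = 0.01, delta_minus = 0.5,
                          lambda = 0.1, w_c = 0.2)
  V <- rep(0.3, 4000)
  # silent inputs: pure regularization decay
  st1 <- plasticity_step(st, rule, list(numeric(0), numeric(0)), V, 2)
  expect_equal(st1$weights, st$weights - 0.1 * (st$weights - 0.2) * 2)
  # w = w_c and silent: exact fixed point
  stc <- ell_state(c(0.2, 0.2))
  st2 <- plasticity_step(stc, rule, list(numeric(0), numeric(0)), V, 5)
  expect_equal(st2$weights, c(0.2, 0.2))
  # V = 0, n spikes: potentiation plus decay only
  st3 <- plasticity_step(st, rule, list(c(10, 20, 30), numeric(0)),
                         rep(0, 4000), 2)
  expect_equal(st3$weights[1],
               0.4 + 0.01 * 3 - 0.1 * (0.4 - 0.2) * 2)
})

test_that("the depression integral equals a brute-force double loop", {
  st <- ell_state(rep(0.1, 3))
  rule <- plasticity_rule(delta_plus = 0, delta_minus = 1, lambda = 0,
                          w_c = 0)
  spikes <- list(c(5, 40), c(22.5), numeric(0))
  n <- 2000
  V <- with_seed(8, rnorm(n))
  st1 <- plasticity_step(st, rule, spikes, V, 1)
  kern <- ell_epsp_kernel(st$epsp)
  t_grid <- (seq_len(n) - 1) * GRID_DT
  brute <- vapply(spikes, function(tr) {
    if (!length(tr)) return(0)
    u <- numeric(n)
    for (tj in tr) {
      idx <- time_to_index(tj)
      m <- min(length(kern), n - idx + 1)
      u[idx:(idx + m - 1)] <- u[idx:(idx + m - 1)] + kern[1:m]
    }
    sum(V * u) * GRID_DT / 1000
  }, numeric(1))
  expect_equal(st$weights - st1$weights, brute, tolerance = 1e-10)
})

test_that("sparse segment updates reproduce the reference plasticity step", {
  n_in <- 20
  t_end <- 500
  spikes <- make_toy_inputs(n_in, t_end, seed = 2)
  n <- time_to_index(t_end)
  st <- ell_state(with_seed(3, rnorm(n_in, 0, 0.05)))
  rule <- plasticity_rule(delta_plus = 0.01, delta_minus = 0.3,
                          lambda = 0.05, w_c = 0.02)
  V <- simulate_ell_block(st, spikes, NULL, n)
  ref <- plasticity_step(st, rule, spikes, V, 1.5)
  kern <- ell_epsp_kernel(st$epsp)
  cvec <- corr_with_kernel(V, kern) * (GRID_DT / 1000)
  S <- spike_matrix(spikes, n)
  w <- plasticity_step_sparse(st$weights, rule, S, cvec, 1.5)
  expect_equal(w, ref$weights, tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("baseline weight is the least-squares matching scalar", {
  n_in <- 10
  spikes <- make_toy_inputs(n_in, seed = 4)
  n <- time_to_index(500)
  st <- ell_state(rep(1, n_in))
  R <- granule_drive(st, spikes, n)  # unit-weight total drive
  expect_equal(set_baseline_weights(st, -R, spikes), 1, tolerance = 1e-10)
  expect_equal(set_baseline_weights(st, numeric(n), spikes), 0)
  expect_equal(set_baseline_weights(st, -2 * R, spikes), 2,
               tolerance = 1e-10)
  expect_error(set_baseline_weights(st, rep(1, n),
                                    rep(list(numeric(0)), n_in)),
               "zero")
})

test_that("residual power ratio matches analytic variance ratios", {
  t <- seq(0, 10, by = 0.01)
  pre <- 2 * sin(t)
  expect_equal(compute_cancellation(pre, pre), 1)
  expect_equal(compute_cancellation(pre, rep(3, length(pre))), 0)
  expect_equal(compute_cancellation(pre, sin(t)), 0.25, tolerance = 1e-6)
  expect_error(compute_cancellation(rep(1, 100), rnorm(100)), "variance")
})

test_that("silenced weights decay to baseline with time constant 1/lambda", {
  rule <- plasticity_rule(lambda = 0.1, w_c = 0.05)
  st <- ell_state(0.05 + 1)  # one unit above baseline
  step_s <- 0.1
  ts <- seq(step_s, 40, by = step_s)
  w <- numeric(length(ts))
  for (i in seq_along(ts)) {
    st <- plasticity_step(st, rule, list(numeric(0)), numeric(100),
                          step_s)
    w[i] <- st$weights
  }
  fit <- stats::lm(log(w - 0.05) ~ ts)
  tau_fit <- -1 / coef(fit)[[2]]
  expect_equal(tau_fit, 10, tolerance = 0.02)
})

test_that("probes are side-effect free and zero blocks leave C = 1", {
  n_in <- 30
  spikes <- make_toy_inputs(n_in, seed = 6)
  n <- time_to_index(500)
  s <- c(numeric(100), rep(0.5, 500), numeric(n - 600))
  inputs <- list("10" = list(spike_trains = spikes, s = s, n_samples = n,
                             window = c(0, 500), rate = 10,
                             n_commands = 5))
  proto <- pairing_protocol(learn_rates = 10, probe_rates = 10,
                            n_learning_blocks = 0)
  st <- ell_state(with_seed(5, rnorm(n_in, 0, 0.02)))
  rule <- plasticity_rule()
  res <- run_pairing_experiment(proto, st, rule, inputs)
  expect_identical(res$state$weights, st$weights)
  expect_equal(res$cancellation[["10"]]$residual_power_ratio, 1)
  expect_equal(res$negative_image, numeric(n))
})

test_that("strong regularization pins weights at w_c and subtracts its image", {
  # In the lambda -> large limit (lambda * duration ~ 1 per segment),
  # learned weights stay at w_c; the post response equals the pre response
  # computed with w = w_c.
  n_in <- 15
  spikes <- make_toy_inputs(n_in, seed = 7)
  n <- time_to_index(500)
  s <- c(numeric(200), rep(0.4, 300), numeric(n - 500))
  inputs <- list("10" = list(spike_trains = spikes, s = s, n_samples = n,
                             window = c(0, 500), rate = 10,
                             n_commands = 5))
  proto <- pairing_protocol(learn_rates = 10, probe_rates = 10,
                            n_learning_blocks = 5, update_every = 5,
                            inter_block_gap = 0)
  rule <- plasticity_rule(delta_plus = 0, delta_minus = 0, lambda = 50,
                          w_c = 0.03)
  st <- ell_state(rep(0.03, n_in))
  res <- run_pairing_experiment(proto, st, rule, inputs)
  expect_equal(res$state$weights, rep(0.03, n_in), tolerance = 1e-6)
  expect_equal(res$cancellation[["10"]]$residual_power_ratio, 1,
               tolerance = 1e-6)
})
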