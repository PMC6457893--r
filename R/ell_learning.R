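# The model ELL neuron: a passive, current-based leaky unit receiving
# excitatory input from the model granule-cell population (plastic weights
# w_i, EPSP kernel E) and sensory input s(t). Anti-Hebbian spike-timing-
# dependent plasticity with weight-decay regularization:
#   dw_i = Delta+ * (number of spikes of input i)
#        - Delta- * integral V(t) (E * r_i)(t) dt
#        - lambda * (w_i - w_c) * block_duration.
# With L0 = E (the depression kernel equal to the EPSP kernel) negative
# images are stable; full regularization uses 1/lambda = 10 s, minimal
# 1/lambda = 1000 s.

#' Anti-Hebbian plasticity rule with weight-decay regularization
#'
#' `delta_plus` is the non-associative potentiation per presynaptic spike;
#' `delta_minus` scales associative depression, whose time dependence L0 is
#' the EPSP kernel E itself. `lambda` (1/s) sets the exponential decay of
#' each weight toward the shared baseline `w_c`. The default magnitudes of
#' `delta_plus`/`delta_minus` are calibrated for the package's default
#' synthetic conditions so that pairing at 10 Hz converges within ~100
#' 25-command blocks at the reference population size of 20,000 inputs;
#' their ratio sets the equilibrium mean depolarization. Both scale as
#' `20000 / n_inputs` so that smaller populations learn at matched drive
#' (see [scale_rule()]).
#'
#' @param delta_plus potentiation per presynaptic spike
#' @param delta_minus associative depression rate
#' @param lambda regularization rate (1/s); 0.1 = full, 0.001 = minimal
#' @param w_c baseline weight toward which weights decay
#' @return object of class `plasticity_rule`
#' @export
plasticity_rule <- function(delta_plus = 4e-6, delta_minus = 0.02,
                            lambda = 0.1, w_c = 0) {
  if (delta_plus < 0 || delta_minus < 0)
    stop("`delta_plus` and `delta_minus` must be >= 0", call. = FALSE)
  structure(list(delta_plus = delta_plus, delta_minus = delta_minus,
                 lambda = lambda, w_c = w_c),
            class = "plasticity_rule")
}

#' Rescale a plasticity rule to a smaller input population
#'
#' Multiplies `delta_plus` and `delta_minus` by `20000 / n_inputs` so that
#' the total granule drive and the learning timescale match the
#' reference-size model.
#'
#' @param rule a [plasticity_rule()]
#' @param n_inputs actual number of granule inputs
#' @param n_ref reference population size
#' @export
scale_rule <- function(rule, n_inputs, n_ref = 20000) {
  rule$delta_plus <- rule$delta_plus * n_ref / n_inputs
  rule$delta_minus <- rule$delta_minus * n_ref / n_inputs
  rule
}

#' Model ELL neuron state
#'
#' @param weights numeric vector of granule->ELL synaptic weights
#' @param epsp a [synapse_params()] describing the granule->ELL EPSP
#'   kernel E (defaults integrate to 1 so weights carry the gain)
#' @param tau_m ELL membrane time constant (ms)
#' @param sensory_gain multiplies s(t)
#' @return object of class `ell_state`
#' @export
ell_state <- function(weights, epsp = synapse_params(2, 0.5, 15, 0.5),
                      tau_m = 10, sensory_gain = 1) {
  structure(list(weights = as.numeric(weights), epsp = epsp,
                 tau_m = tau_m, sensory_gain = sensory_gain),
            class = "ell_state")
}

#' Sampled EPSP kernel E on the simulation grid
#' @param epsp a [synapse_params()]
#' @param duration kernel support (ms); default 8 slow time constants
#' @keywords internal
ell_epsp_kernel <- function(epsp, duration = 8 * epsp$tau_slow) {
  t <- seq(0, duration, by = GRID_DT)
  epsp$w_fast / epsp$tau_fast * exp(-t / epsp$tau_fast) +
    epsp$w_slow / epsp$tau_slow * exp(-t / epsp$tau_slow)
}

#' Total weighted granule drive sum_i w_i (E * r_i)(t)
#'
#' Accumulates a weighted impulse train over all inputs and convolves once
#' with the EPSP kernel.
#' @keywords internal
granule_drive <- function(state, granule_spikes, n_samples) {
  imp <- numeric(n_samples)
  lens <- lengths(granule_spikes)
  if (sum(lens)) {
    idx <- time_to_index(snap_to_grid(unlist(granule_spikes)))
    w <- rep(state$weights, lens)
    ok <- idx >= 1L & idx <= n_samples
    agg <- rowsum(w[ok], idx[ok])
    imp[as.integer(rownames(agg))] <- agg[, 1]
  }
  conv_causal(imp, ell_epsp_kernel(state$epsp))
}

#' Simulate the ELL neuron's membrane response over one block
#'
#' Leaky integration (readout relative to rest, so V = 0 with no input) of
#' the weighted granule drive plus sensory input. The ELL readout is the
#' membrane potential; the model neuron does not spike.
#'
#' @param state an [ell_state()]
#' @param granule_spikes list of granule spike-time vectors, one per input
#'   (length must equal `length(state$weights)`)
#' @param s a `sensory_trace`, a numeric vector on the grid, or `NULL` for
#'   command-alone probes
#' @param n_samples number of grid samples to simulate; default from the
#'   inputs
#' @return numeric voltage trace (length `n_samples`)
#' @export
simulate_ell_block <- function(state, granule_spikes, s = NULL,
                               n_samples = NULL) {
  if (length(granule_spikes) != length(state$weights))
    stop("granule input count must equal weight count", call. = FALSE)
  sv <- if (inherits(s, "sensory_trace")) s$values else s
  if (is.null(n_samples)) {
    n_samples <- max(length(sv),
                     time_to_index(suppressWarnings(
                       max(c(0, unlist(granule_spikes))))) + 1L)
  }
  drive <- granule_drive(state, granule_spikes, n_samples)
  total <- drive
  if (!is.null(sv)) {
    sv <- c(sv, numeric(max(0, n_samples - length(sv))))[1:n_samples]
    total <- total + state$sensory_gain * sv
  }
  em <- exp(-GRID_DT / state$tau_m)
  as.numeric(stats::filter(total * (1 - em), em, method = "recursive"))
}

#' Apply one plasticity update after a paired block
#'
#' `w_i <- w_i + delta_plus * n_i - delta_minus * int V (E*r_i) dt
#'          - lambda (w_i - w_c) * block_duration`.
#' The depression integral is evaluated on the simulation grid via a single
#' correlation of V with the EPSP kernel, looked up at each input's spike
#' times (dt in seconds so the rates have 1/s units).
#'
#' @param state an [ell_state()]
#' @param rule a [plasticity_rule()]
#' @param granule_spikes per-input spike trains of the block
#' @param V_trace the block's membrane trace (same grid)
#' @param block_duration seconds of elapsed time the regularization decay
#'   covers (sequence plus inter-block gap)
#' @return the state with updated weights
#' @export
plasticity_step <- function(state, rule, granule_spikes, V_trace,
                            block_duration) {
  n_i <- lengths(granule_spikes)
  depr <- numeric(length(granule_spikes))
  if (sum(n_i)) {
    cvec <- corr_with_kernel(V_trace, ell_epsp_kernel(state$epsp)) *
      (GRID_DT / 1000)
    idx <- time_to_index(snap_to_grid(unlist(granule_spikes)))
    idx[idx > length(cvec)] <- length(cvec)
    vals <- cvec[idx]
    grp <- rep(seq_along(granule_spikes), n_i)
    agg <- rowsum(vals, grp)
    depr[as.integer(rownames(agg))] <- agg[, 1]
  }
  state$weights <- state$weights + rule$delta_plus * n_i -
    rule$delta_minus * depr -
    rule$lambda * (state$weights - rule$w_c) * block_duration
  state
}

#' Least-squares baseline weight
#'
#' The scalar `w_c` such that the mean granule response scaled by `w_c`
#' (times the input count) best matches the negative of the sensory input:
#' `w_c = argmin_c int (c * N * rbar(t) + s(t))^2 dt`.
#'
#' @param state an [ell_state()] (for the EPSP kernel)
#' @param s sensory trace (object or numeric vector on the grid)
#' @param granule_spikes per-input spike trains
#' @return scalar baseline weight
#' @export
set_baseline_weights <- function(state, s, granule_spikes) {
  sv <- if (inherits(s, "sensory_trace")) s$values else s
  n_samples <- length(sv)
  unit <- ell_state(rep(1, length(granule_spikes)), epsp = state$epsp,
                    tau_m = state$tau_m)
  R <- granule_drive(unit, granule_spikes, n_samples)  # N * rbar
  denom <- sum(R^2)
  if (denom == 0) stop("mean granule response is identically zero",
                       call. = FALSE)
  -sum(sv * R) / denom
}

#' Residual power ratio C
#'
#' Ratio of the mean-subtracted variance (power) of the post-pairing
#' response to the pre-pairing response over a common window. C = 1 means
#' no cancellation, C = 0 perfect cancellation, C > 1 over-cancellation.
#'
#' @param pre,post voltage traces on the same grid
#' @param window `c(t_start, t_end)` in ms; default full trace
#' @return nonnegative scalar
#' @export
compute_cancellation <- function(pre, post, window = NULL) {
  if (length(pre) != length(post))
    stop("pre/post traces must share a grid", call. = FALSE)
  sel <- seq_along(pre)
  if (!is.null(window)) {
    t <- (sel - 1) * GRID_DT
    sel <- which(t >= window[1] & t <= window[2])
  }
  vpre <- sum((pre[sel] - mean(pre[sel]))^2)
  if (vpre == 0) stop("zero pre-pairing variance", call. = FALSE)
  sum((post[sel] - mean(post[sel]))^2) / vpre
}

#' Command-locked negative image
#'
#' Change in the command-alone response (s = 0) relative to the
#' pre-learning command-alone response. After convergence this change is
#' anticorrelated with the sensory input it cancels.
#'
#' @param state post-learning [ell_state()]
#' @param granule_spikes command-alone granule spike trains
#' @param pre_trace pre-learning command-alone response on the same grid
#' @param n_samples grid length
#' @return numeric trace
#' @export
extract_negative_image <- function(state, granule_spikes, pre_trace,
                                   n_samples = length(pre_trace)) {
  simulate_ell_block(state, granule_spikes, s = NULL,
                     n_samples = n_samples) - pre_trace
}

#' Pairing / generalization protocol description
#'
#' Learning is the continuous-time plasticity rule integrated explicitly:
#' within each paired block the weights are updated every `update_every`
#' commands (the membrane response is re-simulated with the current
#' weights between updates). One update per command is a fine enough step
#' for the rule to be stable at the default rates; `update_every =
#' commands_per_block` reproduces a single whole-block update.
#'
#' @param learn_rates commands/s used for paired learning blocks
#' @param probe_rates commands/s probed (plasticity frozen) pre and post
#' @param n_learning_blocks paired 25-command blocks
#' @param commands_per_block commands per block
#' @param inter_block_gap ms of silence between blocks (regularization
#'   decay continues)
#' @param update_every commands between weight updates during learning
#' @param seed integer seed
#' @return object of class `pairing_protocol`
#' @export
pairing_protocol <- function(learn_rates = 10,
                             probe_rates = c(10, 40, 60),
                             n_learning_blocks = 100,
                             commands_per_block = 25,
                             inter_block_gap = 500,
                             update_every = 1, seed = 1) {
  structure(list(learn_rates = learn_rates, probe_rates = probe_rates,
                 n_learning_blocks = n_learning_blocks,
                 commands_per_block = commands_per_block,
                 inter_block_gap = inter_block_gap,
                 update_every = update_every, seed = seed),
            class = "pairing_protocol")
}

#' Sparse spike-count matrix of a set of input trains
#'
#' `n_samples x n_inputs` matrix whose (t, i) entry counts input i's
#' spikes at grid sample t. The weighted impulse train is `S %*% w` and
#' the per-input depression integrals are `t(S) %*% cvec`.
#' @keywords internal
spike_matrix <- function(spike_trains, n_samples) {
  lens <- lengths(spike_trains)
  idx <- time_to_index(snap_to_grid(unlist(spike_trains)))
  col <- rep(seq_along(spike_trains), lens)
  ok <- idx >= 1L & idx <= n_samples
  Matrix::sparseMatrix(i = idx[ok], j = col[ok], x = 1,
                       dims = c(n_samples, length(spike_trains)))
}

#' @keywords internal
ell_membrane_filter <- function(total_input, tau_m) {
  em <- exp(-GRID_DT / tau_m)
  as.numeric(stats::filter(total_input * (1 - em), em,
                           method = "recursive"))
}

#' One explicit learning segment using precomputed spike matrices
#'
#' Equivalent to [plasticity_step()] restricted to the spikes of
#' `S_seg`, with `cvec` the kernel correlation of the current full-block
#' membrane trace (dt in seconds folded in by the caller).
#' @keywords internal
plasticity_step_sparse <- function(weights, rule, S_seg, cvec, duration_s) {
  n_i <- Matrix::colSums(S_seg)
  depr <- as.numeric(Matrix::crossprod(S_seg, cvec[seq_len(nrow(S_seg))]))
  weights + rule$delta_plus * n_i - rule$delta_minus * depr -
    rule$lambda * (weights - rule$w_c) * duration_s
}

#' Run a pairing experiment on prepared inputs
#'
#' Probes all probe rates with the initial weights (plasticity frozen),
#' runs the learning blocks (cycling through `learn_rates`) with plasticity
#' on, then probes all probe rates and the command-alone condition with the
#' final weights. Granule responses and sensory traces per rate are
#' prepared by the caller (see [setup_experiment()]), so the same inputs
#' can be shared across model variants and protocols.
#'
#' @param protocol a [pairing_protocol()]
#' @param state initial [ell_state()]
#' @param rule a [plasticity_rule()]
#' @param inputs_by_rate named list (by rate) with elements
#'   `spike_trains`, `s` (numeric vector), `n_samples`, `window`
#' @return list with per-rate `cancellation` (class `cancellation_result`),
#'   `per_block_C` at the first learn rate, the final `state`, and
#'   pre/post command-alone traces
#' @export
run_pairing_experiment <- function(protocol, state, rule, inputs_by_rate) {
  rate_key <- function(r) as.character(r)
  kernel <- ell_epsp_kernel(state$epsp)
  # precompute per rate: sparse spike matrices (full block and per update
  # segment) and the padded sensory vector
  prep <- lapply(inputs_by_rate, function(inp) {
    S <- spike_matrix(inp$spike_trains, inp$n_samples)
    cmds <- (seq_len(inp$n_commands) - 1) * 1000 / inp$rate
    bounds <- cmds[seq(1, length(cmds),
                       by = max(1L, protocol$update_every))]
    cuts <- unique(c(time_to_index(bounds), inp$n_samples + 1L))
    segs <- lapply(seq_len(length(cuts) - 1L), function(j)
      S[cuts[j]:(cuts[j + 1L] - 1L), , drop = FALSE])
    list(S = S, segs = segs, cuts = cuts, inp = inp)
  })
  sim_fast <- function(weights, p, with_s = TRUE) {
    drive <- conv_causal(as.numeric(p$S %*% weights), kernel)
    total <- if (with_s) drive + p$inp$s else drive
    ell_membrane_filter(total, state$tau_m)
  }
  probe <- function(st, r, with_s = TRUE)
    sim_fast(st$weights, prep[[rate_key(r)]], with_s)
  pre <- lapply(protocol$probe_rates, function(r) probe(state, r))
  names(pre) <- rate_key(protocol$probe_rates)
  pre_alone <- probe(state, protocol$probe_rates[1], with_s = FALSE)

  first_rate <- rate_key(protocol$learn_rates[1])
  per_block_C <- numeric(protocol$n_learning_blocks)
  if (protocol$n_learning_blocks > 0) {
    for (b in seq_len(protocol$n_learning_blocks)) {
      r <- protocol$learn_rates[((b - 1) %% length(protocol$learn_rates)) + 1]
      p <- prep[[rate_key(r)]]
      block_dur_s <- (p$inp$n_samples * GRID_DT +
                        protocol$inter_block_gap) / 1000
      n_seg <- length(p$segs)
      V1 <- NULL
      for (j in seq_len(n_seg)) {
        V <- sim_fast(state$weights, p)
        if (j == 1L) V1 <- V
        cvec <- corr_with_kernel(V, kernel) * (GRID_DT / 1000)
        cseg <- cvec[p$cuts[j]:(p$cuts[j + 1L] - 1L)]
        state$weights <- plasticity_step_sparse(
          state$weights, rule, p$segs[[j]], cseg, block_dur_s / n_seg)
      }
      if (rate_key(r) == first_rate)
        per_block_C[b] <- compute_cancellation(pre[[first_rate]], V1,
                                               p$inp$window)
      else per_block_C[b] <- NA_real_
    }
  }

  post <- lapply(protocol$probe_rates, function(r) probe(state, r))
  names(post) <- rate_key(protocol$probe_rates)
  post_alone <- probe(state, protocol$probe_rates[1], with_s = FALSE)

  results <- lapply(rate_key(protocol$probe_rates), function(r) {
    inp <- inputs_by_rate[[r]]
    structure(list(rate = as.numeric(r), pre_trace = pre[[r]],
                   post_trace = post[[r]],
                   residual_power_ratio =
                     compute_cancellation(pre[[r]], post[[r]], inp$window),
                   window = inp$window),
              class = "cancellation_result")
  })
  names(results) <- rate_key(protocol$probe_rates)
  list(cancellation = results, per_block_C = per_block_C, state = state,
       pre_command_alone = pre_alone, post_command_alone = post_alone,
       negative_image = post_alone - pre_alone)
}
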