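# Inference of integrate-and-fire parameters and excitatory input spike
# times from granule-cell membrane-voltage recordings: gradient-threshold
# artifact/spike removal, continuous-wavelet-transform EPSP detection,
# least-squares parameter fitting with detected times held fixed, and MCMC
# joint sampling of parameters and input times.

#' Remove stimulus artifacts and spikes by a voltage-gradient threshold
#'
#' Samples where the finite-difference gradient magnitude reaches
#' 1.8 mV/ms are excised together with a +/-0.25 ms guard; the gaps are
#' filled by linear interpolation and recorded.
#'
#' @param voltage trace (mV) on the 20 kHz grid (a numeric vector or a
#'   `synthetic_voltage_recording`)
#' @param grad_threshold mV/ms
#' @param guard ms excised on each side of a threshold crossing
#' @return object of class `cleaned_trace` with `sample_times`, `voltage`,
#'   `removed_intervals` (two-column matrix, ms)
#' @export
clean_trace <- function(voltage, grad_threshold = 1.8, guard = 0.25) {
  if (inherits(voltage, "synthetic_voltage_recording"))
    voltage <- voltage$voltage
  n <- length(voltage)
  if (n < 2) stop("trace shorter than 2 samples", call. = FALSE)
  grad <- diff(voltage) / GRID_DT
  bad <- abs(grad) >= grad_threshold
  bad_samples <- unique(c(which(bad), which(bad) + 1L))
  removed <- matrix(numeric(0), ncol = 2,
                    dimnames = list(NULL, c("start", "end")))
  v <- voltage
  if (length(bad_samples)) {
    g <- as.integer(round(guard / GRID_DT))
    mask <- logical(n)
    for (i in bad_samples)
      mask[max(1L, i - g):min(n, i + g)] <- TRUE
    runs <- rle(mask)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    ri <- which(runs$values)
    removed <- cbind(start = (starts[ri] - 1L) * GRID_DT,
                     end = (ends[ri] - 1L) * GRID_DT)
    good <- which(!mask)
    v[mask] <- stats::approx(good, voltage[good], xout = which(mask),
                             rule = 2)$y
  }
  structure(list(sample_times = (seq_len(n) - 1) * GRID_DT, voltage = v,
                 removed_intervals = removed,
                 interpolation_method = "linear"),
            class = "cleaned_trace")
}

#' @keywords internal
ricker_wavelet <- function(scale_ms, dt = GRID_DT) {
  half <- max(2L, as.integer(ceiling(5 * scale_ms / dt)))
  t <- (-half:half) * dt
  u <- t / scale_ms
  psi <- (1 - u^2) * exp(-u^2 / 2)
  psi <- psi - mean(psi)
  psi / sqrt(sum(psi^2))
}

#' @keywords internal
scale_for_freq <- function(freq_hz) 1000 * sqrt(2) / (2 * pi * freq_hz)

#' Detect putative EPSP onset times by a multi-scale wavelet criterion
#'
#' Computes a continuous wavelet transform (Mexican-hat / Ricker mother
#' wavelet, L2-normalized) at 16 scales spanning pseudo-frequencies 800 to
#' 2000 Hz. An EPSP onset is a slope discontinuity, which drives a negative
#' excursion of the transform at these fine scales; per scale, local maxima
#' of the negated coefficients above a noise-adaptive threshold
#' (`thresh_mad` times the median absolute deviation of that scale's
#' coefficients) are collected, times supported by at least `min_scales`
#' scales (within 0.5 ms) become candidates, and candidates closer than
#' 0.5 ms are merged to their support-weighted mean.
#'
#' @param trace a [clean_trace()] result (or numeric voltage vector)
#' @param freqs pseudo-frequencies (Hz) of the 16 scales
#' @param min_scales scales that must support a candidate
#' @param thresh_mad threshold in per-scale MAD units
#' @param merge_window ms; peaks closer than this are one event
#' @return object of class `epsp_candidates` with `times` (ms) and
#'   `scale_support`
#' @export
detect_epsps <- function(trace, freqs = seq(800, 2000, length.out = 16),
                         min_scales = 8, thresh_mad = 6,
                         merge_window = 0.5) {
  v <- if (inherits(trace, "cleaned_trace")) trace$voltage else trace
  n <- length(v)
  peak_times <- vector("list", length(freqs))
  for (k in seq_along(freqs)) {
    psi <- ricker_wavelet(scale_for_freq(freqs[k]))
    half <- (length(psi) - 1L) / 2L
    coef <- conv_causal(c(v - mean(v), numeric(half)), rev(psi))
    coef <- -coef[(half + 1L):(half + n)]  # centered, onset-positive
    # the convolution's implicit zero padding makes the first/last
    # wavelet-width of coefficients meaningless; exclude them
    guard <- 2L * half + 1L
    thr <- thresh_mad * stats::mad(coef, center = 0)
    loc <- which(coef > thr)
    loc <- loc[loc > guard & loc < n - guard]
    loc <- loc[coef[loc] >= coef[loc - 1L] & coef[loc] >= coef[loc + 1L]]
    peak_times[[k]] <- (loc - 1L) * GRID_DT
  }
  all_t <- unlist(peak_times)
  all_scale <- rep(seq_along(freqs), lengths(peak_times))
  if (!length(all_t))
    return(structure(list(times = numeric(0),
                          scale_support = integer(0)),
                     class = "epsp_candidates"))
  ord <- order(all_t)
  all_t <- all_t[ord]; all_scale <- all_scale[ord]
  # greedy clustering of per-scale peaks within the merge window
  cluster <- cumsum(c(TRUE, diff(all_t) > merge_window))
  times <- as.numeric(tapply(all_t, cluster, mean))
  support <- as.integer(tapply(all_scale, cluster,
                               function(s) length(unique(s))))
  keep <- support >= min_scales
  times <- times[keep]; support <- support[keep]
  # enforce minimum candidate separation
  if (length(times) > 1) {
    final_t <- times[1]; final_s <- support[1]
    for (i in 2:length(times)) {
      j <- length(final_t)
      if (times[i] - final_t[j] < merge_window) {
        w <- c(final_s[j], support[i])
        final_t[j] <- sum(c(final_t[j], times[i]) * w) / sum(w)
        final_s[j] <- max(w)
      } else {
        final_t <- c(final_t, times[i]); final_s <- c(final_s, support[i])
      }
    }
    times <- final_t; support <- final_s
  }
  structure(list(times = times, scale_support = support),
            class = "epsp_candidates")
}

#' Assign detected EPSP times to input channels
#'
#' Two-input cells receive one command-locked and one command-independent
#' (tonic) input; a candidate falling within `lock_window` ms after any
#' command is assigned to channel 1, all others to channel 2.
#'
#' @param times candidate times (ms)
#' @param command_times command times (ms); `NULL` puts everything on
#'   channel 1
#' @param n_channels 1 or 2
#' @param lock_window ms
#' @return list of per-channel time vectors
#' @export
assign_channels <- function(times, command_times = NULL, n_channels = 1,
                            lock_window = 15) {
  if (n_channels == 1 || is.null(command_times)) return(list(times))
  locked <- vapply(times, function(tt)
    any(command_times <= tt & tt < command_times + lock_window),
    logical(1))
  list(times[locked], times[!locked])
}

#' @keywords internal
forward_subthreshold <- function(theta, input_times, n_samples) {
  # theta: list(tau_m, E_l, syn = list of per-channel synapse_params)
  nch <- length(input_times)
  times <- snap_to_grid(unlist(input_times))
  site <- rep(seq_len(nch) - 1L, lengths(input_times))
  ord <- order(times)
  out <- cpp_simulate_if(GRID_DT, n_samples, theta$tau_m, theta$E_l,
                         theta$E_l + 1e6, theta$E_l, 0,
                         as.integer(round(times[ord] / GRID_DT)),
                         site[ord], rep(1, length(times)),
                         vapply(theta$syn, `[[`, numeric(1), "tau_fast"),
                         vapply(theta$syn, `[[`, numeric(1), "w_fast"),
                         vapply(theta$syn, `[[`, numeric(1), "tau_slow"),
                         vapply(theta$syn, `[[`, numeric(1), "w_slow"),
                         TRUE)
  out$voltage
}

#' @keywords internal
pack_theta <- function(theta) {
  c(theta$tau_m, theta$E_l,
    unlist(lapply(theta$syn, function(s)
      c(s$tau_fast, s$w_fast, s$tau_slow, s$w_slow))))
}

#' @keywords internal
unpack_theta <- function(par, nch) {
  syn <- lapply(seq_len(nch), function(k) {
    o <- 2 + (k - 1) * 4
    list(tau_fast = par[o + 1], w_fast = par[o + 2],
         tau_slow = par[o + 3], w_slow = par[o + 4])
  })
  list(tau_m = par[1], E_l = par[2], syn = syn)
}

#' Superposed unit-weight EPSP component over a trace
#'
#' Exact subthreshold response (closed form of the linear membrane ODE) to
#' unit synaptic weight of one exponential component at the given spike
#' times.
#' @keywords internal
unit_component <- function(n, spike_times, tau_m, tau_c) {
  if (abs(tau_c - tau_m) < 1e-9) tau_c <- tau_c + 1e-6
  u <- numeric(n)
  kern_len <- as.integer(min(n, ceiling(12 * max(tau_c, tau_m) / GRID_DT)))
  t <- (seq_len(kern_len) - 1L) * GRID_DT
  kern <- (exp(-t / tau_c) - exp(-t / tau_m)) / (tau_c - tau_m)
  for (tj in spike_times) {
    i0 <- time_to_index(snap_to_grid(tj))
    if (i0 > n) next
    m <- min(kern_len, n - i0 + 1L)
    u[i0:(i0 + m - 1L)] <- u[i0:(i0 + m - 1L)] + kern[1:m]
  }
  u
}

#' Least-squares fit of the granule-cell model with fixed input times
#'
#' Treats the detected candidate times as the true input times and
#' minimizes the squared error between the cleaned trace and the
#' subthreshold integrate-and-fire forward model over the membrane time
#' constant, leak potential and per-channel synapse parameters. The model
#' is linear in the leak potential and the synaptic weights given the time
#' constants, so the fit profiles the weights out by linear least squares
#' (variable projection) and optimizes only the log time constants, from
#' seeded multistart initializations; weight positivity is enforced by
#' penalizing negative solutions. The best residual is returned.
#'
#' @param trace a [clean_trace()] result (or numeric vector)
#' @param input_times per-channel list of input spike times (ms), e.g. from
#'   [detect_epsps()] + [assign_channels()]
#' @param n_starts multistart count
#' @param seed integer seed for the initializations
#' @return object of class `gc_fit` with `params`, `input_times`,
#'   `residual`, `fitted`, `converged`
#' @export
fit_least_squares <- function(trace, input_times, n_starts = 8, seed = 1) {
  v <- if (inherits(trace, "cleaned_trace")) trace$voltage else trace
  if (!is.list(input_times)) input_times <- list(input_times)
  input_times <- lapply(input_times, function(x) sort(as.numeric(x)))
  nch <- length(input_times)
  active <- which(lengths(input_times) > 0)
  n <- length(v)

  vv <- sum(v * v)
  solve_weights <- function(taus) {
    # taus: c(tau_m, then tau_fast, tau_slow per active channel)
    tau_m <- taus[1]
    X <- matrix(1, n, 1 + 2 * length(active))
    for (a in seq_along(active)) {
      ch <- active[a]
      X[, 2 * a] <- unit_component(n, input_times[[ch]], tau_m,
                                   taus[2 * a])
      X[, 2 * a + 1] <- unit_component(n, input_times[[ch]], tau_m,
                                       taus[2 * a + 1])
    }
    XtX <- crossprod(X)
    Xtv <- crossprod(X, v)
    cf <- tryCatch(drop(solve(XtX, Xtv)), error = function(e) NULL)
    if (is.null(cf) || anyNA(cf)) return(NULL)
    w <- cf[-1]
    penalty <- sum(pmax(-w, 0))  # discourage negative weights
    cf2 <- c(cf[1], pmax(w, 1e-6))
    # SSE via the quadratic form, avoiding an n-length residual vector
    resid <- max(0, vv - 2 * sum(cf2 * Xtv) +
                   drop(t(cf2) %*% XtX %*% cf2))
    list(E_l = cf[1], w = pmax(w, 1e-6), sse = resid * (1 + 10 * penalty))
  }
  obj <- function(lp) {
    if (any(lp < log(0.2)) || any(lp > log(200))) return(1e12)
    sol <- solve_weights(exp(lp))
    if (is.null(sol)) return(1e12)
    sol$sse
  }

  inits <- with_seed(seed, lapply(seq_len(n_starts), function(i) {
    c(log(runif(1, 4, 30)),
      rep(c(log(runif(1, 0.5, 5)), log(runif(1, 8, 60))),
          length(active)))
  }))
  # two-stage multistart: cheap exploration from every init, then a deep
  # Nelder-Mead polish of the two best basins
  stage1 <- list()
  for (p0 in inits) {
    fit <- tryCatch(
      if (length(p0) == 1L)
        stats::optim(p0, obj, method = "Brent", lower = log(0.2),
                     upper = log(200))
      else
        stats::optim(p0, obj, method = "Nelder-Mead",
                     control = list(maxit = 300, reltol = 1e-8)),
      error = function(e) NULL)
    if (!is.null(fit)) stage1[[length(stage1) + 1]] <- fit
  }
  best <- NULL
  if (length(stage1)) {
    ord <- order(vapply(stage1, `[[`, numeric(1), "value"))
    for (k in ord[seq_len(min(2L, length(ord)))]) {
      fit <- tryCatch(
        if (length(stage1[[k]]$par) == 1L) stage1[[k]]
        else stats::optim(stage1[[k]]$par, obj, method = "Nelder-Mead",
                          control = list(maxit = 2500, reltol = 1e-10)),
        error = function(e) NULL)
      if (!is.null(fit) && (is.null(best) || fit$value < best$value))
        best <- fit
    }
  }
  if (is.null(best) || is.null(solve_weights(exp(best$par))))
    return(structure(list(params = NULL, input_times = input_times,
                          residual = NA_real_, converged = FALSE),
                     class = "gc_fit"))
  # convergence = stationarity: a fresh short restart cannot improve the
  # objective meaningfully (Nelder-Mead rarely reports code 0 on the
  # shallow valleys of this problem even at machine-level residuals)
  converged <- TRUE
  if (length(best$par) > 1L) {
    check <- tryCatch(
      stats::optim(best$par, obj, method = "Nelder-Mead",
                   control = list(maxit = 400, reltol = 1e-9)),
      error = function(e) NULL)
    if (!is.null(check) && check$value < best$value) {
      rel_impr <- (best$value - check$value) /
        max(abs(best$value), 1e-12)
      converged <- rel_impr < 1e-6
      best <- check
    }
  }
  taus <- exp(best$par)
  sol <- solve_weights(taus)
  syn <- rep(list(list(tau_fast = 2, w_fast = 1e-6,
                       tau_slow = 20, w_slow = 1e-6)), nch)
  for (a in seq_along(active)) {
    tf <- taus[2 * a]; ts <- taus[2 * a + 1]
    wf <- sol$w[2 * a - 1]; ws <- sol$w[2 * a]
    if (tf > ts) { tmp <- tf; tf <- ts; ts <- tmp
                   tmp <- wf; wf <- ws; ws <- tmp }
    syn[[active[a]]] <- list(tau_fast = tf, w_fast = wf,
                             tau_slow = ts, w_slow = ws)
  }
  theta <- list(tau_m = taus[1], E_l = unname(sol$E_l), syn = syn)
  structure(list(params = theta, input_times = input_times,
                 residual = sum((forward_subthreshold(theta, input_times,
                                                      n) - v)^2),
                 fitted = forward_subthreshold(theta, input_times, n),
                 converged = converged || best$convergence == 0),
            class = "gc_fit")
}

#' MCMC joint inference of model parameters and input times
#'
#' Metropolis-within-Gibbs sampler alternating (a) Gaussian random-walk
#' updates of each model parameter (log space for time constants and
#' weights, so synaptic weights stay positive) and (b) input-time moves:
#' jitter an existing spike (Normal, sd 0.25 ms), remove a spike, or add a
#' spike uniformly over the trace, accepted by Metropolis-Hastings under a
#' Poisson prior on the per-channel spike count centered on the initial
#' (wavelet-detected) count. The Gaussian likelihood uses a noise SD
#' estimated from the median absolute successive difference of the trace,
#' floored at `sigma_floor`. The first `burn` sweeps are discarded and the
#' rest thinned by `thin`.
#'
#' @param trace a [clean_trace()] result (or numeric vector)
#' @param init per-channel list of initial input times (wavelet detection)
#' @param n_sweeps post-burn-in sweeps
#' @param burn burn-in sweeps
#' @param thin keep every `thin`-th sweep
#' @param seed integer seed (chains are deterministic given it)
#' @param theta0 optional initial parameter list (e.g. a least-squares
#'   fit); defaults to a coarse data-driven guess
#' @param sigma_floor minimum likelihood noise SD (mV)
#' @param jitter_sd spike-time jitter proposal SD (ms)
#' @return object of class `gc_fit` with `posterior_samples` (list of
#'   `params` draws), `posterior_mean`, `posterior_sd`, `input_times`
#'   (posterior modal times of the last sample), acceptance diagnostics
#' @export
fit_mcmc <- function(trace, init, n_sweeps = 1000, burn = 500, thin = 5,
                     seed = 1, theta0 = NULL, sigma_floor = 0.05,
                     jitter_sd = 0.25) {
  v <- if (inherits(trace, "cleaned_trace")) trace$voltage else trace
  if (!is.list(init)) init <- list(init)
  nch <- length(init)
  n <- length(v)
  T_ms <- n * GRID_DT
  sigma <- max(sigma_floor, stats::mad(diff(v)) / sqrt(2))
  lambda_count <- pmax(0.5, lengths(init))

  if (is.null(theta0))
    theta0 <- list(tau_m = 10, E_l = stats::median(v),
                   syn = rep(list(list(tau_fast = 2,
                                       w_fast = max(1, diff(range(v)) * 8),
                                       tau_slow = 20,
                                       w_slow = max(1, diff(range(v)) * 4))),
                             nch))
  par <- pack_theta(theta0)
  log_mask <- c(TRUE, FALSE, rep(TRUE, 4 * nch))  # log-space parameters
  par[log_mask] <- log(par[log_mask])
  prop_sd <- ifelse(log_mask, 0.05, 0.2)
  times <- lapply(init, sort)

  loglik <- function(par, times) {
    p <- par; p[log_mask] <- exp(p[log_mask])
    theta <- unpack_theta(p, nch)
    -sum((forward_subthreshold(theta, times, n) - v)^2) / (2 * sigma^2)
  }

  with_seed(seed, {
    ll <- loglik(par, times)
    keep <- list()
    acc_par <- 0; try_par <- 0
    acc_add <- 0; try_add <- 0; acc_rem <- 0; try_rem <- 0
    # per-parameter acceptance counters for burn-in proposal adaptation
    win_acc <- numeric(length(par)); win_try <- numeric(length(par))
    total <- burn + n_sweeps
    hist_par <- matrix(NA_real_, total, length(par))
    joint_chol <- NULL
    for (sweep in seq_len(total)) {
      for (j in seq_along(par)) {
        cand <- par
        cand[j] <- cand[j] + rnorm(1, 0, prop_sd[j])
        llc <- loglik(cand, times)
        try_par <- try_par + 1
        win_try[j] <- win_try[j] + 1
        if (log(runif(1)) < llc - ll) {
          par <- cand; ll <- llc; acc_par <- acc_par + 1
          win_acc[j] <- win_acc[j] + 1
        }
      }
      # adapt proposal scales toward ~30% acceptance during burn-in only
      if (sweep <= burn && sweep %% 25 == 0) {
        rate <- win_acc / pmax(1, win_try)
        prop_sd <- prop_sd * exp(rate - 0.3)
        win_acc[] <- 0; win_try[] <- 0
      }
      # joint (adaptive-Metropolis) proposal along the empirical
      # parameter covariance: per-coordinate walks mix poorly along the
      # correlated membrane/weight valley
      hist_par[sweep, ] <- par
      if (sweep <= burn && sweep %% 50 == 0 && sweep >= 100) {
        cm <- stats::cov(hist_par[max(1, sweep - 300):sweep, ,
                                  drop = FALSE])
        cm <- cm + diag(1e-10, length(par))
        joint_chol <- tryCatch(chol(cm), error = function(e) NULL)
      }
      if (!is.null(joint_chol)) {
        step <- drop(rnorm(length(par)) %*% joint_chol) *
          2.38 / sqrt(length(par))
        cand <- par + step
        llc <- loglik(cand, times)
        if (log(runif(1)) < llc - ll) { par <- cand; ll <- llc }
      }
      for (ch in seq_len(nch)) {
        nk <- length(times[[ch]])
        # jitter each spike
        if (nk) for (k in seq_len(nk)) {
          cand <- times
          cand[[ch]][k] <- cand[[ch]][k] + rnorm(1, 0, jitter_sd)
          if (cand[[ch]][k] < 0 || cand[[ch]][k] > T_ms) next
          cand[[ch]] <- sort(cand[[ch]])
          llc <- loglik(par, cand)
          if (log(runif(1)) < llc - ll) { times <- cand; ll <- llc }
        }
        # birth / death move
        if (runif(1) < 0.5) {
          cand <- times
          tnew <- runif(1, 0, T_ms)
          cand[[ch]] <- sort(c(cand[[ch]], tnew))
          llc <- loglik(par, cand)
          try_add <- try_add + 1
          if (log(runif(1)) < llc - ll +
              log(lambda_count[ch] / (nk + 1))) {
            times <- cand; ll <- llc; acc_add <- acc_add + 1
          }
        } else if (nk > 0) {
          cand <- times
          kdrop <- sample.int(nk, 1)
          cand[[ch]] <- cand[[ch]][-kdrop]
          llc <- loglik(par, cand)
          try_rem <- try_rem + 1
          if (log(runif(1)) < llc - ll + log(nk / lambda_count[ch])) {
            times <- cand; ll <- llc; acc_rem <- acc_rem + 1
          }
        }
      }
      if (sweep > burn && (sweep - burn) %% thin == 0) {
        p <- par; p[log_mask] <- exp(p[log_mask])
        keep[[length(keep) + 1]] <- list(par = p, times = times)
      }
    }
    draws <- do.call(rbind, lapply(keep, `[[`, "par"))
    post_mean <- colMeans(draws)
    post_sd <- apply(draws, 2, stats::sd)
    structure(list(
      params = unpack_theta(post_mean, nch),
      posterior_mean = unpack_theta(post_mean, nch),
      posterior_sd = unpack_theta(post_sd, nch),
      posterior_samples = keep,
      input_times = keep[[length(keep)]]$times,
      residual = -2 * sigma^2 * ll,
      sigma = sigma,
      acceptance = c(params = acc_par / max(1, try_par),
                     add = acc_add / max(1, try_add),
                     remove = acc_rem / max(1, try_rem)),
      converged = TRUE),
      class = "gc_fit")
  })
}
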