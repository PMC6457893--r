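early_template <- function(n = 4, delay = 3, span = 12)
  mossy_template("early", burst_times = delay + span * seq(0, 1,
                                                           length.out = n))

test_that("early-fiber retention follows the relax-then-reduce closed form", {
  st <- early_drop_state()
  # rested fiber, one command: f drops to alpha = 0.72
  expect_equal(step_early_drop(st, Inf)$f, 0.72)
  # full relaxation between commands returns to the same fixed point
  st2 <- step_early_drop(step_early_drop(st, Inf), 1e9)
  expect_equal(st2$f, 0.72)
  # 60 Hz interval: f = 0.72 * (1 - 0.28 * exp(-16.667/80))
  st3 <- step_early_drop(step_early_drop(st, Inf), 1000 / 60)
  expect_equal(st3$f, 0.72 * (1 - 0.28 * exp(-(1000 / 60) / 80)),
               tolerance = 1e-12)
  expect_error(step_early_drop(st, -1), ">= 0")
  # relaxation toward 1 is monotone in the interval
  fs <- vapply(c(10, 50, 100, 400), function(dt)
    step_early_drop(early_drop_state(f = 0.5), dt)$f, numeric(1))
  expect_true(all(diff(fs) > 0))
})

test_that("early expansion copies bursts (original) and drops from the end (revised)", {
  tmpl <- early_template(n = 4)
  sq60 <- gen_command_sequence(60, 10)
  orig <- expand_early(tmpl, sq60, "original")
  expect_length(orig$spike_times, 10 * 4)

  rev60 <- expand_early(tmpl, sq60, "revised")
  # first command of a rested fiber emits the full burst
  first <- rev60$spike_times[rev60$spike_times < sq60$command_times[2]]
  expect_equal(first, tmpl$burst_times)
  # second command retains fewer spikes, dropped from the end of the burst
  second <- rev60$spike_times[rev60$spike_times >= sq60$command_times[2] &
                              rev60$spike_times < sq60$command_times[3]]
  expect_lt(length(second), 4)
  expect_equal(second - sq60$command_times[2],
               tmpl$burst_times[seq_along(second)])

  # 10 Hz: f recovers nearly fully between commands -> full bursts kept
  sq10 <- gen_command_sequence(10, 10)
  rev10 <- expand_early(tmpl, sq10, "revised")
  expect_equal(length(rev10$spike_times), 10 * 4)

  expect_error(expand_early(mossy_template("medium", burst_times = 20),
                            sq60), "class")
})

test_that("revised early spikes/command is non-increasing in steady rate", {
  tmpl <- early_template(n = 5)
  per_cmd <- vapply(c(10, 20, 30, 40, 50, 60), function(r) {
    sq <- gen_command_sequence(r, 25)
    length(expand_early(tmpl, sq, "revised")$spike_times) / 25
  }, numeric(1))
  expect_true(all(diff(per_cmd) <= 1e-12))
  expect_lt(per_cmd[6], per_cmd[1])
})

test_that("medium expansion repeats the spike set and merges within 1 ms", {
  tmpl <- mossy_template("medium", burst_times = c(15, 25))
  # two commands 20 ms apart: spikes at 15, 25, 35, 45
  sq <- command_sequence(c(0, 20), 50)
  expect_equal(expand_medium(tmpl, sq)$spike_times, c(15, 25, 35, 45))
  # isolated commands reproduce the template
  iso <- command_sequence(c(0, 500), 2)
  expect_equal(expand_medium(tmpl, iso)$spike_times, c(15, 25, 515, 525))
  # rate bound from the merge refractory
  dense <- gen_command_sequence(60, 25)
  sp <- expand_medium(tmpl, dense)$spike_times
  expect_true(all(diff(sp) >= 1))
})

test_that("late expansion accumulates delays and suppresses covered bursts", {
  tmpl <- mossy_template("late", late_delay = 30,
                         late_burst = c(32, 36, 40, 44))
  iso <- command_sequence(0, 2)
  expect_equal(expand_late(tmpl, iso)$spike_times, tmpl$late_burst)
  # interval < delay: earlier burst fully suppressed
  two <- command_sequence(c(0, 20), 50)
  expect_equal(expand_late(tmpl, two)$spike_times, 20 + tmpl$late_burst)
  # 60 Hz train: only the final command's burst survives
  sq60 <- gen_command_sequence(60, 25)
  out <- expand_late(tmpl, sq60)$spike_times
  expect_equal(out, max(sq60$command_times) + tmpl$late_burst)
})

test_that("pause expansion deletes spikes in pause windows", {
  law <- list(shape = 4, mean_isi = 20)  # 50 spikes/s
  tmpl <- mossy_template("pause", pause_duration = 40, isi_law = law)
  # intervals shorter than the pause: firing ceases during the train
  sq60 <- gen_command_sequence(60, 25)
  out <- expand_pause(tmpl, sq60, seed = 3)
  during <- out$spike_times[out$spike_times > 0 &
                            out$spike_times <= max(sq60$command_times) + 40]
  expect_length(during, 0)
  # no spikes in any pause window, ever
  sq10 <- gen_command_sequence(10, 25)
  out10 <- expand_pause(tmpl, sq10, seed = 4)
  for (cmd in sq10$command_times)
    expect_false(any(out10$spike_times > cmd &
                     out10$spike_times <= cmd + 40))
})

test_that("pause thinning matches the window-coverage fraction at 10 Hz", {
  # 40 ms pauses at 10 Hz cover 40% of the train: expect ~0.6 retention
  law <- list(shape = 4, mean_isi = 20)
  tmpl <- mossy_template("pause", pause_duration = 40, isi_law = law)
  sq <- gen_command_sequence(10, 25)
  span <- max(sq$command_times) + 100
  kept <- unpaused <- 0
  for (seed in 1:30) {
    out <- expand_pause(tmpl, sq, seed = seed, t_end = span)
    base <- with_seed(seed, sample_isi_train(law, span))
    kept <- kept + sum(out$spike_times <= max(sq$command_times))
    unpaused <- unpaused + sum(base <= max(sq$command_times))
  }
  expect_equal(kept / unpaused, 0.6, tolerance = 0.05)
})

test_that("tonic retention is the clamped linear law of the command rate", {
  expect_equal(tonic_retention(60), 0.6)
  expect_equal(tonic_retention(10), 1)
  expect_equal(tonic_retention(35), 0.8)
  expect_equal(tonic_retention(c(0, 5)), c(1, 1))
  expect_equal(tonic_retention(100), 0.6)
})

test_that("revised tonic thinning approaches 0.6 during a long 60 Hz train", {
  law <- list(shape = 4, mean_isi = 20)
  tmpl <- mossy_template("tonic", isi_law = law)
  sq <- gen_command_sequence(60, 120)  # ~2 s of 60 Hz commands
  span <- max(sq$command_times)
  n_orig <- n_rev <- 0
  for (seed in 1:20) {
    o <- expand_tonic(tmpl, sq, "original", seed = seed, t_end = span)
    r <- expand_tonic(tmpl, sq, "revised", seed = seed, t_end = span)
    sel <- function(s) sum(s > 150 & s <= span)  # after window fill-up
    n_orig <- n_orig + sel(o$spike_times)
    n_rev <- n_rev + sel(r$spike_times)
  }
  expect_equal(n_rev / n_orig, 0.6, tolerance = 0.05)
})

test_that("original and revised coincide for isolated commands", {
  # early: isolated commands, full relaxation -> identical spike sets
  tmpl <- early_template(n = 5)
  iso <- command_sequence(seq(0, by = 500, length.out = 6), 2)
  expect_equal(expand_early(tmpl, iso, "original")$spike_times,
               expand_early(tmpl, iso, "revised")$spike_times)
  # tonic: retention is 1 at 2 Hz, so the same seed gives the same train
  ton <- mossy_template("tonic", isi_law = list(shape = 4, mean_isi = 25))
  o <- expand_tonic(ton, iso, "original", seed = 11, t_end = 3000)
  r <- expand_tonic(ton, iso, "revised", seed = 11, t_end = 3000)
  expect_equal(o$spike_times, r$spike_times)
})

test_that("expansions are deterministic given template, sequence and seed", {
  lib <- gen_template_library(5, seed = 2)
  sq <- gen_command_sequence(40, 25)
  for (cls in c("early", "medium", "late", "pause", "tonic")) {
    a <- expand_template(lib[[cls]][[1]], sq, "revised", seed = 9)
    b <- expand_template(lib[[cls]][[1]], sq, "revised", seed = 9)
    expect_identical(a$spike_times, b$spike_times)
  }
})
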