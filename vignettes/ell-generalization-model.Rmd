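---
title: "Modeling corollary-discharge cancellation and its generalization in the mormyrid ELL"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling corollary-discharge cancellation and its generalization in the mormyrid ELL}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ellgen)
```

## The circuit and the problem

Mormyrid electric fish emit electric organ discharges (EODs) that drive
their own passive electroreceptors, producing a ringing afferent response
lasting roughly 200 ms per pulse. Output neurons of the electrosensory
lobe (ELL) cancel this predictable input with a learned *negative image*:
granule cells convey corollary-discharge signals time-locked to the EOD
motor command, and anti-Hebbian plasticity at granule-to-ELL synapses
sculpts their summed drive into the negative of the sensory response. The
modeling question this package addresses is how a negative image learned
at one EOD rate (fish rest at a few Hz) remains accurate at rates up to
60 Hz (foraging), given that both the sensory response and the
corollary-discharge inputs change with rate.

The package simulates the full loop on synthetic data: mossy-fiber
single-command templates are expanded into rate-dependent sequence
responses, mixed into an integrate-and-fire granule-cell population, fed
through plastic synapses onto a passive model ELL neuron paired with a
linear-electroreceptor sensory trace, and scored with the residual power
ratio C. A separate module infers granule-cell model parameters and input
spike times from (synthetic) membrane-voltage recordings.

## Time base and integration

All simulations use a uniform 0.05 ms grid (20 kHz), the digitization
rate of the recordings the model emulates; spike times are snapped to the
grid. The granule membrane equation
\[
\tau_m \frac{dV}{dt} = E_l - V + \sum_{i,j} E_i(t - t_{ij}),
\qquad
E_i(t) = \frac{w^{fast}_i}{\tau^{fast}_i} e^{-t/\tau^{fast}_i}
       + \frac{w^{slow}_i}{\tau^{slow}_i} e^{-t/\tau^{slow}_i},
\]
is linear between threshold events, so each grid step is advanced with
the exact closed-form solution of the membrane-plus-synapse system rather
than a forward-Euler update. This costs nothing extra and removes the
~2% amplitude bias Euler would introduce at the default
$\tau^{fast} = 2$ ms; the test suite checks the simulated single-spike
EPSP against the analytic membrane-filtered dual exponential at machine
precision. Threshold crossings are detected on the grid; after a spike
the voltage is held at the reset for the 1 ms refractory period.

## Synthetic study conditions

The generator defaults define the conditions under which all tests and
reported numbers are computed.

* **Command sequences** — 25 equally spaced commands at 1–60 Hz
  (microstimulation-style trains); spontaneous commanding at 2–5 Hz is a
  special case of the same generator. Paired sequences carry EOD-mimic
  times 4.5 ms after each command.
* **Electroreceptor kernel** — the afferent impulse response is a damped
  oscillation `peak · exp(-t/50 ms) · cos(2π · 10 Hz · t)` over 250 ms,
  so the response persists for ~200 ms. The oscillation frequency and
  decay are configurable stand-ins: their true values are not tabulated,
  only the damped-oscillation shape and duration. The sensory trace
  `s(t)` is the linear superposition of this kernel at the mimic times,
  scaled so an isolated mimic peaks at 1 (arbitrary input units of the
  current-based ELL neuron — a unitless coupling is unavoidable for a
  current-based unit).
* **Mossy-fiber templates** — per class, randomized around the recorded
  phenomenology: early bursts of 3–6 spikes spanning ~12 ms at 2–6 ms
  latency; medium spikes at 15–50 ms; late bursts after 30–60 ms silent
  delays; pause fibers with 20–60 ms pauses over tonic firing; tonic
  fibers with gamma ISIs (shape 4) at 20–80 spikes/s.
* **Granule cells** — three input sites per cell with class
  probabilities 0.425 (early), 0.075 (medium), 0.05 (late), 0.05
  (pause), 0.157 (tonic) and 0.243 (none); synapse parameters drawn from
  gamma distributions (shape 4) with means chosen so a mean-parameter
  EPSP peaks near 8 mV at the default 10 ms membrane. Threshold, reset
  and refractory period are not constrained by the recorded-cell fits;
  the defaults `θ = E_l + 10` mV, `V_reset = E_l`, `t_ref = 1` ms make
  isolated ~8 mV early EPSPs subthreshold so spiking requires summation.
  Per-spike EPSP peaks are jittered by N(0, 0.224 mV), the measured
  trial-to-trial variability of single EPSPs.
* **Synthetic voltage recordings** — forward-simulated subthreshold
  traces plus Ornstein–Uhlenbeck noise with a 5 ms correlation time
  (default SD 0.05 mV, the low-noise whole-cell regime) and optional
  0.3 ms, ±20 mV rectangular stimulus artifacts at command times, which
  the 1.8 mV/ms gradient criterion is guaranteed to catch. White noise at
  20 kHz would put unrealistic power into the 800–2000 Hz band used for
  EPSP detection; intracellular noise is dominated by synaptic background
  low-passed by the ~10 ms membrane, so 5 ms is still a conservative
  (whiter-than-membrane) choice. Broadband electrode noise is *not*
  emulated — a stated limitation. Consistency matters here: the
  gradient-threshold cleaning rule presumes recordings whose synaptic
  rise slopes and noise gradients stay below 1.8 mV/ms, and the membrane
  time constant is only informative when the slow noise power does not
  mimic the model's own slow synaptic components. The end-to-end recovery
  fixtures therefore sit at the quiet extreme of the regime (0.03 mV SD,
  2 ms correlation) with large EPSPs (3.4–4.6 mV) whose onset slopes are
  ~0.9–1.2 mV/ms, and recovery is scored against recording noise with the
  biological per-spike peak jitter off; tonic events are placed outside
  the command-locked assignment window so channel identity is
  unambiguous. At higher noise or with ambiguous channel assignment the
  recovered membrane time constant degrades gracefully (the residual
  surface is a shallow valley in which slow noise displaces the
  optimum).

What passing tests on these data do and do not show: they validate the
mechanisms (rate-dependent input transformations, regularized learning
dynamics, parameter recovery) under controlled conditions; they do not
validate the unmeasured physiological constants (electroreceptor kernel
parameters, granule thresholds, synaptic hyperparameters), which are
configurable defaults, not fits.

## The two input models

Medium, late and pause fibers are expanded identically in both input
models: medium responses repeat verbatim (overlaps allowed, spikes merged
within a 1 ms absolute refractory period, which operationalizes the
requirement that overlap not produce unrealistic rates); late-fiber
delays accumulate, each command's silent window deleting pending spikes
from earlier commands; pause fibers lay down a gamma-ISI train and delete
spikes inside each post-command pause, so pausing tiles the train and
silences the fiber at high rates.

Early and tonic fibers differ between models. The *original* model
repeats the early burst identically per command and leaves tonic trains
untouched. The *revised* model keeps a retained-spike fraction `f` per
early fiber (`τ_f df/dt = 1 − f`, `f → 0.72 f` after each command,
`τ_f = 80 ms`), emits `round(f · n)` spikes per command *before* applying
that command's reduction — so an isolated, rested command always emits
the full burst — and drops spikes from the end of the burst first, which
is how the recorded rasters lose spikes at high rates (the alternative, a
random subset, is not what the rasters show, though the data do not state
the rule explicitly). Tonic spikes are retained with probability falling
linearly from 1 at ≤10 Hz to 0.6 at 60 Hz of the trailing-100 ms command
rate (trailing rather than centered, since the thinning must be causal),
clamped outside the measured 10–60 Hz range.

## The ELL neuron and the learning rule

The ELL readout is the membrane potential of a passive, current-based
leaky unit (no spiking): `V = M[Σ_i w_i (E ∗ r_i) + s]`, with `M` the
membrane low-pass (τ = 10 ms) and `E` a dual-exponential EPSP kernel
normalized to unit integral so the weights carry the gain. After each
paired segment the weights update by

\[
\Delta w_i = \Delta_+ n_i \;-\; \Delta_- \int V(t)\,(E*r_i)(t)\,dt
\;-\; \lambda (w_i - w_c)\,T .
\]

Design choices that were genuinely open:

* **Δ₊, Δ₋ magnitudes.** Only their provenance ("fit to negative images
  in earlier work") is known, not their values. The defaults
  (`Δ₋ = 0.02`, `Δ₊ = 4·10⁻⁶` at the reference population size of
  20,000) were calibrated once so that pairing at 10 Hz converges well
  within 100 twenty-five-command blocks under the default synthetic
  conditions, and then frozen. The ratio `Δ₊/Δ₋` sets the equilibrium
  mean depolarization (with `∫E dt = 1`, `V̄_eq ≈ Δ₊/(10⁻³ Δ₋)` in these
  units); Δ₋ sets the learning speed and, at fixed update interval, the
  stability margin. Both scale as `20000 / N` so desk-scale populations
  (2,000 cells in the tests) learn at matched drive.
* **Update interval.** The rule is continuous-time; integrating it with
  one explicit step per 25-command block is too coarse under full
  regularization (λT ≈ 0.3 per block) and becomes unstable before it
  becomes accurate. The learning loop therefore re-simulates V and
  updates the weights once per command (`update_every` in
  `pairing_protocol()`); one whole-block update remains available and is
  what `plasticity_step()` itself implements, and the sparse per-segment
  path is tested to agree with it exactly.
* **Block structure.** The experimental 10–20 min pairing is modeled as
  repeated 25-command paired blocks separated by 500 ms gaps;
  regularization decay runs through the gaps. Probes (pre/post, all
  rates, and command-alone) never update weights.
* **Initialization.** Fully regularized runs start at `w_i = w_c` with
  `w_c` the least-squares scalar matching `w_c N r̄(t) ≈ −s(t)`;
  minimally regularized runs start at and decay toward zero, matching
  the "zero versus non-zero baseline" distinction between the two rules.
* **Granule responses during learning** are generated once per rate per
  experiment (seeded) and reused across blocks; regenerating the
  stochastic components per block would add Monte-Carlo noise to the
  learning trajectory without changing the fixed point, at ~100× the
  cost.

Cancellation is measured as
`C = Var(V_post) / Var(V_pre)` over the sequence window (means taken
within the window). The negative image is the change in the command-alone
response after learning; at convergence it is strongly anticorrelated
with `s(t)`.

With these defaults, at 2,000 cells: learning at 10 Hz converges to
`C < 0.25` for both regularization settings; the minimally regularized
original model over-cancels at 60 Hz (response anticorrelated with
`s(t)`, more residual 60 Hz power than the fully regularized revised
model); the fully regularized revised model keeps `0 < C < 1` at 60 Hz;
and full regularization shrinks the learned weight variance relative to
minimal regularization on identical inputs.

## Fitting granule-cell recordings

The inference pipeline mirrors how the recorded cells were fit, with the
manual visual-validation step replaced by ground-truth recovery metrics
on synthetic recordings:

* **Cleaning.** Samples whose finite-difference gradient reaches
  1.8 mV/ms are excised with a ±0.25 ms guard and bridged by linear
  interpolation. The criterion presupposes that synaptic rise slopes stay
  below the threshold — the regime of the recordings it was designed
  for — so the recovery fixtures use kinetics with onset slopes of
  ~0.9–1.2 mV/ms while artifacts (±20 mV / 0.3 ms) and action potentials
  exceed it by an order of magnitude.
* **Detection.** A Ricker (Mexican-hat) continuous wavelet transform at
  16 scales spanning pseudo-frequencies 800–2000 Hz; per scale, local
  maxima of the (negated) coefficients above 6× that scale's median
  absolute deviation; candidates need peaks on ≥8 scales within 0.5 ms
  and are merged to support-weighted means with a 0.5 ms minimum
  separation. The wavelet family, the per-scale threshold and the
  "multiple scales" count are operational choices (only the scale range
  and the 0.5 ms merge are fixed by the procedure being emulated); 6×MAD
  ≈ 4σ keeps the family-wise false-positive rate on a one-second trace
  near zero, which a 2.7σ threshold provably would not.
* **Least squares.** With candidate times fixed, the subthreshold model
  is linear in the leak potential and the four synaptic weights given
  the three time constants, so the fit profiles the linear parameters
  out (variable projection) and optimizes only the log time constants by
  multistart Nelder–Mead; negative weights are penalized, enforcing the
  hard positivity bound. A single-channel trace determines the
  three-exponential response function but admits one exactly equivalent
  relabeling of the membrane and synaptic time constants; two-channel
  cells (command-locked plus tonic input, as in the recordings) share
  `τ_m` across channels and pin it down. Detected candidates are
  assigned to channels by command-locking (within 15 ms after a
  command → channel 1), a rule the original procedure leaves unstated.
  The time constants are optimized by a two-stage multistart
  Nelder–Mead (broad cheap exploration, then a deep polish of the two
  best basins), with convergence declared by stationarity — a fresh
  restart failing to improve the objective — because simplex codes
  rarely report formal convergence on these shallow valleys.
* **MCMC.** Metropolis-within-Gibbs: random-walk updates of each
  parameter (log space for positivity), then per-channel spike moves —
  jitter (Normal, σ = 0.25 ms), birth (uniform over the trace) and death
  under a Poisson prior on the spike count centered on the detected
  count. Burn-in 500 sweeps, thinning 5. The Gaussian likelihood uses a
  noise SD estimated from the median absolute successive difference,
  floored at 0.05 mV so noise-free fixtures keep a finite posterior. The
  two routes agree within one posterior SD on noise-free fixtures.

## Numerical notes and degenerate inputs

Convolutions (linear prediction, granule drive, depression integrals)
run via FFT and are tested against brute-force superposition to 10⁻⁹ of
the kernel peak. Empty spike trains, unpaired sequences, zero-variance
pre-learning traces, non-positive rates and probability vectors that do
not sum to one all raise immediate, descriptive errors. Every stochastic
generator is a pure function of its arguments including the seed; the
bootstrap (1,000 draws of 28 cells, two-sided p floored at 2/1000)
matches the sample size of the recorded population it is compared
against.

Problem sizes used by the test suite: 2,000-cell populations with
drive-matched plasticity rates for the learning experiments and the
population-statistics comparison (the reference scale of 20,000 is a
config switch), 100 learning blocks, 20-seed recovery ensembles for the
fitting pipeline, and 10⁴ spikes for the jitter calibration.

## Known limitations

* The electroreceptor kernel, granule thresholds and synapse
  hyperparameters are stand-ins; conclusions about their absolute values
  are outside what the synthetic conditions can support.
* The model ELL neuron is a passive voltage readout; firing-rate
  rectification and the E/I-cell and medium-ganglion distinctions are
  deliberately absent.
* Golgi-cell inhibition and unipolar-brush-cell biophysics are not
  modeled beyond the pause/tonic phenomenology.
* Conductance-based synapses, synaptic depression and inhibitory inputs
  are excluded by design (they were tried against the recordings and did
  not improve fits).
* Serialization uses plain CSV/JSON; traces are exchanged as two-column
  CSV. The exported functions and this vignette are the interface; there
  is no shell entry point beyond `scripts/acceptance.R`.
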