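---
title: "Modelling the tactile afferent-to-efferent chain"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the tactile afferent-to-efferent chain}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tactosense)
```

`tactosense` models the chain from a tactile sensor array to a motor
command: spiking mechanoreceptor models encode per-taxel drive into afferent
spike trains, a second-order cuneate stage integrates them, spike-train
features feed a signal-detection account of object discrimination, and a
Laplace-domain transduction function identified between the cuneate firing
rate and the muscle-synergy activation closes a grasp control loop. This
vignette explains the models, the choices behind their defaults, and what
the synthetic data generator can and cannot stand in for.

## First-order afferents

Slowly adapting (SAI) and fast adapting (FAI) type I units are modelled with
the Izhikevich neuron,

$$\dot v = 0.04 v^2 + 5 v + 140 - u + \tfrac{K}{C_m} I(t), \qquad
  \dot u = a (b v - u),$$

with the reset $v \leftarrow c$, $u \leftarrow u + d$ whenever $v$ reaches
30 mV. The SAI unit is driven by the ported sensor signal $K \cdot
I_\mathrm{sensor}(t)$; the FAI unit by the signal's time derivative, which
gives the fast-adapting phenotype: it fires at stimulus transients and is
silent under held pressure, while the SAI unit fires tonically.

Parameter sets. The literature starting point is $a=0.02$, $b=0.2$,
$c=-65$ mV, $d=6$ mV with gain $K=25$; the sets optimised against
microneurography firing rates are $b=0.205$, $d=6.20$, $K=55$ (SAI) and
$b=0.210$, $c=-65.5$, $d=6.15$, $K=56$ (FAI). Only the ratio $K/C_m$ is
identifiable from firing rates, so all gain is folded into $K$ with
$C_m = 1$ exposed as an override.

Numerical choices:

* fixed-step forward Euler at `dt = 0.1` ms, $v$ updated before $u$ (the
  model's original ordering). A step of 1 ms or more triggers a warning:
  the quadratic membrane equation is stiff near threshold. The test suite
  holds the 0.1 ms integration to within one spike per second of a 0.01 ms
  reference.
* a spike is logged at the first sample where $v \ge 30$ mV and the reset
  consumes that step, so the recorded trajectory shows exactly $c$ on the
  sample after a spike.
* initial state $v_0 = -70$ mV, $u_0 = b v_0$: the resting equilibrium.
* the FAI derivative uses central differences (one-sided at the ends) and
  is rectified by default, so both onset and offset transients excite the
  unit; a signed mode is available. The choice is deliberate: fast-adapting
  afferents respond to both edges of a stimulus.

`fit_afferent_params()` maximises the goodness of fit
$\mathrm{FSS} = 1 - \sum_i (r_i - \hat r_i)^2 / \sum_i r_i^2$ between a
reference stimulus-rate table and simulated rates, by a deterministic
coarse grid over the bounded parameters followed by Nelder-Mead
refinement. A derivative-free search was chosen because the spike count is
piecewise constant in the parameters; the returned set is never worse than
the initial one, and fits on fewer than three reference points are flagged
under-determined.

## The cuneate stage

Each afferent train is convolved with a postsynaptic-potential kernel and
summed onto second-order units. The kernel is the causal double exponential

$$k(t) = e^{-t/\tau_\mathrm{slow}} - e^{-t/\tau_\mathrm{fast}},$$

peak-normalised, with $\tau_\mathrm{fast} = 4$ ms and $\tau_\mathrm{slow} =
12.5$ ms. Written with positive exponents, or with the slow constant as the
"decay", the expression diverges or goes negative; the implementation
orients the larger constant as the decay so the kernel is a nonnegative
PSP-shaped pulse with its peak at
$\frac{\tau_s \tau_f}{\tau_s - \tau_f}\ln\frac{\tau_s}{\tau_f} \approx
6.7$ ms.

The afferent-to-cuneate projection uses the average divergence/convergence
ratio 1700/300: $n$ active afferents recruit
$\lceil 1700 n / 300 \rceil$ cuneate neurons (567 for $n = 100$). Each
recruited neuron draws a uniform random subset of afferents capped at the
convergence (300); with the 36-taxel array the cap is not binding and every
cuneate neuron integrates all 36 afferents, which is also what the total-PSP
summation over 36 units describes. Edges are excitatory; a configurable
fraction of inhibitory (weight $-1$) edges is an extension point, default
zero, since no interneuron equations are available to constrain it.

Winner-take-all selects the unit with the largest *time-integrated*
total PSP over the trial rather than the instantaneous maximum: the
integral is stable under sample-level jitter and gives a reproducible,
testable selection (ties resolve to the lowest index). The winner's PSP,
scaled by `gain_cuneate`, drives an Izhikevich unit with the SAI-optimised
parameters — no separate cuneate set is available.

The PSP-to-drive scaling is genuinely unconstrained by any published
value. Summing 36 peak-normalised PSPs under tens of spikes per second
yields a drive of order $10^3$ after the $K = 55$ gain, which saturates the
neuron beyond 2 kHz and erases rate sensitivity. The default
`gain_cuneate = 0.012` was calibrated once, forward from the drive-rate
curve, so that the winning unit of the 36-taxel array fires in the same
30-60 spikes/s regime as the first-order units, matching the second-order
signals' reported character; it remains a configuration parameter.

## Spike-train features and discrimination

Features: mean firing rate over a window, 200-ms binned counts (the last
bin absorbs a partial remainder; counts conserve the total), first-spike
latency from stimulus onset, and the Victor-Purpura distance — the minimal
cost of editing one train into the other with insertions/deletions at cost
1 and shifts at cost $q$ per ms, computed by dynamic programming and
verified against exhaustive matching. The cost parameter is not reported
for the discrimination analysis; the default $q = 0.05$/ms (20 ms
precision) is a mid-range value from the spike-metric literature and is
recorded in all outputs.

Discrimination follows a yes/no signal-detection protocol. Cylinders and
spheres of 50-100 mm diameter are each touched 10 times; every non-baseline
object is discriminated from the 100-mm baseline of the same shape. For
rate coding, the "noise" samples are the winning cuneate unit's spike
counts over the 10 baseline touches and the "signal" samples the counts on
the target object. For the Victor-Purpura feature, "noise" is the 45
pairwise distances among baseline touches and "signal" is one distance per
target touch against the same-index baseline touch — 10 per object pair,
hence 50 per shape and 100 over both shapes. A full cross-pairing (100 per
pair) is available by a flag; the indexed pairing is the default because it
reproduces the 50-per-shape count that the protocol's bookkeeping states.
Sensitivity is $d' = (\bar x_s - \bar x_n) / \sqrt{(s_s^2 + s_n^2)/2}$
(rms of the two standard deviations, since the variances need not be
equal), and the reported hit rate is the unbiased observer's percent
correct $\Phi(d'/2)$. Degenerate distributions (zero pooled sd) yield `NA`
with a warning rather than a number.

## Muscle synergies

EMG preprocessing is the conventional synergy pipeline: 4th-order
Butterworth band-pass 20-450 Hz, full-wave rectification, 4 Hz low-pass
envelope, all zero-phase, with per-channel unit-maximum normalisation.
Synergies are extracted by multiplicative-update NMF (squared Frobenius
error; the objective is non-increasing per iteration), best of 20 seeded
restarts, 500 iterations, relative tolerance $10^{-6}$. The variance
accounted for is the uncentered global ratio
$1 - \|V - WH\|^2 / \|V\|^2$; a per-muscle mean is available by flag since
"mean VAF" is ambiguous. The synergy count is the smallest $k$ with VAF
above 85% and a gain below 6% from the next synergy; if no $k$ qualifies,
the maximum is returned with a warning flag. When stepping $k$, the
previous factorisation (padded with one small extra component) seeds one
restart, which guarantees a non-decreasing VAF curve.

## Transduction functions

The sensorimotor mapping is a strictly proper continuous-time transfer
function from the normalised cuneate firing rate to the synergy activation:
$a/(S^2 + bS + c)$ for active grasping and $a/(S^3 + bS^2 + cS + d)$ for
reactive grasping. The reactive form is kept monic — a leading denominator
coefficient is redundant with the gain. The rate is the only scalar signal
shared by both sides of the mapping, so the 200-ms binned rate,
interpolated to the activation's sample step (10 ms), is the input.

Simulation uses zero-order-hold discretization (exact at the sample points
for piecewise-constant input) through the controllable canonical state
space and the matrix exponential. Identification is output-error: seeded
multi-start Nelder-Mead over the gain and the log of the positive monic
denominator coefficients, initialised from a discretized ARX least-squares
fit, with a final simplex-restart polish. Stability is checked and flagged,
not enforced. Structure selection fits every candidate order and keeps the
best normalised fit $1 - \|y - \hat y\| / \|y - \bar y\|$, treating fits
within $10^{-4}$ as ties resolved towards the lowest order — on noiseless
data every order above the truth can only match it, so the tie rule
recovers the true structure.

## The synthetic generator and the closed loop

No recordings are distributed with the package; a seeded generator stands
in for the rig:

* **Taxel drive.** Plateau amplitude `base_amplitude + curvature_gain /
  diameter` with a centre-peaked spatial profile — spheres fall off along
  both grid axes and carry a 6% amplitude boost for their smaller contact
  patch, cylinders fall off only across their axis. The defaults
  (`base_amplitude = 0.21`, `curvature_gain = 7` a.u. mm, gain $K = 55$)
  were calibrated once, forward from the Izhikevich rate-drive curve, so
  the centre taxel fires in the high-40s of spikes/s on a 50-mm object and
  under 45 spikes/s on a 100-mm object — the regime reported for the
  physical array. Contact is a raised-cosine ramp (100 ms) after onset;
  trial-to-trial variability is a per-taxel amplitude jitter of 5% plus
  low-amplitude white noise.
* **Impact.** Reactive trials superimpose a damped 50 Hz oscillation
  (3x plateau for the 20 g weight, ~100 ms settling) and a brief 70% drive
  dropout mimicking slip shear. The oscillation makes the FAI derivative
  pathway burst at impact.
* **EMG.** Each channel is a nonnegative synergy envelope modulating a
  band-limited carrier with 10% multiplicative noise and a small noise
  floor — low-rank by construction, which is exactly what the extraction
  stage is tested against.
* **Closed loop.** A deliberately minimal plant: pressure =
  grip x stiffness - load, slip below a pressure threshold ends contact
  permanently, commands act after an 80 ms motor delay (the reported
  sensorimotor lag of the artificial system) at a 10 ms control step. The
  controller input is the cuneate rate over a trailing 200 ms window; the
  transduction controller starts from its tonic-grasp equilibrium state so
  an established grasp is not transiently released at $t = 0$.

What the generator does *not* emulate: skin mechanics and strain-energy
transduction (the drive-to-pressure map is an identity with a scale),
somatotopy beyond one taxel patch, sensor hysteresis and thermal drift,
EMG crosstalk and motion artifacts, and any hand kinematics. Passing tests
therefore show that the algorithms recover what the generator put in and
reproduce the study-level qualitative relations (rates and hit rates
increasing with curvature, SAI/FAI phenotypes, controller contrast) — they
do not certify performance on physical recordings.

## Problem sizes

The shipped tests and the acceptance script use: 1-s trials at 0.1 ms
steps for single touches, the full 2-shape x 6-diameter x 10-touch
protocol for discrimination, 100 seeded 2-s EMG trials for the
synergy-count recovery, 600-sample records at 10 ms for transfer-function
recovery with an order search bounded at 10, and 20 seeded reactive trials
per controller for the closed-loop contrast. These sizes were chosen as
the smallest that exercise every pathway with stable statistics.

## Known limitations

* The cuneate population under full connectivity is homogeneous, so
  winner-take-all degenerates to the first unit unless inhibition or a
  binding convergence cap differentiates the units.
* The FAI gain acts on a derivative whose magnitude depends strongly on
  the stimulus rise time; slow ramps can leave the unit silent.
* Output-error identification with Nelder-Mead is not guaranteed to find
  the global optimum for orders far above the truth; the order search
  mitigates this with multi-start and the tie rule.
* The plant is a one-dimensional abstraction: no grip geometry, no tendon
  dynamics, no shear-force model.
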