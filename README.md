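# tactosense

Modelling how tactile input becomes motor output. `tactosense` implements
the computational chain of a neuromorphic artificial tactile sensory
system: per-taxel signals from a 6×6 sensor array are encoded into
mechanoreceptor spike trains, integrated by a second-order cuneate stage,
read out as neural features for object discrimination, and linked to
muscle activity through identified transduction functions that can close a
grasp control loop. It is written for researchers in computational
neuroscience, neuroprosthetics and neuromorphic robotics who want a tested,
scriptable reference implementation of this pipeline, with a seeded
synthetic generator replacing the physical rig.

## The models

**Afferent encoding.** Slowly and fast adapting type I units (SAI/FAI) are
Izhikevich neurons

```
dv/dt = 0.04 v² + 5v + 140 − u + (K/Cm)·I(t)
du/dt = a(bv − u),        v ≥ 30 mV ⇒ v ← c, u ← u + d
```

driven by the gain-ported sensor current (SAI) or its time derivative
(FAI). Fitted parameter sets for both unit types are built in; the fitting
objective `FSS = 1 − Σ(r−r̂)²/Σr²` and a bounded derivative-free optimiser
are exported.

**Cuneate stage.** Afferent trains are convolved with a peak-normalised
double-exponential PSP kernel (τ_fast = 4 ms, τ_slow = 12.5 ms) and summed
onto a population recruited at the 1700/300 divergence/convergence ratio
(100 active afferents ⇒ 567 cuneate neurons); the unit with the largest
integrated PSP is selected by winner-take-all and spiked through the same
neuron model.

**Features and discrimination.** Firing rate, 200-ms binned counts,
first-spike latency and the Victor–Purpura edit distance (cost `q` per ms
of spike shift) feed a signal-detection protocol: d′ between "signal" and
"noise" feature distributions from repeated touches, hit rate Φ(d′/2).

**Synergies and transduction.** EMG envelopes are factorised by
multiplicative-update NMF; the synergy count is the smallest k with VAF
above 85% and below a 6% gain from the next synergy. Transduction
functions `a/(S² + bS + c)` (active grasp) and `a/(S³ + bS² + cS + d)`
(reactive grasp) are identified between the cuneate rate and the synergy
activation by output-error minimisation, and drive a minimal closed-loop
grasp plant with slip detection.

## Worked example

```r
library(tactosense)

# one touch of a 50 mm sphere, end to end
sc <- grasp_scenario(shape = "sphere", diameter_mm = 50, seed = 1)
touch <- simulate_touch(sc)
rates <- vapply(touch$afferents, firing_rate, numeric(1))
```

The 36 SAI afferents fire at 32–52 spikes/s with the maximum on the centre
taxel; the winning cuneate unit fires at 56 spikes/s with its first spike
39.4 ms after contact. Smaller objects (higher curvature) press harder on
the array, so rates and latencies order by diameter.

```r
# discriminate 50-90 mm cylinders from the 100 mm baseline
proto <- discrimination_protocol(shapes = "cylinder", seed = 1)
res <- run_discrimination_protocol(proto)
res[res$feature == "vp", c("diameter_mm", "d_prime", "hit_rate")]
#>  diameter_mm d_prime hit_rate
#>           50   4.457    0.987
#>           60   2.757    0.916
#>           70   1.910    0.830
#>           80   1.300    0.742
#>           90   0.105    0.521
```

Each diameter is touched 10 times; the Victor–Purpura "noise" set is the
45 distances among baseline touches and the "signal" set one distance per
touch pair (50 per shape). Discriminability rises with curvature: a 50 mm
cylinder is told apart from the 100 mm baseline with a 99% hit rate, a
90 mm cylinder barely above chance.

A thin command-line wrapper over the same functions is installed at
`inst/cli/tactosense.R` (`simulate`, `encode`, `cuneate`, `metrics`, `discriminate`, `synergy`, `sysid`, `run`
subcommands), and `run_pipeline()` executes the whole chain from one YAML
configuration with full seed provenance.

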