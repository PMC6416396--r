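---
title: "Simulating photoacoustic-feedback wavefront shaping: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating photoacoustic-feedback wavefront shaping: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pafocus)
```

## The problem

Focusing light through a strongly scattering medium onto a target that no
camera can see requires a feedback signal generated at the target itself.
The photoacoustic effect provides one: an absorber (for instance a blood
vessel, or here a 150 µm black nylon thread) converts the local optical
fluence into an ultrasonic pressure transient that a focused transducer can
pick up noninvasively. A binary-amplitude spatial modulator (a DMD, divided
into N controllable segments) shapes the incident wavefront; a genetic
algorithm searches for the on/off mask that maximizes the photoacoustic
amplitude, i.e. the fluence delivered to the target.

The practical obstacle is that the feedback trace is terrible: the damage
threshold of a DMD limits the pulse energy, so the raw photoacoustic SNR is
only a few units, and the records are contaminated by transient clutter
(electrostatic and amplifier ringing) that occupies the *same frequency
band* as the signal and moves from shot to shot, so band-pass filtering
cannot remove it. `pafocus` implements the two-stage remedy — wavelet
denoising for the white noise, correlation gating for the clutter — inside
a complete, seeded simulation of the optical/acoustic chain.

## Forward model

**Speckle.** The medium couples the N input segments to the speckle field
on the absorber through a transmission matrix with i.i.d. circular complex
Gaussian entries (zero mean, unit variance): fully developed speckle. The
absorber intercepts M independent speckle modes; mode m receives the
coherent sum `I_m = |Σ_n t_mn b_n|²` of the open segments `b`. This is the
statistical model under which the binary-amplitude enhancement theory
(below) is derived; real media with long-range correlations or partial
development will deviate from it.

**Photoacoustic source.** The source amplitude is `s = Γ μ_a Σ_m I_m`
(Grüneisen parameter times absorption coefficient times intercepted
fluence), optionally scaled by a per-absorber transducer sensitivity. The
emitted pulse is modeled as an N-shaped (bipolar, zero-mean) transient —
the derivative of a Gaussian — whose magnitude spectrum peaks at the
size-determined center frequency `f₀ = 0.66 c_s / D_a`; for a 150 µm
absorber in water (c_s = 1500 m/s) that is 6.6 MHz. Only the center
frequency is constrained by theory; the envelope choice is ours, consistent
with standard point-source photoacoustics.

**Transducer.** The 5 MHz receiving transducer is modeled as a flat-top
band-pass (unit response over `f_c (1 ± fbw/2)`, Gaussian skirts of width
0.15 f_c), with a default fractional bandwidth of 0.7 — typical of a
single-element probe — passing 3.25–6.75 MHz, which covers the 6.6 MHz
pulse. A flat top rather than a Gaussian response is deliberate: the
physical transducer's bandwidth *covers* the 6.6 MHz pulse, and a Gaussian
centered at 5 MHz would drag the synthesized pulse's spectral peak down to
~5.3 MHz, contradicting the center-frequency rule the pulse model is built
on. The bandwidth also matters downstream: a narrower band lengthens the
pulse and concentrates its wavelet-domain energy, which lowers the
amplitude below which soft universal thresholding annihilates a weak
signal. No impulse-response deconvolution or diffraction integral is
attempted.

**Noise.** White Gaussian noise `σ ω`, `ω ~ N(0,1)`, models the
oscilloscope/amplifier floor. The default σ is calibrated so that random
Bernoulli(½) masks on the *realized* medium yield a mean pre-denoising SNR
of 3.86 (the documented operating point, measured in an experiment on the
one physical medium at hand). For a fixed transmission matrix the exact
mask-average of the total intensity is
`Σ_m ( |Σ_n t_mn/2|² + Σ_n |t_mn|²/4 )` — each mode's mean-field power
plus half its incoherent variance. Its ensemble expectation is `M N / 2`,
but the mean-field term fluctuates appreciably between media; calibrating
to the realized value (rather than the ensemble mean) keeps the detection
operating point stable across simulated media, exactly as re-measuring the
SNR would in the laboratory.

**Clutter.** Each acquisition receives a Poisson(rate) number of
Gaussian-windowed tone bursts, carrier drawn uniformly inside the
transducer passband (so spectral filtering cannot help), 8 carrier cycles
long, amplitude uniform in 0.5–1.5× the mean random-mask pulse peak, at a
uniformly random record position. Clutter statistics are only
qualitatively characterized in the underlying experiments; these defaults
were fixed once so that the simulated correlation dichotomy matches the
documented one (photoacoustic signals vs. template above 0.8, clutter and
noise below 0.4) and are config-exposed.

**Defaults of the reference world** (`default_world()`): N = 576 segments
(a 32 × 18 grid), M = 7 modes (nearest integer to the theoretical 7.47),
records of 2048 samples at dt = 5 ns starting at t0 = 16 µs, acoustic
arrival at 21 µs (3 cm of water), clutter rate 1 per acquisition.

## Wavelet denoising

Each trace is decomposed to 8 levels with the fourth-order Daubechies
wavelet; detail coefficients are soft-thresholded at the universal
(VisuShrink) threshold `K = σ̂ √(2 ln M)` with M the record length, and the
approximation coefficients are left untouched. σ̂ is the median absolute
deviation of the finest-level detail coefficients divided by 0.6745 — the
standard robust estimator, insensitive to the sparse band-limited pulse.

Numerical choices:

* **Periodized orthogonal transform.** We use circular (periodized)
  convolution rather than symmetric extension. The transform is then
  exactly orthogonal: Parseval holds to machine precision and
  reconstruction is perfect, which is the premise of the universal
  threshold. Simulated traces are essentially zero at the record edges, so
  circular wrap-around is immaterial. The transform was verified against an
  independent implementation during development; the test suite checks
  perfect reconstruction, Parseval and row orthonormality for every
  shipped filter (db2, db4, db8, sym4, sym8, coif4).
* **One global K** across all detail levels (the simplest reading of the
  single threshold formula); soft thresholding by default, hard selectable.
* **Non-power-of-two lengths** are allowed; the decomposition depth is
  capped at the deepest level with an even length, with a warning.
* **Degenerate inputs:** an all-zero trace has σ̂ = 0, K = 0, and passes
  through unchanged.

A practical property worth knowing: soft universal thresholding has a
cliff. A pulse whose wavelet coefficients sit below K (for the default
calibration, masks whose amplitude falls below roughly half the ensemble
mean) is annihilated together with the noise. Those acquisitions fail the
correlation gate and contribute zero fitness — which is the desired
behavior in the optimization loop, and the reason a small percentage of
random-mask acquisitions score low correlations.

## Correlation gating

The reference template is measured the way the experiment starts: an
acquisition with all segments open (strong signal), averaged 16×, denoised.
Each subsequent acquisition is denoised, windowed to the gate (± 0.5 µs
around the expected arrival), and correlated with the template's gated
reference using the normalized correlation coefficient; the acquisition is
accepted iff γ ≥ 0.7. Peak-to-peak is measured inside the gate only, so
clutter elsewhere cannot inflate the fitness. Accepted acquisitions replace
the template (last-accepted wins), letting the reference track the slow
waveform drift as the optimization raises the amplitude.

Design choices:

* **Lag tolerance ±20 ns (four samples).** Acquisitions are time-locked by
  the laser trigger, so the correlation is nearly aligned by construction.
  A wide lag search (e.g. ± one pulse period) would let in-band clutter
  bursts rotate into phase with the template and score up to ~0.84,
  destroying the signal/clutter contrast; a few samples absorb residual
  jitter without that pathology.
* **Rejected shots are excluded** from the 5-shot average (not counted as
  zeros); if all five are rejected the fitness is 0 and the event is
  flagged. A gated window with zero variance (possible only in noise-free
  runs with a dark mask) is treated as a rejection, not an error.
* **Five acquisitions per mask**, matching the experimental protocol.

## Genetic algorithm

Fifty masks per generation, eighty generations, each mask evaluated by five
gated acquisitions. Ranked in descending fitness; the top 2 elites are
copied unchanged; parents are drawn by linear-rank selection (weight
`pop − rank + 1`), children undergo uniform crossover with probability 0.9
and per-bit mutation whose rate decays exponentially from 0.02 to 0.002
with a 30-generation time constant. The protocol sizes are the study's;
the operator settings are ours, chosen once to converge within the
80 × 50 budget on the N = 576 / M = 7 benchmark (the decaying schedule
outperformed a flat 0.005 rate under noisy fitness in our calibration
runs; a scalar `mutation_rate` restores the flat behavior). Identical
masks are re-evaluated rather than cached — noise differs per acquisition,
as in the physical experiment.

## Enhancement accounting

Theory: binary-amplitude control of N segments over M independent modes
predicts

$$\eta = \frac{1/2 + (N-1)/2\pi}{M} \approx \frac{N}{2\pi M}.$$

Measurement: the enhancement of a run is the *noise-free* fitness of the
best mask divided by the noise-free mean fitness of 100 fresh random masks
on the same transmission matrix. The ensemble mean (rather than a single
random mask) is our fixed definition of the denominator; it is logged with
every run. Under this definition the all-on mask scores ≈ 2× the baseline
(expected intensity 2× the Bernoulli(½) mean), so "optimized beats all-on"
is a meaningful, non-trivial check.

For two-point focusing the fitness is `√(P₁ P₂)` with each Pᵢ measured in
its own disjoint gate (± 0.16 µs around each arrival; the 500 µm absorber
separation corresponds to 333 ns of flight, so the gates clear each other).
The two absorbers share one transmission matrix in this model — their
fluences are drawn from the same mode set — which is sufficient for the
gate-separation and fitness-algebra contracts but does not emulate two
independently speckled targets.

## Problem sizes and runtime

The shipped tests and the acceptance script use the study-sized protocol
where it matters (full 50 × 80 × 5 closed-loop runs for the enhancement
checks, 100–200 seeded repetitions for the SNR and correlation operating
points) and deliberately small worlds (10–24 segments, 1–2 modes, a few
generations) for structural and reproducibility checks. A full closed-loop
run is about 20 000 acquisitions and takes well under a minute per run in
this implementation.

## What the simulation does and does not show

Passing tests demonstrate that the *method* — denoise, gate, evolve —
behaves as documented under fully developed speckle with calibrated white
noise and band-overlapping clutter. They do not certify performance on
real tissue: the simulator omits acoustic propagation and attenuation,
transducer impulse response, laser pulse-energy drift (the experimental
photodiode normalization), quantization beyond an optional uniform
rounding, speckle decorrelation during the run, and any nonlinear
photoacoustic effect. The two experimental two-point enhancement values
depend on an unprinted transducer sensitivity profile across the focal
zone and are therefore exercised qualitatively (fitness algebra and gate
separation), not reproduced numerically.
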