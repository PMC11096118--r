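---
title: "Simulating and analyzing tactile discrimination training with sensory electrical stimulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and analyzing tactile discrimination training with sensory electrical stimulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sestrain)
```

`sestrain` simulates a single-session sensory-training experiment — robotic
haptic exploration of virtual gratings, a triangle discrimination test,
subthreshold whole-hand electrical stimulation — together with synthetic
EEG, and implements the analysis chain used for such studies: evoked
potentials, paired phase contrasts, Morlet time–frequency amplitude,
global field power (GFP), global map dissimilarity (GMD), and
cluster-based permutation statistics. This vignette documents the models,
the tunable parameters, the design decisions taken where the design was
genuinely open, and what the simulations can and cannot tell you about
real data.

## 1. Task and trial design

The session has four phases: 8 familiarization trials (a fixed A/B/B
triplet, 100 vs 164 m⁻¹), a 20-trial pre-intervention block, a 60-trial
intervention (three 20-trial blocks) and a 20-trial post-intervention
block. Within every 20-trial block each of the four comparison
frequencies {120, 142, 186, 208} m⁻¹ appears exactly five times (method of
constant stimuli), the triplet arrangement is drawn uniformly from the six
balanced patterns (St/Co/Co … Co/St/St), and the randomized pre block
order is reused verbatim in every intervention block and at post — so
phase effects cannot be confounded by stimulus order.

Familiarization uses a fixed odd position (position 1 by default,
configurable): its purpose in the emulated protocol is acquaintance with
the robot, not measurement, so these trials are generated but excluded
from analysis by default.

### The observer

The experimental protocol itself does not model the participant, so the
package adopts the standard Thurstonian account of the triangle test: each texture
in a triplet evokes an internal magnitude `x_i ~ N(f_i, sigma^2)` on a
perceptual scale where the mean equals the spatial frequency (only
differences matter under the equal-variance Gaussian model, so the
identity mapping is without loss of generality), and the respondent picks
the sample farthest from the midpoint of the other two. Chance performance
is 1/3 at `sigma -> Inf` and perfect discrimination at `sigma = 0`;
discriminability for a single pair is `d' = |f_Co - f_St| / sigma`.

`triangle_power()` gives the exact binomial power of the one-sided test of
p = 1/3: the discrimination probability under the alternative is an
explicit argument because the effect size that a given study assumed is
generally not recoverable; no attempt is made to reproduce any particular
published sample-size figure.

The baseline observer noise defaults to `sigma_base = 25` m⁻¹, which
puts the four comparisons at `d'` between 0.88 and 1.76 and the expected
proportion correct near 0.5 — the mid-range regime such designs aim for.
Group-by-phase sensitivity factors (`default_sigma_factors()`) multiply
`sigma_base`: sham 1.0 / 1.15 / 1.0 and stimulation 1.0 / 0.85 / 0.62
across pre / intervention / post. These were chosen once, via the triangle
psychometric function, to emulate a behavioral pattern in which the
stimulation group gains roughly +0.13 in probability correct from pre to
post while the sham group stays near baseline (slightly below it during
the intervention). They are design choices of the simulator, not measured
quantities.

### Randomness

Every stage derives its own stream from one master seed via a
deterministic hash (`schedule`, `observer`, `staircase`, per-participant
EEG streams, permutation draws), so the schedule, the behavior and the
EEG are independently reproducible and a study run is bit-reproducible
end to end.

## 2. Haptic rendering and guided exploration

Textures are lateral sinusoidal force fields `F_g = C sin(2π f y)` with
`C = 3` N, active only in texture contact. The virtual table is a
one-sided penalty `F_z = K_z (z_tbl − z) − B_z ż` below `z_tbl = 1` mm,
with `K_z = 1960` N/m and `B_z = 28` N·s/m; contact is defined by the same
branch condition `z < z_tbl`. No forces act along x, so the simulation is
planar (y, z).

Haptic guidance is the PD law
`F_hg = ÿ_R + B_hg (ẏ_R − ẏ) + K_hg (y_R − y)` with `K_hg = 300` N/m and
`B_hg = 60` N·s/m, active in contact. The feedforward term enters without
an explicit mass factor, i.e. numerically as a force for a 1 kg reference
mass; the package reproduces the law exactly as stated. The reference
trajectory is the canonical machine-design cycloid
`y_R(t) = y_0 + Δ (t/T − sin(2πt/T)/(2π))`, whose velocity and
acceleration vanish at both segment ends so consecutive sweeps join
smoothly. One trial sweeps each of the three textures once
(`sweep_duration = 1.5` s, 0.4 s transitions).

The hand/end-effector is a point mass (1 kg default) with 5 N·s/m viscous
damping representing passive arm impedance, a constant 2 N downward press
maintaining contact, and a small seeded random force (0.05 N SD) standing
in for the compliance of a passively guided arm — the simplest model in
which the PD controller exhibits realistic, non-zero tracking error.
Integration is fixed-step semi-implicit Euler at 1 kHz, the typical haptic
control rate; with the printed stiffnesses the largest eigenfrequency
(table contact, ≈ 44 rad/s) is far below the stability limit. Texture
layout is not dictated by the rendered-scene parameters, so the package
uses three equal-width regions spanning the 0.20 m table length with
0.01 m gaps (0.06 m each), all configurable.

Kinematic metrics follow the usual definitions: samples count as
*scanning* when the hand is in texture contact and `|ẏ|` exceeds the
0.01 m/s floor; scanning time and path length are averaged over the three
textures and scanning speed is the mean `|ẏ|` over qualifying samples.
When nothing qualifies the metrics are reported missing, not zero. Note
that under full guidance the kinematics are robot-dominated, so the
simulator builds no group differences into them; the behavioral effect
lives entirely in the observer.

## 3. Stimulation and threshold staircase

The stimulation waveform is a rectangular charge-balanced biphasic pulse:
cathodic phase (negative by convention, "cathode-first"), 300 µs per
phase, 10 µs interphase delay, repeated at 50 Hz; sham is the identical
protocol at 0 mA so event structure is preserved across groups. Sampling
a waveform requires `fs ≥ 1` MHz so the interphase delay is resolved; net
charge per pulse is zero up to one sample of quantization.

The sensory threshold is estimated by the three-sweep staircase: ascend
from 0 in 0.5 mA steps until first perceived; descend in 0.2 mA steps
until no longer perceived, starting one coarse step below the
first-perceived intensity (the procedure's sweep starting points are a
free choice; this one makes the estimate's error provably land in
[0, 0.1] mA for any deterministic perceiver); then ascend in 0.1 mA steps
until perceived again — that intensity is the threshold. The simulated
participant is deterministic by default (perceives iff intensity ≥ true
threshold), with an optional logistic mode for report variability. The
intervention intensity is 95 % of the estimated threshold for the
stimulation group and 0 mA for sham, and stimulation is gated to the
intervals where the hand is inside a texture and in contact
(`gate_by_contact()`). Simulated true thresholds are drawn from
N(2.80, 0.74²) mA truncated at 0.5 mA, the intensity range typical for
whole-hand stimulation.

## 4. The synthetic EEG generator

Each epoch is 62-channel data (a 64-channel extended 10–20 montage with
Fz and Oz flagged unusable, mirroring amplifiers with two known-bad
channels), sampled at 1200 Hz by default, in one of two windows: [0, 1.4] s
after the trial-start trigger or [−1.0, 0.4] s around the trial-end
trigger. An epoch is the sum of

* **1/f background**: per-channel Gaussian noise shaped in the frequency
  domain to a power spectrum `∝ f^(−noise_exponent)` (exponent 1 by
  default), spatially smoothed across the montage with a Gaussian kernel
  (width 0.30 head radii) so neighboring electrodes are correlated, and
  calibrated to `noise_scale = 8` µV RMS;
* **alpha oscillation**: one sinusoid per trial with frequency uniform in
  [8, 13] Hz and uniform random phase, amplitude
  `alpha_base × factor(group, phase, trigger)` at the topography peak,
  weighted by a Gaussian centro-parietal topography (centred between Cz
  and Pz, width 0.35 head radii) — a generic sensorimotor alpha
  distribution, since no electrode-level localization is prescribed.

Epochs are average-referenced. `alpha_base` defaults to 6 µV — alpha at
roughly the same order as the background, as on real scalp recordings.
The default effect map multiplies alpha *amplitude* (power goes as the
square): pre 1.0 everywhere; stimulation group 1.3 during and 1.5 after
the intervention; sham 1.2 during and 0.8 after. The factors encode only
the qualitative pattern the simulator is meant to emulate — both groups
up during the intervention, the stimulation group up and the sham group
down afterwards, stimulation > sham throughout — and are otherwise
arbitrary design choices.

What the generator deliberately does **not** contain: evoked (phase-locked)
components, eye/muscle/line artifacts, bad channels to interpolate,
non-stationarities, or any realistic source geometry. Passing tests on
this data therefore validates the *analysis machinery* — that the
pipeline finds the effects that are there, at the stated error rates —
not the robustness of preprocessing to real-world contamination, which is
out of scope.

## 5. Field analyses

`evoked()` averages trials; `paired_contrast()` subtracts two evoked maps
(the [1, −1] weighting of a phase and the pre baseline).

`morlet_tfr()` convolves with complex Morlet wavelets, 8–13 Hz in 1 Hz
steps, 1.5 cycles — a width chosen for temporal precision; its spectral
standard deviation is f/1.5 ≈ 5–9 Hz, so neighboring analysis frequencies
are strongly correlated and the band is best read as one smooth envelope.
Amplitude is `sqrt(re² + im²)`. Wavelets are unit-energy normalized and
truncated at ±5 temporal standard deviations; samples within half a
wavelet of the window edge have incomplete support and are flagged, and
the cluster suite excludes them from statistics. Two modes exist because
both are legitimate readings of "TFR of the average over trials":
**evoked** (transform the trial average; the default for `morlet_tfr()`)
and **induced** (transform each trial, average the amplitudes). The study
pipeline uses the induced mode: the generator's alpha has random per-trial
phase, as ongoing oscillations do, so it survives only in single-trial
amplitudes — in the trial average it cancels by √n.

`gfp()` is the per-sample standard deviation across electrodes in the
population (divide-by-N) convention, which makes GFP equal to the RMS of
the average-referenced map; the sample (N−1) convention would scale every
value by a constant ≈ 1.008 at 62 channels, so the choice is documented
rather than important. `gmd()` average-references both maps, divides each
by its instantaneous GFP and returns the per-sample RMS difference: 0 for
proportional maps, 2 for antipodal ones. Both functions re-reference
internally rather than trusting input state (idempotent and cheap);
zero-GFP samples make GMD undefined and are returned as `NA`, never 0.

The alpha band is taken as 8–13 Hz throughout (the computation-level
definition); the 8–12 Hz convention appears in the literature, and
`morlet_tfr(freqs = 8:12)` reproduces it if wanted.

### One open choice: what is "the GFP of a contrast"?

For the one-sample tests, TFR uses the per-participant *difference of
amplitude maps* (phase − pre) and GMD the per-participant dissimilarity
series GMD(phase, pre) — both direct readings. For GFP the direct reading
"GFP of the paired-contrast map" is non-negative by construction, so a
t-test against zero is trivially one-sided and would flag any noise.
The suite instead tests the *difference of GFP series*,
GFP(phase) − GFP(pre), which is a signed measure of the change in
response strength and supports clusters of either sign. This is the one
place where the package intentionally departs from the most literal
construction, for statistical interpretability.

## 6. Cluster-based permutation inference

Pointwise t statistics (one-sample on participant contrast maps;
independent two-sample with pooled variance between groups) are
thresholded strictly at the two-tailed critical value
`t_thresh = qt(1 − α/2, df)` — recomputed per analysis, 2.1788 at
α = 0.05 with df = 12, conventionally reported truncated to 2.17.
Suprathreshold cells form clusters under 1-D contiguity for series and
4-connectivity in the frequency × time plane (matching the contiguous
shaded clusters of standard TFR figures; the channel dimension is
averaged out before testing). Cluster mass is the sum of t in the
cluster; cells at exactly the threshold are excluded (strict inequality).

The null is the distribution of the **maximum absolute cluster mass** per
permutation, over both sign classes — the standard two-tailed
max-statistic construction. (Testing each sign class against its own-sign
null at α would run two level-α tests and double the family-wise error;
a null simulation during development measured exactly that, ≈ 0.10.)
Permutations are sign flips of whole participant maps (one-sample) or
group-label shuffles (two-sample); when the full permutation group is no
larger than `n_perm` (2ⁿ ≤ n_perm, or C(n, n_A) ≤ n_perm) it is
enumerated completely and p-values are exact. p-values use
`(1 + exceedances) / (1 + permutations)`, so p > 0 always and the
identity permutation is always counted (a tolerance of 1e-8 relative
absorbs floating-point differences between the observed mass and its
recomputation inside the permutation loop). Default `n_perm = 1024`, so
exact enumeration engages automatically up to n = 10 participants.

For the default two-sample threshold the degrees of freedom follow the
per-group convention `min(n_A, n_B) − 1` (this is what reproduces the
conventional 2.17 at 13 per group); the pooled `n_A + n_B − 2` convention
is available via `df_mode = "pooled"`.

`run_full_contrast_suite()` executes the full grid — within-group
int−pre and post−pre one-sample tests for each group, and between-group
two-sample tests of both contrasts (stimulation vs sham reference) — for
TFR, GFP change and GMD, for start- and end-locked epochs, and returns a
tidy table (metric, trigger, comparison, contrast, cluster, sign, mass,
p, spans, exact flag).

## 7. The end-to-end pipeline

`run_study()` chains schedule → staircase → behavior → kinematics →
EEG → features → cluster suite for every participant, processing
participants one at a time so memory stays bounded, and returns tidy
tables plus the suite results; `export_behavior_table()` emits the
long-format `ID, Group, Time, PropRes, ScanTime, PathLength, ScanSpeed`
table. Fitting the group × time mixed model itself (and its multiplicity
corrections) is intentionally left to the established mixed-model tools —
the exported table is the hand-off point.

## 8. Problem sizes used in validation

The validation suite scales the simulations to desk size; the sizes below
are the package's own choices and are stated here so they can be
reproduced or enlarged:

* **Oracle equivalence** — permutation p-values at n = 8 against the
  exhaustive 256-pattern enumeration; GFP/GMD/Morlet against naive-loop
  and direct-convolution implementations at 62 channels.
* **Type-I error** — 1000 null replicates (all alpha factors 1.0) of
  6-vs-6 participants, 3 trials per phase, 128 Hz, GFP-change contrasts,
  199 label shuffles; the family-wise rejection rate is required to sit
  within Monte-Carlo error of α = 0.05.
* **Alpha-effect recovery** — 20 replicates of 13-vs-13 participants with
  the full 20/60/20 trial structure at 100 Hz (alpha lives at 8–13 Hz, so
  a 100 Hz sampling rate preserves the band while keeping the runs
  affordable), start-locked epochs, induced TFR, 256 permutations; the
  stimulation group's intervention−pre positive alpha cluster must be
  detected at p < 0.05 in at least 80 % of replicates, and the sign
  pattern of the full grid (computed once at 20-trial phases, both
  trigger types) must match the emulated directions.

## 9. Known limitations

* The observer has no lapses, bias, learning within a block, or
  inter-individual variability beyond the group × phase factors.
* Kinematics are guidance-dominated; the simulator does not emulate the
  exploration-speed changes a training effect might produce.
* The EEG generator's alpha is a pure sinusoid per trial with a fixed
  topography; there is no 1/f slope change, no evoked response, and no
  artifact model, so preprocessing robustness is untested by design.
* GMD tested against zero is positively biased under pure noise (any two
  noisy maps differ); between-group GMD comparisons are the
  interpretable ones.
* The exact-enumeration switch makes small-n p-values deterministic, but
  their granularity is coarse (minimum p = 3/(2ⁿ + 1) for a symmetric
  one-sample effect); below ~6 participants per cell significant clusters
  are unattainable at α = 0.05.
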