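# sestrain

Simulation and analysis of robotic tactile-discrimination training with
sensory electrical stimulation (SES).

## The problem

Sensory retraining — practising fine tactile discrimination — and
subthreshold electrical stimulation of the hand are two candidate
interventions for recovering touch sensibility, e.g. after stroke. A
natural experimental design combines them: participants explore virtual
textures rendered by a haptic robot, pick the odd one of three in a
*triangle test*, and half of them receive whole-hand electrical
stimulation just below their sensory threshold while they train. EEG
recorded during the task tracks how alpha-band (8–13 Hz) activity, overall
field strength and scalp topography change from the pre-intervention
baseline through the intervention to the post-intervention phase.

`sestrain` is a desk-scale laboratory for that whole experiment. It
simulates every stage — texture rendering, robot-guided exploration, the
psychophysics, the threshold staircase, the stimulation waveform, and
multichannel EEG with the alpha structure such a study manipulates — and
implements the complete analysis chain, so that the statistical pipeline
can be validated end-to-end (oracle equivalence, type-I error control,
parameter recovery) without any recorded data. It is aimed at researchers
designing or power-analysing similar sensory-training studies, and at
anyone who wants a fully reproducible reference implementation of the
analysis stack.

## Models and statistics

**Texture rendering.** A texture of spatial frequency *f* (m⁻¹) is a
lateral sinusoidal force field `F_g = C sin(2π f y)` with `C = 3` N on a
virtual table rendered as a one-sided spring–damper
(`K_z = 1960` N/m, `B_z = 28` N·s/m). The standard stimulus is 164 m⁻¹;
comparisons are {120, 142, 186, 208} m⁻¹.

**Guided exploration.** A PD guidance force
`F_hg = ÿ_R + B_hg(ẏ_R − ẏ) + K_hg(y_R − y)` (`K_hg = 300` N/m,
`B_hg = 60` N·s/m) drives a point-mass hand model along a cycloidal
reference sweeping each texture. Scanning time, path length and scanning
speed are computed from samples in texture contact moving faster than
0.01 m/s.

**Behavior.** Responses come from a Thurstonian observer: each texture
evokes `x_i ~ N(f_i, σ²)` and the observer picks the sample farthest from
the midpoint of the other two; chance is 1/3. Exact binomial power for the
triangle test is provided (`triangle_power()`).

**Stimulation.** Charge-balanced biphasic pulses (cathode-first, 300 µs
phases, 10 µs gap, 50 Hz), a coarse-up / down / fine-up staircase
(0.5 / 0.2 / 0.1 mA) for the sensory threshold, 95 % of threshold for the
stimulation group and 0 mA sham, gated by texture contact.

**EEG analysis.** Evoked potentials and [1, −1] paired phase contrasts;
Morlet time–frequency spectral amplitude (8–13 Hz, 1 Hz steps, 1.5
cycles); global field power (GFP, the per-sample standard deviation across
electrodes); global map dissimilarity (GMD, the RMS difference of
GFP-normalized maps, 0 for proportional and 2 for antipodal maps); and
cluster-based permutation inference with the two-tailed threshold
`t_thresh = qt(1 − α/2, df)` (2.17 at α = 0.05, df = 12), sign-flip nulls
within groups, label-shuffle nulls between groups, and exact enumeration
whenever feasible.

## Worked example

```r
library(sestrain)

# one randomized 20-trial block: each comparison appears five times
blk <- generate_block(stimulus_set(), phase = "pre", seed = 1)
table(blk$f_comparison)
#> 120 142 186 208
#>   5   5   5   5

# a moderately noisy observer (sigma = 25 m^-1)
resp <- simulate_response(blk, observer_params(sigma = 25), seed = 2)
probability_correct(resp$correct)
#> [1] 0.45

triangle_power(p_alt = 0.7, n = 20, alpha = 0.05)
#> [1] 0.952

staircase_threshold(perceiver_model(2.8))   # true threshold 2.8 mA
#> [1] 2.8

t_threshold(0.05, 12, truncate = TRUE)
#> [1] 2.17
```

A full simulated study (26 participants, 20-trial phases, start-locked
epochs at 100 Hz; about a minute of compute):

```r
gen <- generator_config(n_per_group = 13, fs = 100,
                        trials_per_phase = c(pre = 20, intervention = 20,
                                             post = 20))
cfg <- study_config(seed = 1, n_per_group = 13, generator = gen,
                    kin_trials_per_phase = 1, n_perm = 512)
st  <- run_study(cfg, triggers = "start")

glance(st)
#>   n_participants n_per_group mean_threshold_mA sham_post_pre_change
#> 1             26          13              2.86               0.0346
#>   whstim_post_pre_change
#> 1                  0.146
```

The stimulation group improves its probability of correct responses by
+0.146 from pre to post while the sham group changes by +0.035, and the
mean staircase threshold (2.86 mA) sits near the simulated population
mean. The strongest alpha clusters for the stimulation group:

```r
tab <- dplyr::filter(tidy(st), metric == "tfr",
                     comparison == "within:WH-Stim")
dplyr::slice_min(dplyr::group_by(tab, contrast), p, n = 1)
#>   contrast     sign mass n_cells       p freq_min freq_max time_min time_max
#> 1  int-pre positive  156      39 0.00585        8       13     1.04     1.10
#> 2  int-pre positive  154      49 0.00585        8       13     0.77     0.85
#> 3 post-pre positive  758     216 0.00195        8       13     0.75     1.11
```

i.e. significant positive alpha-amplitude clusters during and especially
after the intervention, relative to the pre-intervention baseline —
the pattern the synthetic effect map encodes. `autoplot()` methods
visualize TFR maps, cluster results, GFP series and exploration traces;
`export_behavior_table()` writes the long-format behavioral table
(`ID, Group, Time, PropRes, ScanTime, PathLength, ScanSpeed`) ready for a
`VI ~ Group * Time + (1|ID)` mixed-model fit with external tools.

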