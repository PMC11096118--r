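Package: sestrain
Title: Simulation and Analysis of Robotic Tactile Discrimination Training
    with Sensory Electrical Stimulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates a single-session tactile discrimination study in which
    participants, physically guided by a haptic robot, explore virtual sinusoidal
    grating textures and identify the odd one in a triangle test, with or without
    subthreshold whole-hand sensory electrical stimulation. Provides the texture
    and guidance force models, a Thurstonian observer for the triangle task,
    staircase estimation of sensory thresholds, a biphasic stimulation waveform
    generator, a synthetic multichannel EEG generator with 1/f background and
    condition-dependent alpha oscillations, and the analysis chain: evoked
    potentials, paired contrasts, Morlet time-frequency spectral amplitude,
    global field power, global map dissimilarity, and cluster-based permutation
    tests with sign-flip or label-shuffle nulls.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
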