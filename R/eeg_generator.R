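#' Default alpha-amplitude effect map
#'
#' Multiplicative alpha-amplitude factors per group, phase and trigger type
#' used by the synthetic EEG generator. The pre-intervention factor is 1
#' (reference). The defaults encode the qualitative pattern of the study
#' conditions the generator emulates: the stimulation group's alpha rises
#' during the intervention and more after it, while the sham group rises
#' slightly during the intervention and falls below baseline afterwards.
#' The numeric factors are design choices of the generator, not measured
#' values.
#'
#' @return A tibble with columns `group`, `phase`, `trigger`, `factor`
#'   covering 2 groups x 3 phases x 2 trigger types.
#' @export
default_effect_map <- function() {
  grid <- tidyr::expand_grid(
    group = c("Sham", "WH-Stim"),
    phase = c("pre", "intervention", "post"),
    trigger = c("start", "end")
  )
  fac <- function(group, phase) {
    dplyr::case_when(
      phase == "pre" ~ 1.0,
      group == "WH-Stim" & phase == "intervention" ~ 1.3,
      group == "WH-Stim" & phase == "post" ~ 1.5,
      group == "Sham" & phase == "intervention" ~ 1.2,
      group == "Sham" & phase == "post" ~ 0.8
    )
  }
  dplyr::mutate(grid, factor = fac(group, phase))
}

#' Null effect map (all factors 1)
#'
#' Convenience map with every alpha factor equal to 1, for type-I-error
#' simulations.
#'
#' @return A tibble like [default_effect_map()].
#' @export
null_effect_map <- function() {
  dplyr::mutate(default_effect_map(), factor = 1.0)
}

#' Synthetic EEG generator configuration
#'
#' Defines the study conditions the generator emulates: 62 usable channels
#' sampled at 1200 Hz, epochs locked to the trial start (window 0 to 1.4 s)
#' and trial end (-1.0 to 0.4 s), 20 trials in the pre- and
#' post-intervention phases and 60 during the intervention, and a
#' centro-parietal alpha oscillation (8-13 Hz, random per-trial frequency
#' and phase) riding on spatially smoothed 1/f background noise. Alpha
#' amplitude is `alpha_base` times the effect-map factor for the epoch's
#' group/phase/trigger.
#'
#' @param n_per_group Participants per group.
#' @param fs Sampling rate (Hz); must exceed 80 Hz (twice the 40 Hz band
#'   edge of the emulated recordings).
#' @param window_start,window_end Epoch windows (s) relative to the start
#'   and end triggers.
#' @param alpha_base Baseline alpha amplitude (uV) at the topography peak.
#' @param alpha_band Range (Hz) of the per-trial alpha frequency.
#' @param noise_exponent Spectral exponent of the 1/f background (power
#'   falls as `f^-noise_exponent`).
#' @param noise_scale RMS amplitude (uV) of the background noise per
#'   channel.
#' @param trials_per_phase Named vector of trials for `pre`, `intervention`,
#'   `post`.
#' @param effect_map Alpha factor map, see [default_effect_map()].
#' @param topo_width,smooth_width Widths (normalized head radius) of the
#'   alpha topography and of the noise spatial-correlation kernel.
#' @param seed Master seed; every epoch set derives its own stream from it.
#' @return A list of class `ses_genconfig`.
#' @export
generator_config <- function(n_per_group = 13, fs = 1200,
                             window_start = c(0, 1.4),
                             window_end = c(-1.0, 0.4),
                             alpha_base = 6, alpha_band = c(8, 13),
                             noise_exponent = 1, noise_scale = 8,
                             trials_per_phase = c(pre = 20, intervention = 60,
                                                  post = 20),
                             effect_map = default_effect_map(),
                             topo_width = 0.35, smooth_width = 0.30,
                             seed = 1L) {
  check_scalar_number(n_per_group, "n_per_group", lower = 1)
  check_scalar_number(fs, "fs", lower = 80 + 1e-9)
  if (length(window_start) != 2 || diff(window_start) <= 0 ||
      length(window_end) != 2 || diff(window_end) <= 0) {
    abort("Epoch windows must be increasing length-2 vectors (s).")
  }
  check_scalar_number(alpha_base, "alpha_base", lower = 0)
  check_scalar_number(noise_scale, "noise_scale", lower = 0)
  if (!all(c("pre", "intervention", "post") %in% names(trials_per_phase))) {
    abort("`trials_per_phase` must name pre, intervention and post.")
  }
  if (!all(c("group", "phase", "trigger", "factor") %in% names(effect_map)) ||
      any(effect_map$factor <= 0)) {
    abort("`effect_map` must have positive factors for group/phase/trigger.")
  }
  structure(
    list(n_per_group = as.integer(n_per_group), fs = fs,
         window_start = window_start, window_end = window_end,
         alpha_base = alpha_base, alpha_band = alpha_band,
         noise_exponent = noise_exponent, noise_scale = noise_scale,
         trials_per_phase = trials_per_phase, effect_map = effect_map,
         topo_width = topo_width, smooth_width = smooth_width,
         seed = as.integer(seed), montage = eeg_montage()),
    class = "ses_genconfig"
  )
}

#' Participant roster implied by a generator configuration
#'
#' @param config A [generator_config()].
#' @return A tibble with `participant_id` and `group`.
#' @export
participant_roster <- function(config) {
  n <- config$n_per_group
  tibble(
    participant_id = sprintf("P%02d", seq_len(2L * n)),
    group = rep(c("Sham", "WH-Stim"), each = n)
  )
}

# 1/f-filtered Gaussian noise, one column per (trial x channel) series.
# Filtering in the frequency domain preserves determinism and the target
# spectral slope; the DC bin is zeroed.
pink_noise_matrix <- function(n_time, n_series, fs, exponent) {
  n_fft <- nextn(n_time, 2)                # power of 2 keeps the FFT fast
  white <- matrix(rnorm(n_fft * n_series), nrow = n_fft)
  spec <- mvfft(white)
  f <- c(0, seq_len(n_fft - 1)) * fs / n_fft
  f <- pmin(f, fs - f)                     # two-sided frequency axis
  gain <- c(0, f[-1]^(-exponent / 2))
  out <- Re(mvfft(spec * gain, inverse = TRUE)) / n_fft
  out[seq_len(n_time), , drop = FALSE]
}

# Generate one epoch set: trials x usable-channels x time array plus
# metadata. Internal; use generate_epochs() / generate_participant_epochs().
generate_epoch_set <- function(config, participant_id, group, phase, trigger,
                               n_trials) {
  window <- if (trigger == "start") config$window_start else config$window_end
  fs <- config$fs
  times <- seq(window[1], window[2], by = 1 / fs)
  n_time <- length(times)
  montage <- config$montage
  n_ch <- sum(montage$usable)
  w_topo <- alpha_topography(montage, config$topo_width)
  smoother <- spatial_smoother(montage, config$smooth_width)
  fac <- config$effect_map$factor[
    config$effect_map$group == group & config$effect_map$phase == phase &
      config$effect_map$trigger == trigger]
  if (length(fac) != 1) {
    abort(sprintf("Effect map has no unique entry for %s/%s/%s.",
                  group, phase, trigger))
  }
  seed <- derive_seed(config$seed, paste(participant_id, phase, trigger))
  with_seed(seed, {
    noise <- pink_noise_matrix(n_time, n_trials * n_ch, fs,
                               config$noise_exponent)
    # [time, channel, trial] -> smooth across channels, calibrate RMS
    a <- array(noise, dim = c(n_time, n_ch, n_trials))
    flat <- matrix(aperm(a, c(1, 3, 2)), ncol = n_ch)
    flat <- flat %*% t(smoother)
    rms <- sqrt(mean(flat^2))
    if (rms > 0) flat <- flat * (config$noise_scale / rms)
    a <- aperm(array(flat, dim = c(n_time, n_trials, n_ch)), c(1, 3, 2))
    freqs <- runif(n_trials, config$alpha_band[1], config$alpha_band[2])
    phases <- runif(n_trials, 0, 2 * pi)
    amp <- config$alpha_base * fac
    for (j in seq_len(n_trials)) {
      osc <- amp * sin(2 * pi * freqs[j] * times + phases[j])
      a[, , j] <- a[, , j] + outer(osc, w_topo)
    }
    # average reference per sample
    for (j in seq_len(n_trials)) {
      a[, , j] <- a[, , j] - rowMeans(a[, , j])
    }
    structure(
      list(data = aperm(a, c(3, 2, 1)),   # trials x channels x time
           fs = fs, times = times,
           channels = montage$channel[montage$usable],
           trigger = trigger, participant_id = participant_id,
           group = group, phase = phase),
      class = "ses_epochs"
    )
  })
}

#' Generate synthetic EEG epochs for one participant
#'
#' Produces the six epoch sets (3 phases x 2 trigger types) for one
#' participant. Each epoch is spatially smoothed 1/f background noise plus a
#' centro-parietal alpha oscillation whose amplitude is the baseline times
#' the effect-map factor; epochs are average-referenced. Deterministic given
#' the configuration seed.
#'
#' @param config A [generator_config()].
#' @param participant_id Participant label.
#' @param group `"Sham"` or `"WH-Stim"`.
#' @param triggers Trigger types to generate (`"start"`, `"end"`).
#' @param phases Phases to generate.
#' @return A list of `ses_epochs` objects keyed `"<phase>.<trigger>"`.
#' @export
generate_participant_epochs <- function(config, participant_id, group,
                                        triggers = c("start", "end"),
                                        phases = c("pre", "intervention",
                                                   "post")) {
  grid <- tidyr::expand_grid(phase = phases, trigger = triggers)
  sets <- purrr::pmap(grid, function(phase, trigger) {
    generate_epoch_set(config, participant_id, group, phase, trigger,
                       n_trials = config$trials_per_phase[[phase]])
  })
  names(sets) <- paste(grid$phase, grid$trigger, sep = ".")
  sets
}

#' Generate synthetic EEG epochs for a whole study
#'
#' Calls [generate_participant_epochs()] for every participant in the
#' roster. Intended for small configurations; for study-scale runs prefer
#' [run_study()], which processes participants one at a time.
#'
#' @param config A [generator_config()].
#' @return A named list (by participant id) of per-participant epoch-set
#'   lists, with the roster attached as attribute `"roster"`.
#' @export
generate_epochs <- function(config) {
  roster <- participant_roster(config)
  out <- purrr::map2(roster$participant_id, roster$group,
                     function(pid, grp) {
                       generate_participant_epochs(config, pid, grp)
                     })
  names(out) <- roster$participant_id
  attr(out, "roster") <- roster
  out
}
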