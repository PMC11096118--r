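#' Study configuration
#'
#' Bundles every parameter of an end-to-end simulated study: the trial
#' schedule, the Thurstonian observer and its group-by-phase sensitivity
#' factors, the haptic scene and guidance, the threshold staircase and the
#' stimulated-participant population, the synthetic EEG generator, and the
#' analysis settings. All randomness derives from the single master `seed`.
#'
#' The observer's noise is `sigma_base` multiplied by the group/phase
#' factor; the default factors emulate a stimulation group that improves
#' during and especially after the intervention while the sham group does
#' not (sigma below 1 means lower perceptual noise, hence better
#' discrimination).
#'
#' @param seed Master seed.
#' @param n_per_group Participants per group.
#' @param stim A [stimulus_set()].
#' @param sigma_base Baseline perceptual noise (m^-1).
#' @param sigma_factors Tibble `group`, `phase`, `factor` multiplying
#'   `sigma_base`.
#' @param scene,guidance Haptic parameters ([scene_params()],
#'   [guidance_params()]).
#' @param kin_trials_per_phase Exploration traces simulated per phase for
#'   the kinematic metrics (metrics are averaged across them).
#' @param threshold_mean,threshold_sd Population mean and SD (mA) of the
#'   simulated true sensory thresholds.
#' @param generator A [generator_config()]; its `n_per_group` and `seed`
#'   are overridden by this configuration's values.
#' @param tfr_freqs,tfr_n_cycles Morlet analysis settings.
#' @param alpha Significance level of the cluster tests.
#' @param n_perm Permutations per cluster test.
#' @return A list of class `ses_study_config`.
#' @export
study_config <- function(seed = 1L, n_per_group = 13,
                         stim = stimulus_set(),
                         sigma_base = 25,
                         sigma_factors = default_sigma_factors(),
                         scene = scene_params(),
                         guidance = guidance_params(),
                         kin_trials_per_phase = 2L,
                         threshold_mean = 2.80, threshold_sd = 0.74,
                         generator = generator_config(),
                         tfr_freqs = 8:13, tfr_n_cycles = 1.5,
                         alpha = 0.05, n_perm = 1024) {
  generator$n_per_group <- as.integer(n_per_group)
  generator$seed <- derive_seed(seed, "eeg")
  structure(
    list(seed = as.integer(seed), n_per_group = as.integer(n_per_group),
         stim = stim, sigma_base = sigma_base,
         sigma_factors = sigma_factors, scene = scene, guidance = guidance,
         kin_trials_per_phase = as.integer(kin_trials_per_phase),
         threshold_mean = threshold_mean, threshold_sd = threshold_sd,
         generator = generator, tfr_freqs = tfr_freqs,
         tfr_n_cycles = tfr_n_cycles, alpha = alpha, n_perm = n_perm),
    class = "ses_study_config"
  )
}

#' Default observer sensitivity factors
#'
#' Multipliers of the baseline perceptual noise per group and phase. They
#' encode the emulated behavioral pattern: the sham group is slightly worse
#' during the intervention and back to baseline afterwards, while the
#' stimulation group improves during the intervention and clearly after it.
#'
#' @return A tibble with columns `group`, `phase`, `factor`.
#' @export
default_sigma_factors <- function() {
  tibble(
    group = rep(c("Sham", "WH-Stim"), each = 3),
    phase = rep(c("pre", "intervention", "post"), 2),
    factor = c(1.0, 1.15, 1.0,
               1.0, 0.85, 0.62)
  )
}

sigma_for <- function(config, group, phase) {
  f <- config$sigma_factors$factor[
    config$sigma_factors$group == group &
      config$sigma_factors$phase == phase]
  if (length(f) != 1) abort(sprintf("No sigma factor for %s/%s.", group, phase))
  config$sigma_base * f
}

#' Run a full simulated study
#'
#' Executes the whole pipeline for every participant: trial schedule,
#' staircase threshold estimation and intervention intensity, triangle-test
#' responses under the group/phase observer sensitivities, guided
#' exploration traces and kinematic metrics, synthetic EEG epochs, derived
#' TFR/GFP/GMD contrasts, and the full cluster-permutation contrast grid.
#' Deterministic given the configuration.
#'
#' @param config A [study_config()].
#' @param run_kinematics Simulate exploration traces? (The slowest stage;
#'   disable when only behavior/EEG results are needed.)
#' @param run_suite Run the cluster-permutation contrast grid?
#' @param triggers Trigger types to analyze (`"start"`, `"end"`).
#' @param suite_metrics Metrics passed to [run_full_contrast_suite()].
#' @return A list of class `ses_study` with elements `config`, `roster`,
#'   `thresholds`, `behavior`, `kinematics`, `features`, `suite` (see
#'   [run_full_contrast_suite()]) and `behavior_table`.
#' @export
run_study <- function(config = study_config(), run_kinematics = TRUE,
                      run_suite = TRUE, triggers = c("start", "end"),
                      suite_metrics = c("tfr", "gfp", "gmd")) {
  roster <- participant_roster(config$generator)
  thresholds <- list(); behavior <- list(); kinematics <- list()
  features <- list()
  phases <- c("pre", "intervention", "post")
  for (i in seq_len(nrow(roster))) {
    pid <- roster$participant_id[i]
    grp <- roster$group[i]
    sched <- generate_session(config$stim,
                              seed = derive_seed(config$seed,
                                                 paste("schedule", pid)))
    true_thr <- with_seed(derive_seed(config$seed, paste("threshold", pid)),
                          max(0.5, rnorm(1, config$threshold_mean,
                                         config$threshold_sd)))
    est <- staircase_threshold(perceiver_model(true_thr),
                               seed = derive_seed(config$seed,
                                                  paste("staircase", pid)))
    thresholds[[i]] <- tibble(
      participant_id = pid, group = grp, true_threshold = true_thr,
      threshold_estimate = est,
      intervention_mA = intervention_intensity(est, grp)
    )
    for (phase in phases) {
      trials <- sched[sched$phase == phase, ]
      resp <- simulate_response(
        trials, observer_params(sigma_for(config, grp, phase)),
        seed = derive_seed(config$seed, paste("observer", pid, phase)))
      behavior[[length(behavior) + 1L]] <- tibble(
        participant_id = pid, group = grp, phase = phase,
        n_trials = nrow(resp),
        prop_correct = probability_correct(resp$correct)
      )
      if (run_kinematics && config$kin_trials_per_phase > 0) {
        mets <- purrr::map_dfr(seq_len(config$kin_trials_per_phase),
                               function(k) {
          tr <- simulate_exploration(
            trials[k, ], config$scene, config$guidance,
            seed = derive_seed(config$seed, paste("kin", pid, phase, k)))
          kinematic_metrics(tr)
        })
        kinematics[[length(kinematics) + 1L]] <- dplyr::bind_cols(
          tibble(participant_id = pid, group = grp, phase = phase),
          dplyr::summarise(mets, dplyr::across(dplyr::everything(),
                                               ~ mean(.x, na.rm = TRUE)))
        )
      }
    }
    features[[i]] <- participant_features(config$generator, pid, grp,
                                          freqs = config$tfr_freqs,
                                          n_cycles = config$tfr_n_cycles,
                                          triggers = triggers)
  }
  features <- dplyr::bind_rows(features)
  suite <- if (run_suite) {
    run_full_contrast_suite(features, alpha = config$alpha,
                            n_perm = config$n_perm,
                            seed = derive_seed(config$seed, "suite"),
                            metrics = suite_metrics)
  } else {
    NULL
  }
  out <- structure(
    list(config = config, roster = roster,
         thresholds = dplyr::bind_rows(thresholds),
         behavior = dplyr::bind_rows(behavior),
         kinematics = if (length(kinematics)) dplyr::bind_rows(kinematics)
                      else NULL,
         features = features, suite = suite),
    class = "ses_study"
  )
  out$behavior_table <- export_behavior_table(out)
  out
}

#' Tidy behavioral table for mixed-model fitting
#'
#' Long-format table with one row per participant and phase, ready for a
#' `VI ~ Group * Time + (1 | ID)` style linear mixed model fit with
#' external tooling: columns `ID`, `Group`, `Time`, `PropRes`, `ScanTime`,
#' `PathLength`, `ScanSpeed`.
#'
#' @param study A `ses_study` from [run_study()].
#' @param path Optional path; when given the table is also written as CSV.
#' @return A tibble.
#' @export
export_behavior_table <- function(study, path = NULL) {
  if (!inherits(study, "ses_study")) abort("`study` must be a `ses_study`.")
  tab <- dplyr::select(study$behavior, ID = "participant_id",
                       Group = "group", Time = "phase",
                       PropRes = "prop_correct")
  if (!is.null(study$kinematics)) {
    kin <- dplyr::select(study$kinematics, ID = "participant_id",
                         Time = "phase", ScanTime = "scanning_time",
                         PathLength = "path_length",
                         ScanSpeed = "scanning_speed")
    tab <- dplyr::left_join(tab, kin, by = c("ID", "Time"))
  } else {
    tab$ScanTime <- NA_real_
    tab$PathLength <- NA_real_
    tab$ScanSpeed <- NA_real_
  }
  if (!is.null(path)) readr::write_csv(tab, path)
  tab
}
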