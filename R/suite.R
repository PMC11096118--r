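# Per-participant derived features for the contrast suite. For each trigger
# type and each contrast phase (intervention, post) relative to pre:
#   tfr: difference of induced channel-averaged Morlet amplitude maps
#        (freq x time), with the wavelet edge mask attached;
#   gfp: difference of the GFP series of the phase and pre evoked maps;
#   gmd: GMD series between the phase and pre evoked maps.
participant_features <- function(config, participant_id, group,
                                 freqs = 8:13, n_cycles = 1.5,
                                 triggers = c("start", "end")) {
  sets <- generate_participant_epochs(config, participant_id, group,
                                      triggers = triggers)
  rows <- list()
  for (trigger in triggers) {
    ev <- list(); tf <- list()
    for (phase in c("pre", "intervention", "post")) {
      s <- sets[[paste(phase, trigger, sep = ".")]]
      ev[[phase]] <- evoked(s)
      tf[[phase]] <- morlet_tfr(s, freqs = freqs, n_cycles = n_cycles,
                                mode = "induced")
    }
    for (phase in c("intervention", "post")) {
      contrast <- if (phase == "intervention") "int-pre" else "post-pre"
      tfr_map <- tf[[phase]]$data - tf[["pre"]]$data
      attr(tfr_map, "edge") <- tf[["pre"]]$edge
      attr(tfr_map, "freqs") <- tf[["pre"]]$freqs
      attr(tfr_map, "times") <- tf[["pre"]]$times
      g_phase <- gfp(ev[[phase]])
      g_pre <- gfp(ev[["pre"]])
      gmd_series <- gmd(ev[[phase]], ev[["pre"]])
      rows[[length(rows) + 1L]] <- tibble(
        participant_id = participant_id, group = group,
        trigger = trigger, contrast = contrast,
        tfr = list(tfr_map),
        gfp = list(stats::setNames(g_phase$gfp - g_pre$gfp, NULL)),
        gmd = list(gmd_series$gmd),
        times = list(g_phase$time)
      )
    }
  }
  dplyr::bind_rows(rows)
}

#' Run the full grid of cluster-permutation contrasts
#'
#' Reproduces the study's comparison grid on derived per-participant
#' features: within-group one-sample tests of the intervention-pre and
#' post-pre contrasts (against zero) and between-group two-sample tests of
#' the same contrasts (stimulation group versus sham reference), for the
#' alpha-band TFR amplitude, the GFP change and the GMD series, separately
#' for start- and end-of-trial epochs.
#'
#' @param features Feature tibble from the pipeline (see [run_study()]):
#'   one row per participant x trigger x contrast with list-columns `tfr`,
#'   `gfp`, `gmd`, `times`.
#' @param alpha Significance level for the cluster-forming threshold
#'   (recomputed from the t quantile per test).
#' @param n_perm Permutations per test.
#' @param seed Seed for the permutation draws.
#' @param metrics Which feature metrics to test.
#' @return A list with `table` (tidy tibble: metric, trigger, comparison,
#'   contrast, cluster columns) and `results` (named list of
#'   `ses_cluster_result` objects).
#' @export
run_full_contrast_suite <- function(features, alpha = 0.05, n_perm = 1024,
                                    seed = 1L,
                                    metrics = c("tfr", "gfp", "gmd")) {
  needed <- c("participant_id", "group", "trigger", "contrast",
              metrics, "times")
  missing <- setdiff(needed, names(features))
  if (length(missing) > 0) {
    abort(paste("Features are missing columns:",
                paste(missing, collapse = ", ")))
  }
  groups <- sort(unique(features$group))
  results <- list()
  rows <- list()
  run_one <- function(metric, trigger, contrast, comparison) {
    sel <- features$trigger == trigger & features$contrast == contrast
    ff <- features[sel, ]
    maps_of <- function(grp) ff[[metric]][ff$group == grp]
    axes <- list(time = ff$times[[1]])
    exclude <- NULL
    if (metric == "tfr") {
      axes$freq <- attr(ff[[metric]][[1]], "freqs")
      axes$time <- attr(ff[[metric]][[1]], "times")
      exclude <- attr(ff[[metric]][[1]], "edge")
    }
    key <- paste(metric, trigger, comparison, contrast, sep = ".")
    res <- if (comparison == "between") {
      two_sample_cluster_perm(maps_of("WH-Stim"), maps_of("Sham"),
                              alpha = alpha, n_perm = n_perm,
                              seed = derive_seed(seed, key),
                              exclude = exclude, axes = axes)
    } else {
      one_sample_cluster_perm(maps_of(sub("within:", "", comparison)),
                              alpha = alpha, n_perm = n_perm,
                              seed = derive_seed(seed, key),
                              exclude = exclude, axes = axes)
    }
    results[[key]] <<- res
    tab <- res$clusters
    if (nrow(tab) == 0) {
      tab <- tibble(cluster = NA_integer_, sign = NA_character_,
                    mass = NA_real_, n_cells = NA_integer_, p = NA_real_)
    }
    rows[[length(rows) + 1L]] <<- dplyr::bind_cols(
      tibble(metric = metric, trigger = trigger, comparison = comparison,
             contrast = contrast, threshold = res$threshold,
             exact = res$exact),
      tab
    )
    invisible(NULL)
  }
  for (metric in metrics) {
    for (trigger in unique(features$trigger)) {
      for (contrast in c("int-pre", "post-pre")) {
        for (grp in groups) run_one(metric, trigger, contrast,
                                    paste0("within:", grp))
        if (length(groups) == 2) run_one(metric, trigger, contrast, "between")
      }
    }
  }
  list(table = dplyr::bind_rows(rows), results = results)
}
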