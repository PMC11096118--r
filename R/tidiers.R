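#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a Morlet TFR into long format
#'
#' @param x A `ses_tfr` (channel-averaged).
#' @param ... Unused.
#' @return A tibble with `freq`, `time`, `amplitude`, `edge`.
#' @method tidy ses_tfr
#' @export
tidy.ses_tfr <- function(x, ...) {
  if (!x$channel_average) {
    abort("Only channel-averaged TFRs can be tidied.")
  }
  tibble(
    freq = rep(x$freqs, times = length(x$times)),
    time = rep(x$times, each = length(x$freqs)),
    amplitude = as.vector(x$data),
    edge = as.vector(x$edge)
  )
}

#' Tidy an evoked map into long format
#'
#' @param x A `ses_evoked`.
#' @param ... Unused.
#' @return A tibble with `channel`, `time`, `amplitude`.
#' @method tidy ses_evoked
#' @export
tidy.ses_evoked <- function(x, ...) {
  tibble(
    channel = rep(x$channels, times = length(x$times)),
    time = rep(x$times, each = length(x$channels)),
    amplitude = as.vector(x$data)
  )
}

#' Tidy cluster-permutation results
#'
#' @param x A `ses_cluster_result`.
#' @param ... Unused.
#' @return The cluster tibble (one row per cluster: `sign`, `mass`,
#'   `n_cells`, `p` and domain spans).
#' @method tidy ses_cluster_result
#' @export
tidy.ses_cluster_result <- function(x, ...) {
  x$clusters
}

#' One-row summary of a cluster-permutation test
#'
#' @param x A `ses_cluster_result`.
#' @param ... Unused.
#' @return A tibble with `n_clusters`, `min_p`, `threshold`,
#'   `n_permutations`, `exact`.
#' @method glance ses_cluster_result
#' @export
glance.ses_cluster_result <- function(x, ...) {
  tibble(
    n_clusters = nrow(x$clusters),
    min_p = if (nrow(x$clusters)) min(x$clusters$p) else NA_real_,
    threshold = x$threshold,
    n_permutations = x$n_effective,
    exact = x$exact
  )
}

#' Tidy a simulated study
#'
#' @param x A `ses_study`.
#' @param ... Unused.
#' @return The cluster-contrast results table (or behavioral table when the
#'   suite was not run).
#' @method tidy ses_study
#' @export
tidy.ses_study <- function(x, ...) {
  if (!is.null(x$suite)) x$suite$table else x$behavior_table
}

#' One-row summary of a simulated study
#'
#' @param x A `ses_study`.
#' @param ... Unused.
#' @return A tibble with participant counts, mean threshold estimate and
#'   the group-wise post-minus-pre change in probability correct.
#' @method glance ses_study
#' @export
glance.ses_study <- function(x, ...) {
  chg <- x$behavior |>
    dplyr::filter(.data$phase %in% c("pre", "post")) |>
    tidyr::pivot_wider(id_cols = c("participant_id", "group"),
                       names_from = "phase",
                       values_from = "prop_correct") |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(change = mean(.data$post - .data$pre), .groups = "drop")
  tibble(
    n_participants = nrow(x$roster),
    n_per_group = x$config$n_per_group,
    mean_threshold_mA = mean(x$thresholds$threshold_estimate),
    sham_post_pre_change = chg$change[chg$group == "Sham"],
    whstim_post_pre_change = chg$change[chg$group == "WH-Stim"]
  )
}
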