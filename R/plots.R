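#' @importFrom ggplot2 autoplot ggplot aes geom_raster geom_line geom_rect
#'   geom_tile scale_fill_gradient2 labs theme_minimal facet_wrap
#' @export
ggplot2::autoplot

#' Plot a time-frequency amplitude map
#'
#' @param object A channel-averaged `ses_tfr`.
#' @param ... Unused.
#' @return A ggplot raster of spectral amplitude over time and frequency.
#' @method autoplot ses_tfr
#' @export
autoplot.ses_tfr <- function(object, ...) {
  df <- tidy(object)
  ggplot(df, aes(x = .data$time, y = .data$freq, fill = .data$amplitude)) +
    geom_raster() +
    labs(x = "Time (s)", y = "Frequency (Hz)",
         fill = "Amplitude (µV)", title = object$label) +
    theme_minimal()
}

#' Plot a GFP series
#'
#' @param object A `ses_gfp` tibble.
#' @param ... Unused.
#' @return A ggplot line plot.
#' @method autoplot ses_gfp
#' @export
autoplot.ses_gfp <- function(object, ...) {
  ggplot(object, aes(x = .data$time, y = .data$gfp)) +
    geom_line() +
    labs(x = "Time (s)", y = "GFP (µV)", title = attr(object, "label")) +
    theme_minimal()
}

#' Plot a cluster-permutation result
#'
#' Shows the t map over its domain with significant clusters (p below
#' `alpha`) outlined by shading.
#'
#' @param object A `ses_cluster_result`.
#' @param alpha Significance level used for highlighting.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ses_cluster_result
#' @export
autoplot.ses_cluster_result <- function(object, alpha = 0.05, ...) {
  dims <- object$dims
  axes <- object$axes
  sig_cells <- integer(0)
  if (nrow(object$clusters) > 0) {
    keep <- which(object$clusters$p < alpha)
    ord <- order(object$clusters$cluster)
    for (k in keep) sig_cells <- c(sig_cells, object$cells[[ord[k]]])
  }
  if (length(dims) == 1) {
    time <- if (!is.null(axes$time)) axes$time else seq_len(dims)
    df <- tibble(time = time, t = as.vector(object$t_map),
                 significant = seq_len(dims) %in% sig_cells)
    ggplot(df, aes(x = .data$time, y = .data$t)) +
      geom_line() +
      geom_line(data = df[df$significant, , drop = FALSE],
                colour = "red", linewidth = 1) +
      labs(x = "Time (s)", y = "t value") +
      theme_minimal()
  } else {
    freq <- if (!is.null(axes$freq)) axes$freq else seq_len(dims[1])
    time <- if (!is.null(axes$time)) axes$time else seq_len(dims[2])
    df <- tibble(
      freq = rep(freq, times = dims[2]),
      time = rep(time, each = dims[1]),
      t = as.vector(object$t_map),
      significant = seq_len(prod(dims)) %in% sig_cells
    )
    ggplot(df, aes(x = .data$time, y = .data$freq, fill = .data$t)) +
      geom_raster() +
      geom_tile(data = df[df$significant, , drop = FALSE],
                fill = NA, colour = "black", linewidth = 0.2) +
      scale_fill_gradient2() +
      labs(x = "Time (s)", y = "Frequency (Hz)", fill = "t") +
      theme_minimal()
  }
}

#' Plot an exploration trace
#'
#' Lateral position over time with texture regions shaded.
#'
#' @param object A `ses_trace` from [simulate_exploration()].
#' @param scene The [scene_params()] used for the simulation (for region
#'   shading).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ses_trace
#' @export
autoplot.ses_trace <- function(object, scene = scene_params(), ...) {
  regions <- scene$regions
  ggplot(object, aes(x = .data$t, y = .data$y)) +
    geom_rect(data = regions,
              aes(xmin = -Inf, xmax = Inf,
                  ymin = .data$y_min, ymax = .data$y_max),
              inherit.aes = FALSE, alpha = 0.15, fill = "steelblue") +
    geom_line() +
    labs(x = "Time (s)", y = "Lateral position y (m)") +
    theme_minimal()
}

#' Plot a stimulation waveform
#'
#' @param waveform A tibble from [stim_waveform()].
#' @return A ggplot step plot of the current over time.
#' @export
plot_waveform <- function(waveform) {
  ggplot(waveform, aes(x = .data$t * 1e3, y = .data$current_mA)) +
    geom_line() +
    labs(x = "Time (ms)", y = "Current (mA)") +
    theme_minimal()
}
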