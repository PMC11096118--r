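new_evoked <- function(data, fs, times, channels, trigger, label) {
  structure(
    list(data = data, fs = fs, times = times, channels = channels,
         trigger = trigger, label = label),
    class = "ses_evoked"
  )
}

avg_reference <- function(mat) {
  sweep(mat, 2, colMeans(mat), "-")
}

#' Evoked potential of an epoch set
#'
#' Arithmetic mean across trials for every channel and time sample.
#'
#' @param epochs A `ses_epochs` object from the generator.
#' @return A `ses_evoked` object (`data` is channels x time, uV).
#' @export
evoked <- function(epochs) {
  if (!inherits(epochs, "ses_epochs")) abort("`epochs` must be `ses_epochs`.")
  d <- epochs$data
  if (dim(d)[1] < 1) abort("Epoch set has no trials.")
  m <- colMeans(d, dims = 1)               # trials averaged out
  new_evoked(m, epochs$fs, epochs$times, epochs$channels, epochs$trigger,
             label = paste(epochs$participant_id, epochs$phase,
                           epochs$trigger, sep = "/"))
}

#' Paired contrast of two evoked maps
#'
#' Elementwise difference `a - b`, e.g. intervention minus pre-intervention
#' (the [1, -1] weighting of the two phases). Montage, sampling rate and
#' window must match.
#'
#' @param a,b `ses_evoked` objects.
#' @param label Contrast label recorded on the result.
#' @return A `ses_evoked` object.
#' @export
paired_contrast <- function(a, b, label = paste(a$label, "-", b$label)) {
  if (!inherits(a, "ses_evoked") || !inherits(b, "ses_evoked")) {
    abort("`a` and `b` must be `ses_evoked`.")
  }
  if (!identical(dim(a$data), dim(b$data)) ||
      !isTRUE(all.equal(a$fs, b$fs)) ||
      !identical(a$channels, b$channels)) {
    abort("Evoked maps do not share montage/rate/window.")
  }
  new_evoked(a$data - b$data, a$fs, a$times, a$channels, a$trigger, label)
}

#' Global field power
#'
#' Standard deviation of the voltages across all electrodes at each time
#' sample, using the population (divide by N) convention so that GFP equals
#' the root-mean-square amplitude of the average-referenced map. Maps are
#' re-average-referenced before the computation.
#'
#' @param map A `ses_evoked` object with at least two channels.
#' @return A tibble of class `ses_gfp` with columns `time` and `gfp` (uV).
#' @export
gfp <- function(map) {
  if (!inherits(map, "ses_evoked")) abort("`map` must be `ses_evoked`.")
  if (nrow(map$data) < 2) abort("GFP needs at least two channels.")
  v <- avg_reference(map$data)
  out <- tibble(time = map$times, gfp = sqrt(colMeans(v^2)))
  attr(out, "label") <- map$label
  attr(out, "fs") <- map$fs
  class(out) <- c("ses_gfp", class(out))
  out
}

#' Global map dissimilarity
#'
#' Root mean square of the difference between the two strength-normalized
#' scalp maps at each time sample: both maps are average-referenced, divided
#' by their instantaneous GFP, and the per-channel RMS of the difference is
#' returned. GMD is 0 for proportional maps and 2 for antipodal maps.
#' Samples where either map has zero GFP are returned as `NA`.
#'
#' @param a,b `ses_evoked` objects on the same montage and window.
#' @return A tibble of class `ses_gmd` with columns `time` and `gmd`.
#' @export
gmd <- function(a, b) {
  if (!inherits(a, "ses_evoked") || !inherits(b, "ses_evoked")) {
    abort("`a` and `b` must be `ses_evoked`.")
  }
  if (!identical(dim(a$data), dim(b$data)) ||
      !identical(a$channels, b$channels)) {
    abort("Maps do not share the montage/window.")
  }
  va <- avg_reference(a$data)
  vb <- avg_reference(b$data)
  ga <- sqrt(colMeans(va^2))
  gb <- sqrt(colMeans(vb^2))
  bad <- ga == 0 | gb == 0
  ga[bad] <- NA_real_
  gb[bad] <- NA_real_
  diff <- sweep(va, 2, ga, "/") - sweep(vb, 2, gb, "/")
  out <- tibble(time = a$times, gmd = sqrt(colMeans(diff^2)))
  if (any(bad)) {
    warn(sprintf("%d sample(s) with zero GFP returned as NA.", sum(bad)))
  }
  attr(out, "label") <- paste(a$label, "vs", b$label)
  attr(out, "fs") <- a$fs
  class(out) <- c("ses_gmd", class(out))
  out
}
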