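#' Build the 64-channel scalp montage
#'
#' Extended 10-20 labels with schematic 2-D positions on the unit head disc
#' (nose up, x to the right). Two channels, Fz and Oz, are marked unusable
#' (mirroring amplifier channels excluded from every analysis), leaving 62
#' usable channels.
#'
#' @param exclude Channel labels flagged as bad and dropped from generated
#'   data.
#' @return A tibble of class `ses_montage` with columns `channel`, `x`, `y`,
#'   `usable`.
#' @examples
#' m <- eeg_montage()
#' sum(m$usable)
#' @export
eeg_montage <- function(exclude = c("Fz", "Oz")) {
  rows <- list(
    list(prefix = "Fp", y = 0.80, cols = c("1", "z", "2")),
    list(prefix = "AF", y = 0.64, cols = c("7", "3", "z", "4", "8")),
    list(prefix = "F",  y = 0.48, cols = c("7", "5", "3", "1", "z", "2", "4", "6", "8")),
    list(prefix = "FC", y = 0.24, cols = c("7", "5", "3", "1", "z", "2", "4", "6", "8")),
    list(prefix = "C",  y = 0.00, cols = c("7", "5", "3", "1", "z", "2", "4", "6", "8")),
    list(prefix = "CP", y = -0.24, cols = c("7", "5", "3", "1", "z", "2", "4", "6", "8")),
    list(prefix = "P",  y = -0.48, cols = c("7", "5", "3", "1", "z", "2", "4", "6", "8")),
    list(prefix = "PO", y = -0.64, cols = c("7", "3", "z", "4", "8")),
    list(prefix = "O",  y = -0.80, cols = c("1", "z", "2")),
    list(prefix = "I",  y = -0.95, cols = c("z")),
    list(prefix = "TP", y = -0.24, cols = c("9", "10"))
  )
  col_frac <- function(col) {
    switch(col,
           "z" = 0, "1" = -0.25, "2" = 0.25, "3" = -0.5, "4" = 0.5,
           "5" = -0.75, "6" = 0.75, "7" = -1, "8" = 1,
           "9" = -1.15, "10" = 1.15)
  }
  out <- purrr::map_dfr(rows, function(r) {
    fr <- vapply(r$cols, col_frac, numeric(1))
    half_width <- 0.92 * sqrt(pmax(1 - r$y^2, 0.05))
    lab <- paste0(r$prefix, r$cols)
    # conventional names for the temporal line
    lab[lab == "C7"] <- "T7"; lab[lab == "C8"] <- "T8"
    lab[lab == "FC7"] <- "FT7"; lab[lab == "FC8"] <- "FT8"
    lab[lab == "CP7"] <- "TP7"; lab[lab == "CP8"] <- "TP8"
    tibble(channel = lab, x = fr * half_width, y = r$y)
  })
  stopifnot(nrow(out) == 64L, !anyDuplicated(out$channel))
  out$usable <- !(out$channel %in% exclude)
  class(out) <- c("ses_montage", class(out))
  out
}

# Gaussian alpha topography on the usable channels, centred between Cz and
# Pz, width in normalized head-radius units; peak weight 1.
alpha_topography <- function(montage, width = 0.35) {
  usable <- montage[montage$usable, ]
  cz <- montage[montage$channel == "Cz", ]
  pz <- montage[montage$channel == "Pz", ]
  cx <- (cz$x + pz$x) / 2
  cy <- (cz$y + pz$y) / 2
  d2 <- (usable$x - cx)^2 + (usable$y - cy)^2
  exp(-d2 / (2 * width^2))
}

# Channel-space spatial smoothing kernel (rows normalized) used to
# correlate the background noise between nearby electrodes.
spatial_smoother <- function(montage, width = 0.30) {
  usable <- montage[montage$usable, ]
  d2 <- as.matrix(dist(cbind(usable$x, usable$y)))^2
  k <- exp(-d2 / (2 * width^2))
  sweep(k, 1, rowSums(k), "/")
}
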