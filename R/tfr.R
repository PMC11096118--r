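# Complex Morlet wavelet at frequency f, unit L2 energy, truncated at
# +/- 5 temporal standard deviations. sigma_t = n_cycles / (2 pi f).
morlet_wavelet <- function(f, n_cycles, fs) {
  sigma_t <- n_cycles / (2 * pi * f)
  half <- ceiling(5 * sigma_t * fs)
  t <- seq(-half, half) / fs
  w <- exp(2i * pi * f * t) * exp(-t^2 / (2 * sigma_t^2))
  w / sqrt(sum(Mod(w)^2))
}

# FFT-based convolution of every column of `x` (time x series) with complex
# kernel `w`, returning the central (same-size) part.
fft_convolve_cols <- function(x, w) {
  n <- nrow(x)
  m <- length(w)
  nfft <- nextn(n + m - 1L, 2)
  W <- fft(c(w, rep(0, nfft - m)))
  X <- mvfft(rbind(x, matrix(0, nfft - n, ncol(x))))
  y <- mvfft(X * W, inverse = TRUE) / nfft
  half <- (m - 1L) %/% 2L
  y[(half + 1L):(half + n), , drop = FALSE]
}

#' Morlet time-frequency spectral amplitude
#'
#' Convolves the signal with complex Morlet wavelets (default 8-13 Hz in
#' 1 Hz steps, 1.5 cycles, unit-energy normalization) and returns the
#' spectral amplitude: the square root of the sum of squared real and
#' imaginary parts, in uV (up to the fixed energy-normalization factor).
#'
#' For a `ses_evoked` input the amplitude of the trial-averaged signal is
#' returned (evoked mode). For a `ses_epochs` input, `mode` selects evoked
#' (average first, then transform) or induced (transform every trial, then
#' average the single-trial amplitudes). Channel-averaged output is the
#' default; `channel_average = FALSE` retains the channel dimension.
#' Samples within half a wavelet of either window edge have incomplete
#' wavelet support and are flagged in the `edge` attribute (frequency x
#' time logical matrix).
#'
#' @param x A `ses_evoked` or `ses_epochs` object.
#' @param freqs Analysis frequencies (Hz).
#' @param n_cycles Wavelet width in cycles.
#' @param mode `"evoked"` or `"induced"` (epochs input only).
#' @param channel_average Average amplitude across channels?
#' @return A `ses_tfr` object: `data` is frequencies x time (or an array
#'   freq x channel x time when `channel_average = FALSE`), with `freqs`,
#'   `times`, `fs`, `edge` and `label` fields.
#' @export
morlet_tfr <- function(x, freqs = 8:13, n_cycles = 1.5,
                       mode = c("evoked", "induced"),
                       channel_average = TRUE) {
  mode <- match.arg(mode)
  if (inherits(x, "ses_evoked")) {
    sets <- list(t(x$data))                      # time x channels
    fs <- x$fs; times <- x$times; label <- x$label
  } else if (inherits(x, "ses_epochs")) {
    fs <- x$fs; times <- x$times
    label <- paste(x$participant_id, x$phase, x$trigger, sep = "/")
    if (mode == "evoked") {
      sets <- list(t(evoked(x)$data))
    } else {
      n_tr <- dim(x$data)[1]
      sets <- lapply(seq_len(n_tr), function(j) t(x$data[j, , ]))
    }
  } else {
    abort("`x` must be `ses_evoked` or `ses_epochs`.")
  }
  n_time <- length(times)
  n_ch <- ncol(sets[[1]])
  wavelets <- lapply(freqs, morlet_wavelet, n_cycles = n_cycles, fs = fs)
  supports <- vapply(wavelets, function(w) (length(w) - 1L) %/% 2L,
                     integer(1))
  if (any(2L * supports + 1L > n_time)) {
    abort("Window is shorter than the wavelet at the lowest frequency.")
  }
  # stack all trials as columns and FFT once; each frequency then needs a
  # single inverse transform
  big <- do.call(cbind, sets)
  m_max <- max(lengths(wavelets))
  nfft <- nextn(n_time + m_max - 1L, 2)
  X <- mvfft(rbind(big, matrix(0, nfft - n_time, ncol(big))))
  amp_sum <- array(0, dim = c(length(freqs), n_ch, n_time))
  for (k in seq_along(freqs)) {
    w <- wavelets[[k]]
    W <- fft(c(w, rep(0, nfft - length(w))))
    y <- Mod(mvfft(X * W, inverse = TRUE) / nfft)
    half <- supports[k]
    y <- y[(half + 1L):(half + n_time), , drop = FALSE]
    y <- array(y, dim = c(n_time, n_ch, length(sets)))
    amp_sum[k, , ] <- t(rowMeans(y, dims = 2))
  }
  edge <- matrix(FALSE, length(freqs), n_time)
  for (k in seq_along(freqs)) {
    h <- supports[k]
    if (h > 0) edge[k, c(seq_len(min(h, n_time)),
                         seq.int(max(1L, n_time - h + 1L), n_time))] <- TRUE
  }
  data <- if (channel_average) {
    apply(amp_sum, c(1, 3), mean)
  } else {
    amp_sum
  }
  structure(
    list(data = data, freqs = freqs, times = times, fs = fs,
         edge = edge, n_cycles = n_cycles, mode = mode,
         channel_average = channel_average, label = label),
    class = "ses_tfr"
  )
}
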