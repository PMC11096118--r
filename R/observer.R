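#' Thurstonian observer parameters
#'
#' The simulated participant perceives each texture in a triplet as a
#' Gaussian internal magnitude centred on its spatial frequency (identity
#' perceptual scale) with standard deviation `sigma`; only differences on the
#' scale matter, so the unit of `sigma` is m^-1. `sigma = 0` is a noiseless
#' observer, large `sigma` approaches guessing (probability correct 1/3).
#'
#' @param sigma Perceptual noise standard deviation (m^-1), `>= 0`.
#' @return A list of class `ses_observer`.
#' @export
observer_params <- function(sigma = 25) {
  check_scalar_number(sigma, "sigma", lower = 0)
  structure(list(sigma = sigma), class = "ses_observer")
}

# Triplet frequencies implied by an arrangement string such as "St/Co/Co".
triplet_frequencies <- function(arrangement, f_standard, f_comparison) {
  parts <- strsplit(arrangement, "/", fixed = TRUE)
  t(mapply(function(p, fs, fc) ifelse(p %in% c("St", "B"), fs, fc),
           parts, f_standard, f_comparison))
}

#' Simulate triangle-test responses for a schedule of trials
#'
#' For each trial the observer draws three perceived magnitudes
#' `x_i ~ Normal(f_i, sigma^2)` and picks the position whose value is
#' farthest from the midpoint of the other two (the Thurstonian triangle
#' decision rule). The response is correct when the picked position is the
#' odd one.
#'
#' @param trials A tibble of trials as produced by [generate_block()] or
#'   [generate_session()] (columns `arrangement`, `odd_position`,
#'   `f_standard`, `f_comparison`).
#' @param observer An [observer_params()] object.
#' @param seed Integer seed for the perceptual noise.
#' @return The input tibble with added columns `selected` (position 1-3) and
#'   `correct` (0/1).
#' @examples
#' blk <- generate_block(seed = 1)
#' resp <- simulate_response(blk, observer_params(sigma = 25), seed = 2)
#' mean(resp$correct)
#' @export
simulate_response <- function(trials, observer = observer_params(), seed = 1L) {
  if (!all(c("arrangement", "odd_position", "f_standard", "f_comparison")
           %in% names(trials))) {
    abort("`trials` must contain arrangement, odd_position, f_standard, f_comparison.")
  }
  fam <- trials$arrangement == "A/B/B"
  arrangement <- ifelse(fam, "Co/St/St", trials$arrangement)
  arrangement <- ifelse(fam & trials$odd_position == 2L, "St/Co/St", arrangement)
  arrangement <- ifelse(fam & trials$odd_position == 3L, "St/St/Co", arrangement)
  f <- triplet_frequencies(arrangement, trials$f_standard, trials$f_comparison)
  n <- nrow(trials)
  x <- with_seed(seed, f + observer$sigma * matrix(rnorm(3L * n), nrow = n))
  # distance of each sample from the midpoint of the other two
  d <- cbind(abs(x[, 1] - (x[, 2] + x[, 3]) / 2),
             abs(x[, 2] - (x[, 1] + x[, 3]) / 2),
             abs(x[, 3] - (x[, 1] + x[, 2]) / 2))
  selected <- max.col(d, ties.method = "first")
  dplyr::mutate(trials,
                selected = selected,
                correct = as.integer(selected == .data$odd_position))
}

#' Probability of correct responses
#'
#' The task-performance measure: the number of correct responses in a block
#' divided by the number of trials.
#'
#' @param correct A vector of 0/1 correctness indicators (or a logical
#'   vector).
#' @return Proportion correct in `[0, 1]`.
#' @export
probability_correct <- function(correct) {
  if (length(correct) == 0) abort("`correct` must be non-empty.")
  if (!all(correct %in% c(0, 1))) abort("`correct` must contain only 0/1.")
  mean(correct)
}

#' Exact binomial power of the triangle test
#'
#' Power of the one-sided exact binomial test of H0: p = 1/3 (guessing in
#' the triangle test) against a discrimination probability `p_alt`, at `n`
#' trials and significance level `alpha`. The critical count `k` is the
#' smallest count with `P(X >= k | n, 1/3) <= alpha`; power is
#' `P(X >= k | n, p_alt)`.
#'
#' @param p_alt Discrimination probability under the alternative, in
#'   `[1/3, 1]`.
#' @param n Number of trials.
#' @param alpha Type-I error level.
#' @return Power in `[0, 1]` (0 when no critical value is attainable).
#' @examples
#' triangle_power(p_alt = 0.7, n = 20, alpha = 0.05)
#' @export
triangle_power <- function(p_alt, n, alpha = 0.05) {
  check_scalar_number(p_alt, "p_alt", lower = 1 / 3, upper = 1)
  check_scalar_number(n, "n", lower = 1)
  check_scalar_number(alpha, "alpha", lower = 1e-12, upper = 1 - 1e-12)
  n <- as.integer(n)
  k <- seq.int(0L, n)
  p_ge <- pbinom(k - 1L, n, 1 / 3, lower.tail = FALSE)
  ok <- which(p_ge <= alpha)
  if (length(ok) == 0) return(0)
  k_crit <- k[ok[1]]
  pbinom(k_crit - 1L, n, p_alt, lower.tail = FALSE)
}
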