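#' Stimulus set for the rendered textures
#'
#' The discrimination task uses a fixed standard grating and four comparison
#' gratings that differ in spatial frequency (the inverse of the distance
#' between two adjacent crests). The default set keeps the standard at
#' 164 m^-1 with comparisons at 120, 142, 186 and 208 m^-1, i.e. two coarser
#' and two finer textures.
#'
#' @param f_standard Spatial frequency of the standard stimulus (m^-1).
#' @param f_comparisons Spatial frequencies of the comparison stimuli (m^-1).
#' @return A list of class `ses_stimulus_set` with elements `f_standard` and
#'   `f_comparisons`.
#' @examples
#' stimulus_set()
#' @export
stimulus_set <- function(f_standard = 164,
                         f_comparisons = c(120, 142, 186, 208)) {
  check_scalar_number(f_standard, "f_standard", lower = 1e-9)
  if (!is.numeric(f_comparisons) || any(f_comparisons <= 0)) {
    abort("`f_comparisons` must be positive spatial frequencies (m^-1).")
  }
  if (anyDuplicated(f_comparisons)) {
    abort("`f_comparisons` must be distinct.")
  }
  if (f_standard %in% f_comparisons) {
    abort("`f_standard` must not appear among `f_comparisons`.")
  }
  structure(
    list(f_standard = f_standard, f_comparisons = as.numeric(f_comparisons)),
    class = "ses_stimulus_set"
  )
}

# The six balanced triplet patterns and the position of the odd texture in
# each: in St-minority patterns the standard is odd, in Co-minority patterns
# the comparison is odd.
triplet_arrangements <- function() {
  tibble(
    arrangement = c("St/Co/Co", "Co/St/Co", "Co/Co/St",
                    "St/St/Co", "St/Co/St", "Co/St/St"),
    odd_position = c(1L, 2L, 3L, 3L, 2L, 1L)
  )
}

#' Generate one randomized 20-trial block of triangle-test trials
#'
#' Each block presents every comparison frequency exactly five times, in a
#' random order (method of constant stimuli), with the triplet arrangement
#' drawn uniformly from the six balanced patterns St/Co/Co, Co/St/Co,
#' Co/Co/St, St/St/Co, St/Co/St and Co/St/St.
#'
#' @param stim A [stimulus_set()]; must contain exactly four comparison
#'   frequencies.
#' @param phase Phase label attached to the trials (e.g. `"pre"`).
#' @param seed Integer seed; the same seed reproduces the same block.
#' @return A tibble with 20 rows and columns `trial`, `phase`, `block`,
#'   `arrangement`, `odd_position`, `f_standard`, `f_comparison`.
#' @examples
#' blk <- generate_block(stimulus_set(), phase = "pre", seed = 1)
#' table(blk$f_comparison)
#' @export
generate_block <- function(stim = stimulus_set(), phase = "pre", seed = 1L) {
  if (!inherits(stim, "ses_stimulus_set")) {
    abort("`stim` must be created with `stimulus_set()`.")
  }
  if (length(stim$f_comparisons) != 4) {
    abort("`generate_block()` requires exactly 4 comparison frequencies.")
  }
  arr <- triplet_arrangements()
  with_seed(seed, {
    f_co <- sample(rep(stim$f_comparisons, each = 5L))
    idx <- sample.int(6L, size = 20L, replace = TRUE)
    tibble(
      trial = seq_len(20L),
      phase = phase,
      block = 1L,
      arrangement = arr$arrangement[idx],
      odd_position = arr$odd_position[idx],
      f_standard = stim$f_standard,
      f_comparison = f_co
    )
  })
}

#' Generate a full single-session trial schedule
#'
#' The session comprises 8 familiarization trials (always the same A/B/B
#' triplet with `f_A` = 100 m^-1 and `f_B` = 164 m^-1, odd texture at a fixed
#' position), a 20-trial pre-intervention block whose randomized order is
#' drawn once, three 20-trial intervention blocks and one post-intervention
#' block that all repeat the pre-intervention order exactly.
#'
#' @param stim A [stimulus_set()].
#' @param seed Integer master seed for the schedule randomization.
#' @param f_familiar_odd,f_familiar_pair Spatial frequencies (m^-1) of the odd
#'   and repeated familiarization textures.
#' @param familiar_odd_position Position (1-3) of the odd texture during
#'   familiarization; fixed across the 8 trials.
#' @return A tibble with one row per trial (8 + 20 + 60 + 20 = 108) and
#'   columns as in [generate_block()] plus a session-wide `trial` index.
#' @examples
#' sched <- generate_session(seed = 42)
#' table(sched$phase)
#' @export
generate_session <- function(stim = stimulus_set(), seed = 1L,
                             f_familiar_odd = 100, f_familiar_pair = 164,
                             familiar_odd_position = 1L) {
  fam <- tibble(
    trial = seq_len(8L),
    phase = "familiarization",
    block = 1L,
    arrangement = "A/B/B",
    odd_position = as.integer(familiar_odd_position),
    f_standard = f_familiar_pair,
    f_comparison = f_familiar_odd
  )
  base <- generate_block(stim, phase = "pre", seed = derive_seed(seed, "schedule"))
  blocks <- list(fam, base)
  for (b in 1:3) {
    blocks[[length(blocks) + 1L]] <-
      dplyr::mutate(base, phase = "intervention", block = as.integer(b))
  }
  blocks[[length(blocks) + 1L]] <- dplyr::mutate(base, phase = "post")
  out <- dplyr::bind_rows(blocks)
  out$trial <- seq_len(nrow(out))
  out
}
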