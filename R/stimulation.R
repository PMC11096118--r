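#' Electrical stimulation protocol
#'
#' Rectangular charge-balanced biphasic pulses, cathode-first, delivered at a
#' fixed train rate. Defaults: 50 Hz, 300 us phase width, 10 us interphase
#' delay.
#'
#' @param rate Pulse train rate (Hz).
#' @param phase_width Duration of each rectangular phase (s).
#' @param interphase_delay Gap between the cathodic and anodic phase (s).
#' @param intensity Pulse amplitude (mA), `>= 0`.
#' @return A list of class `ses_protocol`.
#' @export
stim_protocol <- function(rate = 50, phase_width = 300e-6,
                          interphase_delay = 10e-6, intensity = 1) {
  check_scalar_number(rate, "rate", lower = 1e-9)
  check_scalar_number(phase_width, "phase_width", lower = 1e-9)
  check_scalar_number(interphase_delay, "interphase_delay", lower = 0)
  check_scalar_number(intensity, "intensity", lower = 0)
  if (2 * phase_width + interphase_delay >= 1 / rate) {
    abort("Pulse (two phases + delay) must fit within one train period.")
  }
  structure(
    list(rate = rate, phase_width = phase_width,
         interphase_delay = interphase_delay, polarity = "cathode_first",
         intensity = intensity),
    class = "ses_protocol"
  )
}

#' Sampled biphasic stimulation waveform
#'
#' Each pulse is `-intensity` for one phase width (cathodic first), zero for
#' the interphase delay, then `+intensity` for one phase width; pulses repeat
#' at the train rate and the current is zero elsewhere. The sampling rate
#' must resolve the interphase delay.
#'
#' @param protocol A [stim_protocol()].
#' @param duration Waveform duration (s).
#' @param fs Sampling rate (Hz), `>= 1e6` to resolve the 10 us delay.
#' @return A tibble with columns `t` (s) and `current_mA`.
#' @export
stim_waveform <- function(protocol = stim_protocol(), duration = 0.1,
                          fs = 1e6) {
  check_scalar_number(duration, "duration", lower = 1e-9)
  if (fs < 1e6) {
    abort("`fs` must be at least 1e6 Hz to resolve the interphase delay.")
  }
  t <- seq(0, duration - 1 / fs, by = 1 / fs)
  phase_t <- t %% (1 / protocol$rate)
  pw <- protocol$phase_width
  ipd <- protocol$interphase_delay
  current <- numeric(length(t))
  current[phase_t < pw] <- -protocol$intensity
  current[phase_t >= pw + ipd & phase_t < 2 * pw + ipd] <- protocol$intensity
  tibble(t = t, current_mA = current)
}

#' Staircase configuration for sensory threshold estimation
#'
#' Three manual sweeps: coarse ascending (0.5 mA steps) until first
#' perceived, descending (0.2 mA steps) until no longer perceived, fine
#' ascending (0.1 mA steps) until perceived again; that intensity is the
#' sensory threshold.
#'
#' @param up_coarse,down_step,up_fine Step sizes (mA).
#' @param start Starting intensity of the coarse sweep (mA).
#' @return A list of class `ses_staircase`.
#' @export
staircase_config <- function(up_coarse = 0.5, down_step = 0.2,
                             up_fine = 0.1, start = 0) {
  if (!(up_fine <= down_step && down_step <= up_coarse)) {
    abort("Steps must satisfy up_fine <= down_step <= up_coarse.")
  }
  structure(
    list(up_coarse = up_coarse, down_step = down_step,
         up_fine = up_fine, start = start),
    class = "ses_staircase"
  )
}

#' Simulated participant report model for threshold probing
#'
#' Deterministic mode reports "perceived" iff the probe intensity is at or
#' above the true threshold; logistic mode reports with probability
#' `plogis(slope * (intensity - true_threshold))`.
#'
#' @param true_threshold True sensory threshold (mA), `> 0`.
#' @param slope Psychometric steepness (mA^-1); `Inf` for deterministic.
#' @return A list of class `ses_perceiver`.
#' @export
perceiver_model <- function(true_threshold, slope = Inf) {
  check_scalar_number(true_threshold, "true_threshold", lower = 1e-12)
  structure(list(true_threshold = true_threshold, slope = slope),
            class = "ses_perceiver")
}

perceives <- function(perceiver, intensity) {
  if (is.infinite(perceiver$slope)) {
    intensity >= perceiver$true_threshold
  } else {
    runif(1) < stats::plogis(perceiver$slope *
                               (intensity - perceiver$true_threshold))
  }
}

#' Staircase estimate of the sensory threshold
#'
#' Runs the three-sweep procedure against a [perceiver_model()]: coarse
#' ascending steps until the stimulation is first perceived, then descending
#' steps (starting one coarse step below the first-perceived intensity)
#' until no longer perceived, then fine ascending steps until perceived
#' again. Returns the final perceived intensity.
#'
#' @param perceiver A [perceiver_model()].
#' @param config A [staircase_config()].
#' @param seed Seed for a stochastic (logistic) perceiver.
#' @param max_probes Abort after this many probes (pathological perceiver).
#' @return Threshold estimate (mA).
#' @examples
#' staircase_threshold(perceiver_model(2.8))
#' @export
staircase_threshold <- function(perceiver, config = staircase_config(),
                                seed = 1L, max_probes = 1000L) {
  with_seed(seed, {
    probes <- 0L
    probe <- function(i) {
      probes <<- probes + 1L
      if (probes > max_probes) {
        abort("Staircase did not converge within `max_probes` probes.")
      }
      perceives(perceiver, i)
    }
    i <- config$start
    while (!probe(i)) i <- i + config$up_coarse
    first_perceived <- i
    i <- max(first_perceived - config$up_coarse, 0)
    while (i > 0 && probe(i)) i <- i - config$down_step
    i <- max(i, 0)
    repeat {
      i <- i + config$up_fine
      if (probe(i)) break
    }
    i
  })
}

#' Stimulation intensity used during the intervention
#'
#' 95% of the individual sensory threshold for the stimulation group,
#' 0 mA for the sham group.
#'
#' @param threshold Sensory threshold (mA), `>= 0`.
#' @param group `"WH-Stim"` or `"Sham"`.
#' @return Intensity in mA.
#' @examples
#' intervention_intensity(2.80, "WH-Stim")
#' @export
intervention_intensity <- function(threshold, group = c("WH-Stim", "Sham")) {
  check_scalar_number(threshold, "threshold", lower = 0)
  group <- match.arg(group)
  if (group == "Sham") 0 else 0.95 * threshold
}

#' Stimulation-on intervals gated by texture contact
#'
#' Stimulation is delivered only while the hand is in contact with the table
#' and inside one of the three texture regions; this returns those intervals
#' from an exploration trace.
#'
#' @param trace A trace from [simulate_exploration()].
#' @return A tibble with columns `t_on`, `t_off` (s), one row per interval;
#'   zero rows when the trace never touches a texture.
#' @export
gate_by_contact <- function(trace) {
  if (!all(c("t", "in_contact", "region") %in% names(trace))) {
    abort("`trace` must have columns t, in_contact, region.")
  }
  on <- trace$in_contact & !is.na(trace$region)
  if (!any(on)) return(tibble(t_on = numeric(0), t_off = numeric(0)))
  r <- rle(on)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  tibble(t_on = trace$t[starts[keep]], t_off = trace$t[ends[keep]])
}
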