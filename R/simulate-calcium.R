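#' Parameters for the calcium-trace simulator
#'
#' Defaults emulate labellar bitter stimulation of second-order projection
#' neurons: a ~0.7 dF/F ON transient at stimulus onset, a ~0.4 dF/F OFF
#' transient at offset, and much stronger trial-to-trial habituation of the
#' ON than the OFF component.
#'
#' @param frame_rate imaging frame rate, frames/s (default 6.5, typical of
#'   repeated-stimulation two-photon scanning).
#' @param baseline_f baseline fluorescence, arbitrary units (> 0).
#' @param on_amplitude ON transient amplitude, dF/F fraction.
#' @param off_amplitude OFF transient amplitude, dF/F fraction.
#' @param decay_tau exponential decay time constant of transients, s.
#' @param habituation_factor_on,habituation_factor_off per-trial
#'   multiplicative amplitude decrements, in `(0, 1]`.
#' @param noise_sd per-frame fluorescence noise, as a fraction of baseline.
#' @param seed integer seed.
#' @return Validated list of class `"CalciumSimParams"`.
#' @export
calciumSimParams <- function(frame_rate = 6.5, baseline_f = 100,
                             on_amplitude = 0.7, off_amplitude = 0.4,
                             decay_tau = 1.5, habituation_factor_on = 0.6,
                             habituation_factor_off = 0.9, noise_sd = 0.02,
                             seed = 1L) {
  if (baseline_f <= 0) stop("baseline_f must be positive", call. = FALSE)
  if (on_amplitude < 0 || off_amplitude < 0)
    stop("amplitudes must be >= 0", call. = FALSE)
  if (habituation_factor_on <= 0 || habituation_factor_on > 1 ||
        habituation_factor_off <= 0 || habituation_factor_off > 1)
    stop("habituation factors must be in (0, 1]", call. = FALSE)
  if (frame_rate <= 0) stop("frame_rate must be positive", call. = FALSE)
  structure(list(frame_rate = frame_rate, baseline_f = baseline_f,
                 on_amplitude = on_amplitude, off_amplitude = off_amplitude,
                 decay_tau = decay_tau,
                 habituation_factor_on = habituation_factor_on,
                 habituation_factor_off = habituation_factor_off,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "CalciumSimParams")
}

#' Simulate a series of repeated-stimulation calcium trials
#'
#' Each trial carries an ON transient starting at stimulus onset and an OFF
#' transient starting just after stimulus offset; trial `k` is scaled by
#' `habituation_factor^(k-1)` per component. Transients hold their peak for
#' 3 frames before decaying exponentially with `decay_tau`, and the residual
#' ON level is held constant over the frames bracketing stimulus offset, so
#' that the 3-frame moving-average peak statistic and the offset-referenced
#' OFF measurement used by [onOffAmplitudes()] both return the planted
#' amplitudes exactly in the noise-free case.
#'
#' @param params a [calciumSimParams()] list.
#' @param n_trials number of repeated stimulations.
#' @param stim_onset stimulus onset time, s; must leave at least 20
#'   pre-stimulus frames.
#' @param stim_duration stimulus duration, s (default 5).
#' @param post_duration recorded time after stimulus offset, s (default 8).
#' @return list with `traces` (list of [CalciumTrace-class]) and
#'   `groundTruth` (planted per-trial ON/OFF amplitudes, seed).
#' @export
#' @examples
#' sim <- simulateCalciumTrials(calciumSimParams(noise_sd = 0), n_trials = 3,
#'                              stim_onset = 5)
#' max(dff(sim$traces[[1]]))
simulateCalciumTrials <- function(params, n_trials = 3L, stim_onset = 5,
                                  stim_duration = 5, post_duration = 8) {
  if (!inherits(params, "CalciumSimParams"))
    params <- do.call(calciumSimParams, as.list(params))
  fr <- params$frame_rate
  onset_frame <- as.integer(floor(stim_onset * fr)) + 1L
  if (onset_frame < 21L)
    stop("stim_onset must leave at least 20 pre-stimulus frames",
         call. = FALSE)
  n_frames <- as.integer(ceiling((stim_onset + stim_duration +
                                    post_duration) * fr))
  offset_frame <- onset_frame + as.integer(round(stim_duration * fr))
  if (offset_frame + 3L > n_frames)
    stop("trace too short for stimulus and OFF transient", call. = FALSE)

  ## ON: peak held 3 frames, exponential decay, residual held constant from
  ## 2 frames before offset onward (so the offset-referenced OFF measurement
  ## sees a flat pre-offset level).
  onComponent <- function(amp) {
    d <- numeric(n_frames)
    if (amp == 0) return(d)
    hold_end <- min(onset_frame + 2L, n_frames)
    d[onset_frame:hold_end] <- amp
    plateau_start <- max(offset_frame - 2L, hold_end + 1L)
    if (plateau_start > hold_end + 1L) {
      idx <- (hold_end + 1L):(plateau_start - 1L)
      d[idx] <- amp * exp(-((idx - hold_end) / fr) / params$decay_tau)
    }
    if (plateau_start <= n_frames) {
      vstar <- amp * exp(-((plateau_start - hold_end) / fr) /
                           params$decay_tau)
      d[plateau_start:n_frames] <- vstar
    }
    d
  }
  ## OFF: rises the frame after offset, held 3 frames, exponential decay.
  offComponent <- function(amp) {
    d <- numeric(n_frames)
    if (amp == 0) return(d)
    start <- offset_frame + 1L
    hold_end <- min(start + 2L, n_frames)
    d[start:hold_end] <- amp
    if (hold_end < n_frames) {
      idx <- (hold_end + 1L):n_frames
      d[idx] <- amp * exp(-((idx - hold_end) / fr) / params$decay_tau)
    }
    d
  }

  on_amps <- params$on_amplitude *
    params$habituation_factor_on^(seq_len(n_trials) - 1L)
  off_amps <- params$off_amplitude *
    params$habituation_factor_off^(seq_len(n_trials) - 1L)

  traces <- withSeed(params$seed, {
    lapply(seq_len(n_trials), function(k) {
      d <- onComponent(on_amps[k]) + offComponent(off_amps[k])
      f <- params$baseline_f * (1 + d)
      if (params$noise_sd > 0)
        f <- f + stats::rnorm(n_frames, 0,
                              params$noise_sd * params$baseline_f)
      methods::new("CalciumTrace", f = f, frameRate = fr,
                   stimOnsetFrame = onset_frame,
                   stimDuration = stim_duration, trialIndex = k)
    })
  })

  gt <- list(kind = "calcium", seed = params$seed,
             on_amplitudes = on_amps, off_amplitudes = off_amps,
             habituation_factor_on = params$habituation_factor_on,
             habituation_factor_off = params$habituation_factor_off)
  list(traces = traces, groundTruth = gt)
}
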