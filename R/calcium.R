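## deltaF/F computation and ON/OFF response metrics for calcium traces.

#' Construct a calcium trace
#'
#' @param f numeric per-frame ROI-mean fluorescence.
#' @param frameRate frames per second.
#' @param stimOnsetFrame 1-based stimulus onset frame (>= 21 so that 20
#'   baseline frames precede it).
#' @param stimDuration stimulus duration, s (default 5).
#' @param trialIndex 1-based trial index within a repeated series.
#' @return A [CalciumTrace-class].
#' @export
calciumTrace <- function(f, frameRate, stimOnsetFrame, stimDuration = 5,
                         trialIndex = 1L) {
  methods::new("CalciumTrace", f = as.numeric(f), frameRate = frameRate,
               stimOnsetFrame = as.integer(stimOnsetFrame),
               stimDuration = stimDuration,
               trialIndex = as.integer(trialIndex))
}

#' deltaF/F series of a calcium trace
#'
#' The baseline B is the mean fluorescence over the 20 frames preceding
#' stimulus onset; each frame's deltaF/F is `(f - B) / B`. By construction
#' the baseline-window mean of the result is zero, and the series is
#' invariant to rescaling of `f`.
#'
#' @param trace a [CalciumTrace-class].
#' @return numeric deltaF/F series, same length as the trace.
#' @export
#' @examples
#' tr <- calciumTrace(c(rep(100, 25), rep(150, 5)), 5, 26L, stimDuration = 1)
#' dff(tr)[26]  # 0.5
dff <- function(trace) {
  stopifnot(is(trace, "CalciumTrace"))
  f <- fluorescence(trace)
  onset <- stimOnsetFrame(trace)
  B <- mean(f[(onset - 20L):(onset - 1L)])
  if (!is.finite(B) || B <= 0)
    stop("baseline fluorescence must be positive", call. = FALSE)
  (f - B) / B
}

#' ON and OFF response amplitudes
#'
#' ON amplitude is the peak deltaF/F in the stimulus window
#' `[onset, onset + stim_duration]`; OFF amplitude is the peak in the
#' post-offset window `(offset, offset + off_window]` referenced to the
#' deltaF/F level at offset and floored at zero, so that a sustained ON
#' plateau does not register as an OFF transient. Peaks are taken on a
#' 3-frame moving average of the deltaF/F series to suppress single-frame
#' noise; the offset reference is the mean of the 3 raw frames ending at
#' offset.
#'
#' @param trace a [CalciumTrace-class]; must extend at least `off_window`
#'   seconds past stimulus offset.
#' @param off_window post-offset window length, s (default 5).
#' @return data.frame with one row: `trial_index`, `on_amplitude`,
#'   `off_amplitude`.
#' @export
onOffAmplitudes <- function(trace, off_window = 5) {
  stopifnot(is(trace, "CalciumTrace"))
  d <- dff(trace)
  fr <- frameRate(trace)
  onset <- stimOnsetFrame(trace)
  offset <- onset + as.integer(round(stimDuration(trace) * fr))
  off_end <- offset + as.integer(round(off_window * fr))
  if (off_end > length(d))
    stop("trace must extend past the post-offset window", call. = FALSE)
  sm <- movingAverage(d, 3L)
  on_amp <- max(sm[onset:offset])
  ref <- mean(d[(offset - 2L):offset])
  off_amp <- max(0, max(sm[(offset + 1L):off_end]) - ref)
  data.frame(trial_index = trialIndex(trace), on_amplitude = on_amp,
             off_amplitude = off_amp)
}

#' Habituation profile across repeated stimulations
#'
#' Normalizes per-trial ON and OFF amplitudes to the first trial and reports
#' the decay sequences plus the final-to-first ratio per component. A zero
#' first-trial amplitude makes that component's profile undefined (`NA`).
#'
#' @param metrics data.frame with columns `trial_index`, `on_amplitude`,
#'   `off_amplitude` (e.g. rbind of [onOffAmplitudes()] rows), or a list of
#'   such one-row data.frames; at least 2 trials, in stimulation order.
#' @return list with `on`, `off` (normalized amplitude vectors),
#'   `on_final_ratio`, `off_final_ratio`.
#' @export
habituationProfile <- function(metrics) {
  if (is.list(metrics) && !is.data.frame(metrics))
    metrics <- do.call(rbind, metrics)
  metrics <- metrics[order(metrics$trial_index), , drop = FALSE]
  if (nrow(metrics) < 2L)
    stop("habituation profile requires at least 2 trials", call. = FALSE)
  normTo1 <- function(x) if (x[1] == 0) rep(NA_real_, length(x)) else x / x[1]
  on <- normTo1(metrics$on_amplitude)
  off <- normTo1(metrics$off_amplitude)
  list(on = on, off = off,
       on_final_ratio = on[length(on)],
       off_final_ratio = off[length(off)])
}
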