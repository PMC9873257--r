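#' Construct a stimulation protocol
#'
#' Builds a [StimulusProtocol-class] from an epoch table. Epochs of the same
#' kind must not overlap; all epochs must lie inside the session.
#'
#' @param epochs data.frame with columns `start`, `end` (s), `kind`
#'   (`"light"`/`"odor"`), `intensity` (character; uW/mm2 for light, odor id
#'   for odor), `quadrants` (comma-separated `"Q1".."Q4"` subset or `"ALL"`),
#'   `pulse` (`"continuous"` or `"pulsed:<freq>"`). Missing `intensity`,
#'   `quadrants` or `pulse` columns are filled with defaults (`""`, `"ALL"`,
#'   `"continuous"`).
#' @param sessionLength session duration in seconds.
#' @return A [StimulusProtocol-class] object.
#' @export
#' @examples
#' stimulusProtocol(data.frame(start = 10, end = 15, kind = "light"),
#'                  sessionLength = 60)
stimulusProtocol <- function(epochs, sessionLength) {
  epochs <- as.data.frame(epochs)
  if (is.null(epochs$intensity)) epochs$intensity <- ""
  if (is.null(epochs$quadrants)) epochs$quadrants <- "ALL"
  if (is.null(epochs$pulse)) epochs$pulse <- "continuous"
  epochs$intensity <- as.character(epochs$intensity)
  epochs$quadrants <- as.character(epochs$quadrants)
  epochs$pulse <- as.character(epochs$pulse)
  methods::new("StimulusProtocol", epochs = epochs,
               sessionLength = as.numeric(sessionLength))
}

#' Single 5-s light pulse protocol
#'
#' Convenience constructor for the locomotor assay protocol: one full-arena
#' light epoch (default 5 s) with a pre-stimulus baseline and post-stimulus
#' observation period.
#'
#' @param onset light onset time (s); default 10 gives ample pre-onset
#'   baseline.
#' @param duration light duration (s); default 5.
#' @param post observation time after light offset (s); default 30.
#' @param intensity character label (uW/mm2).
#' @return A [StimulusProtocol-class].
#' @export
lightPulseProtocol <- function(onset = 10, duration = 5, post = 30,
                               intensity = "20") {
  stimulusProtocol(
    data.frame(start = onset, end = onset + duration, kind = "light",
               intensity = intensity, quadrants = "ALL",
               pulse = "continuous"),
    sessionLength = onset + duration + post)
}

#' Quadrant preference protocol with counterbalanced switch
#'
#' Two sequential light tests in opposing quadrant pairs (Q1,Q3 then Q2,Q4)
#' separated by a rest period, the design used to measure innate positional
#' preference independently of spatial bias.
#'
#' @param onset start of the first test (s).
#' @param duration duration of each light test (s); default 30.
#' @param rest rest between the two tests (s); default 30.
#' @param intensity character label.
#' @return A [StimulusProtocol-class] with two light epochs.
#' @export
quadrantPreferenceProtocol <- function(onset = 10, duration = 30, rest = 30,
                                       intensity = "4") {
  stimulusProtocol(
    data.frame(
      start = c(onset, onset + duration + rest),
      end = c(onset + duration, onset + 2 * duration + rest),
      kind = "light",
      intensity = intensity,
      quadrants = c("Q1,Q3", "Q2,Q4"),
      pulse = "continuous"),
    sessionLength = onset + 2 * duration + rest + 10)
}

## Fetch one epoch row by index with bounds checking.
getEpoch <- function(protocol, epoch) {
  ep <- epochs(protocol)
  if (!is.numeric(epoch) || epoch < 1L || epoch > nrow(ep))
    stop("epoch index out of range", call. = FALSE)
  ep[epoch, , drop = FALSE]
}
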