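## Feeding microstructure: sip/burst/bout segmentation, closed-loop light
## annotation, feeding summaries and PER suppression indices.

#' Construct an event stream
#'
#' Builds an [EventStream-class] from an interaction table. Light epochs can
#' be supplied or derived later with [closedLoopAnnotation()].
#'
#' @param interactions data.frame with columns `channel`, `start`, `end` (s).
#' @param sessionLength session duration, s.
#' @param channels optional data.frame (`channel`, `food`); defaults to the
#'   channels present in `interactions` with food `"unknown"`.
#' @param lightEpochs optional data.frame (`start`, `end`).
#' @return An [EventStream-class].
#' @export
eventStream <- function(interactions, sessionLength, channels = NULL,
                        lightEpochs = NULL) {
  interactions <- as.data.frame(interactions)
  if (is.null(channels))
    channels <- data.frame(channel = unique(interactions$channel),
                           food = "unknown")
  if (is.null(lightEpochs))
    lightEpochs <- data.frame(start = numeric(0), end = numeric(0))
  methods::new("EventStream", channels = channels,
               interactions = interactions, lightEpochs = lightEpochs,
               sessionLength = sessionLength)
}

#' Segment interactions into sips, bursts and bouts
#'
#' Each interaction interval is one sip (after discarding sensor-noise sips
#' shorter than `min_sip_duration`). On each channel, consecutive sips with
#' an inter-sip gap of at most `intra_burst_gap` share a burst, and
#' consecutive sips with a gap of at most `inter_bout_gap` share a bout.
#' Interactions are sorted before segmentation, so the result is independent
#' of input order.
#'
#' The default gap thresholds (0.5 s and 2 s) are package defaults exposed
#' for configuration; published analyses of this assay type take their
#' thresholds from dedicated methods work.
#'
#' @param stream an [EventStream-class].
#' @param intra_burst_gap maximum within-burst inter-sip gap, s.
#' @param inter_bout_gap maximum within-bout inter-sip gap, s; must exceed
#'   `intra_burst_gap`.
#' @param min_sip_duration sips shorter than this are discarded, s
#'   (default 0.03).
#' @return data.frame with columns `channel`, `sip`, `start`, `end`,
#'   `burst`, `bout` (ids numbered per channel), with the thresholds stored
#'   in attributes `intra_burst_gap` / `inter_bout_gap`.
#' @export
#' @examples
#' es <- eventStream(data.frame(channel = "c1",
#'                              start = c(0, 0.5, 1.0, 6.2, 6.7),
#'                              end = c(0.3, 0.8, 1.3, 6.5, 7.0)),
#'                   sessionLength = 10)
#' segmentSips(es)
segmentSips <- function(stream, intra_burst_gap = 0.5, inter_bout_gap = 2,
                        min_sip_duration = 0.03) {
  stopifnot(is(stream, "EventStream"))
  if (!(intra_burst_gap < inter_bout_gap))
    stop("intra_burst_gap must be smaller than inter_bout_gap",
         call. = FALSE)
  ia <- interactions(stream)
  ia <- ia[ia$end - ia$start >= min_sip_duration, , drop = FALSE]
  out <- lapply(unique(ia$channel), function(ch) {
    sub <- ia[ia$channel == ch, , drop = FALSE]
    sub <- sub[order(sub$start, sub$end), , drop = FALSE]
    n <- nrow(sub)
    if (!n) return(NULL)
    gaps <- if (n > 1L) sub$start[-1L] - sub$end[-n] else numeric(0)
    burst <- cumsum(c(1L, as.integer(gaps > intra_burst_gap)))
    bout <- cumsum(c(1L, as.integer(gaps > inter_bout_gap)))
    data.frame(channel = ch, sip = seq_len(n), start = sub$start,
               end = sub$end, burst = burst, bout = bout)
  })
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(channel = character(0), sip = integer(0),
                      start = numeric(0), end = numeric(0),
                      burst = integer(0), bout = integer(0))
  attr(res, "intra_burst_gap") <- intra_burst_gap
  attr(res, "inter_bout_gap") <- inter_bout_gap
  res
}

#' Closed-loop light epochs triggered by interactions
#'
#' One light epoch of `epoch_duration` seconds (default 1.5) starts at each
#' interaction onset on the stimulated channel; overlapping epochs are
#' merged and epochs are truncated at session end.
#'
#' @param stream an [EventStream-class].
#' @param stim_channel channel id whose interactions trigger light.
#' @param epoch_duration light duration per trigger, s.
#' @return data.frame with columns `start`, `end`.
#' @export
closedLoopAnnotation <- function(stream, stim_channel,
                                 epoch_duration = 1.5) {
  stopifnot(is(stream, "EventStream"))
  if (!stim_channel %in% channels(stream)$channel)
    stop("stim_channel not present in the stream", call. = FALSE)
  ia <- interactions(stream)
  s <- ia$start[ia$channel == stim_channel]
  if (!length(s)) return(data.frame(start = numeric(0), end = numeric(0)))
  ep <- mergeIntervals(s, pmin(s + epoch_duration, sessionLength(stream)))
  ep
}

#' Per-channel feeding summary
#'
#' Counts and durations of the feeding microstructure per channel up to a
#' horizon, plus a per-second cumulative feeding-duration curve and, when
#' both a control and a stimulated channel are named, the control-minus-opto
#' difference in each feeding parameter.
#'
#' @param segmentation data.frame from [segmentSips()].
#' @param horizon analysis horizon, s (default 3600 = 1 hr); sips straddling
#'   the horizon are truncated, later sips are dropped.
#' @param control_channel,stim_channel channel ids used for the difference
#'   block (skipped when either is absent from the segmentation).
#' @return list with `summary` (per-channel data.frame: `channel`,
#'   `total_feeding_duration`, `n_sips`, `n_bursts`, `n_bouts`,
#'   `mean_sip_duration`, `mean_bout_duration`), `cumulative` (long
#'   data.frame `channel`, `t`, `cumulative_duration`), `bout_durations`
#'   (named list) and `differences` (named numeric, control minus opto) or
#'   `NULL`.
#' @export
feedingSummary <- function(segmentation, horizon = 3600,
                           control_channel = "control",
                           stim_channel = "opto") {
  seg <- segmentation
  seg <- seg[seg$start < horizon, , drop = FALSE]
  seg$end <- pmin(seg$end, horizon)
  chans <- unique(segmentation$channel)
  ## a named channel with no surviving sips (e.g. full suppression) still
  ## gets an all-zero row so the control-minus-opto block is defined
  if (length(chans) && any(c(control_channel, stim_channel) %in% chans))
    chans <- union(chans, c(control_channel, stim_channel))
  ts <- 0:as.integer(horizon)

  perChannel <- function(ch) {
    sub <- seg[seg$channel == ch, , drop = FALSE]
    if (!nrow(sub)) {
      return(list(row = data.frame(channel = ch, total_feeding_duration = 0,
                                   n_sips = 0L, n_bursts = 0L, n_bouts = 0L,
                                   mean_sip_duration = 0,
                                   mean_bout_duration = 0),
                  cum = data.frame(channel = ch, t = ts,
                                   cumulative_duration = 0),
                  bouts = numeric(0)))
    }
    dur <- sub$end - sub$start
    bout_dur <- as.numeric(tapply(sub$end, sub$bout, max) -
                             tapply(sub$start, sub$bout, min))
    ## cumulative feeding time at integer seconds
    cum <- vapply(ts, function(t)
      sum(pmax(0, pmin(sub$end, t) - sub$start)), numeric(1))
    list(row = data.frame(channel = ch,
                          total_feeding_duration = sum(dur),
                          n_sips = nrow(sub),
                          n_bursts = length(unique(sub$burst)),
                          n_bouts = length(unique(sub$bout)),
                          mean_sip_duration = mean(dur),
                          mean_bout_duration = mean(bout_dur)),
         cum = data.frame(channel = ch, t = ts, cumulative_duration = cum),
         bouts = bout_dur)
  }

  parts <- lapply(chans, perChannel)
  summary <- do.call(rbind, lapply(parts, `[[`, "row"))
  cumulative <- do.call(rbind, lapply(parts, `[[`, "cum"))
  bouts <- stats::setNames(lapply(parts, `[[`, "bouts"), chans)

  differences <- NULL
  if (all(c(control_channel, stim_channel) %in% chans)) {
    a <- summary[summary$channel == control_channel, , drop = FALSE]
    b <- summary[summary$channel == stim_channel, , drop = FALSE]
    cols <- c("total_feeding_duration", "n_sips", "n_bursts", "n_bouts",
              "mean_sip_duration", "mean_bout_duration")
    differences <- stats::setNames(
      as.numeric(a[1, cols]) - as.numeric(b[1, cols]), cols)
  }
  list(summary = summary, cumulative = cumulative, bout_durations = bouts,
       differences = differences)
}

#' Proboscis-extension suppression index
#'
#' Suppression index `1 - with / without` comparing the PER proportion under
#' the suppressing condition (light, or bitter) to the proportion without
#' it. When `per_without` is zero the index is undefined and `NA` is
#' returned (conditions producing zero baseline PER occur in practice).
#'
#' @param per_with,per_without PER proportions in `[0, 1]` (vectorized).
#' @return numeric suppression index; 0 = no suppression, 1 = complete
#'   suppression, `NA` where undefined.
#' @export
#' @examples
#' perSuppression(0.2, 0.8)  # 0.75
perSuppression <- function(per_with, per_without) {
  if (any(c(per_with, per_without) < 0 | c(per_with, per_without) > 1,
          na.rm = TRUE))
    stop("PER proportions must be in [0, 1]", call. = FALSE)
  ifelse(per_without > 0, 1 - per_with / per_without, NA_real_)
}
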