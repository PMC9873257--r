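## Kinematic stimulus responses and quadrant preference indices from tracked
## arena trajectories.

asTrialList <- function(trials) {
  if (is(trials, "ArenaTrial")) return(list(trials))
  stopifnot(is.list(trials), all(vapply(trials, is, logical(1), "ArenaTrial")))
  trials
}

## Frame indices whose start time lies in [from, to).
framesIn <- function(n_frames, frame_rate, from, to) {
  t <- (seq_len(n_frames) - 1L) / frame_rate
  which(t >= from - 1e-9 & t < to - 1e-9)
}

## Per-frame cross-fly mean of one velocity channel for a trial.
flyAveragedSeries <- function(trial, channel) {
  tr <- tracks(trial)
  col <- switch(channel, forward = "forward_velocity",
                angular = "angular_velocity",
                stop("channel must be 'forward' or 'angular'", call. = FALSE))
  n_frames <- max(tr$frame)
  v <- tapply(tr[[col]], tr$frame, mean, na.rm = TRUE)
  out <- rep(NA_real_, n_frames)
  out[as.integer(names(v))] <- as.numeric(v)
  out[is.nan(out)] <- NA_real_
  out
}

#' Bin a velocity series into fixed-width frame bins
#'
#' Averages per-frame velocities over consecutive non-overlapping bins of
#' `bin_frames` frames (default 10 frames = 0.33 s at 30 frames/s). A
#' trailing partial bin is dropped. With `bin_frames = 1` this is the
#' identity.
#'
#' @param x numeric per-frame series, or an [ArenaTrial-class] (binned per
#'   fly and channel).
#' @param bin_frames frames per bin (>= 1).
#' @return For a numeric input, a numeric vector of length
#'   `floor(length(x) / bin_frames)`; for a trial, a data.frame with columns
#'   `fly_id`, `bin`, `t_mid`, `forward_velocity`, `angular_velocity`.
#' @export
#' @examples
#' binKinematics(rep(5, 30), 10)
binKinematics <- function(x, bin_frames = 10L) {
  if (bin_frames < 1L) stop("bin_frames must be >= 1", call. = FALSE)
  bin_frames <- as.integer(bin_frames)
  binVec <- function(v) {
    n_bins <- length(v) %/% bin_frames
    if (!n_bins) return(numeric(0))
    v <- v[seq_len(n_bins * bin_frames)]
    as.numeric(tapply(v, rep(seq_len(n_bins), each = bin_frames), mean))
  }
  if (is.numeric(x)) {
    if (!length(x)) stop("empty trajectory", call. = FALSE)
    return(binVec(x))
  }
  stopifnot(is(x, "ArenaTrial"))
  tr <- tracks(x)
  if (!nrow(tr)) stop("empty trajectory", call. = FALSE)
  flies <- unique(tr$fly_id)
  out <- lapply(flies, function(id) {
    sub <- tr[tr$fly_id == id, , drop = FALSE]
    sub <- sub[order(sub$frame), , drop = FALSE]
    fwd <- binVec(sub$forward_velocity)
    ang <- binVec(sub$angular_velocity)
    if (!length(fwd)) return(NULL)
    data.frame(fly_id = id, bin = seq_along(fwd),
               t_mid = (seq_along(fwd) - 0.5) * bin_frames / frameRate(x),
               forward_velocity = fwd, angular_velocity = ang)
  })
  do.call(rbind, out)
}

## Shared core of onset/offset responses: delta = mean(win) - mean(base),
## per trial, flies averaged within trial first.
windowDelta <- function(trials, protocol, epoch, channel, base_from, base_to,
                        win_from, win_to, baseline_name) {
  trials <- asTrialList(trials)
  out <- lapply(seq_along(trials), function(i) {
    trial <- trials[[i]]
    fr <- frameRate(trial)
    v <- flyAveragedSeries(trial, channel)
    bi <- framesIn(length(v), fr, base_from, base_to)
    wi <- framesIn(length(v), fr, win_from, win_to)
    if (length(bi) < round(0.99 * (base_to - base_from) * fr))
      stop("insufficient data for baseline window", call. = FALSE)
    if (length(wi) < round(0.99 * (win_to - win_from) * fr))
      stop("insufficient data for response window", call. = FALSE)
    b <- windowMean(v[bi], "baseline window")
    w <- windowMean(v[wi], "response window")
    data.frame(trial = i, channel = channel, baseline = b, response = w,
               delta = w - b)
  })
  do.call(rbind, out)
}

#' Kinematic response at light onset
#'
#' Change in fly-averaged forward or angular velocity at stimulus onset:
#' the mean over the first `onset_window` seconds of the epoch minus the
#' baseline mean over the `baseline_window` seconds preceding onset.
#' Computed per trial (flies averaged within trial); trials are the unit of
#' downstream statistics.
#'
#' @param trials an [ArenaTrial-class] or list of them.
#' @param protocol a [StimulusProtocol-class].
#' @param epoch epoch row index in `epochs(protocol)`.
#' @param channel `"forward"` or `"angular"`.
#' @param baseline_window s before onset used as baseline (default 4).
#' @param onset_window s after onset to average (default 1).
#' @return data.frame with one row per trial: `trial`, `channel`,
#'   `baseline`, `response`, `delta` (response minus baseline).
#' @export
onsetResponse <- function(trials, protocol, epoch = 1L,
                          channel = c("forward", "angular"),
                          baseline_window = 4, onset_window = 1) {
  channel <- match.arg(channel)
  ep <- getEpoch(protocol, epoch)
  if (ep$start < baseline_window)
    stop("epoch needs at least the baseline window of pre-onset data",
         call. = FALSE)
  if (ep$end - ep$start < onset_window)
    stop("epoch shorter than the onset window", call. = FALSE)
  windowDelta(trials, protocol, epoch, channel,
              ep$start - baseline_window, ep$start,
              ep$start, ep$start + onset_window)
}

#' Forward-velocity response after light offset
#'
#' Mean forward velocity over `offset_window` seconds following light offset
#' minus the same pre-onset baseline used by [onsetResponse()]. Negative
#' deltas indicate post-stimulus locomotor suppression (freezing).
#'
#' @inheritParams onsetResponse
#' @param offset_window s after offset to average (default 5).
#' @return data.frame as in [onsetResponse()].
#' @export
offsetResponse <- function(trials, protocol, epoch = 1L,
                           baseline_window = 4, offset_window = 5) {
  ep <- getEpoch(protocol, epoch)
  if (ep$start < baseline_window)
    stop("epoch needs at least the baseline window of pre-onset data",
         call. = FALSE)
  if (ep$end + offset_window > sessionLength(protocol) + 1e-9)
    stop("insufficient post-offset data", call. = FALSE)
  windowDelta(trials, protocol, epoch, "forward",
              ep$start - baseline_window, ep$start,
              ep$end, ep$end + offset_window)
}

#' Quadrant preference index series
#'
#' Per 1-s bin of an epoch, the preference index
#' PI = (# flies in positive-role quadrants - # flies in the others) /
#' total # flies, with fly positions sampled at the bin midpoint frame.
#' For light epochs the positive role defaults to the epoch's lit quadrants,
#' so negative PI means aversion of the lit quadrants. Flies with a lost
#' track at the midpoint frame are excluded from that bin's counts.
#'
#' @param trial an [ArenaTrial-class].
#' @param protocol a [StimulusProtocol-class].
#' @param epoch epoch row index; its quadrant mask must be a strict,
#'   non-empty subset of the four quadrants.
#' @param bin bin width, s (default 1).
#' @param positive_quadrants optional character vector overriding the
#'   epoch's quadrant mask as the positive role (used for conditioned-odor
#'   tests).
#' @return data.frame with columns `bin_start`, `bin_end`, `pi`, `n_flies`.
#' @export
preferenceIndexSeries <- function(trial, protocol, epoch = 1L, bin = 1,
                                  positive_quadrants = NULL) {
  stopifnot(is(trial, "ArenaTrial"))
  ep <- getEpoch(protocol, epoch)
  mask <- if (is.null(positive_quadrants)) parseQuadrants(ep$quadrants)
  else positive_quadrants
  if (length(mask) == 0L || length(mask) >= 4L)
    stop("preference index requires a strict non-empty quadrant subset",
         call. = FALSE)
  tr <- tracks(trial)
  fr <- frameRate(trial)
  n_frames <- max(tr$frame)
  starts <- seq(ep$start, ep$end - bin + 1e-9, by = bin)
  out <- lapply(starts, function(s) {
    mid_frame <- as.integer(floor((s + bin / 2) * fr)) + 1L
    if (mid_frame > n_frames) return(NULL)
    sub <- tr[tr$frame == mid_frame, , drop = FALSE]
    q <- quadrantOf(sub$x, sub$y)
    q <- q[!is.na(q)]
    n <- length(q)
    data.frame(bin_start = s, bin_end = s + bin,
               pi = if (n > 0) (sum(q %in% mask) - sum(!q %in% mask)) / n
               else NA_real_,
               n_flies = n)
  })
  do.call(rbind, out)
}

#' Final preference index of an epoch
#'
#' Mean PI over the last `window` seconds (default 5, i.e. the last five
#' 1-s bins) of a PI series computed over one epoch.
#'
#' @param series data.frame from [preferenceIndexSeries()].
#' @param window s to average at the end of the epoch (default 5).
#' @return scalar mean PI.
#' @export
finalPI <- function(series, window = 5) {
  bin <- series$bin_end[1] - series$bin_start[1]
  n_last <- as.integer(round(window / bin))
  if (nrow(series) < n_last)
    stop("epoch shorter than the final-PI window", call. = FALSE)
  mean(utils::tail(series$pi, n_last))
}

#' Learned odor preference index
#'
#' Combined conditioned-odor preference over two counterbalanced test
#' epochs whose CS+ quadrant assignments are swapped. Per test, the PI
#' series is computed with the CS+ quadrants in the positive role and
#' summarized by its final value (last `window` s); the returned value is
#' the mean of the two tests, which cancels any time-invariant spatial bias
#' by construction.
#'
#' @param trials an [ArenaTrial-class] or list of them (one value returned
#'   per trial).
#' @param protocol a [StimulusProtocol-class].
#' @param test_epochs integer vector of exactly two epoch indices with
#'   complementary quadrant masks.
#' @param window final-PI window, s (default 5).
#' @return numeric vector, one combined learned PI per trial.
#' @export
learnedPI <- function(trials, protocol, test_epochs, window = 5) {
  if (length(test_epochs) != 2L)
    stop("counterbalancing requires exactly two test epochs", call. = FALSE)
  m1 <- parseQuadrants(getEpoch(protocol, test_epochs[1])$quadrants)
  m2 <- parseQuadrants(getEpoch(protocol, test_epochs[2])$quadrants)
  if (!setequal(m2, setdiff(c("Q1", "Q2", "Q3", "Q4"), m1)))
    stop("test epochs must have swapped (complementary) quadrant maps",
         call. = FALSE)
  trials <- asTrialList(trials)
  vapply(trials, function(trial) {
    finals <- vapply(test_epochs, function(e) {
      s <- preferenceIndexSeries(trial, protocol, e)
      finalPI(s, window)
    }, numeric(1))
    mean(finals)
  }, numeric(1))
}
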