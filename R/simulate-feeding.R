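#' Parameters for the feeding-session simulator
#'
#' Defaults emulate a 1-hour two-choice closed-loop assay in which
#' optogenetic stimulation on one food source produces near-complete feeding
#' suppression. Inter-event interval means must be strictly ordered
#' (intra-burst < inter-burst < inter-bout).
#'
#' @param session_length session duration, s (default 3600 = 1 hr).
#' @param sip_duration_mean mean sip duration, s.
#' @param intra_burst_interval_mean mean gap between sips within a burst, s.
#' @param inter_burst_interval_mean mean gap between bursts within a bout, s.
#' @param inter_bout_interval_mean mean gap between bouts, s.
#' @param opto_suppression_factor retention probability for interactions on
#'   the stimulated channel after the first contact, in `[0, 1]` (1 = no
#'   suppression, 0 = full suppression after first contact).
#' @param sips_per_burst_mean,bursts_per_bout_mean mean counts (1 + Poisson).
#' @param seed integer seed.
#' @return Validated list of class `"FeedingSimParams"`.
#' @export
feedingSimParams <- function(session_length = 3600, sip_duration_mean = 0.15,
                             intra_burst_interval_mean = 0.25,
                             inter_burst_interval_mean = 1.0,
                             inter_bout_interval_mean = 30,
                             opto_suppression_factor = 0.1,
                             sips_per_burst_mean = 5,
                             bursts_per_bout_mean = 3, seed = 1L) {
  if (!(intra_burst_interval_mean < inter_burst_interval_mean &&
          inter_burst_interval_mean < inter_bout_interval_mean))
    stop("interval means must satisfy intra_burst < inter_burst < inter_bout",
         call. = FALSE)
  if (opto_suppression_factor < 0 || opto_suppression_factor > 1)
    stop("opto_suppression_factor must be in [0, 1]", call. = FALSE)
  if (session_length <= 0) stop("session_length must be positive",
                                call. = FALSE)
  structure(list(session_length = session_length,
                 sip_duration_mean = sip_duration_mean,
                 intra_burst_interval_mean = intra_burst_interval_mean,
                 inter_burst_interval_mean = inter_burst_interval_mean,
                 inter_bout_interval_mean = inter_bout_interval_mean,
                 opto_suppression_factor = opto_suppression_factor,
                 sips_per_burst_mean = sips_per_burst_mean,
                 bursts_per_bout_mean = bursts_per_bout_mean,
                 seed = as.integer(seed)),
            class = "FeedingSimParams")
}

## Exponential with mean m truncated to (lo, hi); inverse-CDF sampling.
rexpTrunc <- function(n, m, lo = 0, hi = Inf) {
  plo <- stats::pexp(lo, rate = 1 / m)
  phi <- stats::pexp(hi, rate = 1 / m)
  stats::qexp(plo + stats::runif(n) * (phi - plo), rate = 1 / m)
}

## Generator-side bookkeeping of sip/burst/bout counts under the gap rule.
countSegments <- function(start, end, intra_burst_gap, inter_bout_gap) {
  n <- length(start)
  if (!n) return(c(n_sips = 0L, n_bursts = 0L, n_bouts = 0L))
  o <- order(start)
  gaps <- start[o][-1L] - end[o][-n]
  c(n_sips = n,
    n_bursts = 1L + sum(gaps > intra_burst_gap),
    n_bouts = 1L + sum(gaps > inter_bout_gap))
}

#' Simulate a closed-loop two-channel feeding session
#'
#' Generates sip intervals with a three-level hierarchical timing structure
#' (sips within bursts within bouts) on two channels, applies optogenetic
#' suppression by thinning on the stimulated channel, and derives the
#' closed-loop light epochs (1.5 s per triggering interaction, merged when
#' overlapping, truncated at session end).
#'
#' Inter-event gaps are drawn from exponentials truncated to three disjoint
#' ranges delimited by the segmentation thresholds (0, 0.5), (0.5, 2) and
#' (2, Inf) seconds, so the planted hierarchy is exactly identifiable by
#' [segmentSips()] at the default thresholds; the truncation bounds are
#' recorded in the ground truth. Suppression keeps the first interaction on
#' the stimulated channel (the contact that first triggers light) and retains
#' each later sip with probability `opto_suppression_factor`.
#'
#' @param params a [feedingSimParams()] list.
#' @param closed_loop_channel `"opto"` (default) or `"control"`: the channel
#'   whose interactions trigger light.
#' @return list with `stream` (an [EventStream-class]) and `groundTruth`
#'   (planted per-channel sip/burst/bout counts, suppression factor, gap
#'   thresholds, seed).
#' @export
simulateFeedingSession <- function(params, closed_loop_channel = "opto") {
  if (!inherits(params, "FeedingSimParams"))
    params <- do.call(feedingSimParams, as.list(params))
  chans <- c("control", "opto")
  if (!closed_loop_channel %in% chans)
    stop("closed_loop_channel must be 'control' or 'opto'", call. = FALSE)
  g1 <- 0.5  # intra-burst gap threshold, s
  g2 <- 2    # inter-bout gap threshold, s

  genChannel <- function() {
    s <- numeric(0); e <- numeric(0)
    t <- rexpTrunc(1L, params$inter_bout_interval_mean, g2, Inf)
    repeat {
      if (t >= params$session_length) break
      n_bursts <- 1L + stats::rpois(1L, params$bursts_per_bout_mean - 1)
      for (b in seq_len(n_bursts)) {
        n_sips <- 1L + stats::rpois(1L, params$sips_per_burst_mean - 1)
        for (k in seq_len(n_sips)) {
          dur <- max(0.05, rexpTrunc(1L, params$sip_duration_mean, 0.03, 0.45))
          if (t >= params$session_length) break
          s <- c(s, t)
          e <- c(e, min(t + dur, params$session_length))
          t <- t + dur + rexpTrunc(1L, params$intra_burst_interval_mean, 0, g1)
        }
        ## replace the last intra-burst gap with an inter-burst gap
        if (b < n_bursts)
          t <- e[length(e)] +
            rexpTrunc(1L, params$inter_burst_interval_mean, g1, g2)
        if (t >= params$session_length) break
      }
      t <- if (length(e)) e[length(e)] +
        rexpTrunc(1L, params$inter_bout_interval_mean, g2, Inf) else
          params$session_length
    }
    data.frame(start = s, end = e)
  }

  withSeed(params$seed, {
    ctrl <- genChannel()
    opto <- genChannel()
    if (nrow(opto) > 1L && params$opto_suppression_factor < 1) {
      keep <- c(TRUE, stats::runif(nrow(opto) - 1L) <
                  params$opto_suppression_factor)
      opto <- opto[keep, , drop = FALSE]
    }
  })

  ia <- rbind(
    if (nrow(ctrl)) data.frame(channel = "control", ctrl) else NULL,
    if (nrow(opto)) data.frame(channel = "opto", opto) else NULL)
  if (is.null(ia))
    ia <- data.frame(channel = character(0), start = numeric(0),
                     end = numeric(0))
  ia <- ia[order(ia$start), , drop = FALSE]
  rownames(ia) <- NULL

  stream <- methods::new(
    "EventStream",
    channels = data.frame(channel = chans,
                          food = c("sucrose", "sucrose")),
    interactions = ia,
    lightEpochs = data.frame(start = numeric(0), end = numeric(0)),
    sessionLength = params$session_length)
  stream@lightEpochs <- closedLoopAnnotation(stream, closed_loop_channel)

  gt <- list(kind = "feeding", seed = params$seed,
             opto_suppression_factor = params$opto_suppression_factor,
             intra_burst_gap = g1, inter_bout_gap = g2,
             counts = list(
               control = countSegments(ctrl$start, ctrl$end, g1, g2),
               opto = countSegments(opto$start, opto$end, g1, g2)),
             total_duration = c(control = sum(ctrl$end - ctrl$start),
                                opto = sum(opto$end - opto$start)))
  list(stream = stream, groundTruth = gt)
}
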