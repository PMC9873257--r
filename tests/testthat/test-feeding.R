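test_that("sip segmentation follows the gap rule", {
  ## single sip: 1 sip, 1 burst, 1 bout
  es <- eventStream(data.frame(channel = "c1", start = 1, end = 1.4),
                    sessionLength = 10)
  seg <- segmentSips(es)
  expect_equal(c(nrow(seg), max(seg$burst), max(seg$bout)), c(1, 1, 1))

  ## gaps [0.2, 0.2, 5, 0.2] with thresholds (0.5, 2):
  ## 5 sips, 3 bursts, 2 bouts (hand-enumerated from the gap rule)
  starts <- c(0, 0.5, 1.0, 6.3, 6.8)
  ends <- starts + 0.3
  ## gaps between consecutive sips: 0.2, 0.2, 5, 0.2
  es2 <- eventStream(data.frame(channel = "c1", start = starts, end = ends),
                     sessionLength = 20)
  seg2 <- segmentSips(es2, intra_burst_gap = 0.5, inter_bout_gap = 2)
  expect_equal(nrow(seg2), 5L)
  expect_equal(length(unique(seg2$burst)), 2L)
  expect_equal(length(unique(seg2$bout)), 2L)
  ## with a mid-scale gap present, bursts split earlier than bouts
  starts3 <- c(0, 0.2, 1.2, 6.3, 6.6)
  es3 <- eventStream(data.frame(channel = "c1", start = starts3,
                                end = starts3 + 0.1), sessionLength = 20)
  seg3 <- segmentSips(es3, 0.5, 2)
  expect_equal(c(nrow(seg3), length(unique(seg3$burst)),
                 length(unique(seg3$bout))), c(5L, 3L, 2L))

  expect_error(segmentSips(es, intra_burst_gap = 3, inter_bout_gap = 2),
               "smaller")
})

test_that("segmentation is order-independent and discards noise sips", {
  starts <- c(5, 0, 8, 2.5)
  df <- data.frame(channel = "c1", start = starts, end = starts + 0.2)
  seg_a <- segmentSips(eventStream(df, 20))
  seg_b <- segmentSips(eventStream(df[order(-df$start), ], 20))
  expect_identical(seg_a, seg_b)
  ## sub-30 ms contacts are sensor noise
  df2 <- rbind(df, data.frame(channel = "c1", start = 1, end = 1.01))
  expect_identical(nrow(segmentSips(eventStream(df2, 20))), 4L)
})

test_that("raising gap thresholds never increases burst or bout counts", {
  set.seed(4)
  for (rep in 1:20) {
    starts <- sort(runif(30, 0, 60))
    ends <- starts + runif(30, 0.05, 0.3)
    starts[-1] <- pmax(starts[-1], ends[-30] + 0.01)
    ends <- pmax(ends, starts + 0.05)
    es <- eventStream(data.frame(channel = "c1", start = starts,
                                 end = ends), sessionLength = 100)
    thr <- sort(runif(3, 0.1, 5))
    s1 <- segmentSips(es, thr[1], thr[3])
    s2 <- segmentSips(es, thr[2], thr[3])
    expect_gte(length(unique(s1$burst)), length(unique(s2$burst)))
    s3 <- segmentSips(es, thr[1], thr[2])
    expect_gte(length(unique(s3$bout)), length(unique(s1$bout)))
  }
})

test_that("every sip interval is nested in its burst and bout intervals", {
  sim <- simulateFeedingSession(feedingSimParams(session_length = 300,
                                                 seed = 6))
  seg <- segmentSips(sim$stream)
  for (ch in unique(seg$channel)) {
    sub <- seg[seg$channel == ch, ]
    burst_lo <- tapply(sub$start, sub$burst, min)
    burst_hi <- tapply(sub$end, sub$burst, max)
    bout_lo <- tapply(sub$start, sub$bout, min)
    bout_hi <- tapply(sub$end, sub$bout, max)
    expect_true(all(sub$start >= burst_lo[as.character(sub$burst)] &
                      sub$end <= burst_hi[as.character(sub$burst)]))
    expect_true(all(burst_lo >= bout_lo[as.character(
      tapply(sub$bout, sub$burst, unique))]))
    ## counts are weakly ordered
    expect_gte(nrow(sub), length(unique(sub$burst)))
    expect_gte(length(unique(sub$burst)), length(unique(sub$bout)))
  }
})

test_that("closed-loop annotation merges and truncates 1.5-s epochs", {
  es <- eventStream(data.frame(channel = "opto", start = c(10, 11),
                               end = c(10.2, 11.2)), sessionLength = 60)
  ep <- closedLoopAnnotation(es, "opto")
  expect_equal(ep, data.frame(start = 10, end = 12.5))
  ## no interactions -> empty list
  es0 <- eventStream(data.frame(channel = "control", start = 5, end = 5.5),
                     sessionLength = 60,
                     channels = data.frame(channel = c("control", "opto"),
                                           food = "sucrose"))
  expect_equal(nrow(closedLoopAnnotation(es0, "opto")), 0L)
  ## epoch truncated at session end
  es1 <- eventStream(data.frame(channel = "opto", start = 59.5, end = 59.8),
                     sessionLength = 60)
  expect_equal(closedLoopAnnotation(es1, "opto")$end, 60)
  expect_error(closedLoopAnnotation(es1, "nope"), "not present")
})

test_that("feeding summary totals, cumulative curve and differences", {
  df <- data.frame(channel = "c1", start = c(0, 5), end = c(1, 7))
  seg <- segmentSips(eventStream(df, 3600))
  fs <- feedingSummary(seg, horizon = 3600)
  expect_equal(fs$summary$total_feeding_duration, 3)
  ## cumulative curve non-decreasing and ends at the total
  cum <- fs$cumulative$cumulative_duration
  expect_true(all(diff(cum) >= 0))
  expect_equal(cum[length(cum)], 3)
  ## empty stream -> all-zero summary, not an error
  seg0 <- seg[0, ]
  seg0 <- segmentSips(eventStream(
    data.frame(channel = character(0), start = numeric(0),
               end = numeric(0)), 3600,
    channels = data.frame(channel = "c1", food = "x")))
  expect_equal(nrow(seg0), 0L)
  ## full suppression: opto totals zero, difference equals control totals
  sim <- simulateFeedingSession(feedingSimParams(session_length = 400,
                                                 opto_suppression_factor = 0,
                                                 seed = 9))
  ia <- interactions(sim$stream)
  ia <- ia[!(ia$channel == "opto"), , drop = FALSE]  # drop the single trigger
  seg2 <- segmentSips(eventStream(
    ia, 400, channels = data.frame(channel = c("control", "opto"),
                                   food = "sucrose")))
  fs2 <- feedingSummary(seg2, horizon = 400)
  expect_equal(unname(fs2$differences["total_feeding_duration"]),
               fs2$summary$total_feeding_duration[
                 fs2$summary$channel == "control"])
  ## a sip straddling the horizon is truncated
  segh <- segmentSips(eventStream(
    data.frame(channel = "c1", start = 9.5, end = 11), 20))
  expect_equal(feedingSummary(segh,
                              horizon = 10)$summary$total_feeding_duration,
               0.5)
})

test_that("PER suppression index follows 1 - with/without", {
  expect_equal(perSuppression(0.2, 0.8), 0.75)
  expect_equal(perSuppression(0.6, 0.6), 0)
  expect_equal(perSuppression(0, 0.6), 1)
  expect_true(is.na(perSuppression(0.3, 0)))
  expect_error(perSuppression(1.2, 0.5), "0, 1")
})
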