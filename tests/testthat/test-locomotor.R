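test_that("kinematic binning averages frames and drops partial bins", {
  expect_equal(binKinematics(rep(5, 30), 10), c(5, 5, 5))
  expect_equal(binKinematics(c(rep(0, 5), rep(10, 5)), 10), 5)
  expect_length(binKinematics(rnorm(35), 10), 3L)
  ## identity at bin width 1
  x <- rnorm(17)
  expect_equal(binKinematics(x, 1), x)
  expect_error(binKinematics(numeric(0), 10), "empty")
  ## trial interface bins per fly
  tr <- makeTrial(fwd = rep(c(2, 4), each = 15))
  b <- binKinematics(tr, 10)
  expect_equal(b$forward_velocity, c(2, 3, 4))
})

test_that("onset and offset deltas are zero for constant trajectories", {
  pr <- lightPulseProtocol(onset = 10, duration = 5, post = 30)
  tr <- makeTrial(fwd = rep(3, 45 * 30))
  expect_equal(onsetResponse(tr, pr)$delta, 0)
  expect_equal(offsetResponse(tr, pr)$delta, 0)
})

test_that("onset delta equals the planted velocity step", {
  pr <- lightPulseProtocol(onset = 10, duration = 5, post = 30)
  t_frame <- (seq_len(45 * 30) - 1) / 30
  fwd <- ifelse(t_frame >= 10 & t_frame < 15, 8, 2)
  expect_equal(onsetResponse(makeTrial(fwd), pr)$delta, 6)
  ## full freeze after offset: delta = -baseline
  fwd2 <- ifelse(t_frame >= 15, 0, 6)
  expect_equal(offsetResponse(makeTrial(fwd2), pr)$delta, -6)
})

test_that("window preconditions raise errors", {
  pr <- stimulusProtocol(data.frame(start = 2, end = 7, kind = "light"),
                         sessionLength = 20)
  tr <- makeTrial(rep(1, 20 * 30))
  expect_error(onsetResponse(tr, pr), "baseline window")
  pr2 <- stimulusProtocol(data.frame(start = 10, end = 18, kind = "light"),
                          sessionLength = 20)
  expect_error(offsetResponse(tr, pr2), "post-offset")
})

test_that("windows exclude lost-track frames and flag gappy windows", {
  pr <- lightPulseProtocol(onset = 10, duration = 5, post = 30)
  t_frame <- (seq_len(45 * 30) - 1) / 30
  fwd <- ifelse(t_frame >= 10 & t_frame < 15, 8, 2)
  ## a few NA frames in the onset window are tolerated
  fwd[which(t_frame >= 10)[1:10]] <- NA
  expect_equal(onsetResponse(makeTrial(fwd), pr)$delta, 6)
  ## >50% missing raises a quality error
  fwd[t_frame >= 10 & t_frame < 15] <- NA
  fwd[which(t_frame >= 10 & t_frame < 11)[1:5]] <- 8
  expect_error(onsetResponse(makeTrial(fwd), pr), "missing")
})

test_that("preference index follows the counting formula and its bounds", {
  ## 15 of 20 flies in lit quadrants -> PI = 0.5
  xs <- c(rep(1, 15), rep(-1, 5)); ys <- c(rep(1, 15), rep(1, 5))
  ## lit = Q1,Q3: put 15 in Q1, 5 in Q2
  trial <- makeStaticTrial(xs, ys, n_frames = 40 * 30)
  pr <- stimulusProtocol(data.frame(start = 5, end = 35, kind = "light",
                                    quadrants = "Q1,Q3"),
                         sessionLength = 40)
  s <- preferenceIndexSeries(trial, pr, 1L)
  expect_true(all(s$pi == 0.5))
  expect_true(all(s$pi >= -1 & s$pi <= 1))
  expect_equal(finalPI(s), 0.5)
  ## antisymmetry under swapping the mask with its complement
  s_comp <- preferenceIndexSeries(trial, pr, 1L,
                                  positive_quadrants = c("Q2", "Q4"))
  expect_equal(s_comp$pi, -s$pi)
  ## uniform occupancy -> PI = 0
  trial0 <- makeStaticTrial(c(1, -1, -1, 1), c(1, 1, -1, -1), 40 * 30)
  expect_true(all(preferenceIndexSeries(trial0, pr, 1L)$pi == 0))
  ## PI undefined for ALL or empty masks
  prall <- stimulusProtocol(data.frame(start = 5, end = 35, kind = "light",
                                       quadrants = "ALL"),
                            sessionLength = 40)
  expect_error(preferenceIndexSeries(trial, prall, 1L), "strict")
})

test_that("final PI is the mean of the last five 1-s bins", {
  s <- data.frame(bin_start = 0:9, bin_end = 1:10,
                  pi = c(rep(0, 5), -0.2, -0.3, -0.4, -0.5, -0.6),
                  n_flies = 10)
  expect_equal(finalPI(s), -0.4)
  expect_error(finalPI(s[1:3, ]), "window")
})

test_that("counterbalanced learned PI cancels pure spatial bias", {
  ## flies parked in fixed quadrants, no odor effect: combined PI = 0
  trial <- makeStaticTrial(c(1, 1, 1, -1), c(1, 1, 1, 1), 150 * 30)
  pr <- stimulusProtocol(
    data.frame(start = c(10, 80), end = c(40, 110), kind = "odor",
               intensity = "OCT", quadrants = c("Q1,Q3", "Q2,Q4")),
    sessionLength = 150)
  expect_equal(learnedPI(trial, pr, c(1L, 2L)), 0)
  ## flies tracking the CS- odor across the switch -> -1
  n_frames <- 150 * 30
  t_frame <- (seq_len(n_frames) - 1) / 30
  x <- ifelse(t_frame < 60, -1, 1)  # Q2 during test 1, Q1 during test 2
  trial2 <- makeTrial(fwd = rep(0, n_frames), x = x,
                      y = rep(1, n_frames))
  expect_equal(learnedPI(trial2, pr, c(1L, 2L)), -1)
  ## second test must have the swapped map
  pr2 <- stimulusProtocol(
    data.frame(start = c(10, 80), end = c(40, 110), kind = "odor",
               intensity = "OCT", quadrants = c("Q1,Q3", "Q1,Q3")),
    sessionLength = 150)
  expect_error(learnedPI(trial2, pr2, c(1L, 2L)), "swapped")
  ## averaging of two test finals: -0.2 and -0.6 -> -0.4
  s1 <- data.frame(bin_start = 0:29, bin_end = 1:30, pi = -0.2,
                   n_flies = 4)
  s2 <- data.frame(bin_start = 0:29, bin_end = 1:30, pi = -0.6,
                   n_flies = 4)
  expect_equal(mean(c(finalPI(s1), finalPI(s2))), -0.4)
  expect_error(learnedPI(trial, pr, 1L), "exactly two")
})

test_that("simulated quadrant avoidance yields negative steady-state PI", {
  qp <- quadrantPreferenceProtocol()
  sim <- simulateArenaTrial(arenaSimParams(n_flies = 30,
                                           light_attraction = -0.8,
                                           seed = 21), qp)
  s <- preferenceIndexSeries(sim$trial, qp, 1L)
  expect_lt(finalPI(s), 0)
})
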