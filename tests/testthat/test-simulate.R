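test_that("all simulators are deterministic under a fixed seed", {
  pr <- lightPulseProtocol()
  a1 <- simulateArenaTrial(arenaSimParams(n_flies = 6, seed = 11), pr)
  a2 <- simulateArenaTrial(arenaSimParams(n_flies = 6, seed = 11), pr)
  expect_identical(tracks(a1$trial), tracks(a2$trial))

  f1 <- simulateFeedingSession(feedingSimParams(session_length = 300,
                                                seed = 11))
  f2 <- simulateFeedingSession(feedingSimParams(session_length = 300,
                                                seed = 11))
  expect_identical(interactions(f1$stream), interactions(f2$stream))

  c1 <- simulateCalciumTrials(calciumSimParams(seed = 11), 2L)
  c2 <- simulateCalciumTrials(calciumSimParams(seed = 11), 2L)
  expect_identical(fluorescence(c1$traces[[1]]),
                   fluorescence(c2$traces[[1]]))

  g1 <- simulateCircuit(circuitSimParams(seed = 11))
  g2 <- simulateCircuit(circuitSimParams(seed = 11))
  expect_identical(edges(g1$graph), edges(g2$graph))

  ## different seeds give different draws
  a3 <- simulateArenaTrial(arenaSimParams(n_flies = 6, seed = 12), pr)
  expect_false(identical(tracks(a1$trial), tracks(a3$trial)))
})

test_that("noise-free null arena trial has constant baseline speed", {
  p <- arenaSimParams(n_flies = 3, noise_sd = 0, onset_speed_boost = 0,
                      onset_turn_boost = 0, offset_freeze_prob = 0,
                      light_attraction = 0, baseline_speed = 5)
  sim <- simulateArenaTrial(p, lightPulseProtocol())
  expect_true(all(tracks(sim$trial)$forward_velocity == 5))
  expect_true(validObject(sim$trial))
})

test_that("arena simulator rejects invalid parameters and protocols", {
  expect_error(arenaSimParams(frame_rate = 0), "frame_rate")
  expect_error(arenaSimParams(n_flies = 0), "n_flies")
  expect_error(arenaSimParams(offset_freeze_prob = 1.2), "offset_freeze")
  ## overlapping same-kind epochs are a protocol error
  expect_error(stimulusProtocol(
    data.frame(start = c(5, 8), end = c(10, 12), kind = "light"),
    sessionLength = 20), "overlapping")
})

test_that("feeding generator plants an exactly segmentable hierarchy", {
  sim <- simulateFeedingSession(feedingSimParams(session_length = 400,
                                                 opto_suppression_factor = 1,
                                                 seed = 5))
  seg <- segmentSips(sim$stream)
  for (ch in c("control", "opto")) {
    sub <- seg[seg$channel == ch, , drop = FALSE]
    got <- c(n_sips = nrow(sub), n_bursts = length(unique(sub$burst)),
             n_bouts = length(unique(sub$bout)))
    expect_identical(unname(got), unname(sim$groundTruth$counts[[ch]]))
  }
  ## hierarchy: each sip in exactly one burst, each burst in one bout
  expect_true(all(tapply(seg$bout, paste(seg$channel, seg$burst),
                         function(x) length(unique(x)) == 1L)))
})

test_that("full suppression leaves only the first triggering contact", {
  sim <- simulateFeedingSession(feedingSimParams(session_length = 400,
                                                 opto_suppression_factor = 0,
                                                 seed = 7))
  ia <- interactions(sim$stream)
  expect_identical(sum(ia$channel == "opto"), 1L)
  expect_identical(nrow(lightEpochs(sim$stream)), 1L)
})

test_that("feeding parameter validation enforces the interval ordering", {
  expect_error(feedingSimParams(intra_burst_interval_mean = 3,
                                inter_burst_interval_mean = 1),
               "intra_burst < inter_burst")
  expect_error(feedingSimParams(opto_suppression_factor = 2), "0, 1")
})

test_that("calcium trials carry the planted geometric habituation", {
  sim <- simulateCalciumTrials(
    calciumSimParams(noise_sd = 0, on_amplitude = 0.7,
                     habituation_factor_on = 0.5), n_trials = 3L)
  m <- do.call(rbind, lapply(sim$traces, onOffAmplitudes))
  expect_equal(m$on_amplitude, c(0.7, 0.35, 0.175), tolerance = 1e-12)
  ## planted zero-amplitude trace is identically zero
  z <- simulateCalciumTrials(calciumSimParams(noise_sd = 0,
                                              on_amplitude = 0,
                                              off_amplitude = 0), 1L)
  expect_true(all(dff(z$traces[[1]]) == 0))
  ## noise-free peak equals the planted value exactly
  expect_equal(max(dff(sim$traces[[1]])), 0.7, tolerance = 1e-12)
  expect_error(simulateCalciumTrials(calciumSimParams(), 1L,
                                     stim_onset = 1),
               "20 pre-stimulus frames")
})

test_that("circuit generator validates subtype counts and plants structure", {
  expect_error(circuitSimParams(n_seed = 10,
                                seed_subtypes = c(a = 3L, b = 3L)),
               "sum to n_seed")
  sim <- simulateCircuit(circuitSimParams(feedback_fraction = 0, seed = 3))
  l2 <- downstreamLayer(sim$graph, sim$groundTruth$seed_ids, edge_min = 3)
  l3 <- downstreamLayer(sim$graph, sim$groundTruth$layer2_members,
                        edge_min = 3, layer_index = 4L)
  expect_identical(feedbackDetect(l3, sim$groundTruth$seed_ids)$seeds,
                   character(0))
  ## planted membership is recovered exactly (decoys excluded)
  m <- members(l2)
  expect_setequal(m$cell_id[!m$is_source], sim$groundTruth$layer2_members)
})

test_that("a planted single-pair motif is the only nonzero matrix cell", {
  p <- circuitSimParams(
    n_seed = 6L, seed_subtypes = c(A = 3L, B = 3L), n_layer2 = 4L,
    n_layer3 = 0L, n_decoy = 0L,
    planted_motif = data.frame(from = "A", to = "B", n_edges = 4L),
    feedback_fraction = 0, seed = 8)
  sim <- simulateCircuit(p)
  m <- interconnectionMatrix(sim$graph, edge_min = 5)
  expect_identical(m["A", "B"], 4)
  m["A", "B"] <- 0
  expect_true(all(m == 0))
})
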