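test_that("circuit graph construction aggregates duplicate edge pairs", {
  g <- circuitGraph(data.frame(cell_id = c("a", "b")),
                    data.frame(pre = c("a", "a"), post = c("b", "b"),
                               weight = c(2L, 3L)))
  expect_equal(edges(g)$weight, 5L)
  expect_error(circuitGraph(data.frame(cell_id = "a"),
                            data.frame(pre = "a", post = "zzz",
                                       weight = 1L)),
               "endpoints")
})

test_that("downstream layer admission follows the per-edge threshold", {
  nn <- data.frame(cell_id = c("s1", "s2", "t1", "t2", "t3"))
  ee <- data.frame(pre = c("s1", "s2", "s1", "s2"),
                   post = c("t1", "t1", "t2", "t3"),
                   weight = c(5L, 2L, 2L, 3L))
  g <- circuitGraph(nn, ee)
  l <- downstreamLayer(g, c("s1", "s2"), edge_min = 3)
  m <- members(l)
  ## t1 admitted by the s1 edge (5 >= 3), t3 by s2 (3 >= 3); t2 is not
  expect_setequal(m$cell_id, c("t1", "t3"))
  ## totals exclude sub-threshold contributions by default
  expect_equal(m$total_synapses[m$cell_id == "t1"], 5)
  l_all <- downstreamLayer(g, c("s1", "s2"), edge_min = 3,
                           include_subthreshold_in_total = TRUE)
  expect_equal(members(l_all)$total_synapses[
    members(l_all)$cell_id == "t1"], 7)
  ## conservation: totals equal the sum of listed contributing edges
  for (id in m$cell_id) {
    e <- edges(l)[edges(l)$post == id, ]
    expect_equal(m$total_synapses[m$cell_id == id], sum(e$weight))
  }
  ## threshold above every weight empties the layer; empty source too
  expect_equal(nrow(members(downstreamLayer(g, c("s1", "s2"),
                                            edge_min = 99))), 0L)
  expect_equal(nrow(members(downstreamLayer(g, character(0)))), 0L)
  expect_error(downstreamLayer(g, "ghost"), "subset")
})

test_that("downstream layers match brute-force enumeration on random graphs", {
  set.seed(13)
  for (r in 1:40) {
    rg <- randomGraph(sample(8:20, 1))
    sources <- sample(rg$ids, 3)
    emin <- sample(2:6, 1)
    l <- downstreamLayer(rg$graph, sources, edge_min = emin)
    want <- bruteLayer(edges(rg$graph), sources, emin)
    m <- members(l)
    expect_identical(m$cell_id, want$members)
    expect_equal(stats::setNames(m$total_synapses, m$cell_id), want$totals)
    ## monotonicity in the threshold
    l2 <- downstreamLayer(rg$graph, sources, edge_min = emin + 2)
    expect_true(all(members(l2)$cell_id %in% m$cell_id))
  }
})

test_that("top-target selection: population threshold and top-n ranking", {
  mm <- data.frame(cell_id = c("b", "a", "c", "d"),
                   cell_type = "t", n_input_cells = 1L, input_types = "x",
                   total_synapses = c(30, 30, 10, 25),
                   percent_input = NA_real_, regions = "SLP",
                   is_source = FALSE)
  layer <- new("LayerResult", layerIndex = 3L, members = mm,
               edges = data.frame(pre = character(0), post = character(0),
                                  weight = integer(0)))
  expect_setequal(members(topTargets(layer, k = 25))$cell_id,
                  c("a", "b", "d"))
  ## exclusion applies before selection
  expect_setequal(members(topTargets(layer, k = 25,
                                     exclude = "a"))$cell_id, c("b", "d"))
  ## top-n with tie broken by ascending cell id
  expect_identical(members(topTargets(layer, n = 2))$cell_id, c("a", "b"))
  expect_error(topTargets(layer, n = 0), "positive")
  expect_error(topTargets(layer), "exactly one")
  ## brute-force equality of population_min on a random graph
  set.seed(14)
  rg <- randomGraph(15)
  sources <- rg$ids[1:3]
  l <- downstreamLayer(rg$graph, sources, edge_min = 2)
  want <- bruteLayer(edges(rg$graph), sources, 2)
  keep <- names(want$totals)[want$totals >= 8]
  expect_setequal(members(topTargets(l, k = 8))$cell_id, keep)
})

test_that("interconnection matrix matches brute-force pair enumeration", {
  set.seed(15)
  for (r in 1:20) {
    rg <- randomGraph(12)
    map <- stats::setNames(sample(c("A", "B", "C"), 6, replace = TRUE),
                           rg$ids[1:6])
    for (mode in c("count", "weight")) {
      got <- interconnectionMatrix(rg$graph, map, edge_min = 5, mode = mode)
      want <- bruteMotif(edges(rg$graph), map, 5, mode)
      expect_equal(got[rownames(want), colnames(want)], want)
    }
  }
  ## an infinite threshold zeroes the matrix
  rg <- randomGraph(10)
  map <- stats::setNames(rep("A", 4), rg$ids[1:4])
  expect_true(all(interconnectionMatrix(rg$graph, map,
                                        edge_min = Inf) == 0))
  expect_error(interconnectionMatrix(rg$graph,
                                     c(a = "A", b = NA)), "unlabeled")
})

test_that("region fractions respect the laterality rule", {
  mm <- data.frame(cell_id = c("a", "b", "c"), cell_type = "t",
                   n_input_cells = 1L, input_types = "x",
                   total_synapses = 10, percent_input = NA_real_,
                   regions = c("SMP, LH", "SMP(C), LH", "LH,, SLP,"),
                   is_source = FALSE)
  layer <- new("LayerResult", layerIndex = 4L, members = mm,
               edges = data.frame(pre = character(0), post = character(0),
                                  weight = integer(0)))
  rf <- regionFractions(layer, regions = c("SMP", "LH", "SLP"))
  expect_equal(unname(rf), c(1 / 3, 1, 1 / 3))
  rf2 <- regionFractions(layer, regions = "SMP", side_rule = "either")
  expect_equal(unname(rf2), 2 / 3)
  ## single member with one region
  one <- new("LayerResult", layerIndex = 4L, members = mm[3, ],
             edges = data.frame(pre = character(0), post = character(0),
                                weight = integer(0)))
  rf4 <- regionFractions(one, regions = c("LH", "SMP"))
  expect_equal(unname(rf4), c(1, 0))
  ## empty member set -> undefined marker
  empty <- new("LayerResult", layerIndex = 4L, members = mm[0, ],
               edges = data.frame(pre = character(0), post = character(0),
                                  weight = integer(0)))
  expect_true(all(is.na(regionFractions(empty, regions = "SMP"))))
})

test_that("feedback detection returns only threshold-qualifying seeds", {
  nn <- data.frame(cell_id = c("s1", "s2", "m1", "m2"))
  ee <- data.frame(pre = c("s1", "s1", "m1", "m2"),
                   post = c("m1", "m2", "s1", "s2"),
                   weight = c(5L, 5L, 4L, 2L))
  g <- circuitGraph(nn, ee)
  l <- downstreamLayer(g, c("m1", "m2"), edge_min = 3)
  fb <- feedbackDetect(l, c("s1", "s2"))
  ## s1 qualifies (weight 4 >= 3); s2 only via a sub-threshold edge
  expect_identical(fb$seeds, "s1")
  expect_equal(fb$edges$weight, 4L)
})

test_that("path search matches exhaustive enumeration and ranks by weakest edge", {
  ## planted 2-hop chain
  g <- circuitGraph(data.frame(cell_id = c("s", "a", "t")),
                    data.frame(pre = c("s", "a"), post = c("a", "t"),
                               weight = c(10L, 7L)))
  p <- findPaths(g, "s", "t", max_intermediates = 3)
  expect_equal(nrow(p), 1L)
  expect_equal(p$min_weight, 7)
  expect_equal(p$hops, 2L)
  ## edge_min above all weights -> empty result, not an error
  expect_equal(nrow(findPaths(g, "s", "t", edge_min = 99)), 0L)
  expect_error(findPaths(g, "s", "zzz"), "target")
  ## oracle equivalence on random graphs
  set.seed(16)
  for (r in 1:25) {
    rg <- randomGraph(sample(8:14, 1))
    got <- findPaths(rg$graph, rg$ids[1:2], rg$ids[length(rg$ids)],
                     max_intermediates = 2, edge_min = 3)
    want <- brutePaths(edges(rg$graph), rg$ids[1:2],
                       rg$ids[length(rg$ids)], 2, 3)
    expect_identical(sort(got$path), want)
    ## ranking: weakest edge descending, then total weight
    if (nrow(got) > 1)
      expect_true(all(diff(got$min_weight) <= 0))
  }
  ## target may be a cell type
  g2 <- circuitGraph(data.frame(cell_id = c("s", "a", "t1", "t2"),
                                cell_type = c("seed", "mid", "DN", "DN")),
                     data.frame(pre = c("s", "a", "a"),
                                post = c("a", "t1", "t2"),
                                weight = c(9L, 4L, 6L)))
  p2 <- findPaths(g2, "s", "DN")
  expect_equal(nrow(p2), 2L)
})
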