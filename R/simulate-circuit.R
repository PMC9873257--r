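#' Parameters for the planted-structure circuit simulator
#'
#' Generates a layered synaptic graph with known ground truth: a seed
#' population split into subtypes (default 21 cells in three subtypes,
#' matching the scale of a second-order projection population), a planted
#' second layer ("3N-like") and third layer ("4N-like"), a planted
#' seed-subtype interconnection motif, sub-threshold spurious edges onto
#' decoy cells, and optional feedback edges from layer 2 back onto seeds.
#'
#' @param n_seed number of seed cells.
#' @param seed_subtypes named integer vector of subtype counts; must sum to
#'   `n_seed`.
#' @param n_layer2,n_layer3 planted cell counts in layers 2 and 3.
#' @param n_decoy decoy cells that receive only sub-threshold edges.
#' @param edge_weight_range integer range (min, max) for planted edge
#'   weights; the minimum must be at least 5 so planted edges pass both the
#'   layer (3) and motif (5) thresholds.
#' @param planted_motif data.frame with columns `from`, `to`, `n_edges`
#'   giving the number of strong seed-to-seed edges per subtype pair.
#' @param region_catalog character vector of region names to annotate
#'   non-seed cells with.
#' @param feedback_fraction fraction of layer-2 cells sending a strong edge
#'   back to a random seed, in `[0, 1]`.
#' @param seed integer seed.
#' @return Validated list of class `"CircuitSimParams"`.
#' @export
circuitSimParams <- function(n_seed = 21L,
                             seed_subtypes = c(mAL3A = 6L, mAL3B = 5L,
                                               mAL4 = 10L),
                             n_layer2 = 32L, n_layer3 = 30L, n_decoy = 8L,
                             edge_weight_range = c(5L, 30L),
                             planted_motif = data.frame(
                               from = c("mAL3A", "mAL3B", "mAL3A", "mAL3B"),
                               to = c("mAL3B", "mAL3A", "mAL4", "mAL4"),
                               n_edges = c(8L, 2L, 2L, 2L)),
                             region_catalog = c("SLP", "SIP", "SMP", "LH",
                                                "MB", "SCL", "AVLP", "PLP"),
                             feedback_fraction = 0.15, seed = 1L) {
  if (sum(seed_subtypes) != n_seed)
    stop("seed_subtypes counts must sum to n_seed", call. = FALSE)
  if (any(c(n_seed, n_layer2, n_layer3, n_decoy) < 0))
    stop("counts must be >= 0", call. = FALSE)
  if (edge_weight_range[1] < 5 || edge_weight_range[2] < edge_weight_range[1])
    stop("edge_weight_range minimum must be >= 5", call. = FALSE)
  if (feedback_fraction < 0 || feedback_fraction > 1)
    stop("feedback_fraction must be in [0, 1]", call. = FALSE)
  if (!all(c(planted_motif$from, planted_motif$to) %in%
             names(seed_subtypes)))
    stop("planted_motif subtypes must be declared in seed_subtypes",
         call. = FALSE)
  structure(list(n_seed = as.integer(n_seed), seed_subtypes = seed_subtypes,
                 n_layer2 = as.integer(n_layer2),
                 n_layer3 = as.integer(n_layer3),
                 n_decoy = as.integer(n_decoy),
                 edge_weight_range = as.integer(edge_weight_range),
                 planted_motif = planted_motif,
                 region_catalog = region_catalog,
                 feedback_fraction = feedback_fraction,
                 seed = as.integer(seed)),
            class = "CircuitSimParams")
}

#' Simulate a layered circuit graph with planted ground truth
#'
#' Builds a [CircuitGraph-class] containing: strong planted edges from seeds
#' to every layer-2 cell and from layer-2 cells to every layer-3 cell
#' (weights uniform in `edge_weight_range`, so every planted edge passes the
#' 3-synapse layer threshold); sub-threshold spurious edges (weight 1-2)
#' onto decoy cells; the planted seed-subtype motif (edges of planted
#' weight, passing the 5-synapse motif threshold); and feedback edges from a
#' `feedback_fraction` of layer-2 cells back onto random seeds. Non-seed
#' cells get 1-3 random output regions, each contralateral with probability
#' 0.2.
#'
#' @param params a [circuitSimParams()] list.
#' @return list with `graph` (a [CircuitGraph-class]) and `groundTruth`:
#'   `seed_ids`, `layer2_members`, `layer3_members`, `lateral_members`
#'   (seeds receiving qualifying seed-to-seed edges), `feedback_seeds`,
#'   `motif_counts` (subtype-by-subtype matrix of planted strong edges) and
#'   the seed.
#' @export
simulateCircuit <- function(params) {
  if (!inherits(params, "CircuitSimParams"))
    params <- do.call(circuitSimParams, as.list(params))
  st <- params$seed_subtypes
  seed_ids <- sprintf("S%03d", seq_len(params$n_seed))
  seed_type <- rep(names(st), times = st)
  l2_ids <- if (params$n_layer2) sprintf("N3_%03d", seq_len(params$n_layer2))
  else character(0)
  l3_ids <- if (params$n_layer3) sprintf("N4_%03d", seq_len(params$n_layer3))
  else character(0)
  decoy_ids <- if (params$n_decoy) sprintf("D%03d", seq_len(params$n_decoy))
  else character(0)
  wlo <- params$edge_weight_range[1]; whi <- params$edge_weight_range[2]

  withSeed(params$seed, {
    pre <- character(0); post <- character(0); wt <- integer(0)
    pairSeen <- new.env(hash = TRUE)
    addEdge <- function(p, q, w) {
      key <- paste0(p, "->", q)
      if (p == q || !is.null(pairSeen[[key]])) return(FALSE)
      pairSeen[[key]] <- TRUE
      pre <<- c(pre, p); post <<- c(post, q); wt <<- c(wt, as.integer(w))
      TRUE
    }
    rw <- function() sample(wlo:whi, 1L)

    ## seeds -> layer 2: 1-4 strong inputs per layer-2 cell
    for (q in l2_ids) {
      ins <- sample(seed_ids, min(1L + stats::rpois(1L, 2), params$n_seed))
      for (p in ins) addEdge(p, q, rw())
    }
    ## layer 2 -> layer 3
    for (q in l3_ids) {
      ins <- sample(l2_ids, min(1L + stats::rpois(1L, 2),
                                length(l2_ids)))
      for (p in ins) addEdge(p, q, rw())
    }
    ## spurious sub-threshold edges onto decoys
    for (q in decoy_ids) {
      for (p in sample(c(seed_ids, l2_ids), 2L))
        addEdge(p, q, sample(1:2, 1L))
    }
    ## planted seed-subtype motif
    motif_counts <- matrix(0L, length(st), length(st),
                           dimnames = list(names(st), names(st)))
    pm <- params$planted_motif
    for (i in seq_len(nrow(pm))) {
      from_cells <- seed_ids[seed_type == pm$from[i]]
      to_cells <- seed_ids[seed_type == pm$to[i]]
      added <- 0L
      tries <- 0L
      while (added < pm$n_edges[i] && tries < 200L) {
        tries <- tries + 1L
        if (addEdge(sample(from_cells, 1L), sample(to_cells, 1L), rw()))
          added <- added + 1L
      }
      motif_counts[pm$from[i], pm$to[i]] <-
        motif_counts[pm$from[i], pm$to[i]] + added
    }
    ## feedback: layer-2 cells -> seeds
    fb <- l2_ids[stats::runif(length(l2_ids)) < params$feedback_fraction]
    feedback_seeds <- character(0)
    for (p in fb) {
      q <- sample(seed_ids, 1L)
      if (addEdge(p, q, rw()))
        feedback_seeds <- c(feedback_seeds, q)
    }
    ## region annotations for non-seed cells
    randRegions <- function() {
      r <- sample(params$region_catalog, sample(1:3, 1L))
      contra <- stats::runif(length(r)) < 0.2
      paste0(r, ifelse(contra, "(C)", ""), collapse = ";")
    }
    all_ids <- c(seed_ids, l2_ids, l3_ids, decoy_ids)
    regions <- c(rep("SLP;SIP", params$n_seed),
                 vapply(c(l2_ids, l3_ids, decoy_ids),
                        function(i) randRegions(), character(1)))
  })

  edges <- data.frame(pre = pre, post = post, weight = wt)
  incoming <- tapply(edges$weight, edges$post, sum)
  total_in <- incoming[all_ids]
  total_in[is.na(total_in)] <- 0
  neurons <- data.frame(
    cell_id = all_ids,
    cell_type = c(seed_type, rep("L2type", params$n_layer2),
                  rep("L3type", params$n_layer3),
                  rep("decoy", params$n_decoy)),
    subtype_group = c(seed_type, rep(NA_character_,
                                     length(all_ids) - params$n_seed)),
    regions = unname(regions),
    total_input_synapses = as.integer(round(total_in * 20)))

  graph <- methods::new("CircuitGraph", neurons = neurons, edges = edges)
  lateral <- unique(edges$post[edges$pre %in% seed_ids &
                                 edges$post %in% seed_ids &
                                 edges$weight >= 3])
  gt <- list(kind = "circuit", seed = params$seed, seed_ids = seed_ids,
             layer2_members = l2_ids, layer3_members = l3_ids,
             decoy_ids = decoy_ids,
             lateral_members = sort(lateral),
             feedback_seeds = sort(unique(feedback_seeds)),
             motif_counts = motif_counts)
  list(graph = graph, groundTruth = gt)
}
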