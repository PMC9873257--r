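## Layered tracing of weighted synaptic connectivity downstream of a seed
## population: threshold-based layer expansion, top-target ranking, subtype
## interconnection motifs, region-projection fractions, feedback detection
## and bounded weighted path search.

#' Construct a circuit graph
#'
#' @param neurons data.frame with at least `cell_id`; optional `cell_type`,
#'   `subtype_group`, `regions` (semicolon-separated tokens, `"(C)"` suffix
#'   marks contralateral), `total_input_synapses` are filled with `NA`.
#' @param edges data.frame with columns `pre`, `post`, `weight`; multiple
#'   rows for the same ordered pair are aggregated by summing weights.
#' @return A [CircuitGraph-class].
#' @export
circuitGraph <- function(neurons, edges) {
  neurons <- as.data.frame(neurons)
  edges <- as.data.frame(edges)
  for (col in c("cell_type", "subtype_group", "regions"))
    if (is.null(neurons[[col]]))
      neurons[[col]] <- rep(NA_character_, nrow(neurons))
  if (is.null(neurons$total_input_synapses))
    neurons$total_input_synapses <- rep(NA_integer_, nrow(neurons))
  neurons$cell_id <- as.character(neurons$cell_id)
  if (nrow(edges)) {
    edges$pre <- as.character(edges$pre)
    edges$post <- as.character(edges$post)
    key <- paste(edges$pre, edges$post, sep = "\r")
    if (anyDuplicated(key)) {
      agg <- tapply(edges$weight, key, sum)
      parts <- strsplit(names(agg), "\r", fixed = TRUE)
      edges <- data.frame(pre = vapply(parts, `[`, "", 1L),
                          post = vapply(parts, `[`, "", 2L),
                          weight = as.integer(agg))
    }
  }
  methods::new("CircuitGraph", neurons = neurons, edges = edges)
}

#' Expand one layer downstream of a source population
#'
#' Admits every neuron that receives at least one edge of weight
#' `edge_min` or more from the source set (the per-edge admission rule used
#' to define third- and fourth-order neurons downstream of a projection
#' population). Each member's reported total sums its qualifying edges from
#' the source set; sub-threshold edges are excluded from the total unless
#' `include_subthreshold_in_total = TRUE`. Source-set members admitted by
#' lateral or feedback edges are retained and flagged via `is_source`.
#'
#' @param graph a [CircuitGraph-class].
#' @param source_set character vector of source cell ids (must exist in the
#'   graph).
#' @param edge_min per-edge synapse threshold (default 3).
#' @param include_subthreshold_in_total logical; when `TRUE`, a member's
#'   total also counts source edges below `edge_min`.
#' @param layer_index integer label for the resulting layer (default 3).
#' @return A [LayerResult-class].
#' @export
downstreamLayer <- function(graph, source_set, edge_min = 3,
                            include_subthreshold_in_total = FALSE,
                            layer_index = 3L) {
  stopifnot(is(graph, "CircuitGraph"))
  nn <- neurons(graph)
  if (!all(source_set %in% nn$cell_id))
    stop("source_set must be a subset of the graph's neurons", call. = FALSE)
  ee <- edges(graph)
  src <- ee[ee$pre %in% source_set, , drop = FALSE]
  memb_ids <- sort(unique(src$post[src$weight >= edge_min]))
  contrib <- src[src$post %in% memb_ids, , drop = FALSE]
  if (!include_subthreshold_in_total)
    contrib <- contrib[contrib$weight >= edge_min, , drop = FALSE]
  typeOf <- stats::setNames(nn$cell_type, nn$cell_id)
  totalInOf <- stats::setNames(nn$total_input_synapses, nn$cell_id)
  regionsOf <- stats::setNames(nn$regions, nn$cell_id)
  rows <- lapply(memb_ids, function(id) {
    e <- contrib[contrib$post == id, , drop = FALSE]
    tot <- sum(e$weight)
    tin <- totalInOf[[id]]
    data.frame(
      cell_id = id, cell_type = typeOf[[id]],
      n_input_cells = length(unique(e$pre)),
      input_types = paste(sort(unique(typeOf[e$pre])), collapse = ","),
      total_synapses = tot,
      percent_input = if (!is.na(tin) && tin > 0) 100 * tot / tin
      else NA_real_,
      regions = regionsOf[[id]],
      is_source = id %in% source_set)
  })
  members <- if (length(rows)) do.call(rbind, rows) else
    data.frame(cell_id = character(0), cell_type = character(0),
               n_input_cells = integer(0), input_types = character(0),
               total_synapses = numeric(0), percent_input = numeric(0),
               regions = character(0), is_source = logical(0))
  methods::new("LayerResult", layerIndex = as.integer(layer_index),
               members = members, edges = contrib)
}

#' Select the top targets of a layer
#'
#' Two selection modes over a [LayerResult-class]: `population_min` keeps
#' members whose total input from the source population is at least `k`
#' synapses (after removing `exclude`, e.g. the seed cells themselves);
#' `top_n` keeps the `n` members with the largest totals, ties broken by
#' ascending cell id for determinism.
#'
#' @param layer a [LayerResult-class].
#' @param k population-total threshold (population_min mode).
#' @param n number of members to keep (top_n mode). Exactly one of `k`, `n`
#'   must be given.
#' @param exclude character vector of cell ids removed before selection.
#' @return A [LayerResult-class] restricted to the selected members.
#' @export
topTargets <- function(layer, k = NULL, n = NULL, exclude = character(0)) {
  stopifnot(is(layer, "LayerResult"))
  if (is.null(k) == is.null(n))
    stop("give exactly one of k (population_min) or n (top_n)",
         call. = FALSE)
  mm <- members(layer)
  mm <- mm[!mm$cell_id %in% exclude, , drop = FALSE]
  if (!is.null(k)) {
    keep <- mm[mm$total_synapses >= k, , drop = FALSE]
  } else {
    if (n <= 0) stop("n must be positive", call. = FALSE)
    if (!nrow(mm)) stop("layer has no members to rank", call. = FALSE)
    o <- order(-mm$total_synapses, mm$cell_id)
    keep <- mm[o[seq_len(min(n, nrow(mm)))], , drop = FALSE]
  }
  rownames(keep) <- NULL
  ee <- edges(layer)
  methods::new("LayerResult", layerIndex = layerIndex(layer),
               members = keep,
               edges = ee[ee$post %in% keep$cell_id, , drop = FALSE])
}

#' Subtype interconnection motif matrix
#'
#' Aggregates edges of weight `edge_min` or more between labeled subtype
#' groups into a from-by-to matrix, either counting qualifying edges
#' (`mode = "count"`) or summing their synapse weights (`mode = "weight"`).
#' Only edges whose both endpoints carry a subtype label are considered;
#' cells listed in the map with a missing label raise an error.
#'
#' @param graph a [CircuitGraph-class].
#' @param subtype_map named character vector `cell_id -> subtype`; defaults
#'   to the graph's non-`NA` `subtype_group` annotations.
#' @param edge_min per-edge synapse threshold (default 5).
#' @param mode `"count"` or `"weight"`.
#' @return numeric matrix, rows = source subtypes, columns = target
#'   subtypes.
#' @export
interconnectionMatrix <- function(graph, subtype_map = NULL, edge_min = 5,
                                  mode = c("count", "weight")) {
  stopifnot(is(graph, "CircuitGraph"))
  mode <- match.arg(mode)
  nn <- neurons(graph)
  if (is.null(subtype_map)) {
    lab <- nn[!is.na(nn$subtype_group), , drop = FALSE]
    subtype_map <- stats::setNames(lab$subtype_group, lab$cell_id)
  }
  if (any(is.na(subtype_map)))
    stop("subtype_map contains unlabeled cells", call. = FALSE)
  groups <- sort(unique(unname(subtype_map)))
  m <- matrix(0, length(groups), length(groups),
              dimnames = list(groups, groups))
  ee <- edges(graph)
  ee <- ee[ee$pre %in% names(subtype_map) &
             ee$post %in% names(subtype_map) &
             ee$weight >= edge_min, , drop = FALSE]
  for (i in seq_len(nrow(ee))) {
    a <- subtype_map[[ee$pre[i]]]
    b <- subtype_map[[ee$post[i]]]
    m[a, b] <- m[a, b] + if (mode == "count") 1 else ee$weight[i]
  }
  m
}

#' Fraction of members projecting to each region
#'
#' For a set of layer members with output-region annotations, the fraction
#' whose regions include each catalog region. Under `side_rule =
#' "ipsi_only"` only ipsilateral annotations count (tokens without the
#' `"(C)"` mark); under `"either"` a contralateral-only annotation also
#' counts.
#'
#' @param layer a [LayerResult-class] (or its `members` data.frame).
#' @param regions character vector of regions to report; defaults to all
#'   regions observed in the members.
#' @param side_rule `"ipsi_only"` (default) or `"either"`.
#' @return named numeric vector of fractions; all-`NA` when there are no
#'   members.
#' @export
regionFractions <- function(layer, regions = NULL,
                            side_rule = c("ipsi_only", "either")) {
  side_rule <- match.arg(side_rule)
  mm <- if (is(layer, "LayerResult")) members(layer) else layer
  parsed <- lapply(mm$regions, function(s) {
    tok <- splitRegions(s)
    if (!length(tok)) return(data.frame(region = character(0),
                                        side = character(0)))
    p <- parseRegionToken(tok)
    data.frame(region = p$region, side = p$side)
  })
  if (is.null(regions))
    regions <- sort(unique(unlist(lapply(parsed, `[[`, "region"))))
  if (!nrow(mm))
    return(stats::setNames(rep(NA_real_, length(regions)), regions))
  vapply(stats::setNames(regions, regions), function(r) {
    hit <- vapply(parsed, function(p) {
      if (side_rule == "ipsi_only")
        any(p$region == r & p$side == "ipsi")
      else any(p$region == r)
    }, logical(1))
    mean(hit)
  }, numeric(1))
}

#' Detect feedback onto the seed population
#'
#' Seeds of `seed_set` that appear as members of a downstream layer (i.e.
#' receive qualifying input from that layer's source population), with the
#' qualifying edges listed.
#'
#' @param layer a [LayerResult-class] built from the same graph.
#' @param seed_set character vector of seed cell ids.
#' @return list with `seeds` (sorted character vector) and `edges`
#'   (data.frame of the qualifying edges onto those seeds).
#' @export
feedbackDetect <- function(layer, seed_set) {
  stopifnot(is(layer, "LayerResult"))
  fb <- sort(intersect(members(layer)$cell_id, seed_set))
  ee <- edges(layer)
  list(seeds = fb, edges = ee[ee$post %in% fb, , drop = FALSE])
}

#' Bounded weighted path search to a target
#'
#' All simple paths from any source cell to the target (a cell id, or a
#' cell type matched against the graph's annotations) using at most
#' `max_intermediates` intermediate nodes and only edges of weight
#' `edge_min` or more. Paths are ranked by their weakest edge (descending),
#' then by total weight (descending).
#'
#' @param graph a [CircuitGraph-class].
#' @param source_set character vector of source cell ids.
#' @param target target cell id or cell type.
#' @param max_intermediates maximum number of intermediate nodes
#'   (default 3).
#' @param edge_min minimum edge weight (default 1).
#' @return data.frame with columns `path` (arrow-joined node sequence),
#'   `hops` (edge count), `min_weight`, `total_weight`, and a list column
#'   `weights` of per-edge weights; zero rows when the target is
#'   unreachable.
#' @export
findPaths <- function(graph, source_set, target, max_intermediates = 3L,
                      edge_min = 1) {
  stopifnot(is(graph, "CircuitGraph"))
  nn <- neurons(graph)
  targets <- if (target %in% nn$cell_id) target
  else nn$cell_id[!is.na(nn$cell_type) & nn$cell_type == target]
  if (!length(targets))
    stop("target not found as cell id or cell type", call. = FALSE)
  ee <- edges(graph)
  ee <- ee[ee$weight >= edge_min, , drop = FALSE]
  empty <- data.frame(path = character(0), hops = integer(0),
                      min_weight = numeric(0), total_weight = numeric(0))
  empty$weights <- list()
  if (!nrow(ee)) return(empty)
  g <- igraph::graph_from_data_frame(
    ee, directed = TRUE,
    vertices = data.frame(name = nn$cell_id))
  wOf <- stats::setNames(ee$weight, paste(ee$pre, ee$post, sep = "\r"))
  rows <- list()
  for (s in intersect(source_set, nn$cell_id)) {
    for (tg in setdiff(targets, s)) {
      ps <- igraph::all_simple_paths(g, from = s, to = tg,
                                     mode = "out",
                                     cutoff = max_intermediates + 1L)
      for (p in ps) {
        v <- igraph::as_ids(p)
        w <- wOf[paste(v[-length(v)], v[-1L], sep = "\r")]
        rows[[length(rows) + 1L]] <-
          list(path = paste(v, collapse = " -> "),
               hops = length(v) - 1L, min_weight = min(w),
               total_weight = sum(w), weights = unname(w))
      }
    }
  }
  if (!length(rows)) return(empty)
  out <- data.frame(
    path = vapply(rows, `[[`, "", "path"),
    hops = vapply(rows, `[[`, 0L, "hops"),
    min_weight = vapply(rows, function(r) as.numeric(r$min_weight),
                        numeric(1)),
    total_weight = vapply(rows, function(r) as.numeric(r$total_weight),
                          numeric(1)))
  out$weights <- lapply(rows, `[[`, "weights")
  o <- order(-out$min_weight, -out$total_weight, out$path)
  out <- out[o, , drop = FALSE]
  rownames(out) <- NULL
  out
}
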