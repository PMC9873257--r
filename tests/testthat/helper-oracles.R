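## Independent brute-force oracles and small fixture builders used across
## the suite. These deliberately re-derive results by direct enumeration,
## separately from the package's implementations.

## All simple paths source -> target as "a -> b -> c" strings, by recursive
## enumeration over the (thresholded) edge table.
brutePaths <- function(ee, sources, target, max_intermediates, edge_min) {
  ee <- ee[ee$weight >= edge_min, , drop = FALSE]
  adj <- split(seq_len(nrow(ee)), ee$pre)
  res <- character(0)
  walk <- function(path) {
    last <- path[length(path)]
    if (last == target && length(path) > 1L) {
      res <<- c(res, paste(path, collapse = " -> "))
      return(invisible())
    }
    if (length(path) > max_intermediates + 1L) return(invisible())
    for (i in adj[[last]]) {
      nxt <- ee$post[i]
      if (!nxt %in% path) walk(c(path, nxt))
    }
  }
  for (s in sources) if (s != target) walk(s)
  sort(res)
}

## Downstream membership and qualifying totals by direct filtering.
bruteLayer <- function(ee, sources, edge_min) {
  src <- ee[ee$pre %in% sources, , drop = FALSE]
  ids <- sort(unique(src$post[src$weight >= edge_min]))
  tot <- vapply(ids, function(id)
    sum(src$weight[src$post == id & src$weight >= edge_min]), numeric(1))
  list(members = ids, totals = stats::setNames(tot, ids))
}

## Subtype motif by direct pair enumeration.
bruteMotif <- function(ee, map, edge_min, mode = "count") {
  groups <- sort(unique(unname(map)))
  m <- matrix(0, length(groups), length(groups),
              dimnames = list(groups, groups))
  for (i in seq_len(nrow(ee))) {
    if (ee$weight[i] < edge_min) next
    a <- map[ee$pre[i]]; b <- map[ee$post[i]]
    if (is.na(a) || is.na(b)) next
    m[a, b] <- m[a, b] + if (mode == "count") 1 else ee$weight[i]
  }
  m
}

## Random directed weighted graph on n nodes.
randomGraph <- function(n, p = 0.15, wmax = 10L) {
  ids <- sprintf("n%02d", seq_len(n))
  ee <- expand.grid(pre = ids, post = ids, stringsAsFactors = FALSE)
  ee <- ee[ee$pre != ee$post & stats::runif(nrow(ee)) < p, , drop = FALSE]
  ee$weight <- sample.int(wmax, nrow(ee), replace = TRUE)
  list(ids = ids, graph = circuitGraph(data.frame(cell_id = ids), ee))
}

## Hand-built trial: one fly with prescribed velocity/position series.
makeTrial <- function(fwd, ang = rep(0, length(fwd)), x = rep(1, length(fwd)),
                      y = rep(1, length(fwd)), frameRate = 30,
                      fly_id = "f1") {
  arenaTrial(data.frame(frame = seq_along(fwd), fly_id = fly_id, x = x,
                        y = y, forward_velocity = fwd,
                        angular_velocity = ang),
             frameRate = frameRate)
}

## Multi-fly trial with constant positions per fly.
makeStaticTrial <- function(xs, ys, n_frames, frameRate = 30) {
  n <- length(xs)
  arenaTrial(data.frame(
    frame = rep(seq_len(n_frames), times = n),
    fly_id = rep(sprintf("f%02d", seq_len(n)), each = n_frames),
    x = rep(xs, each = n_frames), y = rep(ys, each = n_frames),
    forward_velocity = 0, angular_velocity = 0), frameRate = frameRate)
}
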