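## Internal helpers shared across modules.

#' Assign arena quadrants
#'
#' Maps arena-centred coordinates to quadrant labels Q1..Q4 (Q1 = x>=0,y>=0,
#' counter-clockwise). Points exactly on a boundary line are assigned to the
#' lower-indexed adjacent quadrant; the boundary set has measure zero so
#' occupancy statistics are insensitive to this rule.
#'
#' @param x,y numeric vectors of arena-centred coordinates (mm).
#' @return character vector of `"Q1".."Q4"` (`NA` where x or y is `NA`).
#' @export
#' @examples
#' quadrantOf(c(1, -1, -1, 1, 0), c(1, 1, -1, -1, 2))
quadrantOf <- function(x, y) {
  stopifnot(length(x) == length(y))
  q <- rep(NA_character_, length(x))
  q[x >= 0 & y >= 0] <- "Q1"
  q[x < 0 & y >= 0] <- "Q2"
  q[x <= 0 & y < 0] <- "Q3"
  q[x > 0 & y < 0] <- "Q4"
  q
}

## Merge possibly-overlapping intervals; df with start/end, returns sorted
## disjoint intervals. Touching intervals (end == next start) are merged.
mergeIntervals <- function(start, end) {
  if (!length(start))
    return(data.frame(start = numeric(0), end = numeric(0)))
  o <- order(start, end)
  start <- start[o]; end <- end[o]
  ms <- start[1L]; me <- end[1L]
  out_s <- numeric(0); out_e <- numeric(0)
  for (i in seq_along(start)[-1L]) {
    if (start[i] <= me + 1e-12) {
      me <- max(me, end[i])
    } else {
      out_s <- c(out_s, ms); out_e <- c(out_e, me)
      ms <- start[i]; me <- end[i]
    }
  }
  data.frame(start = c(out_s, ms), end = c(out_e, me))
}

## Centered 3-point moving average with shrinking edges (k must be odd).
movingAverage <- function(x, k = 3L) {
  n <- length(x)
  if (n == 0L || k <= 1L) return(x)
  half <- (k - 1L) %/% 2L
  vapply(seq_len(n), function(i) {
    idx <- max(1L, i - half):min(n, i + half)
    mean(x[idx])
  }, numeric(1))
}

## Mean of a window with NA (lost-track) exclusion; errors when more than
## half of the frames are missing.
windowMean <- function(x, what = "window") {
  if (!length(x))
    stop(sprintf("empty %s", what), call. = FALSE)
  frac_na <- mean(is.na(x))
  if (frac_na > 0.5)
    stop(sprintf("more than 50%% of frames missing in %s", what),
         call. = FALSE)
  mean(x, na.rm = TRUE)
}

## Parse a quadrant mask string ("Q1,Q3" or "ALL") to a character vector.
parseQuadrants <- function(mask) {
  if (length(mask) != 1L || is.na(mask)) stop("invalid quadrant mask")
  if (identical(mask, "ALL")) return(c("Q1", "Q2", "Q3", "Q4"))
  q <- strsplit(mask, ",", fixed = TRUE)[[1]]
  q <- trimws(q)
  if (!length(q) || !all(q %in% c("Q1", "Q2", "Q3", "Q4")))
    stop("quadrant mask must be 'ALL' or a comma-separated subset of Q1..Q4")
  unique(q)
}

## Split a region annotation string into tokens; handles the separators and
## typographic quirks seen in published connectivity tables (comma or
## semicolon separated, stray double/trailing separators, whitespace).
splitRegions <- function(s) {
  if (is.na(s) || !nzchar(trimws(s))) return(character(0))
  tok <- unlist(strsplit(s, "[;,]"))
  tok <- trimws(tok)
  tok[nzchar(tok)]
}

## Region token -> list(region, side). "SMP(C)" -> contra, "SMP" -> ipsi.
parseRegionToken <- function(tok) {
  contra <- grepl("\\(C\\)$", tok)
  region <- sub("\\s*\\(C\\)$", "", tok)
  list(region = region, side = ifelse(contra, "contra", "ipsi"))
}

## Deterministic per-call RNG scope: runs expr with the given seed, restoring
## the caller's RNG state afterwards.
withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv()))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(expr)
}
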