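#' @import methods
NULL

#' Timed stimulation protocol for arena assays
#'
#' Holds the timed light/odor epochs applied to a behavioral arena: when each
#' epoch starts and ends (seconds from trial start), its kind, intensity (in
#' uW/mm2 for light, an odor identifier for odor), which quadrants it is
#' restricted to, and whether the light is continuous or pulsed.
#'
#' @slot epochs data.frame with columns `start`, `end` (numeric, s), `kind`
#'   (`"light"` or `"odor"`), `intensity` (character), `quadrants` (character,
#'   comma-separated subset of Q1..Q4 or `"ALL"`), `pulse` (character,
#'   `"continuous"` or `"pulsed:<freq>"`).
#' @slot sessionLength numeric, total session duration in seconds.
#'
#' @seealso [stimulusProtocol()]
#' @export
setClass("StimulusProtocol",
         slots = c(epochs = "data.frame", sessionLength = "numeric"))

setValidity("StimulusProtocol", function(object) {
  ep <- object@epochs
  need <- c("start", "end", "kind", "intensity", "quadrants", "pulse")
  if (!all(need %in% names(ep)))
    return(paste("epochs must have columns:", paste(need, collapse = ", ")))
  if (length(object@sessionLength) != 1L || object@sessionLength <= 0)
    return("sessionLength must be a single positive number")
  if (nrow(ep)) {
    if (any(ep$start >= ep$end))
      return("every epoch must satisfy start < end")
    if (any(ep$end > object@sessionLength + 1e-9))
      return("epochs must lie within the session")
    if (!all(ep$kind %in% c("light", "odor")))
      return("epoch kind must be 'light' or 'odor'")
    # epochs of the same kind must not overlap
    for (k in unique(ep$kind)) {
      e <- ep[ep$kind == k, , drop = FALSE]
      e <- e[order(e$start), , drop = FALSE]
      if (nrow(e) > 1L && any(e$start[-1L] < e$end[-nrow(e)] - 1e-9))
        return(sprintf("overlapping '%s' epochs are not allowed", k))
    }
  }
  TRUE
})

#' Tracked multi-fly arena trial
#'
#' Per-frame tracker output for one arena trial: position (mm, arena-centred),
#' forward velocity (mm/s) and angular velocity (deg/s) for each fly, at a
#' fixed frame rate. Lost-track frames are `NA`.
#'
#' @slot tracks data.frame with columns `frame` (integer, 1-based), `fly_id`,
#'   `x`, `y` (mm), `forward_velocity` (mm/s), `angular_velocity` (deg/s).
#' @slot frameRate numeric, frames per second.
#' @slot arenaRadius numeric, arena radius in mm.
#'
#' @seealso [arenaTrial()], [simulateArenaTrial()]
#' @export
setClass("ArenaTrial",
         slots = c(tracks = "data.frame", frameRate = "numeric",
                   arenaRadius = "numeric"))

setValidity("ArenaTrial", function(object) {
  tr <- object@tracks
  need <- c("frame", "fly_id", "x", "y", "forward_velocity",
            "angular_velocity")
  if (!all(need %in% names(tr)))
    return(paste("tracks must have columns:", paste(need, collapse = ", ")))
  if (length(object@frameRate) != 1L || object@frameRate <= 0)
    return("frameRate must be a single positive number")
  if (length(object@arenaRadius) != 1L || object@arenaRadius <= 0)
    return("arenaRadius must be a single positive number")
  if (nrow(tr)) {
    n <- tapply(tr$frame, tr$fly_id, length)
    if (length(unique(n)) != 1L)
      return("all flies must have the same number of frames")
    r <- sqrt(tr$x^2 + tr$y^2)
    if (any(r > object@arenaRadius + 1e-6, na.rm = TRUE))
      return("positions must lie within arenaRadius")
  }
  TRUE
})

#' Closed-loop feeding event stream
#'
#' Food-interaction intervals recorded per channel in a two-choice feeding
#' assay, plus the closed-loop light epochs triggered by interactions with the
#' stimulated channel.
#'
#' @slot channels data.frame with columns `channel`, `food`.
#' @slot interactions data.frame with columns `channel`, `start`, `end` (s).
#' @slot lightEpochs data.frame with columns `start`, `end` (s).
#' @slot sessionLength numeric, s.
#'
#' @seealso [eventStream()], [simulateFeedingSession()]
#' @export
setClass("EventStream",
         slots = c(channels = "data.frame", interactions = "data.frame",
                   lightEpochs = "data.frame", sessionLength = "numeric"))

setValidity("EventStream", function(object) {
  ia <- object@interactions
  if (!all(c("channel", "start", "end") %in% names(ia)))
    return("interactions must have columns channel, start, end")
  if (!all(c("start", "end") %in% names(object@lightEpochs)))
    return("lightEpochs must have columns start, end")
  if (length(object@sessionLength) != 1L || object@sessionLength <= 0)
    return("sessionLength must be a single positive number")
  if (nrow(ia)) {
    if (any(ia$start >= ia$end))
      return("every interaction must satisfy start < end")
    if (any(ia$start < 0) || any(ia$end > object@sessionLength + 1e-9))
      return("interactions must lie within the session")
    if (!all(ia$channel %in% object@channels$channel))
      return("interaction channels must be declared in channels")
  }
  TRUE
})

#' Single-trial calcium fluorescence trace
#'
#' Per-frame ROI-mean fluorescence for one stimulation trial, with the
#' stimulus onset frame (1-based; at least 20 baseline frames must precede
#' it), stimulus duration and the trial's position in a repeated-stimulation
#' series.
#'
#' @slot f numeric, per-frame fluorescence (arbitrary units).
#' @slot frameRate numeric, frames per second.
#' @slot stimOnsetFrame integer, 1-based frame index of stimulus onset.
#' @slot stimDuration numeric, stimulus duration in seconds (default 5).
#' @slot trialIndex integer, 1-based index within the stimulation series.
#'
#' @seealso [calciumTrace()], [simulateCalciumTrials()], [dff()]
#' @export
setClass("CalciumTrace",
         slots = c(f = "numeric", frameRate = "numeric",
                   stimOnsetFrame = "integer", stimDuration = "numeric",
                   trialIndex = "integer"))

setValidity("CalciumTrace", function(object) {
  if (length(object@frameRate) != 1L || object@frameRate <= 0)
    return("frameRate must be a single positive number")
  if (length(object@stimOnsetFrame) != 1L || object@stimOnsetFrame < 21L)
    return("stimOnsetFrame must leave at least 20 pre-stimulus frames")
  if (object@stimOnsetFrame > length(object@f))
    return("stimOnsetFrame beyond end of trace")
  if (length(object@stimDuration) != 1L || object@stimDuration <= 0)
    return("stimDuration must be a single positive number")
  TRUE
})

#' Weighted directed synaptic circuit graph
#'
#' Neurons with cell-type, optional seed-subtype labels and output-region
#' annotations (region names suffixed "(C)" for contralateral), plus directed
#' synapse-count edges aggregated to at most one edge per ordered pair.
#'
#' @slot neurons data.frame with columns `cell_id`, `cell_type`,
#'   `subtype_group` (NA when not a seed cell), `regions` (semicolon-separated
#'   region tokens, "(C)" suffix for contralateral), `total_input_synapses`
#'   (NA when unknown).
#' @slot edges data.frame with columns `pre`, `post` (cell ids) and `weight`
#'   (positive integer synapse count).
#'
#' @seealso [circuitGraph()], [simulateCircuit()], [downstreamLayer()]
#' @export
setClass("CircuitGraph",
         slots = c(neurons = "data.frame", edges = "data.frame"))

setValidity("CircuitGraph", function(object) {
  nn <- object@neurons
  ee <- object@edges
  need <- c("cell_id", "cell_type", "subtype_group", "regions",
            "total_input_synapses")
  if (!all(need %in% names(nn)))
    return(paste("neurons must have columns:", paste(need, collapse = ", ")))
  if (!all(c("pre", "post", "weight") %in% names(ee)))
    return("edges must have columns pre, post, weight")
  if (anyDuplicated(nn$cell_id))
    return("cell_id must be unique")
  if (nrow(ee)) {
    if (!all(ee$pre %in% nn$cell_id) || !all(ee$post %in% nn$cell_id))
      return("edge endpoints must be declared neurons")
    if (any(ee$weight < 1) || any(ee$weight != round(ee$weight)))
      return("edge weights must be positive integers")
    if (anyDuplicated(paste(ee$pre, ee$post)))
      return("at most one edge per ordered pair (pre-aggregate weights)")
  }
  TRUE
})

#' One traversal layer of a circuit graph
#'
#' Result of expanding one layer downstream of a source population under a
#' per-edge synapse threshold: each admitted member with its total input from
#' the source set, the contributing source cells and cell types, and (when
#' the graph carries total input counts) the percent of the member's input
#' that comes from the source set.
#'
#' @slot layerIndex integer layer label (2 = seed, 3, 4, ...).
#' @slot members data.frame with columns `cell_id`, `cell_type`,
#'   `n_input_cells`, `input_types` (comma-separated), `total_synapses`,
#'   `percent_input` (NA when unavailable), `regions`, `is_source` (logical:
#'   member also belongs to the source set, i.e. lateral/feedback).
#' @slot edges data.frame of the qualifying contributing edges
#'   (`pre`, `post`, `weight`).
#'
#' @seealso [downstreamLayer()], [topTargets()], [readCircuitTable()]
#' @export
setClass("LayerResult",
         slots = c(layerIndex = "integer", members = "data.frame",
                   edges = "data.frame"))

setValidity("LayerResult", function(object) {
  mm <- object@members
  need <- c("cell_id", "cell_type", "n_input_cells", "input_types",
            "total_synapses", "percent_input", "regions")
  if (!all(need %in% names(mm)))
    return(paste("members must have columns:", paste(need, collapse = ", ")))
  if (anyDuplicated(mm$cell_id))
    return("member cell_id must be unique")
  TRUE
})
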