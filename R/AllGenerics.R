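#' @include AllClasses.R
NULL

#' Accessors for BitterCircuit classes
#'
#' Small accessor generics returning the underlying slots of the S4
#' containers; user code should use these rather than `@`.
#'
#' @param object an object of the documented class.
#' @return The slot value (a data.frame or scalar, see each class).
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("epochs", function(object) standardGeneric("epochs"))

#' @rdname accessors
#' @export
setGeneric("sessionLength", function(object) standardGeneric("sessionLength"))

#' @rdname accessors
#' @export
setGeneric("tracks", function(object) standardGeneric("tracks"))

#' @rdname accessors
#' @export
setGeneric("frameRate", function(object) standardGeneric("frameRate"))

#' @rdname accessors
#' @export
setGeneric("arenaRadius", function(object) standardGeneric("arenaRadius"))

#' @rdname accessors
#' @export
setGeneric("interactions", function(object) standardGeneric("interactions"))

#' @rdname accessors
#' @export
setGeneric("lightEpochs", function(object) standardGeneric("lightEpochs"))

#' @rdname accessors
#' @export
setGeneric("channels", function(object) standardGeneric("channels"))

#' @rdname accessors
#' @export
setGeneric("fluorescence", function(object) standardGeneric("fluorescence"))

#' @rdname accessors
#' @export
setGeneric("stimOnsetFrame", function(object) standardGeneric("stimOnsetFrame"))

#' @rdname accessors
#' @export
setGeneric("stimDuration", function(object) standardGeneric("stimDuration"))

#' @rdname accessors
#' @export
setGeneric("trialIndex", function(object) standardGeneric("trialIndex"))

#' @rdname accessors
#' @export
setGeneric("neurons", function(object) standardGeneric("neurons"))

#' @rdname accessors
#' @export
setGeneric("edges", function(object) standardGeneric("edges"))

#' @rdname accessors
#' @export
setGeneric("members", function(object) standardGeneric("members"))

#' @rdname accessors
#' @export
setGeneric("layerIndex", function(object) standardGeneric("layerIndex"))

## ---- methods -------------------------------------------------------------

#' @rdname accessors
setMethod("epochs", "StimulusProtocol", function(object) object@epochs)

#' @rdname accessors
setMethod("sessionLength", "StimulusProtocol",
          function(object) object@sessionLength)

#' @rdname accessors
setMethod("sessionLength", "EventStream", function(object) object@sessionLength)

#' @rdname accessors
setMethod("tracks", "ArenaTrial", function(object) object@tracks)

#' @rdname accessors
setMethod("frameRate", "ArenaTrial", function(object) object@frameRate)

#' @rdname accessors
setMethod("frameRate", "CalciumTrace", function(object) object@frameRate)

#' @rdname accessors
setMethod("arenaRadius", "ArenaTrial", function(object) object@arenaRadius)

#' @rdname accessors
setMethod("interactions", "EventStream", function(object) object@interactions)

#' @rdname accessors
setMethod("lightEpochs", "EventStream", function(object) object@lightEpochs)

#' @rdname accessors
setMethod("channels", "EventStream", function(object) object@channels)

#' @rdname accessors
setMethod("fluorescence", "CalciumTrace", function(object) object@f)

#' @rdname accessors
setMethod("stimOnsetFrame", "CalciumTrace",
          function(object) object@stimOnsetFrame)

#' @rdname accessors
setMethod("stimDuration", "CalciumTrace", function(object) object@stimDuration)

#' @rdname accessors
setMethod("trialIndex", "CalciumTrace", function(object) object@trialIndex)

#' @rdname accessors
setMethod("neurons", "CircuitGraph", function(object) object@neurons)

#' @rdname accessors
setMethod("edges", "CircuitGraph", function(object) object@edges)

#' @rdname accessors
setMethod("edges", "LayerResult", function(object) object@edges)

#' @rdname accessors
setMethod("members", "LayerResult", function(object) object@members)

#' @rdname accessors
setMethod("layerIndex", "LayerResult", function(object) object@layerIndex)

## ---- show ----------------------------------------------------------------

setMethod("show", "StimulusProtocol", function(object) {
  cat(sprintf("StimulusProtocol: %d epoch(s), session %.1f s\n",
              nrow(object@epochs), object@sessionLength))
  if (nrow(object@epochs))
    print(utils::head(object@epochs, 10L), row.names = FALSE)
})

setMethod("show", "ArenaTrial", function(object) {
  tr <- object@tracks
  cat(sprintf(
    "ArenaTrial: %d flies x %d frames @ %g fps, arena radius %g mm\n",
    length(unique(tr$fly_id)),
    if (nrow(tr)) max(tr$frame) else 0L,
    object@frameRate, object@arenaRadius))
})

setMethod("show", "EventStream", function(object) {
  cat(sprintf(
    "EventStream: %d channel(s), %d interaction(s), %d light epoch(s), session %.0f s\n",
    nrow(object@channels), nrow(object@interactions),
    nrow(object@lightEpochs), object@sessionLength))
})

setMethod("show", "CalciumTrace", function(object) {
  cat(sprintf(
    "CalciumTrace: trial %d, %d frames @ %g fps, stim onset frame %d (%g s stim)\n",
    object@trialIndex, length(object@f), object@frameRate,
    object@stimOnsetFrame, object@stimDuration))
})

setMethod("show", "CircuitGraph", function(object) {
  cat(sprintf("CircuitGraph: %d neurons, %d edges (total weight %d)\n",
              nrow(object@neurons), nrow(object@edges),
              as.integer(sum(object@edges$weight))))
})

setMethod("show", "LayerResult", function(object) {
  cat(sprintf("LayerResult: layer %d, %d member(s)\n",
              object@layerIndex, nrow(object@members)))
  if (nrow(object@members)) {
    m <- object@members
    m <- m[order(-m$total_synapses, m$cell_id), , drop = FALSE]
    print(utils::head(m[, c("cell_id", "cell_type", "n_input_cells",
                            "total_synapses")], 10L), row.names = FALSE)
  }
})
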