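## Readers and writers for the tabular formats consumed and produced by the
## analysis modules: tracker tables, protocols, interaction tables, ROI
## traces, and circuit connectivity tables (edge lists and printed-table
## style summaries).

#' Construct an arena trial from a tracker table
#'
#' @param tracks data.frame with columns `frame`, `fly_id`, `x`, `y`,
#'   `forward_velocity`, `angular_velocity`.
#' @param frameRate frames per second (default 30).
#' @param arenaRadius arena radius, mm (default 50).
#' @return An [ArenaTrial-class].
#' @export
arenaTrial <- function(tracks, frameRate = 30, arenaRadius = 50) {
  methods::new("ArenaTrial", tracks = as.data.frame(tracks),
               frameRate = frameRate, arenaRadius = arenaRadius)
}

## Sniff the field separator of a small delimited text file.
sniffSep <- function(file) {
  line <- readLines(file, n = 1L)
  if (grepl("\t", line)) "\t" else ","
}

#' Read a tracker output table
#'
#' Reads tab- or comma-separated tracker output with columns `frame`,
#' `fly_id`, `x`, `y`, `forward_velocity`, `angular_velocity`.
#'
#' @param file path.
#' @param frameRate,arenaRadius trial metadata (see [arenaTrial()]).
#' @return An [ArenaTrial-class].
#' @export
readTrajectories <- function(file, frameRate = 30, arenaRadius = 50) {
  tr <- utils::read.delim(file, sep = sniffSep(file),
                          stringsAsFactors = FALSE)
  arenaTrial(tr, frameRate = frameRate, arenaRadius = arenaRadius)
}

#' @rdname readTrajectories
#' @param trial an [ArenaTrial-class] to write.
#' @export
writeTrajectories <- function(trial, file) {
  utils::write.table(tracks(trial), file, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(file)
}

#' Read or write a stimulation protocol (YAML or JSON)
#'
#' The serialized protocol is a mapping with `session_length` and an
#' `epochs` list of records (`start`, `end`, `kind`, `intensity`,
#' `quadrants`, `pulse`).
#'
#' @param file path; format chosen by extension (`.json` vs `.yaml`/`.yml`).
#' @return A [StimulusProtocol-class].
#' @export
readProtocol <- function(file) {
  obj <- if (grepl("\\.json$", file, ignore.case = TRUE))
    jsonlite::read_json(file, simplifyVector = TRUE)
  else yaml::read_yaml(file)
  ep <- if (is.data.frame(obj$epochs)) obj$epochs
  else as.data.frame(do.call(rbind, lapply(obj$epochs, as.data.frame)))
  stimulusProtocol(ep, sessionLength = obj$session_length)
}

#' @rdname readProtocol
#' @param protocol a [StimulusProtocol-class] to write.
#' @export
writeProtocol <- function(protocol, file) {
  obj <- list(session_length = sessionLength(protocol),
              epochs = lapply(seq_len(nrow(epochs(protocol))), function(i)
                as.list(epochs(protocol)[i, ])))
  if (grepl("\\.json$", file, ignore.case = TRUE))
    jsonlite::write_json(obj, file, auto_unbox = TRUE, digits = NA)
  else yaml::write_yaml(obj, file)
  invisible(file)
}

#' Read or write a feeding interaction table
#'
#' @param file path to a CSV/TSV with columns `channel`, `start`, `end`.
#' @param sessionLength session duration, s.
#' @return An [EventStream-class].
#' @export
readInteractions <- function(file, sessionLength) {
  ia <- utils::read.delim(file, sep = sniffSep(file),
                          stringsAsFactors = FALSE)
  eventStream(ia, sessionLength = sessionLength)
}

#' @rdname readInteractions
#' @param stream an [EventStream-class] to write.
#' @export
writeInteractions <- function(stream, file) {
  utils::write.table(interactions(stream), file, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' Read calcium traces from an ROI table plus trial manifest
#'
#' The ROI table has columns `trial`, `frame`, `mean_f`; the manifest has
#' one row per trial with columns `trial`, `onset_frame`, `stim_duration`.
#'
#' @param roi_file,manifest_file paths (CSV/TSV).
#' @param frameRate frames per second.
#' @return list of [CalciumTrace-class], in manifest order.
#' @export
readCalciumTraces <- function(roi_file, manifest_file, frameRate) {
  roi <- utils::read.delim(roi_file, sep = sniffSep(roi_file))
  man <- utils::read.delim(manifest_file, sep = sniffSep(manifest_file))
  lapply(seq_len(nrow(man)), function(i) {
    tr <- roi[roi$trial == man$trial[i], , drop = FALSE]
    tr <- tr[order(tr$frame), , drop = FALSE]
    calciumTrace(tr$mean_f, frameRate = frameRate,
                 stimOnsetFrame = man$onset_frame[i],
                 stimDuration = man$stim_duration[i],
                 trialIndex = man$trial[i])
  })
}

#' Write a list of calcium traces as an ROI table plus manifest
#'
#' @param traces list of [CalciumTrace-class].
#' @param roi_file,manifest_file output paths (TSV).
#' @export
writeCalciumTraces <- function(traces, roi_file, manifest_file) {
  roi <- do.call(rbind, lapply(traces, function(tr)
    data.frame(trial = trialIndex(tr),
               frame = seq_along(fluorescence(tr)),
               mean_f = fluorescence(tr))))
  man <- do.call(rbind, lapply(traces, function(tr)
    data.frame(trial = trialIndex(tr), onset_frame = stimOnsetFrame(tr),
               stim_duration = stimDuration(tr))))
  utils::write.table(roi, roi_file, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  utils::write.table(man, manifest_file, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(roi_file)
}

#' Default brain-region catalog
#'
#' The region abbreviations used in the bundled superior-protocerebrum
#' connectivity tables (NeuPrint nomenclature).
#'
#' @return character vector of region abbreviations.
#' @export
defaultRegionCatalog <- function() {
  c("AOTU", "AVLP", "GOR", "IB", "ICL", "LH", "MB", "PLP", "SCL", "SIP",
    "SLP", "SMP", "VES", "CAN", "CRE", "LAL", "POC", "PVLP", "SPS", "mALT")
}

#' Read a circuit connectivity table
#'
#' Two dialects are supported. `edge_list`: a TSV with columns `pre_id`,
#' `post_id`, `weight`, optionally accompanied by a neuron annotation TSV
#' (`cell_id`, `cell_type`, `subtype_group`, `regions`,
#' `total_input_synapses`); returns a [CircuitGraph-class].
#' `summary_table`: a printed-table style TSV with columns `cell_type`,
#' `cell_id`, `n_input_cells`, `input_types`, `n_synapses`,
#' `percent_input`, `target_regions` (region lists comma-separated, `"(C)"`
#' marks contralateral; stray double or trailing separators are tolerated);
#' returns a [LayerResult-class].
#'
#' @param file path to the table.
#' @param dialect `"edge_list"` or `"summary_table"`.
#' @param neurons_file optional neuron annotation TSV (edge_list dialect).
#' @param layer_index layer label for the summary_table dialect (default 3).
#' @param region_catalog optional character vector; when given, region
#'   tokens outside it are handled per `unknown_regions`.
#' @param unknown_regions `"extend"` (warn and accept, default) or
#'   `"reject"` (error).
#' @return A [CircuitGraph-class] or [LayerResult-class].
#' @export
readCircuitTable <- function(file, dialect = c("edge_list", "summary_table"),
                             neurons_file = NULL, layer_index = 3L,
                             region_catalog = NULL,
                             unknown_regions = c("extend", "reject")) {
  dialect <- match.arg(dialect)
  unknown_regions <- match.arg(unknown_regions)
  checkRegions <- function(region_strings) {
    if (is.null(region_catalog)) return(invisible(NULL))
    toks <- unlist(lapply(region_strings, splitRegions))
    bare <- unique(sub("\\s*\\(C\\)$", "", toks))
    unknown <- setdiff(bare, region_catalog)
    if (length(unknown)) {
      msg <- paste("region tokens outside the catalog:",
                   paste(unknown, collapse = ", "))
      if (unknown_regions == "reject") stop(msg, call. = FALSE)
      warning(msg, call. = FALSE)
    }
    invisible(NULL)
  }
  if (dialect == "edge_list") {
    ee <- utils::read.delim(file, sep = "\t", stringsAsFactors = FALSE,
                            colClasses = c("character", "character",
                                           "integer"))
    names(ee)[1:3] <- c("pre", "post", "weight")
    if (!is.null(neurons_file)) {
      nn <- utils::read.delim(neurons_file, sep = "\t",
                              stringsAsFactors = FALSE,
                              colClasses = "character")
      nn$total_input_synapses <-
        suppressWarnings(as.integer(nn$total_input_synapses))
      nn$subtype_group[nn$subtype_group %in% c("", "NA")] <- NA_character_
      checkRegions(nn$regions)
    } else {
      nn <- data.frame(cell_id = unique(c(ee$pre, ee$post)))
    }
    return(circuitGraph(nn, ee))
  }
  ## summary_table dialect
  tab <- utils::read.delim(file, sep = "\t", stringsAsFactors = FALSE,
                           colClasses = "character")
  need <- c("cell_type", "cell_id", "n_input_cells", "input_types",
            "n_synapses", "percent_input", "target_regions")
  if (!all(need %in% names(tab)))
    stop("summary table must have columns: ",
         paste(need, collapse = ", "), call. = FALSE)
  if (anyDuplicated(tab$cell_id)) {
    dup <- tab$cell_id[duplicated(tab$cell_id)]
    conflicting <- any(vapply(unique(dup), function(id) {
      rows <- tab[tab$cell_id == id, , drop = FALSE]
      nrow(unique(rows)) > 1L
    }, logical(1)))
    if (conflicting)
      stop("duplicate cell_id with conflicting attributes", call. = FALSE)
    tab <- tab[!duplicated(tab$cell_id), , drop = FALSE]
  }
  checkRegions(tab$target_regions)
  members <- data.frame(
    cell_id = tab$cell_id,
    cell_type = tab$cell_type,
    n_input_cells = as.integer(tab$n_input_cells),
    input_types = vapply(tab$input_types, function(s)
      paste(trimws(strsplit(s, ",")[[1]]), collapse = ","), character(1),
      USE.NAMES = FALSE),
    total_synapses = as.numeric(tab$n_synapses),
    percent_input = as.numeric(tab$percent_input),
    regions = tab$target_regions,
    is_source = FALSE)
  methods::new("LayerResult", layerIndex = as.integer(layer_index),
               members = members,
               edges = data.frame(pre = character(0), post = character(0),
                                  weight = integer(0)))
}

#' Write a circuit graph as an edge list plus neuron annotations
#'
#' Inverse of the `edge_list` dialect of [readCircuitTable()]; a
#' write-then-read round trip reproduces the graph.
#'
#' @param graph a [CircuitGraph-class].
#' @param edges_file,neurons_file output paths (TSV).
#' @export
writeCircuitTable <- function(graph, edges_file, neurons_file = NULL) {
  ee <- edges(graph)
  names(ee) <- c("pre_id", "post_id", "weight")
  utils::write.table(ee, edges_file, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  if (!is.null(neurons_file))
    utils::write.table(neurons(graph), neurons_file, sep = "\t",
                       row.names = FALSE, quote = FALSE, na = "NA")
  invisible(edges_file)
}

#' Bundled downstream-connectivity tables
#'
#' Paths to the packaged summary tables of the two traced layers downstream
#' of the mlSEZt second-order bitter projection population: the third-order
#' cells receiving at least 20 synapses from the population
#' (`"layer3"`), and the 30 fourth-order cells receiving the strongest
#' top-third-order input (`"layer4"`).
#'
#' @param which `"layer3"` or `"layer4"`.
#' @return path to the TSV fixture.
#' @export
#' @examples
#' t3 <- readCircuitTable(circuitTableFixture("layer3"), "summary_table")
#' nrow(members(t3))
circuitTableFixture <- function(which = c("layer3", "layer4")) {
  which <- match.arg(which)
  fn <- switch(which, layer3 = "mlsezt_3n_inputs.tsv",
               layer4 = "mlsezt_4n_inputs.tsv")
  system.file("extdata", fn, package = "BitterCircuit", mustWork = TRUE)
}
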