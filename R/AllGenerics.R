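## Accessor generics.  Slot access stays internal to the package.

#' @rdname accessors
#' @param object an occupop S4 object.
#' @export
setGeneric("treeNodes", function(object) standardGeneric("treeNodes"))

#' @rdname accessors
#' @export
setGeneric("occurrences", function(object) standardGeneric("occurrences"))

#' @rdname accessors
#' @export
setGeneric("scheduleEvents", function(object) standardGeneric("scheduleEvents"))

#' @rdname accessors
#' @export
setGeneric("lineageCounts", function(object) standardGeneric("lineageCounts"))

#' @rdname accessors
#' @export
setGeneric("probValues", function(object) standardGeneric("probValues"))

#' @rdname accessors
#' @export
setGeneric("posteriorTimes", function(object) standardGeneric("posteriorTimes"))

#' @rdname accessors
#' @export
setGeneric("posteriorMatrix", function(object) standardGeneric("posteriorMatrix"))

#' @rdname accessors
#' @export
setGeneric("logDensity", function(object) standardGeneric("logDensity"))

#' Accessors for occupop objects
#'
#' `treeNodes` returns the node table of a [ReconTree-class];
#' `occurrences` the (time, status) data.frame of an
#' [OccurrenceRecord-class] or [SimOutcome-class]; `scheduleEvents` and
#' `lineageCounts` the event table and per-epoch lineage counts of an
#' [EventSchedule-class]; `probValues` the rescaled numeric vector of a
#' [ProbVector-class] (values multiplied by `exp(logScale)`);
#' `posteriorTimes`, `posteriorMatrix` and `logDensity` the grid, the
#' row-stochastic posterior matrix and the log joint density of a
#' [PosteriorGrid-class].
#'
#' @name accessors
#' @rdname accessors
NULL

#' @rdname accessors
#' @export
setMethod("treeNodes", "ReconTree", function(object) object@nodes)

#' @rdname accessors
#' @export
setMethod("occurrences", "OccurrenceRecord", function(object) object@record)

#' @rdname accessors
#' @export
setMethod("occurrences", "SimOutcome", function(object) object@occurrences@record)

#' @rdname accessors
#' @export
setMethod("scheduleEvents", "EventSchedule", function(object) object@events)

#' @rdname accessors
#' @export
setMethod("lineageCounts", "EventSchedule", function(object) object@kEpoch)

#' @rdname accessors
#' @export
setMethod("probValues", "ProbVector",
          function(object) object@values * exp(object@logScale))

#' @rdname accessors
#' @export
setMethod("posteriorTimes", "PosteriorGrid", function(object) object@times)

#' @rdname accessors
#' @export
setMethod("posteriorMatrix", "PosteriorGrid", function(object) object@probs)

#' @rdname accessors
#' @export
setMethod("logDensity", "PosteriorGrid", function(object) object@logDensity)
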