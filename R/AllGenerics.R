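#' @name dispersalTraits-generics
#' @title Generics for trajectory containers
#' @description Accessor and metric generics for the S4 movement containers.
#' @param object,x an object.
#' @param ... passed to methods.
#' @keywords internal
NULL

#' @rdname dispersalTraits-generics
#' @export
setGeneric("trackId", function(object) standardGeneric("trackId"))

#' @rdname dispersalTraits-generics
#' @export
setGeneric("frames", function(object) standardGeneric("frames"))

#' @rdname dispersalTraits-generics
#' @export
setGeneric("coords", function(object) standardGeneric("coords"))

#' @rdname dispersalTraits-generics
#' @export
setGeneric("tracks", function(object) standardGeneric("tracks"))

#' @rdname dispersalTraits-generics
#' @export
setGeneric("replicateId", function(object) standardGeneric("replicateId"))

#' @rdname dispersalTraits-generics
#' @export
setGeneric("regime", function(object) standardGeneric("regime"))

#' @rdname dispersalTraits-generics
#' @export
setGeneric("fps", function(object) standardGeneric("fps"))

#' @rdname dispersalTraits-generics
#' @export
setGeneric("mmPerPx", function(object) standardGeneric("mmPerPx"))

#' @rdname dispersalTraits-generics
#' @export
setGeneric("isDegenerate", function(object) standardGeneric("isDegenerate"))

#' Arena bounds of a replicate recording
#'
#' The arena edge is defined from the data itself: the maximum and minimum
#' x and y locations recorded across the whole replicate (all tracks pooled).
#'
#' @param rec a [ReplicateRecording-class] with at least one detection.
#' @return An [ArenaBounds-class] object.
#' @export
setGeneric("arenaBounds", function(rec) standardGeneric("arenaBounds"))

#' @rdname pathLengthRate
#' @export
setGeneric("pathLengthRate",
           function(track, fps) standardGeneric("pathLengthRate"))

#' @rdname rediscretize
#' @export
setGeneric("rediscretize", function(x, p) standardGeneric("rediscretize"))

#' @rdname sinuosity
#' @export
setGeneric("sinuosity", function(x, p) standardGeneric("sinuosity"))

#' @rdname edgeAffinity
#' @export
setGeneric("edgeAffinity",
           function(rec, marginMm = 10) standardGeneric("edgeAffinity"))

#' @rdname summarizeReplicate
#' @export
setGeneric("summarizeReplicate",
           function(rec, pValues = c(10, 20), marginMm = 10,
                    minTrackPoints = 2L)
             standardGeneric("summarizeReplicate"))
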