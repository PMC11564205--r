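#' @rdname dispersalTraits-generics
setMethod("trackId", "Track", function(object) object@trackId)

#' @rdname dispersalTraits-generics
setMethod("frames", "Track", function(object) object@frames)

#' @rdname dispersalTraits-generics
setMethod("coords", "Track", function(object) object@xy)

#' @rdname dispersalTraits-generics
setMethod("coords", "RediscretizedPath", function(object) object@points)

#' @rdname dispersalTraits-generics
setMethod("tracks", "ReplicateRecording", function(object) object@tracks)

#' @rdname dispersalTraits-generics
setMethod("replicateId", "ReplicateRecording",
          function(object) object@replicateId)

#' @rdname dispersalTraits-generics
setMethod("replicateId", "MovementSummary",
          function(object) object@replicateId)

#' @rdname dispersalTraits-generics
setMethod("regime", "ReplicateRecording", function(object) object@regime)

#' @rdname dispersalTraits-generics
setMethod("fps", "ReplicateRecording", function(object) object@fps)

#' @rdname dispersalTraits-generics
setMethod("mmPerPx", "ReplicateRecording", function(object) object@mmPerPx)

#' @rdname dispersalTraits-generics
setMethod("isDegenerate", "ArenaBounds", function(object) {
  object@xmax == object@xmin || object@ymax == object@ymin
})

setMethod("length", "Track", function(x) length(x@frames))

setMethod("show", "Track", function(object) {
  cat(sprintf("Track '%s': %d detections, frames %s..%s\n",
              object@trackId, length(object@frames),
              if (length(object@frames)) min(object@frames) else "-",
              if (length(object@frames)) max(object@frames) else "-"))
})

setMethod("show", "ReplicateRecording", function(object) {
  nd <- sum(vapply(object@tracks, length, integer(1)))
  cat(sprintf(
    "ReplicateRecording '%s' (line %s, %s regime, block %s, camera %s)\n",
    object@replicateId, object@lineId, object@regime, object@blockId,
    object@cameraId))
  cat(sprintf("  %d tracks, %d detections, %g fps, scale %s mm/px\n",
              length(object@tracks), nd, object@fps,
              ifelse(is.na(object@mmPerPx), "<unset>",
                     format(object@mmPerPx))))
})

setMethod("show", "ArenaBounds", function(object) {
  cat(sprintf("ArenaBounds: x [%g, %g], y [%g, %g]%s\n",
              object@xmin, object@xmax, object@ymin, object@ymax,
              if (isDegenerate(object)) " (degenerate)" else ""))
})

setMethod("show", "RediscretizedPath", function(object) {
  cat(sprintf("RediscretizedPath: %d points at chord length p = %g\n",
              nrow(object@points), object@p))
})

setMethod("show", "MovementSummary", function(object) {
  cat(sprintf("MovementSummary '%s'\n", object@replicateId))
  cat(sprintf("  path rate: %s px/s over %d tracks (%.1f s tracked)\n",
              format(object@pathRate, digits = 4), object@nTracks,
              object@totalSeconds))
  sv <- paste(sprintf("S(p=%s)=%s", names(object@sinuosity),
                      format(object@sinuosity, digits = 3)),
              collapse = ", ")
  cat("  sinuosity: ", sv, "\n", sep = "")
  cat(sprintf("  edge affinity: %s\n",
              format(object@edgeAffinity, digits = 3)))
})

#' Convert movement summaries to a tidy data.frame
#'
#' @param x a [MovementSummary-class] or a list of them.
#' @param row.names,optional,... ignored (base signature).
#' @return data.frame with one row per replicate: `replicate_id`,
#'   `path_rate_px_s`, one `sinuosity_p<p>` column per rediscretization
#'   distance, `edge_affinity`, `n_tracks`, `total_seconds`.
#' @export
as.data.frame.MovementSummary <- function(x, row.names = NULL,
                                          optional = FALSE, ...) {
  out <- data.frame(replicate_id = x@replicateId,
                    path_rate_px_s = x@pathRate,
                    stringsAsFactors = FALSE)
  for (nm in names(x@sinuosity))
    out[[paste0("sinuosity_p", nm)]] <- unname(x@sinuosity[nm])
  out$edge_affinity <- x@edgeAffinity
  out$n_tracks <- x@nTracks
  out$total_seconds <- x@totalSeconds
  out
}

setMethod("as.data.frame", "MovementSummary", as.data.frame.MovementSummary)

#' Bind a list of MovementSummary objects into one table
#'
#' @param summaries list of [MovementSummary-class] objects.
#' @return data.frame, one row per summary.
#' @export
movementTable <- function(summaries) {
  if (is(summaries, "MovementSummary")) summaries <- list(summaries)
  do.call(rbind, lapply(summaries, as.data.frame))
}
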