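#' Track: one individual's trajectory within a replicate recording
#'
#' A time-ordered sequence of planar detections for a single tracked animal.
#' Coordinates follow the image convention of typical tracker exports:
#' x increases rightward, y increases downward, units are pixels, and frame
#' indices are 0-based integers. Frames need not be consecutive — dropped
#' frames are permitted — but must be strictly increasing.
#'
#' @slot trackId character(1) opaque track identifier.
#' @slot frames integer vector of frame indices, strictly increasing.
#' @slot xy two-column numeric matrix of pixel coordinates, one row per frame.
#'
#' @seealso [ReplicateRecording-class], [pathLengthRate()], [sinuosity()]
#' @export
setClass("Track",
  representation(trackId = "character", frames = "integer", xy = "matrix"))

setValidity("Track", function(object) {
  msg <- character()
  if (length(object@trackId) != 1L) msg <- c(msg, "trackId must be length 1")
  if (!is.numeric(object@xy) || ncol(object@xy) != 2L)
    msg <- c(msg, "xy must be a two-column numeric matrix")
  if (nrow(object@xy) != length(object@frames))
    msg <- c(msg, "frames and xy must have the same length")
  if (length(object@frames) > 1L && any(diff(object@frames) <= 0L))
    msg <- c(msg, "frames must be strictly increasing")
  if (!all(is.finite(object@xy)))
    msg <- c(msg, "all coordinates must be finite")
  if (length(msg)) msg else TRUE
})

#' Construct a Track
#'
#' @param trackId track identifier (coerced to character).
#' @param frames integer frame indices, strictly increasing.
#' @param xy two-column matrix (or xy-coercible data.frame) of pixel
#'   coordinates.
#' @return A [Track-class] object.
#' @examples
#' Track("t1", 0:2, cbind(c(0, 1, 2), c(0, 0, 1)))
#' @export
Track <- function(trackId, frames, xy) {
  xy <- as.matrix(xy)
  storage.mode(xy) <- "double"
  dimnames(xy) <- NULL
  new("Track", trackId = as.character(trackId),
      frames = as.integer(frames), xy = xy)
}

#' ReplicateRecording: all tracks from one arena recording plus metadata
#'
#' Bundles the tracks observed in a single replicate video with the design
#' metadata needed downstream: selection line, regime, temporal block, camera,
#' frame rate, and (optionally) the physical scale of the image. The scale
#' `mmPerPx` is deliberately optional — metrics needing physical units
#' (edge affinity's 10 mm margin) fail loudly when it is absent rather than
#' assuming a calibration.
#'
#' @slot replicateId,lineId,blockId,cameraId character(1) design labels.
#' @slot regime character(1), one of `"high"`, `"low"`, `"control"`.
#' @slot fps numeric(1) frames per second (> 0); recordings in the assay
#'   design run 10 min at 25 fps.
#' @slot mmPerPx numeric(1) millimetres per pixel, or `NA` when uncalibrated.
#' @slot tracks list of [Track-class] objects.
#' @export
setClass("ReplicateRecording",
  representation(replicateId = "character", lineId = "character",
                 regime = "character", blockId = "character",
                 cameraId = "character", fps = "numeric",
                 mmPerPx = "numeric", tracks = "list"))

setValidity("ReplicateRecording", function(object) {
  msg <- character()
  if (!object@regime %in% regimeLevels)
    msg <- c(msg, sprintf("regime must be one of %s",
                          paste(regimeLevels, collapse = ", ")))
  if (!(length(object@fps) == 1L && is.finite(object@fps) && object@fps > 0))
    msg <- c(msg, "fps must be a single positive number")
  if (!(length(object@mmPerPx) == 1L &&
        (is.na(object@mmPerPx) || object@mmPerPx > 0)))
    msg <- c(msg, "mmPerPx must be NA or a single positive number")
  if (!all(vapply(object@tracks, is, logical(1), "Track")))
    msg <- c(msg, "tracks must be a list of Track objects")
  if (length(msg)) msg else TRUE
})

#' Construct a ReplicateRecording
#'
#' @param replicateId,lineId,regime,blockId,cameraId design labels.
#' @param fps frames per second; default 25.
#' @param mmPerPx mm-per-pixel scale, `NA` if uncalibrated.
#' @param tracks list of [Track-class] objects.
#' @return A [ReplicateRecording-class] object.
#' @export
ReplicateRecording <- function(replicateId, lineId, regime,
                               blockId = "1", cameraId = "1",
                               fps = 25, mmPerPx = NA_real_,
                               tracks = list()) {
  new("ReplicateRecording", replicateId = as.character(replicateId),
      lineId = as.character(lineId), regime = as.character(regime),
      blockId = as.character(blockId), cameraId = as.character(cameraId),
      fps = as.numeric(fps), mmPerPx = as.numeric(mmPerPx), tracks = tracks)
}

#' ArenaBounds: data-derived extent of the recording arena
#'
#' The arena edge is inferred from the data as the componentwise minimum and
#' maximum coordinates observed across every track of the replicate, the same
#' convention used to define edge affinity. Bounds may be degenerate (zero
#' width or height, e.g. a single detection); degeneracy is flagged rather
#' than forbidden, and edge affinity is undefined on degenerate bounds.
#'
#' @slot xmin,xmax,ymin,ymax numeric(1) pixel coordinates.
#' @export
setClass("ArenaBounds",
  representation(xmin = "numeric", xmax = "numeric",
                 ymin = "numeric", ymax = "numeric"))

setValidity("ArenaBounds", function(object) {
  msg <- character()
  v <- c(object@xmin, object@xmax, object@ymin, object@ymax)
  if (length(v) != 4L || !all(is.finite(v)))
    msg <- c(msg, "bounds must be four finite numbers")
  else if (object@xmax < object@xmin || object@ymax < object@ymin)
    msg <- c(msg, "xmax must be >= xmin and ymax >= ymin")
  if (length(msg)) msg else TRUE
})

#' @rdname ArenaBounds-class
#' @param xmin,xmax,ymin,ymax pixel extents.
#' @export
ArenaBounds <- function(xmin, xmax, ymin, ymax) {
  new("ArenaBounds", xmin = as.numeric(xmin), xmax = as.numeric(xmax),
      ymin = as.numeric(ymin), ymax = as.numeric(ymax))
}

#' RediscretizedPath: constant-chord resampling of a trajectory
#'
#' Points along the original polyline separated by a constant chord length
#' `p`, produced by [rediscretize()]. By construction the step-length
#' coefficient of variation of such a path is zero, which is what reduces the
#' general sinuosity estimator to its constant-step form.
#'
#' @slot points two-column numeric matrix of resampled coordinates.
#' @slot p numeric(1) chord length in coordinate (pixel) units.
#' @export
setClass("RediscretizedPath",
  representation(points = "matrix", p = "numeric"))

setValidity("RediscretizedPath", function(object) {
  msg <- character()
  if (!is.numeric(object@points) || ncol(object@points) != 2L)
    msg <- c(msg, "points must be a two-column numeric matrix")
  if (!(length(object@p) == 1L && object@p > 0))
    msg <- c(msg, "p must be a single positive number")
  if (length(msg)) msg else TRUE
})

#' MovementSummary: per-replicate activity metrics
#'
#' One row of the replicate-level analysis table: duration-weighted
#' path-length rate (total distance over all tracks divided by total tracked
#' time), mean sinuosity at each rediscretization distance, and the pooled
#' edge affinity. Undefined components (too-short tracks, missing spatial
#' scale, degenerate bounds) are carried as `NA` with contribution counts —
#' missingness is data here, not failure.
#'
#' @slot replicateId character(1).
#' @slot pathRate numeric(1) pixels per second, `NA` if no track qualified.
#' @slot sinuosity named numeric, one value per rediscretization distance p
#'   (names are the p values); units pixel^-1/2.
#' @slot edgeAffinity numeric(1) proportion in `[0, 1]` or `NA`.
#' @slot nTracks integer(1) tracks contributing to the path rate.
#' @slot totalSeconds numeric(1) summed tracked duration.
#' @export
setClass("MovementSummary",
  representation(replicateId = "character", pathRate = "numeric",
                 sinuosity = "numeric", edgeAffinity = "numeric",
                 nTracks = "integer", totalSeconds = "numeric"))

setValidity("MovementSummary", function(object) {
  msg <- character()
  if (!is.na(object@pathRate) && object@pathRate < 0)
    msg <- c(msg, "pathRate must be >= 0")
  if (!is.na(object@edgeAffinity) &&
      (object@edgeAffinity < 0 || object@edgeAffinity > 1))
    msg <- c(msg, "edgeAffinity must lie in [0, 1]")
  if (any(!is.na(object@sinuosity) & object@sinuosity < 0))
    msg <- c(msg, "sinuosity values must be >= 0")
  if (length(msg)) msg else TRUE
})

#' ModelSpec: one row of the regime-comparison model battery
#'
#' Describes a Gaussian identity-link model: a response column, fixed-effect
#' terms (interactions written `"a*b"`), and zero or more random-intercept
#' grouping factors. Specs without random terms are fitted by [stats::lm()],
#' specs with random terms by [lmerTest::lmer()] under REML.
#'
#' @slot response character(1) response column name.
#' @slot fixed character vector of fixed-effect terms.
#' @slot random character vector of random-intercept grouping factors
#'   (possibly empty).
#' @slot data data.frame holding every referenced column.
#' @export
setClass("ModelSpec",
  representation(response = "character", fixed = "character",
                 random = "character", data = "data.frame"))

setValidity("ModelSpec", function(object) {
  msg <- character()
  vars <- unique(unlist(strsplit(c(object@response, object@fixed), "[*:]")))
  vars <- trimws(c(vars, object@random))
  missing <- setdiff(vars, names(object@data))
  if (length(missing))
    msg <- c(msg, paste0("terms not found in data: ",
                         paste(missing, collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' Construct a ModelSpec
#'
#' @param response response column name.
#' @param fixed character vector of fixed-effect terms; write interactions as
#'   `"a*b"` (expanded to main effects plus interaction, as in formulas).
#' @param random character vector of random-intercept grouping factors; empty
#'   for a plain linear model.
#' @param data data.frame with all referenced columns.
#' @return A [ModelSpec-class] object.
#' @examples
#' d <- data.frame(y = rnorm(6), g = rep(c("a", "b"), 3))
#' ModelSpec("y", "g", character(), d)
#' @export
ModelSpec <- function(response, fixed, random = character(), data) {
  new("ModelSpec", response = response, fixed = as.character(fixed),
      random = as.character(random), data = as.data.frame(data))
}
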