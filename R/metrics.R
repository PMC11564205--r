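#' Path-length rate of a single track
#'
#' Total distance travelled, in pixels, per second of tracked time: the sum
#' of consecutive Euclidean chord lengths divided by the elapsed time from
#' first to last frame. Frame gaps contribute their straight-line chord to
#' the distance and their real elapsed time to the duration.
#'
#' @param track a [Track-class] with at least 2 detections.
#' @param fps frames per second of the recording.
#' @return Pixels per second (numeric, >= 0).
#' @examples
#' t <- Track("a", c(0L, 25L), cbind(c(0, 3), c(0, 4)))
#' pathLengthRate(t, 25)  # the 3-4-5 triangle over one second: 5 px/s
#' @rdname pathLengthRate
setMethod("pathLengthRate", signature("Track", "numeric"),
          function(track, fps) {
  if (length(track) < 2L)
    stop("path length undefined: track '", track@trackId,
         "' has fewer than 2 detections")
  if (!(fps > 0)) stop("fps must be positive")
  xy <- track@xy
  dist <- sum(sqrt(diff(xy[, 1])^2 + diff(xy[, 2])^2))
  secs <- (track@frames[length(track@frames)] - track@frames[1]) / fps
  dist / secs
})

#' Constant-chord rediscretization of a track
#'
#' Resamples a trajectory into points separated by a constant chord length
#' `p`: the first point is the first detection; each subsequent point is the
#' first intersection, walking forward along the polyline, of the polyline
#' with the circle of radius `p` centred on the previous resampled point.
#' The walk stops when the remaining polyline never leaves the final circle.
#' Rediscretization removes the dependence of turning-angle statistics on
#' the recording's sampling rate and forces the step-length coefficient of
#' variation to zero.
#'
#' @param x a [Track-class] or a two-column coordinate matrix.
#' @param p chord length in coordinate (pixel) units; the total path length
#'   must be at least `p`.
#' @return A [RediscretizedPath-class]. `NULL` is never returned; an
#'   undefined rediscretization (total path length < p) is an error, which
#'   [summarizeReplicate()] converts to per-track missingness.
#' @examples
#' t <- Track("a", 0:1, cbind(c(0, 10), c(0, 0)))
#' coords(rediscretize(t, 2))  # x = 0, 2, 4, 6, 8, 10
#' @rdname rediscretize
setMethod("rediscretize", signature("matrix", "numeric"), function(x, p) {
  if (!(p > 0)) stop("p must be positive")
  if (nrow(x) < 2L) stop("rediscretization needs at least 2 points")
  total <- sum(sqrt(diff(x[, 1])^2 + diff(x[, 2])^2))
  if (total < p)
    stop(sprintf("total path length (%.3g) is shorter than p = %g",
                 total, p))
  pts <- redisc_chord(x, p)
  new("RediscretizedPath", points = pts, p = p)
})

#' @rdname rediscretize
setMethod("rediscretize", signature("Track", "numeric"),
          function(x, p) rediscretize(coords(x), p))

#' Turning-angle statistics of a rediscretized path
#'
#' Computes the signed turning angles between consecutive steps, wrapped to
#' (-pi, pi], their mean cosine `c`, and the coefficient of variation of the
#' step lengths `b`. For a constant-chord rediscretized path `b` is zero by
#' construction, which is the regime in which the sinuosity estimator
#' simplifies.
#'
#' @param path a [RediscretizedPath-class] (or two-column matrix) with at
#'   least 3 points.
#' @return `list(angles = <numeric>, c = <mean cosine>, b = <step-length CV>)`.
#' @export
turningStats <- function(path) {
  xy <- if (is(path, "RediscretizedPath")) path@points else as.matrix(path)
  if (nrow(xy) < 3L)
    stop("turning statistics need at least 3 points")
  dx <- diff(xy[, 1]); dy <- diff(xy[, 2])
  len <- sqrt(dx^2 + dy^2)
  if (any(len == 0)) stop("zero-length step in path")
  heading <- atan2(dy, dx)
  ang <- diff(heading)
  ang <- ang - 2 * pi * round(ang / (2 * pi))     # wrap to (-pi, pi]
  ang[ang <= -pi] <- ang[ang <= -pi] + 2 * pi
  list(angles = ang, c = mean(cos(ang)), b = sd(len) / mean(len))
}

#' Sinuosity of a track
#'
#' Tortuosity estimator of a path rediscretized at constant step length `p`:
#' \deqn{S = 2 \left[ p \left( \frac{1+c}{1-c} + b^2 \right) \right]^{-1/2}}
#' where `c` is the mean cosine of turning angles and `b` the step-length
#' coefficient of variation (0 on a rediscretized path). A straight path has
#' S = 0 (the c -> 1 limit); larger values mean more tortuous movement.
#' Units are (coordinate unit)^-1/2.
#'
#' @param x a [Track-class], [RediscretizedPath-class], or coordinate matrix.
#' @param p rediscretization step length (pixels). Ignored (taken from the
#'   object) when `x` is already rediscretized.
#' @return S >= 0. Errors if the rediscretized path has fewer than 3 points,
#'   or on the degenerate c = -1, b = 0 path (a perfect back-and-forth),
#'   where the estimator diverges.
#' @examples
#' t <- Track("a", 0:3, cbind(0:3, c(0, 0, 0, 0)))
#' sinuosity(t, 1)  # straight: 0
#' @rdname sinuosity
setMethod("sinuosity", signature("RediscretizedPath", "ANY"),
          function(x, p) {
  if (nrow(x@points) < 3L)
    stop("sinuosity undefined: rediscretized path has fewer than 3 points")
  ts <- turningStats(x)
  cc <- ts$c
  b <- 0   # constant-chord path by construction
  if (cc >= 1) return(0)
  if (cc <= -1) {
    if (b == 0)
      stop("degenerate path: all turns are reversals (c = -1, b = 0); ",
           "sinuosity diverges")
    return(2 / sqrt(x@p * b^2))
  }
  2 / sqrt(x@p * ((1 + cc) / (1 - cc) + b^2))
})

#' @rdname sinuosity
setMethod("sinuosity", signature("Track", "numeric"),
          function(x, p) sinuosity(rediscretize(x, p), p))

#' @rdname sinuosity
setMethod("sinuosity", signature("matrix", "numeric"),
          function(x, p) sinuosity(rediscretize(x, p), p))

#' Edge affinity of a replicate recording
#'
#' Proportion of recorded locations (pooled over all tracks) lying within a
#' physical margin of the arena edge, the edge being defined by the maximum
#' and minimum x and y locations recorded across the whole replicate. A
#' thigmotaxis proxy. The margin is physical (default 10 mm), so the
#' replicate must carry its mm-per-pixel calibration.
#'
#' @param rec a [ReplicateRecording-class] with `mmPerPx` set.
#' @param marginMm margin width in millimetres (default 10).
#' @return Proportion in `[0, 1]`.
#' @rdname edgeAffinity
setMethod("edgeAffinity", "ReplicateRecording",
          function(rec, marginMm = 10) {
  if (is.na(rec@mmPerPx))
    stop("edge affinity needs the physical scale: set mm_per_px for ",
         "replicate '", rec@replicateId, "'")
  b <- arenaBounds(rec)
  if (isDegenerate(b))
    stop("edge affinity undefined: degenerate arena bounds for replicate '",
         rec@replicateId, "'")
  m <- marginMm / rec@mmPerPx
  xy <- do.call(rbind, lapply(rec@tracks, coords))
  near <- xy[, 1] <= b@xmin + m | xy[, 1] >= b@xmax - m |
          xy[, 2] <= b@ymin + m | xy[, 2] >= b@ymax - m
  mean(near)
})

#' Aggregate a replicate's tracks into one MovementSummary
#'
#' Tracks are aggregated to a population-level activity measure per
#' replicate: the path-length rate is duration-weighted (total distance over
#' all usable tracks divided by total tracked seconds), sinuosity at each
#' rediscretization distance is the unweighted mean over tracks for which it
#' is defined, and edge affinity pools all detections. Components that are
#' undefined for every track are `NA` — missingness is recorded, not
#' imputed.
#'
#' @param rec a [ReplicateRecording-class].
#' @param pValues rediscretization distances in pixels (defaults 10 and 20).
#' @param marginMm edge-affinity margin in millimetres (default 10).
#' @param minTrackPoints minimum detections for a track to enter the path
#'   rate (default 2).
#' @return A [MovementSummary-class].
#' @rdname summarizeReplicate
setMethod("summarizeReplicate", "ReplicateRecording",
          function(rec, pValues = c(10, 20), marginMm = 10,
                   minTrackPoints = 2L) {
  usable <- Filter(function(t) length(t) >= max(2L, minTrackPoints),
                   rec@tracks)
  if (length(usable)) {
    dists <- vapply(usable, function(t)
      sum(sqrt(diff(t@xy[, 1])^2 + diff(t@xy[, 2])^2)), numeric(1))
    secs <- vapply(usable, function(t)
      (t@frames[length(t@frames)] - t@frames[1]) / rec@fps, numeric(1))
    rate <- sum(dists) / sum(secs)
  } else {
    rate <- NA_real_
    secs <- numeric(0)
  }

  sinu <- vapply(pValues, function(p) {
    vals <- vapply(usable, function(t) {
      s <- tryCatch(sinuosity(t, p), error = function(e) NA_real_)
      s
    }, numeric(1))
    if (all(is.na(vals))) NA_real_ else mean(vals, na.rm = TRUE)
  }, numeric(1))
  names(sinu) <- as.character(pValues)

  edge <- tryCatch(edgeAffinity(rec, marginMm),
                   error = function(e) NA_real_)

  new("MovementSummary", replicateId = rec@replicateId, pathRate = rate,
      sinuosity = sinu, edgeAffinity = edge,
      nTracks = length(usable), totalSeconds = sum(secs))
})

#' Agreement between automated and manually annotated path distances
#'
#' Pearson product-moment correlation, with a Fisher-z 95% confidence
#' interval, between path distances computed from tracker output and from
#' human-annotated clips of the same recordings — the ground-truthing check
#' for an automated tracking model.
#'
#' @param auto,manual paired numeric vectors of per-clip path distances,
#'   length >= 3.
#' @return `list(r, conf_int, n)`.
#' @examples
#' groundTruthAgreement(c(1, 2, 3, 4), c(2, 4, 6, 9))
#' @export
groundTruthAgreement <- function(auto, manual) {
  if (length(auto) != length(manual))
    stop("auto and manual must be paired vectors of equal length")
  if (length(auto) < 3L) stop("need at least 3 paired clips")
  if (sd(auto) == 0 || sd(manual) == 0)
    stop("correlation undefined: zero variance in one of the vectors")
  ct <- cor.test(auto, manual, method = "pearson", conf.level = 0.95)
  list(r = unname(ct$estimate), conf_int = as.numeric(ct$conf.int),
       n = length(auto))
}
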