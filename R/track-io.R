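#' Read a tracking table and its replicate metadata
#'
#' Parses the tabular export of a multi-animal tracker (one row per
#' detection) together with a metadata table mapping each replicate to its
#' design labels, and assembles one [ReplicateRecording-class] per replicate.
#' Rows within a track are sorted by frame; duplicated (track, frame) pairs
#' are rejected because a tracker cannot detect the same animal twice in one
#' frame.
#'
#' @param tracking path to a CSV (or a data.frame) with columns
#'   `replicate_id, track_id, frame, x, y`.
#' @param metadata path to a CSV (or a data.frame) with columns
#'   `replicate_id, line_id, regime, block_id, camera_id, fps, mm_per_px`
#'   (`mm_per_px` may be empty/NA for uncalibrated recordings).
#' @return Named list of [ReplicateRecording-class] objects, one per
#'   replicate present in `tracking`.
#' @examples
#' trk <- data.frame(replicate_id = "r1", track_id = "t1", frame = 0:1,
#'                   x = c(0, 3), y = c(0, 4))
#' meta <- data.frame(replicate_id = "r1", line_id = "L1", regime = "low",
#'                    block_id = 1, camera_id = 1, fps = 25, mm_per_px = 0.2)
#' readTrackingTable(trk, meta)
#' @export
readTrackingTable <- function(tracking, metadata) {
  trk <- if (is.character(tracking)) read.csv(tracking) else
    as.data.frame(tracking)
  meta <- if (is.character(metadata)) read.csv(metadata) else
    as.data.frame(metadata)

  needTrk <- c("replicate_id", "track_id", "frame", "x", "y")
  missTrk <- setdiff(needTrk, names(trk))
  if (length(missTrk))
    stop("tracking table is missing required column(s): ",
         paste(missTrk, collapse = ", "))
  needMeta <- c("replicate_id", "line_id", "regime", "block_id",
                "camera_id", "fps")
  missMeta <- setdiff(needMeta, names(meta))
  if (length(missMeta))
    stop("metadata table is missing required column(s): ",
         paste(missMeta, collapse = ", "))
  if (!"mm_per_px" %in% names(meta)) meta$mm_per_px <- NA_real_

  for (col in c("frame", "x", "y")) {
    v <- trk[[col]]
    if (!is.numeric(v)) {
      bad <- which(is.na(suppressWarnings(as.numeric(v))))
      stop(sprintf("non-numeric '%s' value at tracking row %d",
                   col, bad[1]))
    }
  }
  if (anyNA(trk$x) || anyNA(trk$y) || anyNA(trk$frame)) {
    bad <- which(is.na(trk$x) | is.na(trk$y) | is.na(trk$frame))
    stop(sprintf("missing coordinate/frame at tracking row %d", bad[1]))
  }

  repIds <- unique(as.character(trk$replicate_id))
  unknown <- setdiff(repIds, as.character(meta$replicate_id))
  if (length(unknown))
    stop("replicates absent from metadata: ", paste(unknown, collapse = ", "))

  recs <- lapply(repIds, function(rid) {
    sub <- trk[as.character(trk$replicate_id) == rid, , drop = FALSE]
    m <- meta[as.character(meta$replicate_id) == rid, , drop = FALSE][1, ]
    trs <- lapply(split(sub, as.character(sub$track_id)), function(tt) {
      tt <- tt[order(tt$frame), , drop = FALSE]
      dup <- duplicated(tt$frame)
      if (any(dup))
        stop(sprintf(
          "duplicated (track, frame) pair: replicate %s, track %s, frame %d",
          rid, tt$track_id[1], tt$frame[which(dup)[1]]))
      Track(tt$track_id[1], tt$frame, cbind(tt$x, tt$y))
    })
    ReplicateRecording(rid, m$line_id, m$regime, m$block_id, m$camera_id,
                       fps = m$fps, mmPerPx = m$mm_per_px,
                       tracks = unname(trs))
  })
  names(recs) <- repIds
  recs
}

#' Write replicate recordings back to tracking + metadata tables
#'
#' Inverse of [readTrackingTable()]: emits the detection-level table and the
#' replicate metadata table. Reading the written files back reproduces every
#' (replicate, track, frame, x, y) tuple exactly.
#'
#' @param recs list of [ReplicateRecording-class] objects.
#' @param trackingFile,metadataFile optional CSV paths; when `NULL` the
#'   corresponding data.frame is only returned.
#' @return Invisibly, `list(tracking = <data.frame>, metadata = <data.frame>)`.
#' @export
writeTrackingTable <- function(recs, trackingFile = NULL,
                               metadataFile = NULL) {
  trk <- do.call(rbind, lapply(recs, function(r) {
    do.call(rbind, lapply(r@tracks, function(t)
      data.frame(replicate_id = r@replicateId, track_id = t@trackId,
                 frame = t@frames, x = t@xy[, 1], y = t@xy[, 2],
                 stringsAsFactors = FALSE)))
  }))
  rownames(trk) <- NULL
  if (!is.null(trackingFile)) {
    # full-precision text so that write -> read round-trips exactly
    onDisk <- trk
    onDisk$x <- sprintf("%.17g", trk$x)
    onDisk$y <- sprintf("%.17g", trk$y)
    write.csv(onDisk, trackingFile, row.names = FALSE, quote = FALSE)
  }
  meta <- do.call(rbind, lapply(recs, function(r)
    data.frame(replicate_id = r@replicateId, line_id = r@lineId,
               regime = r@regime, block_id = r@blockId,
               camera_id = r@cameraId, fps = r@fps, mm_per_px = r@mmPerPx,
               stringsAsFactors = FALSE)))
  rownames(meta) <- NULL
  if (!is.null(metadataFile)) write.csv(meta, metadataFile, row.names = FALSE)
  invisible(list(tracking = trk, metadata = meta))
}

#' Exclude replicates by metadata rule
#'
#' Removes every replicate whose metadata matches any rule, and logs what was
#' removed. This keeps data-quality exclusions (e.g. one misbehaving camera
#' in one block flagged as an extreme outlier during exploration) as explicit,
#' reproducible configuration instead of silent edits.
#'
#' @param recs list of [ReplicateRecording-class] objects.
#' @param exclusions list of rules, each a list/vector with elements `field`
#'   (one of `line_id`, `regime`, `block_id`, `camera_id`, `replicate_id`)
#'   and `value`. A replicate is removed when all fields of any single rule
#'   match (so `list(field = c("camera_id", "block_id"), value = c(11, 2))`
#'   removes camera 11 only within block 2).
#' @return `list(recordings = <kept list>, log = <data.frame>)`; the log has
#'   one row per rule with the number and ids of replicates removed.
#' @examples
#' recs <- list(ReplicateRecording("r1", "L1", "low", cameraId = "11"))
#' excludeRecords(recs, list(list(field = "camera_id", value = "11")))$log
#' @export
excludeRecords <- function(recs, exclusions = list()) {
  fieldSlot <- c(replicate_id = "replicateId", line_id = "lineId",
                 regime = "regime", block_id = "blockId",
                 camera_id = "cameraId")
  keep <- rep(TRUE, length(recs))
  log <- data.frame(rule = character(), n_removed = integer(),
                    removed_ids = character(), stringsAsFactors = FALSE)
  for (rule in exclusions) {
    fields <- as.character(rule$field)
    values <- as.character(rule$value)
    bad <- setdiff(fields, names(fieldSlot))
    if (length(bad))
      stop("exclusion rule names unknown metadata field(s): ",
           paste(bad, collapse = ", "))
    hit <- vapply(recs, function(r)
      all(vapply(seq_along(fields), function(i)
        as.character(slot(r, fieldSlot[[fields[i]]])) == values[i],
        logical(1))), logical(1))
    ids <- vapply(recs[hit & keep], replicateId, character(1))
    log <- rbind(log, data.frame(
      rule = paste(fields, values, sep = "=", collapse = " & "),
      n_removed = length(ids),
      removed_ids = paste(ids, collapse = ";"),
      stringsAsFactors = FALSE))
    keep <- keep & !hit
  }
  list(recordings = recs[keep], log = log)
}

#' @describeIn arenaBounds componentwise min/max over all detections of all
#'   tracks in the replicate.
setMethod("arenaBounds", "ReplicateRecording", function(rec) {
  if (!length(rec@tracks) || !sum(vapply(rec@tracks, length, integer(1))))
    stop("cannot compute arena bounds: replicate '", rec@replicateId,
         "' has no detections")
  xy <- do.call(rbind, lapply(rec@tracks, coords))
  ArenaBounds(min(xy[, 1]), max(xy[, 1]), min(xy[, 2]), max(xy[, 2]))
})
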