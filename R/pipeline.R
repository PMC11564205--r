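#' Default pipeline configuration
#'
#' @return Named list of every recognised configuration key with its default.
#'   Keys: `seed`, `scenario` (`"paper_like"`/`"null"`), `p_values`,
#'   `edge_margin_mm`, `min_track_points`, `exclusions` (list of
#'   field/value rules), `movement` (sub-list: `reps_per_line`,
#'   `duration_s`, `n_individuals`, `fps`, `arena_mm`, `mm_per_px`),
#'   `dispersal_n`, `surface_reps_per_class`, `morph_n_per_cell`.
#' @export
defaultConfig <- function() {
  list(seed = 1L, scenario = "paper_like", p_values = c(10, 20),
       edge_margin_mm = 10, min_track_points = 2L, exclusions = list(),
       movement = list(reps_per_line = 2, duration_s = 600,
                       n_individuals = 10, fps = 25, arena_mm = 110,
                       mm_per_px = 0.2),
       dispersal_n = 200, surface_reps_per_class = 15,
       morph_n_per_cell = 15)
}

loadConfig <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  def <- defaultConfig()
  unknown <- setdiff(names(config), names(def))
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  if (!is.null(config$movement)) {
    badMv <- setdiff(names(config$movement), names(def$movement))
    if (length(badMv))
      stop("unknown movement configuration key(s): ",
           paste(badMv, collapse = ", "))
    config$movement <- modifyList(def$movement, config$movement)
  }
  # exclusion rules are an unnamed list, which modifyList would drop
  excl <- if (is.null(config$exclusions)) def$exclusions else
    config$exclusions
  cfg <- modifyList(def, config[setdiff(names(config), "exclusions")])
  cfg$exclusions <- excl
  cfg
}

#' Run the full analysis pipeline
#'
#' Orchestrates simulate -> metrics -> score -> morph -> models: generates
#' every input with the configured scenario, writes each stage's tidy CSV
#' under `outdir`, fits the model battery, and records a reproducibility
#' manifest (seeds, configuration hash, per-file md5 checksums, row counts,
#' exclusion log). Stages communicate through the CSVs on disk — the
#' tracking tables written by the simulation stage are read back by the
#' metrics stage with the same reader used for real exports — so every
#' stage can be rerun from its predecessor's files with identical results.
#'
#' @param config configuration list or path to a YAML file; see
#'   [defaultConfig()] for the recognised keys. Unknown keys abort before
#'   any computation.
#' @param outdir output directory (created if needed).
#' @return Invisibly, `list(battery, tables, manifest)`.
#' @export
runPipeline <- function(config = list(), outdir = tempfile("pipeline")) {
  cfg <- loadConfig(config)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  eff <- scenarioEffects(cfg$scenario)
  seeds <- deriveSeeds(cfg$seed, 4L)

  # --- simulate ------------------------------------------------------------
  recs <- genMovementStudy(
    eff, repsPerLine = cfg$movement$reps_per_line,
    durationS = cfg$movement$duration_s,
    nIndividuals = cfg$movement$n_individuals, fps = cfg$movement$fps,
    arenaMm = cfg$movement$arena_mm, mmPerPx = cfg$movement$mm_per_px,
    seed = seeds[1])
  trkFile <- file.path(outdir, "tracking.csv")
  metaFile <- file.path(outdir, "metadata.csv")
  writeTrackingTable(recs, trkFile, metaFile)

  dispersal <- genDispersalAssays(eff, n = cfg$dispersal_n, seed = seeds[2])
  surface <- genSurfaceAssays(eff, n = cfg$dispersal_n,
                              repsPerClass = cfg$surface_reps_per_class,
                              seed = seeds[3])
  morph <- genMorphology(eff, nPerCell = cfg$morph_n_per_cell,
                         seed = seeds[4])
  write.csv(dispersal, file.path(outdir, "dispersal.csv"),
            row.names = FALSE)
  write.csv(surface$lines, file.path(outdir, "surface.csv"),
            row.names = FALSE)
  write.csv(surface$selection, file.path(outdir, "surface_selection.csv"),
            row.names = FALSE)
  write.csv(morph$records, file.path(outdir, "morphology.csv"),
            row.names = FALSE)
  write.csv(morph$repeats, file.path(outdir, "morphology_repeats.csv"),
            row.names = FALSE)

  # --- metrics (from the written CSVs, as from a real tracker export) ------
  recs2 <- readTrackingTable(trkFile, metaFile)
  excl <- excludeRecords(recs2, cfg$exclusions)
  summaries <- lapply(excl$recordings, summarizeReplicate,
                      pValues = cfg$p_values, marginMm = cfg$edge_margin_mm,
                      minTrackPoints = cfg$min_track_points)
  mvTab <- movementTable(summaries)
  metaKeep <- writeTrackingTable(excl$recordings)$metadata
  mvTab <- merge(mvTab, metaKeep[, c("replicate_id", "line_id", "regime",
                                     "block_id", "camera_id")],
                 by = "replicate_id", sort = TRUE)
  write.csv(mvTab, file.path(outdir, "movement_summaries.csv"),
            row.names = FALSE)

  # --- morph stage ---------------------------------------------------------
  rep1 <- morph$records[morph$records$individual_id %in%
                          morph$repeats$individual_id, , drop = FALSE]
  rpt <- repeatability(rep1, morph$repeats)
  traits <- setdiff(rpt$retained, character(0))
  cc <- completeCases(morph$records, traits)
  pca <- sizePCA(cc, traits)
  morphTab <- cc
  morphTab$pc1 <- pca$pc1
  morphTab$leg_len <- legLength(morphTab)
  write.csv(rpt$table, file.path(outdir, "repeatability.csv"),
            row.names = FALSE)
  write.csv(morphTab, file.path(outdir, "morphology_scores.csv"),
            row.names = FALSE)

  # --- models --------------------------------------------------------------
  bundle <- list(dispersal = dispersal, movement = mvTab,
                 surface = surface$lines,
                 surface_selection = surface$selection,
                 morphology = morphTab)
  battery <- runTable1Battery(bundle, sinuosityP = cfg$p_values[1])
  coefTab <- batteryTable(battery)
  write.csv(coefTab, file.path(outdir, "model_contrasts.csv"),
            row.names = FALSE)

  # regime summary table mirroring the figure panels, as numbers
  panel <- rbind(
    regimePanel(dispersal, "mean_dispersals", "dispersal"),
    regimePanel(mvTab, "path_rate_px_s", "path_length"),
    regimePanel(mvTab, paste0("sinuosity_p", cfg$p_values[1]), "sinuosity"),
    regimePanel(mvTab, "edge_affinity", "edge_affinity"),
    regimePanel(surface$lines, "proportion", "surface_affinity"),
    regimePanel(morphTab, "pc1", "body_size"))
  write.csv(panel, file.path(outdir, "regime_summary.csv"),
            row.names = FALSE)

  # --- manifest ------------------------------------------------------------
  rowCounts <- c(
    tracking.csv = sum(vapply(recs, function(r)
      sum(vapply(r@tracks, length, integer(1))), numeric(1))),
    metadata.csv = length(recs), dispersal.csv = nrow(dispersal),
    surface.csv = nrow(surface$lines),
    surface_selection.csv = nrow(surface$selection),
    morphology.csv = nrow(morph$records),
    morphology_repeats.csv = nrow(morph$repeats),
    movement_summaries.csv = nrow(mvTab),
    repeatability.csv = nrow(rpt$table),
    morphology_scores.csv = nrow(morphTab),
    model_contrasts.csv = nrow(coefTab), regime_summary.csv = nrow(panel))
  files <- sort(list.files(outdir, pattern = "\\.csv$"))
  manifest <- list(
    seed = cfg$seed, stage_seeds = as.list(setNames(
      seeds, c("movement", "dispersal", "surface", "morphology"))),
    scenario = cfg$scenario,
    config_hash = unname(tools::md5sum(writeTemp(cfg))),
    exclusions = list(n_rules = length(cfg$exclusions),
                      n_removed = sum(excl$log$n_removed),
                      removed = excl$log$removed_ids),
    files = lapply(setNames(files, files), function(f) {
      list(md5 = unname(tools::md5sum(file.path(outdir, f))),
           rows = unname(rowCounts[f]))
    }))
  yaml::write_yaml(manifest, file.path(outdir, "manifest.yaml"))

  invisible(list(battery = battery,
                 tables = list(movement = mvTab, dispersal = dispersal,
                               surface = surface$lines,
                               surface_selection = surface$selection,
                               morphology = morphTab,
                               repeatability = rpt$table,
                               regime_summary = panel,
                               contrasts = coefTab),
                 manifest = manifest))
}

regimePanel <- function(d, col, label) {
  if (!col %in% names(d)) return(NULL)
  ag <- tapply(d[[col]], d$regime, function(v) {
    v <- v[!is.na(v)]
    c(mean = mean(v), se = sd(v) / sqrt(length(v)), n = length(v))
  })
  out <- do.call(rbind, lapply(names(ag), function(r)
    data.frame(metric = label, regime = r, mean = ag[[r]]["mean"],
               se = ag[[r]]["se"], n = ag[[r]]["n"],
               stringsAsFactors = FALSE)))
  rownames(out) <- NULL
  out
}

# serialize the config deterministically for hashing
writeTemp <- function(cfg) {
  f <- tempfile(fileext = ".yaml")
  yaml::write_yaml(cfg[order(names(cfg))], f)
  f
}
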