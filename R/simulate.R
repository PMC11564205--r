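#' Draw von Mises turning angles
#'
#' Best–Fisher rejection sampler for the von Mises(0, kappa) distribution on
#' (-pi, pi]. At kappa = 0 the distribution is uniform. The mean cosine of
#' draws converges to the Bessel ratio I1(kappa)/I0(kappa), which is the
#' analytic `c` used in sinuosity plug-in values.
#'
#' @param n number of draws.
#' @param kappa concentration (>= 0).
#' @return Numeric vector of angles in (-pi, pi].
#' @export
rvonmises <- function(n, kappa) {
  if (kappa < 0) stop("kappa must be >= 0")
  if (n == 0) return(numeric(0))
  if (kappa == 0) return(runif(n, -pi, pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  got <- 0L
  while (got < n) {
    m <- n - got
    u1 <- runif(m); u2 <- runif(m); u3 <- runif(m)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    ok <- (cc * (2 - cc) - u2 > 0) | (log(cc / u2) + 1 - cc >= 0)
    k <- sum(ok)
    if (k > 0) {
      out[got + seq_len(k)] <- sign(u3[ok] - 0.5) * acos(pmin(1, pmax(-1, f[ok])))
      got <- got + k
    }
  }
  out
}

#' Parameters of a correlated-random-walk replicate
#'
#' Describes one simulated arena recording: independent correlated random
#' walks for each individual, with von Mises turning angles (concentration
#' `kappa`), Gamma step lengths with mean `stepMmPerFrame` and coefficient
#' of variation `stepCv` (degenerate at 0 = constant steps), specular
#' reflection at the square arena walls, and pixel output through the
#' `mmPerPx` scale. Defaults mirror the activity-assay design: groups of 10
#' beetles filmed for 10 min at 25 frames per second.
#'
#' @param kappa turning concentration (>= 0; larger = straighter paths).
#' @param stepMmPerFrame mean step length, mm per frame.
#' @param stepCv step-length coefficient of variation (>= 0).
#' @param arenaMm square arena side, mm.
#' @param fps frames per second.
#' @param durationS recording length, seconds.
#' @param nIndividuals tracks per replicate.
#' @param mmPerPx spatial scale, mm per pixel.
#' @param seed integer seed for this replicate.
#' @return A validated parameter list of class `"CrwParams"`.
#' @export
crwParams <- function(kappa = 6, stepMmPerFrame = 1.0, stepCv = 0.3,
                      arenaMm = 110, fps = 25, durationS = 600,
                      nIndividuals = 10, mmPerPx = 0.2, seed = 1L) {
  p <- list(kappa = kappa, stepMmPerFrame = stepMmPerFrame,
            stepCv = stepCv, arenaMm = arenaMm, fps = fps,
            durationS = durationS, nIndividuals = nIndividuals,
            mmPerPx = mmPerPx, seed = as.integer(seed))
  with(p, {
    stopifnot(kappa >= 0, stepCv >= 0, stepMmPerFrame > 0, arenaMm > 0,
              fps > 0, durationS > 0, nIndividuals > 0, mmPerPx > 0)
  })
  if (p$stepMmPerFrame >= p$arenaMm)
    stop("arena smaller than one step")
  class(p) <- "CrwParams"
  p
}

# reflect coordinates into [0, L] (specular reflection at both walls)
foldReflect <- function(x, L) {
  y <- x %% (2 * L)
  ifelse(y > L, 2 * L - y, y)
}

#' Simulate one arena recording of correlated random walks
#'
#' Each individual starts at a uniform position and heading; headings
#' accumulate independent von Mises(0, kappa) increments, step lengths are
#' Gamma(mean, CV) draws (constant when CV = 0), and the walk is folded
#' back into the arena by specular reflection at the walls. Coordinates are
#' emitted in pixels. Fully reproducible from `params$seed`.
#'
#' @param params a [crwParams()] object.
#' @param meta named list/vector of replicate metadata: `replicate_id`,
#'   `line_id`, `regime`, `block_id`, `camera_id` (defaults supplied).
#' @return A [ReplicateRecording-class].
#' @export
genCrwReplicate <- function(params, meta = list()) {
  stopifnot(inherits(params, "CrwParams"))
  md <- modifyList(list(replicate_id = "sim1", line_id = "L1",
                        regime = "control", block_id = "1",
                        camera_id = "1"), as.list(meta))
  set.seed(params$seed)
  nSteps <- round(params$fps * params$durationS)
  trs <- lapply(seq_len(params$nIndividuals), function(i) {
    turns <- rvonmises(nSteps, params$kappa)
    heading <- runif(1, -pi, pi) + cumsum(turns)
    len <- if (params$stepCv == 0) rep(params$stepMmPerFrame, nSteps) else {
      shape <- 1 / params$stepCv^2
      rgamma(nSteps, shape = shape,
             scale = params$stepMmPerFrame / shape)
    }
    x <- runif(1, 0, params$arenaMm) + c(0, cumsum(len * cos(heading)))
    y <- runif(1, 0, params$arenaMm) + c(0, cumsum(len * sin(heading)))
    xy <- cbind(foldReflect(x, params$arenaMm),
                foldReflect(y, params$arenaMm)) / params$mmPerPx
    Track(sprintf("t%02d", i), 0:nSteps, xy)
  })
  ReplicateRecording(md$replicate_id, md$line_id, md$regime, md$block_id,
                     md$camera_id, fps = params$fps,
                     mmPerPx = params$mmPerPx, tracks = trs)
}

#' Per-regime effect settings for the synthetic study
#'
#' Bundles every ground-truth parameter the generators consume, keyed by
#' selection regime (high/low/control). Two named scenarios ship with the
#' package:
#' \describe{
#'   \item{`paper_like`}{effects calibrated to the published line means:
#'     per-opportunity dispersal probabilities 0.2333/0.8133/0.6467
#'     (low/high/control, i.e. line means 0.70/2.44/1.94 of 3); CRW step
#'     lengths reproducing path rates 111/129/125 px/s at 25 fps and
#'     0.2 mm/px; surface probabilities 0.2895/0.785/0.496 (counts
#'     57.9/157/99.2 of 200); a latent size factor with equal trait
#'     loadings 0.8083 (leading eigenvalue 74% of trait variance), regime
#'     and sex shifts matching the reported PC1 group means, tarsus
#'     remeasurement noise tuned to test–retest correlation ~0.73, and
#'     femur missingness 0.577 (330 complete cases of 780 expected);
#'     offspring surface-affinity shift 0.15 between parent classes.}
#'   \item{`null`}{all regime effects zero — every regime shares one
#'     parameter set; used for type-I-error calibration.}
#' }
#'
#' @param scenario `"paper_like"` or `"null"`.
#' @return Effect list of class `"RegimeEffects"`.
#' @export
scenarioEffects <- function(scenario = c("paper_like", "null")) {
  scenario <- match.arg(scenario)
  eff <- if (scenario == "paper_like") list(
    scenario = "paper_like",
    dispersal_p = c(low = 0.70 / 3, high = 2.44 / 3, control = 1.94 / 3),
    kappa = c(low = 5, high = 8, control = 7),
    step_mm = c(low = 111 / 25 * 0.2, high = 129 / 25 * 0.2,
                control = 125 / 25 * 0.2),
    step_cv = 0.3,
    surface_p = c(low = 57.9 / 200, high = 157 / 200, control = 99.2 / 200),
    surface_base = 99.2 / 200,
    surface_shift = 0.15,
    size_shift_regime = c(low = -0.70, high = 0.52, control = 0.45) /
      sqrt(0.74 * 4),
    size_shift_sex = c(M = -0.42, F = 0.39) / sqrt(0.74 * 4),
    trait_loading = sqrt((4 * 0.74 - 1) / 3),
    repeat_noise = c(default = 0.1, tarsus1_len = 0.91),
    missing_femur_rate = 1 - 330 / 780,
    line_sd_step_mm = 0.05,
    line_kappa_cv = 0.15
  ) else list(
    scenario = "null",
    dispersal_p = c(low = 0.5, high = 0.5, control = 0.5),
    kappa = c(low = 6, high = 6, control = 6),
    step_mm = c(low = 1, high = 1, control = 1),
    step_cv = 0.3,
    surface_p = c(low = 0.5, high = 0.5, control = 0.5),
    surface_base = 0.5,
    surface_shift = 0,
    size_shift_regime = c(low = 0, high = 0, control = 0),
    size_shift_sex = c(M = 0, F = 0),
    trait_loading = sqrt((4 * 0.74 - 1) / 3),
    repeat_noise = c(default = 0.1, tarsus1_len = 0.91),
    missing_femur_rate = 1 - 330 / 780,
    line_sd_step_mm = 0.05,
    line_kappa_cv = 0.15
  )
  class(eff) <- "RegimeEffects"
  eff
}

# the selection-line design: 16 high, 16 low, 12 control lines
designLines <- function(nHigh = 16, nLow = 16, nControl = 12) {
  data.frame(
    line_id = c(sprintf("H%02d", seq_len(nHigh)),
                sprintf("L%02d", seq_len(nLow)),
                sprintf("C%02d", seq_len(nControl))),
    regime = rep(c("high", "low", "control"), c(nHigh, nLow, nControl)),
    stringsAsFactors = FALSE)
}

# run seed -> independent child seeds, all < 2^31
deriveSeeds <- function(seed, n) {
  set.seed(as.integer(seed))
  sample.int(.Machine$integer.max - 1L, n)
}

#' Simulate dispersal assays for every line
#'
#' Per individual, dispersals ~ Binomial(3, p_regime); 200 individuals per
#' line by default, over the 16 high / 16 low / 12 control line design.
#' Expected line mean is 3 * p_regime.
#'
#' @param effects a [scenarioEffects()] list.
#' @param n individuals per line (default 200).
#' @param lines integer triple `c(high, low, control)` line counts.
#' @param seed integer seed.
#' @return data.frame `line_id, regime, n, c0..c3, mean_dispersals`.
#' @export
genDispersalAssays <- function(effects, n = 200, lines = c(16, 16, 12),
                               seed = 1L) {
  des <- designLines(lines[1], lines[2], lines[3])
  seeds <- deriveSeeds(seed, nrow(des))
  out <- do.call(rbind, lapply(seq_len(nrow(des)), function(i) {
    set.seed(seeds[i])
    k <- rbinom(n, 3, effects$dispersal_p[[des$regime[i]]])
    cnt <- vapply(0:3, function(j) sum(k == j), integer(1))
    data.frame(line_id = des$line_id[i], regime = des$regime[i], n = n,
               c0 = cnt[1], c1 = cnt[2], c2 = cnt[3], c3 = cnt[4],
               mean_dispersals = scoreDispersal(cnt, n),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Simulate surface-affinity assays
#'
#' Two designs in one generator. Per dispersal line:
#' `n_on_surface ~ Binomial(n, surface_p[regime])`. For the single-generation
#' selection test, offspring of surface-collected parents draw from
#' `surface_base + surface_shift / 2` and offspring of sub-surface parents
#' from `surface_base - surface_shift / 2`, so the expected class difference
#' in proportions equals `surface_shift`.
#'
#' @param effects a [scenarioEffects()] list.
#' @param n individuals per assay (default 200).
#' @param lines line-count triple for the per-line design.
#' @param repsPerClass replicate assays per parent class (default 15).
#' @param seed integer seed.
#' @return `list(lines = <data.frame>, selection = <data.frame>)`.
#' @export
genSurfaceAssays <- function(effects, n = 200, lines = c(16, 16, 12),
                             repsPerClass = 15, seed = 1L) {
  des <- designLines(lines[1], lines[2], lines[3])
  seeds <- deriveSeeds(seed, 2L)

  set.seed(seeds[1])
  block <- rep(c("1", "2"), length.out = nrow(des))
  lineTab <- data.frame(
    population_id = des$line_id, regime = des$regime, block_id = block,
    n_total = n,
    n_on_surface = rbinom(nrow(des), n,
                          effects$surface_p[des$regime]),
    stringsAsFactors = FALSE)
  lineTab$proportion <- lineTab$n_on_surface / lineTab$n_total

  set.seed(seeds[2])
  pUp <- min(1, max(0, effects$surface_base + effects$surface_shift / 2))
  pDn <- min(1, max(0, effects$surface_base - effects$surface_shift / 2))
  sel <- data.frame(
    population_id = sprintf("sel%02d", seq_len(2 * repsPerClass)),
    parent_class = rep(c("surface", "not_surface"), each = repsPerClass),
    block_id = rep(c("1", "2"), length.out = 2 * repsPerClass),
    n_total = n,
    n_on_surface = c(rbinom(repsPerClass, n, pUp),
                     rbinom(repsPerClass, n, pDn)),
    stringsAsFactors = FALSE)
  sel$proportion <- sel$n_on_surface / sel$n_total
  list(lines = lineTab, selection = sel)
}

#' Simulate the morphometrics table
#'
#' Latent-size model for five traits: each individual draws a latent size
#' `z ~ Normal(shift_regime + shift_sex, 1)`; every trait is
#' `mean_t + sd_t * (loading * z + sqrt(1 - loading^2) * noise)`, so the
#' trait correlation matrix is compound-symmetric with off-diagonal
#' `loading^2` and its leading eigenvalue sets the PC1 variance fraction.
#' Femur length is set missing completely at random at `missingFemurRate`.
#' A subset of individuals is remeasured with small per-trait noise; the
#' tarsus noise is inflated to emulate a poorly repeatable measurement.
#' Sampling design: 15 individuals per sex per line from lines 1-10 of each
#' selection regime and 1-6 of the controls (780 records).
#'
#' @param effects a [scenarioEffects()] list.
#' @param nPerCell individuals per sex per line (default 15).
#' @param missingFemurRate MCAR missingness for femur length; defaults to
#'   the scenario's rate.
#' @param nRepeat size of the remeasured subset (default 90).
#' @param seed integer seed.
#' @return `list(records = <repeat_index 1 rows>, repeats = <repeat_index 2
#'   rows>, latent = <data.frame individual_id, z>)`.
#' @export
genMorphology <- function(effects, nPerCell = 15,
                          missingFemurRate = effects$missing_femur_rate,
                          nRepeat = 90, seed = 1L) {
  stopifnot(missingFemurRate >= 0, missingFemurRate <= 1)
  des <- designLines(10, 10, 6)
  cells <- merge(des, data.frame(sex = c("M", "F")), by = NULL)
  idTab <- cells[rep(seq_len(nrow(cells)), each = nPerCell), ]
  nInd <- nrow(idTab)
  idTab$individual_id <- sprintf("ind%04d", seq_len(nInd))

  traitMeans <- c(elytron_len = 2.60, femur_len = 0.95, femur_width = 0.30,
                  tibia_len = 0.85, tarsus1_len = 0.25)
  traitSds <- 0.05 * traitMeans
  lam <- effects$trait_loading

  seeds <- deriveSeeds(seed, 3L)
  set.seed(seeds[1])
  z <- rnorm(nInd, effects$size_shift_regime[idTab$regime] +
                   effects$size_shift_sex[idTab$sex], 1)
  rec <- data.frame(individual_id = idTab$individual_id,
                    line_id = idTab$line_id, regime = idTab$regime,
                    sex = idTab$sex, repeat_index = 1L,
                    stringsAsFactors = FALSE)
  for (tr in names(traitMeans)) {
    e <- rnorm(nInd)
    rec[[tr]] <- traitMeans[[tr]] +
      traitSds[[tr]] * (lam * z + sqrt(1 - lam^2) * e)
  }

  set.seed(seeds[2])
  rec$femur_len[runif(nInd) < missingFemurRate] <- NA_real_

  set.seed(seeds[3])
  sub <- sample(nInd, min(nRepeat, nInd))
  rep2 <- rec[sub, , drop = FALSE]
  rep2$repeat_index <- 2L
  for (tr in names(traitMeans)) {
    tau <- if (tr %in% names(effects$repeat_noise))
      effects$repeat_noise[[tr]] else effects$repeat_noise[["default"]]
    rep2[[tr]] <- rep2[[tr]] + traitSds[[tr]] * tau * rnorm(nrow(rep2))
  }
  rownames(rec) <- rownames(rep2) <- NULL
  list(records = rec, repeats = rep2,
       latent = data.frame(individual_id = idTab$individual_id, z = z,
                           stringsAsFactors = FALSE))
}

#' Simulate the movement-assay recordings for the whole design
#'
#' One or more recorded replicates per line, with blocks and cameras laid
#' out as in the activity assay (lines 1-8 high/low and controls 1-6 in
#' block 1, the remainder in block 2; twelve cameras cycling within block).
#' Each replicate is an independent [genCrwReplicate()] call with a child
#' seed, so any subset is reproducible on its own.
#'
#' Selection lines are genetically differentiated populations, so each line
#' draws a persistent deviation around its regime parameters: a Normal
#' shift of the mean step length (`line_sd_step_mm`, calibrated from the
#' published between-line spread of path rates) and a log-Normal multiplier
#' on the turning concentration (`line_kappa_cv`). This is the variance the
#' battery's line random intercepts estimate; without it every mixed fit
#' would be singular.
#'
#' @param effects a [scenarioEffects()] list.
#' @param repsPerLine recordings per line (default 2).
#' @param durationS recording length in seconds (default 600 = 10 min).
#' @param nIndividuals animals per arena (default 10).
#' @param fps frames per second (default 25).
#' @param arenaMm arena side in mm (default 110).
#' @param mmPerPx spatial scale (default 0.2).
#' @param seed integer seed.
#' @return Named list of [ReplicateRecording-class] objects.
#' @export
genMovementStudy <- function(effects, repsPerLine = 2, durationS = 600,
                             nIndividuals = 10, fps = 25, arenaMm = 110,
                             mmPerPx = 0.2, seed = 1L) {
  des <- designLines()
  lineNum <- as.integer(sub("^[HLC]", "", des$line_id))
  des$block_id <- ifelse(des$regime == "control",
                         ifelse(lineNum <= 6, "1", "2"),
                         ifelse(lineNum <= 8, "1", "2"))
  seeds <- deriveSeeds(seed, nrow(des) * repsPerLine + 1L)
  set.seed(seeds[length(seeds)])
  lineSd <- if (is.null(effects$line_sd_step_mm)) 0 else
    effects$line_sd_step_mm
  kapCv <- if (is.null(effects$line_kappa_cv)) 0 else effects$line_kappa_cv
  des$step_dev <- rnorm(nrow(des), 0, lineSd)
  des$kappa_mul <- exp(rnorm(nrow(des), 0, kapCv))

  reps <- des[rep(seq_len(nrow(des)), each = repsPerLine), ]
  reps$rep <- rep(seq_len(repsPerLine), nrow(des))
  reps$replicate_id <- sprintf("%s_r%d", reps$line_id, reps$rep)
  reps$camera_id <- as.character(1 + (seq_len(nrow(reps)) - 1) %% 12)
  recs <- lapply(seq_len(nrow(reps)), function(i) {
    rg <- reps$regime[i]
    genCrwReplicate(
      crwParams(kappa = effects$kappa[[rg]] * reps$kappa_mul[i],
                stepMmPerFrame = max(0.05, effects$step_mm[[rg]] +
                                       reps$step_dev[i]),
                stepCv = effects$step_cv, arenaMm = arenaMm, fps = fps,
                durationS = durationS, nIndividuals = nIndividuals,
                mmPerPx = mmPerPx, seed = seeds[i]),
      meta = list(replicate_id = reps$replicate_id[i],
                  line_id = reps$line_id[i], regime = rg,
                  block_id = reps$block_id[i],
                  camera_id = reps$camera_id[i]))
  })
  names(recs) <- reps$replicate_id
  recs
}
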