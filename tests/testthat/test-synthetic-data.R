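test_that("generators are byte-identical under a fixed seed", {
  eff <- scenarioEffects("paper_like")
  r1 <- genCrwReplicate(crwParams(kappa = 2, durationS = 2, seed = 101))
  r2 <- genCrwReplicate(crwParams(kappa = 2, durationS = 2, seed = 101))
  expect_identical(lapply(tracks(r1), coords), lapply(tracks(r2), coords))

  expect_identical(genDispersalAssays(eff, seed = 7),
                   genDispersalAssays(eff, seed = 7))
  expect_identical(genSurfaceAssays(eff, seed = 7),
                   genSurfaceAssays(eff, seed = 7))
  expect_identical(genMorphology(eff, seed = 7), genMorphology(eff, seed = 7))

  # different seeds decorrelate
  r3 <- genCrwReplicate(crwParams(kappa = 2, durationS = 2, seed = 102))
  expect_false(identical(coords(tracks(r1)[[1]]), coords(tracks(r3)[[1]])))
})

test_that("CRW turning concentration reproduces von Mises moments", {
  # kappa = 0: uniform turns, mean cosine 0
  p0 <- crwParams(kappa = 0, arenaMm = 1e6, stepCv = 0, durationS = 40,
                  nIndividuals = 2, seed = 21)
  rec0 <- genCrwReplicate(p0)
  ang <- unlist(lapply(tracks(rec0), function(t)
    turningStats(coords(t))$angles))
  expect_lt(abs(mean(cos(ang))), 3 * sd(cos(ang)) / sqrt(length(ang)))

  # kappa = 2: mean cosine at the Bessel ratio (wall-free arena)
  p2 <- crwParams(kappa = 2, arenaMm = 1e6, stepCv = 0, durationS = 40,
                  nIndividuals = 2, seed = 22)
  rec2 <- genCrwReplicate(p2)
  ang2 <- unlist(lapply(tracks(rec2), function(t)
    turningStats(coords(t))$angles))
  target <- besselI(2, 1) / besselI(2, 0)
  expect_lt(abs(mean(cos(ang2)) - target),
            3 * sd(cos(ang2)) / sqrt(length(ang2)))

  # near-deterministic straight walks have near-zero sinuosity
  ps <- crwParams(kappa = 5000, arenaMm = 1e6, stepCv = 0, durationS = 20,
                  nIndividuals = 1, seed = 23, stepMmPerFrame = 2)
  t <- tracks(genCrwReplicate(ps))[[1]]
  p <- 2 / 0.2  # one step in pixels
  expect_lt(sinuosity(t, p), 0.01 * 2 / sqrt(p))

  expect_error(crwParams(stepMmPerFrame = 120, arenaMm = 100),
               "arena smaller than one step")
})

test_that("simulated walks stay inside the arena and carry the design", {
  prm <- crwParams(kappa = 3, durationS = 5, arenaMm = 110, mmPerPx = 0.2,
                   seed = 31)
  rec <- genCrwReplicate(prm, meta = list(replicate_id = "x", regime = "high",
                                          line_id = "H01", block_id = "2",
                                          camera_id = "7"))
  xy <- do.call(rbind, lapply(tracks(rec), coords))
  expect_true(all(xy >= 0 & xy <= 110 / 0.2))
  expect_equal(regime(rec), "high")
  expect_equal(rec@cameraId, "7")
  expect_length(tracks(rec), 10)
  expect_equal(length(tracks(rec)[[1]]), 5 * 25 + 1)
})

test_that("dispersal generator hits its binomial expectations", {
  eff <- scenarioEffects("paper_like")
  zero <- eff; zero$dispersal_p[] <- 0
  expect_true(all(genDispersalAssays(zero, seed = 1)$mean_dispersals == 0))
  three <- eff; three$dispersal_p[] <- 1
  expect_true(all(genDispersalAssays(three, seed = 1)$mean_dispersals == 3))

  d <- genDispersalAssays(eff, n = 200, seed = 5)
  expect_equal(nrow(d), 44)
  expect_true(all(d$c0 + d$c1 + d$c2 + d$c3 == d$n))
  # grand regime means near the calibrated targets 2.44 / 0.70
  for (rg in c("high", "low")) {
    p <- eff$dispersal_p[[rg]]
    m <- mean(d$mean_dispersals[d$regime == rg])
    se <- sqrt(3 * p * (1 - p) / (200 * 16))
    expect_lt(abs(m - 3 * p), 3 * se)
  }
})

test_that("surface generator reproduces class probabilities and the
           selection shift", {
  eff <- scenarioEffects("paper_like")
  all1 <- eff; all1$surface_p[] <- 1
  s1 <- genSurfaceAssays(all1, seed = 2)
  expect_true(all(s1$lines$n_on_surface == s1$lines$n_total))

  half <- eff; half$surface_base <- 0.5; half$surface_shift <- 0
  set.seed(98)
  counts <- replicate(60, {
    g <- genSurfaceAssays(half, repsPerClass = 2,
                          seed = sample.int(1e6, 1))
    mean(g$selection$n_on_surface)
  })
  expect_lt(abs(mean(counts) - 100), 3 * sd(counts) / sqrt(60))

  set.seed(99)
  g <- genSurfaceAssays(eff, repsPerClass = 40, seed = 12)
  diffHat <- mean(g$selection$proportion[g$selection$parent_class ==
                                           "surface"]) -
    mean(g$selection$proportion[g$selection$parent_class == "not_surface"])
  se <- sqrt(2 * 0.5 * 0.5 / (200 * 40))
  expect_lt(abs(diffHat - 0.15), 3 * se)
})

test_that("morphology generator carries the latent-size structure", {
  eff <- scenarioEffects("paper_like")

  noiseFree <- eff; noiseFree$trait_loading <- 1
  nf <- genMorphology(noiseFree, missingFemurRate = 0, seed = 3)
  p <- sizePCA(nf$records)
  expect_equal(p$variance_fractions[1], 1, tolerance = 1e-9)

  m <- genMorphology(eff, missingFemurRate = 0, seed = 4)
  expect_equal(nrow(m$records), 780)
  expect_equal(nrow(m$repeats), 90)
  ps <- sizePCA(m$records)
  expect_gt(cor(ps$pc1, m$latent$z), 0.95)

  # MCAR femur missingness: complete cases near the binomial expectation
  m3 <- genMorphology(eff, missingFemurRate = 0.3, seed = 5)
  cc <- completeCases(m3$records, c("elytron_len", "femur_len",
                                    "femur_width", "tibia_len"))
  expect_lt(abs(nrow(cc) - 780 * 0.7), 3 * sqrt(780 * 0.3 * 0.7))

  # the repeat subset separates stable from unstable traits
  rep1 <- m$records[m$records$individual_id %in%
                      m$repeats$individual_id, ]
  rpt <- repeatability(rep1, m$repeats)
  expect_true(all(rpt$table$rho[rpt$table$trait != "tarsus1_len"] > 0.9))
  expect_lt(rpt$table$rho[rpt$table$trait == "tarsus1_len"], 0.9)
  expect_false("tarsus1_len" %in% rpt$retained)
})
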