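# simulate a simple mixed design: line means per regime + residual noise
simMixed <- function(effect = 1, lineSd = 0.5, residSd = 1, nLines = 16,
                     nPerLine = 5, seed = 1) {
  set.seed(seed)
  lines <- data.frame(
    line_id = sprintf("l%02d", 1:(2 * nLines)),
    regime = rep(c("low", "high"), each = nLines),
    lineEff = rnorm(2 * nLines, 0, lineSd))
  d <- lines[rep(1:nrow(lines), each = nPerLine), ]
  d$y <- ifelse(d$regime == "high", effect, 0) + d$lineEff +
    rnorm(nrow(d), 0, residSd)
  d
}

test_that("fixed-effects fits reduce to OLS group-mean differences", {
  d <- data.frame(y = c(1, 2, 3, 5, 6, 7),
                  g = factor(rep(c("a", "b"), each = 3)))
  fit <- fitModel(ModelSpec("y", "g", character(), d))
  expect_equal(fit$coefficients$estimate[2], mean(5:7) - mean(1:3))
  expect_match(fit$formula, "y ~ g")

  # adding a zero-variance random factor leaves the estimate at OLS
  # (block arrangement chosen so block residual means are all zero)
  d$blk <- factor(c("b1", "b2", "b3", "b3", "b2", "b1"))
  mixed <- fitModel(ModelSpec("y", "g", "blk", d))
  expect_true(any(grepl("singular", mixed$messages)))
  expect_equal(mixed$coefficients$estimate[2], 4, tolerance = 1e-6)
  expect_true("blk" %in% mixed$varcomp$group)

  oneLevel <- data.frame(y = 1:4, g = c("a", "a", "b", "b"), r = "x")
  expect_error(fitModel(ModelSpec("y", "g", "r", oneLevel)),
               "fewer than 2 levels")
})

test_that("mixed-model fits recover a known regime effect", {
  d <- simMixed(effect = 1, seed = 42)
  fit <- fitModel(ModelSpec("y", "regime", "line_id", d))
  row <- fit$coefficients[fit$coefficients$term == "regimelow", ]
  expect_lt(abs(-row$estimate - 1), 3 * row$se)
  expect_true(all(c("line_id", "Residual") %in% fit$varcomp$group))
})

test_that("pairwise contrasts cover all regime pairs and are consistent", {
  set.seed(5)
  d <- data.frame(
    regime = rep(c("low", "high", "control"), each = 40),
    y = rnorm(120) + rep(c(0.70, 2.44, 1.94), each = 40))
  ct <- allPairwiseContrasts(ModelSpec("y", "regime", character(), d))
  expect_setequal(ct$contrast,
                  c("low - high", "low - control", "high - control"))
  mns <- tapply(d$y, d$regime, mean)
  # balanced OLS: every contrast is the raw difference of group means
  expect_equal(ct$estimate[ct$contrast == "low - high"],
               unname(mns["low"] - mns["high"]), tolerance = 1e-10)
  expect_equal(ct$estimate[ct$contrast == "high - control"],
               unname(mns["high"] - mns["control"]), tolerance = 1e-10)
  # linearity: (low - high) = (low - control) + (control - high)
  expect_equal(ct$estimate[ct$contrast == "low - high"],
               ct$estimate[ct$contrast == "low - control"] -
                 ct$estimate[ct$contrast == "high - control"],
               tolerance = 1e-10)

  same <- data.frame(regime = rep(c("low", "high", "control"), each = 3),
                     y = rep(c(1, 1, 1), each = 3))
  # identical groups fit with zero residual: silence the perfect-fit warning
  cts <- suppressWarnings(
    allPairwiseContrasts(ModelSpec("y", "regime", character(), same)))
  expect_equal(cts$estimate, rep(0, 3))

  miss <- d[d$regime != "control", ]
  expect_error(allPairwiseContrasts(ModelSpec("y", "regime", character(),
                                              miss)),
               "missing from data: control")
})

test_that("interaction pruning follows the refit rule", {
  set.seed(6)
  n <- 200
  d <- data.frame(regime = sample(c("low", "high", "control"), n, TRUE),
                  sex = sample(c("M", "F"), n, TRUE))
  d$y <- ifelse(d$regime == "high", 1, 0) + ifelse(d$sex == "M", -0.5, 0) +
    rnorm(n)

  pruned <- pruneInteractions(ModelSpec("y", "regime*sex", character(), d))
  expect_true(pruned$pruned)
  expect_false(any(grepl(":", pruned$fit$coefficients$term)))
  expect_true(all(pruned$interaction_p >= 0.05))

  # strong interaction (2 residual SDs) is retained
  d2 <- d
  d2$y <- d2$y + ifelse(d2$regime == "high" & d2$sex == "M", 2, 0)
  kept <- pruneInteractions(ModelSpec("y", "regime*sex", character(), d2))
  expect_false(kept$pruned)
  expect_true(any(grepl(":", kept$fit$coefficients$term)))

  # alpha = 0: no p-value can be significant, so always pruned
  always <- pruneInteractions(ModelSpec("y", "regime*sex", character(), d2),
                              alpha = 0)
  expect_true(always$pruned)

  expect_error(pruneInteractions(ModelSpec("y", "regime", character(), d)),
               "no interaction term")
})

test_that("the model battery produces one analysis per available table", {
  eff <- scenarioEffects("paper_like")
  recs <- genMovementStudy(eff, repsPerLine = 2, durationS = 4, seed = 2)
  mv <- movementTable(lapply(recs, summarizeReplicate, pValues = c(10, 20)))
  meta <- writeTrackingTable(recs)$metadata
  mv <- merge(mv, meta[, c("replicate_id", "line_id", "regime", "block_id",
                           "camera_id")], by = "replicate_id")
  surf <- genSurfaceAssays(eff, seed = 3)
  morph <- genMorphology(eff, seed = 4)
  cc <- completeCases(morph$records,
                      c("elytron_len", "femur_len", "femur_width",
                        "tibia_len"))
  cc$pc1 <- sizePCA(cc)$pc1
  cc$leg_len <- legLength(cc)
  bundle <- list(dispersal = genDispersalAssays(eff, seed = 5),
                 movement = mv, surface = surf$lines,
                 surface_selection = surf$selection, morphology = cc)

  bat <- runTable1Battery(bundle)
  expect_named(bat, c("dispersal", "path_length", "sinuosity",
                      "edge_affinity", "surface_affinity",
                      "surface_selection", "body_size", "leg_length"))
  produced <- vapply(bat, function(b) is.null(b$skipped), logical(1))
  expect_true(all(produced))
  tab <- batteryTable(bat)
  expect_true(all(tab$se > 0))
  expect_true(all(tab$p_value >= 0 & tab$p_value <= 1))

  # dropping morphology skips exactly the two morphometric rows
  bat2 <- runTable1Battery(bundle[setdiff(names(bundle), "morphology")])
  skipped <- vapply(bat2, function(b) !is.null(b$skipped), logical(1))
  expect_equal(sum(skipped), 2)
  expect_true(all(skipped[c("body_size", "leg_length")]))
})
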