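test_that("path-length rate handles elementary cases", {
  # 3-4-5 triangle over one second
  t <- Track("a", c(0L, 25L), cbind(c(0, 3), c(0, 4)))
  expect_equal(pathLengthRate(t, 25), 5)

  still <- Track("b", c(0L, 100L), cbind(c(2, 2), c(7, 7)))
  expect_equal(pathLengthRate(still, 25), 0)

  short <- Track("c", 0L, cbind(0, 0))
  expect_error(pathLengthRate(short, 25), "fewer than 2 detections")
})

test_that("path-length rate equals the brute-force hypot sum over steps", {
  set.seed(21)
  xy <- matrix(cumsum(rnorm(100)), ncol = 2)
  fr <- sort(sample(0:200, 50))
  t <- Track("a", fr, xy)
  brute <- 0
  for (i in 2:50)
    brute <- brute + sqrt((xy[i, 1] - xy[i - 1, 1])^2 +
                          (xy[i, 2] - xy[i - 1, 2])^2)
  expect_equal(pathLengthRate(t, 25), brute / ((fr[50] - fr[1]) / 25))
})

test_that("rediscretization reproduces hand-checkable geometries", {
  straight <- Track("s", 0:1, cbind(c(0, 10), c(0, 0)))
  expect_equal(coords(rediscretize(straight, 2)),
               cbind(seq(0, 10, 2), rep(0, 6)))

  # 3-4-5: from (0,0) the circle of radius 5 meets the vertical leg at (3,4)
  bend <- matrix(c(0, 3, 3, 0, 0, 5), ncol = 2)
  pts <- coords(rediscretize(bend, 5))
  expect_equal(pts[2, ], c(3, 4))

  expect_error(rediscretize(Track("s", 0:1, cbind(c(0, 1), c(0, 0))), 5),
               "shorter than p")
})

test_that("rediscretized chords are constant and an already-constant-step
           path is returned unchanged", {
  xy <- crwPath(400, kappa = 1.5, step = 2, seed = 5)
  rd <- coords(rediscretize(xy, 2))
  cl <- sqrt(diff(rd[, 1])^2 + diff(rd[, 2])^2)
  expect_lt(max(abs(cl - 2)), 1e-9 * 2)
  # identity on constant-step input (up to endpoint truncation)
  expect_equal(nrow(rd), nrow(xy))
  expect_equal(rd, xy, tolerance = 1e-9)

  smooth <- smoothPath(300, seed = 6)
  rs <- coords(rediscretize(smooth, 1.7))
  cls <- sqrt(diff(rs[, 1])^2 + diff(rs[, 2])^2)
  expect_lt(max(abs(cls - 1.7)), 1e-9 * 1.7)
})

test_that("rediscretization matches the dense-resampling oracle", {
  for (seed in 1:3) {
    xy <- smoothPath(40, seed = seed)
    p <- 1.3
    mine <- coords(rediscretize(xy, p))
    oracle <- denseRediscOracle(xy, p)
    n <- min(nrow(mine), nrow(oracle))
    expect_gte(n, 5)
    expect_lt(max(abs(mine[1:n, ] - oracle[1:n, ])), 1e-6 * p)
  }
})

test_that("turning statistics recover known angle patterns", {
  line <- cbind(0:5, rep(0, 6))
  ts <- turningStats(line)
  expect_equal(ts$angles, rep(0, 4))
  expect_equal(ts$c, 1)
  expect_equal(ts$b, 0)

  # square spiral of unit steps turning +90 degrees each step
  sq <- matrix(c(0, 0, 1, 0, 1, 1, 0, 1, 0, 0), ncol = 2, byrow = TRUE)
  ts2 <- turningStats(sq)
  expect_equal(ts2$angles, rep(pi / 2, 3))
  expect_equal(ts2$c, 0, tolerance = 1e-12)

  expect_error(turningStats(cbind(0:1, 0:1)), "at least 3 points")
})

test_that("sample mean turn cosine matches the Bessel ratio for von Mises
           turns", {
  set.seed(33)
  n <- 40000
  ang <- rvonmises(n, 2)
  target <- besselI(2, 1) / besselI(2, 0)
  se <- sd(cos(ang)) / sqrt(n)
  expect_lt(abs(mean(cos(ang)) - target), 3 * se)
})

test_that("sinuosity has the right limits and closed-form values", {
  straight <- Track("s", 0:10, cbind(0:10, rep(0, 11)))
  expect_equal(sinuosity(straight, 1), 0)

  # alternating +-90 degree unit steps: c = 0, b = 0 -> S = 2/sqrt(p) = 2
  zig <- matrix(c(0, 0, 1, 0, 1, 1, 2, 1, 2, 2, 3, 2), ncol = 2,
                byrow = TRUE)
  expect_equal(sinuosity(zig, 1), 2)

  # pure back-and-forth: c = -1, b = 0 diverges
  back <- matrix(c(0, 0, 1, 0, 0, 0, 1, 0), ncol = 2, byrow = TRUE)
  expect_error(sinuosity(back, 1), "degenerate")
})

test_that("mean sinuosity over CRW tracks sits on the analytic plug-in", {
  kappa <- 1; p <- 1
  S <- vapply(1:60, function(s)
    sinuosity(crwPath(2000, kappa, step = p, seed = 100 + s), p),
    numeric(1))
  se <- sd(S) / sqrt(length(S))
  expect_lt(abs(mean(S) - pluginSinuosity(kappa, p)), 3 * se)
})

test_that("edge affinity counts detections near data-defined arena edges", {
  box <- ReplicateRecording("r", "L", "low", mmPerPx = 1, tracks = list(
    Track("a", 0:3, matrix(c(0, 0, 100, 0, 100, 100, 0, 100), ncol = 2,
                           byrow = TRUE))))
  expect_equal(edgeAffinity(box, marginMm = 10), 1)

  # uniform 20x20 grid spanning a 100 mm square, margin 10 mm
  g <- seq(0, 100, length.out = 20)
  grid <- as.matrix(expand.grid(g, g))
  rec <- ReplicateRecording("r", "L", "low", mmPerPx = 1, tracks = list(
    Track("a", 0:(nrow(grid) - 1L), grid)))
  brute <- mean(grid[, 1] <= 10 | grid[, 1] >= 90 |
                grid[, 2] <= 10 | grid[, 2] >= 90)
  expect_equal(edgeAffinity(rec, marginMm = 10), brute)

  noScale <- ReplicateRecording("r", "L", "low", tracks = list(
    Track("a", 0:1, cbind(c(0, 50), c(0, 50)))))
  expect_error(edgeAffinity(noScale), "mm_per_px")
})

test_that("replicate summaries aggregate tracks as documented", {
  rec <- toyRecording()
  one <- ReplicateRecording("r1", "L1", "low", fps = 25, mmPerPx = 0.2,
                            tracks = tracks(rec)[1])
  s1 <- summarizeReplicate(one, pValues = 10)
  expect_equal(s1@pathRate, pathLengthRate(tracks(rec)[[1]], 25))

  # two equal-duration tracks with rates 10 and 20 -> pooled rate 15
  tA <- Track("a", c(0L, 25L), cbind(c(0, 10), c(0, 0)))
  tB <- Track("b", c(0L, 25L), cbind(c(0, 20), c(0, 0)))
  rec2 <- ReplicateRecording("r2", "L1", "low", fps = 25,
                             tracks = list(tA, tB))
  expect_equal(summarizeReplicate(rec2, pValues = 10)@pathRate, 15)

  # duration-weighted rate equals total distance / total time on 10 tracks
  sim <- genCrwReplicate(crwParams(kappa = 3, durationS = 3, seed = 9))
  s <- summarizeReplicate(sim, pValues = c(10, 20))
  dist <- 0; secs <- 0
  for (t in tracks(sim)) {
    xy <- coords(t)
    dist <- dist + sum(sqrt(diff(xy[, 1])^2 + diff(xy[, 2])^2))
    secs <- secs + (max(frames(t)) - min(frames(t))) / 25
  }
  expect_equal(s@pathRate, dist / secs)
  expect_equal(s@nTracks, 10L)
  expect_true(all(s@sinuosity > 0))

  # undefined metrics surface as NA, not errors
  tiny <- ReplicateRecording("r3", "L1", "low", fps = 25, tracks = list(
    Track("a", 0:1, cbind(c(0, 1), c(0, 0)))))
  s3 <- summarizeReplicate(tiny, pValues = 10)
  expect_true(is.na(s3@sinuosity["10"]))   # path shorter than p
  expect_true(is.na(s3@edgeAffinity))      # no spatial scale
  expect_equal(s3@pathRate, 25)
})

test_that("ground-truth agreement reproduces Pearson r and its Fisher CI", {
  expect_equal(groundTruthAgreement(1:5, 1:5 * 2)$r, 1)
  expect_equal(groundTruthAgreement(1:5, 6 - 1:5)$r, -1)

  x <- c(1, 2, 3, 4); y <- c(2, 4, 6, 9)
  # closed-form covariance oracle
  r0 <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  g <- groundTruthAgreement(x, y)
  expect_equal(g$r, r0)
  z <- atanh(r0)
  expect_equal(g$conf_int,
               tanh(z + c(-1, 1) * qnorm(0.975) / sqrt(4 - 3)),
               tolerance = 1e-8)

  expect_error(groundTruthAgreement(c(1, 1, 1), c(1, 2, 3)),
               "zero variance")
  expect_error(groundTruthAgreement(1:2, 2:3), "at least 3")
})
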