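# Independent oracles and fixture builders shared across the suite.

# Dense-resampling rediscretization oracle: oversample the polyline at equal
# arc steps (piecewise-linear, so samples lie exactly on the original
# segments), greedily find the first sample >= p from the current point, and
# bisect within the bracketing micro-segment to the circle crossing.
# Independent of the chord-walk implementation.
denseRediscOracle <- function(xy, p, arcStep = p / 1e4, tol = 1e-10) {
  seg <- sqrt(diff(xy[, 1])^2 + diff(xy[, 2])^2)
  s <- c(0, cumsum(seg))
  grid <- unique(c(seq(0, s[length(s)], by = arcStep), s[length(s)]))
  px <- approx(s, xy[, 1], xout = grid)$y
  py <- approx(s, xy[, 2], xout = grid)$y
  cur <- c(px[1], py[1])
  out <- matrix(cur, ncol = 2)
  i <- 1L
  n <- length(px)
  repeat {
    if (i >= n) break
    d <- sqrt((px[(i + 1):n] - cur[1])^2 + (py[(i + 1):n] - cur[2])^2)
    j <- which(d >= p)[1]
    if (is.na(j)) break
    j <- i + j                     # first sample at distance >= p
    a <- c(px[j - 1], py[j - 1])
    b <- c(px[j], py[j])
    lo <- 0; hi <- 1
    while (hi - lo > tol) {
      mid <- (lo + hi) / 2
      q <- a + mid * (b - a)
      if (sqrt(sum((q - cur)^2)) < p) lo <- mid else hi <- mid
    }
    cur <- a + hi * (b - a)
    out <- rbind(out, cur)
    i <- j - 1L
  }
  dimnames(out) <- NULL
  out
}

# constant-step correlated random walk as a plain coordinate matrix
crwPath <- function(nSteps, kappa, step = 1, seed = 1, cv = 0) {
  set.seed(seed)
  turns <- rvonmises(nSteps, kappa)
  h <- cumsum(turns)
  len <- if (cv == 0) rep(step, nSteps) else {
    shape <- 1 / cv^2
    rgamma(nSteps, shape = shape, scale = step / shape)
  }
  cbind(c(0, cumsum(len * cos(h))), c(0, cumsum(len * sin(h))))
}

# a smooth random path (cumulative small turns), for geometry oracles
smoothPath <- function(nSteps, seed = 1, step = 0.31) {
  set.seed(seed)
  h <- cumsum(rnorm(nSteps, 0, 0.25))
  cbind(c(0, cumsum(step * cos(h))), c(0, cumsum(step * sin(h))))
}

rigidTransform <- function(xy, theta, dx, dy) {
  R <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2)
  sweep(xy %*% t(R), 2, c(-dx, -dy))
}

# analytic sinuosity for a constant-step von Mises CRW rediscretized at the
# step length: c is the Bessel ratio I1(kappa)/I0(kappa)
pluginSinuosity <- function(kappa, p) {
  cc <- besselI(kappa, 1) / besselI(kappa, 0)
  2 / sqrt(p * (1 + cc) / (1 - cc))
}

# small ready-made recording: two straight tracks on a calibrated arena
toyRecording <- function() {
  t1 <- Track("t1", 0:4, cbind(seq(0, 100, 25), rep(0, 5)))
  t2 <- Track("t2", 0:4, cbind(seq(0, 100, 25), rep(50, 5)))
  ReplicateRecording("r1", "L1", "low", fps = 25, mmPerPx = 0.2,
                     tracks = list(t1, t2))
}
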