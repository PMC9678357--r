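# Shared fixtures and independent oracles, built in code at test time.

# solid cylinder along x: radius in voxels, length in voxels
cylinderPhantom <- function(radius = 3, length = 50, pad = 5) {
  side <- 2 * (radius + pad) + 1
  dims <- c(side, length + 2 * pad, side)
  arr <- array(FALSE, dims)
  c0 <- radius + pad + 1
  for (yy in seq_len(side)) for (zz in seq_len(side)) {
    if ((yy - c0)^2 + (zz - c0)^2 <= radius^2)
      arr[yy, (pad + 1):(pad + length), zz] <- TRUE
  }
  arr
}

# solid torus in the xy-plane
torusPhantom <- function(R = 12, r = 2.5, side = 41, nz = 9) {
  arr <- array(FALSE, c(side, side, nz))
  c0 <- (side + 1) / 2
  cz <- (nz + 1) / 2
  for (yy in seq_len(side)) for (xx in seq_len(side)) for (zz in seq_len(nz)) {
    rr <- sqrt((yy - c0)^2 + (xx - c0)^2)
    if ((rr - R)^2 + (zz - cz)^2 <= r^2) arr[yy, xx, zz] <- TRUE
  }
  arr
}

# exhaustive single-Otsu oracle: direct between-class variance per threshold
otsuOracle <- function(x) {
  v <- round(as.numeric(x))
  h <- tabulate(v + 1L, nbins = 256L)
  n <- sum(h)
  bcv <- vapply(0:254, function(t) {
    w0 <- sum(h[seq_len(t + 1)])
    w1 <- n - w0
    if (w0 == 0 || w1 == 0) return(-Inf)
    m0 <- sum((0:t) * h[seq_len(t + 1)]) / w0
    m1 <- sum(((t + 1):255) * h[(t + 2):256]) / w1
    (w0 / n) * (w1 / n) * (m0 - m1)^2
  }, numeric(1))
  (0:254)[which.max(bcv)]
}

# exhaustive three-class Otsu oracle: per-pair class means and weights
# computed with the textbook sum-of-weighted-squared-deviations formula
multiOtsuOracle <- function(x) {
  v <- round(as.numeric(x))
  h <- tabulate(v + 1L, nbins = 256L)
  p <- h / sum(h)
  lev <- 0:255
  muT <- sum(p * lev)
  best <- -Inf
  bestT <- c(NA, NA)
  for (t1 in 0:253) {
    for (t2 in (t1 + 1):254) {
      i1 <- lev <= t1
      i2 <- lev > t1 & lev <= t2
      i3 <- lev > t2
      w <- c(sum(p[i1]), sum(p[i2]), sum(p[i3]))
      if (any(w == 0)) next
      mu <- c(sum(p[i1] * lev[i1]), sum(p[i2] * lev[i2]),
              sum(p[i3] * lev[i3])) / w
      bcv <- sum(w * (mu - muT)^2)
      if (bcv > best) {
        best <- bcv
        bestT <- c(t1, t2)
      }
    }
  }
  bestT
}

# brute-force maximized marginal Gaussian log-likelihood of the voxel LME
# (profiled GLS beta and sigma; free relative random-effect parameters),
# independent of lme4
lmeLogLikOracle <- function(y, panel) {
  X <- stats::model.matrix(~ tiv + group + f + group:f, panel)
  n <- length(y)
  negll <- function(par) {
    s0 <- exp(par[1]); s1 <- exp(par[2]); rho <- tanh(par[3])
    D <- matrix(c(s0^2, rho * s0 * s1, rho * s0 * s1, s1^2), 2)
    V0 <- matrix(0, n, n)
    for (s in levels(panel$subject)) {
      ix <- which(panel$subject == s)
      Z <- cbind(1, panel$f[ix])
      V0[ix, ix] <- Z %*% D %*% t(Z)
    }
    diag(V0) <- diag(V0) + 1
    R <- chol(V0)
    Xi <- backsolve(R, X, transpose = TRUE)
    yi <- backsolve(R, y, transpose = TRUE)
    b <- qr.solve(Xi, yi)
    r <- yi - Xi %*% b
    s2 <- sum(r^2) / n
    0.5 * (n * log(2 * pi * s2) + 2 * sum(log(diag(R))) + n)
  }
  best <- Inf
  for (st in list(c(0, 0, 0), c(1, -1, 0), c(-1, 1, 0.5),
                  c(0.5, 0.5, -0.5), c(-2, -2, 0))) {
    o <- stats::optim(st, negll, method = "Nelder-Mead",
                      control = list(maxit = 5000, reltol = 1e-14))
    if (o$value < best) best <- o$value
  }
  -best
}

# graph Euler characteristic of a traced skeleton: nodes minus edges
# (each traced chain of m nodes carries m - 1 edges; closed chains repeat
# their start node, so the closing edge is counted)
skeletonEuler <- function(skel) {
  segs <- skeletonSegments(skel)
  e <- sum(vapply(segs, function(s) max(0L, length(s) - 1L), integer(1)))
  nrow(skeletonNodes(skel)) - e
}

# node degrees of a raw skeleton from its traced segments
segmentDegrees <- function(skel) {
  segs <- skeletonSegments(skel)
  deg <- integer(nrow(skeletonNodes(skel)))
  for (s in segs) {
    if (length(s) < 2) next
    pairs <- cbind(s[-length(s)], s[-1])
    for (r in seq_len(nrow(pairs))) {
      deg[pairs[r, 1]] <- deg[pairs[r, 1]] + 1L
      deg[pairs[r, 2]] <- deg[pairs[r, 2]] + 1L
    }
  }
  deg
}
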