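# Seeded generators emulating each data modality, with stored ground truth.

# run expr under a fixed seed, restoring the caller's RNG state
.withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)) {
    old <- get(".Random.seed", envir = .GlobalEnv)
    on.exit(assign(".Random.seed", old, envir = .GlobalEnv))
  }
  set.seed(seed)
  expr
}

#' Simulate a longitudinal two-group volume series
#'
#' Generates modulated-volume maps for a trained and a control group over
#' the six-session schedule, with the generative structure the voxelwise
#' models assume: a constant baseline field, per-subject random intercept
#' and random slope on the trajectory regressor, a group-by-time effect of
#' relative amplitude `effectAmplitude` following `effectShape` restricted
#' to `effectRegion`, and i.i.d. Gaussian noise. In the effect region a
#' trained subject's noise-free trajectory is
#' `baseline * (1 + effectAmplitude * f(t))`. TIVs are drawn from a normal
#' distribution; optional staggered entry (`dropout`) marks early sessions
#' of some trained subjects missing, mirroring designs whose per-session n
#' grows over training.
#'
#' @param seed RNG seed (the generator is byte-reproducible given the seed).
#' @param nPerGroup subjects per group (default 20).
#' @param sessionDays experimental days (default 0, 2, 6, 8, 10, 14).
#' @param grid 3D grid dimensions (default 20 x 20 x 20).
#' @param effectShape trajectory shape of the group effect.
#' @param effectAmplitude relative effect size at `f = 1` (e.g. `-0.04` for
#'   a 4% decrease; 0 for a null simulation).
#' @param effectRegion logical 3D array; default: central 5 x 5 x 5 block.
#' @param baseline baseline modulated value.
#' @param noiseSd,ranInterceptSd,ranSlopeSd Gaussian noise and random-effect
#'   standard deviations (absolute units).
#' @param tivMean,tivSd total-intracranial-volume distribution (mm^3).
#' @param voxelSize voxel edge length in mm (default 0.08).
#' @param dropout fraction of trained subjects entering after baseline
#'   (their first two sessions are marked missing); default 0.
#' @return List: `series` ([VolumeSeries-class]), `truth` (logical effect
#'   region), `params` (the generative parameter values).
#' @export
simLongitudinalVolumes <- function(seed = 1, nPerGroup = 20,
                                   sessionDays = c(0, 2, 6, 8, 10, 14),
                                   grid = c(20, 20, 20),
                                   effectShape = "asymptotic",
                                   effectAmplitude = -0.04,
                                   effectRegion = NULL,
                                   baseline = 0.8,
                                   noiseSd = 0.01,
                                   ranInterceptSd = 0.02,
                                   ranSlopeSd = 0.01,
                                   tivMean = 415, tivSd = 20,
                                   voxelSize = 0.08,
                                   dropout = 0) .withSeed(seed, {
  effectShape <- match.arg(effectShape, TRAJECTORY_SHAPES)
  ns <- 2L * nPerGroup
  nt <- length(sessionDays)
  nvox <- prod(grid)
  if (is.null(effectRegion)) {
    effectRegion <- array(FALSE, dim = grid)
    ctr <- lapply(grid, function(g) {
      lo <- max(1L, floor(g / 2) - 1L)
      seq(lo, min(g, lo + 4L))
    })
    effectRegion[ctr[[1]], ctr[[2]], ctr[[3]]] <- TRUE
  }
  if (!all(dim(effectRegion) == grid))
    stop("effect region lies outside the simulation grid")
  f <- trajectoryBasis(effectShape, sessionDays, max(sessionDays))
  group <- rep(c("control", "trained"), each = nPerGroup)
  g01 <- as.numeric(group == "trained")
  tiv <- abs(stats::rnorm(ns, tivMean, tivSd))
  b0 <- stats::rnorm(ns, 0, ranInterceptSd)
  b1 <- stats::rnorm(ns, 0, ranSlopeSd)
  region <- as.vector(effectRegion)

  # [subject*session, voxel]; subject index varies fastest, then session
  subjMean <- matrix(baseline + rep(b0, nt) + rep(b1, nt) * rep(f, each = ns),
                     ns * nt, 1)
  eff <- (baseline * effectAmplitude) * (g01 * rep(f, each = ns))
  flat <- matrix(subjMean, ns * nt, nvox) +
    outer(eff, as.numeric(region)) +
    matrix(stats::rnorm(ns * nt * nvox, 0, noiseSd), ns * nt, nvox)
  flat <- pmax(flat, 0)

  missing <- matrix(FALSE, ns, nt)
  if (dropout > 0) {
    late <- sample(which(g01 == 1), ceiling(dropout * nPerGroup))
    missing[late, 1:2] <- TRUE
  }
  subjects <- data.frame(
    id = sprintf("%s%02d", ifelse(g01 == 1, "t", "c"),
                 stats::ave(seq_len(ns), group, FUN = seq_along)),
    group = group, tiv = tiv)
  series <- new("VolumeSeries",
                data = array(flat, dim = c(ns, nt, grid)),
                voxelSize = voxelSize, sessionDays = sessionDays,
                subjects = subjects, missing = missing)
  list(series = series, truth = effectRegion,
       params = list(seed = seed, nPerGroup = nPerGroup,
                     effectShape = effectShape,
                     effectAmplitude = effectAmplitude, baseline = baseline,
                     noiseSd = noiseSd, ranInterceptSd = ranInterceptSd,
                     ranSlopeSd = ranSlopeSd))
})

#' Simulate a confocal probe of labeled fibers
#'
#' Builds smooth random 3D polylines (mostly in-plane, as fibers appear in
#' shallow confocal probes), rasterizes them as tubes of the stated radius
#' on the anisotropic grid, modulates intensity by a depth-decay profile
#' emulating limited antibody penetration (full labeling down to
#' `decayDepth`, exponential fall-off below), applies a Gaussian PSF blur
#' and Poisson photon noise, and returns the stack together with the exact
#' ground truth (polylines, arc lengths, radius, plateau depth). Fiber
#' depths are stratified across the labeled band so every labeled slice
#' carries signal.
#'
#' @param seed RNG seed.
#' @param dims stack dimensions `c(y, x, z)` in voxels (default 96 x 96 x 30,
#'   a 17 x 17 um field).
#' @param spacing voxel spacing in um, named `c(x, y, z)`.
#' @param nFibers number of fibers (default 10, chosen so the default
#'   volumetric fraction lands near the upper range of intracortical
#'   myelin, about 5-7%).
#' @param radius tube radius in um (default 0.45; a warning is issued below
#'   one in-plane voxel).
#' @param intensity peak labeled intensity (default 200 of 255).
#' @param background unlabeled intensity (default 20).
#' @param decayDepth labeling plateau depth in um (default 4.8, ten slices).
#' @param decayFalloff exponential fall-off scale below the plateau (um).
#' @param psfSigma Gaussian PSF standard deviations in um, named
#'   `c(x, y, z)` (default 0.1/0.1/0.25, a high-NA oil objective).
#' @param curvature in-plane direction random-walk SD per 0.1 um step
#'   (radians); 0 gives straight fibers.
#' @param noise add Poisson noise (default TRUE).
#' @return List: `stack` ([ProbeStack-class]), `truth` (list with
#'   `polylines`, `totalLength`, `lengthInPlateau`, `radius`,
#'   `plateauDepth`, `trueDensity` computed with the 0.5 um border
#'   correction).
#' @export
simFiberStack <- function(seed = 1, dims = c(y = 96, x = 96, z = 30),
                          spacing = c(x = 0.18, y = 0.18, z = 0.48),
                          nFibers = 10, radius = 0.45,
                          intensity = 200, background = 20,
                          decayDepth = 4.8, decayFalloff = 1,
                          psfSigma = c(x = 0.1, y = 0.1, z = 0.25),
                          curvature = 0.02, noise = TRUE) .withSeed(seed, {
  if (radius < spacing[["x"]])
    warning("tube radius below one in-plane voxel: sub-resolution fibers")
  ext <- c(x = dims[["x"]] * spacing[["x"]], y = dims[["y"]] * spacing[["y"]],
           z = dims[["z"]] * spacing[["z"]])
  ds <- 0.1
  # fibers populate the labeled band from the cut surface (z ~ 0, where
  # superficial fibers are partially cut) down to the penetration plateau
  zSlots <- seq(0.05, max(decayDepth - radius, 0.3),
                length.out = max(nFibers, 2))
  polylines <- vector("list", nFibers)
  totalLength <- 0
  lengthInPlateau <- 0
  placed <- matrix(numeric(0), ncol = 3)  # samples of accepted fibers
  drawFiber <- function(z0) {
    p <- c(stats::runif(1, 0.1 * ext[["x"]], 0.9 * ext[["x"]]),
           stats::runif(1, 0.1 * ext[["y"]], 0.9 * ext[["y"]]))
    th0 <- stats::runif(1, 0, 2 * pi)
    one <- function(th) {
      pts <- matrix(numeric(0), ncol = 3)
      q <- p
      repeat {
        th <- th + stats::rnorm(1, 0, curvature)
        qn <- q + ds * c(cos(th), sin(th))
        if (qn[1] < 0 || qn[1] > ext[["x"]] || qn[2] < 0 ||
            qn[2] > ext[["y"]]) break
        pts <- rbind(pts, c(qn, z0))
        q <- qn
      }
      pts
    }
    fwd <- one(th0)
    bwd <- one(th0 + pi)
    pts <- rbind(bwd[rev(seq_len(nrow(bwd))), , drop = FALSE],
                 matrix(c(p, z0), 1), fwd)
    colnames(pts) <- c("x", "y", "z")
    pts
  }
  # clearance of a candidate centerline from already-placed fibers
  clearance <- function(pts) {
    if (!nrow(placed)) return(Inf)
    nearZ <- placed[abs(placed[, 3] - pts[1, 3]) <
                      2 * radius + 2 * psfSigma[["z"]] + 0.1, ,
                    drop = FALSE]
    if (!nrow(nearZ)) return(Inf)
    sub <- pts[seq(1, nrow(pts), by = 3), , drop = FALSE]
    min(vapply(seq_len(nrow(sub)), function(r)
      min(sqrt((nearZ[, 1] - sub[r, 1])^2 + (nearZ[, 2] - sub[r, 2])^2 +
               (nearZ[, 3] - sub[r, 3])^2)), numeric(1)))
  }
  # resolvability margin: fibers must stay one diameter apart (solid axons
  # exclude each other) plus the PSF footprint, so that distinct fibers
  # remain separable at the stated imaging resolution — the convention for
  # quantitative validation phantoms
  minClear <- 2 * radius + 2 * psfSigma[["z"]]
  for (i in seq_len(nFibers)) {
    z0 <- zSlots[((i - 1) %% length(zSlots)) + 1]
    best <- NULL
    bestClear <- -Inf
    for (att in 1:50) {
      pts <- drawFiber(z0)
      cl <- clearance(pts)
      if (cl > bestClear) {
        best <- pts
        bestClear <- cl
      }
      if (cl >= minClear) break
    }
    pts <- best
    placed <- rbind(placed, pts[seq(1, nrow(pts), by = 3), , drop = FALSE])
    polylines[[i]] <- pts
    L <- sum(sqrt(rowSums(diff(pts)^2)))
    totalLength <- totalLength + L
    if (z0 <= decayDepth) lengthInPlateau <- lengthInPlateau + L
  }
  # rasterize: distance of every voxel to the nearest sampled centerline point
  pointMask <- array(1L, dim = dims)
  for (pts in polylines) {
    iy <- pmin(pmax(round(pts[, "y"] / spacing[["y"]]) + 1, 1), dims[["y"]])
    ix <- pmin(pmax(round(pts[, "x"] / spacing[["x"]]) + 1, 1), dims[["x"]])
    iz <- pmin(pmax(round(pts[, "z"] / spacing[["z"]]) + 1, 1), dims[["z"]])
    pointMask[cbind(iy, ix, iz)] <- 0L
  }
  d2 <- .cppEdt3d(as.integer(pointMask), as.integer(dims),
                  as.numeric(spacing[c("y", "x", "z")]))
  tube <- sqrt(d2) <= radius
  zc <- (seq_len(dims[["z"]]) - 1) * spacing[["z"]]
  decay <- ifelse(zc <= decayDepth, 1, exp(-(zc - decayDepth) / decayFalloff))
  img <- array(background, dim = dims) +
    (intensity - background) * sweep(array(as.numeric(tube), dims), 3,
                                     decay, "*")
  sig <- psfSigma[c("y", "x", "z")] / spacing[c("y", "x", "z")]
  for (ax in 1:3) img <- .convolveAxis(img, .gaussianKernel1d(sig[ax]), ax)
  if (noise) img <- matrix(stats::rpois(length(img), as.vector(img)),
                           ncol = 1)
  img <- array(pmin(pmax(as.numeric(img), 0), 255), dim = dims)
  area <- ext[["x"]] * ext[["y"]]
  list(stack = probeStack(img, spacing),
       truth = list(polylines = polylines, totalLength = totalLength,
                    lengthInPlateau = lengthInPlateau, radius = radius,
                    plateauDepth = decayDepth,
                    trueDensity = lengthInPlateau /
                      (area * (decayDepth + 0.5))))
})

#' Simulate a three-class fluorescence section
#'
#' Background, autofluorescent tissue and specific (labeled) signal classes
#' with stated mean intensities, spatially structured by smooth random
#' fields (background as connected low-intensity regions, specific signal as
#' fiber-like elongated structures), plus Gaussian read noise. The true
#' class map is returned for recovery checks.
#'
#' @param seed RNG seed.
#' @param dims image dimensions `c(rows, cols)` (default 128 x 128).
#' @param classMeans strictly increasing intensity means for background,
#'   autofluorescence and specific signal (default 20, 90, 200).
#' @param noiseSd Gaussian noise SD (default 8).
#' @param specificFraction target area fraction of the specific class
#'   (default 0.15; 0 removes the class).
#' @param backgroundFraction target area fraction of background (default
#'   0.10).
#' @return List: `image` (matrix, `[0, 255]`), `truth` (integer class map
#'   1/2/3), `params`.
#' @export
simSection <- function(seed = 1, dims = c(128, 128),
                       classMeans = c(20, 90, 200), noiseSd = 8,
                       specificFraction = 0.15,
                       backgroundFraction = 0.10) .withSeed(seed, {
  if (is.unsorted(classMeans, strictly = TRUE))
    stop("class means must be strictly increasing")
  smoothField <- function(sigma) {
    f <- matrix(stats::rnorm(prod(dims)), dims[1], dims[2])
    a <- array(f, dim = c(dims, 1))
    k <- .gaussianKernel1d(sigma)
    for (ax in 1:2) a <- .convolveAxis(a, k, ax)
    matrix(a, dims[1], dims[2])
  }
  cls <- matrix(2L, dims[1], dims[2])
  bg <- smoothField(6)
  cls[bg < stats::quantile(bg, backgroundFraction)] <- 1L
  if (specificFraction > 0) {
    fib <- smoothField(2)
    # elongate: directional smoothing produces fiber-like streaks
    k <- .gaussianKernel1d(5)
    a <- array(fib, dim = c(dims, 1))
    fib <- matrix(.convolveAxis(a, k, 2), dims[1], dims[2])
    thr <- stats::quantile(fib, 1 - specificFraction)
    cls[fib > thr & cls != 1L] <- 3L
  }
  img <- matrix(classMeans[cls], dims[1], dims[2]) +
    stats::rnorm(prod(dims), 0, noiseSd)
  img <- pmin(pmax(img, 0), 255)
  list(image = img, truth = cls,
       params = list(seed = seed, classMeans = classMeans,
                     noiseSd = noiseSd))
})

#' Simulate single-pellet reaching sessions
#'
#' Daily success probability follows the saturating learning curve
#' `p(d) = p0 + (pMax - p0)(1 - exp(-rate d))`; each day has
#' `trialsPerDay` Bernoulli trials, attempts per trial are geometric
#' (successful trials included), and a small fraction of trials is flagged
#' invalid (abnormal behavior) and never counts as a success.
#'
#' @param seed RNG seed.
#' @param nAnimals number of animals (default 10).
#' @param days training days (default 1:12).
#' @param trialsPerDay trials per daily session (default 30).
#' @param p0,pMax initial and asymptotic success probability.
#' @param rate learning-curve rate constant per day.
#' @param attemptGeomProb geometric success parameter for attempt counts
#'   (attempts = 1 + geometric; larger means fewer attempts).
#' @param invalidProb probability a trial is invalid (default 0.05).
#' @return data.frame with columns `animal`, `day`, `trial`, `success`,
#'   `attempts`, `invalid`.
#' @export
simBehaviorSessions <- function(seed = 1, nAnimals = 10, days = 1:12,
                                trialsPerDay = 30, p0 = 0.1, pMax = 0.55,
                                rate = 0.3, attemptGeomProb = 0.6,
                                invalidProb = 0.05) .withSeed(seed, {
  p <- p0 + (pMax - p0) * (1 - exp(-rate * days))
  if (any(p < 0 | p > 1)) stop("success probabilities outside [0, 1]")
  rows <- expand.grid(trial = seq_len(trialsPerDay), day = days,
                      animal = seq_len(nAnimals))
  n <- nrow(rows)
  pd <- p[match(rows$day, days)]
  invalid <- stats::runif(n) < invalidProb
  success <- stats::runif(n) < pd & !invalid
  attempts <- 1L + stats::rgeom(n, attemptGeomProb)
  data.frame(animal = sprintf("a%02d", rows$animal), day = rows$day,
             trial = rows$trial, success = success, attempts = attempts,
             invalid = invalid)
})
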