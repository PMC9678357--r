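# Centerline extraction: topology-preserving thinning, skeleton graph,
# node resampling and distance-transform radii.

#' Anisotropic Euclidean distance transform
#'
#' For each foreground voxel, the Euclidean distance (in microns) to the
#' nearest background voxel center, computed on the anisotropic grid
#' directly (no resampling), so z-steps weigh their true physical distance.
#'
#' @param mask logical/0-1 3D array `[y, x, z]`.
#' @param spacing voxel spacing in microns, named `c(x, y, z)`.
#' @return Numeric array of distances in microns (0 on background).
#' @export
distanceTransform <- function(mask, spacing = c(x = 0.18, y = 0.18, z = 0.48)) {
  stopifnot(length(dim(mask)) == 3)
  d2 <- .cppEdt3d(as.integer(mask != 0), as.integer(dim(mask)),
                  as.numeric(spacing[c("y", "x", "z")]))
  array(sqrt(d2), dim = dim(mask))
}

#' Euler characteristic of a 3D binary array
#'
#' Computed on the cubical complex spanned by foreground voxels
#' (vertices - edges + faces - cells); appropriate for solid,
#' face-connected foregrounds. For a thinned skeleton, whose diagonal
#' (26-connected) steps share no voxel faces, use the graph Euler
#' characteristic (nodes minus traced edges) instead; topology-preserving
#' thinning keeps the two in agreement.
#'
#' @param mask logical/0-1 3D array.
#' @return Integer Euler characteristic.
#' @export
eulerCharacteristic <- function(mask) {
  b <- array(mask != 0, dim = dim(mask))
  shift0 <- function(x, axis) {
    d <- dim(x)[axis]
    switch(axis,
           x[-1, , , drop = FALSE] & x[-d, , , drop = FALSE],
           x[, -1, , drop = FALSE] & x[, -d, , drop = FALSE],
           x[, , -1, drop = FALSE] & x[, , -d, drop = FALSE])
  }
  V <- sum(b)
  e1 <- shift0(b, 1); e2 <- shift0(b, 2); e3 <- shift0(b, 3)
  E <- sum(e1) + sum(e2) + sum(e3)
  f12 <- shift0(e1, 2); f13 <- shift0(e1, 3); f23 <- shift0(e2, 3)
  F <- sum(f12) + sum(f13) + sum(f23)
  C <- sum(shift0(f12, 3))
  as.integer(V - E + F - C)
}

# --- skeleton graph machinery ----------------------------------------------

# voxel adjacency (26-connectivity) among a set of voxel indices
.voxelEdges <- function(vox, dims) {
  idxArr <- array(0L, dim = dims)
  idxArr[vox] <- seq_len(nrow(vox))
  offs <- as.matrix(expand.grid(dy = -1:1, dx = -1:1, dz = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  # keep one of each +/- pair
  keep <- offs[, 3] > 0 | (offs[, 3] == 0 & (offs[, 2] > 0 |
            (offs[, 2] == 0 & offs[, 1] > 0)))
  offs <- offs[keep, , drop = FALSE]
  edges <- NULL
  for (r in seq_len(nrow(offs))) {
    ny <- vox[, 1] + offs[r, 1]
    nx <- vox[, 2] + offs[r, 2]
    nz <- vox[, 3] + offs[r, 3]
    ok <- ny >= 1 & ny <= dims[1] & nx >= 1 & nx <= dims[2] &
          nz >= 1 & nz <= dims[3]
    j <- integer(nrow(vox))
    j[ok] <- idxArr[cbind(ny[ok], nx[ok], nz[ok])]
    hit <- which(j > 0)
    if (length(hit))
      edges <- rbind(edges, cbind(hit, j[hit]))
  }
  edges
}

# trace segments (chains between endpoints/junctions, plus closed cycles)
# from a voxel adjacency structure
.traceSegments <- function(nVox, edges) {
  if (is.null(edges) || nrow(edges) == 0)
    return(lapply(seq_len(nVox), function(i) i))  # isolated voxels
  adj <- vector("list", nVox)
  for (r in seq_len(nrow(edges))) {
    i <- edges[r, 1]; j <- edges[r, 2]
    adj[[i]] <- c(adj[[i]], j)
    adj[[j]] <- c(adj[[j]], i)
  }
  deg <- lengths(adj)
  ekey <- function(i, j) paste(min(i, j), max(i, j))
  used <- new.env(hash = TRUE)
  segs <- list()
  walk <- function(start, nxt) {
    chain <- c(start, nxt)
    assign(ekey(start, nxt), TRUE, envir = used)
    prev <- start; cur <- nxt
    while (deg[cur] == 2) {
      nb <- adj[[cur]]
      nx <- nb[nb != prev]
      if (length(nx) == 0) break
      nx <- nx[1]
      if (exists(ekey(cur, nx), envir = used)) break  # closed back
      assign(ekey(cur, nx), TRUE, envir = used)
      chain <- c(chain, nx)
      prev <- cur; cur <- nx
    }
    chain
  }
  for (i in which(deg != 2)) {
    for (j in adj[[i]]) {
      if (!exists(ekey(i, j), envir = used))
        segs[[length(segs) + 1]] <- walk(i, j)
    }
  }
  # remaining unvisited edges belong to pure cycles
  for (r in seq_len(nrow(edges))) {
    i <- edges[r, 1]; j <- edges[r, 2]
    if (!exists(ekey(i, j), envir = used))
      segs[[length(segs) + 1]] <- walk(i, j)
  }
  # isolated voxels
  for (i in which(deg == 0)) segs[[length(segs) + 1]] <- i
  segs
}

# contract compact clusters of 26-adjacent branch voxels (degree >= 3)
# into single junction nodes at their centroids: fibers crossing within a
# small blob then meet at one point instead of fragmenting into sub-voxel
# segments whose arc length would be lost on resampling. Extended junction
# complexes (bounding diagonal above maxExtent) keep their voxel structure,
# since contracting them would discard genuine path length.
.consolidateJunctions <- function(coords, edges, nVox, maxExtent = 0.6) {
  deg <- integer(nVox)
  if (!is.null(edges) && nrow(edges))
    deg <- tabulate(c(edges[, 1], edges[, 2]), nbins = nVox)
  isJ <- deg >= 3
  if (!any(isJ))
    return(list(nodes = coords, edges = edges))
  jid <- which(isJ)
  sub <- edges[isJ[edges[, 1]] & isJ[edges[, 2]], , drop = FALSE]
  g <- igraph::make_empty_graph(n = length(jid), directed = FALSE)
  if (nrow(sub))
    g <- igraph::add_edges(g, t(matrix(match(sub, jid), ncol = 2)))
  memb <- igraph::components(g)$membership
  # keep clusters whose spatial extent exceeds maxExtent as plain voxels
  for (cl in unique(memb)) {
    ix <- jid[memb == cl]
    ext <- sqrt(sum((apply(coords[ix, c("x", "y", "z"), drop = FALSE], 2,
                           function(v) diff(range(v))))^2))
    if (ext > maxExtent) isJ[ix] <- FALSE
  }
  if (!any(isJ))
    return(list(nodes = coords, edges = edges))
  jid <- which(isJ)
  sub <- edges[isJ[edges[, 1]] & isJ[edges[, 2]], , drop = FALSE]
  g <- igraph::make_empty_graph(n = length(jid), directed = FALSE)
  if (nrow(sub))
    g <- igraph::add_edges(g, t(matrix(match(sub, jid), ncol = 2)))
  memb <- igraph::components(g)$membership
  nClu <- max(memb)
  m <- sum(!isJ)
  newId <- integer(nVox)
  newId[!isJ] <- seq_len(m)
  newId[isJ] <- m + memb
  cent <- vapply(seq_len(nClu), function(cl) {
    colMeans(coords[jid[memb == cl], c("x", "y", "z"), drop = FALSE])
  }, numeric(3))
  nodes <- rbind(coords[!isJ, , drop = FALSE],
                 data.frame(x = cent[1, ], y = cent[2, ], z = cent[3, ],
                            radius = NA_real_))
  e2 <- cbind(newId[edges[, 1]], newId[edges[, 2]])
  e2 <- e2[e2[, 1] != e2[, 2], , drop = FALSE]
  if (nrow(e2)) {
    key <- paste(pmin(e2[, 1], e2[, 2]), pmax(e2[, 1], e2[, 2]))
    e2 <- e2[!duplicated(key), , drop = FALSE]
  }
  list(nodes = nodes, edges = e2)
}

.chainLength <- function(nodes, chain) {
  if (length(chain) < 2) return(0)
  dx <- diff(nodes$x[chain]); dy <- diff(nodes$y[chain])
  dz <- diff(nodes$z[chain])
  sum(sqrt(dx^2 + dy^2 + dz^2))
}

#' Skeletonize a binary stack
#'
#' Reduces the foreground to unit-width centerlines by sequential removal of
#' simple points (26-connectivity foreground, 6-connectivity background), so
#' object topology is preserved: segments never split, loops and components
#' survive. The centerline voxels are then assembled into a graph
#' (26-adjacency) and traced into ordered segments between endpoints and
#' branch points; spurious terminal side-branches shorter than
#' `minBranchLength` are pruned.
#'
#' @param mask logical/0-1 3D array `[y, x, z]` (e.g. from [binarizeOtsu()]).
#' @param spacing voxel spacing in microns, named `c(x, y, z)`.
#' @param minBranchLength prune terminal branches shorter than this many
#'   microns (default 1; 0 disables pruning).
#' @param boundaryPad voxels of in-plane edge-replication padding applied
#'   before thinning and cropped afterwards (default 6). Without padding,
#'   fibers cut crosswise by the lateral probe limits erode from the open
#'   end by about one tube radius before a centerline endpoint forms;
#'   extruding the boundary cross-section keeps their centerlines extending
#'   to the probe edge. The z faces are never padded: there fibers are cut
#'   lengthwise (section surface), and extrusion would displace their
#'   centerlines into the padding.
#' @return A raw [FiberSkeleton-class]: one node per centerline voxel
#'   (coordinates in microns, radii `NA`), `nodeSpacing = NA`.
#' @export
skeletonizeStack <- function(mask, spacing = c(x = 0.18, y = 0.18, z = 0.48),
                             minBranchLength = 1, boundaryPad = 6L) {
  stopifnot(length(dim(mask)) == 3)
  spacing <- spacing[c("x", "y", "z")]
  m <- array(mask != 0, dim = dim(mask))
  k <- as.integer(boundaryPad)
  if (k > 0) {
    padIdx <- function(n) c(rep(1L, k), seq_len(n), rep(n, k))
    m <- m[padIdx(dim(m)[1]), padIdx(dim(m)[2]), , drop = FALSE]
  }
  thin <- .cppThin3d(as.integer(m), as.integer(dim(m)))
  thin <- array(thin == 1, dim = dim(m))
  if (k > 0) {
    d0 <- dim(mask)
    thin <- thin[k + seq_len(d0[1]), k + seq_len(d0[2]), , drop = FALSE]
  }
  vox <- which(thin, arr.ind = TRUE)
  if (nrow(vox) == 0)
    return(new("FiberSkeleton",
               nodes = data.frame(x = numeric(), y = numeric(),
                                  z = numeric(), radius = numeric()),
               segments = list(), nodeSpacing = NA_real_))
  dims <- dim(mask)
  mkNodes <- function(vox) data.frame(
    x = (vox[, 2] - 1) * spacing[["x"]],
    y = (vox[, 1] - 1) * spacing[["y"]],
    z = (vox[, 3] - 1) * spacing[["z"]],
    radius = NA_real_)
  repeat {
    edges <- .voxelEdges(vox, dims)
    segs <- .traceSegments(nrow(vox), edges)
    nodes <- mkNodes(vox)
    if (minBranchLength <= 0) break
    deg <- integer(nrow(vox))
    if (!is.null(edges) && nrow(edges)) {
      tab <- tabulate(c(edges[, 1], edges[, 2]), nbins = nrow(vox))
      deg <- tab
    }
    drop <- logical(nrow(vox))
    for (s in segs) {
      if (length(s) < 2) next
      a <- s[1]; b <- s[length(s)]
      isSpur <- xor(deg[a] == 1, deg[b] == 1) &&
        (deg[a] >= 3 || deg[b] >= 3)
      if (isSpur && .chainLength(nodes, s) < minBranchLength) {
        tip <- if (deg[a] == 1) s[-length(s)] else s[-1]
        drop[tip] <- TRUE
      }
    }
    if (!any(drop)) break
    vox <- vox[!drop, , drop = FALSE]
    if (nrow(vox) == 0) {
      nodes <- data.frame(x = numeric(), y = numeric(), z = numeric(),
                          radius = numeric())
      segs <- list()
      break
    }
  }
  if (nrow(nodes)) {
    cons <- .consolidateJunctions(nodes, edges, nrow(vox))
    segs <- .traceSegments(nrow(cons$nodes), cons$edges)
    nodes <- cons$nodes
    rownames(nodes) <- NULL
  }
  new("FiberSkeleton", nodes = nodes, segments = segs,
      nodeSpacing = NA_real_)
}

# trilinear interpolation of a 3D array [y, x, z] at micron coordinates
.interp3 <- function(arr, x, y, z, spacing) {
  d <- dim(arr)
  fi <- pmin(pmax(y / spacing[["y"]] + 1, 1), d[1])
  fj <- pmin(pmax(x / spacing[["x"]] + 1, 1), d[2])
  fk <- pmin(pmax(z / spacing[["z"]] + 1, 1), d[3])
  i0 <- pmin(floor(fi), d[1] - 1); i1 <- i0 + 1
  j0 <- pmin(floor(fj), d[2] - 1); j1 <- j0 + 1
  k0 <- pmin(floor(fk), d[3] - 1); k1 <- k0 + 1
  if (d[1] == 1) { i0 <- i1 <- 1 }
  if (d[2] == 1) { j0 <- j1 <- 1 }
  if (d[3] == 1) { k0 <- k1 <- 1 }
  wi <- fi - i0; wj <- fj - j0; wk <- fk - k0
  g <- function(i, j, k) arr[cbind(i, j, k)]
  (1 - wk) * ((1 - wi) * ((1 - wj) * g(i0, j0, k0) + wj * g(i0, j1, k0)) +
              wi * ((1 - wj) * g(i1, j0, k0) + wj * g(i1, j1, k0))) +
  wk * ((1 - wi) * ((1 - wj) * g(i0, j0, k1) + wj * g(i0, j1, k1)) +
        wi * ((1 - wj) * g(i1, j0, k1) + wj * g(i1, j1, k1)))
}

#' Resample a skeleton at fixed node spacing and measure radii
#'
#' Re-parameterizes every segment by arc length with nodes every
#' `nodeSpacing` microns (0.5 by default; the count is rounded so actual
#' spacing stays within 20% of nominal), and assigns each node a radius from
#' the anisotropic distance transform of the binary stack: the interpolated
#' distance to the nearest background voxel center minus half an in-plane
#' voxel, placing the fiber surface halfway between the last foreground and
#' first background voxel. Segments shorter than the node spacing collapse
#' to a single midpoint node.
#'
#' @param skeleton raw [FiberSkeleton-class] from [skeletonizeStack()].
#' @param distanceMap distance array from [distanceTransform()] of the same
#'   binary stack (microns).
#' @param spacing voxel spacing in microns, named `c(x, y, z)`.
#' @param nodeSpacing nominal spacing between nodes, microns.
#' @return A [FiberSkeleton-class] with equally spaced nodes and positive
#'   radii; `nodeSpacing` records the nominal spacing.
#' @export
resampleAndMeasure <- function(skeleton, distanceMap,
                               spacing = c(x = 0.18, y = 0.18, z = 0.48),
                               nodeSpacing = 0.5) {
  stopifnot(is(skeleton, "FiberSkeleton"), nodeSpacing > 0)
  spacing <- spacing[c("x", "y", "z")]
  halfVox <- min(spacing[c("x", "y")]) / 2
  nodes <- skeleton@nodes
  outX <- outY <- outZ <- numeric(0)
  segs <- list()
  for (chain in skeleton@segments) {
    px <- nodes$x[chain]; py <- nodes$y[chain]; pz <- nodes$z[chain]
    if (length(chain) >= 2) {
      step <- sqrt(diff(px)^2 + diff(py)^2 + diff(pz)^2)
      cum <- c(0, cumsum(step))
      L <- cum[length(cum)]
    } else L <- 0
    if (L >= 0.8 * nodeSpacing && L < nodeSpacing) {
      # representable by two endpoint nodes within the 20% spacing band
      qx <- px[c(1, length(px))]
      qy <- py[c(1, length(py))]
      qz <- pz[c(1, length(pz))]
    } else if (L < nodeSpacing) {
      # single midpoint node
      mid <- if (L > 0) L / 2 else 0
      if (length(chain) >= 2) {
        qx <- stats::approx(cum, px, xout = mid)$y
        qy <- stats::approx(cum, py, xout = mid)$y
        qz <- stats::approx(cum, pz, xout = mid)$y
      } else {
        qx <- px; qy <- py; qz <- pz
      }
    } else {
      nN <- max(2L, round(L / nodeSpacing) + 1L)
      tt <- seq(0, L, length.out = nN)
      qx <- stats::approx(cum, px, xout = tt)$y
      qy <- stats::approx(cum, py, xout = tt)$y
      qz <- stats::approx(cum, pz, xout = tt)$y
    }
    idx <- length(outX) + seq_along(qx)
    outX <- c(outX, qx); outY <- c(outY, qy); outZ <- c(outZ, qz)
    segs[[length(segs) + 1]] <- idx
  }
  r <- .interp3(distanceMap, outX, outY, outZ, spacing) - halfVox
  r <- pmax(r, halfVox / 2)
  new("FiberSkeleton",
      nodes = data.frame(x = outX, y = outY, z = outZ, radius = r),
      segments = segs, nodeSpacing = nodeSpacing)
}
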