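# Labeled-depth screening and depth-corrected fiber metrics.

#' Labeled-depth profile of a probe
#'
#' Antibody penetration limits immunolabeling to a superficial band of the
#' section, so quantification must be restricted to the well-labeled depth.
#' Per z-slice the 0.99 intensity quantile of the *raw* (pre-smoothing)
#' stack is computed; the labeled depth Thref is the contiguous run of
#' slices with q99 above the cutoff (75 of 255), counted from the labeled
#' surface (the stack face with the brighter first slice), times the z-step.
#' Supra-threshold slices beyond the first gap are not counted. A probe is
#' accepted only when Thref exceeds `minDepth` (2 um).
#'
#' @param stack raw [ProbeStack-class] (acquisition-scale intensities).
#' @param cutoff q99 acceptance cutoff (default 75).
#' @param minDepth minimum labeled depth in um for acceptance (default 2).
#' @return List of class `"DepthProfile"`: `q99` (per slice), `surface`
#'   (`"front"` = slice 1, `"back"` = last slice), `thref` (um), `accepted`,
#'   `dz`, `nSlices`.
#' @export
labeledDepth <- function(stack, cutoff = 75, minDepth = 2) {
  stopifnot(is(stack, "ProbeStack"))
  x <- stack@intensity
  nz <- dim(x)[3]
  q99 <- vapply(seq_len(nz),
                function(k) stats::quantile(x[, , k], 0.99, names = FALSE),
                numeric(1))
  surface <- if (q99[1] >= q99[nz]) "front" else "back"
  ord <- if (surface == "front") q99 else rev(q99)
  run <- 0L
  for (v in ord) {
    if (v > cutoff) run <- run + 1L else break
  }
  dz <- stack@spacing[["z"]]
  thref <- run * dz
  structure(list(q99 = q99, surface = surface, thref = thref,
                 accepted = thref > minDepth, dz = dz, nSlices = nz),
            class = "DepthProfile")
}

#' @export
print.DepthProfile <- function(x, ...) {
  cat(sprintf("DepthProfile: Thref = %.2f um from the %s surface (%s)\n",
              x$thref, x$surface,
              if (x$accepted) "accepted" else "rejected"))
  invisible(x)
}

# depth below the labeled surface for node z-coordinates (um)
.nodeDepth <- function(z, profile) {
  if (profile$surface == "front") z
  else (profile$nSlices - 1) * profile$dz - z
}

#' Depth-corrected fiber metrics for one probe
#'
#' Quantifies a resampled skeleton within the labeled depth of an accepted
#' probe. The quantification volume is
#' `V = probeArea * (Thref + borderCorrection)`, the 0.5 um border
#' correction accounting for structures bordering the probe limits. Reported
#' metrics:
#'
#' * `lengthDensity` — total centerline arc length inside the labeled depth
#'   divided by `V` (um per um^3, i.e. um^-2);
#' * `meanDiameter` — mean over in-depth nodes of twice the node radius (um;
#'   `NA` when no fiber lies in the labeled region);
#' * `volumetricFraction` — summed cylinder volume
#'   (pi r^2 integrated along the in-depth arc) over `V`, capped at 1.
#'
#' `lengthDensityUncorrected` (volume without the border correction) is also
#' reported.
#'
#' @param skeleton resampled [FiberSkeleton-class].
#' @param profile accepted `DepthProfile` from [labeledDepth()].
#' @param probeArea probe XY area in um^2.
#' @param borderCorrection section-depth correction in um (default 0.5).
#' @return List of class `"FiberMetrics"`: `lengthDensity`, `meanDiameter`,
#'   `volumetricFraction`, `lengthDensityUncorrected`, `lengthInDepth`,
#'   `volume`, `thref`.
#' @export
fiberMetrics <- function(skeleton, profile, probeArea,
                         borderCorrection = 0.5) {
  stopifnot(is(skeleton, "FiberSkeleton"), inherits(profile, "DepthProfile"),
            probeArea > 0)
  if (!profile$accepted)
    stop(structure(class = c("excludedProbe", "error", "condition"),
                   list(message = sprintf(
                     "probe excluded: labeled depth %.2f um is insufficient",
                     profile$thref), call = sys.call())))
  V <- probeArea * (profile$thref + borderCorrection)
  V0 <- probeArea * profile$thref
  nodes <- skeleton@nodes
  depth <- .nodeDepth(nodes$z, profile)
  inside <- depth >= -1e-9 & depth <= profile$thref + 1e-9
  len <- 0
  cylVol <- 0
  for (chain in skeleton@segments) {
    if (length(chain) < 2) next
    a <- chain[-length(chain)]; b <- chain[-1]
    keep <- inside[a] & inside[b]
    if (!any(keep)) next
    dl <- sqrt((nodes$x[b] - nodes$x[a])^2 + (nodes$y[b] - nodes$y[a])^2 +
               (nodes$z[b] - nodes$z[a])^2)
    len <- len + sum(dl[keep])
    r2 <- (nodes$radius[a]^2 + nodes$radius[b]^2) / 2
    cylVol <- cylVol + sum(pi * r2[keep] * dl[keep])
  }
  nIn <- sum(inside & !is.na(nodes$radius))
  structure(list(
    lengthDensity = len / V,
    meanDiameter = if (nIn > 0) mean(2 * nodes$radius[inside], na.rm = TRUE)
                   else NA_real_,
    volumetricFraction = min(cylVol / V, 1),
    lengthDensityUncorrected = if (V0 > 0) len / V0 else NA_real_,
    lengthInDepth = len,
    volume = V,
    thref = profile$thref
  ), class = "FiberMetrics")
}

#' @export
print.FiberMetrics <- function(x, ...) {
  cat(sprintf(paste0(
    "FiberMetrics: length density %.4g um^-2, mean diameter %.3g um,\n",
    "  volumetric fraction %.4g (Thref %.2f um, volume %.4g um^3)\n"),
    x$lengthDensity, x$meanDiameter, x$volumetricFraction, x$thref,
    x$volume))
  invisible(x)
}

#' Full fiber reconstruction pipeline for one probe
#'
#' Runs the whole chain on a raw probe: labeled-depth screening on the raw
#' intensities, edge-preserving smoothing, Otsu binarization,
#' topology-preserving skeletonization, half-micron node resampling with
#' distance-transform radii, and depth-corrected metrics. Rejected probes
#' return `accepted = FALSE` with `NA` metrics.
#'
#' @param stack raw [ProbeStack-class].
#' @param q99Cutoff labeled-depth intensity cutoff (default 75).
#' @param minDepth minimum labeled depth in um (default 2).
#' @param borderCorrection depth correction in um (default 0.5).
#' @param minBranchLength skeleton spur-pruning length in um (default 1).
#' @param probeArea probe XY area in um^2; defaults to the full stack
#'   footprint.
#' @return List with `accepted`, `metrics` (`FiberMetrics` or `NULL`),
#'   `skeleton`, `profile`, `threshold`.
#' @export
fiberPipeline <- function(stack, q99Cutoff = 75, minDepth = 2,
                          borderCorrection = 0.5, minBranchLength = 1,
                          probeArea = NULL) {
  stopifnot(is(stack, "ProbeStack"))
  d <- dim(stack@intensity)
  sp <- stack@spacing
  if (is.null(probeArea))
    probeArea <- (d[1] * sp[["y"]]) * (d[2] * sp[["x"]])
  profile <- labeledDepth(stack, cutoff = q99Cutoff, minDepth = minDepth)
  if (!profile$accepted)
    return(list(accepted = FALSE, metrics = NULL, skeleton = NULL,
                profile = profile, threshold = NA_real_))
  sm <- preprocessStack(stack)
  bin <- binarizeOtsu(sm)
  skel <- skeletonizeStack(bin$mask, sp, minBranchLength = minBranchLength)
  dmap <- distanceTransform(bin$mask, sp)
  skel <- resampleAndMeasure(skel, dmap, sp)
  metrics <- fiberMetrics(skel, profile, probeArea,
                          borderCorrection = borderCorrection)
  list(accepted = TRUE, metrics = metrics, skeleton = skel,
       profile = profile, threshold = bin$threshold)
}
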