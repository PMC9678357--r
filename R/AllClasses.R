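#' @import methods
NULL

TRAJECTORY_SHAPES <- c("linear", "asymptotic", "quadratic")

#' VolumeSeries: longitudinal voxel volumes for a cohort
#'
#' Container for per-subject, per-session modulated tissue-volume maps (the
#' substrate of voxelwise morphometry). Values are unitless modulated tissue
#' probabilities (probability times Jacobian determinant); the grid is
#' isotropic with voxel size in mm.
#'
#' @slot data 5-d numeric array `[subject, session, x, y, z]`.
#' @slot voxelSize isotropic voxel edge length in mm.
#' @slot sessionDays strictly increasing experimental days, one per session.
#' @slot subjects data.frame with columns `id`, `group`
#'   (`"trained"`/`"control"`), `tiv` (mm^3).
#' @slot missing logical matrix `[subject, session]`; `TRUE` marks a session
#'   that was not acquired for that subject.
#'
#' @seealso [simLongitudinalVolumes()], [readVolumeSeries()],
#'   [voxelwiseMaps()], [extractVoi()]
#' @export
setClass("VolumeSeries",
  representation(
    data = "array",
    voxelSize = "numeric",
    sessionDays = "numeric",
    subjects = "data.frame",
    missing = "matrix"
  )
)

setValidity("VolumeSeries", function(object) {
  d <- dim(object@data)
  msg <- character()
  if (length(d) != 5)
    msg <- c(msg, "data must be a 5-d array [subject, session, x, y, z]")
  if (length(object@voxelSize) != 1 || object@voxelSize <= 0)
    msg <- c(msg, "voxelSize must be a single positive number")
  if (is.unsorted(object@sessionDays, strictly = TRUE))
    msg <- c(msg, "sessionDays must be strictly increasing")
  if (length(d) == 5 && d[2] != length(object@sessionDays))
    msg <- c(msg, "session dimension must match length(sessionDays)")
  if (length(d) == 5 && d[1] != nrow(object@subjects))
    msg <- c(msg, "subject dimension must match nrow(subjects)")
  if (!all(c("id", "group", "tiv") %in% names(object@subjects)))
    msg <- c(msg, "subjects needs columns id, group, tiv")
  else if (any(object@subjects$tiv <= 0))
    msg <- c(msg, "tiv must be positive")
  if (!identical(dim(object@missing), d[1:2]))
    msg <- c(msg, "missing must be a [subject, session] logical matrix")
  if (min(object@data, na.rm = TRUE) < 0)
    msg <- c(msg, "volume values must be non-negative")
  if (length(msg)) msg else TRUE
})

#' VoxelFitMaps: voxelwise statistical maps per trajectory shape
#'
#' Product of [voxelwiseMaps()]: per-shape 3D maps of the group-by-time
#' interaction coefficient, its Wald p-value, AIC and AICc, the per-shape
#' FDR-significant masks split by interaction sign, and the AIC
#' preferred-model label map.
#'
#' @slot shapes character vector of fitted trajectory shapes.
#' @slot beta3,pvalue,aic,aicc named lists of 3D arrays, one per shape.
#' @slot sigPos,sigNeg named lists of logical 3D arrays: FDR-significant
#'   voxels with positive / negative interaction.
#' @slot preferred integer 3D array; 0 = no decisively preferred shape,
#'   otherwise the index into `shapes`.
#' @slot mask logical 3D analysis mask.
#' @slot q FDR level used.
#' @slot deltaAic AIC margin used for the preferred-model map.
#' @slot voxelSize voxel edge length in mm.
#' @slot qc data.frame of degenerate / non-converged voxels.
#' @export
setClass("VoxelFitMaps",
  representation(
    shapes = "character",
    beta3 = "list", pvalue = "list", aic = "list", aicc = "list",
    sigPos = "list", sigNeg = "list",
    preferred = "array",
    mask = "array",
    q = "numeric",
    deltaAic = "numeric",
    voxelSize = "numeric",
    qc = "data.frame"
  )
)

setValidity("VoxelFitMaps", function(object) {
  msg <- character()
  if (!all(object@shapes %in% TRAJECTORY_SHAPES))
    msg <- c(msg, "unknown trajectory shape")
  for (s in object@shapes) {
    p <- object@pvalue[[s]]
    if (is.null(p)) { msg <- c(msg, paste("missing p map for", s)); next }
    pin <- p[object@mask]
    pin <- pin[is.finite(pin)]
    if (length(pin) && (min(pin) < 0 || max(pin) > 1))
      msg <- c(msg, "p-values outside [0, 1]")
    for (sl in c("sigPos", "sigNeg")) {
      m <- slot(object, sl)[[s]]
      if (!is.null(m) && any(m & !object@mask))
        msg <- c(msg, "significance mask escapes the analysis mask")
    }
  }
  if (length(msg)) msg else TRUE
})

#' ProbeStack: 3D confocal intensity stack
#'
#' An 8-bit confocal probe with anisotropic voxel spacing. The intensity
#' array is indexed `[y, x, z]` (rows, columns, slices) and `spacing` is the
#' named vector `c(x=, y=, z=)` in microns; the default matches 0.18 um
#' in-plane sampling with a 0.48 um z-step.
#'
#' @slot intensity 3D numeric array `[y, x, z]`, values in `[0, 255]`.
#' @slot spacing named numeric vector `c(x, y, z)` in microns.
#' @seealso [simFiberStack()], [preprocessStack()], [labeledDepth()]
#' @export
setClass("ProbeStack",
  representation(intensity = "array", spacing = "numeric")
)

setValidity("ProbeStack", function(object) {
  msg <- character()
  if (length(dim(object@intensity)) != 3)
    msg <- c(msg, "intensity must be a 3D array [y, x, z]")
  if (length(object@spacing) != 3 || any(object@spacing <= 0))
    msg <- c(msg, "spacing must be three positive values c(x, y, z)")
  r <- range(object@intensity)
  if (r[1] < 0 || r[2] > 255)
    msg <- c(msg, "intensities must lie in [0, 255]")
  if (length(msg)) msg else TRUE
})

#' FiberSkeleton: centerline graph of reconstructed fibers
#'
#' Fibers are represented by ordered chains of centerline nodes with a local
#' radius at each node. After [resampleAndMeasure()] nodes are spaced 0.5 um
#' (nominal) along each segment.
#'
#' @slot nodes data.frame with columns `x`, `y`, `z` (um) and `radius` (um;
#'   `NA` before radii are measured).
#' @slot segments list of integer vectors, each an ordered chain of row
#'   indices into `nodes`.
#' @slot nodeSpacing nominal arc-length spacing between consecutive nodes in
#'   um (`NA` for a raw voxel-resolution skeleton).
#' @seealso [skeletonizeStack()], [resampleAndMeasure()], [fiberMetrics()]
#' @export
setClass("FiberSkeleton",
  representation(nodes = "data.frame", segments = "list",
                 nodeSpacing = "numeric")
)

setValidity("FiberSkeleton", function(object) {
  msg <- character()
  if (!all(c("x", "y", "z", "radius") %in% names(object@nodes)))
    msg <- c(msg, "nodes needs columns x, y, z, radius")
  r <- object@nodes$radius
  if (any(!is.na(r) & r <= 0)) msg <- c(msg, "radii must be positive")
  ns <- unlist(object@segments)
  if (length(ns) && (min(ns) < 1 || max(ns) > nrow(object@nodes)))
    msg <- c(msg, "segment indices out of range")
  if (length(msg)) msg else TRUE
})

#' ModelComparison: pairwise time-course model comparison
#'
#' Result of comparing trajectory models by AICc. `delta` is the AICc of the
#' runner-up minus the AICc of the preferred model (>= 0); `probability` is
#' the pairwise Akaike probability exp(0.5 D) / (1 + exp(0.5 D)) of the
#' preferred model, and the comparison is `decisive` when delta-AICc > 2.
#'
#' @slot preferred name of the lower-AICc model.
#' @slot delta AICc difference (runner-up minus preferred), >= 0.
#' @slot probability Akaike probability of the preferred model, in [0.5, 1].
#' @slot decisive logical, `delta > 2`.
#' @slot table data.frame with one row per model (model, k, n, logLik, AIC,
#'   AICc, deltaAICc, probability_pct), or a zero-row data.frame when the
#'   comparison was built from bare AICc values.
#' @seealso [akaikeProbability()], [compareTrajectories()]
#' @export
setClass("ModelComparison",
  representation(preferred = "character", delta = "numeric",
                 probability = "numeric", decisive = "logical",
                 table = "data.frame")
)

setValidity("ModelComparison", function(object) {
  msg <- character()
  if (object@delta < 0) msg <- c(msg, "delta must be >= 0")
  if (object@probability < 0.5 - 1e-12 || object@probability > 1)
    msg <- c(msg, "probability must lie in [0.5, 1]")
  if (!identical(object@decisive, object@delta > 2))
    msg <- c(msg, "decisive must equal delta > 2")
  if (length(msg)) msg else TRUE
})
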