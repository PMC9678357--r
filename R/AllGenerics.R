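# Accessor generics and show methods

#' @rdname VolumeSeries-class
#' @param object,x a `VolumeSeries`
#' @export
setGeneric("volumeData", function(x) standardGeneric("volumeData"))
#' @rdname VolumeSeries-class
#' @export
setMethod("volumeData", "VolumeSeries", function(x) x@data)

#' @rdname VolumeSeries-class
#' @export
setGeneric("voxelSize", function(x) standardGeneric("voxelSize"))
#' @rdname VolumeSeries-class
#' @export
setMethod("voxelSize", "VolumeSeries", function(x) x@voxelSize)

#' @rdname VolumeSeries-class
#' @export
setGeneric("sessionDays", function(x) standardGeneric("sessionDays"))
#' @rdname VolumeSeries-class
#' @export
setMethod("sessionDays", "VolumeSeries", function(x) x@sessionDays)

#' @rdname VolumeSeries-class
#' @export
setGeneric("subjectInfo", function(x) standardGeneric("subjectInfo"))
#' @rdname VolumeSeries-class
#' @export
setMethod("subjectInfo", "VolumeSeries", function(x) x@subjects)

#' @rdname VolumeSeries-class
#' @export
setGeneric("missingSessions", function(x) standardGeneric("missingSessions"))
#' @rdname VolumeSeries-class
#' @export
setMethod("missingSessions", "VolumeSeries", function(x) x@missing)

#' @rdname VolumeSeries-class
#' @export
setMethod("show", "VolumeSeries", function(object) {
  d <- dim(object@data)
  cat("VolumeSeries:", d[1], "subjects x", d[2], "sessions, grid",
      paste(d[3:5], collapse = " x "), "\n")
  cat("  voxel size:", object@voxelSize, "mm; days:",
      paste(object@sessionDays, collapse = ", "), "\n")
  cat("  groups:", paste(sprintf("%s (n=%d)",
      names(table(object@subjects$group)), table(object@subjects$group)),
      collapse = ", "), "\n")
  nm <- sum(object@missing)
  if (nm) cat("  missing subject-sessions:", nm, "\n")
})

#' @rdname ProbeStack-class
#' @param object,x a `ProbeStack`
#' @export
setGeneric("intensity", function(x) standardGeneric("intensity"))
#' @rdname ProbeStack-class
#' @export
setMethod("intensity", "ProbeStack", function(x) x@intensity)

#' @rdname ProbeStack-class
#' @export
setGeneric("spacing", function(x) standardGeneric("spacing"))
#' @rdname ProbeStack-class
#' @export
setMethod("spacing", "ProbeStack", function(x) x@spacing)

#' @rdname ProbeStack-class
#' @export
setMethod("show", "ProbeStack", function(object) {
  d <- dim(object@intensity)
  cat("ProbeStack:", d[1], "x", d[2], "px,", d[3], "slices;",
      "spacing", paste(signif(object@spacing, 3), collapse = "/"), "um\n")
  cat("  intensity range:", paste(round(range(object@intensity), 1),
      collapse = " - "), "\n")
})

#' @rdname FiberSkeleton-class
#' @param object,x a `FiberSkeleton`
#' @export
setGeneric("skeletonNodes", function(x) standardGeneric("skeletonNodes"))
#' @rdname FiberSkeleton-class
#' @export
setMethod("skeletonNodes", "FiberSkeleton", function(x) x@nodes)

#' @rdname FiberSkeleton-class
#' @export
setGeneric("skeletonSegments", function(x) standardGeneric("skeletonSegments"))
#' @rdname FiberSkeleton-class
#' @export
setMethod("skeletonSegments", "FiberSkeleton", function(x) x@segments)

#' Total centerline length of a skeleton
#'
#' Sum of Euclidean arc lengths over all segments, in microns.
#' @param x a `FiberSkeleton`
#' @export
setGeneric("skeletonLength", function(x) standardGeneric("skeletonLength"))
#' @rdname skeletonLength
#' @export
setMethod("skeletonLength", "FiberSkeleton", function(x) {
  sum(vapply(x@segments, function(s) .chainLength(x@nodes, s), numeric(1)))
})

#' @rdname FiberSkeleton-class
#' @export
setMethod("show", "FiberSkeleton", function(object) {
  cat("FiberSkeleton:", nrow(object@nodes), "nodes,",
      length(object@segments), "segments, total length",
      round(skeletonLength(object), 2), "um\n")
  if (!is.na(object@nodeSpacing))
    cat("  resampled at", object@nodeSpacing, "um; mean diameter",
        round(mean(2 * object@nodes$radius, na.rm = TRUE), 3), "um\n")
})

#' @rdname ModelComparison-class
#' @param object a `ModelComparison`
#' @export
setMethod("show", "ModelComparison", function(object) {
  cat(sprintf("ModelComparison: preferred '%s' (delta-AICc = %.3g, p = %.2f%%, %s)\n",
              object@preferred, object@delta, 100 * object@probability,
              if (object@decisive) "decisive" else "not decisive"))
  if (nrow(object@table)) print(object@table, row.names = FALSE)
})

#' @rdname VoxelFitMaps-class
#' @param object a `VoxelFitMaps`
#' @export
setMethod("show", "VoxelFitMaps", function(object) {
  cat("VoxelFitMaps:", paste(object@shapes, collapse = ", "), "on",
      sum(object@mask), "in-mask voxels (q =", object@q, ")\n")
  for (s in object@shapes) {
    cat(sprintf("  %-11s sig+ %d, sig- %d voxels\n", s,
                sum(object@sigPos[[s]]), sum(object@sigNeg[[s]])))
  }
  lab <- table(factor(object@preferred[object@mask], levels = seq_along(object@shapes),
                      labels = object@shapes))
  cat("  preferred-model voxels (delta-AIC >", object@deltaAic, "):",
      paste(sprintf("%s %d", names(lab), lab), collapse = ", "), "\n")
  if (nrow(object@qc)) cat("  QC-flagged voxel fits:", nrow(object@qc), "\n")
})
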