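# File-format glue: NIfTI volume series, TIFF stacks, skeleton CSV,
# ROI JSON, statistical-map export.

#' Write a volume series to per-subject-session NIfTI files
#'
#' One gzipped NIfTI-1 file per acquired subject-session, named
#' `<id>_day<day>.nii.gz`, plus `meta.csv` with columns `id`, `group`,
#' `tiv_mm3`, `days_present` (semicolon-separated). Missing sessions are
#' simply not written.
#'
#' @param series a [VolumeSeries-class].
#' @param dir output directory (created if needed).
#' @return The directory, invisibly.
#' @export
writeVolumeSeries <- function(series, dir) {
  stopifnot(is(series, "VolumeSeries"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  d <- dim(series@data)
  vs <- series@voxelSize
  days <- series@sessionDays
  sub <- series@subjects
  present <- character(nrow(sub))
  for (i in seq_len(d[1])) {
    got <- integer(0)
    for (j in seq_len(d[2])) {
      if (series@missing[i, j]) next
      vol <- array(series@data[i, j, , , ], dim = d[3:5])
      img <- RNifti::asNifti(vol, reference = NULL)
      RNifti::pixdim(img) <- rep(vs, 3)
      RNifti::writeNifti(img, file.path(dir, sprintf("%s_day%d.nii.gz",
                                                     sub$id[i], days[j])))
      got <- c(got, days[j])
    }
    present[i] <- paste(got, collapse = ";")
  }
  meta <- data.frame(id = sub$id, group = sub$group, tiv_mm3 = sub$tiv,
                     days_present = present)
  utils::write.csv(meta, file.path(dir, "meta.csv"), row.names = FALSE)
  invisible(dir)
}

#' Read a volume series from NIfTI files and a metadata table
#'
#' Expects the layout written by [writeVolumeSeries()]: one NIfTI per
#' subject-session plus `meta.csv` (`id`, `group`, `tiv_mm3`,
#' `days_present`). A listed but absent file marks that subject-session
#' missing rather than failing; a file on a different grid or voxel size is
#' a hard error naming the offender.
#'
#' @param dir directory with the NIfTI files.
#' @param metaCsv path to the metadata CSV (default `meta.csv` inside
#'   `dir`).
#' @param sessionDays sessions to assemble; defaults to the union of listed
#'   days.
#' @return A [VolumeSeries-class].
#' @export
readVolumeSeries <- function(dir, metaCsv = file.path(dir, "meta.csv"),
                             sessionDays = NULL) {
  meta <- utils::read.csv(metaCsv, stringsAsFactors = FALSE)
  stopifnot(all(c("id", "group", "tiv_mm3", "days_present") %in% names(meta)))
  daysList <- lapply(strsplit(as.character(meta$days_present), ";"),
                     as.numeric)
  if (is.null(sessionDays)) sessionDays <- sort(unique(unlist(daysList)))
  ns <- nrow(meta)
  nt <- length(sessionDays)
  grid <- NULL
  vs <- NULL
  refFile <- NULL
  data <- NULL
  missing <- matrix(TRUE, ns, nt)
  for (i in seq_len(ns)) {
    for (j in seq_len(nt)) {
      f <- file.path(dir, sprintf("%s_day%d.nii.gz", meta$id[i],
                                  sessionDays[j]))
      if (!file.exists(f)) next
      img <- RNifti::readNifti(f)
      vol <- as.array(img)
      pd <- RNifti::pixdim(img)
      if (is.null(grid)) {
        grid <- dim(vol)
        vs <- pd[1]
        refFile <- f
        data <- array(NA_real_, dim = c(ns, nt, grid))
      } else if (!all(dim(vol) == grid) ||
                 max(abs(pd[1:3] - vs)) > 1e-6) {
        stop("grid/voxel-size mismatch: ", f, " differs from ", refFile)
      }
      data[i, j, , , ] <- vol
      missing[i, j] <- FALSE
    }
  }
  if (is.null(grid)) stop("no volume files found in ", dir)
  data[is.na(data)] <- 0
  new("VolumeSeries", data = data, voxelSize = vs,
      sessionDays = sessionDays,
      subjects = data.frame(id = meta$id, group = meta$group,
                            tiv = meta$tiv_mm3),
      missing = missing)
}

# connected components of a logical 3D mask (26-connectivity)
.labelClusters <- function(mask) {
  vox <- which(mask, arr.ind = TRUE)
  if (nrow(vox) == 0)
    return(list(vox = vox, label = integer(0), n = 0L))
  edges <- .voxelEdges(vox, dim(mask))
  g <- igraph::make_empty_graph(n = nrow(vox), directed = FALSE)
  if (!is.null(edges) && nrow(edges))
    g <- igraph::add_edges(g, t(edges))
  comp <- igraph::components(g)
  list(vox = vox, label = comp$membership, n = comp$no)
}

#' Write statistical maps and a cluster table
#'
#' Exports a [VoxelFitMaps-class] as float32 NIfTI maps (interaction
#' estimate, p-value, AIC per shape; significance masks split by sign; the
#' preferred-model label map), a tab-separated cluster table (shape, sign,
#' cluster label, voxel count, volume in mm^3 via [clusterVolume()], peak =
#' minimum-p voxel), and a JSON run manifest.
#'
#' @param maps a [VoxelFitMaps-class].
#' @param dir output directory.
#' @param seed optional seed to record in the manifest.
#' @return Path of the cluster table, invisibly.
#' @export
writeStatMaps <- function(maps, dir, seed = NULL) {
  stopifnot(is(maps, "VoxelFitMaps"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  vs <- maps@voxelSize
  wr <- function(arr, name, type = "float") {
    a <- array(as.numeric(arr), dim = dim(arr))
    img <- RNifti::asNifti(a)
    RNifti::pixdim(img) <- rep(vs, 3)
    RNifti::writeNifti(img, file.path(dir, paste0(name, ".nii.gz")),
                       datatype = type)
  }
  rows <- list()
  for (s in maps@shapes) {
    wr(maps@beta3[[s]], paste0("beta3_", s))
    wr(maps@pvalue[[s]], paste0("p_", s))
    wr(maps@aic[[s]], paste0("aic_", s))
    for (sign in c("pos", "neg")) {
      m <- if (sign == "pos") maps@sigPos[[s]] else maps@sigNeg[[s]]
      wr(m, sprintf("sig_%s_%s", s, sign), type = "uint8")
      lab <- .labelClusters(m)
      if (lab$n == 0) next
      for (cl in seq_len(lab$n)) {
        cvox <- lab$vox[lab$label == cl, , drop = FALSE]
        pv <- maps@pvalue[[s]][cvox]
        pk <- cvox[which.min(pv), ]
        rows[[length(rows) + 1]] <- data.frame(
          shape = s, sign = sign, cluster = cl, n_voxels = nrow(cvox),
          volume_mm3 = clusterVolume(nrow(cvox), vs),
          peak_x = pk[1], peak_y = pk[2], peak_z = pk[3],
          peak_p = min(pv))
      }
    }
  }
  wr(maps@preferred, "preferred_model", type = "int16")
  tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(shape = character(), sign = character(), cluster = integer(),
               n_voxels = integer(), volume_mm3 = numeric(),
               peak_x = integer(), peak_y = integer(), peak_z = integer(),
               peak_p = numeric())
  tabPath <- file.path(dir, "clusters.tsv")
  utils::write.table(tab, tabPath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  manifest <- list(package = "plastimap",
                   version = as.character(utils::packageVersion("plastimap")),
                   rVersion = R.version.string,
                   shapes = maps@shapes, q = maps@q,
                   deltaAic = maps@deltaAic, voxelSize_mm = vs,
                   maskVoxels = sum(maps@mask), seed = seed,
                   units = list(mri = "mm"))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, null = "null")
  invisible(tabPath)
}

#' Read / write a confocal stack as multi-page TIFF
#'
#' 8-bit multi-page TIFF, one page per z-slice; spacing is supplied by the
#' caller (TIFF carries no reliable 3D calibration).
#'
#' @param file TIFF path.
#' @param spacing voxel spacing in um, named `c(x, y, z)`.
#' @return [readStack()]: a [ProbeStack-class]; [writeStack()]: the path,
#'   invisibly.
#' @export
readStack <- function(file, spacing = c(x = 0.18, y = 0.18, z = 0.48)) {
  pages <- tiff::readTIFF(file, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  arr <- vapply(pages, function(p) {
    if (length(dim(p)) == 3) p <- p[, , 1]
    p
  }, matrix(0, nrow(pages[[1]]), ncol(pages[[1]])))
  probeStack(array(arr * 255, dim = dim(arr)), spacing)
}

#' @rdname readStack
#' @param stack a [ProbeStack-class] to write.
#' @export
writeStack <- function(stack, file) {
  stopifnot(is(stack, "ProbeStack"))
  x <- stack@intensity
  pages <- lapply(seq_len(dim(x)[3]),
                  function(k) round(x[, , k]) / 255)
  tiff::writeTIFF(pages, file, bits.per.sample = 8L)
  invisible(file)
}

#' Export skeleton nodes as CSV
#'
#' Writes `x_um, y_um, z_um, diameter_um`, the conventional point-cloud
#' export of fiber reconstructions.
#'
#' @param skeleton a [FiberSkeleton-class].
#' @param file output path.
#' @return The path, invisibly.
#' @export
writeSkeletonCsv <- function(skeleton, file) {
  stopifnot(is(skeleton, "FiberSkeleton"))
  n <- skeleton@nodes
  utils::write.csv(data.frame(x_um = n$x, y_um = n$y, z_um = n$z,
                              diameter_um = 2 * n$radius),
                   file, row.names = FALSE)
  invisible(file)
}

#' Read a polygon ROI from JSON
#'
#' JSON layout: an object with arrays `x` and `y` (pixel coordinates), or a
#' list of `[x, y]` vertex pairs.
#'
#' @param file JSON path.
#' @return Two-column matrix of vertices.
#' @export
readRoiJson <- function(file) {
  j <- jsonlite::read_json(file, simplifyVector = TRUE)
  if (is.list(j) && !is.null(j$x)) cbind(x = j$x, y = j$y)
  else {
    m <- as.matrix(j)
    colnames(m) <- c("x", "y")
    m
  }
}

#' Rectangle ROI helper
#'
#' @param x0,y0,x1,y1 rectangle corners in pixel coordinates.
#' @return Four-vertex polygon matrix for [roiMask()].
#' @export
rectRoi <- function(x0, y0, x1, y1) {
  cbind(x = c(x0, x1, x1, x0), y = c(y0, y0, y1, y1))
}
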