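# Three-class multi-Otsu densitometry of fluorescence sections.

#' Two thresholds separating three intensity classes
#'
#' Exhaustive maximization of the between-class variance over all threshold
#' pairs `(t1, t2)` of the 256-bin histogram, splitting the pixels into
#' background (`<= t1`), intermediate autofluorescence (`t1 < x <= t2`) and
#' specific signal (`> t2`). The search is exact (every pair is evaluated
#' through cumulative histogram sums).
#'
#' @param x numeric vector/array of intensities in `[0, 255]` (at least 3
#'   distinct values).
#' @param classes number of classes; only 3 is supported.
#' @return Integer vector `c(t1, t2)` with `t1 < t2`.
#' @export
multiOtsu <- function(x, classes = 3) {
  if (classes != 3) stop("only three-class segmentation is supported")
  v <- round(as.numeric(x))
  if (min(v) < 0 || max(v) > 255) stop("values must lie in [0, 255]")
  if (length(unique(v)) < 3)
    stop("need at least 3 distinct intensity values for 3 classes")
  h <- tabulate(v + 1L, nbins = 256L)
  p <- h / sum(h)
  W <- cumsum(p)                 # P(x <= t)
  M <- cumsum(p * (0:255))       # sum of x p(x), x <= t
  muT <- M[256]
  best <- -Inf
  bestT <- c(NA_integer_, NA_integer_)
  for (t1 in 0:253) {
    w1 <- W[t1 + 1]
    if (w1 <= 0) next
    m1 <- M[t1 + 1]
    t2 <- (t1 + 1):254
    w2 <- W[t2 + 1] - w1
    m2 <- M[t2 + 1] - m1
    w3 <- 1 - W[t2 + 1]
    m3 <- muT - M[t2 + 1]
    ok <- w2 > 0 & w3 > 0
    if (!any(ok)) next
    bcv <- ifelse(ok,
                  m1^2 / w1 + m2^2 / w2 + m3^2 / w3 - muT^2,
                  -Inf)
    i <- which.max(bcv)
    if (bcv[i] > best) {
      best <- bcv[i]
      bestT <- c(t1, t2[i])
    }
  }
  as.integer(bestT)
}

#' Rasterize a polygon ROI to a pixel mask
#'
#' @param dims image dimensions `c(nrow, ncol)`.
#' @param polygon two-column matrix/data.frame of `(x, y)` vertices in pixel
#'   coordinates (x = column, y = row).
#' @return Logical matrix: pixels whose centers fall inside the polygon.
#' @export
roiMask <- function(dims, polygon) {
  polygon <- as.matrix(polygon)[, 1:2, drop = FALSE]
  if (min(polygon) < 0.5 || max(polygon[, 1]) > dims[2] + 0.5 ||
      max(polygon[, 2]) > dims[1] + 0.5)
    stop("ROI polygon extends beyond the image bounds")
  px <- expand.grid(y = seq_len(dims[1]), x = seq_len(dims[2]))
  inside <- mgcv::in.out(rbind(polygon, polygon[1, ]),
                         cbind(px$x, px$y))
  matrix(inside, dims[1], dims[2])
}

#' Myelin immunoreactivity of one section ROI
#'
#' Segments the ROI pixels into three intensity classes by [multiOtsu()] and
#' quantifies the specific signal as the top class (pixels above `t2`):
#' `immunoreactivity` is their mean intensity and `specificFraction` the
#' area fraction they occupy. When no pixel exceeds `t2` the value is
#' missing (with a warning). Per-subject values are the unweighted mean of
#' `immunoreactivity` over that subject's sections.
#'
#' @param image 2D numeric matrix, intensities in `[0, 255]`.
#' @param roi logical matrix mask (from [roiMask()]) or `NULL` for the whole
#'   image.
#' @return List of class `"DensitometryResult"`: `t1`, `t2`,
#'   `immunoreactivity`, `specificFraction`, `nPixels`.
#' @export
myelinImmunoreactivity <- function(image, roi = NULL) {
  stopifnot(is.matrix(image))
  vals <- if (is.null(roi)) as.numeric(image) else {
    stopifnot(identical(dim(roi), dim(image)))
    image[roi]
  }
  if (!length(vals)) stop("ROI selects no pixels")
  t12 <- multiOtsu(vals)
  spec <- vals[vals > t12[2]]
  if (!length(spec)) {
    warning("no pixel above the upper threshold; immunoreactivity missing")
    ir <- NA_real_
  } else ir <- mean(spec)
  structure(list(t1 = t12[1], t2 = t12[2], immunoreactivity = ir,
                 specificFraction = length(spec) / length(vals),
                 nPixels = length(vals)),
            class = "DensitometryResult")
}

#' @export
print.DensitometryResult <- function(x, ...) {
  cat(sprintf(paste0("DensitometryResult: thresholds (%d, %d); ",
                     "immunoreactivity %.2f over %.1f%% of %d px\n"),
              x$t1, x$t2, x$immunoreactivity, 100 * x$specificFraction,
              x$nPixels))
  invisible(x)
}
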