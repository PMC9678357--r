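# Volume-level utilities: Gaussian smoothing and tissue-probability masking.

# Separable 1D convolution along each axis of a 3D array with half-sample
# symmetric (reflective) padding; kernel is normalized, so the array total
# is preserved for any symmetric kernel.
.gaussianKernel1d <- function(sigma) {
  if (sigma <= 0) return(1)
  r <- max(1L, ceiling(4 * sigma))
  k <- stats::dnorm(seq(-r, r), sd = sigma)
  k / sum(k)
}

.reflectIndex <- function(i, n) {
  # half-sample symmetric: ..., 2, 1, | 1, 2, ..., n, | n, n-1, ...
  j <- (i - 1) %% (2 * n)
  ifelse(j < n, j + 1, 2 * n - j)
}

.convolveAxis <- function(x, kernel, axis) {
  if (length(kernel) == 1) return(x)
  d <- dim(x)
  perm <- c(axis, setdiff(seq_along(d), axis))
  xp <- aperm(x, perm)
  n <- dim(xp)[1]
  m <- matrix(xp, nrow = n)
  r <- (length(kernel) - 1) / 2
  out <- matrix(0, n, ncol(m))
  for (o in seq(-r, r)) {
    idx <- .reflectIndex(seq_len(n) + o, n)
    out <- out + kernel[o + r + 1] * m[idx, , drop = FALSE]
  }
  aperm(array(out, dim = dim(xp)), order(perm))
}

.gaussianSmooth3d <- function(x, sigmaVox) {
  sigmaVox <- rep(sigmaVox, length.out = 3)
  for (ax in 1:3) x <- .convolveAxis(x, .gaussianKernel1d(sigmaVox[ax]), ax)
  x
}

#' Gaussian smoothing of a 3D volume
#'
#' Isotropic Gaussian smoothing with the kernel width given as full width at
#' half maximum in mm (the convention of morphometry pipelines, where
#' smoothing at five times the voxel size precedes statistics). The standard
#' deviation in voxels is `fwhm / (2 sqrt(2 ln 2)) / voxelSize`. Reflective
#' (half-sample symmetric) padding preserves the volume total. `fwhm = 0`
#' returns the input unchanged.
#'
#' @param volume 3D numeric array.
#' @param fwhm kernel full width at half maximum, mm.
#' @param voxelSize isotropic voxel size, mm.
#' @return Smoothed array of the same dimensions.
#' @examples
#' v <- array(0, c(9, 9, 9)); v[5, 5, 5] <- 1
#' sum(smoothVolume(v, fwhm = 0.4, voxelSize = 0.08))  # 1
#' @export
smoothVolume <- function(volume, fwhm, voxelSize = 0.08) {
  stopifnot(length(dim(volume)) == 3, fwhm >= 0, voxelSize > 0)
  if (fwhm == 0) return(volume)
  sigma <- fwhm / (2 * sqrt(2 * log(2))) / voxelSize
  .gaussianSmooth3d(volume, sigma)
}

#' Threshold a tissue-probability map into a binary mask
#'
#' Voxels whose tissue probability meets or exceeds the threshold (default
#' 0.2, i.e. 20%) enter the mask; used to restrict voxelwise statistics to
#' plausible gray- or white-matter voxels.
#'
#' @param prob array of tissue probabilities in `[0, 1]`.
#' @param threshold inclusion threshold (inclusive).
#' @return Logical array of the same shape.
#' @export
tpmMask <- function(prob, threshold = 0.2) {
  r <- range(prob)
  if (r[1] < 0 || r[2] > 1) stop("probabilities must lie in [0, 1]")
  array(prob >= threshold, dim = dim(prob))
}
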