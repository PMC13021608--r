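## Volume IO and preprocessing.
##
## The package assumes co-registered template-space inputs; registration and
## bias-field correction are upstream. IO is NIfTI-1 via RNifti.

.checkGeometry <- function(a, b, what = "volumes") {
  if (!identical(dim(a@data), dim(b@data)))
    stop(sprintf("geometry mismatch: %s have different dimensions", what))
  if (max(abs(a@spacing - b@spacing)) > 1e-5)
    stop(sprintf("geometry mismatch: %s have different spacing", what))
  invisible(TRUE)
}

#' Read a 3D NIfTI-1 volume
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @param mask if `TRUE`, return a [LesionMask] (binarized at 0.5).
#' @return a [BrainVolume] (or [LesionMask]).
#' @export
readVolume <- function(path, mask = FALSE) {
  if (!file.exists(path))
    stop(sprintf("file not found: %s", path))
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e)
                    stop(sprintf("malformed NIfTI file '%s': %s",
                                 path, conditionMessage(e))))
  d <- dim(img)
  if (length(d) == 4L && d[4] == 1L) {
    img2 <- array(as.numeric(img), d[1:3])
  } else if (length(d) != 3L) {
    stop(sprintf("expected 3D volume, got %dD in '%s'", length(d), path))
  } else {
    img2 <- array(as.numeric(img), d)
  }
  spacing <- RNifti::pixdim(img)[1:3]
  xf <- try(RNifti::xform(img), silent = TRUE)
  origin <- if (inherits(xf, "try-error")) c(0, 0, 0) else xf[1:3, 4]
  if (mask) LesionMask(img2, spacing, origin)
  else BrainVolume(img2, spacing, origin)
}

#' Write a volume as NIfTI-1
#'
#' Round-trip write-then-read preserves voxel data bit-exactly (data are
#' stored as float64) and geometry to float32 precision.
#'
#' @param volume a [BrainVolume] or [LesionMask].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
writeVolume <- function(volume, path) {
  stopifnot(is(volume, "BrainVolume"))
  img <- RNifti::asNifti(volume@data)
  RNifti::pixdim(img) <- volume@spacing
  aff <- diag(4)
  diag(aff)[1:3] <- volume@spacing
  aff[1:3, 4] <- volume@origin
  RNifti::sform(img) <- structure(aff, code = 2L)
  RNifti::qform(img) <- structure(aff, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Z-score intensity normalization over included voxels
#'
#' Standardizes intensities to mean 0 / SD 1 over voxels that are neither
#' background (exact zeros) nor inside `maskExclude`; excluded and background
#' voxels are set to 0 in the output. Because the statistics are computed
#' only over included voxels, the output is exactly invariant to any affine
#' rescaling of the input and to arbitrary intensity changes inside the
#' excluded region.
#'
#' @param volume a [BrainVolume].
#' @param maskExclude optional [LesionMask] of voxels to exclude.
#' @return a normalized [BrainVolume].
#' @export
normalizeIntensity <- function(volume, maskExclude = NULL) {
  stopifnot(is(volume, "BrainVolume"))
  x <- volume@data
  include <- x != 0
  if (!is.null(maskExclude)) {
    .checkGeometry(volume, maskExclude, "volume and mask")
    include <- include & maskExclude@data == 0
  }
  v <- x[include]
  if (length(v) == 0L)
    stop("empty ROI: no foreground voxels outside the exclusion mask")
  if (length(unique(v)) < 2L)
    stop("cannot normalize: included region is constant (zero variance)")
  out <- array(0, dim(x))
  out[include] <- (v - mean(v)) / sd(v)
  BrainVolume(out, volume@spacing, volume@origin)
}

#' Resample a volume to isotropic spacing by trilinear interpolation
#'
#' The output grid covers the physical extent of the input (edge samples are
#' clamped to the border); constant images remain constant and resampling at
#' the native spacing is the identity.
#'
#' @param volume a [BrainVolume].
#' @param targetSpacing isotropic output voxel size in mm (> 0).
#' @return a resampled [BrainVolume].
#' @export
resampleIsotropic <- function(volume, targetSpacing) {
  stopifnot(is(volume, "BrainVolume"))
  if (length(targetSpacing) != 1L || !is.finite(targetSpacing) ||
      targetSpacing <= 0)
    stop("targetSpacing must be a single positive value")
  x <- volume@data
  d <- dim(x)
  s <- volume@spacing
  nOut <- pmax(1L, as.integer(ceiling((d - 1) * s / targetSpacing)) + 1L)
  # target voxel centers in input voxel units (0-based), clamped to the grid
  crd <- lapply(1:3, function(a) {
    p <- (seq_len(nOut[a]) - 1) * targetSpacing / s[a]
    pmin(pmax(p, 0), d[a] - 1)
  })
  px <- rep(crd[[1]], times = nOut[2] * nOut[3])
  py <- rep(rep(crd[[2]], each = nOut[1]), times = nOut[3])
  pz <- rep(crd[[3]], each = nOut[1] * nOut[2])
  vals <- .trilinearSample(x, px, py, pz)
  BrainVolume(array(vals, nOut), rep(targetSpacing, 3), volume@origin)
}

# trilinear interpolation at 0-based continuous voxel coordinates
.trilinearSample <- function(x, px, py, pz) {
  d <- dim(x)
  i0 <- pmin(floor(px), d[1] - 1); fx <- px - i0; i0 <- pmax(i0, 0)
  j0 <- pmin(floor(py), d[2] - 1); fy <- py - j0; j0 <- pmax(j0, 0)
  k0 <- pmin(floor(pz), d[3] - 1); fz <- pz - k0; k0 <- pmax(k0, 0)
  i1 <- pmin(i0 + 1, d[1] - 1)
  j1 <- pmin(j0 + 1, d[2] - 1)
  k1 <- pmin(k0 + 1, d[3] - 1)
  idx <- function(i, j, k) 1 + i + d[1] * (j + d[2] * k)
  x[idx(i0, j0, k0)] * (1 - fx) * (1 - fy) * (1 - fz) +
    x[idx(i1, j0, k0)] * fx * (1 - fy) * (1 - fz) +
    x[idx(i0, j1, k0)] * (1 - fx) * fy * (1 - fz) +
    x[idx(i1, j1, k0)] * fx * fy * (1 - fz) +
    x[idx(i0, j0, k1)] * (1 - fx) * (1 - fy) * fz +
    x[idx(i1, j0, k1)] * fx * (1 - fy) * fz +
    x[idx(i0, j1, k1)] * (1 - fx) * fy * fz +
    x[idx(i1, j1, k1)] * fx * fy * fz
}

#' Dice similarity coefficient between two masks
#'
#' `2|A intersect B| / (|A| + |B|)`; two empty masks are defined to agree
#' perfectly (Dice 1).
#'
#' @param a,b [LesionMask] objects with identical geometry.
#' @return Dice coefficient in `[0, 1]`.
#' @export
diceCoefficient <- function(a, b) {
  stopifnot(is(a, "LesionMask"), is(b, "LesionMask"))
  .checkGeometry(a, b, "masks")
  sa <- sum(a@data); sb <- sum(b@data)
  if (sa + sb == 0) return(1.0)
  2 * sum(a@data * b@data) / (sa + sb)
}

#' ICC(2,1): two-way random effects, absolute agreement, single measure
#'
#' Standard mean-squares estimator with the F-distribution confidence bounds
#' (McGraw & Wong). Intended for per-subject scalar summaries (e.g. lesion
#' volumes from two raters).
#'
#' @param ratings numeric matrix, subjects x raters; no missing cells.
#' @param conf confidence level for the interval (default 0.95).
#' @return list with `icc`, `lower`, `upper`, `n`, `k`.
#' @export
icc21 <- function(ratings, conf = 0.95) {
  ratings <- as.matrix(ratings)
  n <- nrow(ratings); k <- ncol(ratings)
  if (k < 2L) stop("need at least 2 raters")
  if (n < 3L) stop("need at least 3 subjects")
  if (any(!is.finite(ratings))) stop("ratings must have no missing cells")

  grand <- mean(ratings)
  SSR <- k * sum((rowMeans(ratings) - grand)^2)
  SSC <- n * sum((colMeans(ratings) - grand)^2)
  SST <- sum((ratings - grand)^2)
  SSE <- SST - SSR - SSC
  MSR <- SSR / (n - 1)
  MSC <- SSC / (k - 1)
  MSE <- SSE / ((n - 1) * (k - 1))

  icc <- (MSR - MSE) / (MSR + (k - 1) * MSE + k * (MSC - MSE) / n)

  alpha <- 1 - conf
  a <- k * icc / (n * (1 - icc))
  b <- 1 + k * icc * (n - 1) / (n * (1 - icc))
  v <- (a * MSC + b * MSE)^2 /
    ((a * MSC)^2 / (k - 1) + (b * MSE)^2 / ((n - 1) * (k - 1)))
  FL <- qf(1 - alpha / 2, n - 1, v)
  FU <- qf(1 - alpha / 2, v, n - 1)
  lower <- n * (MSR - FL * MSE) /
    (FL * (k * MSC + (k * n - k - n) * MSE) + n * MSR)
  upper <- n * (FU * MSR - MSE) /
    (k * MSC + (k * n - k - n) * MSE + n * FU * MSR)
  list(icc = icc, lower = lower, upper = upper, n = n, k = k)
}
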