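## ROI-Align pooling in 3D.
##
## The pooled output is a fixed-size grid laid uniformly over a continuous
## box in feature-map coordinates; each cell averages a fixed number of
## trilinear-interpolated sample points, so the operator is linear in the
## feature map. It is materialized as a sparse matrix, which makes the
## backward pass a transpose multiplication.
##
## Coordinate convention: voxel centers sit at 0-based integer coordinates;
## a box spanning voxels i0..i1 is [i0 - 0.5, i1 + 0.5]. Sample points are
## clamped to the feature-map extent.

# sparse pooling operator: rows = output cells (column-major), cols = voxels
.roiAlignMatrix <- function(dims, roiBox, outputGrid, samplesPerCell) {
  lo <- roiBox[1:3]; hi <- roiBox[4:6]
  if (any(hi - lo <= 0))
    stop("degenerate ROI box: extent must be positive on every axis")
  if (any(hi < -0.5) || any(lo > dims - 0.5))
    stop("ROI box does not intersect the feature map")
  g <- outputGrid
  spc <- samplesPerCell
  w <- (hi - lo) / g

  ncell <- prod(g)
  npt <- spc^3
  cellI <- seq_len(ncell) - 1L
  jx <- cellI %% g[1]
  jy <- (cellI %/% g[1]) %% g[2]
  jz <- cellI %/% (g[1] * g[2])
  off <- (seq_len(spc) - 0.5) / spc
  ox <- rep(off, times = spc^2)
  oy <- rep(rep(off, each = spc), times = spc)
  oz <- rep(off, each = spc^2)

  px <- lo[1] + w[1] * (rep(jx, each = npt) + rep(ox, times = ncell))
  py <- lo[2] + w[2] * (rep(jy, each = npt) + rep(oy, times = ncell))
  pz <- lo[3] + w[3] * (rep(jz, each = npt) + rep(oz, times = ncell))
  rows <- rep(seq_len(ncell), each = npt)

  px <- pmin(pmax(px, 0), dims[1] - 1)
  py <- pmin(pmax(py, 0), dims[2] - 1)
  pz <- pmin(pmax(pz, 0), dims[3] - 1)

  i0 <- pmax(pmin(floor(px), dims[1] - 1), 0); fx <- px - i0
  j0 <- pmax(pmin(floor(py), dims[2] - 1), 0); fy <- py - j0
  k0 <- pmax(pmin(floor(pz), dims[3] - 1), 0); fz <- pz - k0
  i1 <- pmin(i0 + 1, dims[1] - 1)
  j1 <- pmin(j0 + 1, dims[2] - 1)
  k1 <- pmin(k0 + 1, dims[3] - 1)

  lin <- function(i, j, k) 1 + i + dims[1] * (j + dims[2] * k)
  corners <- list(
    list(lin(i0, j0, k0), (1 - fx) * (1 - fy) * (1 - fz)),
    list(lin(i1, j0, k0), fx * (1 - fy) * (1 - fz)),
    list(lin(i0, j1, k0), (1 - fx) * fy * (1 - fz)),
    list(lin(i1, j1, k0), fx * fy * (1 - fz)),
    list(lin(i0, j0, k1), (1 - fx) * (1 - fy) * fz),
    list(lin(i1, j0, k1), fx * (1 - fy) * fz),
    list(lin(i0, j1, k1), (1 - fx) * fy * fz),
    list(lin(i1, j1, k1), fx * fy * fz))

  Matrix::sparseMatrix(
    i = rep(rows, 8L),
    j = unlist(lapply(corners, `[[`, 1L)),
    x = unlist(lapply(corners, `[[`, 2L)) / npt,
    dims = c(ncell, prod(dims)))
}

#' ROI-Align pooling of a 3D feature map
#'
#' Resamples an arbitrarily sized continuous region of a feature map onto a
#' fixed output grid: `samplesPerCell^3` trilinear-interpolated sample
#' points are averaged per output cell. The output shape is
#' `outputGrid x channels` regardless of the box size.
#'
#' @param featureMap 3D numeric array, or 4D with channels last.
#' @param roiBox numeric length-6 `(x0, y0, z0, x1, y1, z1)` in 0-based
#'   continuous feature-map coordinates (a box spanning voxels `i0..i1` along
#'   an axis is `[i0 - 0.5, i1 + 0.5]`).
#' @param outputGrid integer length-3 pooled grid size.
#' @param samplesPerCell interpolation sample points per axis per cell
#'   (default 2, i.e. 8 points per cell; 1 samples the cell center).
#' @return array of dimension `outputGrid` (3D input) or
#'   `c(outputGrid, channels)` (4D input).
#' @export
roiAlignPool <- function(featureMap, roiBox, outputGrid,
                         samplesPerCell = 2L) {
  nd <- length(dim(featureMap))
  if (!nd %in% c(3L, 4L))
    stop("featureMap must be a 3D array or a 4D array with channels last")
  dims <- dim(featureMap)[1:3]
  nch <- if (nd == 4L) dim(featureMap)[4] else 1L
  outputGrid <- as.integer(outputGrid)
  stopifnot(length(outputGrid) == 3L, all(outputGrid >= 1L))
  P <- .roiAlignMatrix(dims, as.numeric(roiBox), outputGrid,
                       as.integer(samplesPerCell))
  fm <- matrix(as.vector(featureMap), prod(dims), nch)
  pooled <- as.matrix(P %*% fm)
  if (nd == 4L) array(pooled, c(outputGrid, nch))
  else array(pooled, outputGrid)
}

# tight ROI box (0-based continuous input coordinates) around the nonzero
# voxels of a lesion-excluded, normalized volume
.roiBoxFromArray <- function(arr) {
  fg <- which(arr != 0, arr.ind = TRUE)
  if (nrow(fg) == 0L)
    stop("empty ROI: no foreground voxels outside the exclusion mask")
  lo <- apply(fg, 2, min) - 1 - 0.5
  hi <- apply(fg, 2, max) - 1 + 0.5
  c(lo, hi)
}
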