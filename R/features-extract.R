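## Radiomic feature extraction from the lesion region.
##
## A compact, fully specified 19-feature set: 11 first-order statistics
## (intensity histogram entropy over 32 fixed-width bins), 4 shape features,
## and 4 gray-level co-occurrence (GLCM) texture features at distance 1,
## averaged over the 13 unique 3D directions after 32-level quantization
## over the lesion intensity range. All features are deterministic; the
## selection pipeline equally accepts any externally computed CSV.

.GLCM_LEVELS <- 32L
.GLCM_OFFSETS <- {
  o <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  o <- o[!(o$dx == 0 & o$dy == 0 & o$dz == 0), ]
  # keep one of each +/- pair: 13 unique directions
  keep <- o$dz > 0 | (o$dz == 0 & (o$dy > 0 | (o$dy == 0 & o$dx > 0)))
  as.matrix(o[keep, ])
}

.glcmFeatures <- function(q, maskArr) {
  d <- dim(q)
  lev <- .GLCM_LEVELS
  feats <- matrix(NA_real_, nrow(.GLCM_OFFSETS), 4,
                  dimnames = list(NULL, c("contrast", "correlation",
                                          "energy", "homogeneity")))
  qn <- q
  qn[maskArr == 0] <- NA_integer_
  for (r in seq_len(nrow(.GLCM_OFFSETS))) {
    off <- .GLCM_OFFSETS[r, ]
    sx <- max(1, 1 + off[1]):min(d[1], d[1] + off[1])
    sy <- max(1, 1 + off[2]):min(d[2], d[2] + off[2])
    sz <- max(1, 1 + off[3]):min(d[3], d[3] + off[3])
    a <- qn[sx - off[1], sy - off[2], sz - off[3]]
    b <- qn[sx, sy, sz]
    ok <- !is.na(a) & !is.na(b)
    if (!any(ok)) next
    cnt <- tabulate((a[ok] - 1L) * lev + b[ok], nbins = lev * lev)
    P <- matrix(cnt, lev, lev)
    P <- P + t(P)                      # symmetric GLCM
    P <- P / sum(P)
    i <- row(P); j <- col(P)
    mu <- sum(i * P)                   # symmetric: row/col means equal
    s2 <- sum((i - mu)^2 * P)
    feats[r, "contrast"] <- sum(P * (i - j)^2)
    feats[r, "energy"] <- sum(P^2)
    feats[r, "homogeneity"] <- sum(P / (1 + abs(i - j)))
    feats[r, "correlation"] <-
      if (s2 > 0) sum((i - mu) * (j - mu) * P) / s2 else 1
  }
  colMeans(feats, na.rm = TRUE)
}

#' Extract radiomic features from a lesion
#'
#' Computes the package's 19-feature radiomic vector from the voxels under
#' the mask: first-order statistics (mean, SD, skewness, kurtosis, median,
#' 10th/90th percentiles, 32-bin histogram entropy, minimum, maximum,
#' range), shape (voxel volume in mm^3, surface-voxel count, a sphericity
#' proxy comparing the equivalent-sphere surface to the surface-voxel area,
#' maximum 3D diameter in mm), and GLCM texture at distance 1 (contrast,
#' correlation, energy, homogeneity). Intensity shifts change only the
#' location features; SD, entropy and GLCM features are shift-invariant by
#' construction.
#'
#' @param volume a [BrainVolume].
#' @param mask a non-empty [LesionMask] aligned to `volume`.
#' @return named numeric vector of 19 features.
#' @export
extractRadiomicFeatures <- function(volume, mask) {
  stopifnot(is(volume, "BrainVolume"), is(mask, "LesionMask"))
  .checkGeometry(volume, mask, "volume and mask")
  m <- mask@data == 1
  if (!any(m)) stop("empty mask: no lesion voxels to extract features from")
  v <- volume@data[m]
  sp <- volume@spacing

  ## first order
  mu <- mean(v); s <- if (length(v) > 1L) sd(v) else 0
  ctr <- v - mu
  skew <- if (s > 0) mean(ctr^3) / s^3 else 0
  kurt <- if (s > 0) mean(ctr^4) / s^4 else 0
  rng <- diff(range(v))
  entropy <- if (rng > 0) {
    br <- seq(min(v), max(v), length.out = .GLCM_LEVELS + 1L)
    p <- tabulate(findInterval(v, br, rightmost.closed = TRUE),
                  nbins = .GLCM_LEVELS)
    p <- p / sum(p)
    -sum(p[p > 0] * log2(p[p > 0]))
  } else 0

  ## shape
  nvox <- sum(m)
  volMm3 <- nvox * prod(sp)
  d <- dim(m)
  interiorOf <- function(arr) {
    # voxels whose 6 neighbors are all inside the mask (boundary = outside)
    out <- array(TRUE, d)
    pad <- array(FALSE, d + 2L)
    pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- arr
    out <- pad[1:d[1], 2:(d[2] + 1), 2:(d[3] + 1)] &
      pad[3:(d[1] + 2), 2:(d[2] + 1), 2:(d[3] + 1)] &
      pad[2:(d[1] + 1), 1:d[2], 2:(d[3] + 1)] &
      pad[2:(d[1] + 1), 3:(d[2] + 2), 2:(d[3] + 1)] &
      pad[2:(d[1] + 1), 2:(d[2] + 1), 1:d[3]] &
      pad[2:(d[1] + 1), 2:(d[2] + 1), 3:(d[3] + 2)]
    out
  }
  surface <- m & !interiorOf(m)
  nSurf <- sum(surface)
  faceArea <- mean(c(sp[1] * sp[2], sp[2] * sp[3], sp[1] * sp[3]))
  areaProxy <- max(nSurf, 1) * faceArea
  sphericity <- (pi^(1 / 3) * (6 * volMm3)^(2 / 3)) / areaProxy
  sIdx <- which(surface, arr.ind = TRUE)
  if (nrow(sIdx) > 3000L)
    sIdx <- sIdx[seq(1, nrow(sIdx), length.out = 3000L), , drop = FALSE]
  coords <- sweep(sIdx, 2, sp, `*`)
  maxDiam <- if (nrow(coords) > 1L) max(stats::dist(coords)) else max(sp)

  ## GLCM after 32-level quantization over the lesion range
  q <- array(1L, d)
  if (rng > 0) {
    qv <- 1L + as.integer(floor((volume@data - min(v)) / rng * .GLCM_LEVELS))
    q <- array(pmin(pmax(qv, 1L), .GLCM_LEVELS), d)
  }
  glcm <- .glcmFeatures(q, m)

  c(fo_mean = mu, fo_sd = s, fo_skewness = skew, fo_kurtosis = kurt,
    fo_median = median(v),
    fo_p10 = unname(quantile(v, 0.10)), fo_p90 = unname(quantile(v, 0.90)),
    fo_entropy = entropy, fo_min = min(v), fo_max = max(v), fo_range = rng,
    shape_volume_mm3 = volMm3, shape_surface_voxels = nSurf,
    shape_sphericity = sphericity, shape_max_diameter_mm = maxDiam,
    glcm_contrast = unname(glcm["contrast"]),
    glcm_correlation = unname(glcm["correlation"]),
    glcm_energy = unname(glcm["energy"]),
    glcm_homogeneity = unname(glcm["homogeneity"]))
}

#' Extract the radiomic feature table of a cohort's glioma subjects
#'
#' @param cohort a [PhantomCohort] (or any list-compatible volumes/masks).
#' @return data.frame of features (rows named by subject id, provenance
#'   attribute `"radiomic"`) for subjects with non-empty masks.
#' @export
extractFeatureTable <- function(cohort) {
  stopifnot(is(cohort, "PhantomCohort"))
  has <- vapply(cohort@masks, function(m) sum(m@data) > 0, logical(1))
  rows <- lapply(which(has), function(i)
    extractRadiomicFeatures(cohort@volumes[[i]], cohort@masks[[i]]))
  tab <- as.data.frame(do.call(rbind, rows))
  rownames(tab) <- cohort@subjects$id[has]
  attr(tab, "provenance") <- setNames(rep("radiomic", ncol(tab)), names(tab))
  tab
}
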