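## Dataset handling for Brain Age Network training.

#' Stratified train/validation/test split
#'
#' Partitions subjects into disjoint, exhaustive train/validation/test sets
#' (default 70/10/20) with per-stratum largest-remainder rounding, so each
#' stratum's proportions are within one subject of the targets. Strata with
#' fewer than 3 subjects are collapsed into the neighboring stratum with a
#' warning. Deterministic under `seed`.
#'
#' @param subjects data.frame of subjects (or anything with `nrow`).
#' @param fractions length-3 fractions summing to 1.
#' @param stratifyOn optional factor/vector of stratum labels (length
#'   `nrow(subjects)`), or a column name of `subjects`.
#' @param seed RNG seed.
#' @return list of integer row indices: `train`, `val`, `test`.
#' @export
splitDataset <- function(subjects, fractions = c(0.70, 0.10, 0.20),
                         stratifyOn = NULL, seed = 1L) {
  n <- nrow(subjects)
  if (abs(sum(fractions) - 1) > 1e-8 || length(fractions) != 3L)
    stop("fractions must be three values summing to 1")
  strata <- if (is.null(stratifyOn)) {
    factor(rep("all", n))
  } else if (is.character(stratifyOn) && length(stratifyOn) == 1L &&
             stratifyOn %in% names(subjects)) {
    factor(subjects[[stratifyOn]])
  } else {
    if (length(stratifyOn) != n)
      stop("stratifyOn must match the number of subjects")
    factor(stratifyOn)
  }
  strata <- droplevels(strata)

  ## collapse strata smaller than 3 into the neighboring (adjacent) level
  repeat {
    cnt <- table(strata)
    small <- names(cnt)[cnt < 3 & cnt > 0]
    if (!length(small) || nlevels(strata) == 1L) break
    lev <- levels(strata)
    s <- small[1]
    pos <- match(s, lev)
    neighbor <- if (pos > 1) lev[pos - 1] else lev[pos + 1]
    warning(sprintf("stratum '%s' has fewer than 3 subjects; collapsed into '%s'",
                    s, neighbor))
    levels(strata)[levels(strata) == s] <- neighbor
    strata <- droplevels(strata)
  }

  set.seed(seed)
  out <- list(train = integer(), val = integer(), test = integer())
  for (lev in levels(strata)) {
    idx <- which(strata == lev)
    idx <- idx[sample.int(length(idx))]
    m <- length(idx)
    exact <- m * fractions
    sizes <- floor(exact)
    rem <- m - sum(sizes)
    if (rem > 0) {
      frac <- exact - sizes
      give <- order(-frac, seq_along(frac))[seq_len(rem)]
      sizes[give] <- sizes[give] + 1
    }
    bounds <- cumsum(sizes)
    out$train <- c(out$train, idx[seq_len(sizes[1])])
    if (sizes[2] > 0)
      out$val <- c(out$val, idx[(bounds[1] + 1):bounds[2]])
    if (sizes[3] > 0)
      out$test <- c(out$test, idx[(bounds[2] + 1):bounds[3]])
  }
  lapply(out, sort)
}

#' Inverse-frequency age-bin loss weights
#'
#' Each subject's weight is proportional to the reciprocal of its age bin's
#' occupancy, normalized so the mean weight over subjects is 1. Consequently
#' the total weight (count x weight) is identical across occupied bins,
#' countering age-distribution imbalance in the regression loss.
#'
#' @param ages numeric vector of ages (years).
#' @param binEdges strictly increasing bin edges covering every age.
#' @return numeric vector of per-subject weights (mean 1).
#' @export
computeBinWeights <- function(ages, binEdges = seq(0, 110, by = 10)) {
  bin <- findInterval(ages, binEdges, rightmost.closed = TRUE)
  if (any(bin == 0L | bin == length(binEdges)))
    stop("every age must fall within the bin edges")
  cnt <- table(bin)
  w <- 1 / as.numeric(cnt[as.character(bin)])
  w / mean(w)
}

#' Exclude the lesion region from a volume
#'
#' Sets voxels under the mask to the fill value 0 and leaves every other
#' voxel untouched, so any two inputs that differ only inside the mask map
#' to identical outputs.
#'
#' @param volume a [BrainVolume] (normalized).
#' @param mask an aligned [LesionMask].
#' @return a [BrainVolume] with the lesion region zeroed.
#' @export
applyLesionExclusion <- function(volume, mask) {
  stopifnot(is(volume, "BrainVolume"), is(mask, "LesionMask"))
  .checkGeometry(volume, mask, "volume and mask")
  out <- volume@data
  out[mask@data == 1] <- 0
  BrainVolume(out, volume@spacing, volume@origin)
}

#' Mean absolute error of age predictions
#'
#' @param predictions,truths equal-length numeric vectors (years).
#' @return list with `mae` (mean absolute residual) and `sd` (SD of the
#'   absolute residuals), both in years.
#' @export
evaluateMae <- function(predictions, truths) {
  if (length(predictions) != length(truths) || length(predictions) < 1L)
    stop("predictions and truths must be non-empty and of equal length")
  a <- abs(predictions - truths)
  list(mae = mean(a), sd = if (length(a) > 1) sd(a) else 0)
}
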