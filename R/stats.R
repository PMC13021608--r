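## Nonparametric statistics used throughout the framework: Mann-Whitney U
## with an exact small-sample tail, Spearman rank correlation, group
## comparison reports with multiplicity correction, and rank-based AUC.

#' Mann-Whitney U test
#'
#' `U = #\{(i, j): x_i > y_j\} + ties/2`. For tie-free samples with
#' `n_x + n_y <= 12` the p-value is exact (null tail of the U distribution);
#' otherwise a normal approximation with tie correction and continuity
#' correction is used.
#'
#' @param x,y non-empty numeric samples.
#' @param alternative `"two.sided"` (default), `"greater"` (x tends larger)
#'   or `"less"`.
#' @return list with `U`, `p`, and `method` (`"exact"` or `"normal"`).
#' @export
mannWhitneyU <- function(x, y, alternative = c("two.sided", "greater",
                                               "less")) {
  alternative <- match.arg(alternative)
  if (length(x) < 1L || length(y) < 1L)
    stop("both samples must be non-empty")
  nx <- length(x); ny <- length(y)
  r <- rank(c(x, y))
  U <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  hasTies <- anyDuplicated(c(x, y)) > 0

  if (!hasTies && nx + ny <= 12L) {
    lower <- pwilcox(U, nx, ny)                    # P(U <= u)
    upper <- 1 - pwilcox(U - 1, nx, ny)            # P(U >= u)
    p <- switch(alternative,
                two.sided = min(1, 2 * min(lower, upper)),
                greater = upper,
                less = lower)
    return(list(U = U, p = p, method = "exact"))
  }

  n <- nx + ny
  mu <- nx * ny / 2
  tieTab <- table(c(x, y))
  tieCorr <- sum(tieTab^3 - tieTab) / (n * (n - 1))
  sigma <- sqrt(nx * ny / 12 * ((n + 1) - tieCorr))
  if (sigma == 0)
    return(list(U = U, p = 1, method = "normal"))
  z <- U - mu
  cc <- switch(alternative,                         # continuity correction
               two.sided = sign(z) * 0.5, greater = 0.5, less = -0.5)
  z <- (z - cc) / sigma
  p <- switch(alternative,
              two.sided = 2 * pnorm(-abs(z)),
              greater = pnorm(z, lower.tail = FALSE),
              less = pnorm(z))
  list(U = U, p = min(1, p), method = "normal")
}

#' Spearman rank correlation
#'
#' Pearson correlation of mid-ranks; ties are mid-ranked.
#'
#' @param x,y numeric vectors, `n >= 3`, neither constant.
#' @return rho in `[-1, 1]`.
#' @export
spearmanRho <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L)
    stop("need at least 3 paired observations")
  if (var(x) == 0 || var(y) == 0)
    stop("cannot rank-correlate a constant vector")
  cor(rank(x), rank(y))
}

#' Group comparison report for BAI (or MAE) values
#'
#' Per-group descriptives (mean +/- SD), per-group normality checks
#' (Kolmogorov-Smirnov against a normal with the sample moments, and
#' Shapiro-Wilk), and all pairwise Mann-Whitney tests with multiplicity
#' adjustment.
#'
#' @param values numeric vector (e.g. BAI per subject).
#' @param labels group labels (e.g. control / epileptic / non_epileptic);
#'   at least 2 groups with at least 2 members each.
#' @param correction `"bonferroni"` or `"bh"` (Benjamini-Hochberg).
#' @return list with `descriptives`, `normality` and `pairwise` data.frames.
#' @export
compareGroups <- function(values, labels, correction = c("bonferroni", "bh")) {
  correction <- match.arg(correction)
  labels <- as.character(labels)
  groups <- sort(unique(labels))
  if (length(groups) < 2L) stop("need at least 2 groups")
  split_ <- split(values, labels)
  if (any(lengths(split_) < 2L)) stop("each group needs at least 2 members")

  desc <- data.frame(group = groups,
                     n = as.integer(lengths(split_)[groups]),
                     mean = vapply(split_[groups], mean, numeric(1)),
                     sd = vapply(split_[groups], sd, numeric(1)),
                     row.names = NULL)

  norm <- do.call(rbind, lapply(groups, function(g) {
    v <- split_[[g]]
    ksP <- tryCatch(
      suppressWarnings(ks.test(v, "pnorm", mean(v), sd(v))$p.value),
      error = function(e) NA_real_)
    swP <- if (length(v) >= 3 && length(v) <= 5000 && var(v) > 0)
      shapiro.test(v)$p.value else NA_real_
    data.frame(group = g, ks_p = ksP, shapiro_p = swP)
  }))

  pairs <- combn(groups, 2)
  pw <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(j) {
    g1 <- pairs[1, j]; g2 <- pairs[2, j]
    mw <- mannWhitneyU(split_[[g1]], split_[[g2]])
    data.frame(group1 = g1, group2 = g2, U = mw$U, p_raw = mw$p)
  }))
  pw$p_adj <- p.adjust(pw$p_raw,
                       method = if (correction == "bh") "BH" else "bonferroni")
  list(descriptives = desc, normality = norm, pairwise = pw)
}

#' Rank-based ROC AUC
#'
#' Probability that a random positive outranks a random negative; with ties,
#' the mid-rank AUC, equal to the tie-corrected `U / (n1 * n0)`.
#'
#' @param probabilities numeric scores.
#' @param labels binary labels (the larger / `"pos"` level is positive).
#' @return AUC in `[0, 1]`.
#' @export
aucRank <- function(probabilities, labels) {
  y <- .asBinary(labels)
  n1 <- sum(y == 1L); n0 <- sum(y == 0L)
  if (n1 == 0L || n0 == 0L)
    stop("AUC undefined: need both classes present")
  r <- rank(probabilities)
  (sum(r[y == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# coerce labels to 0/1; accepts logical, 0/1 numeric, or 2-level factor
.asBinary <- function(labels) {
  if (is.logical(labels)) return(as.integer(labels))
  if (is.numeric(labels)) {
    u <- sort(unique(labels))
    if (!all(u %in% c(0, 1))) stop("numeric labels must be 0/1")
    return(as.integer(labels))
  }
  f <- as.factor(labels)
  if (nlevels(f) > 2L) stop("labels must be binary")
  as.integer(f) - 1L
}
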