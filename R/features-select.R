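## The feature-selection chain: Mann-Whitney filter (raw p < 0.05, no
## multiplicity correction at this stage), Spearman correlation pruning
## (strict |rho| > 0.9), greedy iterative redundancy reduction (secondary
## threshold 0.8), and L1-penalized logistic regression with 10-fold
## cross-validation at the minimum mean CV deviance.

.featurePvalues <- function(table, labels) {
  y <- .asBinary(labels)
  vapply(names(table), function(f) {
    v <- table[[f]]
    if (var(v) == 0) return(1)
    mannWhitneyU(v[y == 1L], v[y == 0L])$p
  }, numeric(1))
}

#' Mann-Whitney feature filter
#'
#' Retains features whose two-sided Mann-Whitney p-value against the binary
#' label is below `alpha`. No multiplicity correction is applied at this
#' stage. Constant features get p = 1.
#'
#' @param table data.frame of numeric features.
#' @param labels binary labels (two classes, each with >= 2 members).
#' @param alpha significance threshold (default 0.05).
#' @return character vector of retained feature names, with the full named
#'   p-value vector in attribute `"p"`.
#' @export
mwuFilter <- function(table, labels, alpha = 0.05) {
  y <- .asBinary(labels)
  if (length(unique(y)) < 2L) stop("labels must contain two classes")
  if (min(tabulate(y + 1L, nbins = 2L)) < 2L)
    stop("each class needs at least 2 members")
  p <- .featurePvalues(table, labels)
  retained <- names(p)[p < alpha]
  attr(retained, "p") <- p
  retained
}

# connected components of the |rho| > threshold graph (strict inequality)
.corComponents <- function(rho, threshold) {
  adj <- abs(rho) > threshold
  diag(adj) <- FALSE
  n <- nrow(adj)
  comp <- integer(n)
  cur <- 0L
  for (i in seq_len(n)) {
    if (comp[i] != 0L) next
    cur <- cur + 1L
    queue <- i
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      if (comp[v] != 0L) next
      comp[v] <- cur
      queue <- c(queue, which(adj[v, ] & comp == 0L))
    }
  }
  comp
}

#' Spearman correlation pruning
#'
#' Builds a graph on features with edges where |Spearman rho| exceeds the
#' threshold (strictly; a pair at exactly the threshold keeps both) and
#' retains exactly one representative per connected component: the feature
#' with the smallest Mann-Whitney p-value against the labels, ties broken
#' lexicographically. Constant columns are dropped with a warning before
#' graphing. Deterministic.
#'
#' @param table data.frame of numeric features.
#' @param threshold correlation threshold (default 0.9).
#' @param labels optional binary labels used to rank representatives; when
#'   absent, representatives are chosen lexicographically.
#' @param pvalues optional named p-value vector (overrides `labels`).
#' @return character vector of retained feature names.
#' @export
correlationPrune <- function(table, threshold = 0.9, labels = NULL,
                             pvalues = NULL) {
  if (ncol(table) < 1L) stop("need at least 1 feature")
  constant <- vapply(table, function(v) var(v) == 0, logical(1))
  if (any(constant)) {
    warning(sprintf("dropping constant feature(s): %s",
                    paste(names(table)[constant], collapse = ", ")))
    table <- table[, !constant, drop = FALSE]
  }
  if (ncol(table) == 0L) return(character())
  if (ncol(table) == 1L) return(names(table))

  if (is.null(pvalues))
    pvalues <- if (!is.null(labels)) .featurePvalues(table, labels)
               else setNames(rep(1, ncol(table)), names(table))
  rho <- cor(vapply(table, rank, numeric(nrow(table))))
  comp <- .corComponents(rho, threshold)
  nm <- names(table)
  retained <- vapply(sort(unique(comp)), function(cc) {
    members <- nm[comp == cc]
    members[order(pvalues[members], members)][1]
  }, character(1))
  nm[nm %in% retained]
}

#' Iterative redundancy reduction
#'
#' Greedy refinement after correlation pruning: while any pairwise
#' |Spearman rho| among the retained features exceeds the secondary
#' threshold, drop the feature with the highest mean absolute correlation to
#' the remaining set (ties broken lexicographically). Idempotent and
#' deterministic.
#'
#' @param table data.frame of numeric features.
#' @param retained feature names to start from (output of
#'   [correlationPrune()]).
#' @param threshold secondary correlation threshold (default 0.8).
#' @return character vector of retained feature names.
#' @export
reduceRedundancy <- function(table, retained = names(table),
                             threshold = 0.8) {
  keep <- retained
  while (length(keep) > 1L) {
    rho <- cor(vapply(table[keep], rank, numeric(nrow(table))))
    a <- abs(rho); diag(a) <- NA
    if (max(a, na.rm = TRUE) <= threshold) break
    meanAbs <- rowMeans(a, na.rm = TRUE)
    drop <- keep[order(-meanAbs, keep)][1]
    keep <- setdiff(keep, drop)
  }
  keep
}

# deterministic stratified fold assignment
.stratifiedFolds <- function(y, k, seed) {
  set.seed(seed)
  fold <- integer(length(y))
  for (cl in unique(y)) {
    idx <- which(y == cl)
    fold[idx] <- sample(rep(seq_len(k), length.out = length(idx)))
  }
  fold
}

#' LASSO signature selection
#'
#' L1-penalized logistic regression on internally standardized features;
#' the penalty is chosen by stratified 10-fold cross-validation at the
#' minimum mean cross-validated deviance (the minimum-criteria rule).
#' Features with nonzero coefficients form the radiomic signature, reported
#' on the standardized scale together with the frozen standardization.
#'
#' @param table data.frame of numeric features (`n >= folds`).
#' @param labels binary labels.
#' @param folds CV folds (default 10).
#' @param seed RNG seed for fold assignment.
#' @param lambda optional fixed penalty; skips cross-validation.
#' @return a [RadiomicSignature].
#' @export
lassoSelect <- function(table, labels, folds = 10L, seed = 1L,
                        lambda = NULL) {
  y <- .asBinary(labels)
  if (length(unique(y)) < 2L) stop("labels must contain two classes")
  if (nrow(table) < folds) stop("need at least as many subjects as folds")
  keep <- vapply(table, function(v) var(v) > 0, logical(1))
  table <- table[, keep, drop = FALSE]
  ctr <- vapply(table, mean, numeric(1))
  scl <- vapply(table, sd, numeric(1))
  x <- scale(as.matrix(table), center = ctr, scale = scl)

  if (is.null(lambda)) {
    foldid <- .stratifiedFolds(y, folds, seed)
    cvfit <- glmnet::cv.glmnet(x, y, family = "binomial", foldid = foldid,
                               type.measure = "deviance",
                               standardize = FALSE)
    lambda <- cvfit$lambda.min
    fit <- cvfit$glmnet.fit
  } else {
    fit <- glmnet::glmnet(x, y, family = "binomial", standardize = FALSE)
  }
  cf <- as.numeric(glmnet::coef.glmnet(fit, s = lambda, exact = FALSE))
  names(cf) <- c("(Intercept)", colnames(x))
  nz <- cf[-1][cf[-1] != 0]
  sel <- names(nz)
  new("RadiomicSignature", features = sel, coefficients = unname(nz),
      intercept = cf[[1]], lambda = lambda,
      center = ctr[sel], scale = scl[sel])
}

#' Radiomic score of a feature vector
#'
#' `intercept + sum(coefficient x standardized feature)` using the
#' signature's frozen standardization.
#'
#' @param features named numeric vector, or a data.frame of feature rows.
#' @param signature a [RadiomicSignature].
#' @return numeric score (one per row for data.frame input).
#' @export
radiomicScore <- function(features, signature) {
  stopifnot(is(signature, "RadiomicSignature"))
  if (is.data.frame(features)) {
    missing <- setdiff(signature@features, names(features))
    if (length(missing))
      stop(sprintf("missing signature feature(s): %s",
                   paste(missing, collapse = ", ")))
    if (length(signature@features) == 0L)
      return(rep(signature@intercept, nrow(features)))
    z <- scale(as.matrix(features[signature@features]),
               center = signature@center, scale = signature@scale)
    return(as.numeric(signature@intercept + z %*% signature@coefficients))
  }
  missing <- setdiff(signature@features, names(features))
  if (length(missing))
    stop(sprintf("missing signature feature(s): %s",
                 paste(missing, collapse = ", ")))
  if (length(signature@features) == 0L) return(signature@intercept)
  z <- (features[signature@features] - signature@center) / signature@scale
  signature@intercept + sum(z * signature@coefficients)
}

#' Select clinical variables associated with epileptic status
#'
#' Tests each candidate clinical column against the binary label —
#' Mann-Whitney for continuous variables, chi-square for categorical — and
#' retains those with p < `alpha`. All candidates are always reported with
#' their p-values.
#'
#' @param table data.frame of clinical candidates (e.g. chronological age,
#'   grade, BAI, sex).
#' @param labels binary epilepsy labels.
#' @param alpha significance threshold (default 0.05).
#' @return list with `retained` (names) and `report` (variable, type, p).
#' @export
selectClinical <- function(table, labels, alpha = 0.05) {
  y <- .asBinary(labels)
  report <- do.call(rbind, lapply(names(table), function(nm) {
    v <- table[[nm]]
    if (is.numeric(v)) {
      p <- if (var(v) == 0) 1 else mannWhitneyU(v[y == 1L], v[y == 0L])$p
      data.frame(variable = nm, type = "continuous", p = p)
    } else {
      tb <- base::table(v, y)
      p <- if (nrow(tb) < 2L) 1 else
        suppressWarnings(chisq.test(tb)$p.value)
      data.frame(variable = nm, type = "categorical", p = p)
    }
  }))
  keep <- if (alpha >= 1) rep(TRUE, nrow(report)) else report$p < alpha
  list(retained = report$variable[keep], report = report)
}
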