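## Gradient-boosting component models, random hyperparameter search over the
## printed grid, out-of-fold probability stacking into a logistic fusion
## model, and classifier evaluation.
##
## The boosting backend is xgboost configured as a leaf-wise
## gradient-boosted decision tree learner; the search-space fields map onto
## its parameters (num_leaves -> max_leaves with loss-guided growth,
## min_data_in_leaf -> min_child_weight via the 1/4 hessian bound of the
## logistic loss, l1/l2 -> alpha/lambda, feature_fraction ->
## colsample_bytree).

#' The hyperparameter search space of the boosting models
#'
#' @return named list of candidate values: learning_rate (0.01, 0.05, 0.1),
#'   num_leaves (31, 63, 127), max_depth (5, 7, 10, -1), min_data_in_leaf
#'   (20, 50), l1 and l2 (0, 0.1, 0.01), feature_fraction (0.8, 0.9, 1.0).
#' @export
defaultSearchSpace <- function() {
  list(learning_rate = c(0.01, 0.05, 0.1),
       num_leaves = c(31, 63, 127),
       max_depth = c(5, 7, 10, -1),
       min_data_in_leaf = c(20, 50),
       l1 = c(0, 0.1, 0.01),
       l2 = c(0, 0.1, 0.01),
       feature_fraction = c(0.8, 0.9, 1.0))
}

.gbmParams <- function(cfg) {
  list(objective = "binary:logistic",
       eta = cfg$learning_rate,
       max_leaves = as.integer(cfg$num_leaves),
       max_depth = if (cfg$max_depth == -1) 0L else as.integer(cfg$max_depth),
       min_child_weight = cfg$min_data_in_leaf * 0.25,
       alpha = cfg$l1, lambda = cfg$l2,
       colsample_bytree = cfg$feature_fraction,
       grow_policy = "lossguide", tree_method = "hist",
       nthread = 1L)
}

.gbmTrain <- function(X, y, cfg, nrounds = 100L) {
  dtrain <- xgboost::xgb.DMatrix(as.matrix(X), label = y)
  xgboost::xgb.train(params = .gbmParams(cfg), data = dtrain,
                     nrounds = nrounds, verbose = 0)
}

.gbmPredict <- function(booster, X) {
  predict(booster, xgboost::xgb.DMatrix(as.matrix(X)))
}

#' Random hyperparameter search with fixed 5-fold cross-validation
#'
#' Samples `nDraws` configurations from the grid without replacement (when
#' the grid is large enough), evaluates each by mean AUC over a stratified
#' 5-fold split fixed by `seed`, and returns the configuration maximizing
#' the mean cross-validated AUC plus the full trial table.
#'
#' @param X feature matrix / data.frame.
#' @param y binary labels (>= `folds` subjects per class).
#' @param space search space (see [defaultSearchSpace()]).
#' @param nDraws number of sampled configurations (default 50).
#' @param folds CV folds (default 5).
#' @param seed RNG seed (sampling and fold assignment).
#' @param nrounds boosting rounds per fit.
#' @return list with `best` (named list of hyperparameters), `bestAuc`, and
#'   `trials` (data.frame of all configurations with `mean_auc`).
#' @export
randomSearch <- function(X, y, space = defaultSearchSpace(), nDraws = 50L,
                         folds = 5L, seed = 1L, nrounds = 100L) {
  y <- .asBinary(y)
  if (min(tabulate(y + 1L, nbins = 2L)) < folds)
    stop("need at least `folds` subjects per class")
  grid <- expand.grid(space, KEEP.OUT.ATTRS = FALSE)
  set.seed(seed)
  take <- if (nDraws <= nrow(grid)) sample.int(nrow(grid), nDraws)
          else sample.int(nrow(grid), nDraws, replace = TRUE)
  foldid <- .stratifiedFolds(y, folds, seed)

  trials <- grid[take, , drop = FALSE]
  trials$mean_auc <- vapply(seq_len(nrow(trials)), function(t) {
    cfg <- as.list(trials[t, seq_along(space)])
    mean(vapply(seq_len(folds), function(f) {
      tr <- foldid != f
      fit <- .gbmTrain(X[tr, , drop = FALSE], y[tr], cfg, nrounds)
      aucRank(.gbmPredict(fit, X[!tr, , drop = FALSE]), y[!tr])
    }, numeric(1)))
  }, numeric(1))
  rownames(trials) <- NULL
  bestIdx <- which.max(trials$mean_auc)
  list(best = as.list(trials[bestIdx, seq_along(space)]),
       bestAuc = trials$mean_auc[bestIdx], trials = trials,
       foldMap = foldid)
}

#' Out-of-fold probabilities of a boosting model
#'
#' Each subject's probability comes from the model trained on the folds not
#' containing it, so every subject is covered exactly once. The fold map is
#' returned (and can be supplied) so that several component models share the
#' identical fold assignment.
#'
#' @param X feature matrix / data.frame.
#' @param y binary labels.
#' @param cfg hyperparameter configuration (named list).
#' @param folds CV folds (default 5).
#' @param seed RNG seed for fold assignment (ignored when `foldMap` given).
#' @param foldMap optional integer fold id per subject, for fold sharing.
#' @param nrounds boosting rounds.
#' @return list with `oof` (probability per subject) and `foldMap`.
#' @export
oofProbabilities <- function(X, y, cfg, folds = 5L, seed = 1L,
                             foldMap = NULL, nrounds = 100L) {
  y <- .asBinary(y)
  n <- length(y)
  if (n < folds) stop("need at least as many subjects as folds")
  if (is.null(foldMap)) foldMap <- .stratifiedFolds(y, folds, seed)
  oof <- rep(NA_real_, n)
  for (f in sort(unique(foldMap))) {
    tr <- foldMap != f
    fit <- .gbmTrain(X[tr, , drop = FALSE], y[tr], cfg, nrounds)
    oof[!tr] <- .gbmPredict(fit, X[!tr, , drop = FALSE])
  }
  list(oof = oof, foldMap = as.integer(foldMap))
}

#' Fit the logistic stacking (fusion) model
#'
#' Logistic regression of the label on the two out-of-fold probability
#' streams. The fit never sees in-fold probabilities; the `oofRecord` slot
#' documents the construction. The operating threshold is Youden's J on the
#' training OOF fusion probabilities, frozen before any test evaluation.
#'
#' @param oofRadiomic,oofClinical out-of-fold probabilities in `[0, 1]`,
#'   sharing one fold map.
#' @param y binary labels.
#' @param radiomicModel,clinicalModel component model bundles (lists with
#'   `booster`, `cfg`, `features`) applied to new data at inference.
#' @param foldMap shared integer fold assignment.
#' @param seed RNG seed recorded with the model.
#' @return a [FusionModel].
#' @export
fitFusion <- function(oofRadiomic, oofClinical, y,
                      radiomicModel = list(), clinicalModel = list(),
                      foldMap = integer(), seed = 1L) {
  y <- .asBinary(y)
  stopifnot(length(oofRadiomic) == length(y),
            length(oofClinical) == length(y))
  if (any(oofRadiomic < 0 | oofRadiomic > 1) ||
      any(oofClinical < 0 | oofClinical > 1))
    stop("probabilities must lie in [0, 1]")
  if (var(oofRadiomic) == 0 && var(oofClinical) == 0)
    warning("both probability streams are constant; fusion reduces to the base rate")
  df <- data.frame(y = y, p_rad = oofRadiomic, p_clin = oofClinical)
  fit <- suppressWarnings(glm(y ~ p_rad + p_clin, data = df,
                              family = binomial()))
  cf <- coef(fit)
  cf[is.na(cf)] <- 0
  fused <- plogis(cf[1] + cf[2] * oofRadiomic + cf[3] * oofClinical)
  thr <- .youdenThreshold(fused, y)
  new("FusionModel",
      radiomicModel = radiomicModel, clinicalModel = clinicalModel,
      stackCoefs = unname(cf), foldMap = as.integer(foldMap),
      oofRecord = data.frame(row = seq_along(y), fold = if (length(foldMap))
        as.integer(foldMap) else NA_integer_,
        oof_radiomic = oofRadiomic, oof_clinical = oofClinical),
      threshold = thr, seed = as.integer(seed))
}

.youdenThreshold <- function(prob, y) {
  cand <- sort(unique(prob))
  j <- vapply(cand, function(t) {
    pred <- prob >= t
    sens <- sum(pred & y == 1L) / sum(y == 1L)
    spec <- sum(!pred & y == 0L) / sum(y == 0L)
    sens + spec - 1
  }, numeric(1))
  cand[which.max(j)]
}

#' Train the complete clinic-radiomic fusion model
#'
#' Runs the random search for the radiomic and the clinical component with
#' the identical seed, data splitting and optimization process, computes
#' their out-of-fold probabilities on the shared fold map, stacks them with
#' a logistic regression, and refits both components on the full training
#' set for inference.
#'
#' @param Xrad radiomic feature table (training subjects).
#' @param Xclin clinical feature table (same subjects, same order).
#' @param y binary epilepsy labels.
#' @param space hyperparameter search space.
#' @param nDraws random-search draws (default 50).
#' @param folds CV folds (default 5).
#' @param seed RNG seed.
#' @param nrounds boosting rounds.
#' @return a [FusionModel] ready for [predictFusion()].
#' @export
trainFusionModel <- function(Xrad, Xclin, y, space = defaultSearchSpace(),
                             nDraws = 50L, folds = 5L, seed = 1L,
                             nrounds = 100L) {
  y <- .asBinary(y)
  searchRad <- randomSearch(Xrad, y, space, nDraws, folds, seed, nrounds)
  searchClin <- randomSearch(Xclin, y, space, nDraws, folds, seed, nrounds)
  foldMap <- searchRad$foldMap            # identical seed => identical folds
  oofR <- oofProbabilities(Xrad, y, searchRad$best, folds, seed,
                           foldMap = foldMap, nrounds = nrounds)
  oofC <- oofProbabilities(Xclin, y, searchClin$best, folds, seed,
                           foldMap = foldMap, nrounds = nrounds)
  radBundle <- list(booster = .gbmTrain(Xrad, y, searchRad$best, nrounds),
                    cfg = searchRad$best, features = colnames(Xrad),
                    cv_auc = searchRad$bestAuc)
  clinBundle <- list(booster = .gbmTrain(Xclin, y, searchClin$best, nrounds),
                     cfg = searchClin$best, features = colnames(Xclin),
                     cv_auc = searchClin$bestAuc)
  fitFusion(oofR$oof, oofC$oof, y, radBundle, clinBundle, foldMap, seed)
}

#' Predict fusion probabilities for new subjects
#'
#' Applies both component models and combines their probabilities with the
#' learned logistic weights.
#'
#' @param model a [FusionModel] with fitted component bundles.
#' @param Xrad,Xclin feature tables of the new subjects.
#' @return list with `fused`, `radiomic` and `clinical` probabilities.
#' @export
predictFusion <- function(model, Xrad, Xclin) {
  stopifnot(is(model, "FusionModel"))
  if (is.null(model@radiomicModel$booster))
    stop("fusion model has no fitted component models")
  pr <- .gbmPredict(model@radiomicModel$booster,
                    Xrad[, model@radiomicModel$features, drop = FALSE])
  pc <- .gbmPredict(model@clinicalModel$booster,
                    Xclin[, model@clinicalModel$features, drop = FALSE])
  cf <- model@stackCoefs
  list(fused = plogis(cf[1] + cf[2] * pr + cf[3] * pc),
       radiomic = pr, clinical = pc)
}

#' Classification metrics with a bootstrap AUC interval
#'
#' Rank-based ROC AUC, accuracy, sensitivity and specificity at the policy
#' threshold, and a 95% percentile CI for the AUC from a seeded stratified
#' bootstrap.
#'
#' @param probabilities scores in `[0, 1]`.
#' @param labels binary labels (both classes must be present).
#' @param threshold operating threshold; by default Youden's J on these
#'   probabilities. Supply a frozen training-derived threshold for honest
#'   test evaluation.
#' @param nBoot bootstrap resamples (default 2000).
#' @param seed bootstrap seed.
#' @return list with `auc`, `auc_ci` (length 2), `accuracy`, `sensitivity`,
#'   `specificity`, `threshold`, `n`.
#' @export
evaluateClassifier <- function(probabilities, labels, threshold = NULL,
                               nBoot = 2000L, seed = 1L) {
  y <- .asBinary(labels)
  if (length(unique(y)) < 2L)
    stop("AUC undefined: need both classes present")
  auc <- aucRank(probabilities, y)
  if (is.null(threshold)) threshold <- .youdenThreshold(probabilities, y)
  pred <- probabilities >= threshold
  sens <- sum(pred & y == 1L) / sum(y == 1L)
  spec <- sum(!pred & y == 0L) / sum(y == 0L)
  acc <- mean(pred == (y == 1L))

  set.seed(seed)
  pos <- which(y == 1L); neg <- which(y == 0L)
  boot <- vapply(seq_len(nBoot), function(b) {
    idx <- c(sample(pos, length(pos), replace = TRUE),
             sample(neg, length(neg), replace = TRUE))
    aucRank(probabilities[idx], y[idx])
  }, numeric(1))
  ci <- unname(quantile(boot, c(0.025, 0.975)))

  list(auc = auc, auc_ci = ci, accuracy = acc, sensitivity = sens,
       specificity = spec, threshold = threshold, n = length(y))
}
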