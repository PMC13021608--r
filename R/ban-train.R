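## Training protocol: Adam on a bin-weighted L1 loss, learning-rate halving
## after a 5-epoch training-loss plateau, early stopping after 20 epochs
## without validation-MAE improvement, best-weights restore.

# normalize + lesion-exclude one subject; returns the input array and its
# non-lesion foreground ROI box
.preprocessSubject <- function(volume, mask = NULL) {
  norm <- normalizeIntensity(volume, mask)
  if (!is.null(mask)) norm <- applyLesionExclusion(norm, mask)
  arr <- norm@data
  list(x = arr, roi = .roiBoxFromArray(arr))
}

#' Train the Brain Age Network
#'
#' Minimizes the age-bin-weighted L1 loss with Adam under the configured
#' protocol. The regression target is standardized internally (center and
#' scale frozen from the training split and stored with the model), so
#' optimization starts from the mean-predictor baseline and step sizes are
#' well-scaled at the protocol learning rate; losses and MAEs are reported
#' in years. Weights with the best validation MAE are restored at the end.
#' Deterministic under the config seed in single-threaded BLAS mode.
#'
#' @param volumes list of [BrainVolume].
#' @param masks list of [LesionMask] or `NULL` entries (controls may pass
#'   `NULL`); lesion exclusion is applied before any feature extraction.
#' @param ages numeric chronological ages (years).
#' @param splits list with integer indices `train` and `val`
#'   (see [splitDataset()]).
#' @param config a [BanConfig].
#' @param verbose print per-epoch progress.
#' @return a trained [BrainAgeNetwork] with per-epoch `history` and the
#'   training-set predictions recorded in `biasFitInputs`.
#' @export
trainBan <- function(volumes, masks, ages, splits, config = BanConfig(),
                     verbose = FALSE) {
  stopifnot(length(volumes) == length(ages))
  if (length(splits$train) < 1L) stop("training split is empty")
  inputShape <- dim(volumes[[1]]@data)

  prep <- lapply(seq_along(volumes), function(i)
    .preprocessSubject(volumes[[i]],
                       if (is.null(masks)) NULL else masks[[i]]))

  model <- buildBan(config, inputShape)     # seeds RNG with config@seed
  params <- model@params

  # the network regresses the standardized age (center/scale frozen from the
  # training split) so that optimization distances are O(1) at the protocol
  # learning rate; reported losses and MAEs are in years
  ageCenter <- mean(ages[splits$train])
  ageScale <- max(sd(ages[splits$train]), 1)
  aStd <- (ages - ageCenter) / ageScale

  wTrain <- computeBinWeights(ages[splits$train], config@ageBinEdges)
  weights <- numeric(length(ages))
  weights[splits$train] <- wTrain

  adam <- .adamInit(params)
  lr <- config@learningRate
  bestTrain <- Inf; plateau <- 0L
  bestVal <- Inf; sinceBest <- 0L
  bestParams <- params
  hist <- data.frame(epoch = integer(), lr = numeric(),
                     train_loss = numeric(), val_mae = numeric())

  valMae <- function(p) {
    pred <- vapply(splits$val, function(i)
      .banForward(p, config, inputShape, prep[[i]]$x, prep[[i]]$roi)$pred,
      numeric(1))
    if (length(pred) == 0) return(NA_real_)
    mean(abs(ageCenter + ageScale * pred - ages[splits$val]))
  }

  for (epoch in seq_len(config@maxEpochs)) {
    ord <- splits$train[sample.int(length(splits$train))]
    batches <- split(ord, ceiling(seq_along(ord) / config@batchSize))
    epochLoss <- 0
    for (bt in batches) {
      grads <- NULL
      bLoss <- 0
      for (i in bt) {
        fw <- .banForward(params, config, inputShape, prep[[i]]$x,
                          prep[[i]]$roi, withCache = TRUE)
        if (!is.finite(fw$pred))
          stop(sprintf(
            "divergent loss: non-finite prediction at epoch %d (lr %.2g)",
            epoch, lr))
        err <- fw$pred - aStd[i]
        bLoss <- bLoss + weights[i] * abs(err) * ageScale
        dPred <- weights[i] * sign(err) / length(bt)
        g <- .banBackward(params, config, fw$caches, dPred)
        grads <- if (is.null(grads)) g else .leafMap2(grads, g, `+`)
      }
      step <- .adamStep(params, grads, adam, lr, config@beta1,
                        config@beta2, config@weightDecay)
      params <- step$params
      adam <- step$state
      epochLoss <- epochLoss + bLoss
    }
    epochLoss <- epochLoss / length(ord)

    vm <- valMae(params)
    hist <- rbind(hist, data.frame(epoch = epoch, lr = lr,
                                   train_loss = epochLoss, val_mae = vm))
    if (verbose)
      message(sprintf("epoch %3d  lr %.5f  train %.3f  val MAE %.3f",
                      epoch, lr, epochLoss, vm))

    # plateau scheduler on the training loss
    if (epochLoss < bestTrain - 1e-8) {
      bestTrain <- epochLoss; plateau <- 0L
    } else {
      plateau <- plateau + 1L
      if (plateau >= config@plateauPatience) {
        lr <- lr * config@plateauFactor
        plateau <- 0L
      }
    }

    # early stopping on validation MAE
    if (is.finite(vm) && vm < bestVal - 1e-8) {
      bestVal <- vm; sinceBest <- 0L; bestParams <- params
    } else {
      sinceBest <- sinceBest + 1L
      if (sinceBest >= config@earlyStopPatience) break
    }
  }
  if (is.finite(bestVal)) params <- bestParams

  fitPred <- ageCenter + ageScale * vapply(splits$train, function(i)
    .banForward(params, config, inputShape, prep[[i]]$x, prep[[i]]$roi)$pred,
    numeric(1))

  model@params <- params
  model@ageNorm <- c(ageCenter, ageScale)
  model@trained <- TRUE
  model@history <- hist
  model@biasFitInputs <- data.frame(index = splits$train,
                                    age = ages[splits$train],
                                    predicted = fitPred)
  model
}

#' Predict age for one subject
#'
#' Applies the training-time preprocessing (z-score normalization excluding
#' the lesion, lesion exclusion, non-lesion ROI box) and the trained
#' network. Predictions are exactly invariant to arbitrary intensity changes
#' strictly inside the exclusion mask.
#'
#' @param model a trained [BrainAgeNetwork].
#' @param volume a [BrainVolume] in the training geometry.
#' @param mask optional [LesionMask]; `NULL` for controls.
#' @return predicted age in years (finite scalar).
#' @export
predictAge <- function(model, volume, mask = NULL) {
  stopifnot(is(model, "BrainAgeNetwork"))
  if (!model@trained) stop("model is not trained")
  if (!identical(dim(volume@data), as.integer(model@inputShape)))
    stop(sprintf("geometry mismatch: model expects %s, volume is %s",
                 paste(model@inputShape, collapse = "x"),
                 paste(dim(volume@data), collapse = "x")))
  p <- .preprocessSubject(volume, mask)
  model@ageNorm[1] + model@ageNorm[2] *
    .banForward(model@params, model@config, model@inputShape, p$x, p$roi)$pred
}

#' Predict ages for a list of subjects
#'
#' @param model a trained [BrainAgeNetwork].
#' @param volumes list of [BrainVolume].
#' @param masks list of [LesionMask] (or `NULL`).
#' @return numeric vector of predicted ages.
#' @export
predictAges <- function(model, volumes, masks = NULL) {
  vapply(seq_along(volumes), function(i)
    predictAge(model, volumes[[i]],
               if (is.null(masks)) NULL else masks[[i]]),
    numeric(1))
}

#' K-fold cross-validation of the Brain Age Network on a training subset
#'
#' Five-fold cross-validation (by default) for hyperparameter selection:
#' each fold is held out once as validation while the network trains on the
#' rest. Fold assignment is deterministic under the config seed.
#'
#' @param volumes,masks,ages as in [trainBan()].
#' @param config a [BanConfig].
#' @param folds number of folds.
#' @return data.frame with one row per fold: fold, n_val, val_mae.
#' @export
crossValidateBan <- function(volumes, masks, ages, config = BanConfig(),
                             folds = 5L) {
  n <- length(volumes)
  if (n < folds) stop("need at least as many subjects as folds")
  set.seed(config@seed)
  foldId <- sample(rep(seq_len(folds), length.out = n))
  res <- lapply(seq_len(folds), function(f) {
    sp <- list(train = which(foldId != f), val = which(foldId == f))
    fit <- trainBan(volumes, masks, ages, sp, config)
    data.frame(fold = f, n_val = length(sp$val),
               val_mae = min(fit@history$val_mae, na.rm = TRUE))
  })
  do.call(rbind, res)
}
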