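#' @import methods
#' @importFrom stats rnorm runif rbinom plogis qnorm pnorm qf pf sd var cor
#'   median quantile lm coef glm binomial predict ks.test shapiro.test
#'   chisq.test p.adjust pwilcox complete.cases setNames aggregate
#' @importFrom utils combn head modifyList
NULL

## ---------------------------------------------------------------------------
## Volumes and masks
## ---------------------------------------------------------------------------

#' BrainVolume: a 3D scalar image with geometry metadata
#'
#' Minimal container for a 3D structural volume: a numeric array plus voxel
#' spacing (mm) and origin (mm). Orientation is assumed RAS-aligned; the
#' package operates on co-registered template-space images.
#'
#' @slot data 3D numeric array of voxel intensities.
#' @slot spacing Numeric length-3, voxel size in mm (strictly positive).
#' @slot origin Numeric length-3, position of the first voxel in mm.
#' @export
setClass("BrainVolume",
  representation(data = "array", spacing = "numeric", origin = "numeric"),
  prototype(spacing = c(2, 2, 2), origin = c(0, 0, 0))
)

setValidity("BrainVolume", function(object) {
  msg <- character()
  if (length(dim(object@data)) != 3L)
    msg <- c(msg, "data must be a 3D array")
  if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
      any(object@spacing <= 0))
    msg <- c(msg, "spacing must be 3 strictly positive finite values")
  if (length(object@origin) != 3L || any(!is.finite(object@origin)))
    msg <- c(msg, "origin must be 3 finite values")
  if (any(!is.finite(object@data)))
    msg <- c(msg, "voxel data must be finite")
  if (length(msg)) msg else TRUE
})

#' LesionMask: a binary volume aligned to a BrainVolume
#'
#' Marks tumor core plus peritumoral edema. Values are strictly 0/1; an
#' all-zero mask denotes a lesion-free (control) subject.
#'
#' @export
setClass("LesionMask", contains = "BrainVolume")

setValidity("LesionMask", function(object) {
  if (!all(object@data %in% c(0, 1)))
    return("mask values must be 0 or 1")
  TRUE
})

#' @describeIn BrainVolume constructor
#' @param data 3D numeric array.
#' @param spacing voxel size in mm.
#' @param origin origin in mm.
#' @export
BrainVolume <- function(data, spacing = c(2, 2, 2), origin = c(0, 0, 0)) {
  new("BrainVolume", data = data, spacing = as.numeric(spacing),
      origin = as.numeric(origin))
}

#' @describeIn LesionMask constructor; values are thresholded at 0.5
#' @param data 3D array (binarized at 0.5).
#' @param spacing,origin geometry, as for [BrainVolume()].
#' @export
LesionMask <- function(data, spacing = c(2, 2, 2), origin = c(0, 0, 0)) {
  new("LesionMask", data = (data > 0.5) * 1,
      spacing = as.numeric(spacing), origin = as.numeric(origin))
}

## ---------------------------------------------------------------------------
## Phantom generator configuration
## ---------------------------------------------------------------------------

#' PhantomConfig: parameters of the synthetic cohort generator
#'
#' Defaults emulate the framework's study conditions: ages uniform on
#' 20-85 years, 30\% glioma prevalence, high-grade fraction 0.7, group-level
#' accelerated-aging shifts of 15 (non-epileptic) and 10 (epileptic)
#' years-equivalent, and a logistic epilepsy label model on tumor grade and a
#' latent aging perturbation.
#'
#' @slot nSubjects number of subjects.
#' @slot volumeShape voxel dimensions (default 32x32x32 at 2 mm isotropic).
#' @slot ageRange chronological age interval in years.
#' @slot ageSignalStrength ventricle-radius change per effective-age year
#'   (voxels/year); 0 removes the structural age signal.
#' @slot noiseSd additive Gaussian intensity noise inside the brain.
#' @slot gliomaFraction proportion of subjects with a lesion.
#' @slot lesionRadiusRange semi-axis range of the ellipsoidal lesion core
#'   (voxels).
#' @slot edemaVoxels dilation of the core into an edema shell (voxels).
#' @slot agingShiftNonEpileptic,agingShiftEpileptic group mean aging shifts
#'   (years-equivalent); epileptic must not exceed non-epileptic.
#' @slot agingShiftSd subject-level SD of the shift around its group mean.
#' @slot epilepsyLogitCoefs coefficients (intercept, high-grade, latent
#'   perturbation) of the epilepsy label model.
#' @slot gradeHighFraction probability a glioma is high grade.
#' @slot maxVentricleOverlap maximum allowed fraction of the ventricle region
#'   covered by a lesion mask.
#' @slot seed RNG seed; identical config + seed gives bit-identical cohorts.
#' @export
setClass("PhantomConfig",
  representation(
    nSubjects = "integer", volumeShape = "integer", ageRange = "numeric",
    ageSignalStrength = "numeric", noiseSd = "numeric",
    gliomaFraction = "numeric", lesionRadiusRange = "numeric",
    edemaVoxels = "integer",
    agingShiftNonEpileptic = "numeric", agingShiftEpileptic = "numeric",
    agingShiftSd = "numeric", epilepsyLogitCoefs = "numeric",
    gradeHighFraction = "numeric", maxVentricleOverlap = "numeric",
    seed = "integer"
  ),
  prototype(
    nSubjects = 100L, volumeShape = c(32L, 32L, 32L), ageRange = c(20, 85),
    ageSignalStrength = 0.06, noiseSd = 0.08,
    gliomaFraction = 0.3, lesionRadiusRange = c(3, 5), edemaVoxels = 2L,
    agingShiftNonEpileptic = 15, agingShiftEpileptic = 10,
    agingShiftSd = 2,
    epilepsyLogitCoefs = c(intercept = -0.6, grade_high = -0.4,
                           perturbation = -0.5),
    gradeHighFraction = 0.7, maxVentricleOverlap = 0.05, seed = 1L
  )
)

setValidity("PhantomConfig", function(object) {
  msg <- character()
  if (object@nSubjects < 1L)
    msg <- c(msg, "nSubjects must be >= 1")
  if (length(object@volumeShape) != 3L || any(object@volumeShape < 8L))
    msg <- c(msg, "volumeShape must be three positive dimensions (>= 8)")
  if (object@gliomaFraction < 0 || object@gliomaFraction > 1)
    msg <- c(msg, "gliomaFraction must lie in [0, 1]")
  if (object@agingShiftEpileptic > object@agingShiftNonEpileptic)
    msg <- c(msg, "agingShiftEpileptic must be <= agingShiftNonEpileptic")
  if (diff(object@ageRange) < 0 || any(object@ageRange <= 0))
    msg <- c(msg, "ageRange must be a positive interval")
  if (length(object@epilepsyLogitCoefs) != 3L)
    msg <- c(msg, "epilepsyLogitCoefs must have 3 elements")
  if (length(msg)) msg else TRUE
})

#' @describeIn PhantomConfig constructor; any slot can be overridden by name
#' @param ... named slot overrides, e.g. \code{nSubjects = 50, seed = 7}.
#' @export
PhantomConfig <- function(...) {
  args <- list(...)
  for (nm in c("nSubjects", "volumeShape", "edemaVoxels", "seed"))
    if (!is.null(args[[nm]])) args[[nm]] <- as.integer(args[[nm]])
  do.call(new, c(list("PhantomConfig"), args))
}

#' PhantomCohort: a generated synthetic cohort
#'
#' @slot volumes list of [BrainVolume] objects.
#' @slot masks list of [LesionMask] objects (all-zero for controls).
#' @slot subjects data.frame with id, age, sex, site, grade, epilepsy.
#' @slot truth data.frame of generative parameters per subject (aging shift,
#'   lesion volume, ventricle radius). Consumed only by tests and reports,
#'   never by model fitting.
#' @export
setClass("PhantomCohort",
  representation(volumes = "list", masks = "list",
                 subjects = "data.frame", truth = "data.frame"))

setValidity("PhantomCohort", function(object) {
  n <- nrow(object@subjects)
  if (length(object@volumes) != n || length(object@masks) != n ||
      nrow(object@truth) != n)
    return("volumes, masks, subjects and truth must have equal lengths")
  TRUE
})

## ---------------------------------------------------------------------------
## Brain Age Network
## ---------------------------------------------------------------------------

#' BanConfig: architecture and optimization protocol of the Brain Age Network
#'
#' A VGG-style 3D backbone with residual units and stride-2 convolutional
#' downsampling, ROI-Align pooling over the non-lesion bounding box, and a
#' linear regression head. Optimization follows Adam (lr 0.001, weight decay
#' 1e-6, beta1 0.9, beta2 0.999) with learning-rate halving after a 5-epoch
#' training-loss plateau and early stopping after 20 epochs without
#' validation-MAE improvement.
#'
#' @slot convChannels channels per stage; stage 1 keeps full resolution,
#'   every later stage opens with a stride-2 convolution.
#' @slot blocksPerStage residual units per stage.
#' @slot roiOutputGrid pooled grid size of the ROI-Align head.
#' @slot samplesPerCell interpolation sample points per axis per pooled cell.
#' @slot ageBinEdges bin edges (years) for inverse-frequency loss weights.
#' @slot learningRate,weightDecay,beta1,beta2 Adam hyperparameters.
#' @slot plateauFactor,plateauPatience training-loss plateau scheduler.
#' @slot earlyStopPatience validation-MAE early-stopping patience (epochs).
#' @slot maxEpochs,batchSize training budget.
#' @slot seed RNG seed for initialization, shuffling and fold assignment.
#' @export
setClass("BanConfig",
  representation(
    convChannels = "integer", blocksPerStage = "integer",
    roiOutputGrid = "integer", samplesPerCell = "integer",
    ageBinEdges = "numeric",
    learningRate = "numeric", weightDecay = "numeric",
    beta1 = "numeric", beta2 = "numeric",
    plateauFactor = "numeric", plateauPatience = "integer",
    earlyStopPatience = "integer", maxEpochs = "integer",
    batchSize = "integer", seed = "integer"
  ),
  prototype(
    convChannels = c(16L, 32L, 64L), blocksPerStage = 1L,
    roiOutputGrid = c(2L, 2L, 2L), samplesPerCell = 2L,
    ageBinEdges = seq(0, 110, by = 10),
    learningRate = 0.001, weightDecay = 1e-6, beta1 = 0.9, beta2 = 0.999,
    plateauFactor = 0.5, plateauPatience = 5L, earlyStopPatience = 20L,
    maxEpochs = 50L, batchSize = 8L, seed = 1L
  )
)

setValidity("BanConfig", function(object) {
  msg <- character()
  if (any(object@roiOutputGrid < 1L) || length(object@roiOutputGrid) != 3L)
    msg <- c(msg, "roiOutputGrid must be three positive integers")
  if (is.unsorted(object@ageBinEdges, strictly = TRUE))
    msg <- c(msg, "ageBinEdges must be strictly increasing")
  if (object@plateauPatience < 1L || object@earlyStopPatience < 1L)
    msg <- c(msg, "patience values must be positive")
  if (object@samplesPerCell < 1L)
    msg <- c(msg, "samplesPerCell must be >= 1")
  if (length(msg)) msg else TRUE
})

#' @describeIn BanConfig constructor with named overrides
#' @param ... named slot overrides.
#' @export
BanConfig <- function(...) {
  args <- list(...)
  ints <- c("convChannels", "blocksPerStage", "roiOutputGrid",
            "samplesPerCell", "plateauPatience", "earlyStopPatience",
            "maxEpochs", "batchSize", "seed")
  for (nm in ints)
    if (!is.null(args[[nm]])) args[[nm]] <- as.integer(args[[nm]])
  do.call(new, c(list("BanConfig"), args))
}

#' BrainAgeNetwork: the (possibly trained) Brain Age Network
#'
#' @slot params list of layer parameters (convolution kernels, biases,
#'   regression head).
#' @slot config the [BanConfig] the network was built with.
#' @slot inputShape voxel dimensions the network accepts.
#' @slot trained logical.
#' @slot ageNorm internal target standardization `c(center, scale)` (years);
#'   the network regresses the standardized age and predictions are unscaled.
#' @slot history per-epoch data.frame: epoch, lr, train_loss, val_mae.
#' @slot biasFitInputs predictions on the designated healthy fit set
#'   (id, age, predicted), recorded at training time.
#' @export
setClass("BrainAgeNetwork",
  representation(params = "list", config = "BanConfig",
                 inputShape = "integer", trained = "logical",
                 ageNorm = "numeric",
                 history = "data.frame", biasFitInputs = "data.frame"),
  prototype(trained = FALSE, ageNorm = c(0, 1), history = data.frame(),
            biasFitInputs = data.frame()))

## ---------------------------------------------------------------------------
## Bias correction and BAI
## ---------------------------------------------------------------------------

#' BiasCorrection: linear age-bias correction fitted on a reference cohort
#'
#' Holds the slope and intercept of the regression of predicted on
#' chronological age, plus the fit cohort's mean absolute error, which enters
#' the corrected-age formula as a constant offset.
#'
#' @slot alpha slope (dimensionless).
#' @slot beta intercept (years).
#' @slot maeTerm mean absolute error on the fit cohort (years, >= 0).
#' @slot fitCohortId provenance label of the fit cohort.
#' @export
setClass("BiasCorrection",
  representation(alpha = "numeric", beta = "numeric", maeTerm = "numeric",
                 fitCohortId = "character"),
  prototype(fitCohortId = "unspecified"))

setValidity("BiasCorrection", function(object) {
  msg <- character()
  if (!is.finite(object@alpha) || !is.finite(object@beta))
    msg <- c(msg, "alpha and beta must be finite")
  if (object@maeTerm < 0) msg <- c(msg, "maeTerm must be >= 0")
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## Radiomic signature and fusion model
## ---------------------------------------------------------------------------

#' RadiomicSignature: LASSO-selected features and their weights
#'
#' Coefficients are on the standardized feature scale; the standardization
#' (center, scale) learned at selection time is stored so scores are a fixed
#' transform at inference.
#'
#' @slot features selected feature names (all with nonzero coefficients).
#' @slot coefficients weights per selected feature (standardized scale).
#' @slot intercept model intercept.
#' @slot lambda penalty at which the signature was selected (> 0).
#' @slot center,scale per-feature standardization parameters.
#' @export
setClass("RadiomicSignature",
  representation(features = "character", coefficients = "numeric",
                 intercept = "numeric", lambda = "numeric",
                 center = "numeric", scale = "numeric"))

setValidity("RadiomicSignature", function(object) {
  msg <- character()
  if (length(object@features) != length(object@coefficients))
    msg <- c(msg, "features and coefficients must have equal length")
  if (any(object@coefficients == 0))
    msg <- c(msg, "signature coefficients must all be nonzero")
  if (object@lambda <= 0) msg <- c(msg, "lambda must be > 0")
  if (length(msg)) msg else TRUE
})

#' FusionModel: stacked clinic-radiomic epilepsy classifier
#'
#' Two gradient-boosted component models (radiomic and clinical) whose
#' out-of-fold probabilities are combined by a logistic regression. The fold
#' assignment is shared between the two components and the stacking fit only
#' ever sees out-of-fold probabilities.
#'
#' @slot radiomicModel,clinicalModel component model bundles (booster +
#'   hyperparameters + feature names).
#' @slot stackCoefs logistic weights (intercept, radiomic, clinical).
#' @slot foldMap integer fold id per training subject.
#' @slot oofRecord data.frame (subject row, fold, oof_radiomic, oof_clinical)
#'   documenting that stacking inputs were out-of-fold.
#' @slot threshold operating probability threshold (Youden's J on the
#'   training OOF fusion probabilities, frozen before test evaluation).
#' @slot seed RNG seed.
#' @export
setClass("FusionModel",
  representation(radiomicModel = "list", clinicalModel = "list",
                 stackCoefs = "numeric", foldMap = "integer",
                 oofRecord = "data.frame", threshold = "numeric",
                 seed = "integer"),
  prototype(threshold = 0.5, seed = 1L))

## ---------------------------------------------------------------------------
## show methods
## ---------------------------------------------------------------------------

setMethod("show", "BrainVolume", function(object) {
  d <- dim(object@data)
  cat(sprintf("%s %dx%dx%d, spacing %.3gx%.3gx%.3g mm\n",
              class(object), d[1], d[2], d[3],
              object@spacing[1], object@spacing[2], object@spacing[3]))
  cat(sprintf("  intensity range [%.4g, %.4g]\n",
              min(object@data), max(object@data)))
})

setMethod("show", "LesionMask", function(object) {
  d <- dim(object@data)
  cat(sprintf("LesionMask %dx%dx%d, %d lesion voxels\n",
              d[1], d[2], d[3], sum(object@data)))
})

setMethod("show", "PhantomCohort", function(object) {
  s <- object@subjects
  cat(sprintf("PhantomCohort: %d subjects (%d glioma, %d control)\n",
              nrow(s), sum(s$grade != "none"), sum(s$grade == "none")))
  cat(sprintf("  ages %.1f-%.1f y; %d epileptic\n",
              min(s$age), max(s$age), sum(s$epilepsy == "yes")))
})

setMethod("show", "BiasCorrection", function(object) {
  cat(sprintf(
    "BiasCorrection (fit on '%s'): alpha = %.4f, beta = %.3f y, MAE = %.3f y\n",
    object@fitCohortId, object@alpha, object@beta, object@maeTerm))
})

setMethod("show", "BrainAgeNetwork", function(object) {
  cfg <- object@config
  cat(sprintf("BrainAgeNetwork (%s): stages %s, ROI grid %s\n",
              if (object@trained) "trained" else "untrained",
              paste(cfg@convChannels, collapse = "/"),
              paste(cfg@roiOutputGrid, collapse = "x")))
  if (object@trained && nrow(object@history)) {
    best <- min(object@history$val_mae, na.rm = TRUE)
    cat(sprintf("  %d epochs, best validation MAE %.3f y\n",
                nrow(object@history), best))
  }
})

setMethod("show", "RadiomicSignature", function(object) {
  cat(sprintf("RadiomicSignature: %d features at lambda = %.4g\n",
              length(object@features), object@lambda))
  if (length(object@features))
    cat("  ", paste(object@features, collapse = ", "), "\n")
})

setMethod("show", "FusionModel", function(object) {
  cat(sprintf(
    "FusionModel: logistic stack over %d-fold OOF probabilities\n",
    length(unique(object@foldMap))))
  cat(sprintf("  weights: intercept %.3f, radiomic %.3f, clinical %.3f; threshold %.3f\n",
              object@stackCoefs[1], object@stackCoefs[2],
              object@stackCoefs[3], object@threshold))
})

## ---------------------------------------------------------------------------
## accessors
## ---------------------------------------------------------------------------

#' Accessors for package classes
#'
#' @param object an object of the documented class.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("volumeData", function(object) standardGeneric("volumeData"))
#' @rdname accessors
#' @export
setMethod("volumeData", "BrainVolume", function(object) object@data)

#' @rdname accessors
#' @export
setGeneric("voxelSpacing", function(object) standardGeneric("voxelSpacing"))
#' @rdname accessors
#' @export
setMethod("voxelSpacing", "BrainVolume", function(object) object@spacing)

#' @rdname accessors
#' @export
setGeneric("subjectTable", function(object) standardGeneric("subjectTable"))
#' @rdname accessors
#' @export
setMethod("subjectTable", "PhantomCohort", function(object) object@subjects)

#' @rdname accessors
#' @export
setGeneric("truthTable", function(object) standardGeneric("truthTable"))
#' @rdname accessors
#' @export
setMethod("truthTable", "PhantomCohort", function(object) object@truth)

#' @rdname accessors
#' @export
setGeneric("cohortVolumes", function(object) standardGeneric("cohortVolumes"))
#' @rdname accessors
#' @export
setMethod("cohortVolumes", "PhantomCohort", function(object) object@volumes)

#' @rdname accessors
#' @export
setGeneric("cohortMasks", function(object) standardGeneric("cohortMasks"))
#' @rdname accessors
#' @export
setMethod("cohortMasks", "PhantomCohort", function(object) object@masks)

#' @rdname accessors
#' @export
setGeneric("trainingHistory", function(object) standardGeneric("trainingHistory"))
#' @rdname accessors
#' @export
setMethod("trainingHistory", "BrainAgeNetwork", function(object) object@history)

#' @rdname accessors
#' @export
setGeneric("banConfig", function(object) standardGeneric("banConfig"))
#' @rdname accessors
#' @export
setMethod("banConfig", "BrainAgeNetwork", function(object) object@config)

#' @rdname accessors
#' @export
setGeneric("signatureFeatures", function(object) standardGeneric("signatureFeatures"))
#' @rdname accessors
#' @export
setMethod("signatureFeatures", "RadiomicSignature", function(object) object@features)
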