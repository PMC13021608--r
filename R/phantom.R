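## Synthetic phantom cohorts.
##
## Volumes encode age through two structural signals that survive per-volume
## z-scoring: a central ventricle-like sphere whose radius grows linearly with
## effective age (chronological age + planted aging shift), and a bright
## cortical band whose thickness shrinks linearly with effective age. Glioma
## subjects carry an ellipsoidal lesion core plus an edema shell obtained by
## binary dilation; the lesion is placed off-center so it can never erase the
## ventricular age signal.

# subject-level anatomical variability of the ventricle radius (voxels);
# keeps the structural summary non-degenerate when ageSignalStrength = 0
.RADIUS_JITTER_SD <- 0.3

.voxelGrid <- function(dims) {
  list(x = array(rep(seq_len(dims[1]), times = dims[2] * dims[3]), dims),
       y = array(rep(rep(seq_len(dims[2]), each = dims[1]), dims[3]), dims),
       z = array(rep(seq_len(dims[3]), each = dims[1] * dims[2]), dims))
}

# 6-neighborhood binary dilation, `k` iterations
.dilate3d <- function(mask, k) {
  d <- dim(mask)
  for (i in seq_len(k)) {
    out <- mask
    out[-1, , ] <- out[-1, , ] | mask[-d[1], , ]
    out[-d[1], , ] <- out[-d[1], , ] | mask[-1, , ]
    out[, -1, ] <- out[, -1, ] | mask[, -d[2], ]
    out[, -d[2], ] <- out[, -d[2], ] | mask[, -1, ]
    out[, , -1] <- out[, , -1] | mask[, , -d[3]]
    out[, , -d[3]] <- out[, , -d[3]] | mask[, , -1]
    mask <- out
  }
  mask
}

#' Generate a synthetic cohort of brain phantoms
#'
#' Builds `nSubjects` 3D phantoms with a known, linear structural age code,
#' lesion masks for glioma subjects, a subject table and a generative truth
#' table. Among glioma subjects the epilepsy label is drawn from a logistic
#' model on tumor grade and a latent aging perturbation; the planted aging
#' shift is the group mean (epileptic <= non-epileptic) plus that
#' perturbation, so group ordering of accelerated aging
#' (control < epileptic < non-epileptic) is known by construction.
#'
#' @param config a [PhantomConfig].
#' @return a [PhantomCohort].
#' @examples
#' coh <- generateCohort(PhantomConfig(nSubjects = 6, seed = 1))
#' subjectTable(coh)
#' @export
generateCohort <- function(config) {
  stopifnot(is(config, "PhantomConfig"))
  validObject(config)
  n <- config@nSubjects
  dims <- config@volumeShape
  set.seed(config@seed)

  ## ---- subject-level draws -------------------------------------------------
  age <- runif(n, config@ageRange[1], config@ageRange[2])
  sex <- sample(c("F", "M"), n, replace = TRUE)
  site <- sample(c("siteA", "siteB", "siteC"), n, replace = TRUE)

  nGlioma <- round(n * config@gliomaFraction)
  glioma <- rep(FALSE, n)
  glioma[sample.int(n, nGlioma)] <- TRUE

  grade <- rep("none", n)
  grade[glioma] <- ifelse(
    runif(nGlioma) < config@gradeHighFraction, "high", "low")

  z <- rep(0, n)                     # latent aging perturbation
  z[glioma] <- rnorm(nGlioma)
  co <- config@epilepsyLogitCoefs
  pEpi <- plogis(co[1] + co[2] * (grade == "high") + co[3] * z)
  epilepsy <- rep("n/a", n)
  epilepsy[glioma] <- ifelse(runif(nGlioma) < pEpi[glioma], "yes", "no")

  shift <- rep(0, n)
  shift[glioma] <- ifelse(epilepsy[glioma] == "yes",
                          config@agingShiftEpileptic,
                          config@agingShiftNonEpileptic) +
    config@agingShiftSd * z[glioma]
  shift[glioma] <- pmax(shift[glioma], 0)

  effAge <- age + shift
  rJitter <- rnorm(n, 0, .RADIUS_JITTER_SD)

  ## ---- geometry ------------------------------------------------------------
  g <- .voxelGrid(dims)
  ctr <- (dims + 1) / 2
  dist2 <- (g$x - ctr[1])^2 + (g$y - ctr[2])^2 + (g$z - ctr[3])^2
  brainR <- 0.42 * min(dims)
  brain <- dist2 <= brainR^2

  ventR <- pmin(pmax(5 + config@ageSignalStrength * (effAge - 50) + rJitter,
                     1.2), 0.6 * brainR)
  bandT <- pmin(pmax(3.5 - (config@ageSignalStrength / 2) * (effAge - 50),
                     1.0), 6.0)

  volumes <- vector("list", n)
  masks <- vector("list", n)
  lesionVol <- integer(n)

  for (i in seq_len(n)) {
    vol <- array(0, dims)
    vol[brain] <- 1.0
    vent <- dist2 <= ventR[i]^2
    vol[vent] <- 0.25
    band <- brain & dist2 >= (brainR - bandT[i])^2
    vol[band] <- 1.35

    maskArr <- array(0, dims)
    if (glioma[i]) {
      texSd <- if (epilepsy[i] == "yes") 0.25 else 0.10
      ax0 <- runif(3, config@lesionRadiusRange[1], config@lesionRadiusRange[2])
      for (try in 1:40) {
        u <- rnorm(3); u <- u / sqrt(sum(u^2))
        lc <- ctr + u * runif(1, 0.28, 0.36) * min(dims)
        ax <- ax0 * if (try > 20) 0.9^(try - 20) else 1
        core <- (((g$x - lc[1]) / ax[1])^2 + ((g$y - lc[2]) / ax[2])^2 +
                   ((g$z - lc[3]) / ax[3])^2) <= 1
        core <- core & brain
        lesion <- .dilate3d(core, config@edemaVoxels) & brain
        overlap <- sum(lesion & vent) / max(sum(vent), 1L)
        if (overlap <= config@maxVentricleOverlap && sum(core) > 0) break
      }
      if (overlap > config@maxVentricleOverlap) {
        # guarantee the invariant: carve the protected ventricular region
        # out of the mask so the age signal can never be fully excluded
        core <- core & !vent
        lesion <- lesion & !vent
      }
      edema <- lesion & !core
      vol[core] <- 1.8 + rnorm(sum(core), 0, texSd)
      vol[edema] <- 1.4 + rnorm(sum(edema), 0, texSd * 0.7)
      maskArr[lesion] <- 1
      lesionVol[i] <- sum(lesion)
    }

    vol[brain] <- vol[brain] + rnorm(sum(brain), 0, config@noiseSd)
    volumes[[i]] <- BrainVolume(vol)
    masks[[i]] <- LesionMask(maskArr)
  }

  ids <- sprintf("sub%04d", seq_len(n))
  subjects <- data.frame(
    id = ids, age = age, sex = sex, site = site,
    grade = grade, epilepsy = epilepsy, stringsAsFactors = FALSE)
  truth <- data.frame(
    id = ids, group = ifelse(!glioma, "control",
                             ifelse(epilepsy == "yes", "epileptic",
                                    "non_epileptic")),
    aging_shift = shift, perturbation = z,
    ventricle_radius = ventR, band_thickness = bandT,
    lesion_voxels = lesionVol, stringsAsFactors = FALSE)

  new("PhantomCohort", volumes = volumes, masks = masks,
      subjects = subjects, truth = truth)
}

#' Generate a synthetic feature table with planted class structure
#'
#' Fixture generator for the feature-selection chain: `nInformative` features
#' shifted by `effectSize` (standardized units) between two balanced classes,
#' `nNoise` label-independent features, and `nDuplicates` near-copies
#' (Spearman rho > 0.95 by construction) of informative parents (of noise
#' parents when there are no informative features).
#'
#' @param nSubjects number of rows (>= 4).
#' @param nInformative,nNoise,nDuplicates feature counts (>= 0).
#' @param effectSize standardized between-class shift (>= 0).
#' @param seed RNG seed.
#' @return list with `features` (data.frame, provenance attribute
#'   `"radiomic"`), `labels` (factor `neg`/`pos`) and `informative`
#'   (the informative column names).
#' @export
generateFeatureTable <- function(nSubjects, nInformative, nNoise,
                                 nDuplicates, effectSize = 1.0, seed = 1L) {
  if (nSubjects < 4)
    stop("nSubjects must be >= 4")
  stopifnot(nInformative >= 0, nNoise >= 0, nDuplicates >= 0, effectSize >= 0)
  set.seed(seed)
  labels <- sample(rep(c(0L, 1L), length.out = nSubjects))

  cols <- list()
  infNames <- if (nInformative > 0) sprintf("inf_%02d", seq_len(nInformative))
              else character()
  for (j in seq_len(nInformative))
    cols[[infNames[j]]] <- rnorm(nSubjects) + effectSize * labels
  for (j in seq_len(nNoise))
    cols[[sprintf("noise_%03d", j)]] <- rnorm(nSubjects)

  parents <- if (nInformative > 0) infNames else names(cols)
  if (nDuplicates > 0 && length(parents) == 0)
    stop("cannot create duplicates without any parent features")
  for (j in seq_len(nDuplicates)) {
    p <- parents[((j - 1) %% length(parents)) + 1]
    cols[[sprintf("dup_%02d_%s", j, p)]] <-
      cols[[p]] + rnorm(nSubjects, 0, 0.08)
  }

  features <- as.data.frame(cols, check.names = FALSE)
  attr(features, "provenance") <-
    setNames(rep("radiomic", ncol(features)), names(features))
  list(features = features,
       labels = factor(ifelse(labels == 1, "pos", "neg"),
                       levels = c("neg", "pos")),
       informative = infNames)
}

#' Write a phantom cohort to disk
#'
#' Writes NIfTI volumes and masks plus `subjects.csv` and `truth.csv` in the
#' layout the pipeline readers expect (`<id>_T1.nii.gz`, `<id>_mask.nii.gz`).
#'
#' @param cohort a [PhantomCohort].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeCohort <- function(cohort, dir) {
  stopifnot(is(cohort, "PhantomCohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ids <- cohort@subjects$id
  for (i in seq_along(ids)) {
    writeVolume(cohort@volumes[[i]],
                file.path(dir, paste0(ids[i], "_T1.nii.gz")))
    writeVolume(cohort@masks[[i]],
                file.path(dir, paste0(ids[i], "_mask.nii.gz")))
  }
  utils::write.csv(cohort@subjects, file.path(dir, "subjects.csv"),
                   row.names = FALSE)
  utils::write.csv(cohort@truth, file.path(dir, "truth.csv"),
                   row.names = FALSE)
  invisible(dir)
}
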