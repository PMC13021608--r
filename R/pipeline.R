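## End-to-end orchestration: simulate -> train BAN -> bias-correct/BAI ->
## radiomic features -> fusion -> evaluate, with per-stage artifacts and a
## reproducible run manifest.

.deriveSeed <- function(seed, k) {
  as.integer((as.numeric(seed) + k * 10007) %% (.Machine$integer.max - 1) + 1)
}

#' Default pipeline configuration
#'
#' @return nested list of per-stage settings, all overridable through
#'   [runPipeline()]'s `config`.
#' @export
defaultPipelineConfig <- function() {
  list(
    phantom = list(nSubjects = 300L),
    ban = list(convChannels = c(4L, 8L), blocksPerStage = 1L,
               maxEpochs = 25L, batchSize = 16L),
    bai = list(includeMae = TRUE, correction = "bonferroni"),
    features = list(alpha = 0.05, pruneThreshold = 0.9,
                    redundancyThreshold = 0.8, lassoFolds = 10L),
    fusion = list(nDraws = 8L, folds = 5L, nrounds = 60L,
                  testFraction = 0.3, minimalClinical = FALSE),
    writeVolumes = FALSE
  )
}

#' Validate a cohort directory
#'
#' Checks that every subject's volume exists, that glioma subjects have a
#' mask with matching geometry, and that the subject table is complete
#' (age, grade, epilepsy for glioma rows). Problems are reported, not
#' raised.
#'
#' @param dir cohort directory with `subjects.csv` and
#'   `<id>_T1.nii.gz` / `<id>_mask.nii.gz` files.
#' @return data.frame of flags (id, problem); zero rows when clean.
#' @export
validateInputs <- function(dir) {
  if (!dir.exists(dir)) stop(sprintf("directory not found: %s", dir))
  subjFile <- file.path(dir, "subjects.csv")
  if (!file.exists(subjFile)) stop("subjects.csv not found")
  subj <- utils::read.csv(subjFile, stringsAsFactors = FALSE)
  flags <- list()
  flag <- function(id, problem)
    flags[[length(flags) + 1L]] <<- data.frame(id = id, problem = problem)
  for (i in seq_len(nrow(subj))) {
    id <- subj$id[i]
    vPath <- file.path(dir, paste0(id, "_T1.nii.gz"))
    mPath <- file.path(dir, paste0(id, "_mask.nii.gz"))
    if (!file.exists(vPath)) {
      flag(id, sprintf("missing volume file %s", basename(vPath)))
      next
    }
    if (is.na(subj$age[i]) || subj$age[i] <= 0)
      flag(id, "missing or non-positive age")
    isGlioma <- !is.na(subj$grade[i]) && subj$grade[i] != "none"
    if (isGlioma) {
      if (is.na(subj$grade[i]) || subj$grade[i] == "")
        flag(id, "missing grade")
      if (is.na(subj$epilepsy[i]) || !subj$epilepsy[i] %in% c("yes", "no"))
        flag(id, "missing epilepsy label")
      if (!file.exists(mPath)) {
        flag(id, sprintf("missing mask file %s", basename(mPath)))
      } else {
        v <- readVolume(vPath)
        m <- readVolume(mPath, mask = TRUE)
        ok <- tryCatch({ .checkGeometry(v, m); TRUE },
                       error = function(e) FALSE)
        if (!ok)
          flag(id, sprintf("geometry mismatch between %s and %s",
                           basename(vPath), basename(mPath)))
      }
    }
  }
  if (length(flags)) do.call(rbind, flags)
  else data.frame(id = character(), problem = character())
}

#' Run the full pipeline on a synthetic cohort
#'
#' Executes the requested stages in order (simulate, ban, bai, features,
#' fusion), writes each stage's artifacts under `outDir`, and returns a run
#' manifest (seeds, stage settings, artifact checksums). Two runs with the
#' identical config and seed produce identical manifests and metric files.
#'
#' @param config nested per-stage settings merged over
#'   [defaultPipelineConfig()].
#' @param outDir writable output directory.
#' @param seed global seed; all stage seeds derive from it.
#' @param stages character subset of
#'   `c("simulate", "ban", "bai", "features", "fusion")`; later stages
#'   resume from artifacts of earlier runs in `outDir`.
#' @param verbose log stage progress.
#' @return the manifest (list), invisibly written to `manifest.json`.
#' @export
runPipeline <- function(config = list(), outDir, seed = 1L,
                        stages = c("simulate", "ban", "bai", "features",
                                   "fusion"),
                        verbose = FALSE) {
  cfg <- modifyList(defaultPipelineConfig(), config)
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(seed = seed, stages = list(),
                   package_version = as.character(utils::packageVersion("lesionBAI")))
  say <- function(...) if (verbose) message(sprintf(...))
  runStage <- function(name, fun) {
    say("stage %s ...", name)
    t0 <- Sys.time()
    res <- tryCatch(fun(), error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
    manifest$stages[[name]] <<- c(res, list(
      elapsed_s = round(as.numeric(difftime(Sys.time(), t0, units = "secs")), 2)))
    invisible(res)
  }

  env <- new.env()

  if ("simulate" %in% stages) runStage("simulate", function() {
    pcfg <- do.call(PhantomConfig,
                    c(cfg$phantom, list(seed = .deriveSeed(seed, 1))))
    env$cohort <- generateCohort(pcfg)
    utils::write.csv(env$cohort@subjects, file.path(outDir, "subjects.csv"),
                     row.names = FALSE)
    utils::write.csv(env$cohort@truth, file.path(outDir, "truth.csv"),
                     row.names = FALSE)
    if (isTRUE(cfg$writeVolumes)) writeCohort(env$cohort, outDir)
    list(n_subjects = pcfg@nSubjects, seed = pcfg@seed)
  })

  # stages resume from earlier runs: the cohort is regenerated
  # deterministically from config + derived seed, and stage outputs are
  # re-read from outDir when not in memory
  getCohort <- function() {
    if (is.null(env$cohort)) {
      pcfg <- do.call(PhantomConfig,
                      c(cfg$phantom, list(seed = .deriveSeed(seed, 1))))
      env$cohort <- generateCohort(pcfg)
    }
    env$cohort
  }
  # downstream stages always read predictions back from the CSV artifact so
  # that fresh runs and resumed runs see bit-identical (round-tripped) values
  getPredictions <- function() {
    f <- file.path(outDir, "predictions.csv")
    if (file.exists(f)) return(utils::read.csv(f, stringsAsFactors = FALSE))
    stop("no BAN predictions available; run the 'ban' stage first")
  }

  if ("ban" %in% stages) runStage("ban", function() {
    cohort <- getCohort()
    subj <- cohort@subjects
    isControl <- subj$grade == "none"
    missingMask <- which(!isControl &
                           vapply(cohort@masks, function(m) sum(m@data) == 0,
                                  logical(1)))
    if (length(missingMask))
      stop(sprintf("glioma subject(s) without lesion mask: %s",
                   paste(subj$id[missingMask], collapse = ", ")))
    ctrlIdx <- which(isControl)
    sp <- splitDataset(subj[ctrlIdx, ], stratifyOn = subj$sex[ctrlIdx],
                       seed = .deriveSeed(seed, 2))
    splits <- lapply(sp, function(i) ctrlIdx[i])
    bcfg <- do.call(BanConfig, c(cfg$ban, list(seed = .deriveSeed(seed, 3))))
    env$ban <- trainBan(cohort@volumes, cohort@masks, subj$age, splits,
                        bcfg, verbose = verbose)
    env$splits <- splits
    pred <- predictAges(env$ban, cohort@volumes, cohort@masks)
    env$pred <- data.frame(id = subj$id, age = subj$age, predicted = pred,
                           split = "none", stringsAsFactors = FALSE)
    env$pred$split[splits$train] <- "train"
    env$pred$split[splits$val] <- "val"
    env$pred$split[splits$test] <- "test"
    utils::write.csv(env$pred, file.path(outDir, "predictions.csv"),
                     row.names = FALSE)
    hist <- env$ban@history
    utils::write.csv(hist, file.path(outDir, "ban_history.csv"),
                     row.names = FALSE)
    list(epochs = nrow(hist), best_val_mae = min(hist$val_mae, na.rm = TRUE),
         n_train = length(splits$train))
  })

  if ("bai" %in% stages) runStage("bai", function() {
    cohort <- getCohort()
    subj <- cohort@subjects
    pred <- getPredictions()
    fitRows <- pred[pred$split == "train", ]
    bc <- fitBiasCorrection(fitRows$predicted, fitRows$age, "healthy_train")
    env$correction <- bc
    env$bai <- agePredictionTable(pred$id, pred$predicted,
                                  pred$age, bc,
                                  includeMae = isTRUE(cfg$bai$includeMae))
    group <- ifelse(subj$grade == "none", "control",
                    ifelse(subj$epilepsy == "yes", "epileptic",
                           "non_epileptic"))
    env$bai$group <- group
    utils::write.csv(env$bai, file.path(outDir, "bai.csv"),
                     row.names = FALSE)
    rep <- compareGroups(env$bai$bai, group, cfg$bai$correction)
    jsonlite::write_json(rep, file.path(outDir, "bai_stats.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
    list(alpha = bc@alpha, beta = bc@beta, mae_term = bc@maeTerm,
         mean_bai = setNames(as.list(rep$descriptives$mean),
                             rep$descriptives$group))
  })

  if ("features" %in% stages) runStage("features", function() {
    cohort <- getCohort()
    feats <- extractFeatureTable(cohort)
    env$features <- feats
    glioma <- cohort@subjects[cohort@subjects$grade != "none", ]
    labels <- glioma$epilepsy[match(rownames(feats), glioma$id)] == "yes"
    env$gliomaLabels <- labels
    fs <- cfg$features
    retained <- mwuFilter(feats, labels, fs$alpha)
    pruned <- correlationPrune(feats[retained], fs$pruneThreshold,
                               pvalues = attr(retained, "p"))
    reduced <- reduceRedundancy(feats, pruned, fs$redundancyThreshold)
    sig <- lassoSelect(feats[reduced], labels, folds = fs$lassoFolds,
                       seed = .deriveSeed(seed, 4))
    env$signature <- sig
    env$radScore <- radiomicScore(feats, sig)
    utils::write.csv(cbind(id = rownames(feats), feats,
                           rad_score = env$radScore),
                     file.path(outDir, "features.csv"), row.names = FALSE)
    jsonlite::write_json(
      list(features = sig@features, coefficients = sig@coefficients,
           intercept = sig@intercept, lambda = sig@lambda,
           center = sig@center, scale = sig@scale),
      file.path(outDir, "signature.json"), auto_unbox = TRUE, digits = NA)
    list(n_extracted = ncol(feats), n_filtered = length(retained),
         n_pruned = length(pruned), n_reduced = length(reduced),
         n_signature = length(sig@features))
  })

  if ("fusion" %in% stages) runStage("fusion", function() {
    cohort <- getCohort()
    subj <- cohort@subjects
    glioma <- subj[subj$grade != "none", ]
    if (is.null(env$bai)) {
      f <- file.path(outDir, "bai.csv")
      if (!file.exists(f)) stop("run the 'bai' stage first")
      env$bai <- utils::read.csv(f, stringsAsFactors = FALSE)
    }
    if (is.null(env$features)) env$features <- extractFeatureTable(cohort)
    if (is.null(env$signature)) {
      f <- file.path(outDir, "signature.json")
      if (!file.exists(f)) stop("run the 'features' stage first")
      sj <- jsonlite::read_json(f, simplifyVector = TRUE)
      env$signature <- new("RadiomicSignature",
                           features = as.character(sj$features),
                           coefficients = as.numeric(sj$coefficients),
                           intercept = sj$intercept, lambda = sj$lambda,
                           center = unlist(sj$center),
                           scale = unlist(sj$scale))
    }
    feats <- env$features
    stopifnot(identical(rownames(feats), glioma$id))
    y <- glioma$epilepsy == "yes"
    baiG <- env$bai$bai[match(glioma$id, env$bai$id)]
    clin <- data.frame(age = glioma$age,
                       grade = as.integer(glioma$grade == "high"),
                       bai = baiG)
    if (!isTRUE(cfg$fusion$minimalClinical))
      clin$sex <- as.integer(glioma$sex == "M")
    Xrad <- feats[, env$signature@features, drop = FALSE]
    if (ncol(Xrad) == 0L) Xrad <- feats

    fu <- cfg$fusion
    sp <- splitDataset(glioma, fractions = c(1 - fu$testFraction, 0,
                                             fu$testFraction),
                       stratifyOn = ifelse(y, "pos", "neg"),
                       seed = .deriveSeed(seed, 5))
    tr <- sp$train; te <- sp$test
    model <- trainFusionModel(Xrad[tr, , drop = FALSE],
                              clin[tr, , drop = FALSE], y[tr],
                              nDraws = fu$nDraws, folds = fu$folds,
                              seed = .deriveSeed(seed, 6),
                              nrounds = fu$nrounds)
    env$fusion <- model
    predTr <- predictFusion(model, Xrad[tr, , drop = FALSE],
                            clin[tr, , drop = FALSE])
    predTe <- predictFusion(model, Xrad[te, , drop = FALSE],
                            clin[te, , drop = FALSE])
    evTr <- evaluateClassifier(predTr$fused, y[tr],
                               threshold = model@threshold,
                               seed = .deriveSeed(seed, 7))
    evTe <- evaluateClassifier(predTe$fused, y[te],
                               threshold = model@threshold,
                               seed = .deriveSeed(seed, 8))
    metrics <- list(train = evTr, test = evTe,
                    component_cv_auc = list(
                      radiomic = model@radiomicModel$cv_auc,
                      clinical = model@clinicalModel$cv_auc))
    jsonlite::write_json(metrics, file.path(outDir, "fusion_metrics.json"),
                         auto_unbox = TRUE, digits = NA)
    env$fusionMetrics <- metrics
    list(train_auc = evTr$auc, test_auc = evTe$auc,
         test_sensitivity = evTe$sensitivity,
         test_specificity = evTe$specificity,
         n_train = length(tr), n_test = length(te))
  })

  files <- list.files(outDir, pattern = "\\.(csv|json)$", full.names = TRUE)
  manifest$artifacts <- lapply(setNames(files, basename(files)),
                               function(f) unname(tools::md5sum(f)))
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  manifest$state <- env
  invisible(manifest)
}
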