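test_that("stratified splitting hits the 70/10/20 targets with largest-remainder rounding", {
  subj <- data.frame(id = seq_len(1000),
                     sex = rep(c("F", "M"), 500))
  sp <- splitDataset(subj, stratifyOn = "sex", seed = 3)
  expect_equal(lengths(sp), c(train = 700L, val = 100L, test = 200L))

  sp10 <- splitDataset(data.frame(id = 1:10), seed = 1)
  expect_equal(lengths(sp10), c(train = 7L, val = 1L, test = 2L))

  # partition: exhaustive and pairwise disjoint
  all10 <- c(sp10$train, sp10$val, sp10$test)
  expect_setequal(all10, 1:10)
  expect_equal(length(all10), 10)

  # determinism
  expect_identical(sp, splitDataset(subj, stratifyOn = "sex", seed = 3))

  # tiny strata collapse with a warning
  s2 <- data.frame(id = 1:20, g = c(rep("a", 18), "b", "b"))
  expect_warning(splitDataset(s2, stratifyOn = "g", seed = 1), "collapsed")
})

test_that("inverse-frequency bin weights balance occupied bins", {
  ages <- c(rep(25, 10), rep(45, 40))
  w <- computeBinWeights(ages, binEdges = c(20, 40, 60))
  expect_equal(unique(w[1:10]), 2.5)
  expect_equal(unique(w[11:50]), 0.625)
  expect_equal(mean(w), 1)
  # equal total weight per occupied bin (exact)
  expect_equal(sum(w[1:10]), sum(w[11:50]))

  wu <- computeBinWeights(c(25, 45, 65), binEdges = c(20, 40, 60, 80))
  expect_true(all(wu == 1))
  expect_error(computeBinWeights(c(5, 25), binEdges = c(20, 40)), "bin edges")
})

test_that("lesion exclusion zeroes exactly the masked region", {
  ph <- gliomaPhantom()
  v <- normalizeIntensity(ph$volume, ph$mask)
  empty <- LesionMask(array(0, dim(volumeData(v))))
  expect_identical(volumeData(applyLesionExclusion(v, empty)),
                   volumeData(v))

  # two volumes differing only inside the mask -> identical outputs
  v2 <- volumeData(v)
  v2[volumeData(ph$mask) == 1] <- 99
  out1 <- applyLesionExclusion(v, ph$mask)
  out2 <- applyLesionExclusion(BrainVolume(v2, voxelSpacing(v)), ph$mask)
  expect_identical(volumeData(out1), volumeData(out2))
})

test_that("ROI-Align pools constants, identity subgrids and ramps exactly", {
  fm <- array(5, c(8, 8, 8))
  p <- roiAlignPool(fm, c(0.2, 1.1, 0.4, 6.3, 7.0, 5.2), c(3, 3, 3))
  expect_true(all(abs(p - 5) < 1e-12))

  # box spanning an integer subgrid, matching grid, 1 sample per cell
  fm2 <- array(seq_len(6^3), c(6, 6, 6))
  sub <- fm2[2:5, 3:6, 1:4]
  p2 <- roiAlignPool(fm2, c(0.5, 1.5, -0.5, 4.5, 5.5, 3.5), c(4, 4, 4),
                     samplesPerCell = 1)
  expect_equal(p2, sub, tolerance = 1e-12, ignore_attr = TRUE)

  # linear ramp pools to the ramp at the cell-center coordinates
  ramp <- array(rep(0:7, times = 64), c(8, 8, 8))
  box <- c(0.5, 0.5, 0.5, 6.5, 6.5, 6.5)
  g <- c(4L, 3L, 2L)
  p3 <- roiAlignPool(ramp, box, g, samplesPerCell = 2)
  w <- 6 / g[1]
  centers <- 0.5 + w * (seq_len(g[1]) - 0.5)
  for (j in 1:3) for (k in 1:2)
    expect_equal(p3[, j, k], centers, tolerance = 1e-5)

  expect_error(roiAlignPool(fm, c(1, 1, 1, 1, 2, 2), c(2, 2, 2)),
               "degenerate")
  expect_error(roiAlignPool(fm, c(20, 20, 20, 30, 30, 30), c(2, 2, 2)),
               "intersect")
})

test_that("network construction is reproducible and guards its input size", {
  cfg <- BanConfig(convChannels = c(2L, 4L), seed = 5)
  m1 <- buildBan(cfg, c(16L, 16L, 16L))
  m2 <- buildBan(cfg, c(16L, 16L, 16L))
  expect_identical(numParameters(m1), numParameters(m2))
  expect_identical(m1@params, m2@params)
  expect_error(buildBan(cfg, c(2L, 2L, 2L)), "minimum admissible shape")
})

test_that("forward pass returns a finite scalar and residual units reduce to shortcuts", {
  cfg <- BanConfig(convChannels = c(2L, 4L), seed = 5)
  m <- buildBan(cfg, c(16L, 16L, 16L))
  set.seed(1)
  x <- array(rnorm(16^3), c(16, 16, 16))
  roi <- c(-0.5, -0.5, -0.5, 15.5, 15.5, 15.5)
  fw <- lesionBAI:::.banForward(m@params, cfg, c(16L, 16L, 16L), x, roi)
  expect_length(fw$pred, 1)
  expect_true(is.finite(fw$pred))

  # zeroing every residual branch leaves only the shortcut path: the
  # prediction must be unchanged when branch outputs are forced to zero
  # twice in a row (idempotence of the zeroed branch), and differ from the
  # untouched network
  z <- m@params
  for (s in seq_along(z$stages))
    for (u in seq_along(z$stages[[s]]$units)) {
      z$stages[[s]]$units[[u]]$conv2$W[] <- 0
      z$stages[[s]]$units[[u]]$conv2$b[] <- 0
    }
  # with the branch zeroed, adding another zeroed unit changes nothing:
  # the unit output equals its input (shortcut)
  zfw <- lesionBAI:::.banForward(z, cfg, c(16L, 16L, 16L), x, roi,
                                 withCache = TRUE)
  cA <- zfw$caches$stages[[1]]$units[[1]]
  stageIn <- pmax(zfw$caches$stages[[1]]$down$conv$y, 0)
  unitOut <- pmax(cA$c2$y + stageIn, 0)
  expect_equal(unitOut, stageIn, tolerance = 1e-12)
})

test_that("the optimization protocol halves the rate on plateaus and stops early", {
  coh <- smallCohort()
  subj <- subjectTable(coh)
  cfg <- BanConfig(convChannels = c(2L), learningRate = 1e-12,
                   plateauPatience = 2L, earlyStopPatience = 6L,
                   maxEpochs = 50L, seed = 9)
  sp <- list(train = 1:10, val = 11:16)
  fit <- trainBan(cohortVolumes(coh), cohortMasks(coh), subj$age, sp, cfg)
  h <- trainingHistory(fit)
  # effectively frozen training: validation MAE never improves after the
  # first epoch, so training stops at exactly the patience bound
  expect_equal(nrow(h), 1L + 6L)
  # two consecutive plateau triggers: lr drops to lr0 * 0.5^2
  expect_equal(h$lr[6], 1e-12 * 0.25, tolerance = 1e-20)
})

test_that("a trained network predicts deterministically and ignores lesion interiors", {
  fx <- tinyTrainedBan()
  ph <- gliomaPhantom()
  p1 <- predictAge(fx$model, ph$volume, ph$mask)
  expect_true(is.finite(p1))
  expect_identical(p1, predictAge(fx$model, ph$volume, ph$mask))

  # arbitrary intensity rewrites strictly inside the mask: bit-identical
  set.seed(77)
  inside <- volumeData(ph$mask) == 1
  for (rep in 1:5) {
    v2 <- volumeData(ph$volume)
    v2[inside] <- runif(sum(inside), -100, 100)
    expect_identical(predictAge(fx$model,
                                BrainVolume(v2, voxelSpacing(ph$volume)),
                                ph$mask), p1)
  }

  # geometry mismatch is rejected
  small <- BrainVolume(array(1, c(16, 16, 16)))
  expect_error(predictAge(fx$model, small), "geometry mismatch")
})

test_that("a mask covering all foreground voxels yields an empty-ROI error", {
  ph <- gliomaPhantom()
  full <- LesionMask((volumeData(ph$volume) != 0) * 1,
                     voxelSpacing(ph$volume))
  fx <- tinyTrainedBan()
  expect_error(predictAge(fx$model, ph$volume, full), "empty ROI")
})

test_that("MAE evaluation matches direct recomputation", {
  expect_equal(evaluateMae(c(1, 2, 3), c(1, 2, 3)), list(mae = 0, sd = 0))
  expect_equal(evaluateMae(c(2, 0), c(1, 3))$mae, 2.0)
  set.seed(4)
  p <- rnorm(1000); y <- rnorm(1000)
  res <- evaluateMae(p, y)
  expect_equal(res$mae, mean(abs(p - y)), tolerance = 1e-12)
  expect_equal(res$sd, sd(abs(p - y)), tolerance = 1e-12)
  expect_error(evaluateMae(numeric(), numeric()), "non-empty")
})

test_that("cross-validation of the network produces one held-out MAE per fold", {
  coh <- smallCohort()
  subj <- subjectTable(coh)
  cfg <- BanConfig(convChannels = c(2L), maxEpochs = 1L, seed = 21)
  cv <- crossValidateBan(cohortVolumes(coh), cohortMasks(coh), subj$age,
                         cfg, folds = 4L)
  expect_equal(nrow(cv), 4)
  expect_equal(sum(cv$n_val), nrow(subj))
  expect_true(all(is.finite(cv$val_mae)))
})
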