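test_that("random search samples reproducibly and returns the argmax trial", {
  set.seed(61)
  n <- 60
  X <- data.frame(x1 = rnorm(n), x2 = rnorm(n))
  y <- as.integer(X$x1 + 0.5 * X$x2 + rnorm(n, 0, 0.3) > 0)
  r1 <- randomSearch(X, y, nDraws = 5, seed = 4, nrounds = 20)
  r2 <- randomSearch(X, y, nDraws = 5, seed = 4, nrounds = 20)
  expect_equal(r1$trials, r2$trials)
  expect_equal(nrow(unique(r1$trials[seq_len(7)])), 5)  # distinct configs
  expect_equal(r1$bestAuc, max(r1$trials$mean_auc))
  expect_equal(unlist(r1$best),
               unlist(r1$trials[which.max(r1$trials$mean_auc),
                                seq_len(7)]))
})

test_that("linearly separable data reaches near-perfect cross-validated AUC", {
  set.seed(62)
  n <- 100
  y <- rep(c(0L, 1L), each = n / 2)
  X <- data.frame(sep = y * 4 + rnorm(n, 0, 0.2), junk = rnorm(n))
  r <- randomSearch(X, y, nDraws = 4, seed = 2, nrounds = 30)
  expect_gt(r$bestAuc, 0.95)
})

test_that("out-of-fold probabilities cover every subject exactly once", {
  set.seed(63)
  n <- 55
  X <- data.frame(a = rnorm(n), b = rnorm(n))
  y <- rbinom(n, 1, 0.4)
  cfg <- list(learning_rate = 0.1, num_leaves = 31, max_depth = 5,
              min_data_in_leaf = 20, l1 = 0, l2 = 0, feature_fraction = 1)
  r <- oofProbabilities(X, y, cfg, folds = 5, seed = 8, nrounds = 20)
  expect_length(r$oof, n)
  expect_false(anyNA(r$oof))
  expect_setequal(unique(r$foldMap), 1:5)
  # stratification: each fold holds both classes
  expect_true(all(tapply(y, r$foldMap, function(v) length(unique(v))) == 2))
  # determinism
  r2 <- oofProbabilities(X, y, cfg, folds = 5, seed = 8, nrounds = 20)
  expect_identical(r$oof, r2$oof)
})

test_that("label-independent features give chance-level out-of-fold AUC", {
  set.seed(64)
  n <- 300
  X <- as.data.frame(matrix(rnorm(n * 5), n))
  y <- rbinom(n, 1, 0.5)
  cfg <- list(learning_rate = 0.1, num_leaves = 31, max_depth = 5,
              min_data_in_leaf = 20, l1 = 0, l2 = 0, feature_fraction = 1)
  r <- oofProbabilities(X, y, cfg, folds = 5, seed = 3, nrounds = 40)
  expect_lt(abs(aucRank(r$oof, y) - 0.5), 0.1)
})

test_that("a perfect probability stream dominates the fusion", {
  set.seed(65)
  n <- 40
  y <- rep(c(0, 1), n / 2)
  oofClin <- y                              # probabilities 0/1, identical to y
  oofRad <- runif(n)
  fm <- fitFusion(oofRad, oofClin, y, foldMap = rep(1:5, 8))
  fused <- plogis(fm@stackCoefs[1] + fm@stackCoefs[2] * oofRad +
                    fm@stackCoefs[3] * oofClin)
  expect_equal(aucRank(fused, y), 1.0)
  expect_equal(aucRank(oofClin, y), 1.0)

  # constant streams: fusion predicts the base rate, with a warning
  expect_warning(fm0 <- fitFusion(rep(0.5, n), rep(0.5, n), y), "constant")
  p0 <- plogis(fm0@stackCoefs[1] + fm0@stackCoefs[2] * 0.5 +
                 fm0@stackCoefs[3] * 0.5)
  expect_equal(p0, mean(y), tolerance = 1e-6)

  expect_error(fitFusion(c(0.5, 1.2), c(0.1, 0.2), c(0, 1)), "\\[0, 1\\]")
})

test_that("stacking records only out-of-fold probabilities with a shared fold map", {
  set.seed(66)
  n <- 60
  y <- rep(c(0L, 1L), each = n / 2)
  Xr <- data.frame(f = y + rnorm(n)); Xc <- data.frame(g = y + rnorm(n))
  cfg <- list(learning_rate = 0.1, num_leaves = 31, max_depth = 5,
              min_data_in_leaf = 20, l1 = 0, l2 = 0, feature_fraction = 1)
  a <- oofProbabilities(Xr, y, cfg, seed = 5, nrounds = 20)
  b <- oofProbabilities(Xc, y, cfg, foldMap = a$foldMap, nrounds = 20)
  fm <- fitFusion(a$oof, b$oof, y, foldMap = a$foldMap)
  expect_identical(fm@foldMap, a$foldMap)
  expect_identical(fm@oofRecord$oof_radiomic, a$oof)
  expect_identical(fm@oofRecord$oof_clinical, b$oof)
  expect_identical(fm@oofRecord$fold, a$foldMap)
})

test_that("classifier evaluation matches rank arithmetic and pair counting", {
  y <- c(0, 0, 0, 1, 1)
  expect_equal(evaluateClassifier(c(0.1, 0.2, 0.3, 0.8, 0.9), y,
                                  nBoot = 10)$auc, 1.0)
  expect_equal(evaluateClassifier(c(0.9, 0.8, 0.7, 0.2, 0.1), y,
                                  nBoot = 10)$auc, 0.0)

  # AUC equals brute-force U / (n1 n0), ties counted half
  set.seed(67)
  prob <- round(runif(200), 2)              # induces ties
  lab <- rbinom(200, 1, 0.5)
  pos <- prob[lab == 1]; neg <- prob[lab == 0]
  U <- sum(vapply(pos, function(p) sum(p > neg) + 0.5 * sum(p == neg),
                  numeric(1)))
  expect_equal(aucRank(prob, lab), U / (sum(lab == 1) * sum(lab == 0)),
               tolerance = 1e-12)

  ev <- evaluateClassifier(prob, lab, nBoot = 200, seed = 2)
  expect_true(ev$auc_ci[1] <= ev$auc && ev$auc <= ev$auc_ci[2])
  expect_true(all(c(ev$accuracy, ev$sensitivity, ev$specificity) >= 0))
  expect_error(evaluateClassifier(runif(5), rep(1, 5)), "both classes")

  # frozen threshold semantics
  ev2 <- evaluateClassifier(c(0.1, 0.4, 0.6, 0.9), c(0, 0, 1, 1),
                            threshold = 0.5, nBoot = 10)
  expect_equal(ev2$sensitivity, 1)
  expect_equal(ev2$specificity, 1)
  expect_equal(ev2$threshold, 0.5)
})
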