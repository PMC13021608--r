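test_that("radiomic features honor degenerate textures, geometry and shifts", {
  # constant-intensity lesion
  vol <- array(0, c(12, 12, 12)); msk <- array(0, c(12, 12, 12))
  vol[4:8, 4:8, 4:8] <- 2.5; msk[4:8, 4:8, 4:8] <- 1
  f <- extractRadiomicFeatures(BrainVolume(vol), LesionMask(msk))
  expect_length(f, 19)
  expect_equal(unname(f["fo_sd"]), 0)
  expect_equal(unname(f["fo_entropy"]), 0)
  expect_equal(unname(f["glcm_energy"]), 1)
  expect_equal(unname(f["glcm_contrast"]), 0)

  # single voxel at 2 mm spacing -> 8 mm^3
  v1 <- array(1, c(8, 8, 8)); m1 <- array(0, c(8, 8, 8)); m1[4, 4, 4] <- 1
  f1 <- extractRadiomicFeatures(BrainVolume(v1, c(2, 2, 2)), LesionMask(m1))
  expect_equal(unname(f1["shape_volume_mm3"]), 8)

  # intensity shift: location features move by +c, dispersion/texture fixed
  set.seed(3)
  vol2 <- array(rnorm(12^3), c(12, 12, 12))
  fA <- extractRadiomicFeatures(BrainVolume(vol2), LesionMask(msk))
  fB <- extractRadiomicFeatures(BrainVolume(vol2 + 4.2), LesionMask(msk))
  for (nm in c("fo_mean", "fo_median", "fo_p10", "fo_p90", "fo_min", "fo_max"))
    expect_equal(unname(fB[nm] - fA[nm]), 4.2, tolerance = 1e-9)
  for (nm in c("fo_sd", "fo_entropy", "fo_range", "glcm_contrast",
               "glcm_correlation", "glcm_energy", "glcm_homogeneity",
               "shape_volume_mm3", "shape_surface_voxels"))
    expect_equal(unname(fB[nm]), unname(fA[nm]), tolerance = 1e-9)

  expect_error(extractRadiomicFeatures(BrainVolume(v1),
                                       LesionMask(array(0, c(8, 8, 8)))),
               "empty mask")
})

test_that("the Mann-Whitney filter keeps planted effects and respects alpha", {
  set.seed(21)
  lab <- rep(c(0, 1), each = 50)
  tab <- data.frame(planted = rnorm(100) + 2 * lab,   # 2-SD shift
                    flat = rnorm(100))
  kept <- mwuFilter(tab, lab)
  expect_true("planted" %in% kept)
  expect_length(mwuFilter(tab, lab, alpha = 0), 0)
  expect_error(mwuFilter(tab, rep(0, 100)), "two classes")
})

test_that("correlation pruning keeps one representative per correlated cluster", {
  set.seed(31)
  f1 <- rnorm(80)
  tab <- data.frame(f1 = f1, f2 = f1, f3 = rnorm(80))
  expect_setequal(correlationPrune(tab), c("f1", "f3"))

  # a pair at exactly the threshold keeps both (strict inequality)
  n <- 10
  a <- 1:n
  b <- c(2, 1, 3:(n - 2), n, n - 1)       # engineered rank displacement
  rho <- cor(rank(a), rank(b))
  tab2 <- data.frame(a = a, b = b)
  expect_setequal(correlationPrune(tab2, threshold = rho), c("a", "b"))
  expect_equal(correlationPrune(tab2, threshold = rho - 1e-9), "a")

  # a clique of 4 near-duplicates collapses to one
  base <- rnorm(120)
  tab3 <- data.frame(w = base, x = base + rnorm(120, 0, 0.01),
                     y = base + rnorm(120, 0, 0.01),
                     z = base + rnorm(120, 0, 0.01),
                     ind = rnorm(120))
  kept3 <- correlationPrune(tab3)
  expect_length(kept3, 2)
  expect_true("ind" %in% kept3)

  expect_warning(correlationPrune(data.frame(c1 = rep(1, 9), ok = rnorm(9))),
                 "constant")
})

test_that("redundancy reduction follows the greedy mean-correlation rule", {
  # construct a chain f1~f2, f2~f3 with f1 and f3 nearly independent (with
  # orthogonal ends the shared middle cannot exceed |rho| = 1/sqrt(2), so
  # the rule is exercised at a threshold below that bound)
  set.seed(41)
  n <- 400
  u <- rnorm(n); v <- rnorm(n)
  tab <- data.frame(f1 = u + rnorm(n, 0, 0.2),
                    f3 = v + rnorm(n, 0, 0.2))
  tab$f2 <- (u + v) / sqrt(2)
  r12 <- abs(spearmanRho(tab$f1, tab$f2))
  r23 <- abs(spearmanRho(tab$f2, tab$f3))
  r13 <- abs(spearmanRho(tab$f1, tab$f3))
  expect_gt(r12, 0.6); expect_gt(r23, 0.6); expect_lt(r13, 0.3)
  kept <- reduceRedundancy(tab, names(tab), threshold = 0.6)
  expect_setequal(kept, c("f1", "f3"))          # f2 has the highest mean |rho|

  # fixed point and idempotence
  indep <- as.data.frame(matrix(rnorm(300), 100))
  names(indep) <- c("a", "b", "c")
  expect_identical(reduceRedundancy(indep, names(indep)), names(indep))
  expect_identical(reduceRedundancy(tab, kept), kept)
})

test_that("LASSO selection shrinks fully at large lambda and is deterministic", {
  ft <- generateFeatureTable(120, 3, 20, 0, effectSize = 1.2, seed = 13)
  sigEmpty <- lassoSelect(ft$features, ft$labels, lambda = 1e3)
  expect_length(signatureFeatures(sigEmpty), 0)

  s1 <- lassoSelect(ft$features, ft$labels, seed = 5)
  s2 <- lassoSelect(ft$features, ft$labels, seed = 5)
  expect_identical(signatureFeatures(s1), signatureFeatures(s2))
  expect_identical(s1@coefficients, s2@coefficients)
  expect_true(all(s1@coefficients != 0))
  expect_gt(s1@lambda, 0)
  expect_error(lassoSelect(ft$features, rep(1, 120)), "two classes")
})

test_that("the radiomic score is the standardized linear combination", {
  sig <- new("RadiomicSignature", features = c("a", "b"),
             coefficients = c(0.5, -0.2), intercept = 0,
             lambda = 0.1, center = c(a = 0, b = 0), scale = c(a = 1, b = 1))
  expect_equal(radiomicScore(c(a = 2, b = 5), sig), 0.0)
  expect_error(radiomicScore(c(a = 2), sig), "missing signature feature")

  sig0 <- new("RadiomicSignature", features = character(),
              coefficients = numeric(), intercept = 1.5, lambda = 0.1,
              center = numeric(), scale = numeric())
  expect_equal(radiomicScore(c(a = 2), sig0), 1.5)

  # score ordering is invariant to consistent positive rescaling because the
  # standardization absorbs the scale
  set.seed(9)
  tab <- data.frame(a = rnorm(30), b = rnorm(30))
  y <- rep(c(0, 1), 15)
  s <- lassoSelect(tab, y, lambda = 0.01)
  sc1 <- radiomicScore(tab, s)
  tab2 <- data.frame(a = 10 * tab$a, b = 10 * tab$b)
  s2 <- lassoSelect(tab2, y, lambda = 0.01)
  sc2 <- radiomicScore(tab2, s2)
  expect_equal(order(sc1), order(sc2))
})

test_that("clinical variable selection tests each candidate appropriately", {
  set.seed(51)
  y <- rep(c(0, 1), each = 40)
  tab <- data.frame(
    bai = 0.05 + 0.08 * y + rnorm(80, 0, 0.03),   # planted group shift
    age = rnorm(80, 55, 10),                      # independent
    grade = rep(c("low", "high"), 40),            # perfectly balanced
    stringsAsFactors = FALSE)
  res <- selectClinical(tab, y)
  expect_true("bai" %in% res$retained)
  expect_false("grade" %in% res$retained)
  expect_equal(nrow(res$report), 3)
  resAll <- selectClinical(tab, y, alpha = 1)
  expect_setequal(as.character(resAll$retained), names(tab))
})

test_that("the selection chain is row-order stable and decorrelated", {
  ft <- generateFeatureTable(150, 3, 30, 2, effectSize = 1.0, seed = 17)
  chain <- function(tab, labels) {
    kept <- mwuFilter(tab, labels)
    pruned <- correlationPrune(tab[kept], pvalues = attr(kept, "p"))
    reduceRedundancy(tab, pruned)
  }
  r1 <- chain(ft$features, ft$labels)
  perm <- sample(seq_len(150))
  r2 <- chain(ft$features[perm, ], ft$labels[perm])
  expect_setequal(r1, r2)

  # post-condition: no retained pair above the pruning threshold
  if (length(r1) > 1) {
    rho <- cor(vapply(ft$features[r1], rank, numeric(150)))
    diag(rho) <- 0
    expect_lte(max(abs(rho)), 0.9)
  }
})
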