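test_that("bias-correction fitting recovers exact and noisy linear relations", {
  omega <- seq(30, 80, length.out = 50)

  bc0 <- fitBiasCorrection(omega, omega)
  expect_equal(bc0@alpha, 1, tolerance = 1e-12)
  expect_equal(bc0@beta, 0, tolerance = 1e-10)
  expect_equal(bc0@maeTerm, 0, tolerance = 1e-12)

  bc1 <- fitBiasCorrection(0.5 * omega + 10, omega)
  expect_equal(bc1@alpha, 0.5, tolerance = 1e-12)
  expect_equal(bc1@beta, 10, tolerance = 1e-10)

  # noisy slope estimate lands within 3 standard errors of truth
  set.seed(10)
  om <- runif(500, 20, 85)
  pred <- 0.7 * om + 12 + rnorm(500, 0, 2)
  bc2 <- fitBiasCorrection(pred, om)
  se <- 2 / sqrt(sum((om - mean(om))^2))
  expect_lt(abs(bc2@alpha - 0.7), 3 * se)

  expect_error(fitBiasCorrection(c(1, 2, 3), c(5, 5, 5)), "zero variance")
  expect_error(fitBiasCorrection(1, 1), "at least 3")
})

test_that("the corrected-age formula evaluates exactly as printed", {
  mk <- function(a, b, mae) new("BiasCorrection", alpha = a, beta = b,
                                maeTerm = mae, fitCohortId = "t")
  expect_equal(correctedAge(60, 50, mk(1, 0, 0)), 60)
  expect_equal(correctedAge(55, 50, mk(0.8, 10, 3)), 58)

  # after fitting on a noiseless linear cohort, corrected - omega is the
  # constant MAE term for every subject (age dependence removed exactly)
  omega <- seq(25, 85, by = 5)
  pred <- 0.6 * omega + 18
  bc <- fitBiasCorrection(pred, omega)
  corr <- correctedAge(pred, omega, bc)
  gaps <- corr - omega
  expect_equal(max(gaps) - min(gaps), 0, tolerance = 1e-9)
  expect_equal(unique(round(gaps, 9)), round(bc@maeTerm, 9))
  # and the slope of (corrected - omega) on omega is zero
  expect_equal(unname(coef(lm(gaps ~ omega))[2]), 0, tolerance = 1e-10)

  expect_error(correctedAge(60, -1, mk(1, 0, 0)), "positive")
})

test_that("the Brain Age Index matches its closed forms and invariances", {
  expect_equal(brainAgeIndex(110, 90), 0.1)
  expect_equal(brainAgeIndex(50, 50), 0)
  expect_equal(brainAgeIndex(30, 90), -0.5)
  expect_error(brainAgeIndex(-50, 30), "degenerate")

  # strict boundedness on a positive grid
  grid <- expand.grid(c = seq(0.5, 150, length.out = 80),
                      o = seq(0.5, 150, length.out = 80))
  bai <- brainAgeIndex(grid$c, grid$o)
  expect_lt(max(abs(bai)), 1)

  # monotone increasing in corrected age, decreasing in omega
  cseq <- seq(10, 100, by = 1)
  expect_true(all(diff(brainAgeIndex(cseq, 50)) > 0))
  expect_true(all(diff(brainAgeIndex(60, cseq)) < 0))

  # scale covariance: common rescaling leaves BAI unchanged
  expect_equal(brainAgeIndex(3 * 72, 3 * 55), brainAgeIndex(72, 55),
               tolerance = 1e-15)
})

test_that("Mann-Whitney U handles exact, tied and approximate regimes", {
  r <- mannWhitneyU(c(1, 2), c(3, 4))
  expect_equal(r$U, 0)
  expect_equal(r$p, 2 / 6, tolerance = 1e-12)
  expect_equal(r$method, "exact")

  # identical multisets: U = n^2 / 2 under the tie convention
  r2 <- mannWhitneyU(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r2$U, 9 / 2)

  # exact and normal-approximation p agree within 0.02 at n = 6 + 6
  set.seed(5)
  for (i in 1:50) {
    x <- rnorm(6); y <- rnorm(6)
    ex <- mannWhitneyU(x, y)$p
    U <- sum(rank(c(x, y))[1:6]) - 21
    z <- (U - 18 - sign(U - 18) * 0.5) / sqrt(36 / 12 * 13)
    expect_lt(abs(ex - 2 * pnorm(-abs(z))), 0.02)
  }

  expect_error(mannWhitneyU(numeric(), 1), "non-empty")
})

test_that("Spearman's rho matches a rank-then-Pearson oracle", {
  x <- c(3, 1, 4, 1.5, 9, 2.6)
  expect_equal(spearmanRho(x, exp(x)), 1.0)
  expect_equal(spearmanRho(x, -x), -1.0)
  set.seed(6)
  for (i in 1:100) {
    a <- rnorm(30); b <- rnorm(30)
    oracle <- cor(rank(a), rank(b))        # brute-force recomputation
    expect_equal(spearmanRho(a, b), oracle, tolerance = 1e-12)
  }
  expect_error(spearmanRho(rep(1, 5), rnorm(5)), "constant")
})

test_that("group comparison reports descriptives, normality and adjusted tests", {
  set.seed(12)
  vals <- c(rnorm(30, 0), rnorm(30, 1), rnorm(30, 2))
  labs <- rep(c("control", "epileptic", "non_epileptic"), each = 30)
  rep_ <- compareGroups(vals, labs, correction = "bonferroni")
  expect_equal(nrow(rep_$descriptives), 3)
  expect_equal(nrow(rep_$pairwise), 3)
  expect_true(all(c("ks_p", "shapiro_p") %in% names(rep_$normality)))
  # Bonferroni: multiply by the number of comparisons, capped at 1
  expect_equal(rep_$pairwise$p_adj,
               pmin(1, rep_$pairwise$p_raw * 3), tolerance = 1e-12)
  repBH <- compareGroups(vals, labs, correction = "bh")
  expect_equal(repBH$pairwise$p_adj,
               p.adjust(repBH$pairwise$p_raw, "BH"), tolerance = 1e-12)
  expect_error(compareGroups(vals[1:3], labs[1:3]), "at least 2")
})

test_that("pairwise tests keep their nominal level on permuted copies", {
  set.seed(77)
  hits <- vapply(1:200, function(s) {
    v <- rnorm(100)
    lab <- sample(rep(c("a", "b"), 50))
    mannWhitneyU(v[lab == "a"], v[lab == "b"])$p < 0.05
  }, logical(1))
  rate <- mean(hits)
  band <- 2.576 * sqrt(0.05 * 0.95 / 200)
  expect_lt(abs(rate - 0.05), band)
})
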