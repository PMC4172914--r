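simulateS2 <- function(n, m, a, b, seed) {
  set.seed(seed)
  sigma2 <- 1 / rgamma(n, shape = a, scale = b)
  sigma2 * rchisq(n, df = m) / m
}

test_that("hyperparameter fit recovers generating values and is an argmax", {
  s2 <- simulateS2(20000, m = 4, a = 2, b = 1, seed = 99)
  fit <- fitRvm(s2, df = 4)
  expect_true(fit@converged)
  expect_lt(abs(fit@a - 2) / 2, 0.10)
  expect_lt(abs(fit@b - 1) / 1, 0.10)
  # the fitted loglik dominates the truth's (definition of an argmax)
  expect_gte(fit@loglik, rvmLoglik(list(a = 2, b = 1), s2, 4))
})

test_that("fit rejects degenerate inputs", {
  expect_error(fitRvm(c(1, 2), df = 4), ">= 10 features")
  expect_error(fitRvm(rep(0, 50), df = 4), "positive residual variance")
  expect_error(fitRvm(runif(20), df = 0.5), "df must be")
})

test_that("moderated t matches closed forms in both prior limits", {
  panel <- tinyPanel(nf = 50, seed = 7)
  dct <- deltaCt(panel)
  x <- deltaCtValues(dct)
  g <- as.character(groupLabels(dct))
  m1 <- rowMeans(x[, g == "newborn"]); m2 <- rowMeans(x[, g == "adult"])
  v1 <- apply(x[, g == "newborn"], 1, var)
  v2 <- apply(x[, g == "adult"], 1, var)
  s2 <- (2 * v1 + 2 * v2) / 4

  # prior-dominated limit: a huge with a*b = 1/sigma_bar^2 pins every
  # variance at sigma_bar^2, giving a z-like equal-variance statistic
  sbar2 <- mean(s2)
  strong <- new("RvmFit", a = 1e6, b = 1 / (1e6 * sbar2), converged = TRUE,
                loglik = 0, nFeaturesUsed = 50L)
  tt <- rvmTest(dct, strong, reference = "newborn", comparison = "adult")
  z <- (m1 - m2) / sqrt(sbar2 * (2 / 3))
  expect_equal(tt$t, unname(z), tolerance = 0.01)

  # vanishing prior: b -> Inf, a -> 0 recovers the ordinary pooled t-test
  weak <- new("RvmFit", a = 1e-9, b = 1e12, converged = TRUE,
              loglik = 0, nFeaturesUsed = 50L)
  tw <- rvmTest(dct, weak, reference = "newborn", comparison = "adult")
  t_ord <- (m1 - m2) / sqrt(s2 * (2 / 3))
  expect_equal(tw$t, unname(t_ord), tolerance = 1e-6)
  expect_equal(tw$df, rep(4 + 2e-9, 50))
})

test_that("null features give calibrated, uniform p-values", {
  sim <- simulateCtPanel(panelConfig(nFeatures = 5000, nUp = 0, nDown = 0,
                                     varianceHyperA = 2, varianceHyperB = 1,
                                     seed = 1234))
  tt <- rvmTest(deltaCt(sim$panel), reference = "newborn",
                comparison = "adult")
  alpha <- 0.05
  reject <- mean(tt$p_value < alpha)
  half <- 2.576 * sqrt(alpha * (1 - alpha) / nrow(tt))
  expect_gt(reject, alpha - half)
  expect_lt(reject, alpha + half)
  expect_gt(suppressWarnings(
    ks.test(tt$p_value, "punif")$p.value), 0.01)
})

test_that("identical group means give t = 0 and p = 1", {
  ct <- rbind("miR-1" = c(25, 26, 27, 27, 26, 25),
              matrix(rnorm(9 * 6, 28), nrow = 9,
                     dimnames = list(paste0("miR-", 2:10), NULL)),
              U44 = rep(20, 6), U48 = rep(20, 6))
  colnames(ct) <- paste0("s", 1:6)
  panel <- CtPanel(ct, rep(c("newborn", "adult"), each = 3),
                   c("U44", "U48"))
  fit <- new("RvmFit", a = 2, b = 1, converged = TRUE, loglik = 0,
             nFeaturesUsed = 10L)
  tt <- rvmTest(deltaCt(panel), fit, reference = "newborn",
                comparison = "adult")
  expect_equal(tt$t[tt$mirna_id == "miR-1"], 0)
  expect_equal(tt$p_value[tt$mirna_id == "miR-1"], 1)
})

test_that("variance sharing buys power over the ordinary t-test at n = 3", {
  # moderate planted effects where the ordinary test struggles
  set.seed(505)
  n <- 2000; m <- 4
  sigma2 <- 1 / rgamma(n, shape = 2, scale = 1)
  effect <- 2  # cycles
  x1 <- matrix(rnorm(n * 3, 0, sqrt(sigma2)), nrow = n)
  x2 <- matrix(rnorm(n * 3, effect, sqrt(sigma2)), nrow = n)
  v1 <- apply(x1, 1, var); v2 <- apply(x2, 1, var)
  s2 <- (2 * v1 + 2 * v2) / m
  d <- rowMeans(x1) - rowMeans(x2)
  fit <- fitRvm(s2, m)
  s2_mod <- (m * s2 + 2 / fit@b) / (m + 2 * fit@a)
  p_rvm <- 2 * pt(-abs(d / sqrt(s2_mod * (2 / 3))), m + 2 * fit@a)
  p_ord <- 2 * pt(-abs(d / sqrt(s2 * (2 / 3))), m)
  expect_gte(mean(p_rvm < 0.05), mean(p_ord < 0.05))
})

test_that("BH adjustment matches the step-up definition and its invariants", {
  expect_equal(bhAdjust(0.03), 0.03)
  expect_equal(bhAdjust(c(0.01, 0.02, 0.04)), c(0.03, 0.03, 0.04))
  expect_equal(bhAdjust(rep(0.2, 5)), rep(0.2, 5))
  expect_error(bhAdjust(c(0.5, 0)), "0, 1")
  expect_error(bhAdjust(c(0.5, 1.2)), "0, 1")
  set.seed(8)
  for (i in 1:25) {
    p <- runif(sample(1:40, 1))^sample(1:3, 1)
    q <- bhAdjust(p)
    expect_equal(q, bruteBH(p))
    expect_true(all(q >= p - 1e-15) && all(q <= 1))
    o <- order(p)
    expect_true(all(diff(q[o]) >= -1e-15))  # monotone after sorting by p
  }
})

test_that("differential selection applies thresholds and the direction rule", {
  ref <- referenceFoldChanges()
  res <- data.frame(mirna_id = ref$mirna_id, fold_change = ref$fold_change,
                    p_value = 1e-4)
  de <- selectDifferential(res, pThreshold = 0.05, fcThreshold = 2)
  expect_equal(sum(de$direction == "up"), 16L)
  expect_equal(sum(de$direction == "down"), 2L)
  # empty in, empty out
  expect_equal(nrow(selectDifferential(res[0, ])), 0L)
  # fold change exactly 1 is never differential
  tie <- data.frame(mirna_id = "m", fold_change = 1, p_value = 1e-9)
  expect_equal(nrow(selectDifferential(tie, fcThreshold = 1)), 0L)
  # non-significant or small-change features are dropped
  mix <- data.frame(mirna_id = c("a", "b", "c"),
                    fold_change = c(3, 1.5, 0.2),
                    p_value = c(0.2, 1e-5, 1e-5))
  kept <- selectDifferential(mix)
  expect_equal(kept$mirna_id, "c")
  expect_equal(kept$direction, "down")
})
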