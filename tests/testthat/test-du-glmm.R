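# The binomial GLMM and its likelihood-ratio test.

test_that("with the random effect dropped, the fit reproduces an ordinary binomial GLM", {
  set.seed(21)
  J <- 12
  cond <- factor(rep(c("a", "b"), each = J / 2))
  y <- rpois(J, 150) + 20
  x <- rbinom(J, y, plogis(-0.4 + 0.9 * (cond == "b")))
  X <- model.matrix(~cond)
  fit <- fitBinomGlmm(x, y, seq_len(J), X, sigma2Fixed = 0)
  ref <- glm(cbind(x, y - x) ~ cond, family = binomial)
  expect_equal(unname(fit$beta), unname(coef(ref)), tolerance = 1e-4)
  expect_equal(fit$loglik, as.numeric(logLik(ref)), tolerance = 1e-6)
  expect_equal(fit$sigma2, 0)
})

test_that("estimates and LRT p-values agree with an independent GLMM implementation", {
  skip_if_not_installed("lme4")
  set.seed(33)
  J <- 10
  cond <- factor(rep(c("a", "b"), each = J))
  sid <- factor(seq_len(2 * J))
  phi <- rnorm(2 * J, 0, 0.5)
  y <- rpois(2 * J, 150) + 30
  x <- rbinom(2 * J, y, plogis(-0.3 + 0.6 * (cond == "b") + phi))
  ours <- fitDuBulk(x, y, cond)
  m1 <- lme4::glmer(cbind(x, y - x) ~ cond + (1 | sid),
                    family = binomial)
  m0 <- lme4::glmer(cbind(x, y - x) ~ 1 + (1 | sid), family = binomial)
  expect_equal(ours$beta0, unname(lme4::fixef(m1))[1], tolerance = 1e-3)
  expect_equal(ours$beta, unname(lme4::fixef(m1))[2], tolerance = 1e-3)
  expect_equal(ours$sigma2,
               as.numeric(lme4::VarCorr(m1)$sid), tolerance = 1e-3)
  pRef <- anova(m0, m1)$`Pr(>Chisq)`[2]
  expect_equal(ours$pValue, pRef, tolerance = 1e-4)
})

test_that("symmetric data yield a near-zero condition effect and large p", {
  J <- 10
  cond <- factor(rep(c("a", "b"), each = J / 2))
  x <- rep(50, J); y <- rep(100, J)
  fit <- fitDuBulk(x, y, cond)
  expect_lt(abs(fit$beta), 1e-3)
  expect_gt(fit$pValue, 0.5)
})

test_that("a large usage separation is detected with overwhelming significance", {
  set.seed(8)
  J <- 10
  cond <- factor(rep(c("a", "b"), each = J))
  y <- rep(100, 2 * J)
  x <- c(rbinom(J, 100, 0.1), rbinom(J, 100, 0.9))
  fit <- fitDuBulk(x, y, cond)
  expect_lt(fit$pValue, 1e-6)
  expect_true(fit$converged)
})

test_that("the bulk fit stays finite and converged at J = 2 per group", {
  cond <- factor(c("a", "a", "b", "b"))
  fit <- fitDuBulk(c(5, 8, 90, 85), c(100, 100, 100, 100), cond)
  expect_true(fit$converged)
  expect_true(is.finite(fit$pValue))
  expect_gte(fit$lrt, 0)
})

test_that("cell-level and pseudo-bulk tests agree to numerical precision", {
  set.seed(14)
  J <- 6; I <- 40
  cond <- setNames(factor(rep(c("a", "b"), each = J / 2)),
                   paste0("s", seq_len(J)))
  cellSample <- factor(rep(paste0("s", seq_len(J)), each = I),
                       levels = paste0("s", seq_len(J)))
  phi <- rnorm(J, 0, 0.3)
  theta <- plogis(qlogis(0.4) + 0.5 * (cond == "b") + phi)
  y <- rpois(J * I, 3)
  x <- rbinom(J * I, y, theta[as.integer(cellSample)])
  fc <- fitDuCell(x, y, cellSample, cond)
  xs <- as.vector(rowsum(x, cellSample))
  ys <- as.vector(rowsum(y, cellSample))
  fb <- fitDuBulk(xs, ys, cond)
  expect_lt(abs(fc$pValue - fb$pValue), 1e-6)
  expect_equal(fc$beta, fb$beta, tolerance = 1e-5)
})

test_that("the null rejection rate of the test is calibrated at the nominal level", {
  set.seed(99)
  nRep <- 300
  J <- 10
  cond <- factor(rep(c("a", "b"), each = J / 2))
  p <- vapply(seq_len(nRep), function(r) {
    theta <- plogis(qlogis(runif(1, 0.2, 0.8)) + rnorm(J, 0, 0.3))
    y <- rpois(J, 120) + 30
    x <- rbinom(J, y, theta)
    fitDuBulk(x, y, cond)$pValue
  }, numeric(1))
  rate <- mean(p < 0.05, na.rm = TRUE)
  mcSe <- sqrt(0.05 * 0.95 / nRep)
  expect_lte(rate, 0.05 + 3 * mcSe)
})

test_that("BH adjustment matches the brute-force step-up procedure", {
  expect_equal(bhAdjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bhAdjust(0.03), 0.03)
  expect_equal(bhAdjust(c(0.5, 1.0)), c(1, 1))
  set.seed(2)
  for (rep in 1:200) {
    p <- runif(sample(1:30, 1))
    if (rep %% 5 == 0) p[sample(length(p), 1)] <- NA
    expect_equal(bhAdjust(p), bruteForceBH(p))
  }
})

test_that("rank-sum comparator handles degenerate, separated, and bulk-aggregated usage", {
  J <- 10
  cellSample <- factor(rep(paste0("s", seq_len(J)), each = 4))
  cond <- setNames(factor(rep(c("a", "b"), each = J / 2)),
                   paste0("s", seq_len(J)))
  # identical usage everywhere: p = 1
  x <- rep(2, 40); y <- rep(4, 40)
  expect_equal(wilcoxonDu(x, y, cellSample, cond, level = "cell"), 1)
  # complete separation at bulk level, 5 vs 5, distinct per-sample
  # usages: the exact two-sided rank-sum minimum is 2 / choose(10, 5)
  xs <- rep(c(0:4, 6:10), each = 4); ys <- rep(10, 40)
  pB <- wilcoxonDu(xs, ys, cellSample, cond, level = "bulk")
  expect_equal(pB, 2 / choose(10, 5))
  # a group with no usable usage gives NA
  yNA <- c(rep(0, 20), rep(4, 20))
  expect_true(is.na(wilcoxonDu(x, yNA, cellSample, cond,
                               level = "bulk")))
})

test_that("Wasserstein statistic and permutation test behave on known cases", {
  expect_equal(wasserstein1(0.2, 0.7), 0.5)
  expect_equal(wasserstein1(c(1, 2), c(1, 2)), 0)
  # triangle-ish check: W1 between shifted samples equals the shift
  expect_equal(wasserstein1(c(1, 2, 3), c(2, 3, 4)), 1)

  set.seed(6)
  cond <- factor(rep(c("a", "b"), each = 3))
  identicalUsage <- replicate(6, rep(0.5, 30), simplify = FALSE)
  resId <- ideasModifiedDu(identicalUsage, cond, nPerm = 200)
  expect_equal(resId$statistic, 0)
  expect_gt(resId$pValue, 0.5)

  # with 4 + 4 samples the label space (70 assignments) admits p < 0.05
  cond4 <- factor(rep(c("a", "b"), each = 4))
  shifted <- c(replicate(4, rbeta(60, 2, 8), simplify = FALSE),
               replicate(4, rbeta(60, 8, 2), simplify = FALSE))
  resSh <- ideasModifiedDu(shifted, cond4, nPerm = 2000)
  expect_lt(resSh$pValue, 0.05)

  expect_warning(ideasModifiedDu(list(runif(5), runif(5)),
                                 factor(c("a", "b")), nPerm = 10),
                 "too few")
})

test_that("testDifferentialUsage runs over a combined matrix and BH-adjusts", {
  set.seed(11)
  cl <- c(simpleClusters("chr1", c(100, 300), c(200, 400), "+",
                         gene = c("g1", "g1")),
          simpleClusters("chr1", 500, 600, "+", gene = "g2"))
  mats <- lapply(1:4, function(s) {
    nCells <- 30
    bc <- sprintf("%02d-1", seq_len(nCells))
    usage <- if (s <= 2) 0.2 else 0.8
    rec <- NULL
    for (i in seq_len(nCells)) {
      n1 <- rbinom(1, 10, usage)
      rec <- c(rec, list(mappedTss("chr1", c(150, 350), c(n1, 10 - n1),
                                   "+", barcode = rep(bc[i], 2))))
    }
    rec <- suppressWarnings(do.call(c, rec))
    rec <- rec[rec$count > 0]
    quantifyClusters(rec, cl, sampleId = paste0("s", s))
  })
  comb <- combineSamples(mats)
  cond <- setNames(factor(c("a", "a", "b", "b")), paste0("s", 1:4))
  du <- testDifferentialUsage(comb, cond, level = "bulk",
                              minDetect = 0.1)
  expect_equal(nrow(du), 2L)         # the two clusters of g1; g2 dropped
  expect_true(all(du$gene == "g1"))
  expect_lt(du$pValue[1], 0.01)
  expect_equal(du$pAdjusted, bhAdjust(du$pValue))
  # the two clusters of one two-cluster gene carry mirrored effects
  expect_equal(du$beta[1], -du$beta[2], tolerance = 1e-3)
})

test_that("gene filters apply per-sample detection and the multi-cluster rule", {
  cl <- c(simpleClusters("chr1", c(100, 300), c(200, 400), "+",
                         gene = c("g1", "g1")),
          simpleClusters("chr1", 500, 600, "+", gene = "g2"))
  # sample 1: g1 in all 4 cells, g2 in 1 of 4 cells
  mk <- function(sid, g2cells) {
    bc <- sprintf("%02d-1", 1:4)
    rec <- mappedTss("chr1", rep(150, 4), rep(2, 4), "+", barcode = bc)
    if (g2cells > 0)
      rec <- c(rec, mappedTss("chr1", rep(550, g2cells), rep(1, g2cells),
                              "+", barcode = bc[seq_len(g2cells)]))
    quantifyClusters(rec, cl, sampleId = sid)
  }
  comb <- combineSamples(list(mk("s1", 1), mk("s2", 0)))
  expect_equal(filterGenes(comb, minDetect = 0.25), "g1")
  # boundary: detection exactly at the threshold is kept
  comb2 <- combineSamples(list(mk("s1", 1), mk("s2", 1)))
  expect_equal(filterGenes(comb2, minDetect = 0.25,
                           requireMulticluster = FALSE),
               c("g1", "g2"))
  expect_equal(filterGenes(comb2, minDetect = 0.25), "g1")
})
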