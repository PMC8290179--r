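mkTable <- function(m, ids = sprintf("P%02d", seq_len(nrow(m)))) {
  rownames(m) <- ids
  if (is.null(colnames(m))) colnames(m) <- sprintf("f%d", seq_len(ncol(m)))
  featureTable(m)
}

test_that("standardization hits mean 0 / population SD 1 and drops constants", {
  tab <- mkTable(cbind(c(2, 4, 6), c(1, 1, 1), c(0, 5, 10)))
  res <- standardizeFeatures(tab)
  z <- as.matrix(res$table)
  expect_equal(unname(z[, "f1"]), c(-1.22474487139159, 0, 1.22474487139159),
               tolerance = 1e-9)
  expect_false("f2" %in% featureNames(res$table))
  expect_true(res$report@diagnostics$dropped_constant[2])
  expect_true(all(abs(colMeans(z)) < 1e-9))
  expect_true(all(abs(sqrt(colMeans(sweep(z, 2, colMeans(z))^2)) - 1) < 1e-9))

  # idempotence
  again <- standardizeFeatures(res$table)
  expect_equal(as.matrix(again$table), z, tolerance = 1e-9)
  expect_error(standardizeFeatures(mkTable(matrix(1, 1, 2))), "2 patients")
})

test_that("correlation pruning keeps the highest-variance member per cluster", {
  set.seed(31)
  A <- rnorm(100)
  B <- 2 * A + rnorm(100, sd = 0.01)   # |r| > 0.99, larger raw variance
  C <- rnorm(100)
  tab <- mkTable(cbind(A = A, B = B, C = C))
  rawVar <- apply(as.matrix(tab), 2, var)
  std <- standardizeFeatures(tab)$table
  res <- correlationPrune(std, threshold = 0.95, variability = rawVar)
  expect_setequal(featureNames(res$table), c("B", "C"))
  expect_equal(res$report@diagnostics$component[1],
               res$report@diagnostics$component[2])

  # nothing above threshold: everything retained
  set.seed(32)
  ind <- mkTable(matrix(rnorm(300), 100, 3))
  resI <- correlationPrune(ind, 0.95,
                           variability = apply(as.matrix(ind), 2, var))
  expect_equal(featureNames(resI$table), featureNames(ind))

  # exact duplicates (tied variance): earliest column kept
  D <- rnorm(50)
  dup <- mkTable(cbind(x1 = D, x2 = D, y = rnorm(50)))
  resD <- correlationPrune(dup, 0.95,
                           variability = apply(as.matrix(dup), 2, var))
  expect_setequal(featureNames(resD$table), c("x1", "y"))

  expect_error(correlationPrune(std, 0.95, variability = c(A = 1)),
               "cover")
})

test_that("VIF matches its definition on orthogonal, duplicate and collinear designs", {
  # mutually uncorrelated columns (orthogonal after centering) -> VIF 1
  set.seed(30)
  q <- qr.Q(qr(cbind(1, matrix(rnorm(60), 20, 3))))[, 2:4]
  tab <- mkTable(q)
  for (j in 1:3) expect_equal(computeVif(tab, j), 1, tolerance = 1e-8)

  # exact duplicate -> +Inf
  set.seed(33)
  A <- rnorm(30)
  dup <- mkTable(cbind(A = A, B = A))
  expect_identical(computeVif(dup, "B"), Inf)

  # C = A + B + small noise -> large VIF, checked against a normal-equations oracle
  set.seed(3)
  A <- rnorm(60); B <- rnorm(60); C <- A + B + rnorm(60, sd = 0.1)
  m <- scale(cbind(A = A, B = B, C = C))
  tab3 <- mkTable(m)
  vifC <- computeVif(tab3, "C")
  expect_gt(vifC, 10)
  X <- cbind(1, m[, c("A", "B")])
  beta <- solve(t(X) %*% X, t(X) %*% m[, "C"])
  r2 <- 1 - sum((m[, "C"] - X %*% beta)^2) / sum((m[, "C"] - mean(m[, "C"]))^2)
  expect_equal(vifC, 1 / (1 - r2), tolerance = 1e-8)

  expect_equal(computeVif(mkTable(matrix(rnorm(10), 10, 1)), 1), 1)
})

test_that("VIF pruning leaves max VIF under the threshold (re-verified)", {
  set.seed(40)
  q <- qr.Q(qr(cbind(1, matrix(rnorm(100), 20, 5))))[, 2:6]
  ortho <- mkTable(q)
  res <- vifPrune(ortho, 10)
  expect_equal(featureNames(res$table), featureNames(ortho))

  set.seed(33)
  A <- rnorm(40)
  dup <- mkTable(scale(cbind(a = A, b = A, c = rnorm(40))))
  resD <- vifPrune(dup, 10)
  expect_equal(ncol(resD$table), 2)

  # one collinear block of 4 among independents
  set.seed(11)
  z <- rnorm(80)
  block <- sapply(1:4, function(i) z + rnorm(80, sd = 0.1))
  m <- scale(cbind(block, matrix(rnorm(80 * 4), 80, 4)))
  resB <- vifPrune(mkTable(m), 10)
  final <- sapply(featureNames(resB$table),
                  function(f) computeVif(resB$table, f))
  expect_lte(max(final), 10)
  expect_true(all(c("f5", "f6", "f7", "f8") %in% featureNames(resB$table)))
})

test_that("PCA keeps the minimal component count reaching the variance target", {
  # rank-1 data
  set.seed(34)
  u <- rnorm(30)
  r1 <- mkTable(outer(u, c(1, 2, 3)))
  expect_equal(ncol(pcaReduce(r1, 0.95)$table), 1)

  # orthogonal directions with variances 100, 10, 1: cumulative 90.1%, 99.1%
  n <- 2000
  set.seed(35)
  m <- cbind(rnorm(n, sd = 10), rnorm(n, sd = sqrt(10)), rnorm(n, sd = 1))
  res <- pcaReduce(mkTable(m), 0.95)
  expect_equal(ncol(res$table), 2)
  ratios <- res$report@diagnostics$explained_variance_ratio
  expect_equal(ratios[1], 100 / 111, tolerance = 0.05)

  # variance fraction 1 keeps the full rank
  set.seed(36)
  full <- mkTable(matrix(rnorm(50 * 4), 50, 4))
  expect_equal(ncol(pcaReduce(full, 1)$table), 4)

  # scores are mutually orthogonal
  sc <- as.matrix(pcaReduce(full, 1)$table)
  cc <- cor(sc)
  expect_lt(max(abs(cc[upper.tri(cc)])), 1e-8)

  expect_error(pcaReduce(mkTable(matrix(0, 5, 2)), 0.95), "degenerate")
})

test_that("univariate p-values equal the lm slope test and behave at extremes", {
  set.seed(37)
  n <- 25
  m <- matrix(rnorm(n * 3), n, 3)
  surv <- 300 + 40 * m[, 1] + rnorm(n, sd = 50)
  tab <- mkTable(m)
  p <- univariatePvalues(tab, surv)
  for (j in 1:3) {
    pLm <- summary(lm(surv ~ m[, j]))$coefficients[2, 4]
    expect_equal(unname(p[j]), pLm, tolerance = 1e-10)
  }
  # perfect linear feature -> p below 1e-6
  perfect <- mkTable(cbind(g1 = surv, g2 = m[, 2], g3 = m[, 3]))
  expect_lt(univariatePvalues(perfect, surv)[1], 1e-6)

  expect_error(univariatePvalues(mkTable(matrix(1:4, 2, 2)), c(1, 2)),
               "at least 4")
  expect_error(univariatePvalues(mkTable(cbind(rep(1, 10), rnorm(10))),
                                 rnorm(10)), "constant feature")
})

test_that("BH selection matches the literal step-up rule", {
  # worked example: every rank satisfies p_(i) <= i * 0.01
  expect_equal(bhSelect(c(0.01, 0.02, 0.03, 0.04, 0.05), 0.05), 1:5)
  expect_equal(bhSelect(rep(1, 10), 0.05), integer())
  expect_equal(bhSelect(0.04, 0.05), 1L)
  expect_error(bhSelect(c(0.5, 1.2)), "0, 1")

  set.seed(38)
  for (rep in 1:200) {
    p <- runif(sample(3:40, 1))^sample(1:3, 1)
    expect_identical(bhSelect(p, 0.05), as.integer(bruteBH(p, 0.05)))
    # cross-check against the adjusted-p route
    expect_setequal(bhSelect(p, 0.05), which(p.adjust(p, "BH") <= 0.05))
  }
})

test_that("the full cascade runs in order and its postconditions hold", {
  study <- makeSyntheticStudy(nPatients = 60, seed = 5, nBlocks = 4,
                              blockSize = 4, nNoiseFeatures = 6)
  red <- suppressMessages(
    reduceFeatures(study$radiomics, survivalDays(study$cohort),
                   pipelineConfig()))
  expect_named(red$reports, c("standardize", "correlation", "vif", "pca",
                              "bh_vif", "bh_pca"))
  # each stage consumed the previous stage's output
  expect_equal(red$reports$correlation@inputFeatures,
               red$reports$standardize@retainedFeatures)
  expect_equal(red$reports$vif@inputFeatures,
               red$reports$correlation@retainedFeatures)
  expect_equal(red$reports$pca@inputFeatures,
               red$reports$vif@retainedFeatures)
  # VIF postcondition on the surviving table
  final <- sapply(featureNames(red$vifTable),
                  function(f) computeVif(red$vifTable, f))
  expect_lte(max(final), 10)
  # within-block redundancy collapsed: at most one feature per block
  kept <- red$reports$correlation@retainedFeatures
  blocks <- study$blockMap[kept]
  expect_lte(max(table(blocks[blocks > 0])), 1)
})
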