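test_that("survival dichotomization uses the >= 450 boundary rule", {
  expect_equal(dichotomizeSurvival(c(3, 449, 450, 451, 1767)),
               c("short", "short", "long", "long", "long"))
  expect_equal(dichotomizeSurvival(100, cutoff = 90), "long")
  expect_error(dichotomizeSurvival(c(10, 0)), "positive")
})

test_that("resection split partitions the cohort", {
  coh <- cohortTable(sprintf("P%03d", 1:200), rep(c(300, 600), 100),
                     c(rep("GTR", 101), rep("NA", 99)))
  parts <- splitByResection(coh)
  expect_equal(nrow(as.data.frame(parts$GTR)), 101)
  expect_equal(nrow(as.data.frame(parts$`NA`)), 99)
  expect_equal(nrow(as.data.frame(parts$GTR)) +
               nrow(as.data.frame(parts$`NA`)), 200)

  onlyG <- cohortTable("A1", 500, "GTR")
  pg <- splitByResection(onlyG)
  expect_equal(nrow(as.data.frame(pg$`NA`)), 0)
  empty <- splitByResection(cohortTable(character(), numeric(), character()))
  expect_equal(nrow(as.data.frame(empty$GTR)), 0)
  expect_equal(nrow(as.data.frame(empty$`NA`)), 0)
})

test_that("confusion metrics follow their definitions and flag 0/0", {
  cm <- confusionMetrics(3, 1, 4, 2)
  expect_equal(cm@accuracy, 0.7)
  expect_equal(cm@precision, 0.75)
  expect_equal(cm@sensitivity, 0.6)
  expect_equal(cm@specificity, 0.8)

  undef <- confusionMetrics(0, 0, 10, 0)
  expect_true(is.nan(undef@precision))
  expect_true("precision" %in% undef@undefined)

  perfect <- confusionMetrics(5, 0, 7, 0)
  expect_equal(c(perfect@accuracy, perfect@precision, perfect@sensitivity,
                 perfect@specificity), rep(1, 4))
  expect_error(confusionMetrics(0, 0, 0, 0), "zero")
})

test_that("univariate regression is exact on a perfect monotone signal", {
  set.seed(41)
  x <- rnorm(60, sd = 2)
  y <- 2 * x + 500
  res <- regressUnivariate(x, y, "LR", seed = 3)
  expect_equal(res@spearmanR, 1)
  expect_lt(res@mse / mean(y^2), 1e-6)
  expect_lt(res@pValue, 1e-10)
  expect_error(regressUnivariate(rep(1, 60), y, "LR"), "constant")
  expect_error(regressUnivariate(x[1:8], y[1:8], "LR", cvFolds = 5),
               "per fold")
})

test_that("cross-validated metrics are reproducible for a fixed seed", {
  set.seed(42)
  x <- rnorm(50)
  y <- pmax(10, 400 + 50 * x + rnorm(50, sd = 80))
  for (mk in c("LR", "RFR", "SVR")) {
    a <- regressUnivariate(x, y, mk, seed = 11)
    b <- regressUnivariate(x, y, mk, seed = 11)
    expect_identical(a@spearmanR, b@spearmanR)
    expect_identical(a@mse, b@mse)
  }
  cls <- dichotomizeSurvival(y)
  tab <- featureTable(matrix(c(x, rnorm(50)), 50, 2,
                             dimnames = list(sprintf("P%02d", 1:50),
                                             c("a", "b"))))
  for (mk in c("ANN", "RFC", "KNN")) {
    a <- classifyMultivariate(tab, cls, mk, seed = 11)
    b <- classifyMultivariate(tab, cls, mk, seed = 11)
    expect_identical(a@accuracy, b@accuracy)
    expect_identical(c(a@tp, a@fp, a@tn, a@fn), c(b@tp, b@fp, b@tn, b@fn))
  }
})

test_that("null features yield weak regression fits", {
  # pooled out-of-fold correlation is mildly anti-conservative under the
  # null (fold-mean coupling), so the calibrated claims are about |r| and
  # the bulk of the p distribution, not its extreme tail
  set.seed(5)
  rs <- ps <- numeric(40)
  for (rep in 1:40) {
    x <- rnorm(100)
    y <- pmax(10, rnorm(100, 500, 150))
    res <- regressUnivariate(x, y, "LR", seed = rep)
    rs[rep] <- res@spearmanR; ps[rep] <- res@pValue
  }
  expect_gte(mean(abs(rs) < 0.3), 0.95)
  expect_gt(median(ps), 0.05)
})

test_that("a real location effect is recovered with the right sign", {
  found <- 0L
  for (s in 1:25) {
    study <- makeSyntheticStudy(nPatients = 120, seed = 1000 + s)
    y <- as.matrix(study$location)[, "Y"]
    days <- survivalDays(study$cohort)
    res <- regressUnivariate(y, days, "LR", seed = s)
    slope <- coef(lm(days ~ y))[2]
    if (slope < 0 && res@pValue < 0.05) found <- found + 1L
  }
  expect_gte(found, 24)   # >= 95%: recovered slope negative, significant
})

test_that("classifiers separate well-separated classes and not permuted ones", {
  set.seed(43)
  n <- 100
  cls <- rep(c("short", "long"), each = n / 2)
  m <- matrix(rnorm(n * 4), n, 4,
              dimnames = list(sprintf("P%03d", 1:n), paste0("f", 1:4)))
  m[cls == "long", 1] <- m[cls == "long", 1] + 6   # 6 SD apart
  tab <- featureTable(m)
  for (mk in c("ANN", "RFC", "KNN")) {
    cm <- classifyMultivariate(tab, cls, mk, seed = 7)
    expect_gte(cm@accuracy, 0.95)
    expect_equal(cm@tp + cm@fp + cm@tn + cm@fn, n)   # pooled counts cover all
  }
  expect_error(classifyMultivariate(tab, rep("short", n), "KNN"),
               "single-class")

  # permutation null: mean accuracy near chance (KNN, cheap)
  accs <- vapply(1:60, function(s) {
    perm <- withr::with_seed(s, sample(cls))
    classifyMultivariate(tab, perm, "KNN", seed = s)@accuracy
  }, numeric(1))
  expect_lt(abs(mean(accs) - 0.5), 0.1)
})

test_that("one-way ANOVA matches its definition and degenerate contracts", {
  expect_equal(anovaPvalue(c(1, 2, 3, 1, 2, 3), rep(c("a", "b"), each = 3)), 1)
  p <- anovaPvalue(c(0, 0, 0, 0, 10, 10, 10, 10) +
                     withr::with_seed(2, rnorm(8, sd = 1e-3)),
                   rep(c("a", "b"), each = 4))
  expect_lt(p, 1e-6)
  # agreement with stats::oneway.test on generic data
  set.seed(44)
  v <- rnorm(30); g <- rep(c("x", "y", "z"), 10)
  expect_equal(anovaPvalue(v, g),
               oneway.test(v ~ factor(g), var.equal = TRUE)$p.value)
  expect_error(anovaPvalue(1:4, c("a", "a", "a", "b")), "at least 2")
  expect_error(anovaPvalue(rep(1, 6), rep(c("a", "b"), each = 3)),
               "equal means")
})
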