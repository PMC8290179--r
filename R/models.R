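#' Dichotomize survival days
#'
#' Survival at or above the cutoff is "long", below it "short". The
#' boundary day itself is assigned to "long" (the class definitions
#' "< cutoff" / "> cutoff" leave it open; >= is adopted and documented).
#'
#' @param days positive survival days.
#' @param cutoff cutoff in days (default 450).
#' @return character vector of "short" / "long".
#' @examples
#' dichotomizeSurvival(c(3, 450, 1767))
#' @export
dichotomizeSurvival <- function(days, cutoff = 450) {
  if (any(!is.finite(days)) || any(days <= 0))
    stop("survival days must be positive", call. = FALSE)
  ifelse(days >= cutoff, "long", "short")
}

#' Split a cohort by resection status
#'
#' @param cohort a [CohortTable-class].
#' @return named list of sub-[CohortTable-class]s, one per status in
#'   \{GTR, NA\} (empty strata included); sizes sum to the cohort size.
#' @export
splitByResection <- function(cohort) {
  stopifnot(is(cohort, "CohortTable"))
  d <- cohort@data
  out <- lapply(c(GTR = "GTR", "NA" = "NA"), function(s)
    new("CohortTable", data = d[d$resection_status == s, , drop = FALSE],
        metadata = cohort@metadata))
  out
}

# deterministic k-fold assignment; stratified when classes given
makeFolds <- function(n, k, seed, classes = NULL) {
  if (n < 2L * k) stop("need at least 2 patients per fold", call. = FALSE)
  withSeed(seed, {
    fold <- integer(n)
    if (is.null(classes)) {
      fold <- sample(rep_len(seq_len(k), n))
    } else {
      for (cl in unique(classes)) {
        idx <- which(classes == cl)
        fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
      }
    }
    fold
  })
}

#' Cross-validated univariate survival regression
#'
#' Fits one regressor of survival days on a single feature under seeded
#' k-fold cross-validation, pools the out-of-fold predictions, and scores
#' them against the observed days: Spearman R, mean squared error, median
#' and mean absolute error, and the two-sided p-value of the Spearman
#' correlation test between out-of-fold predictions and truth (defined
#' uniformly for all three model kinds, since random forests and support
#' vector machines have no native slope test).
#'
#' Model kinds: "LR" (least-squares linear regression), "RFR" (random
#' forest, 100 trees), "SVR" (radial-kernel support vector regression with
#' unit kernel scale).
#'
#' @param feature numeric feature vector.
#' @param survivalDays positive numeric, same length.
#' @param modelKind "LR", "RFR" or "SVR".
#' @param cvFolds folds (default 5); needs >= 2 patients per fold.
#' @param seed integer seed; fixes the fold split and learner RNG.
#' @param rfTrees random-forest tree count.
#' @return a [RegressionMetrics-class].
#' @export
regressUnivariate <- function(feature, survivalDays,
                              modelKind = c("LR", "RFR", "SVR"),
                              cvFolds = 5L, seed = 1L, rfTrees = 100L) {
  modelKind <- match.arg(modelKind)
  n <- length(feature)
  stopifnot(length(survivalDays) == n)
  if (any(!is.finite(feature))) stop("non-finite feature", call. = FALSE)
  if (modelKind == "LR" && stats::sd(feature) == 0)
    stop("constant feature: linear regression undefined", call. = FALSE)
  fold <- makeFolds(n, cvFolds, seed)
  seeds <- childSeeds(seed, cvFolds)
  pred <- numeric(n)
  for (f in seq_len(cvFolds)) {
    tr <- fold != f
    d <- data.frame(x = feature[tr], y = survivalDays[tr])
    newd <- data.frame(x = feature[!tr])
    pred[!tr] <- withSeed(seeds[f], switch(modelKind,
      LR = stats::predict(stats::lm(y ~ x, data = d), newd),
      RFR = stats::predict(
        randomForest::randomForest(y ~ x, data = d, ntree = rfTrees), newd),
      SVR = stats::predict(
        e1071::svm(y ~ x, data = d, kernel = "radial", gamma = 1), newd)))
  }
  spearmanMetrics(pred, survivalDays, modelKind)
}

# metrics between pooled out-of-fold predictions and truth
spearmanMetrics <- function(pred, truth, model) {
  ct <- suppressWarnings(
    stats::cor.test(pred, truth, method = "spearman", exact = FALSE))
  new("RegressionMetrics",
      spearmanR = unname(ct$estimate),
      mse = mean((pred - truth)^2),
      medianAE = stats::median(abs(pred - truth)),
      meanAE = mean(abs(pred - truth)),
      pValue = ct$p.value, model = model)
}

#' Cross-validated multivariate survival classification
#'
#' Fits one classifier of the binary survival class on a feature table
#' under seeded stratified k-fold cross-validation (both classes present
#' in every training fold), pools the out-of-fold predicted classes into a
#' single confusion matrix, and derives the metrics via
#' [confusionMetrics()].
#'
#' Model kinds: "ANN" (single hidden layer of 16 logistic units, logistic
#' output, trained on the binary cross-entropy, at most 1000 iterations),
#' "RFC" (random forest, 100 trees), "KNN" (k-nearest neighbours, k = 5).
#' Hyperparameters are fixed defaults, overridable.
#'
#' @param table a [FeatureTable-class].
#' @param classes character "short"/"long" per patient.
#' @param modelKind "ANN", "RFC" or "KNN".
#' @param cvFolds folds (default 5).
#' @param seed integer seed fixing fold split, initial weights, tree
#'   bootstraps and tie-breaks.
#' @param annHidden,annMaxit,rfTrees,knnK hyperparameters.
#' @return a [ClassificationMetrics-class].
#' @export
classifyMultivariate <- function(table, classes,
                                 modelKind = c("ANN", "RFC", "KNN"),
                                 cvFolds = 5L, seed = 1L, annHidden = 16L,
                                 annMaxit = 1000L, rfTrees = 100L,
                                 knnK = 5L) {
  modelKind <- match.arg(modelKind)
  stopifnot(is(table, "FeatureTable"))
  m <- as.matrix(table)
  n <- nrow(m)
  stopifnot(length(classes) == n)
  if (length(unique(classes)) < 2L)
    stop("single-class cohort: classification undefined", call. = FALSE)
  y <- factor(classes, levels = c("short", "long"))
  fold <- makeFolds(n, cvFolds, seed, classes = classes)
  seeds <- childSeeds(seed, cvFolds)
  pred <- character(n)
  for (f in seq_len(cvFolds)) {
    tr <- fold != f
    if (length(unique(y[tr])) < 2L)
      stop("a training fold lost a class; reduce cvFolds", call. = FALSE)
    pred[!tr] <- withSeed(seeds[f], switch(modelKind,
      ANN = {
        fit <- nnet::nnet(x = m[tr, , drop = FALSE], y = as.numeric(y[tr]) - 1,
                          size = annHidden, entropy = TRUE, maxit = annMaxit,
                          trace = FALSE)
        ifelse(stats::predict(fit, m[!tr, , drop = FALSE]) >= 0.5,
               "long", "short")
      },
      RFC = as.character(stats::predict(
        randomForest::randomForest(x = m[tr, , drop = FALSE], y = y[tr],
                                   ntree = rfTrees),
        m[!tr, , drop = FALSE])),
      KNN = as.character(class::knn(m[tr, , drop = FALSE],
                                    m[!tr, , drop = FALSE],
                                    cl = y[tr], k = knnK))))
  }
  tp <- sum(pred == "short" & classes == "short")
  fp <- sum(pred == "short" & classes == "long")
  tn <- sum(pred == "long" & classes == "long")
  fn <- sum(pred == "long" & classes == "short")
  out <- confusionMetrics(tp, fp, tn, fn)
  out@model <- modelKind
  out
}

#' Metrics from confusion counts
#'
#' Accuracy = (TP+TN)/total, precision = TP/(TP+FP), sensitivity =
#' TP/(TP+FN), specificity = TN/(TN+FP). The positive class is "short"
#' survival. A ratio with zero denominator is NaN and flagged in
#' \code{undefined} — never silently zero.
#'
#' @param tp,fp,tn,fn non-negative counts, not all zero.
#' @return a [ClassificationMetrics-class].
#' @examples
#' confusionMetrics(3, 1, 4, 2)
#' @export
confusionMetrics <- function(tp, fp, tn, fn) {
  counts <- c(tp, fp, tn, fn)
  if (any(counts < 0)) stop("counts must be >= 0", call. = FALSE)
  if (sum(counts) == 0) stop("all confusion counts are zero", call. = FALSE)
  ratio <- function(num, den) if (den == 0) NaN else num / den
  acc <- ratio(tp + tn, sum(counts))
  prec <- ratio(tp, tp + fp)
  sens <- ratio(tp, tp + fn)
  spec <- ratio(tn, tn + fp)
  undef <- c("precision", "sensitivity", "specificity")[
    is.nan(c(prec, sens, spec))]
  new("ClassificationMetrics", accuracy = acc, precision = prec,
      sensitivity = sens, specificity = spec,
      tp = as.integer(tp), fp = as.integer(fp), tn = as.integer(tn),
      fn = as.integer(fn), undefined = undef)
}

#' One-way fixed-effects ANOVA p-value
#'
#' The classical F test of equal group means with a pooled within-group
#' variance, as used to check that age and survival do not differ between
#' the resection strata.
#'
#' @param values numeric observations.
#' @param groups group labels, same length; >= 2 groups with >= 2
#'   observations each.
#' @return the upper-tail p-value of the F statistic (1 when F = 0).
#' @export
anovaPvalue <- function(values, groups) {
  stopifnot(length(values) == length(groups))
  g <- factor(groups)
  if (nlevels(g) < 2L) stop("need at least 2 groups", call. = FALSE)
  sizes <- table(g)
  if (any(sizes < 2L))
    stop("every group needs at least 2 observations", call. = FALSE)
  withinVar <- tapply(values, g, stats::var)
  if (all(withinVar == 0)) {
    means <- tapply(values, g, mean)
    if (max(means) == min(means))
      stop("zero within-group variance with equal means: F undefined",
           call. = FALSE)
    return(0)
  }
  res <- stats::oneway.test(values ~ g, var.equal = TRUE)
  p <- res$p.value
  if (is.nan(res$statistic)) stop("F statistic undefined", call. = FALSE)
  if (res$statistic == 0) 1 else p
}
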