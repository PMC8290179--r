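#' Standardize a feature table
#'
#' Centers and scales every column to mean 0 and population (divide-by-N)
#' SD 1. Constant columns cannot be scaled; they are dropped and named in
#' the report. The returned center/scale record allows the inverse
#' transform.
#'
#' @param table a [FeatureTable-class] with >= 2 patients.
#' @return list: \code{table} (standardized [FeatureTable-class]),
#'   \code{center} and \code{scale} (named numeric over retained features),
#'   \code{report} ([ReductionReport-class]; dropped constants in
#'   diagnostics).
#' @export
standardizeFeatures <- function(table) {
  stopifnot(is(table, "FeatureTable"))
  m <- as.matrix(table)
  if (nrow(m) < 2L) stop("need at least 2 patients", call. = FALSE)
  mu <- colMeans(m)
  sdev <- sqrt(colMeans(sweep(m, 2, mu)^2))
  constant <- sdev == 0
  keep <- !constant
  if (!any(keep)) stop("all features are constant", call. = FALSE)
  z <- sweep(sweep(m[, keep, drop = FALSE], 2, mu[keep]), 2, sdev[keep], "/")
  rep <- new("ReductionReport", stage = "standardize",
             inputFeatures = colnames(m), retainedFeatures = colnames(z),
             diagnostics = data.frame(feature = colnames(m), mean = mu,
                                      sd = sdev, dropped_constant = constant,
                                      row.names = NULL),
             thresholds = list())
  list(table = featureTable(z), center = mu[keep], scale = sdev[keep],
       report = rep)
}

# connected components of an undirected adjacency matrix (logical), BFS
connComponents <- function(adj) {
  p <- nrow(adj)
  comp <- integer(p)
  cur <- 0L
  for (s in seq_len(p)) {
    if (comp[s]) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue)) {
      v <- queue[1L]
      queue <- queue[-1L]
      nb <- which(adj[v, ] & comp == 0L)
      comp[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  comp
}

#' Prune highly correlated features
#'
#' Builds the graph whose edges join feature pairs with |Pearson r| above
#' the threshold, takes its connected components (clusters of mutual high
#' correlation), and keeps from each multi-feature component exactly the
#' feature with the highest raw-scale variance (ties: earliest column).
#' Features in singleton components are untouched. Because components are
#' the transitive closure of the relation, a retained feature may still
#' exceed the threshold against a pruned one, but no above-threshold pair
#' both survive.
#'
#' Variability is judged on pre-standardization variances, passed
#' explicitly — after standardization all variances are 1 and the rule
#' would have no effect.
#'
#' @param table a [FeatureTable-class] (typically standardized), >= 3
#'   patients.
#' @param threshold |r| threshold in (0, 1].
#' @param variability named numeric of raw-scale variances covering every
#'   feature; default: the column variances of \code{table} itself.
#' @return list: \code{table} (pruned) and \code{report}
#'   ([ReductionReport-class] whose diagnostics give each feature's
#'   component and maximum within-component |r|).
#' @export
correlationPrune <- function(table, threshold = 0.95, variability = NULL) {
  stopifnot(is(table, "FeatureTable"))
  m <- as.matrix(table)
  if (nrow(m) < 3L) stop("need at least 3 patients", call. = FALSE)
  if (threshold <= 0 || threshold > 1)
    stop("threshold must lie in (0, 1]", call. = FALSE)
  feats <- colnames(m)
  if (is.null(variability)) variability <- apply(m, 2, stats::var)
  if (!all(feats %in% names(variability)))
    stop("variability vector does not cover all features", call. = FALSE)
  variability <- variability[feats]
  r <- suppressWarnings(stats::cor(m))
  r[is.na(r)] <- 0
  adj <- abs(r) > threshold
  diag(adj) <- FALSE
  comp <- connComponents(adj)
  keep <- logical(ncol(m))
  for (cid in unique(comp)) {
    members <- which(comp == cid)
    # ties on variance: earliest column index wins (which.max does that)
    keep[members[which.max(variability[members])]] <- TRUE
  }
  maxR <- vapply(seq_len(ncol(m)), function(j) {
    others <- which(comp == comp[j] & seq_len(ncol(m)) != j)
    if (length(others)) max(abs(r[j, others])) else 0
  }, numeric(1))
  rep <- new("ReductionReport", stage = "correlation",
             inputFeatures = feats, retainedFeatures = feats[keep],
             diagnostics = data.frame(feature = feats, component = comp,
                                      variance = as.numeric(variability),
                                      max_within_component_r = maxR,
                                      retained = keep, row.names = NULL),
             thresholds = list(correlationThreshold = threshold))
  list(table = featureTable(m[, keep, drop = FALSE]), report = rep)
}

# R^2 of regressing column j on all other columns; rank-aware QR so wide
# or collinear designs are handled (fitted values are unique regardless).
regressR2 <- function(m, j) {
  y <- m[, j]
  X <- cbind(1, m[, -j, drop = FALSE])
  fit <- qr.fitted(qr(X), y)
  sst <- sum((y - mean(y))^2)
  if (sst == 0) return(0)
  max(0, 1 - sum((y - fit)^2) / sst)
}

#' Variance inflation factor of one feature
#'
#' VIF = 1 / (1 - R^2), where R^2 comes from the least-squares regression
#' of the feature on all other features (rank-aware, so wide tables are
#' handled). Features that are perfectly collinear with the rest
#' (R^2 >= 1 - 1e-12) report +Inf. A single-feature table has VIF 1.
#'
#' @param table a [FeatureTable-class], standardized.
#' @param feature feature name or column index.
#' @return the VIF value.
#' @export
computeVif <- function(table, feature) {
  stopifnot(is(table, "FeatureTable"))
  m <- as.matrix(table)
  if (is.character(feature)) {
    j <- match(feature, colnames(m))
    if (is.na(j)) stop("unknown feature: ", feature, call. = FALSE)
  } else j <- as.integer(feature)
  if (ncol(m) == 1L) return(1)
  r2 <- regressR2(m, j)
  if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
}

# all VIFs at once; via the inverse correlation matrix when well
# conditioned (diag(solve(R)) equals 1/(1-R^2_j) for standardized data),
# else per-feature QR regressions.
allVifs <- function(m) {
  p <- ncol(m)
  if (p == 1L) return(stats::setNames(1, colnames(m)))
  vifs <- rep(NA_real_, p)
  R <- suppressWarnings(stats::cor(m))
  ok <- !anyNA(R) && nrow(m) > p
  if (ok) {
    rc <- rcond(R)
    if (is.finite(rc) && rc > 1e-10) {
      v <- diag(solve(R))
      v[v < 1] <- 1
      vifs <- v
      ok <- TRUE
    } else ok <- FALSE
  }
  if (!ok || anyNA(vifs)) {
    for (j in seq_len(p)) {
      r2 <- regressR2(m, j)
      vifs[j] <- if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
    }
  }
  stats::setNames(vifs, colnames(m))
}

#' Iteratively prune features by variance inflation factor
#'
#' While any feature's VIF exceeds \code{vifMax}, removes the feature with
#' the largest VIF (+Inf first; ties toward the earliest column) and
#' recomputes. On exit every retained feature has VIF <= \code{vifMax},
#' re-verified by a final recomputation.
#'
#' @param table a [FeatureTable-class], standardized.
#' @param vifMax largest acceptable VIF (default 10).
#' @return list: \code{table} (pruned) and \code{report}
#'   ([ReductionReport-class]; diagnostics give the VIF at removal for
#'   pruned features and the final VIF for retained ones).
#' @export
vifPrune <- function(table, vifMax = 10) {
  stopifnot(is(table, "FeatureTable"))
  m <- as.matrix(table)
  feats <- colnames(m)
  removalVif <- stats::setNames(rep(NA_real_, length(feats)), feats)
  repeat {
    vifs <- allVifs(m)
    worst <- which.max(vifs)   # ties and Inf -> earliest index
    if (!is.finite(vifs[worst]) || vifs[worst] > vifMax) {
      removalVif[colnames(m)[worst]] <- vifs[worst]
      m <- m[, -worst, drop = FALSE]
      if (ncol(m) == 0L)
        stop("VIF pruning removed every feature", call. = FALSE)
    } else break
  }
  finalVifs <- allVifs(m)
  stopifnot(all(finalVifs <= vifMax + 1e-8))   # postcondition, re-verified
  diag <- data.frame(feature = feats,
                     retained = feats %in% colnames(m),
                     vif = ifelse(feats %in% colnames(m),
                                  finalVifs[feats], removalVif[feats]),
                     row.names = NULL)
  rep <- new("ReductionReport", stage = "vif",
             inputFeatures = feats, retainedFeatures = colnames(m),
             diagnostics = diag, thresholds = list(vifMax = vifMax))
  list(table = featureTable(m), report = rep)
}

#' Reduce to principal components covering a variance fraction
#'
#' PCA on the covariance of the (already standardized) table — i.e.
#' correlation PCA. The explained-variance ratio of a component is its
#' eigenvalue over the trace; k is the smallest component count whose
#' cumulative ratio reaches \code{varianceFraction}. Returns the k score
#' columns (named PC1..PCk) and the loadings in the report.
#'
#' @param table a [FeatureTable-class], standardized, >= 2 patients.
#' @param varianceFraction cumulative explained-variance target in (0, 1].
#' @return list: \code{table} (component scores as a
#'   [FeatureTable-class]) and \code{report} ([ReductionReport-class] with
#'   loadings and explained-variance ratios in \code{extra}).
#' @export
pcaReduce <- function(table, varianceFraction = 0.95) {
  stopifnot(is(table, "FeatureTable"))
  m <- as.matrix(table)
  if (nrow(m) < 2L) stop("need at least 2 patients", call. = FALSE)
  if (varianceFraction <= 0 || varianceFraction > 1)
    stop("varianceFraction must lie in (0, 1]", call. = FALSE)
  pc <- stats::prcomp(m, center = TRUE, scale. = FALSE)
  eig <- pc$sdev^2
  if (sum(eig) == 0) stop("degenerate input: zero total variance",
                          call. = FALSE)
  ratio <- eig / sum(eig)
  k <- which(cumsum(ratio) >= varianceFraction - 1e-12)[1L]
  scores <- pc$x[, seq_len(k), drop = FALSE]
  rownames(scores) <- rownames(m)
  rep <- new("ReductionReport", stage = "pca",
             inputFeatures = colnames(m), retainedFeatures = colnames(scores),
             diagnostics = data.frame(component = colnames(pc$x),
                                      explained_variance_ratio = ratio,
                                      cumulative = cumsum(ratio),
                                      retained = seq_along(ratio) <= k,
                                      row.names = NULL),
             thresholds = list(pcaVarianceFraction = varianceFraction),
             extra = list(loadings = pc$rotation[, seq_len(k), drop = FALSE],
                          center = pc$center))
  list(table = featureTable(scores), report = rep)
}

#' Per-feature univariate p-values against survival
#'
#' For every feature, the two-sided p-value of the t-test on the slope of
#' the simple least-squares regression of survival days on that feature
#' (equivalently, the Pearson correlation test on n - 2 degrees of
#' freedom).
#'
#' @param table a [FeatureTable-class], >= 4 patients.
#' @param survivalDays positive numeric of length nrow(table).
#' @return named numeric vector of p-values.
#' @export
univariatePvalues <- function(table, survivalDays) {
  stopifnot(is(table, "FeatureTable"))
  m <- as.matrix(table)
  n <- nrow(m)
  if (n < 4L) stop("need at least 4 patients (insufficient df)",
                   call. = FALSE)
  if (length(survivalDays) != n)
    stop("survivalDays length does not match table", call. = FALSE)
  if (stats::sd(survivalDays) == 0)
    stop("survival is constant", call. = FALSE)
  sds <- apply(m, 2, stats::sd)
  if (any(sds == 0))
    stop("constant feature(s): ",
         paste(colnames(m)[sds == 0], collapse = ", "), call. = FALSE)
  r <- drop(stats::cor(m, survivalDays))
  r <- clip(r, -1, 1)
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  p[abs(r) >= 1 - 1e-15] <- 0
  stats::setNames(p, colnames(m))
}

#' Benjamini-Hochberg step-up selection
#'
#' Sorts the p-values ascending, finds the largest rank i with
#' \eqn{p_{(i)} \le (i / m) \alpha}, and selects every feature with
#' \eqn{p \le p_{(i)}}; when no rank qualifies the selection is empty.
#' Controls the false discovery rate at level alpha.
#'
#' @param pvalues numeric p-values in \[0, 1\] (names kept if present).
#' @param alpha FDR level in (0, 1), default 0.05.
#' @return integer indices of the selected features (named when
#'   \code{pvalues} is).
#' @examples
#' bhSelect(c(0.001, 0.2, 0.04, 0.9), alpha = 0.05)
#' @export
bhSelect <- function(pvalues, alpha = 0.05) {
  if (any(!is.finite(pvalues)) || any(pvalues < 0) || any(pvalues > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)",
                                     call. = FALSE)
  m <- length(pvalues)
  ord <- order(pvalues)
  ps <- pvalues[ord]
  ok <- which(ps <= seq_len(m) / m * alpha)
  if (!length(ok)) return(integer())
  cut <- ps[max(ok)]
  sel <- which(pvalues <= cut)
  if (!is.null(names(pvalues))) names(sel) <- names(pvalues)[sel]
  sel
}

#' Run the full feature-reduction cascade
#'
#' Fixed stage order: standardize, correlation pruning (variability judged
#' on the raw input variances), VIF pruning, then two parallel final
#' subsets — the VIF-selected features themselves and their principal
#' components — each filtered by univariate slope tests with
#' Benjamini-Hochberg selection against survival days.
#'
#' @param table raw [FeatureTable-class].
#' @param survivalDays positive numeric aligned with the table rows.
#' @param config a [PipelineConfig-class] supplying every threshold.
#' @return list: \code{vifTable}, \code{pcaTable} (reduced
#'   [FeatureTable-class]s), \code{vifSelected}, \code{pcaSelected}
#'   (BH-selected feature names), \code{reports} (list of
#'   [ReductionReport-class] per stage).
#' @export
reduceFeatures <- function(table, survivalDays, config = pipelineConfig()) {
  stopifnot(is(table, "FeatureTable"), is(config, "PipelineConfig"))
  rawVar <- apply(as.matrix(table), 2, stats::var)
  std <- standardizeFeatures(table)
  stageLog("reduce", "standardize: %d -> %d features",
           ncol(table), ncol(std$table))
  cp <- correlationPrune(std$table, config@correlationThreshold,
                         variability = rawVar)
  stageLog("reduce", "correlation: %d -> %d features",
           ncol(std$table), ncol(cp$table))
  vp <- vifPrune(cp$table, config@vifMax)
  stageLog("reduce", "vif: %d -> %d features", ncol(cp$table), ncol(vp$table))
  pca <- pcaReduce(vp$table, config@pcaVarianceFraction)
  stageLog("reduce", "pca: %d -> %d components",
           ncol(vp$table), ncol(pca$table))

  selectStage <- function(tab, stage) {
    p <- univariatePvalues(tab, survivalDays)
    sel <- bhSelect(p, config@bhAlpha)
    rep <- new("ReductionReport", stage = stage,
               inputFeatures = featureNames(tab),
               retainedFeatures = featureNames(tab)[sel],
               diagnostics = data.frame(feature = featureNames(tab),
                                        p_value = as.numeric(p),
                                        selected = seq_along(p) %in% sel,
                                        row.names = NULL),
               thresholds = list(bhAlpha = config@bhAlpha))
    list(selected = featureNames(tab)[sel], report = rep)
  }
  bhVif <- selectStage(vp$table, "bh_vif")
  bhPca <- selectStage(pca$table, "bh_pca")
  stageLog("reduce", "BH selection: %d of %d VIF features, %d of %d PCs",
           length(bhVif$selected), ncol(vp$table),
           length(bhPca$selected), ncol(pca$table))
  list(vifTable = vp$table, pcaTable = pca$table,
       vifSelected = bhVif$selected, pcaSelected = bhPca$selected,
       reports = list(standardize = std$report, correlation = cp$report,
                      vif = vp$report, pca = pca$report,
                      bh_vif = bhVif$report, bh_pca = bhPca$report))
}
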