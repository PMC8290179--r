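#' @import methods
NULL

BRATS_LABELS <- c(0L, 1L, 2L, 4L)

#' Labeled segmentation volume
#'
#' A 3D integer label grid following the BraTS convention (0 background,
#' 1 necrotic/non-enhancing core, 2 edema, 4 enhancing tumor), together with
#' the per-axis voxel spacing in millimetres and an axes tag recording the
#' anatomical meaning of each array axis. The default convention is axial
#' slicing along the third array axis, with axis 1 longitudinal and axis 2
#' transverse within a slice.
#'
#' @slot voxels 3D integer array of labels.
#' @slot spacing numeric(3), voxel size per axis in mm, all > 0.
#' @slot axes character(3) tag naming the axes.
#' @exportClass LabeledVolume
setClass("LabeledVolume",
  representation(voxels = "array", spacing = "numeric", axes = "character"),
  prototype(spacing = c(1, 1, 1),
            axes = c("longitudinal", "transverse", "axial")))

setValidity("LabeledVolume", function(object) {
  msg <- character()
  if (length(dim(object@voxels)) != 3L)
    msg <- c(msg, "voxels must be a 3D array")
  if (any(dim(object@voxels) < 1L))
    msg <- c(msg, "every axis must have extent >= 1")
  bad <- setdiff(unique(as.vector(object@voxels)), BRATS_LABELS)
  if (length(bad))
    msg <- c(msg, paste0("labels outside {0,1,2,4}: ",
                         paste(sort(bad), collapse = ", ")))
  if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
      any(object@spacing <= 0))
    msg <- c(msg, "spacing must be three positive finite values")
  if (length(object@axes) != 3L)
    msg <- c(msg, "axes tag must have three entries")
  if (length(msg)) msg else TRUE
})

#' Intensity volume
#'
#' A 3D real-valued image (arbitrary intensity units) with voxel spacing in
#' mm and the same axes tag as [LabeledVolume-class]. Values must be finite.
#'
#' @slot voxels 3D numeric array.
#' @slot spacing numeric(3), voxel size per axis in mm.
#' @slot axes character(3) axes tag.
#' @exportClass IntensityVolume
setClass("IntensityVolume",
  representation(voxels = "array", spacing = "numeric", axes = "character"),
  prototype(spacing = c(1, 1, 1),
            axes = c("longitudinal", "transverse", "axial")))

setValidity("IntensityVolume", function(object) {
  msg <- character()
  if (length(dim(object@voxels)) != 3L)
    msg <- c(msg, "voxels must be a 3D array")
  if (any(!is.finite(object@voxels)))
    msg <- c(msg, "intensity values must all be finite")
  if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
      any(object@spacing <= 0))
    msg <- c(msg, "spacing must be three positive finite values")
  if (length(msg)) msg else TRUE
})

#' Patient cohort table
#'
#' Per-patient clinical data: unique patient id, age in years (may be NA),
#' overall survival in days (positive integer), resection status
#' (\code{"GTR"} or \code{"NA"}; subtotal resection \code{"STR"} only when
#' explicitly allowed at load time), and the derived binary survival class
#' (\code{"short"} / \code{"long"} around the dichotomization cutoff).
#'
#' @slot data data.frame with columns patient_id, age, survival_days,
#'   resection_status, survival_class.
#' @slot metadata list; carries e.g. the rows rejected at load time and the
#'   cutoff used to derive the class.
#' @exportClass CohortTable
setClass("CohortTable",
  representation(data = "data.frame", metadata = "list"),
  prototype(metadata = list()))

setValidity("CohortTable", function(object) {
  d <- object@data
  msg <- character()
  need <- c("patient_id", "age", "survival_days", "resection_status",
            "survival_class")
  if (!all(need %in% names(d)))
    return(paste("cohort data must have columns:", paste(need, collapse = ", ")))
  if (anyDuplicated(d$patient_id))
    msg <- c(msg, "duplicate patient ids")
  if (nrow(d) && (any(!is.finite(d$survival_days)) || any(d$survival_days < 1)))
    msg <- c(msg, "survival_days must be >= 1")
  ok_status <- c("GTR", "NA", "STR")
  if (nrow(d) && !all(d$resection_status %in% ok_status))
    msg <- c(msg, "resection_status must be one of GTR, NA, STR")
  if (nrow(d) && !all(d$survival_class %in% c("short", "long")))
    msg <- c(msg, "survival_class must be short or long")
  if (length(msg)) msg else TRUE
})

#' Patients x features numeric matrix
#'
#' A wide feature table: rows are patients (rownames are patient ids),
#' columns are named features. All values are finite; feature names are
#' unique.
#'
#' @slot values numeric matrix with rownames (patient ids) and unique
#'   colnames (feature names).
#' @exportClass FeatureTable
setClass("FeatureTable", representation(values = "matrix"))

setValidity("FeatureTable", function(object) {
  v <- object@values
  msg <- character()
  if (!is.numeric(v)) msg <- c(msg, "values must be numeric")
  if (is.null(rownames(v))) msg <- c(msg, "rownames (patient ids) required")
  if (is.null(colnames(v))) msg <- c(msg, "colnames (feature names) required")
  if (!is.null(colnames(v)) && anyDuplicated(colnames(v)))
    msg <- c(msg, "duplicate feature names")
  if (!is.null(rownames(v)) && anyDuplicated(rownames(v)))
    msg <- c(msg, "duplicate patient ids")
  if (any(!is.finite(v))) msg <- c(msg, "all values must be finite")
  if (length(msg)) msg else TRUE
})

#' Pipeline configuration
#'
#' Holds every tunable threshold of the analysis with the defaults used
#' throughout: correlation pruning at |r| > 0.95, maximum VIF 10, PCA
#' retaining 95% of variance, Benjamini-Hochberg level 0.05, survival
#' dichotomization at 450 days, 5-fold cross-validation.
#'
#' @slot correlationThreshold numeric in (0, 1].
#' @slot vifMax numeric > 1.
#' @slot pcaVarianceFraction numeric in (0, 1].
#' @slot bhAlpha numeric in (0, 1).
#' @slot survivalCutoffDays numeric > 0.
#' @slot cvFolds integer >= 2.
#' @slot randomSeed integer.
#' @slot tumorLabels integer labels defining the tumor mask (default whole
#'   tumor \{1, 2, 4\}).
#' @slot annHidden,annMaxit,rfTrees,knnK learner hyperparameters (fixed so
#'   runs are reproducible; overridable here).
#' @exportClass PipelineConfig
setClass("PipelineConfig",
  representation(correlationThreshold = "numeric", vifMax = "numeric",
                 pcaVarianceFraction = "numeric", bhAlpha = "numeric",
                 survivalCutoffDays = "numeric", cvFolds = "integer",
                 randomSeed = "integer", tumorLabels = "integer",
                 annHidden = "integer", annMaxit = "integer",
                 rfTrees = "integer", knnK = "integer"),
  prototype(correlationThreshold = 0.95, vifMax = 10,
            pcaVarianceFraction = 0.95, bhAlpha = 0.05,
            survivalCutoffDays = 450, cvFolds = 5L, randomSeed = 1L,
            tumorLabels = c(1L, 2L, 4L), annHidden = 16L, annMaxit = 1000L,
            rfTrees = 100L, knnK = 5L))

setValidity("PipelineConfig", function(object) {
  msg <- character()
  if (!(object@correlationThreshold > 0 && object@correlationThreshold <= 1))
    msg <- c(msg, "correlationThreshold must be in (0, 1]")
  if (object@vifMax <= 1) msg <- c(msg, "vifMax must be > 1")
  if (!(object@pcaVarianceFraction > 0 && object@pcaVarianceFraction <= 1))
    msg <- c(msg, "pcaVarianceFraction must be in (0, 1]")
  if (!(object@bhAlpha > 0 && object@bhAlpha < 1))
    msg <- c(msg, "bhAlpha must be in (0, 1)")
  if (object@survivalCutoffDays <= 0)
    msg <- c(msg, "survivalCutoffDays must be > 0")
  if (object@cvFolds < 2L) msg <- c(msg, "cvFolds must be >= 2")
  if (length(msg)) msg else TRUE
})

#' Ellipsoidal tumor phantom specification
#'
#' Concentric ellipsoidal shells centred at \code{center} with outer semi-axes
#' \code{radii} (voxels). Each shell is the outer ellipsoid scaled by a
#' fraction; a voxel takes the label of the innermost shell containing it.
#' The default shells emulate the BraTS sub-region structure: necrotic core
#' (label 1) inside enhancing tumor (label 4) inside edema (label 2).
#'
#' @slot center numeric(3) voxel coordinates (array indices).
#' @slot radii numeric(3) outer semi-axes in voxels, all > 0.
#' @slot shellFractions increasing numeric vector in (0, 1], one per shell.
#' @slot shellLabels integer labels, innermost first.
#' @exportClass TumorSpec
setClass("TumorSpec",
  representation(center = "numeric", radii = "numeric",
                 shellFractions = "numeric", shellLabels = "integer"),
  prototype(shellFractions = c(0.4, 0.7, 1.0), shellLabels = c(1L, 4L, 2L)))

setValidity("TumorSpec", function(object) {
  msg <- character()
  if (length(object@center) != 3L) msg <- c(msg, "center must have length 3")
  if (length(object@radii) != 3L || any(object@radii <= 0))
    msg <- c(msg, "radii must be three positive values")
  if (length(object@shellFractions) != length(object@shellLabels))
    msg <- c(msg, "one label per shell required")
  if (is.unsorted(object@shellFractions, strictly = TRUE) ||
      any(object@shellFractions <= 0) || any(object@shellFractions > 1))
    msg <- c(msg, "shellFractions must be strictly increasing in (0, 1]")
  if (!all(object@shellLabels %in% c(1L, 2L, 4L)))
    msg <- c(msg, "shell labels must be in {1, 2, 4}")
  if (length(msg)) msg else TRUE
})

#' Noisy linear survival model for synthetic cohorts
#'
#' Survival days are generated as
#' \code{round(clip(intercept + sum(coef_i * feature_i) + eps))} with
#' Gaussian noise \code{eps} of standard deviation \code{noiseSD}, clipped
#' to \code{clipRange} (default 3 to 1767 days, the observed range in the
#' BraTS 2019 glioblastoma training cohort).
#'
#' @slot intercept numeric, days.
#' @slot coefficients named numeric, days per unit of each location feature.
#' @slot noiseSD numeric >= 0, days.
#' @slot clipRange numeric(2) within \[1, Inf).
#' @exportClass SurvivalModelSpec
setClass("SurvivalModelSpec",
  representation(intercept = "numeric", coefficients = "numeric",
                 noiseSD = "numeric", clipRange = "numeric"),
  prototype(noiseSD = 0, clipRange = c(3, 1767)))

setValidity("SurvivalModelSpec", function(object) {
  msg <- character()
  if (object@noiseSD < 0) msg <- c(msg, "noiseSD must be >= 0")
  if (length(object@clipRange) != 2L || object@clipRange[1] < 1 ||
      diff(object@clipRange) < 0)
    msg <- c(msg, "clipRange must be an ordered pair within [1, Inf)")
  if (length(object@coefficients) &&
      is.null(names(object@coefficients)))
    msg <- c(msg, "coefficients must be named by feature")
  if (length(msg)) msg else TRUE
})

#' The four tumor location features of one patient
#'
#' \code{sliceIndex} is the axial slice with the largest in-plane tumor
#' diameter (ties broken toward the smaller index); \code{diameterMM} is
#' that maximal diameter in mm; \code{xOffsetMM} / \code{yOffsetMM} are the
#' signed longitudinal / transverse offsets (mm) of the tumor centroid from
#' the brain-mask centroid on that slice, positive toward increasing array
#' index.
#'
#' @slot sliceIndex integer >= 1.
#' @slot diameterMM numeric >= 0.
#' @slot xOffsetMM,yOffsetMM finite numeric.
#' @exportClass LocationFeatureSet
setClass("LocationFeatureSet",
  representation(sliceIndex = "integer", diameterMM = "numeric",
                 xOffsetMM = "numeric", yOffsetMM = "numeric"))

setValidity("LocationFeatureSet", function(object) {
  msg <- character()
  if (object@sliceIndex < 1L) msg <- c(msg, "sliceIndex must be >= 1")
  if (object@diameterMM < 0) msg <- c(msg, "diameterMM must be >= 0")
  if (!is.finite(object@xOffsetMM) || !is.finite(object@yOffsetMM))
    msg <- c(msg, "offsets must be finite")
  if (length(msg)) msg else TRUE
})

#' Z-score normalization statistics
#'
#' The mean and population standard deviation actually used by
#' [zscoreNormalize()], plus a description of the voxels they were computed
#' over, sufficient to reproduce (or invert) the transform.
#'
#' @slot mu,sigma numeric; sigma > 0.
#' @slot maskDescription character.
#' @slot nVoxels integer, voxels in scope.
#' @exportClass NormalizationStats
setClass("NormalizationStats",
  representation(mu = "numeric", sigma = "numeric",
                 maskDescription = "character", nVoxels = "integer"))

#' Report of one feature-reduction stage
#'
#' Records what a stage consumed, what survived and why: stage name, input
#' and retained feature names (for PCA, component names), a per-feature
#' diagnostics data.frame (correlation partner, VIF, p-value, as
#' applicable), and the thresholds applied.
#'
#' @slot stage character.
#' @slot inputFeatures,retainedFeatures character vectors.
#' @slot diagnostics data.frame.
#' @slot thresholds named list echoing the configuration.
#' @slot extra list, stage-specific payloads (e.g. PCA loadings).
#' @exportClass ReductionReport
setClass("ReductionReport",
  representation(stage = "character", inputFeatures = "character",
                 retainedFeatures = "character", diagnostics = "data.frame",
                 thresholds = "list", extra = "list"),
  prototype(diagnostics = data.frame(), thresholds = list(), extra = list()))

setValidity("ReductionReport", function(object) {
  if (object@stage != "pca" &&
      !all(object@retainedFeatures %in% object@inputFeatures))
    return("retained features must be a subset of input features")
  TRUE
})

#' Cross-validated regression metrics
#'
#' Out-of-fold performance of a univariate survival regressor: Spearman R
#' between pooled out-of-fold predictions and observed days, mean squared
#' error (days^2), median and mean absolute error (days), and the two-sided
#' p-value of the Spearman correlation test.
#'
#' @slot spearmanR numeric in \[-1, 1\].
#' @slot mse,medianAE,meanAE numeric >= 0.
#' @slot pValue numeric in \[0, 1\].
#' @slot model character, one of LR/RFR/SVR.
#' @exportClass RegressionMetrics
setClass("RegressionMetrics",
  representation(spearmanR = "numeric", mse = "numeric", medianAE = "numeric",
                 meanAE = "numeric", pValue = "numeric", model = "character"))

setValidity("RegressionMetrics", function(object) {
  msg <- character()
  if (is.finite(object@spearmanR) && abs(object@spearmanR) > 1 + 1e-12)
    msg <- c(msg, "spearmanR must lie in [-1, 1]")
  if (any(c(object@mse, object@medianAE, object@meanAE) < 0))
    msg <- c(msg, "errors must be >= 0")
  if (is.finite(object@pValue) && (object@pValue < 0 || object@pValue > 1))
    msg <- c(msg, "pValue must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' Pooled-confusion classification metrics
#'
#' Accuracy, precision, sensitivity and specificity derived from pooled
#' out-of-fold confusion counts. A ratio with zero denominator is reported
#' as NaN and named in \code{undefined} — never silently zero. The positive
#' class is "short" survival (< cutoff days).
#'
#' @slot accuracy,precision,sensitivity,specificity numeric in \[0, 1\] or NaN.
#' @slot tp,fp,tn,fn integer counts >= 0.
#' @slot undefined character, names of undefined metrics.
#' @slot model character, one of ANN/RFC/KNN (or "" for raw counts).
#' @exportClass ClassificationMetrics
setClass("ClassificationMetrics",
  representation(accuracy = "numeric", precision = "numeric",
                 sensitivity = "numeric", specificity = "numeric",
                 tp = "integer", fp = "integer", tn = "integer",
                 fn = "integer", undefined = "character", model = "character"),
  prototype(undefined = character(), model = ""))

setValidity("ClassificationMetrics", function(object) {
  counts <- c(object@tp, object@fp, object@tn, object@fn)
  msg <- character()
  if (any(counts < 0L)) msg <- c(msg, "confusion counts must be >= 0")
  if (sum(counts) == 0L) msg <- c(msg, "confusion counts must not all be zero")
  for (m in c("accuracy", "precision", "sensitivity", "specificity")) {
    v <- slot(object, m)
    if (!is.nan(v) && (v < 0 || v > 1))
      msg <- c(msg, paste(m, "must lie in [0, 1]"))
  }
  if (length(msg)) msg else TRUE
})

#' Provenance manifest of one pipeline run
#'
#' Everything needed to audit and re-run a pipeline execution
#' bit-identically: the configuration snapshot, md5 digests of every input
#' file, the per-stage reduction reports, the paths of every output
#' written, the seed and timestamps.
#'
#' @slot config [PipelineConfig-class] snapshot.
#' @slot inputs named character, md5 digest per input path.
#' @slot reports list of [ReductionReport-class] per stratum.
#' @slot outputs character, files written.
#' @slot seed integer.
#' @slot started,finished character timestamps.
#' @exportClass RunManifest
setClass("RunManifest",
  representation(config = "PipelineConfig", inputs = "character",
                 reports = "list", outputs = "character", seed = "integer",
                 started = "character", finished = "character"))
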