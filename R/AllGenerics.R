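#' @name accessors
#' @title Accessors for TumorLoc objects
#' @description Slot access for the package's S4 containers. Use these
#'   rather than `@`.
#' @param x an object of the documented class.
#' @return the slot value.
NULL

#' @rdname accessors
#' @export
setGeneric("voxels", function(x) standardGeneric("voxels"))

#' @rdname accessors
#' @export
setGeneric("spacing", function(x) standardGeneric("spacing"))

#' @rdname accessors
#' @export
setGeneric("axesTag", function(x) standardGeneric("axesTag"))

#' @rdname accessors
#' @export
setGeneric("patientIds", function(x) standardGeneric("patientIds"))

#' @rdname accessors
#' @export
setGeneric("featureNames", function(x) standardGeneric("featureNames"))

#' @rdname accessors
#' @export
setGeneric("survivalDays", function(x) standardGeneric("survivalDays"))

#' @rdname accessors
#' @export
setGeneric("resectionStatus", function(x) standardGeneric("resectionStatus"))

#' @rdname accessors
#' @export
setGeneric("survivalClass", function(x) standardGeneric("survivalClass"))

#' @rdname accessors
#' @export
setGeneric("retainedFeatures", function(x) standardGeneric("retainedFeatures"))

#' @rdname accessors
#' @export
setGeneric("metadata", function(x) standardGeneric("metadata"))

setMethod("voxels", "LabeledVolume", function(x) x@voxels)
setMethod("voxels", "IntensityVolume", function(x) x@voxels)
setMethod("spacing", "LabeledVolume", function(x) x@spacing)
setMethod("spacing", "IntensityVolume", function(x) x@spacing)
setMethod("axesTag", "LabeledVolume", function(x) x@axes)
setMethod("axesTag", "IntensityVolume", function(x) x@axes)

#' @exportMethod dim
setMethod("dim", "LabeledVolume", function(x) dim(x@voxels))
setMethod("dim", "IntensityVolume", function(x) dim(x@voxels))
setMethod("dim", "FeatureTable", function(x) dim(x@values))

setMethod("patientIds", "FeatureTable", function(x) rownames(x@values))
setMethod("patientIds", "CohortTable", function(x) x@data$patient_id)
setMethod("featureNames", "FeatureTable", function(x) colnames(x@values))
setMethod("survivalDays", "CohortTable", function(x) x@data$survival_days)
setMethod("resectionStatus", "CohortTable", function(x) x@data$resection_status)
setMethod("survivalClass", "CohortTable", function(x) x@data$survival_class)
setMethod("retainedFeatures", "ReductionReport", function(x) x@retainedFeatures)
setMethod("metadata", "CohortTable", function(x) x@metadata)

#' @describeIn accessors the feature matrix of a [FeatureTable-class].
#' @param ... ignored.
#' @export
as.matrix.FeatureTable <- function(x, ...) x@values

#' @exportMethod as.matrix
setMethod("as.matrix", "FeatureTable", as.matrix.FeatureTable)

#' @describeIn accessors the cohort as a base data.frame.
#' @param row.names,optional passed through (unused).
#' @export
as.data.frame.CohortTable <- function(x, row.names = NULL, optional = FALSE,
                                      ...) {
  x@data
}

#' @exportMethod as.data.frame
setMethod("as.data.frame", "CohortTable", as.data.frame.CohortTable)

#' @exportMethod show
setMethod("show", "LabeledVolume", function(object) {
  d <- dim(object@voxels)
  labs <- sort(unique(as.vector(object@voxels)))
  cat(sprintf("LabeledVolume %dx%dx%d, spacing %s mm, labels {%s}\n",
              d[1], d[2], d[3],
              paste(format(object@spacing), collapse = "x"),
              paste(labs, collapse = ",")))
})

setMethod("show", "IntensityVolume", function(object) {
  d <- dim(object@voxels)
  cat(sprintf("IntensityVolume %dx%dx%d, spacing %s mm, range [%.3g, %.3g]\n",
              d[1], d[2], d[3],
              paste(format(object@spacing), collapse = "x"),
              min(object@voxels), max(object@voxels)))
})

setMethod("show", "FeatureTable", function(object) {
  d <- dim(object@values)
  cat(sprintf("FeatureTable: %d patients x %d features\n", d[1], d[2]))
  if (d[2]) {
    shown <- utils::head(colnames(object@values), 5L)
    cat("  features: ", paste(shown, collapse = ", "),
        if (d[2] > 5L) ", ..." else "", "\n", sep = "")
  }
})

setMethod("show", "CohortTable", function(object) {
  d <- object@data
  cat(sprintf("CohortTable: %d patients (GTR %d, NA %d; short %d, long %d)\n",
              nrow(d), sum(d$resection_status == "GTR"),
              sum(d$resection_status == "NA"),
              sum(d$survival_class == "short"),
              sum(d$survival_class == "long")))
})

setMethod("show", "LocationFeatureSet", function(object) {
  cat(sprintf(
    "LocationFeatureSet: Slice %d, Diameter %.2f mm, X %+.2f mm, Y %+.2f mm\n",
    object@sliceIndex, object@diameterMM, object@xOffsetMM, object@yOffsetMM))
})

setMethod("show", "ReductionReport", function(object) {
  cat(sprintf("ReductionReport [%s]: %d -> %d features\n", object@stage,
              length(object@inputFeatures), length(object@retainedFeatures)))
})

setMethod("show", "RegressionMetrics", function(object) {
  cat(sprintf(
    "RegressionMetrics [%s]: Spearman R %.3f, MSE %.1f, medianAE %.1f, meanAE %.1f, p %.3g\n",
    object@model, object@spearmanR, object@mse, object@medianAE,
    object@meanAE, object@pValue))
})

setMethod("show", "ClassificationMetrics", function(object) {
  cat(sprintf(
    "ClassificationMetrics [%s]: acc %.3f, prec %.3f, sens %.3f, spec %.3f (TP %d FP %d TN %d FN %d)\n",
    object@model, object@accuracy, object@precision, object@sensitivity,
    object@specificity, object@tp, object@fp, object@tn, object@fn))
  if (length(object@undefined))
    cat("  undefined:", paste(object@undefined, collapse = ", "), "\n")
})

setMethod("show", "PipelineConfig", function(object) {
  cat(sprintf(
    "PipelineConfig: |r|>%.2f, VIF<=%.1f, PCA %.0f%%, BH alpha %.2f, cutoff %g d, %d-fold CV, seed %d\n",
    object@correlationThreshold, object@vifMax,
    100 * object@pcaVarianceFraction, object@bhAlpha,
    object@survivalCutoffDays, object@cvFolds, object@randomSeed))
})

setMethod("show", "RunManifest", function(object) {
  cat(sprintf("RunManifest: seed %d, %d inputs, %d outputs, %s -> %s\n",
              object@seed, length(object@inputs), length(object@outputs),
              object@started, object@finished))
})
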