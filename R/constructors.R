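#' Construct a LabeledVolume
#'
#' @param voxels 3D array of integer labels in \{0, 1, 2, 4\}.
#' @param spacing voxel size per axis in mm (default 1 mm isotropic).
#' @param axes axes tag; default axial slicing along the third axis.
#' @return a [LabeledVolume-class].
#' @examples
#' v <- labeledVolume(array(0L, c(4, 4, 4)))
#' dim(v)
#' @export
labeledVolume <- function(voxels, spacing = c(1, 1, 1),
                          axes = c("longitudinal", "transverse", "axial")) {
  stopIfNot3D(voxels, "voxels")
  storage.mode(voxels) <- "integer"
  new("LabeledVolume", voxels = voxels, spacing = as.numeric(spacing),
      axes = axes)
}

#' Construct an IntensityVolume
#'
#' @param voxels 3D numeric array of finite intensities.
#' @param spacing voxel size per axis in mm.
#' @param axes axes tag.
#' @return an [IntensityVolume-class].
#' @export
intensityVolume <- function(voxels, spacing = c(1, 1, 1),
                            axes = c("longitudinal", "transverse", "axial")) {
  stopIfNot3D(voxels, "voxels")
  storage.mode(voxels) <- "double"
  new("IntensityVolume", voxels = voxels, spacing = as.numeric(spacing),
      axes = axes)
}

#' Construct a FeatureTable
#'
#' @param values patients x features numeric matrix; rownames are patient
#'   ids, colnames are feature names (both required and unique).
#' @return a [FeatureTable-class].
#' @examples
#' m <- matrix(rnorm(6), 2, 3,
#'             dimnames = list(c("p1", "p2"), c("f1", "f2", "f3")))
#' featureTable(m)
#' @export
featureTable <- function(values) {
  new("FeatureTable", values = as.matrix(values))
}

#' Construct a CohortTable
#'
#' Derives the binary survival class from the cutoff: days >= cutoff is
#' "long", otherwise "short".
#'
#' @param patient_id character ids, unique.
#' @param survival_days positive survival in days.
#' @param resection_status "GTR" or "NA" (or "STR" when allowed upstream).
#' @param age years; may be NA.
#' @param cutoff dichotomization cutoff in days (default 450).
#' @param metadata optional list (e.g. rejected rows from loading).
#' @return a [CohortTable-class].
#' @export
cohortTable <- function(patient_id, survival_days, resection_status,
                        age = NA_real_, cutoff = 450, metadata = list()) {
  n <- length(patient_id)
  d <- data.frame(
    patient_id = as.character(patient_id),
    age = rep_len(as.numeric(age), n),
    survival_days = as.numeric(survival_days),
    resection_status = as.character(resection_status),
    survival_class = if (n) dichotomizeSurvival(survival_days, cutoff)
                     else character(),
    stringsAsFactors = FALSE)
  metadata$cutoff <- cutoff
  new("CohortTable", data = d, metadata = metadata)
}

#' Construct a PipelineConfig
#'
#' @param correlationThreshold pairwise |Pearson r| above which features are
#'   clustered and pruned (default 0.95).
#' @param vifMax largest acceptable variance inflation factor (default 10).
#' @param pcaVarianceFraction cumulative explained-variance fraction the
#'   retained principal components must reach (default 0.95).
#' @param bhAlpha Benjamini-Hochberg false-discovery level (default 0.05).
#' @param survivalCutoffDays dichotomization cutoff (default 450 days).
#' @param cvFolds cross-validation folds (default 5).
#' @param randomSeed integer seed driving every stochastic step.
#' @param tumorLabels labels forming the tumor mask (default c(1, 2, 4),
#'   i.e. whole tumor).
#' @param annHidden,annMaxit,rfTrees,knnK learner hyperparameters.
#' @return a [PipelineConfig-class].
#' @export
pipelineConfig <- function(correlationThreshold = 0.95, vifMax = 10,
                           pcaVarianceFraction = 0.95, bhAlpha = 0.05,
                           survivalCutoffDays = 450, cvFolds = 5L,
                           randomSeed = 1L, tumorLabels = c(1L, 2L, 4L),
                           annHidden = 16L, annMaxit = 1000L,
                           rfTrees = 100L, knnK = 5L) {
  new("PipelineConfig",
      correlationThreshold = correlationThreshold, vifMax = vifMax,
      pcaVarianceFraction = pcaVarianceFraction, bhAlpha = bhAlpha,
      survivalCutoffDays = survivalCutoffDays, cvFolds = as.integer(cvFolds),
      randomSeed = as.integer(randomSeed),
      tumorLabels = as.integer(tumorLabels), annHidden = as.integer(annHidden),
      annMaxit = as.integer(annMaxit), rfTrees = as.integer(rfTrees),
      knnK = as.integer(knnK))
}

#' Read a PipelineConfig from a YAML file
#'
#' Unknown keys are rejected; missing keys take their defaults.
#'
#' @param path YAML file whose keys match the arguments of
#'   [pipelineConfig()].
#' @return a [PipelineConfig-class].
#' @export
readPipelineConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  vals <- yaml::read_yaml(path)
  known <- names(formals(pipelineConfig))
  bad <- setdiff(names(vals), known)
  if (length(bad))
    stop("unknown config keys: ", paste(bad, collapse = ", "), call. = FALSE)
  do.call(pipelineConfig, vals)
}

#' Construct a TumorSpec
#'
#' @param center ellipsoid center in voxel coordinates (array indices).
#' @param radii outer semi-axes in voxels, all > 0.
#' @param shellFractions increasing fractions of the outer ellipsoid, one
#'   per shell (default c(0.4, 0.7, 1)).
#' @param shellLabels labels innermost first (default c(1, 4, 2): necrotic
#'   core, enhancing tumor, edema).
#' @return a [TumorSpec-class].
#' @export
tumorSpec <- function(center, radii, shellFractions = c(0.4, 0.7, 1.0),
                      shellLabels = c(1L, 4L, 2L)) {
  new("TumorSpec", center = as.numeric(center), radii = as.numeric(radii),
      shellFractions = as.numeric(shellFractions),
      shellLabels = as.integer(shellLabels))
}

#' Construct a SurvivalModelSpec
#'
#' @param intercept baseline survival, days.
#' @param coefficients named numeric vector: days per unit of each location
#'   feature (names among Slice, Diameter, X, Y).
#' @param noiseSD Gaussian noise SD, days.
#' @param clipRange survival clipped to this range before rounding; the
#'   default c(3, 1767) matches the observed range of the BraTS 2019
#'   glioblastoma training cohort.
#' @return a [SurvivalModelSpec-class].
#' @export
survivalModelSpec <- function(intercept, coefficients = numeric(),
                              noiseSD = 0, clipRange = c(3, 1767)) {
  new("SurvivalModelSpec", intercept = as.numeric(intercept),
      coefficients = coefficients, noiseSD = as.numeric(noiseSD),
      clipRange = as.numeric(clipRange))
}

#' Construct a LocationFeatureSet
#'
#' @param sliceIndex axial index of the maximal-diameter slice.
#' @param diameterMM maximal in-plane diameter, mm.
#' @param xOffsetMM,yOffsetMM signed longitudinal/transverse offsets, mm.
#' @return a [LocationFeatureSet-class].
#' @export
locationFeatureSet <- function(sliceIndex, diameterMM, xOffsetMM, yOffsetMM) {
  new("LocationFeatureSet", sliceIndex = as.integer(sliceIndex),
      diameterMM = as.numeric(diameterMM), xOffsetMM = as.numeric(xOffsetMM),
      yOffsetMM = as.numeric(yOffsetMM))
}

#' Combine per-patient location features into a FeatureTable
#'
#' @param features named list of [LocationFeatureSet-class], names are
#'   patient ids.
#' @return a [FeatureTable-class] with columns Slice, Diameter, X, Y.
#' @export
locationFeatureTable <- function(features) {
  if (!length(features)) stop("empty feature list", call. = FALSE)
  if (is.null(names(features)))
    stop("features must be named by patient id", call. = FALSE)
  m <- t(vapply(features, function(f)
    c(Slice = as.numeric(f@sliceIndex), Diameter = f@diameterMM,
      X = f@xOffsetMM, Y = f@yOffsetMM), numeric(4)))
  featureTable(m)
}
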