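#' Run the end-to-end survival-prediction pipeline
#'
#' Orchestrates the five stages per resection stratum: (1) ingest (and
#' optionally z-score normalize intensity volumes), (2) extract location
#' features from each patient's segmentation, (3) ingest the externally
#' produced radiomic-style feature table, (4) run the reduction cascade,
#' (5) evaluate univariate regressors on each location feature and
#' multivariate classifiers on the reduced radiomic subsets with and
#' without location features. Metrics are written as CSV per stratum and a
#' JSON [RunManifest-class] records configuration, input digests, reports
#' and every output path, so a rerun with the same manifest reproduces the
#' outputs bit-identically.
#'
#' Strata with too few patients for cross-validation are skipped with a
#' warning (e.g. an all-GTR cohort yields no NA outputs).
#'
#' @param cohortPath cohort CSV (see [loadCohort()]).
#' @param featurePath radiomic feature CSV (see [loadFeatureTable()]).
#' @param locationPath optional CSV of precomputed location features with
#'   columns Slice, Diameter, X, Y. Alternatively supply
#'   \code{segmentationDir} with one \code{<patient_id>_seg.nii.gz} per
#'   patient to extract them here.
#' @param segmentationDir directory of segmentation NIfTIs (used when
#'   \code{locationPath} is NULL).
#' @param brainMask logical array used for every segmentation when
#'   extracting location features (default: nonzero labels' bounding
#'   sphere is not assumed — all voxels).
#' @param outDir output directory, created if missing.
#' @param config a [PipelineConfig-class].
#' @return a [RunManifest-class], invisibly; outputs on disk.
#' @export
runPipeline <- function(cohortPath, featurePath, locationPath = NULL,
                        segmentationDir = NULL, brainMask = NULL,
                        outDir = "tumorloc_out",
                        config = pipelineConfig()) {
  started <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  inputs <- c(cohort = cohortPath, features = featurePath)

  cohort <- loadCohort(cohortPath, cutoff = config@survivalCutoffDays)
  radiomics <- loadFeatureTable(featurePath)
  stageLog("ingest", "cohort %d patients, radiomics %d x %d",
           nrow(cohort@data), nrow(radiomics), ncol(radiomics))

  if (!is.null(locationPath)) {
    location <- loadFeatureTable(locationPath)
    inputs <- c(inputs, location = locationPath)
  } else if (!is.null(segmentationDir)) {
    ids <- patientIds(cohort)
    feats <- lapply(ids, function(id) {
      p <- file.path(segmentationDir, paste0(id, "_seg.nii.gz"))
      vol <- loadVolume(p, kind = "labels")
      bm <- if (is.null(brainMask)) array(TRUE, dim(vol)) else brainMask
      extractLocationFeatures(vol, tumorLabels = config@tumorLabels,
                              brainMask = bm)
    })
    names(feats) <- ids
    location <- locationFeatureTable(feats)
  } else {
    stop("supply either locationPath or segmentationDir", call. = FALSE)
  }
  stageLog("locate", "location features for %d patients", nrow(location))

  strata <- splitByResection(cohort)
  outputs <- character()
  reports <- list()
  for (status in names(strata)) {
    sub <- strata[[status]]
    ids <- patientIds(sub)
    if (length(ids) < 2L * config@cvFolds) {
      warning(sprintf("stratum %s has %d patients; too few for %d-fold CV, skipped",
                      status, length(ids), config@cvFolds))
      next
    }
    miss <- setdiff(ids, patientIds(radiomics))
    if (length(miss))
      stop("radiomic table lacks patients: ", paste(miss, collapse = ", "),
           call. = FALSE)
    rad <- featureTable(as.matrix(radiomics)[ids, , drop = FALSE])
    loc <- featureTable(as.matrix(location)[ids, , drop = FALSE])
    days <- survivalDays(sub)
    cls <- survivalClass(sub)

    red <- reduceFeatures(rad, days, config)
    reports[[status]] <- red$reports

    # univariate regressors per location feature
    regRows <- list()
    for (feat in featureNames(loc)) {
      for (mk in c("LR", "RFR", "SVR")) {
        rm_ <- regressUnivariate(as.matrix(loc)[, feat], days, mk,
                                 cvFolds = config@cvFolds,
                                 seed = config@randomSeed,
                                 rfTrees = config@rfTrees)
        regRows[[length(regRows) + 1L]] <- data.frame(
          status = status, feature = feat, model = mk,
          spearman_r = rm_@spearmanR, mse = rm_@mse,
          median_ae = rm_@medianAE, mean_ae = rm_@meanAE,
          p_value = rm_@pValue)
      }
    }
    regPath <- file.path(outDir, paste0("regression_", status, ".csv"))
    utils::write.csv(do.call(rbind, regRows), regPath, row.names = FALSE)
    outputs <- c(outputs, regPath)

    # multivariate classifiers on each subset, with and without location
    subsets <- list(vif = red$vifTable, pca = red$pcaTable)
    clsRows <- list()
    for (sn in names(subsets)) {
      base <- as.matrix(subsets[[sn]])
      locStd <- scale(as.matrix(loc))
      variants <- list(radiomics = base,
                       radiomics_location = cbind(base, locStd))
      for (vn in names(variants)) {
        tab <- featureTable(variants[[vn]])
        for (mk in c("ANN", "RFC", "KNN")) {
          cm <- classifyMultivariate(tab, cls, mk,
                                     cvFolds = config@cvFolds,
                                     seed = config@randomSeed,
                                     annHidden = config@annHidden,
                                     annMaxit = config@annMaxit,
                                     rfTrees = config@rfTrees,
                                     knnK = config@knnK)
          clsRows[[length(clsRows) + 1L]] <- data.frame(
            status = status, subset = sn, features = vn, model = mk,
            accuracy = cm@accuracy, precision = cm@precision,
            sensitivity = cm@sensitivity, specificity = cm@specificity,
            tp = cm@tp, fp = cm@fp, tn = cm@tn, fn = cm@fn)
        }
      }
    }
    clsPath <- file.path(outDir, paste0("classification_", status, ".csv"))
    utils::write.csv(do.call(rbind, clsRows), clsPath, row.names = FALSE)
    outputs <- c(outputs, clsPath)
    stageLog("models", "stratum %s: %d regression rows, %d classification rows",
             status, length(regRows), length(clsRows))
  }

  manifest <- new("RunManifest", config = config,
                  inputs = vapply(inputs, function(p)
                    unname(tools::md5sum(p)), character(1)),
                  reports = reports, outputs = outputs,
                  seed = config@randomSeed, started = started,
                  finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  manifestPath <- file.path(outDir, "manifest.json")
  writeManifest(manifest, manifestPath)
  stageLog("pipeline", "done; manifest at %s", manifestPath)
  invisible(manifest)
}

#' Serialize a RunManifest to JSON
#'
#' @param manifest a [RunManifest-class].
#' @param path destination JSON.
#' @return the path, invisibly.
#' @export
writeManifest <- function(manifest, path) {
  cfg <- manifest@config
  cfgList <- lapply(slotNames(cfg), function(s) slot(cfg, s))
  names(cfgList) <- slotNames(cfg)
  reports <- lapply(manifest@reports, function(stages)
    lapply(stages, function(r)
      list(stage = r@stage, n_input = length(r@inputFeatures),
           n_retained = length(r@retainedFeatures),
           retained = r@retainedFeatures, thresholds = r@thresholds)))
  jsonlite::write_json(
    list(config = cfgList, inputs = as.list(manifest@inputs),
         reports = reports, outputs = manifest@outputs,
         seed = manifest@seed, started = manifest@started,
         finished = manifest@finished),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
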