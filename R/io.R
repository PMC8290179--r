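#' Load a NIfTI volume
#'
#' Reads a 3D NIfTI image (.nii or .nii.gz) into a [LabeledVolume-class] or
#' [IntensityVolume-class]. Spacing is taken from the header; when the
#' header carries no spacing it falls back to 1 mm isotropic with a warning
#' (BraTS volumes are resampled to 1 mm). Label volumes are validated
#' against the BraTS label set \{0, 1, 2, 4\}.
#'
#' @param path path to a readable NIfTI file.
#' @param kind "labels" or "intensity".
#' @param axes axes tag to attach; remap for differently oriented files.
#' @return a [LabeledVolume-class] or [IntensityVolume-class].
#' @seealso [saveVolume()]
#' @export
loadVolume <- function(path, kind = c("labels", "intensity"),
                       axes = c("longitudinal", "transverse", "axial")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  img <- RNifti::readNifti(path)
  a <- array(as.vector(img), dim(img))
  if (length(dim(a)) == 4L && dim(a)[4] == 1L) a <- a[, , , 1L, drop = TRUE]
  if (length(dim(a)) != 3L)
    stop("not a 3D image: ", path, " (dims ",
         paste(dim(a), collapse = "x"), ")", call. = FALSE)
  sp <- RNifti::pixdim(img)[seq_len(3)]
  if (any(!is.finite(sp)) || any(sp <= 0)) {
    warning("header has no usable spacing; assuming 1 mm isotropic")
    sp <- c(1, 1, 1)
  }
  if (kind == "labels") {
    bad <- setdiff(unique(as.vector(a)), BRATS_LABELS)
    if (length(bad))
      stop("label volume ", path, " contains labels outside {0,1,2,4}: ",
           paste(sort(bad), collapse = ", "), call. = FALSE)
    labeledVolume(a, spacing = sp, axes = axes)
  } else {
    if (any(!is.finite(a)))
      stop("intensity volume contains non-finite values: ", path,
           call. = FALSE)
    intensityVolume(a, spacing = sp, axes = axes)
  }
}

#' Save a volume as NIfTI
#'
#' Round-trips losslessly through [loadVolume()]: integer labels exactly,
#' intensities to double precision.
#'
#' @param volume a [LabeledVolume-class] or [IntensityVolume-class].
#' @param path destination .nii or .nii.gz; the parent directory must exist.
#' @return the path, invisibly.
#' @export
saveVolume <- function(volume, path) {
  stopifnot(is(volume, "LabeledVolume") || is(volume, "IntensityVolume"))
  if (!dir.exists(dirname(path)))
    stop("directory does not exist: ", dirname(path), call. = FALSE)
  img <- RNifti::asNifti(voxels(volume))
  RNifti::pixdim(img) <- spacing(volume)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Load a patient cohort CSV
#'
#' Expects a header with columns \code{patient_id}, \code{age},
#' \code{survival_days}, \code{resection_status}. Rows whose resection
#' status is outside \{GTR, NA\} (e.g. STR) are rejected and reported via a
#' warning and the returned object's metadata, unless \code{allowSTR} is
#' set. The literal string "NA" in the status column means unknown
#' resection status, not a missing value.
#'
#' @param path CSV path (comma-separated, UTF-8, "." decimal).
#' @param cutoff survival dichotomization cutoff in days.
#' @param allowSTR admit rows with status "STR" instead of rejecting them.
#' @return a [CohortTable-class]; rejected rows in
#'   \code{metadata(x)$rejected}.
#' @export
loadCohort <- function(path, cutoff = 450, allowSTR = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  d <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = c(resection_status = "character"),
                       na.strings = character())
  need <- c("patient_id", "age", "survival_days", "resection_status")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("cohort CSV missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(d$patient_id))
    stop("duplicate patient ids: ",
         paste(unique(d$patient_id[duplicated(d$patient_id)]),
               collapse = ", "), call. = FALSE)
  surv <- suppressWarnings(as.numeric(d$survival_days))
  if (any(is.na(surv)))
    stop("non-numeric survival_days at rows: ",
         paste(which(is.na(surv)), collapse = ", "), call. = FALSE)
  ok_status <- if (allowSTR) c("GTR", "NA", "STR") else c("GTR", "NA")
  keep <- d$resection_status %in% ok_status
  rejected <- d[!keep, , drop = FALSE]
  if (nrow(rejected)) {
    warning(sprintf("rejected %d row(s) with resection status outside {%s}: %s (status %s)",
                    nrow(rejected), paste(ok_status, collapse = ", "),
                    paste(rejected$patient_id, collapse = ", "),
                    paste(unique(rejected$resection_status), collapse = ", ")))
  }
  d <- d[keep, , drop = FALSE]
  age <- suppressWarnings(as.numeric(d$age))
  cohortTable(d$patient_id, surv[keep], d$resection_status, age = age,
              cutoff = cutoff, metadata = list(rejected = rejected,
                                              source = path))
}

#' Save a cohort as CSV
#'
#' @param cohort a [CohortTable-class].
#' @param path destination CSV.
#' @return the path, invisibly.
#' @export
saveCohort <- function(cohort, path) {
  stopifnot(is(cohort, "CohortTable"))
  utils::write.csv(cohort@data, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Load / save a feature table CSV
#'
#' The first column holds patient ids; every remaining column is one
#' numeric feature. Round-trips are lossless to at least 12 significant
#' digits.
#'
#' @param path CSV path.
#' @return [loadFeatureTable()]: a [FeatureTable-class].
#' @export
loadFeatureTable <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  d <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (ncol(d) < 2L)
    stop("feature CSV must have an id column and at least one feature",
         call. = FALSE)
  feats <- names(d)[-1L]
  if (anyDuplicated(feats))
    stop("duplicate feature name(s): ",
         paste(unique(feats[duplicated(feats)]), collapse = ", "),
         call. = FALSE)
  m <- as.matrix(d[, -1L, drop = FALSE])
  if (!is.numeric(m)) {
    badcol <- feats[vapply(d[, -1L, drop = FALSE],
                           function(x) !is.numeric(x), logical(1))]
    stop("non-numeric feature column(s): ", paste(badcol, collapse = ", "),
         call. = FALSE)
  }
  rownames(m) <- as.character(d[[1L]])
  featureTable(m)
}

#' @rdname loadFeatureTable
#' @param table a [FeatureTable-class].
#' @export
saveFeatureTable <- function(table, path) {
  stopifnot(is(table, "FeatureTable"))
  m <- as.matrix(table)
  d <- data.frame(patient_id = rownames(m), stringsAsFactors = FALSE)
  for (j in seq_len(ncol(m))) d[[colnames(m)[j]]] <- format(m[, j], digits = 15)
  names(d)[-1] <- colnames(m)
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
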