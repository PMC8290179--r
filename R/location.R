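#' Maximal in-plane tumor diameter of one slice
#'
#' The maximum pairwise Euclidean distance between in-mask voxel centers,
#' in mm. Coordinates are scaled by the in-plane spacing first, then the
#' convex hull of the scaled points is taken and the maximum is found over
#' hull vertex pairs — exactly equal to the brute-force all-pairs maximum,
#' since the farthest pair of a point set are both hull vertices. Empty and
#' single-voxel slices have diameter 0.
#'
#' @param maskSlice 2D logical (or 0/1) matrix; TRUE marks tumor voxels.
#' @param spacing in-plane voxel spacing (mm, mm).
#' @return the diameter in mm.
#' @examples
#' m <- matrix(FALSE, 5, 5); m[1, 1] <- m[4, 5] <- TRUE
#' sliceDiameter(m)  # 3-4-5 triangle: 5
#' @export
sliceDiameter <- function(maskSlice, spacing = c(1, 1)) {
  if (is.null(dim(maskSlice)) || length(dim(maskSlice)) != 2L)
    stop("maskSlice must be a 2D array", call. = FALSE)
  idx <- which(maskSlice != 0, arr.ind = TRUE)
  n <- nrow(idx)
  if (n < 2L) return(0)
  pts <- cbind(idx[, 1] * spacing[1], idx[, 2] * spacing[2])
  if (n > 3L) {
    hull <- grDevices::chull(pts)
    pts <- pts[hull, , drop = FALSE]
    n <- nrow(pts)
  }
  best <- 0
  for (a in seq_len(n - 1L)) {
    d2 <- (pts[(a + 1L):n, 1] - pts[a, 1])^2 +
          (pts[(a + 1L):n, 2] - pts[a, 2])^2
    best <- max(best, d2)
  }
  sqrt(best)
}

#' Extract the four location features from a segmentation volume
#'
#' Walks every axial slice (the third array axis), computing the in-plane
#' diameter of the tumor mask (union of \code{tumorLabels}); the slice with
#' the largest diameter is the tumor's middle surface (\code{Slice}, ties
#' broken toward the smaller index) and that maximum is \code{Diameter}.
#' On the selected slice, \code{X} and \code{Y} are the signed
#' longitudinal / transverse offsets (mm) of the tumor-mask centroid from
#' the brain-mask centroid, positive toward increasing array index.
#'
#' The brain center is taken as the centroid of the brain mask on the
#' selected slice; \code{center = "midline"} instead uses the geometric
#' center of the brain mask's bounding box on that slice (the midline
#' crossing of an idealized symmetric brain).
#'
#' @param volume a [LabeledVolume-class].
#' @param tumorLabels labels forming the tumor mask; default whole tumor
#'   c(1, 2, 4); use c(1, 4) for the tumor core.
#' @param brainMask logical array of the volume's shape; voxels inside the
#'   brain. Required — derive it from the paired intensity volume (nonzero
#'   voxels) or supply an analytic mask.
#' @param center "centroid" (default) or "midline".
#' @return a [LocationFeatureSet-class].
#' @export
extractLocationFeatures <- function(volume, tumorLabels = c(1L, 2L, 4L),
                                    brainMask,
                                    center = c("centroid", "midline")) {
  stopifnot(is(volume, "LabeledVolume"))
  center <- match.arg(center)
  vox <- voxels(volume)
  if (!identical(dim(brainMask), dim(vox)))
    stop("brain mask shape does not match volume", call. = FALSE)
  sp <- spacing(volume)
  tumor <- array(vox %in% tumorLabels, dim(vox))
  if (!any(tumor)) stop("empty tumor mask", call. = FALSE)
  nSlices <- dim(vox)[3]
  diams <- vapply(seq_len(nSlices), function(k)
    sliceDiameter(tumor[, , k], spacing = sp[1:2]), numeric(1))
  kBest <- which.max(diams)   # ties -> smallest index
  tIdx <- which(tumor[, , kBest], arr.ind = TRUE)
  bIdx <- which(brainMask[, , kBest], arr.ind = TRUE)
  if (nrow(bIdx) == 0L)
    stop("brain mask empty on selected slice ", kBest, call. = FALSE)
  tCentroid <- colMeans(tIdx)
  bCenter <- if (center == "centroid") colMeans(bIdx)
             else (apply(bIdx, 2, min) + apply(bIdx, 2, max)) / 2
  locationFeatureSet(
    sliceIndex = kBest,
    diameterMM = diams[kBest],
    xOffsetMM = (tCentroid[1] - bCenter[1]) * sp[1],
    yOffsetMM = (tCentroid[2] - bCenter[2]) * sp[2])
}
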