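#' Z-score intensity normalization
#'
#' Transforms in-scope voxels as \eqn{z = (x - \mu) / \sigma} with the
#' population (divide-by-N) standard deviation, so that after the transform
#' the in-scope mean is exactly 0 and the population SD exactly 1.
#' Out-of-scope voxels are set to 0.
#'
#' By default the statistics are computed over the brain mask — the voxels
#' with nonzero intensity — rather than the full grid, because background
#' air would dominate the mean and SD; pass \code{scope = "image"} for
#' whole-grid statistics, or an explicit logical \code{mask}.
#'
#' @param volume an [IntensityVolume-class].
#' @param mask optional logical array of the volume's shape selecting the
#'   voxels in scope (overrides \code{scope}).
#' @param scope "brain" (nonzero voxels) or "image" (all voxels).
#' @return list: \code{volume} (normalized [IntensityVolume-class]) and
#'   \code{stats} ([NormalizationStats-class] reproducing the transform).
#' @examples
#' v <- intensityVolume(array(c(1, 2, 3, 2), c(2, 2, 1)))
#' zscoreNormalize(v, scope = "image")$stats@mu
#' @export
zscoreNormalize <- function(volume, mask = NULL,
                            scope = c("brain", "image")) {
  stopifnot(is(volume, "IntensityVolume"))
  scope <- match.arg(scope)
  x <- voxels(volume)
  if (is.null(mask)) {
    mask <- if (scope == "brain") x != 0 else array(TRUE, dim(x))
    desc <- if (scope == "brain") "nonzero-intensity voxels" else "all voxels"
  } else {
    if (!identical(dim(mask), dim(x)))
      stop("mask shape does not match volume", call. = FALSE)
    desc <- "user-supplied mask"
  }
  n <- sum(mask)
  if (n == 0L) stop("empty mask: no voxels in scope", call. = FALSE)
  if (n < 2L) stop("need at least 2 voxels in scope", call. = FALSE)
  vals <- x[mask]
  mu <- mean(vals)
  sigma <- sqrt(mean((vals - mu)^2))   # population SD
  if (sigma == 0)
    stop("constant image in scope: sigma = 0, z-score undefined",
         call. = FALSE)
  out <- array(0, dim(x))
  out[mask] <- (vals - mu) / sigma
  list(volume = intensityVolume(out, spacing = spacing(volume),
                                axes = axesTag(volume)),
       stats = new("NormalizationStats", mu = mu, sigma = sigma,
                   maskDescription = desc, nVoxels = as.integer(n)))
}

#' Bias-field correction adapter
#'
#' Low-frequency intensity non-uniformity is removed by the established N4
#' algorithm, reached through an external backend; this package does not
#' re-derive N4. With \code{backend = "external-N4"} the volume is handed
#' to SimpleITK's \code{N4BiasFieldCorrectionImageFilter} via the
#' \code{python} interpreter on the PATH; if that backend is unavailable
#' the call errors rather than silently falling back. With
#' \code{backend = "passthrough"} the input is returned unchanged and a
#' warning notes that no correction was applied.
#'
#' @param volume an [IntensityVolume-class].
#' @param mask optional logical array restricting the fit (the algorithm's
#'   mask image); default: voxels with nonzero intensity.
#' @param backend "passthrough" or "external-N4".
#' @return the corrected [IntensityVolume-class].
#' @export
applyBiasCorrection <- function(volume, mask = NULL,
                                backend = c("passthrough", "external-N4")) {
  stopifnot(is(volume, "IntensityVolume"))
  backend <- match.arg(backend)
  if (backend == "passthrough") {
    warning("bias correction backend 'passthrough': volume returned unchanged")
    return(volume)
  }
  py <- Sys.which("python")
  if (py == "")
    stop("external-N4 backend requires a python interpreter on the PATH",
         call. = FALSE)
  probe <- suppressWarnings(system2(py, c("-c", shQuote("import SimpleITK")),
                                    stdout = FALSE, stderr = FALSE))
  if (probe != 0L)
    stop("external-N4 backend unavailable: python lacks SimpleITK",
         call. = FALSE)
  tmpdir <- tempfile("n4_")
  dir.create(tmpdir)
  on.exit(unlink(tmpdir, recursive = TRUE))
  inPath <- file.path(tmpdir, "in.nii.gz")
  maskPath <- file.path(tmpdir, "mask.nii.gz")
  outPath <- file.path(tmpdir, "out.nii.gz")
  saveVolume(volume, inPath)
  if (is.null(mask)) mask <- voxels(volume) != 0
  if (!identical(dim(mask), dim(volume)))
    stop("mask shape does not match volume", call. = FALSE)
  mimg <- RNifti::asNifti(array(as.integer(mask), dim(mask)))
  RNifti::pixdim(mimg) <- spacing(volume)
  RNifti::writeNifti(mimg, maskPath)
  script <- paste(
    "import sys, SimpleITK as sitk",
    "img = sitk.ReadImage(sys.argv[1], sitk.sitkFloat64)",
    "msk = sitk.ReadImage(sys.argv[2], sitk.sitkUInt8)",
    "out = sitk.N4BiasFieldCorrection(img, msk)",
    "sitk.WriteImage(out, sys.argv[3])",
    sep = "; ")
  status <- system2(py, c("-c", shQuote(script), shQuote(inPath),
                          shQuote(maskPath), shQuote(outPath)),
                    stdout = FALSE, stderr = "")
  if (status != 0L || !file.exists(outPath))
    stop("external N4 correction failed (exit status ", status, ")",
         call. = FALSE)
  loadVolume(outPath, kind = "intensity", axes = axesTag(volume))
}
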