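#' Generate a labeled ellipsoidal tumor phantom
#'
#' Voxelizes the concentric ellipsoidal shells of a [TumorSpec-class] into a
#' label grid: a voxel center (i, j, k) belongs to shell f when
#' \eqn{\sum_a ((x_a - c_a) / (f r_a))^2 \le 1} (boundary voxels are inside),
#' and takes the label of the innermost shell containing it. The whole
#' construction is deterministic.
#'
#' The accompanying ground-truth record carries, for the whole-tumor (outer)
#' ellipsoid, the analytic center, the analytic in-plane diameter of every
#' axial slice through the continuous ellipsoid, and the slice of maximal
#' analytic diameter, so that extraction accuracy downstream is assertable.
#'
#' @param shape integer(3) grid extents; default 64 x 64 x 48 (full BraTS
#'   geometry 240 x 240 x 155 available by passing it here).
#' @param spec a [TumorSpec-class]; the outer ellipsoid must fit inside the
#'   grid.
#' @param spacing voxel spacing in mm.
#' @return list with elements \code{volume} ([LabeledVolume-class]) and
#'   \code{truth} (list: center, radii, maxSlice, sliceDiametersMM,
#'   diameterMM).
#' @examples
#' res <- makeLabeledVolume(c(32, 32, 24), tumorSpec(c(16, 16, 12), c(6, 4, 5)))
#' res$truth$maxSlice
#' @export
makeLabeledVolume <- function(shape = c(64, 64, 48), spec,
                              spacing = c(1, 1, 1)) {
  stopifnot(is(spec, "TumorSpec"))
  validObject(spec)
  shape <- as.integer(shape)
  ctr <- spec@center
  if (any(ctr < 1) || any(ctr > shape))
    stop("tumor center outside grid", call. = FALSE)
  if (any(ctr - spec@radii < 1) || any(ctr + spec@radii > shape))
    stop("ellipsoid exceeds grid: center ", paste(ctr, collapse = ","),
         ", radii ", paste(spec@radii, collapse = ","), call. = FALSE)

  di <- (seq_len(shape[1]) - ctr[1]) / spec@radii[1]
  dj <- (seq_len(shape[2]) - ctr[2]) / spec@radii[2]
  dk <- (seq_len(shape[3]) - ctr[3]) / spec@radii[3]
  # squared normalized distance field, built separably
  q <- outer(outer(di^2, dj^2, `+`), dk^2, `+`)
  vox <- array(0L, shape)
  # outermost shell first, innermost last so inner labels overwrite
  for (s in rev(seq_along(spec@shellFractions))) {
    f <- spec@shellFractions[s]
    vox[q <= f^2] <- spec@shellLabels[s]
  }
  # analytic in-plane diameter per axial slice of the outer ellipsoid:
  # at height k the section has semi-axes r * sqrt(1 - ((k - ck)/rk)^2)
  kk <- seq_len(shape[3])
  shrink2 <- 1 - ((kk - ctr[3]) / spec@radii[3])^2
  shrink2[shrink2 < 0] <- NA_real_
  inplane <- sqrt(shrink2)
  sliceDiam <- 2 * pmax(spec@radii[1] * spacing[1],
                        spec@radii[2] * spacing[2]) * inplane
  sliceDiam[is.na(sliceDiam)] <- 0
  list(volume = labeledVolume(vox, spacing = spacing),
       truth = list(center = ctr, radii = spec@radii,
                    maxSlice = which.max(sliceDiam),
                    sliceDiametersMM = sliceDiam,
                    diameterMM = max(sliceDiam)))
}

#' Generate an intensity volume over a label map
#'
#' Emulates acquisition diversity: each tissue class gets a constant mean,
#' multiplied by a smooth low-frequency bias field, plus Gaussian noise.
#' The bias field is the exponential of a separable quadratic polynomial in
#' the normalized coordinates, scaled so its maximum absolute log equals
#' \code{biasAmplitude} (0 disables it). Deterministic for a fixed seed.
#'
#' @param labeled a [LabeledVolume-class].
#' @param tissueMeans named numeric; one mean per label present in the
#'   volume (names are label values as strings, e.g. "0", "1", "2", "4").
#' @param biasAmplitude maximum |log| of the multiplicative bias field.
#' @param noiseSD SD of additive Gaussian noise, intensity units.
#' @param seed integer RNG seed.
#' @return an [IntensityVolume-class].
#' @export
makeIntensityVolume <- function(labeled, tissueMeans, biasAmplitude = 0,
                                noiseSD = 0, seed = 1L) {
  stopifnot(is(labeled, "LabeledVolume"))
  labs <- sort(unique(as.vector(voxels(labeled))))
  miss <- setdiff(as.character(labs), names(tissueMeans))
  if (length(miss))
    stop("missing tissue mean for label(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  d <- dim(labeled)
  base <- array(tissueMeans[as.character(voxels(labeled))], d)
  if (biasAmplitude > 0) {
    # separable quadratic in [-1, 1]^3, rescaled to max |.| = biasAmplitude
    u <- lapply(d, function(n) seq(-1, 1, length.out = n))
    poly <- outer(outer(u[[1]]^2 - 0.5, 0.7 * u[[2]]^2 - 0.2, `+`),
                  0.5 * u[[3]]^2, `+`)
    poly <- poly / max(abs(poly)) * biasAmplitude
    base <- base * exp(poly)
  }
  if (noiseSD > 0)
    base <- base + withSeed(seed, array(stats::rnorm(prod(d), 0, noiseSD), d))
  intensityVolume(base, spacing = spacing(labeled), axes = axesTag(labeled))
}

#' Generate a wide feature table with block correlation structure
#'
#' Emulates the redundancy of radiomic panels: features come in blocks that
#' share one latent Gaussian factor. Each block feature is
#' \eqn{\sqrt{\rho} z + \sqrt{1 - \rho}\, \epsilon} with the block factor z
#' and feature-specific noise, so every within-block pair has population
#' correlation \eqn{\rho}. Additional noise features are independent
#' standard Gaussians.
#'
#' @param nPatients rows; must be >= 2 for correlations to exist.
#' @param nBlocks number of correlated blocks.
#' @param blockSize features per block.
#' @param withinBlockCorr population within-block correlation in \[0, 1).
#' @param nNoiseFeatures independent features appended after the blocks.
#' @param seed integer RNG seed.
#' @return list with \code{table} ([FeatureTable-class], columns
#'   \code{blk<b>_f<i>} then \code{noise<i>}) and \code{blockMap} (named
#'   integer: block index per feature, 0 for noise features).
#' @export
makeFeatureTable <- function(nPatients, nBlocks, blockSize,
                             withinBlockCorr = 0.98, nNoiseFeatures = 0,
                             seed = 1L) {
  if (nPatients < 2L)
    stop("need at least 2 patients (correlation undefined)", call. = FALSE)
  if (withinBlockCorr < 0 || withinBlockCorr >= 1)
    stop("withinBlockCorr must lie in [0, 1)", call. = FALSE)
  withSeed(seed, {
    cols <- list()
    map <- integer()
    for (b in seq_len(nBlocks)) {
      z <- stats::rnorm(nPatients)
      for (i in seq_len(blockSize)) {
        cols[[sprintf("blk%d_f%d", b, i)]] <-
          sqrt(withinBlockCorr) * z +
          sqrt(1 - withinBlockCorr) * stats::rnorm(nPatients)
        map[sprintf("blk%d_f%d", b, i)] <- b
      }
    }
    for (i in seq_len(nNoiseFeatures)) {
      cols[[sprintf("noise%d", i)]] <- stats::rnorm(nPatients)
      map[sprintf("noise%d", i)] <- 0L
    }
    m <- do.call(cbind, cols)
    rownames(m) <- sprintf("P%03d", seq_len(nPatients))
    list(table = featureTable(m), blockMap = map)
  })
}

#' Generate a survival cohort from location features
#'
#' Survival days follow the noisy linear model of a
#' [SurvivalModelSpec-class]:
#' \code{round(clip(intercept + sum(coef * feature) + eps))}, clipped to the
#' model's range before rounding. Resection statuses are assigned GTR / NA
#' by a seeded draw at the requested split fraction. Deterministic per seed.
#'
#' @param locationFeatures named list of [LocationFeatureSet-class] (names
#'   are patient ids), or a [FeatureTable-class] holding the model's
#'   feature columns.
#' @param model a [SurvivalModelSpec-class]; every coefficient name must be
#'   a feature.
#' @param resectionSplitFraction expected fraction of GTR patients.
#' @param seed integer RNG seed.
#' @param cutoff dichotomization cutoff for the derived class.
#' @return a [CohortTable-class].
#' @export
makeCohort <- function(locationFeatures, model, resectionSplitFraction = 0.5,
                       seed = 1L, cutoff = 450) {
  stopifnot(is(model, "SurvivalModelSpec"))
  validObject(model)
  tab <- if (is(locationFeatures, "FeatureTable")) locationFeatures
         else locationFeatureTable(locationFeatures)
  m <- as.matrix(tab)
  if (nrow(m) == 0L) stop("empty feature list", call. = FALSE)
  cf <- model@coefficients
  miss <- setdiff(names(cf), colnames(m))
  if (length(miss))
    stop("model coefficients reference unknown feature(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  lin <- model@intercept +
    if (length(cf)) drop(m[, names(cf), drop = FALSE] %*% cf) else 0
  withSeed(seed, {
    eps <- if (model@noiseSD > 0) stats::rnorm(nrow(m), 0, model@noiseSD)
           else 0
    days <- round(clip(lin + eps, model@clipRange[1], model@clipRange[2]))
    nGTR <- round(resectionSplitFraction * nrow(m))
    status <- rep("NA", nrow(m))
    status[sample.int(nrow(m), nGTR)] <- "GTR"
    age <- round(stats::rnorm(nrow(m), 60, 10), 1)
  })
  cohortTable(rownames(m), days, status, age = age, cutoff = cutoff)
}

#' Generate a complete synthetic study
#'
#' One call producing everything the pipeline consumes with known ground
#' truth: per-patient tumor phantoms at randomized centers and radii inside
#' a common brain mask, their analytic location features, a wide radiomic-
#' style feature table, and a survival cohort driven by the chosen location
#' feature.
#'
#' The survival model used (unless overridden) is
#' \code{days = 400 - 15 * Y + noise(SD 100)} clipped to \[3, 1767\]: all of
#' the survival signal lives in the transverse offset Y, none in the
#' radiomic-style features, so any accuracy gain from adding location
#' features to the classifiers is attributable to them by construction.
#'
#' @param nPatients cohort size.
#' @param shape grid extents per patient volume.
#' @param seed integer master seed; every per-patient draw derives from it.
#' @param model optional [SurvivalModelSpec-class] override.
#' @param nBlocks,blockSize,withinBlockCorr,nNoiseFeatures passed to
#'   [makeFeatureTable()].
#' @param withVolumes also generate and keep the label volumes (slower);
#'   otherwise only analytic features are returned.
#' @return list: \code{cohort}, \code{location} (FeatureTable of
#'   Slice/Diameter/X/Y extracted from the phantoms or analytic),
#'   \code{radiomics} (FeatureTable), \code{truth} (per-patient ground
#'   truth records), \code{volumes} (list of LabeledVolume or NULL),
#'   \code{brainMask} (logical array).
#' @export
makeSyntheticStudy <- function(nPatients = 100, shape = c(64, 64, 48),
                               seed = 1L, model = NULL, nBlocks = 6,
                               blockSize = 5, withinBlockCorr = 0.98,
                               nNoiseFeatures = 10, withVolumes = FALSE) {
  seeds <- childSeeds(seed, 4L)
  ctr0 <- (shape + 1) / 2
  # spherical brain mask filling most of the grid
  brainRadii <- shape * 0.45
  di <- (seq_len(shape[1]) - ctr0[1]) / brainRadii[1]
  dj <- (seq_len(shape[2]) - ctr0[2]) / brainRadii[2]
  dk <- (seq_len(shape[3]) - ctr0[3]) / brainRadii[3]
  brainMask <- outer(outer(di^2, dj^2, `+`), dk^2, `+`) <= 1

  geom <- withSeed(seeds[1], {
    data.frame(
      ci = round(ctr0[1] + stats::runif(nPatients, -8, 8)),
      cj = round(ctr0[2] + stats::runif(nPatients, -8, 8)),
      ck = round(ctr0[3] + stats::runif(nPatients, -6, 6)),
      ra = stats::runif(nPatients, 4, 9),
      rb = stats::runif(nPatients, 4, 9),
      rc = stats::runif(nPatients, 4, 8))
  })
  ids <- sprintf("P%03d", seq_len(nPatients))
  volumes <- if (withVolumes) vector("list", nPatients) else NULL
  truth <- vector("list", nPatients)
  loc <- vector("list", nPatients)
  for (p in seq_len(nPatients)) {
    spec <- tumorSpec(center = c(geom$ci[p], geom$cj[p], geom$ck[p]),
                      radii = c(geom$ra[p], geom$rb[p], geom$rc[p]))
    res <- makeLabeledVolume(shape, spec)
    truth[[p]] <- res$truth
    loc[[p]] <- extractLocationFeatures(res$volume, brainMask = brainMask)
    if (withVolumes) volumes[[p]] <- res$volume
  }
  names(truth) <- names(loc) <- ids
  if (withVolumes) names(volumes) <- ids
  location <- locationFeatureTable(loc)

  rad <- makeFeatureTable(nPatients, nBlocks, blockSize, withinBlockCorr,
                          nNoiseFeatures, seed = seeds[2])
  radiomics <- rad$table

  if (is.null(model))
    model <- survivalModelSpec(intercept = 400, coefficients = c(Y = -15),
                               noiseSD = 100)
  cohort <- makeCohort(location, model, resectionSplitFraction = 0.5,
                       seed = seeds[3])
  list(cohort = cohort, location = location, radiomics = radiomics,
       truth = truth, volumes = volumes, brainMask = brainMask,
       blockMap = rad$blockMap, model = model)
}
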