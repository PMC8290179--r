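# Independent oracles used across the suite. These are deliberately naive
# (brute force / literal definitions) and never share code with the package.

# O(n^2) all-pairs maximal distance of a 2D mask, scaled by spacing
bruteDiameter <- function(mask, spacing = c(1, 1)) {
  idx <- which(mask != 0, arr.ind = TRUE)
  if (nrow(idx) < 2) return(0)
  pts <- cbind(idx[, 1] * spacing[1], idx[, 2] * spacing[2])
  best <- 0
  for (a in seq_len(nrow(pts) - 1))
    for (b in (a + 1):nrow(pts))
      best <- max(best, sum((pts[a, ] - pts[b, ])^2))
  sqrt(best)
}

# literal step-up definition of Benjamini-Hochberg selection
bruteBH <- function(p, alpha) {
  m <- length(p)
  ord <- order(p)
  i <- max(c(0, which(p[ord] <= seq_len(m) / m * alpha)))
  if (i == 0) return(integer())
  which(p <= p[ord][i])
}

# random blob mask: n voxels scattered in a grid
randomMask <- function(seed, nr = 20, nc = 20, n = 30) {
  set.seed(seed)
  m <- matrix(FALSE, nr, nc)
  m[sample(nr * nc, min(n, nr * nc))] <- TRUE
  m
}

# small valid cohort CSV on disk; returns the path
writeCohortCsv <- function(rows, path = tempfile(fileext = ".csv")) {
  writeLines(c("patient_id,age,survival_days,resection_status", rows), path)
  path
}

expect_slot_equal <- function(object, slotName, expected, tol = 1e-9) {
  expect_equal(methods::slot(object, slotName), expected, tolerance = tol)
}
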