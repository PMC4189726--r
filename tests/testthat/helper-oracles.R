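# Independent oracles and fixture builders shared across the test files.
# Each oracle is deliberately written as a direct, unoptimized evaluation of
# the defining rule, separate from the package's implementation path.

# Scalar even-odd point-in-polygon test (classic crossing loop), applied one
# pixel center at a time.
oracleInsideMask <- function(polygon, shape) {
  vr <- polygon[, 1]; vc <- polygon[, 2]
  nv <- length(vr)
  inside1 <- function(pr, pc) {
    inside <- FALSE
    j <- nv
    for (i in seq_len(nv)) {
      if ((vr[i] > pr) != (vr[j] > pr)) {
        cint <- vc[j] + (pr - vr[j]) * (vc[i] - vc[j]) / (vr[i] - vr[j])
        if (pc < cint) inside <- !inside
      }
      j <- i
    }
    inside
  }
  out <- matrix(FALSE, shape[1], shape[2])
  for (r in seq_len(shape[1]))
    for (c in seq_len(shape[2]))
      out[r, c] <- inside1(r, c)
  out
}

# Random star-shaped (hence simple) polygon around a center.
randomSimplePolygon <- function(nVertices, center, rMin, rMax) {
  th <- sort(stats::runif(nVertices, 0, 2 * pi))
  rad <- stats::runif(nVertices, rMin, rMax)
  cbind(center[1] + rad * sin(th), center[2] + rad * cos(th))
}

# Exhaustive-scan Otsu oracle on raw values: evaluates the between-class
# variance directly from the pixel values at every candidate threshold and
# returns the profile.
oracleOtsuProfile <- function(vals, candidates) {
  vapply(candidates, function(t) {
    lo <- vals[vals <= t]; hi <- vals[vals > t]
    if (!length(lo) || !length(hi)) return(-Inf)
    w0 <- length(lo) / length(vals)
    w0 * (1 - w0) * (mean(lo) - mean(hi))^2
  }, numeric(1))
}

# Between-class variance oracle on a histogram (counts, mids): direct double
# computation of the class means from the histogram at each split.
oracleOtsuHistProfile <- function(counts, mids) {
  m <- length(counts)
  vapply(seq_len(m - 1L), function(i) {
    n0 <- sum(counts[1:i]); n1 <- sum(counts[(i + 1L):m])
    if (n0 == 0 || n1 == 0) return(-Inf)
    mu0 <- sum(counts[1:i] * mids[1:i]) / n0
    mu1 <- sum(counts[(i + 1L):m] * mids[(i + 1L):m]) / n1
    w0 <- n0 / (n0 + n1)
    w0 * (1 - w0) * (mu0 - mu1)^2
  }, numeric(1))
}

# Recursive flood-fill component labeling (independent of the package BFS).
oracleLabel <- function(mask, connectivity = 8) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  if (connectivity == 4) {
    nb <- cbind(c(-1, 1, 0, 0), c(0, 0, -1, 1))
  } else {
    nb <- cbind(rep(c(-1, 0, 1), each = 3), rep(c(-1, 0, 1), 3))
    nb <- nb[!(nb[, 1] == 0 & nb[, 2] == 0), ]
  }
  lbl <- 0L
  for (r0 in seq_len(nr)) for (c0 in seq_len(nc)) {
    if (!mask[r0, c0] || lab[r0, c0] != 0L) next
    lbl <- lbl + 1L
    todo <- list(c(r0, c0)); lab[r0, c0] <- lbl
    while (length(todo)) {
      p <- todo[[1]]; todo <- todo[-1]
      for (k in seq_len(nrow(nb))) {
        r <- p[1] + nb[k, 1]; c <- p[2] + nb[k, 2]
        if (r >= 1 && r <= nr && c >= 1 && c <= nc &&
            mask[r, c] && lab[r, c] == 0L) {
          lab[r, c] <- lbl
          todo[[length(todo) + 1]] <- c(r, c)
        }
      }
    }
  }
  lab
}

# Axis-aligned rectangle polygon (r1..r2, c1..c2 in image coordinates).
rectPolygon <- function(r1, r2, c1, c2) {
  rbind(c(r1, c1), c(r1, c2), c(r2, c2), c(r2, c1))
}

# Annular test slice: concentric circular contours on an n x n grid with a
# given pixel-value generator applied to the myocardium.
annulusFixture <- function(n = 45, rEndo = 10, rEpi = 20, fill = 100,
                           spacing = 1) {
  ctr <- c((n + 1) / 2, (n + 1) / 2)
  cs <- contourSet(endo = circlePolygon(ctr, rEndo),
                   epi = circlePolygon(ctr, rEpi))
  myo <- buildMyocardiumMask(cs, c(n, n))
  px <- matrix(0, n, n)
  px[myo] <- fill
  list(contours = cs, myo = myo, pixels = px, center = ctr,
       image = function(p) sliceImage(p, pixelSpacing = spacing))
}

# Small phantom spec used by the heavier loops (fast to generate).
smallPhantomSpec <- function(seed, ...) {
  phantomSpec(imageSize = 64L, nSlices = 3L, epiRadiusPx = 20,
              endoRadiusPx = 11, lesionAreaMeanPx = 50,
              lesionAreaRangePx = c(10, 140), rngSeed = seed, ...)
}

# Strip non-dim attributes (e.g. nPixels) for mask comparisons.
bareMask <- function(m) matrix(as.logical(m), nrow(m))
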