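# Polygon geometry and rasterization.
#
# All polygons are n x 2 matrices (columns: row, col) in continuous image
# coordinates; pixel (r, c) has its center at (r, c).  The closing edge is
# implicit.  Inside tests use the even-odd (crossing-number) rule evaluated
# at pixel centers; centers falling exactly on a boundary are resolved by a
# fixed half-open rule (strict comparison against the edge crossing), so
# counts are deterministic.

#' Signed area of a polygon (shoelace formula)
#'
#' @param polygon n x 2 matrix of vertices (row, col).
#' @return Signed area; positive or negative depending on vertex orientation.
#' @export
polygonArea <- function(polygon) {
  r <- polygon[, 1]; c <- polygon[, 2]
  n <- nrow(polygon)
  j <- c(n, seq_len(n - 1L))
  sum(c[j] * r - c * r[j]) / 2
}

#' Even-odd point-in-polygon test
#'
#' Vectorized crossing-number test with a half-open tie-break rule: a point
#' whose rightward ray passes exactly through an edge crossing is counted on
#' one fixed side only, so boundary pixels are assigned deterministically.
#'
#' @param pr,pc numeric vectors of point coordinates (row, col).
#' @param polygon n x 2 vertex matrix.
#' @return Logical vector, TRUE where the point lies inside.
#' @export
pointInPolygon <- function(pr, pc, polygon) {
  vr <- polygon[, 1]; vc <- polygon[, 2]
  n <- length(vr)
  j <- c(n, seq_len(n - 1L))
  inside <- rep(FALSE, length(pr))
  for (i in seq_len(n)) {
    r1 <- vr[j[i]]; c1 <- vc[j[i]]
    r2 <- vr[i];    c2 <- vc[i]
    if (r1 == r2) next
    crosses <- (r1 > pr) != (r2 > pr)
    if (any(crosses)) {
      cint <- c1 + (pr[crosses] - r1) * (c2 - c1) / (r2 - r1)
      hit <- pc[crosses] < cint
      idx <- which(crosses)[hit]
      inside[idx] <- !inside[idx]
    }
  }
  inside
}

# Proper segment-intersection test used by the simplicity check.
segmentsIntersect <- function(p1, p2, p3, p4) {
  d <- function(a, b, c) (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
  d1 <- d(p3, p4, p1); d2 <- d(p3, p4, p2)
  d3 <- d(p1, p2, p3); d4 <- d(p1, p2, p4)
  if (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
      ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0))) return(TRUE)
  on <- function(a, b, c) {
    min(a[1], b[1]) <= c[1] && c[1] <= max(a[1], b[1]) &&
    min(a[2], b[2]) <= c[2] && c[2] <= max(a[2], b[2])
  }
  (d1 == 0 && on(p3, p4, p1)) || (d2 == 0 && on(p3, p4, p2)) ||
  (d3 == 0 && on(p1, p2, p3)) || (d4 == 0 && on(p1, p2, p4))
}

#' Is a closed polygon simple (non-self-intersecting)?
#'
#' Adjacent edges (sharing a vertex) are exempt from the pairwise test.
#'
#' @param polygon n x 2 vertex matrix.
#' @return TRUE if no two non-adjacent edges intersect.
#' @export
polygonIsSimple <- function(polygon) {
  n <- nrow(polygon)
  if (n < 3L) return(FALSE)
  edges <- lapply(seq_len(n), function(i) {
    j <- if (i == n) 1L else i + 1L
    list(polygon[i, ], polygon[j, ])
  })
  for (i in seq_len(n - 1L)) {
    for (k in (i + 1L):n) {
      # skip adjacent edges (consecutive, or first/last which share a vertex)
      if (k == i + 1L || (i == 1L && k == n)) next
      if (segmentsIntersect(edges[[i]][[1]], edges[[i]][[2]],
                            edges[[k]][[1]], edges[[k]][[2]])) return(FALSE)
    }
  }
  TRUE
}

#' Rasterize a polygon onto a pixel grid
#'
#' A pixel belongs to the mask iff its center lies inside the polygon under
#' the even-odd rule.  Deterministic for fixed inputs.
#'
#' @param polygon n x 2 vertex matrix (row, col), n >= 3, non-zero area.
#' @param shape integer length-2, (nrow, ncol) of the target grid.
#' @return Logical matrix of dimension \code{shape}.
#' @examples
#' sq <- rbind(c(0.5, 0.5), c(0.5, 2.5), c(2.5, 2.5), c(2.5, 0.5))
#' sum(rasterizePolygon(sq, c(4, 4)))  # 4 pixel centers inside
#' @export
rasterizePolygon <- function(polygon, shape) {
  if (!is.matrix(polygon) || ncol(polygon) != 2L || nrow(polygon) < 3L)
    stop("degenerate polygon: need an n x 2 matrix with n >= 3 vertices")
  if (abs(polygonArea(polygon)) <= .Machine$double.eps)
    stop("degenerate polygon: zero area")
  shape <- as.integer(shape)
  if (length(shape) != 2L || any(shape <= 0L))
    stop("shape must be two positive integers")
  nr <- shape[1]; nc <- shape[2]
  pr <- rep(seq_len(nr), times = nc)
  pc <- rep(seq_len(nc), each = nr)
  # restrict the test to the polygon's bounding box
  rb <- range(polygon[, 1]); cb <- range(polygon[, 2])
  inbox <- pr >= floor(rb[1]) & pr <= ceiling(rb[2]) &
           pc >= floor(cb[1]) & pc <= ceiling(cb[2])
  inside <- rep(FALSE, nr * nc)
  if (any(inbox))
    inside[inbox] <- pointInPolygon(pr[inbox], pc[inbox], polygon)
  matrix(inside, nr, nc)
}

#' Build the myocardial mask from a contour set
#'
#' The mask is (inside epicardium) AND NOT (inside endocardium) AND NOT
#' (inside any exclusion polygon): an annulus with the endocardial hole left
#' open, minus flagged artifact/blood-pool regions.
#'
#' @param contours a \linkS4class{ContourSet}.
#' @param shape target grid dimension (nrow, ncol), or a
#'   \linkS4class{SliceImage} whose pixel dimensions are used.
#' @return Logical matrix; attribute \code{nPixels} holds the pixel count.
#' @export
buildMyocardiumMask <- function(contours, shape) {
  if (is(shape, "SliceImage")) shape <- dim(shape@pixels)
  validObject(contours)
  mask <- rasterizePolygon(contours@epi, shape) &
          !rasterizePolygon(contours@endo, shape)
  for (ex in contours@exclusions)
    mask <- mask & !rasterizePolygon(ex, shape)
  if (!any(mask))
    stop("empty myocardium: contours/exclusions leave no myocardial pixels")
  attr(mask, "nPixels") <- sum(mask)
  mask
}

#' Regular polygon approximating a circle
#'
#' Convenience for building contours and disk-shaped reference ROIs.
#'
#' @param center length-2 (row, col).
#' @param radius radius in pixels.
#' @param nVertices number of vertices.
#' @return An nVertices x 2 polygon matrix.
#' @export
circlePolygon <- function(center, radius, nVertices = 64L) {
  th <- seq(0, 2 * pi, length.out = nVertices + 1L)[-(nVertices + 1L)]
  cbind(center[1] + radius * sin(th), center[2] + radius * cos(th))
}

#' Annular sector polygon
#'
#' Wedge of an annulus between two angles (radians) and two radii, used for
#' remote-myocardium reference regions.
#'
#' @param center length-2 (row, col).
#' @param rInner,rOuter inner and outer radii in pixels.
#' @param thetaStart,thetaEnd angular range in radians (counter-clockwise,
#'   \code{thetaEnd > thetaStart}).
#' @param nArc vertices per arc.
#' @return Polygon matrix tracing the outer arc then the inner arc back.
#' @export
annularSectorPolygon <- function(center, rInner, rOuter, thetaStart, thetaEnd,
                                 nArc = 24L) {
  th <- seq(thetaStart, thetaEnd, length.out = nArc)
  outer <- cbind(center[1] + rOuter * sin(th), center[2] + rOuter * cos(th))
  inner <- cbind(center[1] + rInner * sin(rev(th)), center[2] + rInner * cos(rev(th)))
  rbind(outer, inner)
}
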