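# Polygon geometry and ROI rasterization.
#
# Masks are logical matrices the same shape as the image; a pixel belongs to
# a region iff its CENTER satisfies the region's predicate. Polygon membership
# uses the even-odd rule with the standard half-open ray-casting convention
# (ray toward +x; an edge is counted when it spans the scan line half-open in
# y), so centers exactly on a shared edge of two polygons belong to exactly
# one of them.

#' Coerce to a polygon matrix
#'
#' Accepts an n x 2 matrix or a list of `[x, y]` pairs and returns an n x 2
#' numeric matrix with columns `x`, `y` (mm image coordinates).
#'
#' @param p polygon vertices: n x 2 matrix or list of length-2 vectors.
#' @return n x 2 numeric matrix.
#' @keywords internal
as_polygon <- function(p) {
  if (is.list(p) && !is.data.frame(p)) p <- do.call(rbind, lapply(p, as.numeric))
  p <- as.matrix(p)
  storage.mode(p) <- "double"
  if (ncol(p) != 2L) stop("polygon must have two columns (x, y)")
  if (!all(is.finite(p))) stop("polygon vertices must be finite")
  # drop an explicitly repeated closing vertex; closure is implicit
  n <- nrow(p)
  if (n >= 2L && all(p[1L, ] == p[n, ])) p <- p[-n, , drop = FALSE]
  colnames(p) <- c("x", "y")
  p
}

#' Signed polygon area (shoelace formula)
#'
#' @param poly polygon (see [as_polygon()]).
#' @return signed area in mm^2 (positive if counter-clockwise).
#' @export
polygon_area <- function(poly) {
  p <- as_polygon(poly)
  x <- p[, 1]; y <- p[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  sum(x * yn - xn * y) / 2
}

# orientation of point r relative to segment p->q (>0 left, <0 right, 0 collinear)
.orient <- function(p, q, r) {
  (q[1] - p[1]) * (r[2] - p[2]) - (q[2] - p[2]) * (r[1] - p[1])
}

.on_segment <- function(p, q, r) {
  # r collinear with p-q assumed; is r within the bounding box of p-q?
  min(p[1], q[1]) <= r[1] && r[1] <= max(p[1], q[1]) &&
    min(p[2], q[2]) <= r[2] && r[2] <= max(p[2], q[2])
}

.segments_intersect <- function(p1, p2, p3, p4) {
  d1 <- .orient(p3, p4, p1); d2 <- .orient(p3, p4, p2)
  d3 <- .orient(p1, p2, p3); d4 <- .orient(p1, p2, p4)
  if (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
      ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0))) return(TRUE)
  if (d1 == 0 && .on_segment(p3, p4, p1)) return(TRUE)
  if (d2 == 0 && .on_segment(p3, p4, p2)) return(TRUE)
  if (d3 == 0 && .on_segment(p1, p2, p3)) return(TRUE)
  if (d4 == 0 && .on_segment(p1, p2, p4)) return(TRUE)
  FALSE
}

#' Test whether a closed polygon is simple (non-self-intersecting)
#'
#' Adjacent edges sharing one vertex are allowed; any other contact between
#' edges (crossing or touching) makes the polygon non-simple.
#'
#' @param poly polygon.
#' @return `TRUE` or `FALSE`.
#' @export
polygon_is_simple <- function(poly) {
  p <- as_polygon(poly)
  n <- nrow(p)
  if (n < 3L) return(FALSE)
  if (anyDuplicated(p)) return(FALSE)
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      adjacent <- (j == i + 1L) || (i == 1L && j == n)
      if (adjacent) next
      a <- p[i, ]; b <- p[if (i == n) 1L else i + 1L, ]
      c_ <- p[j, ]; d <- p[if (j == n) 1L else j + 1L, ]
      if (.segments_intersect(a, b, c_, d)) return(FALSE)
    }
  }
  TRUE
}

.validate_polygon <- function(poly, role = "polygon") {
  p <- as_polygon(poly)
  if (nrow(p) < 3L)
    stop(sprintf("%s must have at least 3 vertices (got %d)", role, nrow(p)))
  if (!polygon_is_simple(p))
    stop(sprintf("%s is self-intersecting", role))
  if (abs(polygon_area(p)) <= 0)
    stop(sprintf("%s has zero area (degenerate)", role))
  p
}

#' Point-in-polygon test (even-odd rule)
#'
#' Half-open ray-casting convention: an edge contributes a crossing when it
#' spans the point's y half-open (`y1 > y` xor `y2 > y`) and the edge's x at
#' that height lies strictly to the right of the point.
#'
#' @param px,py point coordinates (vectors of equal length), mm.
#' @param poly polygon.
#' @return logical vector.
#' @export
point_in_polygon <- function(px, py, poly) {
  p <- as_polygon(poly)
  n <- nrow(p)
  inside <- logical(length(px))
  j <- n
  for (i in seq_len(n)) {
    x1 <- p[j, 1]; y1 <- p[j, 2]; x2 <- p[i, 1]; y2 <- p[i, 2]
    if (y1 != y2) {
      spans <- (y1 > py) != (y2 > py)
      xint <- x1 + (py - y1) * (x2 - x1) / (y2 - y1)
      inside <- xor(inside, spans & (px < xint))
    }
    j <- i
  }
  inside
}

#' Rasterize a circle onto a slice grid
#'
#' A pixel is in the mask iff its center lies at Euclidean distance (in mm,
#' using the slice's anisotropic spacing) at most `diameter_mm / 2` from
#' `center`. The circle may lie partly or wholly outside the image; an empty
#' mask is a legal result.
#'
#' @param center length-2 numeric `(x, y)` in mm image coordinates.
#' @param diameter_mm positive circle diameter in mm.
#' @param template an [image_slice()] supplying grid shape and spacing.
#' @return logical matrix with the shape of `template$pixels`.
#' @export
rasterize_circle <- function(center, diameter_mm, template) {
  stopifnot(inherits(template, "image_slice"))
  if (!is.numeric(diameter_mm) || length(diameter_mm) != 1L || diameter_mm <= 0)
    stop("diameter_mm must be a positive number")
  center <- as.numeric(center)
  if (length(center) != 2L || !all(is.finite(center)))
    stop("center must be a finite (x, y) pair")
  ax <- .pixel_axes(template)
  r2 <- (diameter_mm / 2)^2
  outer((ax$y - center[2])^2, (ax$x - center[1])^2, "+") <= r2
}

#' Rasterize a simple polygon onto a slice grid
#'
#' A pixel is in the mask iff its center is inside the polygon under the
#' even-odd rule (see [point_in_polygon()] for the boundary convention).
#'
#' @param poly closed simple polygon with at least 3 vertices, mm coordinates.
#' @param template an [image_slice()] supplying grid shape and spacing.
#' @return logical matrix with the shape of `template$pixels`.
#' @export
rasterize_polygon <- function(poly, template) {
  stopifnot(inherits(template, "image_slice"))
  p <- .validate_polygon(poly)
  ax <- .pixel_axes(template)
  nr <- length(ax$y); nc <- length(ax$x)
  count <- matrix(0L, nr, nc)
  n <- nrow(p)
  j <- n
  for (i in seq_len(n)) {
    x1 <- p[j, 1]; y1 <- p[j, 2]; x2 <- p[i, 1]; y2 <- p[i, 2]
    if (y1 != y2) {
      spans <- (y1 > ax$y) != (y2 > ax$y)              # over rows
      xint <- x1 + (ax$y - y1) * (x2 - x1) / (y2 - y1) # over rows
      if (any(spans)) {
        cross <- outer(xint, ax$x, ">") & spans        # [row, col]
        count <- count + cross
      }
    }
    j <- i
  }
  count %% 2L == 1L
}
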