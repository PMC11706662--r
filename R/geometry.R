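# Planar convex-polygon primitives used for residency hulls.
# Polygons are n x 2 matrices of projected metres, vertices in
# counter-clockwise order, not closed (first vertex not repeated).

#' Convex hull of projected points
#'
#' Returns the convex hull as a counter-clockwise polygon. Degenerate
#' inputs (fewer than 3 unique points, or collinear points) are buffered
#' by `buffer_m` so that every hull has positive area: a single point
#' becomes a small square, a segment a thin rectangle.
#'
#' @param xy n x 2 matrix of projected coordinates (metres).
#' @param buffer_m buffer applied to degenerate hulls (default 1 m).
#' @return polygon matrix with columns x, y.
#' @export
convex_hull_poly <- function(xy, buffer_m = 1) {
  if (!is.matrix(xy)) xy <- matrix(xy, ncol = 2)
  xy <- unique(round(xy, 9))
  n <- nrow(xy)
  if (n == 1) {
    p <- xy[1, ]
    return(cbind(x = p[1] + buffer_m * c(-1, 1, 1, -1),
                 y = p[2] + buffer_m * c(-1, -1, 1, 1)))
  }
  idx <- grDevices::chull(xy[, 1], xy[, 2])
  hull <- xy[idx, , drop = FALSE]
  if (nrow(hull) < 3 || abs(polygon_area(hull)) < buffer_m^2 * 1e-6) {
    # collinear: buffer the extremal segment
    d <- as.matrix(stats::dist(xy))
    ij <- which(d == max(d), arr.ind = TRUE)[1, ]
    a <- xy[ij[1], ]; b <- xy[ij[2], ]
    u <- b - a
    u <- u / sqrt(sum(u^2))
    v <- c(-u[2], u[1]) # unit normal
    hull <- rbind(a - buffer_m * (u + v), b + buffer_m * (u - v),
                  b + buffer_m * (u + v), a - buffer_m * (u - v))
    colnames(hull) <- c("x", "y")
  }
  # enforce counter-clockwise orientation
  if (polygon_area_signed(hull) < 0) hull <- hull[rev(seq_len(nrow(hull))), ]
  colnames(hull) <- c("x", "y")
  hull
}

polygon_area_signed <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  xs <- c(x[-1], x[1]); ys <- c(y[-1], y[1])
  sum(x * ys - xs * y) / 2
}

#' Area of a simple polygon (shoelace formula)
#' @param poly polygon matrix (columns x, y), not closed.
#' @return area in squared input units.
#' @export
polygon_area <- function(poly) abs(polygon_area_signed(poly))

#' Intersection of two convex polygons (Sutherland-Hodgman clipping)
#'
#' @param p,q convex polygons, counter-clockwise vertex matrices.
#' @return the intersection polygon, or NULL if empty.
#' @export
convex_intersect <- function(p, q) {
  out <- p
  nq <- nrow(q)
  for (i in seq_len(nq)) {
    if (is.null(out) || nrow(out) == 0) return(NULL)
    a <- q[i, ]
    b <- q[if (i == nq) 1 else i + 1, ]
    # keep points on the left of edge a->b (ccw interior)
    side <- function(pt) (b[1] - a[1]) * (pt[2] - a[2]) -
      (b[2] - a[2]) * (pt[1] - a[1])
    res <- matrix(numeric(0), ncol = 2)
    m <- nrow(out)
    for (j in seq_len(m)) {
      cur <- out[j, ]
      prv <- out[if (j == 1) m else j - 1, ]
      sc <- side(cur); sp <- side(prv)
      if (sc >= 0) {
        if (sp < 0) res <- rbind(res, seg_line_intersect(prv, cur, a, b))
        res <- rbind(res, cur)
      } else if (sp >= 0) {
        res <- rbind(res, seg_line_intersect(prv, cur, a, b))
      }
    }
    out <- res
  }
  if (is.null(out) || nrow(out) < 3) return(NULL)
  colnames(out) <- c("x", "y")
  out
}

seg_line_intersect <- function(p1, p2, a, b) {
  d1 <- p2 - p1; d2 <- b - a
  den <- d1[1] * d2[2] - d1[2] * d2[1]
  if (abs(den) < 1e-300) return(p1)
  t <- ((a[1] - p1[1]) * d2[2] - (a[2] - p1[2]) * d2[1]) / den
  p1 + t * d1
}

#' Test whether points fall inside a convex polygon (closed: boundary counts)
#'
#' @param xy n x 2 matrix of points.
#' @param poly convex counter-clockwise polygon.
#' @param tol boundary tolerance in input units (default 1e-9).
#' @return logical vector.
#' @export
point_in_convex <- function(xy, poly, tol = 1e-9) {
  if (!is.matrix(xy)) xy <- matrix(xy, ncol = 2)
  n <- nrow(poly)
  inside <- rep(TRUE, nrow(xy))
  for (i in seq_len(n)) {
    a <- poly[i, ]
    b <- poly[if (i == n) 1 else i + 1, ]
    cr <- (b[1] - a[1]) * (xy[, 2] - a[2]) - (b[2] - a[2]) * (xy[, 1] - a[1])
    inside <- inside & (cr >= -tol)
  }
  inside
}

#' Hull overlap fraction: intersection area over the smaller hull's area
#'
#' @param p,q convex polygons.
#' @return fraction in [0, 1].
#' @export
hull_overlap_fraction <- function(p, q) {
  inter <- convex_intersect(p, q)
  if (is.null(inter)) return(0)
  min(1, polygon_area(inter) / min(polygon_area(p), polygon_area(q)))
}
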