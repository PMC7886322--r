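# Planar polygon helpers used by the parametric cross-section generator.
# Polygons are n x 2 matrices of vertices in order; they are treated as
# closed (last vertex connects back to the first) and must be simple.

#' Signed area of a simple polygon (shoelace formula)
#'
#' Positive for counter-clockwise orientation.
#'
#' @param poly numeric matrix with two columns (x, y).
#' @return signed area in the square of the coordinate unit.
#' @keywords internal
polygon_signed_area <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  xs <- c(x[-1], x[1]); ys <- c(y[-1], y[1])
  sum(x * ys - xs * y) / 2
}

#' Absolute polygon area, orientation-independent
#' @inheritParams polygon_signed_area
#' @return area (> 0 for non-degenerate polygons).
#' @export
polygon_area <- function(poly) abs(polygon_signed_area(poly))

polygon_centroid <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  xs <- c(x[-1], x[1]); ys <- c(y[-1], y[1])
  cr <- x * ys - xs * y
  a <- sum(cr) / 2
  if (abs(a) < .Machine$double.eps) return(colMeans(poly))
  c(sum((x + xs) * cr), sum((y + ys) * cr)) / (6 * a)
}

# Clip polygon against half-plane {p : dot(p, n) <= c} (Sutherland-Hodgman).
clip_halfplane <- function(poly, n, c) {
  m <- nrow(poly)
  d <- poly %*% n - c
  out <- matrix(0, m * 2, 2)
  k <- 0
  for (i in seq_len(m)) {
    j <- if (i == m) 1L else i + 1L
    di <- d[i]; dj <- d[j]
    if (di <= 0) { k <- k + 1; out[k, ] <- poly[i, ] }
    if ((di < 0 && dj > 0) || (di > 0 && dj < 0)) {
      t <- di / (di - dj)
      k <- k + 1; out[k, ] <- poly[i, ] + t * (poly[j, ] - poly[i, ])
    }
  }
  out[seq_len(k), , drop = FALSE]
}

#' Test whether a polygon is simple (non-self-intersecting)
#'
#' O(n^2) pairwise edge check; used to validate generated sections.
#'
#' @inheritParams polygon_signed_area
#' @param tol geometric tolerance for the intersection test.
#' @return logical.
#' @export
polygon_is_simple <- function(poly, tol = 1e-9) {
  n <- nrow(poly)
  if (n < 3) return(FALSE)
  seg <- function(i) rbind(poly[i, ], poly[if (i == n) 1L else i + 1L, ])
  inter <- function(p1, p2, p3, p4) {
    d1 <- p2 - p1; d2 <- p4 - p3
    den <- d1[1] * d2[2] - d1[2] * d2[1]
    if (abs(den) < tol) return(FALSE)
    t <- ((p3[1] - p1[1]) * d2[2] - (p3[2] - p1[2]) * d2[1]) / den
    s <- ((p3[1] - p1[1]) * d1[2] - (p3[2] - p1[2]) * d1[1]) / den
    t > tol && t < 1 - tol && s > tol && s < 1 - tol
  }
  for (i in seq_len(n - 2)) {
    for (j in seq(i + 2, n)) {
      if (i == 1 && j == n) next
      a <- seg(i); b <- seg(j)
      if (inter(a[1, ], a[2, ], b[1, ], b[2, ])) return(FALSE)
    }
  }
  TRUE
}

rotate2d <- function(pts, angle_deg) {
  th <- angle_deg * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  pts %*% t(R)
}
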