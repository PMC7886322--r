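# 2D Delaunay triangulation (Bowyer-Watson). No computational-geometry
# package ships with the environment this package targets, so a small,
# dependency-free triangulator is provided. It is only ever called on a few
# hundred points per cross-section region, where the O(n * m) incremental
# scheme is ample.

#' Delaunay triangulation of a 2D point set
#'
#' Incremental Bowyer-Watson algorithm. Points are rescaled to the unit box
#' internally; a tiny amount of deterministic symmetry-breaking noise is the
#' caller's responsibility (regular grids contain co-circular quadruples).
#'
#' @param pts numeric matrix, n x 2, n >= 3. Duplicated points are an error.
#' @return integer matrix, m x 3, counter-clockwise vertex indices into `pts`.
#' @keywords internal
delaunay_triangulate <- function(pts) {
  n <- nrow(pts)
  if (n < 3) stop("need at least 3 points")
  if (anyDuplicated(round(pts, 12))) stop("duplicated points")
  mn <- apply(pts, 2, min)
  span <- max(apply(pts, 2, max) - mn, .Machine$double.eps)
  p <- sweep(pts, 2, mn) / span
  # enclosing super-triangle, far outside the unit box
  allp <- rbind(p, c(-20, -20), c(40, -20), c(0.5, 40))
  sup <- n + 1:3

  tri <- matrix(sup, nrow = 1)
  cc <- matrix(circumcircle(allp[tri[1, 1], ], allp[tri[1, 2], ], allp[tri[1, 3], ]), nrow = 1)

  for (ip in seq_len(n)) {
    px <- p[ip, 1]; py <- p[ip, 2]
    bad <- which((px - cc[, 1])^2 + (py - cc[, 2])^2 <= cc[, 3] * (1 + 1e-12))
    if (length(bad) == 0L) stop("triangulation failure: point outside all circumcircles")
    # cavity boundary = edges of bad triangles appearing exactly once
    bt <- tri[bad, , drop = FALSE]
    e <- rbind(bt[, c(1, 2)], bt[, c(2, 3)], bt[, c(3, 1)])
    key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
    single <- !(key %in% key[duplicated(key)])
    be <- e[single, , drop = FALSE]
    tri <- tri[-bad, , drop = FALSE]
    cc <- cc[-bad, , drop = FALSE]
    newt <- cbind(be, ip)
    newc <- t(apply(newt, 1, function(t3)
      circumcircle(allp[t3[1], ], allp[t3[2], ], allp[t3[3], ])))
    tri <- rbind(tri, newt)
    cc <- rbind(cc, newc)
  }
  keep <- rowSums(matrix(tri %in% sup, nrow = nrow(tri))) == 0
  tri <- tri[keep, , drop = FALSE]
  # orient counter-clockwise, drop degenerate slivers
  a2 <- (allp[tri[, 2], 1] - allp[tri[, 1], 1]) * (allp[tri[, 3], 2] - allp[tri[, 1], 2]) -
        (allp[tri[, 2], 2] - allp[tri[, 1], 2]) * (allp[tri[, 3], 1] - allp[tri[, 1], 1])
  flip <- a2 < 0
  tri[flip, ] <- tri[flip, c(1, 3, 2)]
  tri[abs(a2) > 1e-13, , drop = FALSE]
}

circumcircle <- function(a, b, c) {
  d <- 2 * (a[1] * (b[2] - c[2]) + b[1] * (c[2] - a[2]) + c[1] * (a[2] - b[2]))
  if (abs(d) < 1e-300) return(c(Inf, Inf, Inf))
  a2 <- sum(a^2); b2 <- sum(b^2); c2 <- sum(c^2)
  ux <- (a2 * (b[2] - c[2]) + b2 * (c[2] - a[2]) + c2 * (a[2] - b[2])) / d
  uy <- (a2 * (c[1] - b[1]) + b2 * (a[1] - c[1]) + c2 * (b[1] - a[1])) / d
  c(ux, uy, (a[1] - ux)^2 + (a[2] - uy)^2)
}
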