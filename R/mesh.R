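# Lofted quadratic tetrahedral meshing of the three-sub-tendon geometry.
#
# A single 2D template triangulation of the partitioned cross-section is
# built once (conforming across the two partition chords), then extruded
# along z with the per-level twist applied as a rigid in-plane rotation.
# Each triangular prism between consecutive levels is split into three
# tetrahedra with the minimum-global-index diagonal rule, which guarantees
# neighbouring prisms pick matching diagonals, i.e. a conforming mesh.
# Straight-sided 10-node tetrahedra are then formed by inserting shared
# edge-midpoint nodes. Finally interface nodes are duplicated per sub-tendon
# and matched into penalty pairs with a local (n, t1, t2) frame.

# ---------------------------------------------------------------------------
# 2D templates

points_in_polygon <- function(pts, poly) {
  n <- nrow(poly)
  inside <- rep(FALSE, nrow(pts))
  j <- n
  for (i in seq_len(n)) {
    yi <- poly[i, 2]; yj <- poly[j, 2]
    xi <- poly[i, 1]; xj <- poly[j, 1]
    denom <- yj - yi
    cr <- ((yi > pts[, 2]) != (yj > pts[, 2])) &
      (pts[, 1] < xi + (xj - xi) * (pts[, 2] - yi) / ifelse(denom == 0, Inf, denom))
    inside <- xor(inside, cr)
    j <- i
  }
  inside
}

min_dist_to_boundary <- function(pts, poly) {
  n <- nrow(poly)
  d2 <- rep(Inf, nrow(pts))
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    a <- poly[i, ]; b <- poly[j, ]
    ab <- b - a
    len2 <- sum(ab^2)
    t <- ((pts[, 1] - a[1]) * ab[1] + (pts[, 2] - a[2]) * ab[2]) / max(len2, 1e-300)
    t <- pmin(pmax(t, 0), 1)
    dx <- pts[, 1] - (a[1] + t * ab[1]); dy <- pts[, 2] - (a[2] + t * ab[2])
    d2 <- pmin(d2, dx^2 + dy^2)
  }
  sqrt(d2)
}

# Triangulate one convex region whose boundary points are FIXED (shared with
# neighbouring regions). Interior points come from a hexagonal grid; the grid
# is shifted deterministically and retried if the triangulation fails to
# reproduce the boundary edges.
triangulate_region <- function(boundary, h) {
  nb <- nrow(boundary)
  for (try. in 0:3) {
    off <- c(0.31, 0.17) * h * try.
    xr <- range(boundary[, 1]); yr <- range(boundary[, 2])
    dy <- h * sqrt(3) / 2
    ys <- if (yr[1] + 0.5 * dy > yr[2]) numeric(0) else
      seq(yr[1] + 0.5 * dy, yr[2], by = dy)
    interior <- NULL
    if (length(ys)) {
      rows <- lapply(seq_along(ys), function(k) {
        x0 <- xr[1] + off[1] + if (k %% 2 == 0) h / 2 else 0
        if (x0 > xr[2]) return(NULL)
        xs <- seq(x0, xr[2], by = h)
        cbind(xs, ys[k] + off[2])
      })
      interior <- do.call(rbind, rows)
    }
    if (!is.null(interior) && nrow(interior)) {
      keep <- points_in_polygon(interior, boundary)
      interior <- interior[keep, , drop = FALSE]
      if (nrow(interior)) {
        keep <- min_dist_to_boundary(interior, boundary) >= 0.55 * h
        interior <- interior[keep, , drop = FALSE]
      }
      if (nrow(interior)) {
        # deterministic symmetry breaking (regular grids are co-circular)
        ij <- seq_len(nrow(interior))
        interior <- interior + 1e-5 * h * cbind(sin(7.13 * ij), cos(3.71 * ij))
      }
    }
    pts <- rbind(boundary, interior)
    tri <- tryCatch(delaunay_triangulate(pts), error = function(e) NULL)
    if (is.null(tri)) next
    # Laplacian smoothing of interior points (boundary fixed), re-triangulated
    ni <- if (is.null(interior)) 0L else nrow(interior)
    if (ni > 0) {
      for (sm in 1:2) {
        nbr <- vector("list", nrow(pts))
        for (k in seq_len(nrow(tri))) {
          t3 <- tri[k, ]
          nbr[[t3[1]]] <- c(nbr[[t3[1]]], t3[2:3])
          nbr[[t3[2]]] <- c(nbr[[t3[2]]], t3[c(1, 3)])
          nbr[[t3[3]]] <- c(nbr[[t3[3]]], t3[1:2])
        }
        for (ip in nb + seq_len(ni)) {
          nn <- unique(nbr[[ip]])
          if (length(nn) >= 3) pts[ip, ] <- colMeans(pts[nn, , drop = FALSE])
        }
        tri2 <- tryCatch(delaunay_triangulate(pts), error = function(e) NULL)
        if (is.null(tri2)) break
        tri <- tri2
      }
    }
    # validation: all boundary edges present, full area covered
    edges <- rbind(tri[, 1:2], tri[, 2:3], tri[, c(3, 1)])
    ekey <- paste(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
    bi <- seq_len(nb); bj <- c(bi[-1], 1L)
    bkey <- paste(pmin(bi, bj), pmax(bi, bj))
    if (!all(bkey %in% ekey)) next
    area <- sum(vapply(seq_len(nrow(tri)), function(k)
      abs(polygon_signed_area(pts[tri[k, ], ])), numeric(1)))
    if (abs(area - polygon_area(boundary)) > 1e-6 * polygon_area(boundary)) next
    return(list(points = pts, tri = tri, n_boundary = nb))
  }
  stop("2D region triangulation failed")
}

subdivide_segment <- function(a, b, h) {
  len <- sqrt(sum((b - a)^2))
  k <- max(1L, round(len / (0.8 * h)))
  if (k == 1L) return(matrix(numeric(0), 0, 2))
  t <- seq_len(k - 1L) / k
  cbind(a[1] + t * (b[1] - a[1]), a[2] + t * (b[2] - a[2]))
}

# Conforming three-region template of the partitioned elliptical section,
# in the canonical (untwisted) frame.
section_template <- function(csa, fractions, aspect, h) {
  fractions <- fractions[SUB_TENDONS] / sum(fractions[SUB_TENDONS])
  a <- sqrt(csa * aspect / pi); b <- a / aspect
  per <- pi * (3 * (a + b) - sqrt((3 * a + b) * (a + 3 * b)))
  # boundary spacing must track h: a much finer boundary than the interior
  # grid breeds sliver triangles along the arcs
  n_arc <- max(16L, as.integer(ceiling(per / (0.8 * h))))
  th <- seq(0, 2 * pi, length.out = n_arc + 1L)[-(n_arc + 1L)]
  outer <- cbind(a * cos(th), b * sin(th))
  outer <- outer * sqrt(csa / polygon_area(outer))
  b_eff <- max(outer[, 2])

  f_sol <- fractions[["SOL"]]; f_mg <- fractions[["MG"]]
  c1 <- stats::uniroot(function(c.) polygon_area(clip_halfplane(outer, c(0, 1), c.)) - f_sol * csa,
                       lower = -b_eff * 0.999, upper = b_eff * 0.999, tol = 1e-12)$root
  post <- clip_halfplane(outer, c(0, -1), -c1)
  c2 <- stats::uniroot(function(c.) polygon_area(clip_halfplane(post, c(1, 0), c.)) - f_mg * csa,
                       lower = min(post[, 1]) * 0.999, upper = max(post[, 1]) * 0.999, tol = 1e-12)$root

  # chord-ellipse intersections: A_l / A_r on y = c1, B on x = c2 (upper arc)
  y <- outer[, 2]; x <- outer[, 1]
  nb <- nrow(outer)
  cross1 <- which((y <= c1) != (y[c(2:nb, 1)] <= c1))
  ipt <- function(i, fun) {
    j <- if (i == nb) 1L else i + 1L
    t <- fun(outer[i, ], outer[j, ])
    outer[i, ] + t * (outer[j, ] - outer[i, ])
  }
  pts1 <- t(vapply(cross1, ipt, numeric(2),
                   fun = function(p, q) (c1 - p[2]) / (q[2] - p[2])))
  A_l <- pts1[which.min(pts1[, 1]), ]; A_r <- pts1[which.max(pts1[, 1]), ]
  upper <- which(y > c1)
  cross2 <- which((x <= c2) != (x[c(2:nb, 1)] <= c2))
  pts2 <- t(vapply(cross2, ipt, numeric(2),
                   fun = function(p, q) (c2 - p[1]) / (q[1] - p[1])))
  B <- pts2[which.max(pts2[, 2]), ]
  C <- c(c2, c1)

  # shared boundary primitives
  near <- function(P, Q, tol) sqrt(sum((P - Q)^2)) < tol
  tol_sl <- 0.35 * h
  arc_ids <- seq_len(nb)
  ang <- atan2(y, x)
  # soleus (anterior) arc, ordered CCW from A_l through the bottom to A_r
  sol_arc <- arc_ids[y < c1]
  sol_arc <- sol_arc[order((ang[sol_arc] - atan2(A_l[2], A_l[1])) %% (2 * pi))]
  sol_arc <- sol_arc[!vapply(sol_arc, function(i) near(outer[i, ], A_r, tol_sl) ||
                               near(outer[i, ], A_l, tol_sl), logical(1))]
  # posterior arc, ordered CCW from A_r through the top to A_l
  post_arc <- arc_ids[y > c1]
  post_arc <- post_arc[order((ang[post_arc] - atan2(A_r[2], A_r[1])) %% (2 * pi))]
  post_arc <- post_arc[!vapply(post_arc, function(i) near(outer[i, ], A_r, tol_sl) ||
                                 near(outer[i, ], A_l, tol_sl) ||
                                 near(outer[i, ], B, tol_sl), logical(1))]
  lg_arc <- post_arc[x[post_arc] > c2]   # from A_r up to B
  mg_arc <- post_arc[x[post_arc] < c2]   # from B down to A_l

  reg <- new.env()
  reg$coords <- matrix(numeric(0), 0, 2)
  add_pts <- function(m) {
    if (!nrow(m)) return(integer(0))
    ids <- reg$n + seq_len(nrow(m))
    reg$coords <- rbind(reg$coords, m)
    reg$n <- reg$n + nrow(m)
    ids
  }
  reg$n <- 0L
  id_arc <- add_pts(outer)               # all arc vertices (some unused)
  id_Al <- add_pts(rbind(A_l)); id_Ar <- add_pts(rbind(A_r))
  id_B <- add_pts(rbind(B)); id_C <- add_pts(rbind(C))
  ch1L <- add_pts(subdivide_segment(A_l, C, h))   # A_l -> C interior points
  ch1R <- add_pts(subdivide_segment(C, A_r, h))   # C -> A_r
  ch2 <- add_pts(subdivide_segment(C, B, h))      # C -> B

  loops <- list(
    SOL = c(id_Al, id_arc[sol_arc], id_Ar, rev(ch1R), id_C, rev(ch1L)),
    MG  = c(id_B, id_arc[mg_arc], id_Al, ch1L, id_C, ch2),
    LG  = c(id_Ar, id_arc[lg_arc], id_B, rev(ch2), id_C, ch1R)
  )
  tris <- list(); labels <- character(0)
  for (nm in SUB_TENDONS) {
    loop <- loops[[nm]]
    bpts <- reg$coords[loop, , drop = FALSE]
    if (polygon_signed_area(bpts) < 0) { loop <- rev(loop); bpts <- bpts[rev(seq_len(nrow(bpts))), ] }
    tr <- triangulate_region(bpts, h)
    nbp <- tr$n_boundary
    np <- nrow(tr$points)
    gid <- integer(np)
    gid[seq_len(nbp)] <- loop
    if (np > nbp) gid[(nbp + 1L):np] <- add_pts(tr$points[(nbp + 1L):np, , drop = FALSE])
    tris[[nm]] <- matrix(gid[tr$tri], ncol = 3)
    labels <- c(labels, rep(nm, nrow(tr$tri)))
  }
  tri <- do.call(rbind, tris)
  used <- sort(unique(as.vector(tri)))
  remap <- integer(reg$n); remap[used] <- seq_along(used)
  pts <- reg$coords[used, , drop = FALSE]
  tri <- matrix(remap[tri], ncol = 3)
  # corner-vertex dedupe along the chords trims a sliver of boundary area;
  # rescale uniformly so the triangulated section area is exactly the CSA
  # (uniform scaling preserves the partition fractions and conformity)
  area_tot <- sum(vapply(seq_len(nrow(tri)), function(k)
    abs(polygon_signed_area(pts[tri[k, ], ])), numeric(1)))
  pts <- pts * sqrt(csa / area_tot)
  list(points = pts, tri = tri, label = labels)
}

# Structured rectangle template (verification bars); single region.
rect_template <- function(width, thickness, h, label = "SOL") {
  nx <- max(1L, ceiling(width / h)); ny <- max(1L, ceiling(thickness / h))
  xs <- seq(-width / 2, width / 2, length.out = nx + 1L)
  ys <- seq(-thickness / 2, thickness / 2, length.out = ny + 1L)
  pts <- as.matrix(expand.grid(x = xs, y = ys))
  id <- function(i, j) (j - 1L) * (nx + 1L) + i
  tris <- list()
  for (j in seq_len(ny)) for (i in seq_len(nx)) {
    n1 <- id(i, j); n2 <- id(i + 1L, j); n3 <- id(i + 1L, j + 1L); n4 <- id(i, j + 1L)
    tris[[length(tris) + 1L]] <- rbind(c(n1, n2, n3), c(n1, n3, n4))
  }
  list(points = pts, tri = do.call(rbind, tris),
       label = rep(label, 2L * nx * ny))
}

#' Rectangular single-material bar geometry (verification)
#'
#' A prismatic bar used as an analytic verification case (tip-loaded bar,
#' closed-form displacement FL/(EA)). Behaves like a degenerate single
#' sub-tendon labelled with `label`.
#'
#' @param width,thickness,length bar dimensions, mm.
#' @param label sub-tendon label used for material lookup.
#' @return object of class `bar_geometry`.
#' @export
bar_geometry <- function(width, thickness, length, label = "SOL") {
  stopifnot(width > 0, thickness > 0, length > 0, label %in% SUB_TENDONS)
  structure(list(width = width, thickness = thickness, length = length,
                 label = label), class = "bar_geometry")
}

# ---------------------------------------------------------------------------
# Lofting

# Dompierre minimum-index prism-to-tets split: bottom (v1,v2,v3), top
# (v4,v5,v6) with v4 above v1. Neighbouring prisms agree on quad-face
# diagonals because the rule depends on global indices only.
split_prism <- function(v) {
  i0 <- which.min(v)
  perm <- switch(i0,
                 `1` = c(1, 2, 3, 4, 5, 6), `2` = c(2, 3, 1, 5, 6, 4),
                 `3` = c(3, 1, 2, 6, 4, 5), `4` = c(4, 6, 5, 1, 3, 2),
                 `5` = c(5, 4, 6, 2, 1, 3), `6` = c(6, 5, 4, 3, 2, 1))
  p <- v[perm]
  if (min(p[2], p[6]) < min(p[3], p[5])) {
    rbind(p[c(1, 2, 3, 6)], p[c(1, 2, 6, 5)], p[c(1, 5, 6, 4)])
  } else {
    rbind(p[c(1, 2, 3, 5)], p[c(1, 5, 3, 6)], p[c(1, 5, 6, 4)])
  }
}

#' Loft a tendon geometry into a labelled TET10 mesh
#'
#' @param geometry a `tendon_geometry` (from [make_archetype()]) or a
#'   `bar_geometry`.
#' @param max_edge_length target maximum element edge length, mm.
#' @param axial_factor layer spacing as a fraction of `max_edge_length`.
#' @param merge_interfaces if `TRUE` the sub-tendons share nodes across
#'   interfaces (a single bonded continuum; used as the tied-contact oracle)
#'   and no interface pairs are created.
#' @return object of class `tendon_mesh` with fields `nodes` (N x 3, mm),
#'   `elements` (E x 10, VTK quadratic-tetra ordering), `label` (per
#'   element), `face_sets` (named list of m x 6 face matrices:
#'   `distal_*`, `proximal_*` per sub-tendon plus `exterior_*`), and
#'   `interface_pairs` (`a`, `b`, `normal`, `t1`, `t2`, `area`).
#' @export
loft_mesh <- function(geometry, max_edge_length, axial_factor = 0.7,
                      merge_interfaces = FALSE) {
  stopifnot(max_edge_length > 0)
  h <- max_edge_length
  h2d <- h
  if (inherits(geometry, "tendon_geometry")) {
    # shrink the 2D template spacing until no in-plane edge exceeds 1.2 h,
    # keeping the lofted diagonals under the declared 1.5 h bound
    for (k in 1:4) {
      tpl <- section_template(geometry$csa, unlist(geometry$fractions),
                              geometry$aspect, h2d)
      el <- max(vapply(seq_len(nrow(tpl$tri)), function(t.) {
        p <- tpl$points[tpl$tri[t., ], ]
        max(sqrt(sum((p[1, ] - p[2, ])^2)), sqrt(sum((p[2, ] - p[3, ])^2)),
            sqrt(sum((p[1, ] - p[3, ])^2)))
      }, numeric(1)))
      if (el <= 1.2 * h) break
      h2d <- h2d * 0.8
    }
    L <- geometry$length
    zs_sec <- vapply(geometry$sections, `[[`, numeric(1), "z")
    tw_sec <- vapply(geometry$sections, `[[`, numeric(1), "twist_angle")
    total <- geometry$twist
    rot_fun <- function(z) stats::approx(zs_sec, tw_sec, xout = z, rule = 2)$y - total
  } else if (inherits(geometry, "bar_geometry")) {
    tpl <- rect_template(geometry$width, geometry$thickness, h, geometry$label)
    L <- geometry$length
    rot_fun <- function(z) 0
  } else stop("unsupported geometry object")

  np2 <- nrow(tpl$points)
  nz <- max(1L, as.integer(ceiling(L / (axial_factor * h))))
  zlev <- L * (0:nz) / nz
  nodes <- do.call(rbind, lapply(seq_along(zlev), function(k) {
    p <- rotate2d(tpl$points, rot_fun(zlev[k]))
    cbind(p, zlev[k])
  }))

  ntri <- nrow(tpl$tri)
  tets <- matrix(0L, 3L * ntri * nz, 4)
  label <- character(3L * ntri * nz)
  r <- 0L
  for (k in seq_len(nz)) {
    base <- (k - 1L) * np2
    for (t in seq_len(ntri)) {
      v <- c(tpl$tri[t, ] + base, tpl$tri[t, ] + base + np2)
      tt <- split_prism(v)
      tets[r + 1:3, ] <- tt
      label[r + 1:3] <- tpl$label[t]
      r <- r + 3L
    }
  }

  # enforce positive orientation (corner order is free; faces are sets)
  storage.mode(tets) <- "integer"
  m <- tet_metrics(nodes, tets)
  if (any(m$vol6 == 0)) stop("degenerate (zero-volume) tetrahedra after lofting")
  neg <- m$vol6 < 0
  if (any(neg)) tets[neg, 2:3] <- tets[neg, c(3, 2)]

  # TET10: shared edge midpoints
  E <- nrow(tets)
  edge_pairs <- rbind(tets[, c(1, 2)], tets[, c(2, 3)], tets[, c(1, 3)],
                      tets[, c(1, 4)], tets[, c(2, 4)], tets[, c(3, 4)])
  lo <- pmin(edge_pairs[, 1], edge_pairs[, 2])
  hi <- pmax(edge_pairs[, 1], edge_pairs[, 2])
  key <- lo * (nrow(nodes) + 1) + hi
  uk <- !duplicated(key)
  mid_id <- nrow(nodes) + match(key, key[uk])
  mids <- (nodes[lo[uk], , drop = FALSE] + nodes[hi[uk], , drop = FALSE]) / 2
  nodes <- rbind(nodes, mids)
  elements <- cbind(tets, matrix(as.integer(mid_id), E, 6))

  mesh <- build_face_sets(nodes, elements, label, L, merge_interfaces)
  mesh$h <- h
  qm <- tet_metrics(mesh$nodes, mesh$elements)
  if (any(qm$vol6 <= 0)) stop("non-positive Jacobian after lofting")
  mesh$max_edge <- max(qm$max_edge)
  mesh$volume <- sum(qm$vol6) / 6
  mesh
}

# Face bookkeeping + interface-node duplication. Internal.
build_face_sets <- function(nodes, elements, label, L, merge_interfaces) {
  dimnames(nodes) <- NULL
  E <- nrow(elements)
  # faces: corner triples with their midside nodes (VTK tetra face/edge map)
  fc <- list(c(1, 2, 3, 5, 6, 7), c(1, 2, 4, 5, 9, 8),
             c(1, 3, 4, 7, 10, 8), c(2, 3, 4, 6, 10, 9))
  faces <- do.call(rbind, lapply(fc, function(ix) elements[, ix, drop = FALSE]))
  felem <- rep(seq_len(E), 4L)
  corn <- faces[, 1:3]
  skey <- apply(corn, 1, function(v) paste(sort(v), collapse = "_"))
  tab <- table(skey)
  once <- skey %in% names(tab[tab == 1L])
  twice_idx <- split(which(!once), skey[!once])

  boundary_faces <- faces[once, , drop = FALSE]
  boundary_owner <- felem[once]
  iface_rows <- lapply(twice_idx, function(ii) {
    if (length(ii) != 2L) stop("non-manifold face")
    if (label[felem[ii[1]]] != label[felem[ii[2]]]) ii else NULL
  })
  iface_rows <- iface_rows[!vapply(iface_rows, is.null, logical(1))]

  ztol <- 1e-6 * max(L, 1)
  z_of <- matrix(nodes[boundary_faces, 3], nrow = nrow(boundary_faces))
  is_distal <- apply(abs(z_of) < ztol, 1, all)
  is_prox <- apply(abs(z_of - L) < ztol, 1, all)

  face_sets <- list()
  for (st in unique(label)) {
    sel <- boundary_owner %in% which(label == st)
    for (kind in c("distal", "proximal", "exterior")) {
      rows <- switch(kind, distal = sel & is_distal, proximal = sel & is_prox,
                     exterior = sel & !is_distal & !is_prox)
      if (any(rows))
        face_sets[[paste(kind, st, sep = "_")]] <- boundary_faces[rows, , drop = FALSE]
    }
  }

  pairs <- list(a = integer(0), b = integer(0),
                normal = matrix(numeric(0), 0, 3), t1 = matrix(numeric(0), 0, 3),
                t2 = matrix(numeric(0), 0, 3), area = numeric(0),
                face_a = matrix(integer(0), 0, 3),
                t1_coef = matrix(numeric(0), 0, 2))

  if (!merge_interfaces && length(iface_rows)) {
    ifc_face <- do.call(rbind, lapply(iface_rows, function(ii) faces[ii[1], ]))
    ifc_e1 <- vapply(iface_rows, function(ii) felem[ii[1]], integer(1))
    ifc_e2 <- vapply(iface_rows, function(ii) felem[ii[2]], integer(1))
    ifc_nodes <- unique(as.vector(ifc_face))

    # element-membership labels per interface node
    lab_lv <- SUB_TENDONS[SUB_TENDONS %in% unique(label)]
    node_regs <- vector("list", length(ifc_nodes))
    names(node_regs) <- as.character(ifc_nodes)
    einc <- which(matrix(elements %in% ifc_nodes, nrow = E), arr.ind = TRUE)
    for (r in seq_len(nrow(einc))) {
      n <- as.character(elements[einc[r, 1], einc[r, 2]])
      node_regs[[n]] <- union(node_regs[[n]], label[einc[r, 1]])
    }
    copy_id <- new.env()
    nn <- nrow(nodes)
    extra <- list()
    for (n in ifc_nodes) {
      regs <- lab_lv[lab_lv %in% node_regs[[as.character(n)]]]
      assign(paste(n, regs[1]), n, envir = copy_id)
      for (rg in regs[-1]) {
        nn <- nn + 1L
        extra[[length(extra) + 1L]] <- nodes[n, ]
        assign(paste(n, rg), nn, envir = copy_id)
      }
    }
    if (length(extra)) nodes <- rbind(nodes, do.call(rbind, extra))
    lookup <- function(n, rg) {
      key <- paste(n, rg)
      if (exists(key, envir = copy_id, inherits = FALSE)) get(key, envir = copy_id) else n
    }
    # remap element connectivity
    for (r in seq_len(nrow(einc))) {
      e <- einc[r, 1]; cpos <- einc[r, 2]
      elements[e, cpos] <- lookup(elements[e, cpos], label[e])
    }
    # remap boundary face sets via owner labels
    for (nm in names(face_sets)) {
      fs <- face_sets[[nm]]
      st <- sub("^[a-z]+_", "", nm)
      for (r in seq_len(nrow(fs))) for (c. in 1:6)
        fs[r, c.] <- lookup(fs[r, c.], st)
      face_sets[[nm]] <- fs
    }

    # pairs with accumulated normals / tributary areas
    acc <- new.env(); acc$map <- list()
    for (f in seq_along(ifc_e1)) {
      fa <- ifc_face[f, ]
      la <- label[ifc_e1[f]]; lb <- label[ifc_e2[f]]
      if (match(la, lab_lv) > match(lb, lab_lv)) { tmp <- la; la <- lb; lb <- tmp
        e1 <- ifc_e2[f] } else e1 <- ifc_e1[f]
      p1 <- nodes[fa[1], ]; p2 <- nodes[fa[2], ]; p3 <- nodes[fa[3], ]
      nrm <- c((p2 - p1)[2] * (p3 - p1)[3] - (p2 - p1)[3] * (p3 - p1)[2],
               (p2 - p1)[3] * (p3 - p1)[1] - (p2 - p1)[1] * (p3 - p1)[3],
               (p2 - p1)[1] * (p3 - p1)[2] - (p2 - p1)[2] * (p3 - p1)[1])
      ar <- sqrt(sum(nrm^2)) / 2
      nrm <- nrm / (2 * ar)
      ecent <- colMeans(nodes[elements[e1, 1:4], , drop = FALSE])
      if (sum(nrm * (colMeans(rbind(p1, p2, p3)) - ecent)) < 0) nrm <- -nrm
      corners_a <- vapply(fa[1:3], lookup, integer(1), rg = la)
      for (n in fa) {
        ka <- lookup(n, la); kb <- lookup(n, lb)
        key <- paste(ka, kb)
        cur <- acc$map[[key]]
        if (is.null(cur)) cur <- list(a = ka, b = kb, nsum = c(0, 0, 0), area = 0,
                                      face_a = corners_a)
        cur$nsum <- cur$nsum + nrm * ar
        cur$area <- cur$area + ar / 6
        acc$map[[key]] <- cur
      }
    }
    plist <- acc$map
    P <- length(plist)
    pa <- integer(P); pb <- integer(P); nr <- matrix(0, P, 3); arv <- numeric(P)
    face_a <- matrix(0L, P, 3)
    for (i in seq_len(P)) {
      pa[i] <- plist[[i]]$a; pb[i] <- plist[[i]]$b
      nv <- plist[[i]]$nsum
      nr[i, ] <- nv / sqrt(sum(nv^2))
      arv[i] <- plist[[i]]$area
      face_a[i, ] <- plist[[i]]$face_a
    }
    ez <- c(0, 0, 1)
    t1 <- t(apply(nr, 1, function(n) {
      v <- ez - sum(ez * n) * n
      v / sqrt(sum(v^2))
    }))
    t2 <- cbind(nr[, 2] * t1[, 3] - nr[, 3] * t1[, 2],
                nr[, 3] * t1[, 1] - nr[, 1] * t1[, 3],
                nr[, 1] * t1[, 2] - nr[, 2] * t1[, 1])
    # coefficients expressing the longitudinal tangent in the reference edge
    # basis of the stored adjacent face: the frame convects with the face
    # deformation, and the normal is the face's own (the penalty constrains
    # the faceted surfaces, so the facet frame is the consistent one)
    tc <- matrix(0, P, 2)
    for (i in seq_len(P)) {
      E1 <- nodes[face_a[i, 2], ] - nodes[face_a[i, 1], ]
      E2 <- nodes[face_a[i, 3], ] - nodes[face_a[i, 1], ]
      G <- rbind(c(sum(E1 * E1), sum(E1 * E2)), c(sum(E1 * E2), sum(E2 * E2)))
      tc[i, ] <- solve(G, c(sum(E1 * t1[i, ]), sum(E2 * t1[i, ])))
    }
    ord <- order(pa, pb)
    pairs <- list(a = pa[ord], b = pb[ord], normal = nr[ord, , drop = FALSE],
                  t1 = t1[ord, , drop = FALSE], t2 = t2[ord, , drop = FALSE],
                  area = arv[ord], face_a = face_a[ord, , drop = FALSE],
                  t1_coef = tc[ord, , drop = FALSE])
  }

  structure(list(nodes = nodes, elements = elements, label = label,
                 face_sets = face_sets, interface_pairs = pairs, length = L),
            class = "tendon_mesh")
}

#' @export
print.tendon_mesh <- function(x, ...) {
  cat(sprintf("<tendon_mesh> %d nodes, %d TET10 elements (%s), %d interface pairs\n",
              nrow(x$nodes), nrow(x$elements),
              paste(names(table(x$label)), table(x$label), sep = ":", collapse = " "),
              length(x$interface_pairs$a)))
  invisible(x)
}

#' Mesh convergence by successive refinement
#'
#' Solves the load case on meshes of decreasing edge length until the
#' monitored scalar (mean longitudinal displacement of a proximal face)
#' changes by less than `criterion` between successive refinements, and
#' returns the coarser edge length of the converged pair.
#'
#' @param geometry geometry object accepted by [loft_mesh()].
#' @param materials a `material_map`.
#' @param load a `load_case`.
#' @param interface an `interface_model` (default bonded).
#' @param criterion relative-change stopping criterion (default 0.01, i.e.
#'   1 percent).
#' @param refinement_factor multiplicative edge-length reduction per step.
#' @param h0 starting edge length; defaults to a quarter of the section's
#'   larger semi-axis.
#' @param max_refine refinement budget before giving up.
#' @param monitor_face face-set name to monitor; default the proximal face
#'   of the soleus.
#' @return list with `max_edge_length` (the chosen, coarser value) and
#'   `table` (tibble of edge length, elements, monitored displacement,
#'   relative change).
#' @export
converge_mesh <- function(geometry, materials, load,
                          interface = interface_model("bonded"),
                          criterion = 0.01, refinement_factor = 0.7,
                          h0 = NULL, max_refine = 6L,
                          monitor_face = "proximal_SOL") {
  stopifnot(criterion > 0, refinement_factor > 0, refinement_factor < 1)
  if (is.null(h0)) {
    h0 <- if (inherits(geometry, "bar_geometry"))
      max(geometry$width, geometry$thickness) / 2
    else sqrt(geometry$csa) / 2
  }
  hs <- h0 * refinement_factor^(0:max_refine)
  prev <- NA_real_
  rows <- list()
  for (i in seq_along(hs)) {
    mesh <- loft_mesh(geometry, hs[i])
    if (!monitor_face %in% names(mesh$face_sets))
      stop("monitor face set not present: ", monitor_face)
    sol <- solve_static(mesh, materials, load, interface)
    u <- mean_face_displacement(sol, monitor_face)
    rel <- if (is.na(prev)) NA_real_ else abs(u - prev) / max(abs(u), 1e-300)
    rows[[i]] <- tibble::tibble(max_edge_length = hs[i],
                                n_elements = nrow(mesh$elements),
                                displacement = u, rel_change = rel)
    if (!is.na(rel) && rel < criterion) {
      return(list(max_edge_length = hs[i - 1],
                  table = do.call(rbind, rows)))
    }
    prev <- u
  }
  stop("mesh did not converge within the refinement budget")
}
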