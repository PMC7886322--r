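# Outcome measures: proximal soleus-face displacement, normalization to the
# frictionless condition, mean / peak von Mises stress, peak location and
# transverse face rotation.

#' Area-weighted mean longitudinal displacement of a face
#'
#' Nodal tributary areas (one sixth of each adjacent quadratic face's
#' reference area) weight the z-displacement average, making the measure
#' robust to non-uniform surface meshing.
#'
#' @param solution a `solution_field`.
#' @param face face-set name (e.g. `"proximal_SOL"`) or an m x 6 face matrix.
#' @return mean displacement, mm.
#' @export
mean_face_displacement <- function(solution, face = "proximal_SOL") {
  faces <- if (is.character(face)) solution$mesh$face_sets[[face]] else face
  if (is.null(faces) || nrow(faces) == 0) stop("empty face set")
  w <- numeric(nrow(solution$mesh$nodes))
  for (r in seq_len(nrow(faces))) {
    p <- solution$mesh$nodes[faces[r, 1:3], , drop = FALSE]
    v1 <- p[2, ] - p[1, ]; v2 <- p[3, ] - p[1, ]
    ar <- sqrt(sum(c(v1[2] * v2[3] - v1[3] * v2[2],
                     v1[3] * v2[1] - v1[1] * v2[3],
                     v1[1] * v2[2] - v1[2] * v2[1])^2)) / 2
    w[faces[r, ]] <- w[faces[r, ]] + ar / 6
  }
  idx <- which(w > 0)
  sum(solution$u[idx, 3] * w[idx]) / sum(w[idx])
}

von_mises_from_components <- function(s) {
  sqrt(0.5 * ((s[, 1] - s[, 2])^2 + (s[, 2] - s[, 3])^2 + (s[, 3] - s[, 1])^2) +
         3 * (s[, 4]^2 + s[, 5]^2 + s[, 6]^2))
}

#' Von Mises stress field from centroid Cauchy stresses
#'
#' sigma_vM = sqrt(3/2 dev(sigma):dev(sigma)).
#'
#' @param solution a `solution_field` (or an E x 6 stress matrix with
#'   columns 11, 22, 33, 12, 23, 13).
#' @return per-element von Mises stress, MPa.
#' @export
von_mises_field <- function(solution) {
  s <- if (inherits(solution, "solution_field")) solution$stress else solution
  von_mises_from_components(s)
}

# Element layer rings away from the fixed distal face (ring 1 touches it).
element_rings <- function(mesh, n_rings) {
  distal_nodes <- unique(unlist(lapply(
    mesh$face_sets[grepl("^distal_", names(mesh$face_sets))], as.vector)))
  ring <- integer(nrow(mesh$elements))
  frontier_nodes <- distal_nodes
  for (k in seq_len(n_rings)) {
    touch <- which(ring == 0L &
                     rowSums(matrix(mesh$elements %in% frontier_nodes,
                                    nrow = nrow(mesh$elements))) > 0)
    if (!length(touch)) break
    ring[touch] <- k
    frontier_nodes <- unique(as.vector(mesh$elements[touch, ]))
  }
  ring
}

#' Mean, peak and peak-location summary of the stress field
#'
#' The mean is the volume-weighted element average of von Mises stress over
#' the whole mesh (`weighting = "plain"` gives the unweighted element mean).
#' The peak is taken over elements at least `exclusion_layers` element rings
#' away from the fixed distal face, where the rigid constraint creates a
#' discretization-driven stress concentration. The peak location is reported
#' as centroid coordinates, owning sub-tendon, and a surface region from the
#' dominant axis of the nearest exterior face normal (+/-y posterior /
#' anterior, +/-x lateral / medial, interface-adjacent or buried elements
#' "internal"; near-ties go to "internal").
#'
#' @param solution a `solution_field`.
#' @param exclusion_layers element rings excluded next to the distal face.
#' @param weighting `"volume"` or `"plain"` element averaging for the mean.
#' @return list with `mean_vm`, `peak_vm` (MPa) and `peak_location`
#'   (`coords`, `sub_tendon`, `region`).
#' @export
stress_summaries <- function(solution, exclusion_layers = 1L,
                             weighting = c("volume", "plain")) {
  weighting <- match.arg(weighting)
  stopifnot(exclusion_layers >= 0)
  mesh <- solution$mesh
  vm <- solution$vm
  vol <- tet_metrics(mesh$nodes, mesh$elements)$vol6 / 6
  mean_vm <- if (weighting == "volume") sum(vm * vol) / sum(vol) else mean(vm)

  keep <- rep(TRUE, length(vm))
  if (exclusion_layers > 0) {
    ring <- element_rings(mesh, exclusion_layers)
    keep <- ring == 0L | ring > exclusion_layers
  }
  if (!any(keep)) stop("all elements excluded from the peak search")
  pe <- which(keep)[which.max(vm[keep])]
  peak_vm <- vm[pe]
  coords <- colMeans(mesh$nodes[mesh$elements[pe, 1:4], , drop = FALSE])

  region <- "internal"
  enodes <- mesh$elements[pe, ]
  ext_sets <- mesh$face_sets[grepl("^exterior_", names(mesh$face_sets))]
  ifc_nodes <- unique(c(mesh$interface_pairs$a, mesh$interface_pairs$b))
  on_iface <- any(enodes %in% ifc_nodes)
  best <- NULL
  for (fs in ext_sets) {
    hit <- which(rowSums(matrix(fs[, 1:3] %in% enodes[1:4], nrow = nrow(fs))) == 3)
    if (length(hit)) { best <- fs[hit[1], ]; break }
  }
  if (!is.null(best) && !on_iface) {
    p <- mesh$nodes[best[1:3], , drop = FALSE]
    v1 <- p[2, ] - p[1, ]; v2 <- p[3, ] - p[1, ]
    nrm <- c(v1[2] * v2[3] - v1[3] * v2[2], v1[3] * v2[1] - v1[1] * v2[3],
             v1[1] * v2[2] - v1[2] * v2[1])
    nrm <- nrm / sqrt(sum(nrm^2))
    if (sum(nrm * (colMeans(p) - coords)) < 0) nrm <- -nrm
    ax <- abs(nrm[1:2])
    if (abs(ax[1] - ax[2]) < 0.05 * max(ax)) region <- "internal"
    else if (ax[2] > ax[1]) region <- if (nrm[2] > 0) "posterior" else "anterior"
    else region <- if (nrm[1] > 0) "lateral" else "medial"
  }
  list(mean_vm = mean_vm, peak_vm = peak_vm,
       peak_location = list(coords = coords,
                            sub_tendon = mesh$label[pe], region = region))
}

#' Normalize a sweep to its frictionless rows
#'
#' Within each (model, loaded sub-tendon) group, displacement and mean
#' stress are divided by the frictionless value, exposing the relative
#' effect of increasing inter-sub-tendon cohesion.
#'
#' @param sweep tibble from [run_full_sweep()].
#' @return the sweep with `normalized_displacement` and `mean_vm_normalized`
#'   recomputed.
#' @export
normalize_sweep <- function(sweep) {
  key <- paste(sweep$model_id, sweep$loaded)
  out <- sweep
  out$normalized_displacement <- NA_real_
  out$mean_vm_normalized <- NA_real_
  for (k in unique(key)) {
    rows <- which(key == k)
    ref <- rows[sweep$interface[rows] == "frictionless"]
    if (length(ref) != 1) stop("missing (or duplicated) frictionless reference in group ", k)
    d0 <- sweep$soleus_face_displacement[ref]
    s0 <- sweep$mean_vm[ref]
    if (d0 == 0) stop("zero frictionless reference displacement in group ", k)
    out$normalized_displacement[rows] <- sweep$soleus_face_displacement[rows] / d0
    out$mean_vm_normalized[rows] <- sweep$mean_vm[rows] / s0
  }
  out
}

#' Best-fit transverse rotation of a face
#'
#' Least-squares rigid rotation angle about the longitudinal (z) axis
#' mapping the reference in-plane face node positions to the deformed ones
#' (2D orthogonal Procrustes about the face centroid).
#'
#' @param solution a `solution_field`.
#' @param face face-set name or face matrix.
#' @return rotation angle, degrees (positive = counter-clockwise looking
#'   from proximal).
#' @export
face_rotation <- function(solution, face = "proximal_SOL") {
  faces <- if (is.character(face)) solution$mesh$face_sets[[face]] else face
  if (is.null(faces) || nrow(faces) == 0) stop("empty face set")
  ids <- unique(as.vector(faces))
  X <- solution$mesh$nodes[ids, 1:2, drop = FALSE]
  if (nrow(X) < 3) stop("need at least 3 face nodes")
  Y <- X + solution$u[ids, 1:2, drop = FALSE]
  Xc <- sweep(X, 2, colMeans(X)); Yc <- sweep(Y, 2, colMeans(Y))
  if (min(svd(Xc)$d) < 1e-9 * max(svd(Xc)$d)) stop("collinear face nodes")
  ang <- atan2(sum(Xc[, 1] * Yc[, 2] - Xc[, 2] * Yc[, 1]),
               sum(Xc[, 1] * Yc[, 1] + Xc[, 2] * Yc[, 2]))
  ang * 180 / pi
}
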