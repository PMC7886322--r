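# Parametric three-sub-tendon geometry.
#
# The three Achilles sub-tendons arise from the lateral gastrocnemius (LG),
# medial gastrocnemius (MG) and soleus (SOL) muscles. Dissection studies give
# only a handful of quantitative geometric facts per specimen: total
# cross-sectional area (CSA), free-tendon length, the proximal arrangement
# (SOL anterior, MG posterior-medial, LG posterior-lateral) and a qualitative
# lateral twist moving distally. The generator here encodes exactly those
# facts: an elliptical outer boundary is partitioned by two chords into three
# regions with prescribed area fractions, stacked along the longitudinal axis
# with a linear twist.
#
# Coordinates: z longitudinal (+z proximal, z = 0 the fixed distal face),
# x lateral (+x lateral, -x medial), y posterior (+y posterior, -y anterior).
# Units mm / N / MPa throughout.

#' Sub-tendon identifiers
#'
#' The three sub-tendons of the Achilles: lateral gastrocnemius (`"LG"`),
#' medial gastrocnemius (`"MG"`) and soleus (`"SOL"`).
#' @export
SUB_TENDONS <- c("LG", "MG", "SOL")

# Table-1 mean sub-tendon CSAs (mm^2), used as default area fractions.
.default_fractions <- c(LG = 9.3, MG = 13.4, SOL = 32.8) / (9.3 + 13.4 + 32.8)

.archetype_defaults <- list(
  `1` = list(length = 70, csa = 89.1, twist = 90),
  `2` = list(length = 40, csa = 90.4, twist = 40),
  `3` = list(length = 40, csa = 42.3, twist = 40)
)

#' Build one partitioned elliptical cross-section
#'
#' An ellipse of the requested total area is split by a horizontal chord
#' (separating the anterior soleus region) and a vertical chord (splitting
#' the posterior part into medial MG and lateral LG) so that the partition
#' areas match the requested fractions. The whole section is then rotated by
#' `twist_offset` about the longitudinal axis.
#'
#' @param csa total cross-sectional area, mm^2.
#' @param fractions named numeric, area fractions for LG, MG, SOL (sum 1).
#' @param z axial position, mm.
#' @param twist_angle rotation relative to the distal section, degrees
#'   (stored metadata).
#' @param twist_offset absolute rotation applied to the section, degrees.
#' @param aspect ellipse width-to-thickness ratio (lateral semi-axis over
#'   posterior semi-axis).
#' @param n_arc number of vertices used to discretise the ellipse boundary.
#' @return a `cross_section` list with elements `z`, `outer_boundary`,
#'   `partitions` (named list of polygons) and `twist_angle`.
#' @export
cross_section <- function(csa, fractions = .default_fractions, z = 0,
                          twist_angle = 0, twist_offset = twist_angle,
                          aspect = 2.5, n_arc = 96) {
  stopifnot(csa > 0, aspect > 0, n_arc >= 16)
  fractions <- fractions[SUB_TENDONS]
  if (any(is.na(fractions)) || any(fractions <= 0))
    stop("fractions must be positive and named LG, MG, SOL")
  fractions <- fractions / sum(fractions)

  a <- sqrt(csa * aspect / pi)      # lateral semi-axis
  b <- a / aspect                   # posterior semi-axis
  th <- seq(0, 2 * pi, length.out = n_arc + 1L)[-(n_arc + 1L)]
  outer <- cbind(a * cos(th), b * sin(th))
  outer <- outer * sqrt(csa / polygon_area(outer))  # exact polygon area
  b_eff <- max(outer[, 2])

  # anterior chord: SOL = { y <= c1 }
  f_sol <- fractions[["SOL"]]
  c1 <- stats::uniroot(function(c.) polygon_area(clip_halfplane(outer, c(0, 1), c.)) - f_sol * csa,
                       lower = -b_eff * 0.999, upper = b_eff * 0.999, tol = 1e-12)$root
  sol <- clip_halfplane(outer, c(0, 1), c1)
  post <- clip_halfplane(outer, c(0, -1), -c1)

  # medial chord within the posterior part: MG = { x <= c2 }
  a_eff <- max(post[, 1]); a_min <- min(post[, 1])
  f_mg <- fractions[["MG"]]
  c2 <- stats::uniroot(function(c.) polygon_area(clip_halfplane(post, c(1, 0), c.)) - f_mg * csa,
                       lower = a_min * 0.999, upper = a_eff * 0.999, tol = 1e-12)$root
  mg <- clip_halfplane(post, c(1, 0), c2)
  lg <- clip_halfplane(post, c(-1, 0), -c2)

  parts <- list(LG = lg, MG = mg, SOL = sol)
  if (twist_offset != 0) {
    outer <- rotate2d(outer, twist_offset)
    parts <- lapply(parts, rotate2d, angle_deg = twist_offset)
  }
  structure(list(z = z, outer_boundary = outer, partitions = parts,
                 twist_angle = twist_angle, chords = c(anterior = c1, medial = c2)),
            class = "cross_section")
}

#' Parametric archetype geometries
#'
#' Three archetypes mirror the dissected free Achilles tendons the pipeline
#' emulates: archetype 1 is long (70 mm, 89.1 mm^2) with the largest twist
#' (90 degrees total), archetype 2 short and thick (40 mm, 90.4 mm^2, 40
#' degrees), archetype 3 short and thin (40 mm, 42.3 mm^2, 40 degrees).
#' Sections are spaced 10 mm apart; twist is linear in z and oriented so the
#' proximal section carries the canonical arrangement (SOL anterior, MG
#' posterior-medial, LG posterior-lateral) with the stack rotating laterally
#' toward the distal end.
#'
#' @param model_id 1, 2 or 3.
#' @param overrides named list; recognised keys `csa`, `length`, `twist`
#'   (total twist, degrees), `fractions` (named LG/MG/SOL), `aspect`,
#'   `section_spacing`, `n_arc`.
#' @return a `tendon_geometry` object.
#' @export
make_archetype <- function(model_id, overrides = list()) {
  key <- as.character(model_id)
  if (!key %in% names(.archetype_defaults)) stop("unknown model_id: ", model_id)
  def <- .archetype_defaults[[key]]
  allowed <- c("csa", "length", "twist", "fractions", "aspect",
               "section_spacing", "n_arc")
  bad <- setdiff(names(overrides), allowed)
  if (length(bad)) stop("unknown override keys: ", paste(bad, collapse = ", "))
  p <- list(csa = def$csa, length = def$length, twist = def$twist,
            fractions = .default_fractions, aspect = 2.5,
            section_spacing = 10, n_arc = 96)
  p[names(overrides)] <- overrides
  if (p$csa <= 0 || p$length <= 0) stop("overrides produce non-positive geometry")
  if (any(unlist(p$fractions) <= 0)) stop("overrides produce non-positive areas")

  zs <- seq(0, p$length, by = p$section_spacing)
  if (zs[length(zs)] < p$length) zs <- c(zs, p$length)
  sections <- lapply(zs, function(z) {
    tw <- p$twist * z / p$length
    cross_section(p$csa, p$fractions, z = z, twist_angle = tw,
                  twist_offset = tw - p$twist, aspect = p$aspect, n_arc = p$n_arc)
  })
  geo <- structure(list(sections = sections, length = p$length,
                        model_id = model_id, section_spacing = p$section_spacing,
                        csa = p$csa, twist = p$twist,
                        fractions = p$fractions, aspect = p$aspect),
                   class = "tendon_geometry")
  validate_geometry(geo)
  geo
}

#' Validate a tendon geometry against its structural invariants
#'
#' Checks section ordering, twist monotonicity, polygon simplicity,
#' positive partition areas and the 1 mm^2 partition-area closure.
#'
#' @param geometry a `tendon_geometry`.
#' @return the geometry, invisibly; errors on violation.
#' @export
validate_geometry <- function(geometry) {
  stopifnot(inherits(geometry, "tendon_geometry"))
  zs <- vapply(geometry$sections, `[[`, numeric(1), "z")
  if (length(zs) < 2) stop("need at least 2 sections")
  if (zs[1] != 0 || any(diff(zs) <= 0)) stop("z must increase strictly from 0")
  if (abs(zs[length(zs)] - geometry$length) > 1e-9) stop("last section must sit at z = length")
  tw <- vapply(geometry$sections, `[[`, numeric(1), "twist_angle")
  if (any(diff(tw) < -1e-9) && any(diff(tw) > 1e-9)) stop("twist must be monotone in z")
  for (s in geometry$sections) {
    areas <- vapply(s$partitions, polygon_area, numeric(1))
    if (any(areas <= 0)) stop("degenerate partition (area <= 0)")
    if (abs(sum(areas) - polygon_area(s$outer_boundary)) > 1)
      stop("partition areas do not close the outer area within 1 mm^2")
    if (!all(vapply(s$partitions, polygon_is_simple, logical(1))))
      stop("non-simple partition polygon")
  }
  invisible(geometry)
}

#' Per-section sub-tendon areas
#'
#' @param geometry a `tendon_geometry`.
#' @return tibble with columns `z`, `sub_tendon`, `area_mm2`.
#' @export
section_areas <- function(geometry) {
  stopifnot(inherits(geometry, "tendon_geometry"))
  rows <- lapply(geometry$sections, function(s) {
    areas <- vapply(s$partitions, polygon_area, numeric(1))
    if (any(areas <= 0)) stop("degenerate partition polygon (area <= 0)")
    tibble::tibble(z = s$z, sub_tendon = names(areas), area_mm2 = unname(areas))
  })
  do.call(rbind, rows)
}

#' @export
print.tendon_geometry <- function(x, ...) {
  cat(sprintf("<tendon_geometry> archetype %s: length %g mm, CSA %g mm^2, twist %g deg, %d sections\n",
              as.character(x$model_id), x$length, x$csa, x$twist, length(x$sections)))
  invisible(x)
}
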