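# End-to-end orchestration of the simulation grid and the report tables.

#' Run the full interface-by-load sweep for one archetype
#'
#' Builds the geometry and mesh, solves all interface modes (frictionless,
#' the frictional coefficients, bonded) crossed with the three isolated
#' 100 N load cases, and post-processes each solution into the sweep table:
#' mean proximal soleus-face displacement, its normalization to the
#' frictionless row, volume-weighted mean and peak von Mises stress, peak
#' location, and transverse face rotation.
#'
#' @param model_id archetype 1, 2 or 3 (or a ready `tendon_geometry`).
#' @param materials a `material_map`.
#' @param max_edge_length mesh edge length, mm.
#' @param mu_values frictional coefficients to sweep.
#' @param force per-sub-tendon load, N.
#' @param ramp_steps load increments per solve.
#' @param k_n,k_t interface penalty stiffnesses, MPa/mm.
#' @param exclusion_layers distal element rings excluded from the peak.
#' @param overrides geometry overrides (when `model_id` is an id).
#' @param out_dir optional output directory; when given, the sweep table is
#'   written as CSV, each solution as VTU, plus a JSON run manifest.
#' @param keep_solutions keep the solution fields in the result.
#' @return tibble (class `sweep_result`): one row per grid point with the
#'   outcome measures; solutions attached as attribute `"solutions"` when
#'   requested.
#' @export
run_full_sweep <- function(model_id, materials = material_map(),
                           max_edge_length = 2.5,
                           mu_values = c(0.2, 0.4, 0.6, 0.8, 1.0),
                           force = 100, ramp_steps = 2L,
                           k_n = 1000, k_t = 1000, exclusion_layers = 1L,
                           overrides = list(), out_dir = NULL,
                           keep_solutions = FALSE) {
  geometry <- if (inherits(model_id, "tendon_geometry")) model_id
              else make_archetype(model_id, overrides)
  mid <- if (inherits(model_id, "tendon_geometry")) model_id$model_id else model_id
  mesh <- loft_mesh(geometry, max_edge_length)
  interfaces <- default_interface_grid(mu_values, k_n = k_n, k_t = k_t)
  loads <- lapply(SUB_TENDONS, function(st) load_case(st, force, ramp_steps))
  sols <- run_load_cases(mesh, materials, interfaces, loads)
  grid <- attr(sols, "grid")

  rows <- lapply(seq_along(sols), function(k) {
    s <- sols[[k]]
    ss <- stress_summaries(s, exclusion_layers)
    tibble::tibble(model_id = mid,
                   interface = grid$interface[k], mu = grid$mu[k],
                   loaded = grid$loaded[k],
                   soleus_face_displacement = mean_face_displacement(s, "proximal_SOL"),
                   mean_vm = ss$mean_vm, peak_vm = ss$peak_vm,
                   peak_x = ss$peak_location$coords[1],
                   peak_y = ss$peak_location$coords[2],
                   peak_z = ss$peak_location$coords[3],
                   peak_sub_tendon = ss$peak_location$sub_tendon,
                   peak_region = ss$peak_location$region,
                   face_rotation = face_rotation(s, "proximal_SOL"))
  })
  sweep <- normalize_sweep(do.call(rbind, rows))
  class(sweep) <- c("sweep_result", class(sweep))

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    csv <- file.path(out_dir, sprintf("sweep_model%s.csv", mid))
    utils::write.csv(sweep, csv, row.names = FALSE)
    files <- csv
    for (k in seq_along(sols)) {
      vtu <- file.path(out_dir, sprintf("model%s_%s_%s_%s.vtu", mid,
                                        grid$interface[k],
                                        ifelse(is.na(grid$mu[k]), "na", grid$mu[k]),
                                        grid$loaded[k]))
      write_vtu(sols[[k]], vtu)
      files <- c(files, vtu)
    }
    manifest <- list(model_id = mid, max_edge_length = max_edge_length,
                     mu_values = mu_values, force = force,
                     n_elements = nrow(mesh$elements),
                     package_version = as.character(utils::packageVersion("subtendon")),
                     files = lapply(files, function(f)
                       list(path = f, md5 = unname(tools::md5sum(f)))))
    jsonlite::write_json(manifest, file.path(out_dir, sprintf("manifest_model%s.json", mid)),
                         auto_unbox = TRUE, digits = NA)
  }
  if (keep_solutions) attr(sweep, "solutions") <- sols
  sweep
}

#' In vitro report: summary table, omnibus tests and post hoc stars
#'
#' @param records per-specimen table (default the packaged dataset).
#' @param threshold post hoc significance threshold.
#' @return list with `summary` (mean/SD per metric and sub-tendon, with the
#'   post hoc significance stars on LG/MG), `kruskal_wallis` (per metric)
#'   and `posthoc` tibbles.
#' @export
run_invitro_report <- function(records = read_specimen_table(), threshold = 0.017) {
  if (length(unique(records$specimen)) < 2) stop("need at least 2 specimens")
  summ <- summarize_group(records)
  kw <- do.call(rbind, lapply(.metric_cols, function(m) {
    groups <- lapply(split(records[[m]], records$sub_tendon), identity)
    tst <- kruskal_wallis(groups)
    tibble::tibble(metric = m, H = tst$statistic, p_value = tst$p_value)
  }))
  ph <- posthoc_vs_soleus(records, threshold)
  if (nrow(ph)) {
    summ$starred <- mapply(function(st, m) {
      hit <- ph$significant[ph$sub_tendon == st & ph$metric == m]
      length(hit) == 1 && hit
    }, summ$sub_tendon, summ$metric)
  }
  list(summary = summ, kruskal_wallis = kw, posthoc = ph)
}

#' Male/female subgroup means of whole-tendon CSA and failure force
#'
#' Per-specimen combined values (sum over the three sub-tendons) averaged
#' within sex, read from the age-sex specimen code.
#'
#' @param records per-specimen table.
#' @return tibble with `sex`, `combined_csa_mm2`, `combined_failure_force_n`.
#' @export
sex_subgroup_means <- function(records = read_specimen_table()) {
  sex <- ifelse(grepl("M$", records$specimen), "M", "F")
  agg <- stats::aggregate(cbind(csa_mm2, failure_force_n) ~ specimen,
                          data = cbind(records, sex = sex), FUN = sum)
  agg$sex <- ifelse(grepl("M$", agg$specimen), "M", "F")
  out <- stats::aggregate(cbind(csa_mm2, failure_force_n) ~ sex, data = agg, FUN = mean)
  tibble::tibble(sex = out$sex, combined_csa_mm2 = out$csa_mm2,
                 combined_failure_force_n = out$failure_force_n)
}
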