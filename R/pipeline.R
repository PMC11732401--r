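input_error <- function(...) {
  stop(errorCondition(paste0(...), class = c("atriamesh_input_error",
                                             "error", "condition")))
}

#' Load and validate a pipeline configuration
#'
#' YAML configuration with strict key checking (unknown keys are rejected).
#' All defaults are materialised so the resolved configuration written by
#' [run_pipeline] is complete.
#'
#' @param path YAML file path, or a named list.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(path) {
  cfg <- if (is.character(path)) {
    if (!file.exists(path)) input_error("config file not found: ", path)
    yaml::read_yaml(path)
  } else as.list(path)
  known <- c("output_dir", "seed", "contours", "target_mesh", "cloud",
             "structures", "fields", "contact_threshold_mm",
             "reconstruction", "gicp", "exclusions", "poisson_depth")
  extra <- setdiff(names(cfg), known)
  if (length(extra) > 0L)
    input_error("unknown config keys: ", paste(extra, collapse = ", "))
  cfg$output_dir <- cfg$output_dir %||% "atriamesh_out"
  cfg$seed <- as.integer(cfg$seed %||% 1L)
  cfg$contact_threshold_mm <- cfg$contact_threshold_mm %||% 3
  cfg$poisson_depth <- cfg$poisson_depth %||% 6L
  rknown <- names(formals(reconstruction_config))
  rextra <- setdiff(names(cfg$reconstruction), rknown)
  if (length(rextra) > 0L)
    input_error("unknown reconstruction config keys: ",
                paste(rextra, collapse = ", "))
  cfg$reconstruction <- do.call(reconstruction_config,
                                cfg$reconstruction %||% list())
  gknown <- names(formals(gicp_config))
  gextra <- setdiff(names(cfg$gicp), gknown)
  if (length(gextra) > 0L)
    input_error("unknown gicp config keys: ", paste(gextra, collapse = ", "))
  cfg$gicp <- do.call(gicp_config, cfg$gicp %||% list())
  structure(cfg, class = "pipeline_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full reconstruction-registration-analysis pipeline
#'
#' Orchestrates: contour reconstruction, optional target acquisition (a
#' given mesh or a Poisson reconstruction from a point cloud), exclusion
#' editing, generalized-ICP registration, geometric/clinical comparison,
#' proximity analysis against adjacent structures, and contact statistics
#' for supplied vertex fields. All artefacts are written under
#' `output_dir`: meshes, the transform, JSON reports, proximity CSVs, a
#' resolved configuration and a timing log.
#'
#' @param cfg a [pipeline_config] (or path/list accepted by it).
#' @return invisible list with the main in-memory results (`recon`,
#'   `registration`, `comparison`, `proximity`, `contact_stats`,
#'   `report`).
#' @export
run_pipeline <- function(cfg) {
  if (!inherits(cfg, "pipeline_config")) cfg <- pipeline_config(cfg)
  out <- cfg$output_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out, "pipeline.log")
  logf <- function(...) {
    line <- paste0(format(Sys.time(), "%H:%M:%S"), " ", ...)
    cat(line, "\n", file = log_path, append = TRUE)
    message(line)
  }
  timing <- function(stage, expr) {
    t0 <- proc.time()[["elapsed"]]
    r <- tryCatch(expr, error = function(e) {
      logf("stage '", stage, "' FAILED: ", conditionMessage(e))
      stop(e)
    })
    logf("stage '", stage, "' done in ",
         round(proc.time()[["elapsed"]] - t0, 2), " s")
    r
  }
  yaml::write_yaml(unclass_config(cfg), file.path(out, "resolved_config.yaml"))
  logf("pipeline start, seed ", cfg$seed)
  results <- list()
  report <- list(seed = cfg$seed)

  if (is.null(cfg$contours)) input_error("config: 'contours' input is required")
  if (!file.exists(cfg$contours))
    input_error("contours file not found: ", cfg$contours)
  cs <- timing("read_contours", read_contours(cfg$contours))
  if (!is.null(cs$transverse))
    cs <- timing("align_axial_stack", align_axial_stack(cs))
  recon <- timing("reconstruct", reconstruct(cs, cfg$reconstruction))
  results$recon <- recon
  write_mesh(recon$mesh, file.path(out, "mri_reconstruction.ply"))
  report$reconstruction <- list(
    contour_distance_mean_mm = recon$distance$mean,
    contour_distance_sd_mm = recon$distance$sd,
    volume_ml = enclosed_volume(recon$mesh),
    surface_area_mm2 = surface_area(recon$mesh),
    n_vertices = nrow(recon$mesh$vertices),
    iterations = recon$iterations, converged = recon$converged)

  target <- NULL
  if (!is.null(cfg$target_mesh)) {
    if (!file.exists(cfg$target_mesh))
      input_error("target mesh not found: ", cfg$target_mesh)
    target <- read_mesh(cfg$target_mesh)
  } else if (!is.null(cfg$cloud)) {
    if (!file.exists(cfg$cloud)) input_error("cloud file not found: ", cfg$cloud)
    cloud <- as.matrix(utils::read.csv(cfg$cloud))[, 1:3]
    cloud <- trim_cloud_outliers(cloud)
    target <- timing("poisson_reconstruct",
                     poisson_reconstruct(cloud, depth = cfg$poisson_depth))
    write_mesh(target, file.path(out, "icus_reconstruction.ply"))
  }

  T_reg <- NULL
  if (!is.null(target)) {
    regions <- NULL
    if (!is.null(cfg$exclusions)) {
      regions <- lapply(cfg$exclusions, function(d)
        exclusion_region(unlist(d$center_mm), d$radius_mm,
                         label = d$label %||% "other"))
    }
    src_edit <- if (is.null(regions)) recon$mesh else
      exclude_regions(recon$mesh, regions, cap_holes = TRUE)
    tgt_edit <- if (is.null(regions)) target else
      exclude_regions(target, regions, cap_holes = TRUE)
    reg <- timing("generalized_icp",
                  generalized_icp(src_edit, tgt_edit, cfg$gicp))
    results$registration <- reg
    T_reg <- reg$transform
    write_transform(T_reg, file.path(out, "transform.json"))
    moved <- apply_transform(recon$mesh, T_reg)
    write_mesh(moved, file.path(out, "mri_registered.ply"))
    comp <- timing("compare", compare_reconstructions(moved, target,
                                                      regions = regions))
    results$comparison <- comp
    report$comparison <- list(
      distance_mean_mm = comp$distance$mean,
      distance_sd_mm = comp$distance$sd,
      distance_a_to_b_mm = comp$distance$mean_a_to_b,
      distance_b_to_a_mm = comp$distance$mean_b_to_a,
      volume_mri_ml = comp$volume_a_ml, volume_target_ml = comp$volume_b_ml,
      relative_volume_pct = comp$relative_volume_pct,
      gicp_rms_mm = reg$rms, gicp_iterations = reg$iterations)
  }

  if (!is.null(cfg$structures) && length(cfg$structures) > 0L) {
    # proximity runs on the mesh that carries the conduction fields: the
    # target (mapping-system) reconstruction when present, otherwise the
    # registered contour reconstruction; structures follow the same
    # registration transform as the chamber
    la <- if (!is.null(target)) target
          else if (is.null(T_reg)) recon$mesh
          else apply_transform(recon$mesh, T_reg)
    prs <- list()
    for (sp in cfg$structures) {
      if (!file.exists(sp)) input_error("structure mesh not found: ", sp)
      st <- read_mesh(sp)
      if (!is.null(T_reg)) st <- apply_transform(st, T_reg)
      lab <- tools::file_path_sans_ext(basename(sp))
      prs[[lab]] <- structure_distance(la, st, structure_label = lab)
    }
    prox <- timing("proximity",
                   contact_mask(prs, threshold = cfg$contact_threshold_mm))
    results$proximity <- prox
    write_proximity(prox, file.path(out, "proximity.csv"))
    report$proximity <- list(
      structures = names(prs),
      contact_vertices = sum(prox$contact),
      total_vertices = length(prox$contact),
      threshold_mm = cfg$contact_threshold_mm)

    if (!is.null(cfg$fields) && length(cfg$fields) > 0L) {
      stats_list <- list()
      for (fp in cfg$fields) {
        if (!file.exists(fp)) input_error("field file not found: ", fp)
        fld <- read_vertex_field(fp)
        gc <- compare_by_contact(fld, prox)
        stats_list[[fld$kind]] <- list(
          median_contact = gc$median_contact,
          iqr_contact = gc$iqr_contact,
          median_noncontact = gc$median_noncontact,
          iqr_noncontact = gc$iqr_noncontact,
          U = gc$U, p_value = gc$p_value)
      }
      results$contact_stats <- stats_list
      report$contact_stats <- stats_list
      jsonlite::write_json(stats_list, file.path(out, "contact_stats.json"),
                           auto_unbox = TRUE, digits = NA)
    }
  }

  jsonlite::write_json(report, file.path(out, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  logf("pipeline complete")
  results$report <- report
  invisible(results)
}

unclass_config <- function(cfg) {
  out <- unclass(cfg)
  out$reconstruction <- unclass(out$reconstruction)
  out$gicp <- unclass(out$gicp)
  out
}
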