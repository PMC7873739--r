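#' Default end-to-end pipeline configuration
#'
#' Nested configuration for every stage, fully serialised into each run's
#' output for provenance. `phantom$scale` < 1 runs the whole study on a
#' geometrically reduced phantom (faster meshes at identical physics).
#'
#' @param seed Global seed; per-stage sub-seeds derive from it.
#' @return Nested list of class `run_config`.
#' @export
default_config <- function(seed = 1L) {
  structure(list(
    seed = as.integer(seed),
    phantom = list(voxel_spacing = 0.6, noise_sd = 15, scale = 1),
    calibration = list(),
    material = list(e_min = 0.01, poisson = 0.3, metal_hu = 2000),
    geometry = list(bone_threshold_hu = 200, presmooth = 1,
                    smooth_iterations = 6, smooth_factor = 0.7,
                    remesh_edge = 0.6, sharp_angle_deg = 60),
    fe = list(element_size = 3, load_n = 500,
              convergence_sizes = seq(2, 6, by = 0.5),
              caudal_fraction = 1 / 3, endplate_depth = 3),
    guide = list(tube_inner_diameter = 2.7, tube_outer_diameter = 7,
                 tube_length = 18, shell_thickness = 3, resolution = 0.45),
    evaluation = list(tilt_deg = c(S1 = 4.42, ALA = 2.4),
                      corridor_clearance = 4, bit_diameter = 2.5),
    run_convergence = FALSE,
    remesh_surfaces = FALSE),
    class = "run_config")
}

config_keys <- function() names(default_config())

#' Validate a pipeline configuration
#'
#' Checks the nested schema against [default_config()]: unknown keys are
#' rejected by name, missing required sections error.
#' @param config A list (e.g. parsed from YAML).
#' @return The validated `run_config` (defaults filled in).
#' @export
validate_config <- function(config) {
  def <- default_config()
  unknown <- setdiff(names(config), names(def))
  if (length(unknown) > 0)
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  if (is.null(config$seed)) stop("config is missing required key: seed")
  for (nm in names(def)) {
    if (is.null(config[[nm]])) {
      config[[nm]] <- def[[nm]]
    } else if (is.list(def[[nm]])) {
      sub_unknown <- setdiff(names(config[[nm]]), names(def[[nm]]))
      if (length(sub_unknown) > 0)
        stop(sprintf("unknown config key(s) under '%s': %s", nm,
                     paste(sub_unknown, collapse = ", ")))
      for (k in names(def[[nm]]))
        if (is.null(config[[nm]][[k]])) config[[nm]][[k]] <- def[[nm]][[k]]
    }
  }
  config$seed <- as.integer(config$seed)
  structure(config[names(def)], class = "run_config")
}

#' Read a pipeline configuration from YAML
#' @param path YAML file.
#' @export
read_config <- function(path) validate_config(yaml::read_yaml(path))

#' Run the full planning/audit pipeline on the synthetic phantom
#'
#' Executes phantom generation, phantom-based calibration, trajectory
#' planning and virtual screw insertion, heterogeneous tet10 FE pull-out
#' comparison of the two trajectories, drill-guide construction, the
#' simulated drilling + accuracy audit, and (optionally) the nine-size mesh
#' convergence sweep. All artifacts (volumes, meshes, tables, reports, the
#' full config) are written under `out_dir`; a run fails loudly with the
#' stage name, keeping completed artifacts on disk.
#'
#' @param config A `run_config` (see [default_config()], [validate_config()]).
#' @param out_dir Output directory (created).
#' @param quiet Suppress progress messages.
#' @return The summary list (also written as `summary.json`).
#' @export
run_pipeline <- function(config = default_config(), out_dir, quiet = FALSE) {
  config <- validate_config(unclass(config))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message(sprintf(...))
  timings <- list()
  stage <- function(name, expr) {
    say("[%s] ...", name)
    t0 <- proc.time()[3]
    res <- tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s (artifacts in %s)",
                   name, conditionMessage(e), out_dir), call. = FALSE))
    timings[[name]] <<- round(proc.time()[3] - t0, 2)
    res
  }

  ph <- stage("phantom", {
    spec <- phantom_spec(voxel_spacing = config$phantom$voxel_spacing,
                         noise_sd = config$phantom$noise_sd,
                         scale = config$phantom$scale,
                         seed = config$seed)
    generate_phantom(spec)
  })
  write_volume(ph$volume, file.path(out_dir, "phantom.nii.gz"))
  write_stl(ph$truth$true_surfaces$bone, file.path(out_dir, "bone_truth.stl"))

  law <- stage("calibrate", {
    samples <- sample_rods(ph$volume, ph$truth$rods)
    utils::write.csv(samples, file.path(out_dir, "calibration_samples.csv"),
                     row.names = FALSE)
    fit_hu_to_density(samples)
  })
  model <- density_modulus_model(
    hu_to_density = law,
    e_min = config$material$e_min, poisson = config$material$poisson)
  jsonlite::write_json(list(
    hu_to_density = law[c("intercept", "slope")],
    density_to_modulus = model$density_to_modulus[c("intercept", "slope")],
    r_squared = attr(law, "r_squared")),
    file.path(out_dir, "calibration.json"), auto_unbox = TRUE, digits = NA)

  geo <- stage("geometry", {
    mask <- segment(ph$volume, config$geometry$bone_threshold_hu,
                    config$material$metal_hu - 1)
    bone <- extract_surface(mask, presmooth = config$geometry$presmooth)
    bone <- smooth_surface(bone, config$geometry$smooth_iterations,
                           config$geometry$smooth_factor)
    if (isTRUE(config$remesh_surfaces))
      bone <- remesh_uniform(bone, config$geometry$remesh_edge,
                             config$geometry$sharp_angle_deg)
    bone
  })
  write_stl(geo, file.path(out_dir, "bone_segmented.stl"))

  plan_res <- stage("plan", {
    plans <- ph$truth$plans
    assy <- assembly(bone = ph$truth$true_surfaces$bone,
                     fragment = ph$truth$true_surfaces$fragment)
    for (pl in plans) assy <- place_screw(assy, pl)
    collisions <- if (!is.null(assy$fragment))
      lapply(plans, check_collision, fragment = assy$fragment,
             clearance = 0.5) else NULL
    jsonlite::write_json(
      lapply(plans, function(p) list(label = p$label, entry = p$entry,
                                     direction = p$direction,
                                     length = p$screw$length,
                                     diameter = p$screw$diameter)),
      file.path(out_dir, "plans.json"), auto_unbox = TRUE, digits = NA)
    list(plans = plans, assy = assy, collisions = collisions)
  })

  fe <- stage("fe_compare", {
    out <- list()
    for (nm in names(plan_res$plans)) {
      pl <- plan_res$plans[[nm]]
      assy1 <- assembly(bone = ph$truth$true_surfaces$bone,
                        fragment = ph$truth$true_surfaces$fragment)
      assy1 <- place_screw(assy1, pl)
      mesh <- tetrahedralize(assy1, config$fe$element_size)
      mesh <- assign_element_materials(mesh, ph$volume, model,
                                       metal_hu = config$material$metal_hu)
      sets <- define_node_sets(
        mesh, list(depth = config$fe$endplate_depth),
        config$fe$caudal_fraction, head_spec = list(plan = pl))
      load <- load_case(config$fe$load_n, -pl$direction)
      r <- solve_static(mesh, sets, load)
      export_inp(mesh, sets, load,
                 file.path(out_dir, sprintf("model_%s.inp", nm)))
      utils::write.csv(mesh$material_report,
                       file.path(out_dir, sprintf("materials_%s.csv", nm)),
                       row.names = FALSE)
      out[[nm]] <- r
    }
    out
  })
  k <- vapply(fe, function(r) r$stiffness, numeric(1))

  conv <- NULL
  if (isTRUE(config$run_convergence)) {
    conv <- stage("convergence", {
      lapply(names(plan_res$plans), function(nm) {
        pl <- plan_res$plans[[nm]]
        assy1 <- assembly(bone = ph$truth$true_surfaces$bone,
                          fragment = ph$truth$true_surfaces$fragment)
        assy1 <- place_screw(assy1, pl)
        tab <- convergence_sweep(assy1, config$fe$convergence_sizes,
                                 ph$volume, model, pl,
                                 load_case(config$fe$load_n, -pl$direction))
        utils::write.csv(tab, file.path(out_dir,
                                        sprintf("convergence_%s.csv", nm)),
                         row.names = FALSE)
        tab
      }) |> stats::setNames(names(plan_res$plans))
    })
  }

  guide <- stage("guide", {
    region <- list(direction = c(0, 1, 0), max_normal_angle_deg = 60,
                   xlim = c(2, 30) * config$phantom$scale,
                   zlim = c(-6, 10) * config$phantom$scale)
    patch <- extract_contact_patch(ph$truth$true_surfaces$bone, region)
    gs <- guide_spec(config$guide$tube_inner_diameter,
                     config$guide$tube_outer_diameter,
                     config$guide$tube_length, config$guide$shell_thickness)
    g <- build_guide(patch, plan_res$plans, gs,
                     resolution = config$guide$resolution)
    write_stl(g, file.path(out_dir, "guide.stl"))
    g
  })

  audit <- stage("evaluate", {
    tilts <- config$evaluation$tilt_deg
    realized <- list()
    for (nm in names(plan_res$plans)) {
      pl <- plan_res$plans[[nm]]
      tilt <- tilts[[nm]] %||% 0
      perp <- perpendicular_unit(pl$direction, salt = match(nm, names(plan_res$plans)))
      Rt <- rotation_about_axis(perp, tilt)
      mid <- pl$entry + 15 * config$phantom$scale * pl$direction
      dir2 <- as.numeric(Rt %*% pl$direction)
      realized[[nm]] <- line3d(mid - 15 * config$phantom$scale * dir2, dir2)
    }
    pose <- with_seed(config$seed + 1L, {
      axis <- stats::rnorm(3); ang <- stats::runif(1, 2, 8)
      rigid_transform(rotation_about_axis(axis, ang),
                      stats::rnorm(3, 0, 5))
    })
    pd <- simulate_postdrill_volume(ph$truth, realized, pose,
                                    bit_diameter = config$evaluation$bit_diameter)
    write_volume(pd, file.path(out_dir, "postdrill.nii.gz"))
    utils::write.csv(
      data.frame(label = paste0("L", seq_len(nrow(pd$landmarks$post))),
                 pd$landmarks$post),
      file.path(out_dir, "landmarks_postdrill.csv"), row.names = FALSE)
    rep <- evaluate_drilling(plan_res$plans, pd, ph$truth$true_surfaces$bone,
                             corridor_clearance = config$evaluation$corridor_clearance,
                             bit_diameter = config$evaluation$bit_diameter)
    jsonlite::write_json(rep$per_trajectory,
                         file.path(out_dir, "accuracy_report.json"),
                         auto_unbox = TRUE, digits = NA)
    rep
  })

  summary <- list(
    config = unclass(config),
    calibration = list(intercept = law$intercept, slope = law$slope,
                       r_squared = attr(law, "r_squared")),
    insertion = lapply(plan_res$assy$plans, function(p)
      list(inserted_length_mm = p$inserted_length_mm,
           cortex_crossings = p$cortex_crossings,
           bicortical = p$bicortical)),
    collision = if (!is.null(plan_res$collisions))
      lapply(plan_res$collisions, function(cc)
        list(distance_mm = cc$distance_mm, pass = cc$pass)),
    stiffness_n_mm = as.list(k),
    stiffness_ratio = as.numeric(k["S1"] / k["ALA"]),
    convergence = if (!is.null(conv))
      lapply(conv, function(tab) as.list(tab[, c("size_mm", "n_elements",
                                                 "mean_u_head_mm",
                                                 "stiffness_n_mm")])),
    guide = list(n_faces = nrow(guide$faces), genus = mesh_genus(guide)),
    accuracy = audit$per_trajectory)
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  jsonlite::write_json(timings, file.path(out_dir, "timings.json"),
                       auto_unbox = TRUE)
  say("done: %s", out_dir)
  invisible(summary)
}

# deterministic unit vector perpendicular to d
perpendicular_unit <- function(d, salt = 1) {
  ref <- if (abs(d[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  if (salt %% 2 == 0) ref <- c(0, 0, 1)
  v <- c(d[2] * ref[3] - d[3] * ref[2],
         d[3] * ref[1] - d[1] * ref[3],
         d[1] * ref[2] - d[2] * ref[1])
  v / sqrt(sum(v^2))
}
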