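## Configuration files, named presets, and run outputs (CSV time series,
## VTK structured-grid snapshots, JSON run summary).

#' Named case-study presets
#'
#' Each preset is a complete [scenario_config()] reproducing one of the
#' studied configurations.  Kickstart product scales inversely with the
#' inoculation density (1e-5 cell equivalents for two-cell runs down to
#' 1e-8 at the largest populations).
#'
#' @param name preset name; call with no arguments to list presets.
#' @param seed RNG seed.
#' @param ... overrides passed to [scenario_config()] (e.g. `duration`,
#'   `gravity_mode`, `diffusivity`).
#' @return a [scenario_config()], or a character vector of preset names.
#' @export
preset_config <- function(name = NULL, seed = 1L, ...) {
  presets <- list(
    two_cell_near = list(placement = list(recipe = "two_cells", distance = 1),
                         kickstart_product = 1e-5),
    two_cell_far = list(placement = list(recipe = "two_cells", distance = 218),
                        kickstart_product = 1e-5),
    two_cell_near_high = list(placement = list(recipe = "two_cells",
                                               distance = 1),
                              kickstart_product = 1e-2),
    two_cell_far_high = list(placement = list(recipe = "two_cells",
                                              distance = 218),
                             kickstart_product = 1e-2),
    fig4_dense = list(placement = list(recipe = "dense_sphere", n = 2000),
                      diffusivity = "liquid", kickstart_product = 1e-8),
    fig4_random = list(placement = list(recipe = "random_uniform", n = 2000),
                       diffusivity = "liquid", kickstart_product = 1e-8),
    fig6a = list(placement = list(recipe = "dense_sphere", n = 2000,
                                  counts = c(1956, 44)),
                 kickstart_product = 1e-8),
    fig6b = list(placement = list(recipe = "random_uniform", n = 2000,
                                  counts = c(1956, 44)),
                 kickstart_product = 1e-8),
    fig7_rwv = list(placement = list(recipe = "dense_sphere", n = 2000,
                                     counts = c(1956, 44)),
                    gravity_mode = "RWV", kickstart_product = 1e-8),
    fig8_separated = list(placement = list(recipe = "separated_colonies",
                                           n1 = 1895, n2 = 105),
                          kickstart_product = 1e-8),
    fig9_yield_sweep = list(placement = list(recipe = "dense_sphere",
                                             n = 2000),
                            gravity_mode = "RWV", diffusivity = "biofilm",
                            kickstart_product = 1e-8),
    fig10_floor_sphere = list(placement = list(recipe = "floor_biofilm",
                                               shape = "SPHERE", n = 500),
                              gravity_mode = "ONE_G",
                              diffusivity = "biofilm",
                              kickstart_product = 1e-6,
                              colony_mode = "STATIC")
  )
  if (is.null(name)) return(names(presets))
  if (!name %in% names(presets)) {
    stop(sprintf("unknown preset '%s'; available: %s", name,
                 paste(names(presets), collapse = ", ")))
  }
  args <- utils::modifyList(presets[[name]], list(...))
  args$name <- name
  args$seed <- seed
  do.call(scenario_config, args)
}

#' Read / write a scenario configuration as YAML
#'
#' @param config a [scenario_config()].
#' @param path file path.
#' @return `write_config` returns the path invisibly; `read_config` a
#'   [scenario_config()].
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  vals <- yaml::yaml.load_file(path)
  do.call(scenario_config, vals)
}

#' Write the per-species time series of a run to CSV
#'
#' @param result a `sim_result` from [simulate_scenario()].
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_timeseries_csv <- function(result, path) {
  utils::write.csv(result$series, path, row.names = FALSE)
  invisible(path)
}

#' Write a JSON run summary
#'
#' Echoes the configuration and seed (sufficient to regenerate the run) and
#' the headline statistics, with every reported mean growth rate tagged
#' steady or not.
#'
#' @param result a `sim_result`.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_run_summary <- function(result, path) {
  summary <- list(
    config = unclass(result$config),
    wall_events = result$wall_events,
    audit_max_relative = result$audit$max_relative,
    species = lapply(result$steady, function(st) {
      list(mu_bar = st$mu_bar, steady = st$steady)
    })
  )
  jsonlite::write_json(summary, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Write a field snapshot as a legacy VTK structured-points file
#'
#' Exports the per-metabolite concentrations, the modified pressure, and
#' the cell-centered velocity vector on the parcel grid, readable by
#' ParaView/VisIt.
#'
#' @param fields a [field_set()].
#' @param path output file (`.vtk`).
#' @param title dataset title line.
#' @return the path, invisibly.
#' @export
write_vtk_snapshot <- function(fields, path, title = "rwvsim snapshot") {
  grid <- fields$grid
  n <- grid$n
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0", title, "ASCII",
               "DATASET STRUCTURED_POINTS",
               sprintf("DIMENSIONS %d %d %d", n[1], n[2], n[3]),
               sprintf("ORIGIN %g %g %g", grid$parcel_um[1] / 2,
                       grid$parcel_um[2] / 2, grid$parcel_um[3] / 2),
               sprintf("SPACING %g %g %g", grid$parcel_um[1],
                       grid$parcel_um[2], grid$parcel_um[3]),
               sprintf("POINT_DATA %d", prod(n))), con)
  fmt <- function(x) formatC(x, format = "g", digits = 9)
  for (nm in names(fields$conc)) {
    writeLines(c(sprintf("SCALARS %s double 1", nm),
                 "LOOKUP_TABLE default"), con)
    writeLines(fmt(as.vector(fields$conc[[nm]])), con)
  }
  writeLines(c("SCALARS p_rgh double 1", "LOOKUP_TABLE default"), con)
  writeLines(fmt(as.vector(fields$flow$p)), con)
  writeLines(c("SCALARS void_fraction double 1", "LOOKUP_TABLE default"), con)
  writeLines(fmt(as.vector(fields$eps)), con)
  uc <- flow_center_velocity(fields$flow)
  writeLines("VECTORS velocity double", con)
  writeLines(paste(fmt(as.vector(uc$u)), fmt(as.vector(uc$v)),
                   fmt(as.vector(uc$w))), con)
  invisible(path)
}

#' Run a named preset and write all artifacts
#'
#' Convenience wrapper used by the command-line script: simulates the
#' preset and writes the time-series CSV, a final-state VTK snapshot, and
#' the JSON summary to `output_dir`.
#'
#' @param name preset name (see [preset_config()]).
#' @param seed RNG seed.
#' @param output_dir output directory (created if missing).
#' @param ... configuration overrides.
#' @return the `sim_result`, invisibly.
#' @export
run_preset <- function(name, seed = 1L, output_dir = ".", ...) {
  config <- preset_config(name, seed = seed, ...)
  result <- simulate_scenario(config)
  if (!dir.exists(output_dir)) dir.create(output_dir, recursive = TRUE)
  write_timeseries_csv(result, file.path(output_dir,
                                         paste0(name, "_timeseries.csv")))
  write_vtk_snapshot(result$state$fields,
                     file.path(output_dir, paste0(name, "_final.vtk")))
  write_run_summary(result, file.path(output_dir,
                                      paste0(name, "_summary.json")))
  write_config(config, file.path(output_dir, paste0(name, "_config.yaml")))
  invisible(result)
}
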