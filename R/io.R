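#' Read / write a belt scene
#'
#' CSV carries the footprints only (columns `id, label, x_min, x_max, y_min,
#' y_max`, meters to 6 decimals); JSON round-trips the full scene including
#' its scenario configuration and provenance columns.
#'
#' @param scene a `belt_scene`.
#' @param path file path.
#' @param config optional [scenario_config()] to attach when reading CSV.
#' @return readers return a `belt_scene`.
#' @export
write_scene_csv <- function(scene, path) {
  w <- scene$weeds
  df <- data.frame(id = w$id, label = w$label,
                   x_min = sprintf("%.6f", w$x_min),
                   x_max = sprintf("%.6f", w$x_max),
                   y_min = sprintf("%.6f", w$y_min),
                   y_max = sprintf("%.6f", w$y_max))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_scene_csv
#' @export
read_scene_csv <- function(path, config = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "label", "x_min", "x_max", "y_min", "y_max")
  if (!all(need %in% names(df)))
    stop("scene CSV must have columns ", paste(need, collapse = ","))
  new_belt_scene(df[need], config)
}

#' @rdname write_scene_csv
#' @export
write_scene_json <- function(scene, path) {
  jsonlite::write_json(list(config = unclass(scene$config),
                            weeds = scene$weeds),
                       path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

#' @rdname write_scene_csv
#' @export
read_scene_json <- function(path) {
  rec <- jsonlite::fromJSON(path)
  cfg <- rec$config
  config <- scenario_config(scenario = cfg$scenario, n_weeds = cfg$n_weeds,
                            gap_range = unlist(cfg$gap_range),
                            belt_length = cfg$belt_length,
                            belt_width = cfg$belt_width, seed = cfg$seed,
                            max_diameter = cfg$max_diameter,
                            min_sep = cfg$min_sep)
  new_belt_scene(as.data.frame(rec$weeds), config)
}

#' Write one trial's artefacts to a directory
#'
#' Writes `scene.csv`, `speed.csv`, `edges.csv`, `commands.csv`,
#' `deposition.json` and `metrics.tsv` for a completed trial.
#'
#' @param log a `sim_log` from [run_trial()].
#' @param dir output directory (created if missing).
#' @return the directory, invisibly.
#' @export
write_trial_outputs <- function(log, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_scene_csv(log$scene, file.path(dir, "scene.csv"))
  write_speed_csv(log$profile, file.path(dir, "speed.csv"))
  write_edges_csv(log$edges, file.path(dir, "edges.csv"))
  write_commands_csv(log$commands, file.path(dir, "commands.csv"))
  dep <- lapply(log$deposition, function(m)
    if (nrow(m) == 0) list() else apply(m, 1, function(r)
      list(on = r[[1]], off = r[[2]]), simplify = FALSE))
  jsonlite::write_json(dep, file.path(dir, "deposition.json"),
                       auto_unbox = TRUE, digits = NA)
  write_metrics_tsv(log$weed_results, file.path(dir, "metrics.tsv"))
  invisible(dir)
}
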