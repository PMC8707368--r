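# Output plumbing: VTK point-cloud export, run configs and manifests.

#' Write particle fields as a legacy-ASCII VTK point cloud
#'
#' One POINTS block plus one scalar array per requested field column.
#' Readable by ParaView/VTK as unstructured point data.
#'
#' @param fields tibble with `x, y, z` and field columns, or an
#'   `mca_packing` (exports the region index).
#' @param path output file.
#' @param scalars field columns to export; defaults to every numeric
#'   column except the coordinates.
#' @return `path`, invisibly.
#' @export
write_vtk <- function(fields, path, scalars = NULL) {
  if (inherits(fields, "mca_packing"))
    fields <- dplyr::mutate(fields$particles,
                            region_id = as.integer(factor(.data$region)))
  n <- nrow(fields)
  if (is.null(scalars))
    scalars <- setdiff(names(fields)[vapply(fields, is.numeric, TRUE)],
                       c("x", "y", "z", "id"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0", "poromca fields", "ASCII",
               "DATASET POLYDATA", paste("POINTS", n, "double")), con)
  utils::write.table(format(as.data.frame(fields)[, c("x", "y", "z")],
                            digits = 9),
                     con, row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  writeLines(paste("POINT_DATA", n), con)
  for (sc in scalars) {
    writeLines(c(paste("SCALARS", sc, "double 1"),
                 "LOOKUP_TABLE default"), con)
    writeLines(format(as.numeric(fields[[sc]]), digits = 9), con)
  }
  invisible(path)
}

#' Run configuration files
#'
#' A run config bundles the geometry spec, protocol choice, numerical
#' parameters and seed; YAML by default, JSON accepted. Unknown keys are
#' rejected by name.
#'
#' @param path config file (`.yml`/`.yaml`/`.json`).
#' @param config a named list.
#' @return `read_run_config()` returns the list; `write_run_config()`
#'   returns `path` invisibly.
#' @export
read_run_config <- function(path) {
  cfg <- if (grepl("\\.json$", path)) jsonlite::read_json(path,
                                                          simplifyVector = TRUE)
         else yaml::read_yaml(path)
  known <- c("geometry", "materials", "protocol", "d", "sizes", "levels",
             "u_total", "safety", "damping_ratio", "n_transit", "seed",
             "coverage", "t_sim", "pulse_t_total", "Z", "out_dir")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  cfg
}

#' @rdname read_run_config
#' @export
write_run_config <- function(config, path) {
  if (grepl("\\.json$", path))
    jsonlite::write_json(config, path, auto_unbox = TRUE, digits = NA)
  else yaml::write_yaml(config, path)
  invisible(path)
}

#' Run manifest
#'
#' Everything needed to re-execute a run: the config, seed, package
#' version and (optionally) dosimetry, serialised as JSON.
#'
#' @param config run config list.
#' @param seed integer seed.
#' @param extra named list appended verbatim (e.g. a dosimetry table).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(config, seed, path, extra = list()) {
  man <- c(list(package = "poromca",
                version = as.character(utils::packageVersion("poromca")),
                seed = seed, config = config), extra)
  jsonlite::write_json(man, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
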