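# Reading and writing the package's on-disk formats: multi-page 16-bit
# TIFF stacks, ground-truth/point-set CSVs, and JSON/YAML sidecars.

#' Read a z-stack from a multi-page TIFF
#'
#' @param path Path to a single-channel multi-page TIFF.
#' @return Numeric array `[row, col, z]` in the file's native integer
#'   units.
#' @export
read_stack <- function(path) {
  abort_if(!file.exists(path), paste0("no such file: ", path))
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  stack <- array(0, dim = c(dim(pages[[1]]), length(pages)))
  for (z in seq_along(pages)) stack[, , z] <- pages[[z]]
  stack
}

#' Write a z-stack as a 16-bit multi-page TIFF
#'
#' Values are rounded and clamped to the 16-bit range `[0, 65535]`.
#'
#' @param stack Numeric array `[row, col, z]` or matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  if (is.matrix(stack)) stack <- array(stack, dim = c(dim(stack), 1L))
  pages <- lapply(seq_len(dim(stack)[3]), function(z) {
    plane <- round(stack[, , z])
    plane[plane < 0] <- 0
    plane[plane > 65535] <- 65535
    plane / 65535
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(path)
}

#' Write a scene to disk
#'
#' One 16-bit multi-page TIFF per color (`channel1.tif`, `channel2.tif`),
#' the ground-truth table as `truth.csv`, and the configuration echoed as
#' `scene_config.yaml`.
#'
#' @param scene Result of [generate_scene()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_scene <- function(scene, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_stack(scene$channel1, file.path(dir, "channel1.tif"))
  write_stack(scene$channel2, file.path(dir, "channel2.tif"))
  write.csv(scene$truth, file.path(dir, "truth.csv"), row.names = FALSE)
  cfg <- scene$config
  cfg_list <- unclass(cfg)
  cfg_list$image_shape <- as.integer(cfg_list$image_shape)
  yaml::write_yaml(cfg_list, file.path(dir, "scene_config.yaml"))
  invisible(dir)
}

#' Read a scene configuration from a YAML/JSON sidecar
#'
#' @param path Path to a YAML (or JSON) file with `scene_config` fields.
#' @return A [scene_config()].
#' @export
read_scene_config <- function(path) {
  vals <- if (grepl("\\.json$", path)) jsonlite::read_json(path, simplifyVector = TRUE)
          else yaml::read_yaml(path)
  vals <- vals[names(vals) %in% names(formals(scene_config))]
  do.call(scene_config, vals)
}

#' Write a tibble as CSV
#'
#' List-columns (such as `pixels`) are dropped with a message, keeping the
#' output a plain delimited table.
#'
#' @param x Data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_table_csv <- function(x, path) {
  is_list <- vapply(x, is.list, TRUE)
  if (any(is_list)) x <- x[, !is_list, drop = FALSE]
  write.csv(x, path, row.names = FALSE)
  invisible(path)
}
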