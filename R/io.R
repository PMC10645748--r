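#' Write an image stack as multi-page TIFF with voxel metadata
#'
#' Intensities are stored as 16-bit TIFF pages scaled to the stack maximum;
#' the voxel size and intensity scale travel in a JSON sidecar
#' (`<path>.json`) that [read_stack()] requires. A stack without that
#' metadata cannot be segmented, so readers refuse files lacking it.
#'
#' @param stack an `image_stack` (or 3D array with `voxel_size_um`).
#' @param path output TIFF path.
#' @param voxel_size_um voxel size, taken from the stack if present.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path, voxel_size_um = NULL) {
  voxel_size_um <- voxel_size_um %||% voxel_size(stack)
  if (is.null(voxel_size_um)) stopf("`voxel_size_um` is required")
  dat <- unclass(stack)
  if (length(dim(dat)) == 2L) dat <- array(dat, dim = c(dim(dat), 1L))
  scale <- max(dat, 1e-12)
  pages <- lapply(seq_len(dim(dat)[3]),
                  function(z) pmin(pmax(dat[, , z] / scale, 0), 1))
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  meta <- list(voxel_size_um = as.numeric(voxel_size_um),
               intensity_scale = scale, dim = dim(dat))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read an image stack written by [write_stack()]
#'
#' @param path TIFF path; the `<path>.json` sidecar with voxel metadata must
#'   exist.
#' @return an `image_stack` with voxel-size metadata.
#' @export
read_stack <- function(path) {
  meta_path <- paste0(path, ".json")
  if (!file.exists(meta_path))
    stopf(paste("no voxel-size metadata found for '%s' (expected '%s');",
                "stacks without voxel metadata cannot be analyzed"),
          path, meta_path)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  dat <- array(unlist(pages), dim = c(dim(pages[[1]]), length(pages)))
  new_image_stack(dat * meta$intensity_scale,
                  as.numeric(meta$voxel_size_um))
}

.check_columns <- function(df, required, what) {
  missing <- setdiff(required, names(df))
  if (length(missing))
    stopf("%s is missing required column(s): %s", what,
          paste(missing, collapse = ", "))
  invisible(df)
}

#' Write/read a cluster table as CSV
#'
#' Columns: `id`, `volume_um3`, `x_um`, `y_um`, `z_um`, `on_membrane`.
#' @param pop a `cluster_population`.
#' @param path CSV path.
#' @return `path` (write) / a `cluster_population` (read).
#' @export
write_clusters <- function(pop, path) {
  write.csv(as.data.frame(pop), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_clusters
#' @export
read_clusters <- function(path) {
  df <- read.csv(path)
  .check_columns(df, c("id", "volume_um3", "x_um", "y_um", "z_um",
                       "on_membrane"), sprintf("cluster table '%s'", path))
  structure(df, class = c("cluster_population", "data.frame"))
}

#' Write/read a size distribution as CSV
#'
#' Columns: `size`, `count`, `relative_frequency`.
#' @param dist a `size_distribution`.
#' @param path CSV path.
#' @return `path` (write) / a `size_distribution` (read).
#' @export
write_size_distribution <- function(dist, path) {
  write.csv(as.data.frame(dist), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_size_distribution
#' @export
read_size_distribution <- function(path) {
  df <- read.csv(path)
  .check_columns(df, c("size", "count", "relative_frequency"),
                 sprintf("size distribution '%s'", path))
  structure(df, class = c("size_distribution", "data.frame"))
}

#' Write/read a sparklet trace as CSV
#'
#' Columns: `frame`, `signal`; the sampling rate is kept in a header comment.
#' @param trace a `sparklet_trace`.
#' @param path CSV path.
#' @param sampling_rate Hz, for reading files without the header.
#' @return `path` (write) / a `sparklet_trace` (read).
#' @export
write_trace <- function(trace, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# sampling_rate_hz=%g",
                     attr(trace, "sampling_rate") %||% 100), con)
  write.csv(as.data.frame(trace), con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path, sampling_rate = NULL) {
  first <- readLines(path, n = 1L)
  if (grepl("^# sampling_rate_hz=", first))
    sampling_rate <- as.numeric(sub("^# sampling_rate_hz=", "", first))
  df <- read.csv(path, comment.char = "#")
  .check_columns(df, c("frame", "signal"),
                 sprintf("sparklet trace '%s'", path))
  sparklet_trace(df$signal, sampling_rate %||% 100, frame = df$frame)
}

#' Write/read idealized records as CSV (`frame`, `level`)
#' @param record an `idealized_record`.
#' @param path CSV path.
#' @return `path` (write) / an `idealized_record` (read).
#' @export
write_record <- function(record, path) {
  write.csv(data.frame(frame = seq_along(record$levels),
                       level = record$levels), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_record
#' @export
read_record <- function(path) {
  df <- read.csv(path)
  .check_columns(df, c("frame", "level"),
                 sprintf("idealized record '%s'", path))
  new_idealized_record(df$level)
}
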