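# Serialization: contour CSV + JSON sidecar, distribution CSV, heat-map
# TIFF/CSV, z-stack TIFF + JSON sidecar, flat key-value configs, GUV
# record tables.

sidecar_path <- function(path) paste0(tools::file_path_sans_ext(path), ".json")

#' Write / read a contour as CSV with a JSON sidecar
#'
#' The CSV holds columns `x_px`, `y_px`; the sidecar records
#' `pixel_size_um` and `label`.
#'
#' @param contour a [shape_contour()].
#' @param path CSV path; the sidecar takes the same stem with `.json`.
#' @return `path` (write) or a `shape_contour` (read).
#' @export
write_contour_csv <- function(contour, path) {
  assert_contour(contour)
  df <- data.frame(x_px = contour$points[, 1], y_px = contour$points[, 2])
  utils::write.csv(df, path, row.names = FALSE)
  jsonlite::write_json(list(pixel_size_um = contour$pixel_size,
                            label = contour$label),
                       sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_contour_csv
#' @export
read_contour_csv <- function(path) {
  if (!file.exists(path)) stop_io(sprintf("cannot read '%s'", path))
  df <- utils::read.csv(path)
  if (!all(c("x_px", "y_px") %in% names(df)))
    stop_io("contour CSV needs columns x_px, y_px")
  meta <- list(pixel_size_um = 1, label = "")
  sp <- sidecar_path(path)
  if (file.exists(sp)) meta <- utils::modifyList(meta, jsonlite::read_json(sp))
  shape_contour(cbind(df$x_px, df$y_px), meta$pixel_size_um, meta$label)
}

#' Write / read an angular distribution as CSV
#'
#' Columns: `bin_low_deg`, `bin_high_deg`, `probability`, `count`.
#'
#' @param dist an `angular_distribution`.
#' @param path CSV path.
#' @return `path` (write) or an `angular_distribution` (read).
#' @export
write_distribution_csv <- function(dist, path) {
  if (!inherits(dist, "angular_distribution"))
    stop_invalid_input("expected an 'angular_distribution'")
  n <- length(dist$probabilities)
  df <- data.frame(bin_low_deg = dist$bin_edges[-(n + 1)],
                   bin_high_deg = dist$bin_edges[-1],
                   probability = dist$probabilities,
                   count = dist$counts)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_distribution_csv
#' @export
read_distribution_csv <- function(path) {
  if (!file.exists(path)) stop_io(sprintf("cannot read '%s'", path))
  df <- utils::read.csv(path)
  structure(list(bin_edges = c(df$bin_low_deg, df$bin_high_deg[nrow(df)]),
                 probabilities = df$probability,
                 counts = if (is.null(df$count)) df$probability else df$count),
            class = "angular_distribution")
}

#' Write a heat map as 32-bit float TIFF plus long-format CSV
#'
#' @param hm a `heat_map`.
#' @param tiff_path TIFF output path (`NULL` to skip).
#' @param csv_path CSV output path (`NULL` to skip); columns `x_px`,
#'   `y_px`, `density` for all pixels inside the extent.
#' @return Invisibly, the paths written.
#' @export
write_heatmap <- function(hm, tiff_path = NULL, csv_path = NULL) {
  if (!inherits(hm, "heat_map")) stop_invalid_input("expected a 'heat_map'")
  if (!is.null(tiff_path))
    tiff::writeTIFF(t(hm$values), tiff_path, bits.per.sample = 32L,
                    reduce = FALSE)
  if (!is.null(csv_path)) {
    d <- dim(hm$values)
    df <- data.frame(
      x_px = rep(seq(hm$extent[1], hm$extent[2]), times = d[2]),
      y_px = rep(seq(hm$extent[3], hm$extent[4]), each = d[1]),
      density = as.vector(hm$values))
    utils::write.csv(df, csv_path, row.names = FALSE)
  }
  invisible(c(tiff_path, csv_path))
}

#' Write / read a z-stack as multi-page TIFF with a JSON sidecar
#'
#' Pages are channel-major (all slices of the first channel, then the
#' next); the sidecar records `pixel_size_um`, `z_spacing_um`,
#' `channel_names` and `n_slices`. Intensities must lie in \[0, 1\].
#'
#' @param stack a [z_stack()].
#' @param path TIFF path; sidecar at the same stem with `.json`.
#' @return `path` (write) or a `z_stack` (read).
#' @export
write_zstack <- function(stack, path) {
  if (!inherits(stack, "z_stack")) stop_invalid_input("expected a z_stack")
  pages <- list()
  for (ch in stack$channels) {
    for (z in seq_len(dim(ch)[3]))
      pages[[length(pages) + 1]] <- t(pmin(pmax(ch[, , z], 0), 1))
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  jsonlite::write_json(list(pixel_size_um = stack$pixel_size,
                            z_spacing_um = stack$z_spacing,
                            channel_names = names(stack$channels),
                            n_slices = dim(stack$channels[[1]])[3]),
                       sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_zstack
#' @export
read_zstack <- function(path) {
  if (!file.exists(path)) stop_io(sprintf("cannot read '%s'", path))
  sp <- sidecar_path(path)
  if (!file.exists(sp)) stop_io(sprintf("missing sidecar '%s'", sp))
  meta <- jsonlite::read_json(sp, simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  nz <- meta$n_slices
  chn <- meta$channel_names
  if (length(pages) != nz * length(chn))
    stop_io("page count does not match sidecar channels x slices")
  channels <- list()
  k <- 1
  for (nm in chn) {
    d <- dim(pages[[k]])
    arr <- array(0, dim = c(d[2], d[1], nz))
    for (z in seq_len(nz)) {
      arr[, , z] <- t(pages[[k]])
      k <- k + 1
    }
    channels[[nm]] <- arr
  }
  z_stack(channels, meta$z_spacing_um, meta$pixel_size_um)
}

#' Write / read a flat key-value config file
#'
#' Lines of `key = value`; `#` starts a comment. Values that parse as
#' numbers are returned numeric.
#'
#' @param config named list.
#' @param path file path.
#' @return `path` (write) or a named list (read).
#' @export
write_config <- function(config, path) {
  writeLines(sprintf("%s = %s", names(config),
                     vapply(config, as.character, character(1))), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop_io(sprintf("cannot read '%s'", path))
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[grepl("=", lines)])
  out <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    key <- trimws(kv[1])
    val <- trimws(paste(kv[-1], collapse = "="))
    num <- suppressWarnings(as.numeric(val))
    out[[key]] <- if (!is.na(num)) num else val
  }
  out
}

#' Write / read GUV deformation records as CSV
#'
#' Columns: `guv_id`, `major_um`, `minor_um`, `ratio`, `pattern_label`.
#'
#' @param records list of [guv_record()] objects or a compatible data
#'   frame.
#' @param path CSV path.
#' @return `path` (write) or a data frame (read).
#' @export
write_records_csv <- function(records, path) {
  df <- records_to_frame(records)
  utils::write.csv(
    df[, c("guv_id", "major_um", "minor_um", "ratio", "pattern_label")],
    path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_records_csv
#' @export
read_records_csv <- function(path) {
  if (!file.exists(path)) stop_io(sprintf("cannot read '%s'", path))
  df <- utils::read.csv(path)
  need <- c("guv_id", "major_um", "minor_um", "ratio")
  if (!all(need %in% names(df)))
    stop_io(sprintf("records CSV needs columns %s",
                    paste(need, collapse = ", ")))
  df
}
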