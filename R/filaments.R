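# Traced-filament ("snake") files, per-filament orientation by principal
# component analysis, and experimental angular distributions.
#
# Snake dialect: optional header lines (anything that does not parse as a
# data row), then whitespace-separated rows
#   snake_id point_index x y z intensity
# with snakes delimited by id changes or blank lines. Extra trailing
# columns are ignored; z is carried but ignored by the 2D analysis.

#' Construct a filament trace
#'
#' @param id integer trace id.
#' @param points n x 2 (or n x 3, z dropped) matrix of ordered coordinates
#'   in pixels, n >= 2, with at least two distinct points.
#' @param intensity optional per-point intensities.
#' @return A `filament_trace` object.
#' @export
filament_trace <- function(id, points, intensity = NULL) {
  pts <- as.matrix(points)
  if (ncol(pts) > 2) pts <- pts[, 1:2, drop = FALSE]
  if (!is.numeric(pts) || ncol(pts) != 2 || any(!is.finite(pts)))
    stop_invalid_input("trace points must be finite numeric x,y pairs")
  if (nrow(pts) < 2 || nrow(unique(pts)) < 2)
    stop_invalid_input("a trace needs at least 2 distinct points")
  colnames(pts) <- c("x", "y")
  structure(list(id = as.integer(id), points = pts, intensity = intensity),
            class = "filament_trace")
}

#' Parse a snake-dialect traced-filament file
#'
#' @param path path to the text file.
#' @return List of [filament_trace()] objects, one per snake id, points in
#'   file order. Malformed lines and single-point snakes are skipped with
#'   a warning giving line numbers.
#' @export
parse_snake_file <- function(path) {
  if (!file.exists(path)) stop_io(sprintf("cannot read '%s'", path))
  lines <- tryCatch(readLines(path, warn = FALSE),
                    error = function(e) stop_io(conditionMessage(e)))
  rows <- list()
  bad <- integer(0)
  seen_data <- FALSE
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (ln == "" || startsWith(ln, "#")) next
    tok <- strsplit(ln, "[[:space:]]+")[[1]]
    vals <- suppressWarnings(as.numeric(tok))
    if (length(vals) < 6 || anyNA(vals[1:6])) {
      if (seen_data) bad <- c(bad, i)  # pre-data lines are headers
      next
    }
    seen_data <- TRUE
    rows[[length(rows) + 1]] <-
      c(vals[1], vals[3], vals[4], vals[5], vals[6])
  }
  if (length(bad) > 0)
    warning(sprintf("skipped %d malformed line(s): %s", length(bad),
                    paste(utils::head(bad, 10), collapse = ", ")))
  if (length(rows) == 0)
    stop_empty_input(sprintf("no valid snake data in '%s'", path))
  m <- do.call(rbind, rows)
  traces <- list()
  short <- integer(0)
  for (id in unique(m[, 1])) {
    sub <- m[m[, 1] == id, , drop = FALSE]
    tr <- tryCatch(
      filament_trace(id, sub[, 2:3, drop = FALSE], intensity = sub[, 5]),
      guv_invalid_input = function(e) NULL)
    if (is.null(tr)) short <- c(short, id) else
      traces[[length(traces) + 1]] <- tr
  }
  if (length(short) > 0)
    warning(sprintf("skipped %d degenerate snake(s) (ids: %s)",
                    length(short), paste(short, collapse = ", ")))
  if (length(traces) == 0)
    stop_empty_input(sprintf("no usable snake in '%s'", path))
  traces
}

#' Write filament traces in the snake dialect
#'
#' Inverse of [parse_snake_file()]: round-tripping preserves ids, point
#' order and coordinates.
#'
#' @param traces list of [filament_trace()] objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_snake_file <- function(traces, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# snake traces",
               "# columns: snake_id point_index x y z intensity"), con)
  for (tr in traces) {
    n <- nrow(tr$points)
    inten <- if (is.null(tr$intensity)) rep(1, n) else tr$intensity
    writeLines(sprintf("%d %d %.6f %.6f %.6f %.6f", tr$id, seq_len(n) - 1,
                       tr$points[, 1], tr$points[, 2], rep(0, n), inten),
               con)
    writeLines("", con)
  }
  invisible(path)
}

#' Orientation of a filament trace by principal component analysis
#'
#' The first principal axis of the trace's point cloud gives the filament
#' orientation; the angle relative to `reference_angle` is folded into
#' \[0, 90\] degrees by mirror symmetry ([fold_angle()]). The anisotropy
#' (ratio of first to second principal variance) reports how line-like the
#' trace is; near-isotropic traces are flagged but still return an angle.
#'
#' @param trace a [filament_trace()].
#' @param reference_angle reference axis in degrees (e.g. the GUV
#'   contour's major-axis angle); default 0, the image x axis.
#' @param isotropy_tol anisotropy below `1 + isotropy_tol` raises the
#'   `isotropic` flag.
#' @return A `filament_angle`: list with `trace_id`, `angle` (degrees in
#'   \[0, 90\]), `anisotropy` (>= 1) and `isotropic` flag.
#' @examples
#' tr <- filament_trace(1, cbind(0:5, 0:5))
#' filament_angle(tr)$angle  # 45
#' @export
filament_angle <- function(trace, reference_angle = 0, isotropy_tol = 0.05) {
  if (!inherits(trace, "filament_trace"))
    stop_invalid_input("expected a 'filament_trace'")
  pts <- trace$points
  cv <- stats::cov(pts)
  if (!all(is.finite(cv)) || sum(diag(cv)) <= 0)
    stop_degenerate_trace("trace has zero variance")
  e <- eigen(cv, symmetric = TRUE)
  lam <- pmax(e$values, 0)
  theta <- (atan2(e$vectors[2, 1], e$vectors[1, 1]) * 180 / pi) %% 180
  anis <- if (lam[2] <= .Machine$double.eps * lam[1]) Inf else
    lam[1] / lam[2]
  structure(list(trace_id = trace$id,
                 angle = fold_angle(theta, reference_angle),
                 anisotropy = anis,
                 isotropic = is.finite(anis) && anis < 1 + isotropy_tol),
            class = "filament_angle")
}

angles_from_input <- function(x) {
  if (is.numeric(x)) return(as.numeric(x))
  if (inherits(x, "filament_angle")) return(x$angle)
  if (is.list(x) && all(vapply(x, inherits, logical(1), "filament_angle")))
    return(vapply(x, function(a) a$angle, numeric(1)))
  stop_invalid_input(
    "expected numeric angles or filament_angle objects")
}

#' Experimental angular distribution of traced filaments
#'
#' Histogram of folded filament angles over \[0, 90\] degrees, normalized
#' to sum 1, using the same bin convention as the confinement model.
#'
#' @param angles numeric vector of folded angles or a list of
#'   `filament_angle` objects.
#' @param n_bins number of bins over \[0, 90\].
#' @return An `angular_distribution` with integer `counts`.
#' @export
experimental_distribution <- function(angles, n_bins = 18) {
  a <- angles_from_input(angles)
  if (length(a) < 1) stop_empty_input("no filament angles")
  angular_distribution_from_angles(a, n_bins, domain = 90)
}

#' Pool filament angles across GUVs
#'
#' Filament-weighted pooling: every filament counts equally regardless of
#' which GUV it came from, matching per-filament histograms pooled over
#' many vesicles per pattern type.
#'
#' @param per_guv list with one entry per GUV; each entry a numeric vector
#'   of folded angles, a list of `filament_angle` objects, or an
#'   `angular_distribution` carrying counts.
#' @param n_bins number of bins over \[0, 90\].
#' @return The pooled `angular_distribution`.
#' @export
pool_guvs <- function(per_guv, n_bins = 18) {
  if (!is.list(per_guv) || length(per_guv) < 1)
    stop_empty_input("no GUV entries to pool")
  counts <- rep(0, n_bins)
  for (entry in per_guv) {
    if (inherits(entry, "angular_distribution")) {
      if (length(entry$counts) != n_bins)
        stop_invalid_input("distribution binning does not match n_bins")
      counts <- counts + entry$counts
    } else {
      d <- experimental_distribution(angles_from_input(entry), n_bins)
      counts <- counts + d$counts
    }
  }
  if (sum(counts) <= 0) stop_empty_input("pooled counts are all zero")
  structure(list(bin_edges = seq(0, 90, length.out = n_bins + 1),
                 probabilities = counts / sum(counts),
                 counts = counts),
            class = "angular_distribution")
}
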