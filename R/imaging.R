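# Plane selection and contour extraction from multi-channel z-stacks.
#
# Image arrays are indexed [x, y] (first dimension rightward, second
# downward), matching EBImage; z-stacks are [x, y, z] per channel. The
# analysis plane is the slice a fixed physical offset above the pattern
# surface, the surface being the slice of maximal pattern-channel
# intensity.

#' Construct a multi-channel z-stack
#'
#' @param channels named list of 3D numeric arrays indexed \[x, y, z\],
#'   all of identical dimensions; names typically include `"membrane"` and
#'   `"pattern"`.
#' @param z_spacing slice spacing in micrometres (> 0).
#' @param pixel_size lateral pixel size in micrometres per pixel (> 0).
#' @return A `z_stack` object.
#' @export
z_stack <- function(channels, z_spacing, pixel_size) {
  if (!is.list(channels) || length(channels) < 1 ||
      is.null(names(channels)) || any(names(channels) == ""))
    stop_invalid_input("channels must be a non-empty named list of arrays")
  dims <- lapply(channels, dim)
  if (any(vapply(dims, length, integer(1)) != 3))
    stop_invalid_input("each channel must be a 3D [x, y, z] array")
  if (length(unique(vapply(dims, paste, character(1), collapse = "x"))) != 1)
    stop_invalid_input("all channels must have identical dimensions")
  if (!is.numeric(z_spacing) || z_spacing <= 0)
    stop_invalid_input("z_spacing must be positive")
  if (!is.numeric(pixel_size) || pixel_size <= 0)
    stop_invalid_input("pixel_size must be positive")
  structure(list(channels = channels, z_spacing = z_spacing,
                 pixel_size = pixel_size),
            class = "z_stack")
}

#' @export
print.z_stack <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat(sprintf("z_stack: %d x %d px, %d slices, channels: %s (%g um/px, dz %g um)\n",
              d[1], d[2], d[3], paste(names(x$channels), collapse = ", "),
              x$pixel_size, x$z_spacing))
  invisible(x)
}

#' Select the analysis plane of a z-stack
#'
#' The pattern surface is the slice with the highest summed
#' pattern-channel intensity (summation resists hot pixels); the analysis
#' plane lies `offset_um` above it, rounded to the nearest slice.
#'
#' @param stack a [z_stack()].
#' @param offset_um offset above the surface in micrometres (>= 0);
#'   default 2.
#' @param pattern_channel name of the pattern channel.
#' @return A `plane_selection`: list with 1-based `surface_index`,
#'   `analysis_index` and `offset_um`.
#' @export
select_analysis_plane <- function(stack, offset_um = 2,
                                  pattern_channel = "pattern") {
  if (!inherits(stack, "z_stack")) stop_invalid_input("expected a z_stack")
  if (!is.numeric(offset_um) || offset_um < 0)
    stop_invalid_input("offset_um must be >= 0")
  ch <- stack$channels[[pattern_channel]]
  if (is.null(ch))
    stop_invalid_input(sprintf("no channel named '%s'", pattern_channel))
  totals <- apply(ch, 3, sum)
  if (all(totals <= 0))
    stop_ambiguous_surface("pattern channel is all zero; surface undefined")
  surface <- which.max(totals)
  analysis <- surface + round(offset_um / stack$z_spacing)
  if (analysis > dim(ch)[3])
    stop_out_of_range(sprintf(
      "analysis plane %d exceeds stack extent (%d slices)",
      analysis, dim(ch)[3]))
  structure(list(surface_index = surface, analysis_index = analysis,
                 offset_um = offset_um),
            class = "plane_selection")
}

# Gaussian smoothing + Otsu threshold + hole filling + largest connected
# component; returns the filled component mask together with the pre-fill
# thresholded band of that component (used to centre ring-like membrane
# signals), or NULL when nothing passes the area floor
segment_largest_object <- function(img, sigma = 1, min_area = 100) {
  rng <- range(img)
  if (!is.finite(diff(rng)) || diff(rng) <= 0) return(NULL)
  norm <- (img - rng[1]) / diff(rng)
  sm <- as.array(EBImage::gblur(EBImage::Image(norm), sigma = sigma))
  thr <- EBImage::otsu(EBImage::Image(sm))
  band <- sm > thr
  filled <- EBImage::fillHull(EBImage::Image(band))
  lab <- EBImage::bwlabel(filled)
  tab <- tabulate(as.integer(as.array(lab)))
  if (length(tab) == 0 || max(tab) < min_area) return(NULL)
  mask <- as.array(lab) == which.max(tab)
  list(mask = mask, band = band & mask)
}

# circular moving average of polygon vertices (odd window)
smooth_polygon <- function(pts, window = 5) {
  n <- nrow(pts)
  if (n <= window) return(pts)
  h <- (window - 1) / 2
  idx <- outer(seq_len(n), -h:h, function(i, o) ((i + o - 1) %% n) + 1)
  cbind(rowMeans(matrix(pts[idx, 1], n)), rowMeans(matrix(pts[idx, 2], n)))
}

# shift every vertex inward (toward the centroid side) along its local
# normal; used to move a filled-band boundary onto the membrane ridge.
# Vertices are smoothed and tangents taken over a wide window so pixel
# jitter cannot fold the offset polygon; if the result still
# self-intersects, fall back to a radial shrink, then to the input.
offset_contour_inward <- function(contour, dist) {
  pts <- smooth_polygon(contour$points)
  n <- nrow(pts)
  h <- min(3, max(1, n %/% 8))
  prv <- pts[((seq_len(n) - 1 - h) %% n) + 1, , drop = FALSE]
  nxt <- pts[((seq_len(n) - 1 + h) %% n) + 1, , drop = FALSE]
  tang <- nxt - prv
  nrm <- cbind(tang[, 2], -tang[, 1])
  nrm <- nrm / pmax(sqrt(rowSums(nrm^2)), 1e-12)
  ctr <- contour_centroid(pts)
  sgn <- sign(rowSums((rep(1, n) %o% ctr - pts) * nrm))
  sgn[sgn == 0] <- 1
  normal_off <- tryCatch(
    shape_contour(pts + dist * sgn * nrm, contour$pixel_size, contour$label),
    guv_invalid_input = function(e) NULL)
  if (!is.null(normal_off)) return(normal_off)
  rad <- sweep(pts, 2, ctr)
  rl <- pmax(sqrt(rowSums(rad^2)), 1e-12)
  tryCatch(
    shape_contour(sweep(rad * pmax(1 - dist / rl, 0.1), 2, ctr, "+"),
                  contour$pixel_size, contour$label),
    guv_invalid_input = function(e) contour)
}

# marching-squares boundary of a filled mask at the 0.5 level; 0-based
# sub-pixel coordinates, decimated until the polygon is simple
mask_to_contour <- function(mask, pixel_size, label = "",
                            max_vertices = 240) {
  d <- dim(mask)
  cl <- grDevices::contourLines(x = seq_len(d[1]) - 1, y = seq_len(d[2]) - 1,
                                z = mask + 0, levels = 0.5)
  if (length(cl) == 0) stop_no_object("no boundary found in mask")
  lens <- vapply(cl, function(c) length(c$x), integer(1))
  cv <- cl[[which.max(lens)]]
  pts <- cbind(cv$x, cv$y)
  for (k in c(1, 2, 4, 8, 16)) {
    step <- max(1L, ceiling(nrow(pts) / max_vertices) * k)
    keep <- seq(1, nrow(pts), by = step)
    sub <- pts[keep, , drop = FALSE]
    if (nrow(sub) < 3) break
    ct <- tryCatch(shape_contour(sub, pixel_size, label),
                   guv_invalid_input = function(e) NULL)
    if (!is.null(ct)) return(ct)
  }
  stop_no_object("boundary could not be reduced to a simple polygon")
}

#' Extract the GUV contour from an image or z-stack slice
#'
#' Pipeline: Gaussian smoothing (sigma 1 px), global Otsu threshold, hole
#' filling, largest connected component, sub-pixel boundary by marching
#' squares, decimation to a simple polygon.
#'
#' @param x a [z_stack()] or a 2D numeric matrix indexed \[x, y\].
#' @param ... passed to methods.
#' @return A [shape_contour()] in pixel coordinates carrying the stack's
#'   pixel size.
#' @export
extract_contour <- function(x, ...) UseMethod("extract_contour")

#' @rdname extract_contour
#' @param plane a `plane_selection` from [select_analysis_plane()]; default
#'   selects with a 2 um offset.
#' @param channel channel to segment (default `"membrane"`).
#' @param sigma smoothing sigma in pixels.
#' @param min_area minimum object area in pixels.
#' @param label label for the returned contour.
#' @export
extract_contour.z_stack <- function(x, plane = NULL, channel = "membrane",
                                    sigma = 1, min_area = 100,
                                    label = "guv", ...) {
  ch <- x$channels[[channel]]
  if (is.null(ch))
    stop_invalid_input(sprintf("no channel named '%s'", channel))
  if (is.null(plane)) plane <- select_analysis_plane(x)
  img <- ch[, , plane$analysis_index]
  extract_contour(img, pixel_size = x$pixel_size, sigma = sigma,
                  min_area = min_area, label = label)
}

#' @rdname extract_contour
#' @param pixel_size pixel size in micrometres per pixel.
#' @details For ring-like membrane signals (the thresholded band encloses
#'   a dark interior) the filled-component boundary sits on the band's
#'   outer edge; the returned contour is shifted inward by half the band
#'   thickness so it tracks the membrane ridge instead. Solid objects are
#'   returned as segmented.
#' @export
extract_contour.default <- function(x, pixel_size = 1, sigma = 1,
                                    min_area = 100, label = "guv", ...) {
  img <- as.matrix(x)
  seg <- segment_largest_object(img, sigma = sigma, min_area = min_area)
  if (is.null(seg))
    stop_no_object(sprintf("no object above %d px found", min_area))
  ct <- mask_to_contour(seg$mask, pixel_size, label)
  ring_frac <- sum(seg$band) / sum(seg$mask)
  if (ring_frac < 0.6) {
    perim <- sum(sqrt(rowSums((ct$points -
                                 ct$points[c(2:nrow(ct$points), 1), ])^2)))
    thickness <- sum(seg$band) / perim
    ct <- offset_contour_inward(ct, thickness / 2)
  }
  ct
}

#' Per-slice contours of a z-stack
#'
#' Applies [extract_contour()] to every slice of the membrane channel;
#' slices without a detectable object are omitted. The result supports 3D
#' reconstruction of the adherent GUV from its stack.
#'
#' @param stack a [z_stack()].
#' @param channel channel to segment.
#' @param sigma,min_area segmentation parameters, see [extract_contour()].
#' @return List (ordered by z) of entries `list(z_index, contour)`.
#' @export
stack_contours <- function(stack, channel = "membrane", sigma = 1,
                           min_area = 100) {
  if (!inherits(stack, "z_stack")) stop_invalid_input("expected a z_stack")
  ch <- stack$channels[[channel]]
  if (is.null(ch))
    stop_invalid_input(sprintf("no channel named '%s'", channel))
  nz <- dim(ch)[3]
  out <- list()
  for (z in seq_len(nz)) {
    ct <- tryCatch(
      extract_contour(ch[, , z], pixel_size = stack$pixel_size,
                      sigma = sigma, min_area = min_area,
                      label = sprintf("slice_%d", z)),
      guv_no_object = function(e) NULL)
    if (!is.null(ct)) out[[length(out) + 1]] <- list(z_index = z, contour = ct)
  }
  out
}
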