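# GUV deformation versus size: axis-ratio records, size-group binning and
# unpaired two-sample comparison. Ratios are measured at the analysis
# plane (2 um above the pattern).

SIZE_GROUPS <- c("5-10", "10-15", "15-20", "20-25", ">25")
SIZE_EDGES <- c(5, 10, 15, 20, 25, Inf)

#' Assign a GUV to a size group by major-axis length
#'
#' Groups are half-open, lower-closed intervals of major-axis length in
#' micrometres: \[5,10), \[10,15), \[15,20), \[20,25), \[25, Inf).
#' A GUV below 5 um is flagged `"<5"`.
#'
#' @param axes an `axis_measurement` from [measure_axes()], or a numeric
#'   major-axis length in micrometres.
#' @return One of `"<5"`, `"5-10"`, `"10-15"`, `"15-20"`, `"20-25"`,
#'   `">25"`.
#' @export
assign_size_group <- function(axes) {
  major <- if (inherits(axes, "axis_measurement")) axes$major_length else
    as.numeric(axes)
  if (!is.finite(major) || major <= 0)
    stop_invalid_input("major length must be a positive number")
  if (major < 5) return("<5")
  SIZE_GROUPS[findInterval(major, SIZE_EDGES)]
}

#' Unpaired two-sample comparison of deformation ratios
#'
#' Classical unpaired two-sample t test giving a two-tailed p-value;
#' equal-variance (Student) by default, Welch via `welch = TRUE`.
#'
#' @param a,b numeric vectors of axis ratios, each of length >= 2.
#' @param welch use the Welch (unequal-variance) statistic.
#' @return Two-tailed p-value in (0, 1\].
#' @export
compare_groups <- function(a, b, welch = FALSE) {
  if (length(a) < 2 || length(b) < 2)
    stop_invalid_input("each group needs at least 2 values")
  if (stats::var(a) + stats::var(b) <= 0) {
    if (isTRUE(all.equal(mean(a), mean(b)))) return(1)
    stop_invalid_input("zero within-group variance in both groups")
  }
  stats::t.test(a, b, var.equal = !welch)$p.value
}

#' Build a GUV record
#'
#' @param guv_id integer id.
#' @param contour a [shape_contour()] at the analysis plane.
#' @param pattern_label pattern type the GUV adhered to.
#' @return A `guv_record`: list with `guv_id`, `contour`, `axes`
#'   (recomputed from the contour), `pattern_label` and `size_group`.
#' @export
guv_record <- function(guv_id, contour, pattern_label = "") {
  assert_contour(contour)
  axes <- measure_axes(contour)
  structure(list(guv_id = as.integer(guv_id), contour = contour,
                 axes = axes, pattern_label = pattern_label,
                 size_group = assign_size_group(axes)),
            class = "guv_record")
}

records_to_frame <- function(records) {
  if (is.data.frame(records)) {
    if (nrow(records) < 1) stop_empty_input("no GUV records")
    return(records)
  }
  if (length(records) < 1) stop_empty_input("no GUV records")
  do.call(rbind, lapply(records, function(r) {
    if (inherits(r, "guv_record"))
      data.frame(guv_id = r$guv_id, major_um = r$axes$major_length,
                 minor_um = r$axes$minor_length, ratio = r$axes$ratio,
                 pattern_label = r$pattern_label,
                 size_group = r$size_group)
    else as.data.frame(r)
  }))
}

#' Deformation summary by size group
#'
#' Per-group sample size and mean axis ratio, plus two-tailed p-values of
#' the unpaired t test of each group against the smallest-size group
#' present. Groups with fewer than 2 records are reported with n only.
#'
#' @param records list of [guv_record()] objects, or a data frame with
#'   columns `ratio` and either `size_group` or `major_um`.
#' @param welch use Welch's t statistic.
#' @return Data frame with columns `size_group`, `n`, `mean_ratio`,
#'   `p_vs_smallest`.
#' @export
deformation_report <- function(records, welch = FALSE) {
  df <- records_to_frame(records)
  if (is.null(df$size_group))
    df$size_group <- vapply(df$major_um, assign_size_group, character(1))
  groups <- SIZE_GROUPS[SIZE_GROUPS %in% df$size_group]
  if ("<5" %in% df$size_group) groups <- c("<5", groups)
  out <- data.frame(size_group = groups,
                    n = vapply(groups,
                               function(g) sum(df$size_group == g),
                               numeric(1)),
                    mean_ratio = vapply(groups, function(g)
                      mean(df$ratio[df$size_group == g]), numeric(1)),
                    p_vs_smallest = NA_real_)
  testable <- out$size_group[out$n >= 2]
  if (length(testable) >= 2) {
    ref <- testable[1]  # smallest size group with n >= 2
    ref_ratios <- df$ratio[df$size_group == ref]
    for (g in setdiff(testable, ref)) {
      p <- tryCatch(
        compare_groups(ref_ratios, df$ratio[df$size_group == g],
                       welch = welch),
        guv_invalid_input = function(e) NA_real_)
      out$p_vs_smallest[out$size_group == g] <- p
    }
  }
  rownames(out) <- NULL
  out
}
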