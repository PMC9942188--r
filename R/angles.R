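# Folded-angle conventions shared by the confinement model and the
# experimental filament pipeline.

#' Fold orientation angles into \[0, 90\] degrees
#'
#' Orientations of unpolarized filaments are axes, not vectors: theta,
#' theta + 180 and 180 - theta are indistinguishable under the mirror
#' symmetry of the shapes, so angles are reduced first modulo 180 and then
#' folded about 90: `fold = min(phi, 180 - phi)`. A filament perpendicular
#' to the reference axis folds to exactly 90.
#'
#' @param theta numeric vector of angles in degrees.
#' @param reference reference angle in degrees subtracted before folding
#'   (e.g. the contour's major-axis angle).
#' @return Angles in \[0, 90\].
#' @examples
#' fold_angle(c(0, 45, 90, 135, 180, 270))
#' @export
fold_angle <- function(theta, reference = 0) {
  phi <- (theta - reference) %% 180
  pmin(phi, 180 - phi)
}

# right-closed bins over [0, 90]: (lo, hi], with 0 kept in the first bin
# and 90 in the closed top bin
angle_bin_index <- function(folded, n_bins, domain = 90) {
  width <- domain / n_bins
  idx <- ceiling(folded / width)
  pmin(pmax(idx, 1L), n_bins)
}

#' Construct an angular probability distribution
#'
#' Histogram of folded angles over \[0, 90\] degrees (or \[0, 180\] for
#' unfolded distributions), normalized to sum to 1. Bins are right-closed,
#' `(lo, hi]`, with 0 included in the first bin.
#'
#' @param angles numeric vector of angles, already folded into the domain.
#' @param n_bins number of equal-width bins.
#' @param weights optional non-negative weights, one per angle.
#' @param domain upper edge of the angular domain (90 for folded angles).
#' @return An `angular_distribution`: list with `bin_edges` (length
#'   `n_bins + 1`), `probabilities` (sum 1) and `counts` (total weight per
#'   bin).
#' @export
angular_distribution_from_angles <- function(angles, n_bins = 18,
                                             weights = NULL, domain = 90) {
  if (length(angles) < 1) stop_empty_input("no angles to bin")
  if (any(!is.finite(angles)) || any(angles < 0) || any(angles > domain))
    stop_invalid_input(sprintf("angles must lie in [0, %g]", domain))
  if (is.null(weights)) weights <- rep(1, length(angles))
  if (length(weights) != length(angles) || any(weights < 0))
    stop_invalid_input("weights must be non-negative, one per angle")
  idx <- angle_bin_index(angles, n_bins, domain)
  counts <- vapply(seq_len(n_bins),
                   function(b) sum(weights[idx == b]), numeric(1))
  total <- sum(counts)
  if (total <= 0) stop_empty_input("total weight is zero")
  structure(list(bin_edges = seq(0, domain, length.out = n_bins + 1),
                 probabilities = counts / total,
                 counts = counts),
            class = "angular_distribution")
}

#' @export
print.angular_distribution <- function(x, ...) {
  n <- length(x$probabilities)
  cat(sprintf("angular_distribution: %d bins over [0, %g] deg, total %g\n",
              n, max(x$bin_edges), sum(x$probabilities)))
  invisible(x)
}

#' Uniform angular distribution
#'
#' @param n_bins number of bins.
#' @param domain upper edge of the domain in degrees.
#' @return An `angular_distribution` with equal probabilities.
#' @export
uniform_angular_distribution <- function(n_bins = 18, domain = 90) {
  structure(list(bin_edges = seq(0, domain, length.out = n_bins + 1),
                 probabilities = rep(1 / n_bins, n_bins),
                 counts = rep(1, n_bins)),
            class = "angular_distribution")
}

check_same_bins <- function(a, b) {
  if (!inherits(a, "angular_distribution") ||
      !inherits(b, "angular_distribution"))
    stop_invalid_input("expected angular_distribution objects")
  if (length(a$probabilities) != length(b$probabilities) ||
      max(abs(a$bin_edges - b$bin_edges)) > 1e-9)
    stop_invalid_input("distributions have different binning")
}

#' Total variation distance between two binned distributions
#'
#' @param a,b `angular_distribution` objects on the same bins.
#' @return `0.5 * sum(|p_a - p_b|)`, in \[0, 1\].
#' @export
tv_distance <- function(a, b) {
  check_same_bins(a, b)
  sum(abs(a$probabilities - b$probabilities)) / 2
}

#' Kolmogorov-Smirnov distance between two binned distributions
#'
#' Maximum absolute difference of the binned cumulative distributions.
#'
#' @param a,b `angular_distribution` objects on the same bins.
#' @return KS distance in \[0, 1\].
#' @export
ks_distance <- function(a, b) {
  check_same_bins(a, b)
  max(abs(cumsum(a$probabilities) - cumsum(b$probabilities)))
}
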