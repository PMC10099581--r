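# Goodness-of-fit and pattern metrics for comparing utilisation and
# occurrence distributions.

# Coerce a ud or raster_layer to a probability vector + geometry, warning
# and renormalising if it does not already sum to 1.
as_prob <- function(u, label = "distribution") {
  if (inherits(u, "ud")) {
    list(p = u$p, area = u$area)
  } else if (inherits(u, "raster_layer")) {
    p <- as.vector(u$values)
    if (any(p < 0)) stopf("%s has negative cell masses", label)
    s <- sum(p)
    if (abs(s - 1) > 1e-6) {
      warning(sprintf("%s does not sum to 1 (%.6g); renormalising", label, s),
              call. = FALSE)
    }
    list(p = p / s, area = as_study_area(u))
  } else stopf("%s must be a ud or raster_layer", label)
}

#' Bhattacharyya's affinity between two distributions
#'
#' `BA = sum over cells of sqrt(u1 * u2)`, the recommended overlap measure
#' between two utilisation or occurrence distributions on a common grid:
#' 1 for identical distributions, 0 for disjoint supports, and in `[0, 1]`
#' always.
#'
#' @param u1,u2 [ud()]s or [raster_layer()]s on the same grid (renormalised
#'   with a warning if they do not sum to 1).
#' @return A scalar in `[0, 1]`.
#' @examples
#' area <- study_area(1, 2)
#' bhattacharyya_affinity(ud(c(0.5, 0.5), area), ud(c(0.25, 0.75), area))
#' @export
bhattacharyya_affinity <- function(u1, u2) {
  a <- as_prob(u1, "u1"); b <- as_prob(u2, "u2")
  check_same_grid(a$area, b$area)
  min(1, sum(sqrt(a$p * b$p)))
}

#' Locational variance of a point set or distribution
#'
#' The mean squared Euclidean distance from the (mass-weighted) centroid:
#' for points, `mean(|x_i - xbar|^2)`; for a UD, `sum u(s) |c_s - cbar|^2`
#' over cell centres. A simple, smoothing-free measure of UD/home-range
#' size, proportional to standard area measures; invariant under
#' translation and rotation and scaling as the square of a dilation.
#'
#' @param x an n x 2 matrix of points, a [ud()], or a [raster_layer()] of
#'   masses.
#' @return Non-negative scalar in squared coordinate units.
#' @export
locational_variance <- function(x) {
  if (inherits(x, c("ud", "raster_layer"))) {
    u <- as_prob(x)
    centres <- cell_centres(u$area)
    cx <- sum(u$p * centres[, 1]); cy <- sum(u$p * centres[, 2])
    sum(u$p * ((centres[, 1] - cx)^2 + (centres[, 2] - cy)^2))
  } else {
    x <- as.matrix(x)
    if (nrow(x) < 1L) stopf("at least one point is required")
    cx <- mean(x[, 1]); cy <- mean(x[, 2])
    mean((x[, 1] - cx)^2 + (x[, 2] - cy)^2)
  }
}

#' Ratio of model to reference UD size
#'
#' `locational_variance(model) / locational_variance(reference)`; 1
#' indicates agreement in distribution size, above 1 a model that spreads
#' too widely, below 1 one that concentrates too much.
#'
#' @param model,reference [ud()]s, rasters or point matrices in the same
#'   coordinate units.
#' @return A positive scalar.
#' @export
ud_size_ratio <- function(model, reference) {
  vr <- locational_variance(reference)
  if (vr <= 0)
    stopf("reference distribution has zero locational variance (point mass); size ratio is undefined")
  locational_variance(model) / vr
}

#' Segregation index of a set of UDs
#'
#' `1 - mean pairwise Bhattacharyya affinity`: 0 when all distributions
#' coincide, approaching 1 when they are pairwise disjoint. A monotone
#' diagnostic for avoidance sweeps (stronger mutual avoidance gives more
#' segregated space use).
#'
#' @param uds list of at least two [ud()]s or [raster_layer()]s on one
#'   grid.
#' @return A scalar in `[0, 1]`.
#' @export
segregation_index <- function(uds) {
  if (length(uds) < 2L) stopf("at least two distributions are required")
  pairs <- utils::combn(length(uds), 2L)
  ba <- apply(pairs, 2L, function(ij)
    bhattacharyya_affinity(uds[[ij[1]]], uds[[ij[2]]]))
  1 - mean(ba)
}
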