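# Linearized Sholl profile and Gaussian-kernel spatial density.

#' Linearized Sholl analysis
#'
#' Unipolar neurons keep the soma outside the arbor, so classical
#' concentric-sphere Sholl analysis is replaced by its somatofugal
#' path-length equivalent: linearly spaced distances from zero to the
#' maximum soma-to-tip path length, with the crossing count at distance D
#' equal to the number of parent-child node pairs whose cumulative
#' path-length interval straddles D (half-open convention
#' \code{[d_parent, d_child)}: a pair sitting exactly on a sampled
#' distance counts once). The count just above zero equals the number of
#' primary filaments leaving the soma and the count beyond the maximum
#' path length is zero.
#'
#' @param g a [NeuronGeometry-class]
#' @param nDistances number of linearly spaced sample distances
#'   (default 100).
#' @param excludeAxons drop axon terminal filaments (default TRUE).
#' @return data.frame with \code{distance} (micrometres),
#'   \code{crossings} (integer), \code{normCount} (crossings / max
#'   crossings) and \code{normDistance} (distance / max soma-to-tip path
#'   length).
#' @export
linearizedSholl <- function(g, nDistances = 100, excludeAxons = TRUE) {
  stopifnot(is(g, "NeuronGeometry"), nDistances >= 2)
  pd <- .pathDistances(g)
  pr <- .parentRow(g)
  drop <- if (excludeAxons) .axonNodeRows(g) else integer()
  rows <- setdiff(seq_len(nNodes(g))[-1L], drop)
  paths <- suppressWarnings(somaPaths(g, excludeAxons))
  maxLen <- if (nrow(paths)) max(paths$pathLength) else max(pd[rows], 0)
  dists <- seq(0, maxLen, length.out = nDistances)
  dPar <- pd[pr[rows]]; dChild <- pd[rows]
  crossings <- vapply(dists, function(D)
    sum(dPar <= D & D < dChild), integer(1))
  maxC <- max(crossings, 1L)
  data.frame(distance = dists, crossings = crossings,
             normCount = crossings / maxC,
             normDistance = if (maxLen > 0) dists / maxLen else dists)
}

# scipy-style Gaussian KDE: full data covariance scaled by Scott's
# factor n^(-1/(d+4)) squared; density evaluated at the data points
.gaussKde2d <- function(xy, at = xy) {
  n <- nrow(xy); d <- ncol(xy)
  factor <- n^(-1 / (d + 4))
  S <- stats::cov(xy) * factor^2
  # guard rank deficiency (collinear clouds)
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < 1e-12 * max(ev, 1e-12))
    S <- S + diag(1e-8 * max(diag(S), 1e-8), d)
  Sinv <- solve(S)
  detS <- det(S)
  norm <- 1 / (n * (2 * pi)^(d / 2) * sqrt(detS))
  vapply(seq_len(nrow(at)), function(i) {
    dx <- sweep(xy, 2, at[i, ])
    m <- rowSums((dx %*% Sinv) * dx)
    norm * sum(exp(-0.5 * m))
  }, numeric(1))
}

#' Spatial density map
#'
#' Gaussian kernel density estimate over the node x-y coordinates
#' (Scott's rule for the bandwidth: the full data covariance scaled by
#' n^(-1/(d+4)) squared), evaluated at each node and rescaled so the
#' maximum within the neuron is exactly 1. A bird's-eye view of relative
#' neurite density in the neuropil plane.
#'
#' @param g a [NeuronGeometry-class] with at least 3 nodes.
#' @return data.frame \code{nodeId}, \code{x}, \code{y}, \code{density}
#'   (in [0, 1], max exactly 1); attribute \code{"bandwidthRule"} is
#'   \code{"scott"}.
#' @export
spatialDensity <- function(g) {
  stopifnot(is(g, "NeuronGeometry"))
  if (nNodes(g) < 3L) stop("spatial density needs at least 3 nodes")
  xy <- .coords(g)[, 1:2, drop = FALSE]
  dens <- .gaussKde2d(xy)
  out <- data.frame(nodeId = g@nodes$id, x = xy[, 1], y = xy[, 2],
                    density = dens / max(dens))
  attr(out, "bandwidthRule") <- "scott"
  out
}
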