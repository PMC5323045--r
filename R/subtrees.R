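# Subtree decomposition and elliptical neuritic fields.

#' Main path(s) of a neuron
#'
#' The segments connecting the soma to the axon origin(s): the primary
#' neurite. Neurons with several axons have several main paths whose
#' union (sharing the proximal trunk) is returned. The main path contains
#' no terminating tips.
#'
#' @param g a [NeuronGeometry-class] with at least one tagged axon.
#' @return list with \code{segIds} (segments on the union of main
#'   paths), \code{nodeIds} (nodes on it, soma included) and
#'   \code{nPaths} (number of axons / main paths).
#' @export
mainPath <- function(g) {
  stopifnot(is(g, "NeuronGeometry"))
  if (!length(g@axonTips))
    stop("no tagged axon: the main path is undefined (see tagAxons)")
  segs <- neuronSegments(g)
  axSegs <- which(segs$axon)
  mp <- integer()
  for (a in axSegs) {
    cur <- segs$parentSeg[a]          # axon filament itself is not main path
    while (!is.na(cur)) { mp <- c(mp, cur); cur <- segs$parentSeg[cur] }
  }
  mp <- sort(unique(mp))
  nodeRows <- sort(unique(c(1L, unlist(segs$rows[mp]))))
  list(segIds = segs$segId[mp], nodeIds = g@nodes$id[nodeRows],
       nPaths = length(axSegs))
}

#' Detect subtrees
#'
#' A subtree is any collection of branches projecting from the same
#' secondary neurite: one subtree per segment that departs the main path
#' (its root segment) and reaches at least one terminating tip. Branches
#' leading only to axons do not qualify. The subtree count therefore
#' equals the number of qualifying secondary branches.
#'
#' @param g a [NeuronGeometry-class] with tagged axon(s).
#' @return list of subtrees, each a list with \code{rootSegId},
#'   \code{segIds} (member segments), \code{tipIds} (terminating tips),
#'   \code{tipCoords} (matrix), \code{centerOfMass} (3-vector) and
#'   \code{clusterRadius} (micrometres).
#' @export
detectSubtrees <- function(g) {
  mp <- mainPath(g)
  segs <- neuronSegments(g)
  onMain <- segs$segId %in% mp$segIds
  rootSegs <- which(!onMain & !segs$axon &
                      segs$fromId %in% mp$nodeIds)
  xyz <- .coords(g)
  tips <- terminatingTips(g)
  out <- list()
  for (rs in rootSegs) {
    members <- rs
    frontier <- rs
    while (length(frontier)) {
      ch <- which(segs$parentSeg %in% frontier)
      frontier <- setdiff(ch, members)
      members <- union(members, frontier)
    }
    stTips <- intersect(segs$toId[members[segs$terminal[members] &
                                            !segs$axon[members]]], tips)
    if (!length(stTips)) next
    tc <- xyz[match(stTips, g@nodes$id), , drop = FALSE]
    com <- colMeans(tc)
    cr <- mean(sqrt(rowSums(sweep(tc, 2, com)^2)))
    out[[length(out) + 1L]] <- list(
      rootSegId = segs$segId[rs],
      segIds = segs$segId[sort(members)],
      tipIds = stTips,
      tipCoords = tc,
      centerOfMass = com,
      clusterRadius = cr)
  }
  out
}

#' Tip center of mass
#'
#' Arithmetic mean of a subtree's terminating-tip coordinates.
#'
#' @param tipCoords numeric matrix (n x 3) of tip coordinates, or a
#'   subtree list from [detectSubtrees()].
#' @return numeric 3-vector (micrometres)
#' @export
tipCenterOfMass <- function(tipCoords) {
  if (is.list(tipCoords) && !is.null(tipCoords$tipCoords))
    tipCoords <- tipCoords$tipCoords
  colMeans(as.matrix(tipCoords))
}

#' Tip cluster radius
#'
#' Mean Euclidean distance from the tip center of mass to each tip.
#'
#' @param tipCoords numeric matrix (n x 3) of tip coordinates, or a
#'   subtree list from [detectSubtrees()].
#' @return micrometres (0 for a single tip)
#' @export
clusterRadius <- function(tipCoords) {
  if (is.list(tipCoords) && !is.null(tipCoords$tipCoords))
    tipCoords <- tipCoords$tipCoords
  tc <- as.matrix(tipCoords)
  com <- colMeans(tc)
  mean(sqrt(rowSums(sweep(tc, 2, com)^2)))
}

#' Fit an elliptical neuritic field
#'
#' Covariance ellipsoid of a subtree's tip cloud: centered on the tip
#' center of mass, oriented along the eigenvectors of the tip coordinate
#' covariance, with semi-axes \code{scale * sqrt(eigenvalues)} (the
#' default scale 2 covers about 95 percent of a 1D Gaussian). Clouds with
#' fewer than 4 tips or a rank-deficient covariance fall back to a sphere
#' of radius [clusterRadius()].
#'
#' @param tipCoords numeric matrix (n x 3), or a subtree list.
#' @param scale semi-axis multiple of sqrt(eigenvalue), default 2.
#' @return list of class \code{"Ellipsoid"}: \code{center} (3-vector),
#'   \code{axes} (3 semi-axis lengths, sorted descending), \code{rotation}
#'   (3 x 3 orthonormal columns matching \code{axes}), \code{sphere}
#'   (fallback flag).
#' @export
fitNeuriticField <- function(tipCoords, scale = 2) {
  if (is.list(tipCoords) && !is.null(tipCoords$tipCoords))
    tipCoords <- tipCoords$tipCoords
  tc <- as.matrix(tipCoords)
  center <- colMeans(tc)
  if (nrow(tc) < 4L)
    return(structure(list(center = center,
                          axes = rep(clusterRadius(tc), 3),
                          rotation = diag(3), sphere = TRUE),
                     class = "Ellipsoid"))
  S <- stats::cov(tc)
  e <- eigen(S, symmetric = TRUE)
  if (min(e$values) < 1e-10 * max(e$values, 1e-10))
    return(structure(list(center = center,
                          axes = rep(clusterRadius(tc), 3),
                          rotation = diag(3), sphere = TRUE),
                     class = "Ellipsoid"))
  structure(list(center = center, axes = scale * sqrt(e$values),
                 rotation = e$vectors, sphere = FALSE),
            class = "Ellipsoid")
}

#' @export
print.Ellipsoid <- function(x, ...) {
  cat("Ellipsoid", if (x$sphere) "(sphere fallback)", "\n")
  cat("  center:", paste(signif(x$center, 4), collapse = ", "), "um\n")
  cat("  semi-axes:", paste(signif(x$axes, 4), collapse = ", "), "um\n")
  invisible(x)
}

# x-y shadow of a 3D ellipsoid. For quadratic form A = inverse shape
# matrix (x^T A x <= 1 around the center), the projection onto x-y is the
# ellipse with matrix Axy - b b^T / c (Schur complement on the z block).
.projectEllipseXY <- function(field) {
  A3 <- with(field, rotation %*% diag(1 / pmax(axes, 1e-9)^2) %*%
               t(rotation))
  Axy <- A3[1:2, 1:2]
  b <- A3[1:2, 3]; cz <- A3[3, 3]
  M <- Axy - tcrossprod(b) / cz
  list(center = field$center[1:2], M = M)
}

# boundary points of the projected ellipse (n angles)
.ellipseBoundary <- function(proj, n = 360L) {
  e <- eigen(proj$M, symmetric = TRUE)
  ax <- 1 / sqrt(pmax(e$values, 1e-18))
  th <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  pts <- cbind(ax[1] * cos(th), ax[2] * sin(th)) %*% t(e$vectors)
  sweep(pts, 2, proj$center, `+`)
}

.insideEllipse <- function(pts, proj, tol = 1e-6) {
  dx <- sweep(pts, 2, proj$center)
  rowSums((dx %*% proj$M) * dx) <= 1 + tol
}

#' Count overlapping neuritic fields
#'
#' Number of unordered pairs of subtree neuritic fields whose x-y plane
#' projections intersect. Intersection is decided robustly by sampling
#' 360 boundary points of each projected ellipse plus mutual center
#' containment (exact conic solving is avoided). Also reports the
#' per-subtree alternative count: subtrees intersecting at least one
#' other.
#'
#' @param fields list of \code{"Ellipsoid"} objects (see
#'   [fitNeuriticField()]).
#' @param boundaryPoints number of boundary samples per ellipse
#'   (default 360).
#' @param tol containment tolerance in micrometres (default 1e-6).
#' @return integer: number of intersecting pairs; attribute
#'   \code{"subtreesOverlapping"} gives the element-wise count.
#' @export
countOverlaps <- function(fields, boundaryPoints = 360L, tol = 1e-6) {
  k <- length(fields)
  if (k < 2L)
    return(structure(0L, subtreesOverlapping = 0L))
  projs <- lapply(fields, .projectEllipseXY)
  bounds <- lapply(projs, .ellipseBoundary, n = boundaryPoints)
  hit <- matrix(FALSE, k, k)
  for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
    ov <- any(.insideEllipse(bounds[[i]], projs[[j]], tol)) ||
      any(.insideEllipse(bounds[[j]], projs[[i]], tol)) ||
      .insideEllipse(rbind(projs[[i]]$center), projs[[j]], tol) ||
      .insideEllipse(rbind(projs[[j]]$center), projs[[i]], tol)
    hit[i, j] <- hit[j, i] <- ov
  }
  structure(sum(hit[upper.tri(hit)]),
            subtreesOverlapping = sum(rowSums(hit) > 0))
}

#' Per-subtree table
#'
#' One row per subtree: tip count, cluster radius and fitted field
#' semi-axes. The radius column equals [clusterRadius()] on the same
#' tips.
#'
#' @param g a [NeuronGeometry-class] with tagged axon(s).
#' @param scale ellipsoid scale passed to [fitNeuriticField()].
#' @return data.frame \code{subtree}, \code{rootSegId}, \code{nTips},
#'   \code{radius}, \code{ax1}, \code{ax2}, \code{ax3}
#' @export
subtreeTable <- function(g, scale = 2) {
  sts <- detectSubtrees(g)
  if (!length(sts))
    return(data.frame(subtree = integer(), rootSegId = integer(),
                      nTips = integer(), radius = numeric(),
                      ax1 = numeric(), ax2 = numeric(), ax3 = numeric()))
  do.call(rbind, lapply(seq_along(sts), function(i) {
    f <- fitNeuriticField(sts[[i]], scale)
    data.frame(subtree = i, rootSegId = sts[[i]]$rootSegId,
               nTips = length(sts[[i]]$tipIds),
               radius = sts[[i]]$clusterRadius,
               ax1 = f$axes[1], ax2 = f$axes[2], ax3 = f$axes[3])
  }))
}
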