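# Synthetic minimal spanning neurite trees grown under the wiring cost
# total cost = wiring cost + bf * path length cost, and their comparison
# to real neurons.

#' Fit a bounding ellipsoid to a neuron
#'
#' Covariance ellipsoid over all node coordinates, scaled so that at
#' least \code{coverage} of the nodes fall inside: the space a synthetic
#' tree should occupy. Degenerate (coplanar or collinear) clouds get a
#' minimum semi-axis floor of 1 micrometre with a warning.
#'
#' @param g a [NeuronGeometry-class]
#' @param coverage fraction of nodes to enclose (default 0.95).
#' @return an \code{"Ellipsoid"} (see [fitNeuriticField()] for the shape
#'   of the object).
#' @export
fitBoundingEllipsoid <- function(g, coverage = 0.95) {
  stopifnot(is(g, "NeuronGeometry"))
  X <- .coords(g)
  center <- colMeans(X)
  S <- stats::cov(X)
  e <- eigen(S, symmetric = TRUE)
  if (min(e$values) < 1e-10 * max(e$values, 1e-10)) {
    warning("degenerate node cloud; flooring semi-axes at 1 um")
    e$values <- pmax(e$values, 1e-10)
  }
  # Mahalanobis radius that encloses >= coverage of the nodes
  W <- sweep(X, 2, center) %*% e$vectors
  d2 <- rowSums(sweep(W, 2, sqrt(e$values), `/`)^2)
  r <- sqrt(stats::quantile(d2, coverage, type = 1, names = FALSE))
  axes <- pmax(sqrt(e$values) * r, 1)
  ord <- order(axes, decreasing = TRUE)
  structure(list(center = center, axes = axes[ord],
                 rotation = e$vectors[, ord, drop = FALSE],
                 sphere = FALSE),
            class = "Ellipsoid")
}

#' Sample carrier points in an ellipsoid
#'
#' Uniform points in an elliptical volume: rejection sampling from the
#' bounding cube of the unit ball, then the affine map of the ellipsoid.
#' Reproducible under the seed.
#'
#' @param volume an \code{"Ellipsoid"}.
#' @param n number of points (>= 1).
#' @param seed integer RNG seed.
#' @return n x 3 matrix of points (micrometres).
#' @export
sampleCarrierPoints <- function(volume, n, seed = 1) {
  stopifnot(n >= 1)
  set.seed(seed)
  pts <- matrix(NA_real_, n, 3)
  got <- 0L
  while (got < n) {
    m <- max(16L, 2L * (n - got))
    u <- matrix(stats::runif(3 * m, -1, 1), m, 3)
    keep <- rowSums(u^2) <= 1
    u <- u[keep, , drop = FALSE]
    take <- min(nrow(u), n - got)
    if (take > 0)
      pts[(got + 1):(got + take), ] <- u[seq_len(take), , drop = FALSE]
    got <- got + take
  }
  sweep(pts %*% diag(volume$axes) %*% t(volume$rotation), 2,
        volume$center, `+`)
}

#' Grow a minimal spanning neurite tree
#'
#' Greedy growth under the wiring-cost rule: starting from the root, the
#' unconnected carrier point p minimising, over tree nodes n,
#' \code{||p - n|| + bf * (PL(n) + ||p - n||)} is attached to its best
#' node, where PL(n) is n's path length to the root. The first term is
#' the wiring (cable) cost of the new edge, the second the resulting
#' root path length of p weighted by the balancing factor bf: bf = 0
#' gives pure nearest-point cable minimisation, larger bf favours direct,
#' straight root-to-tip paths at the expense of cable. Attachment is
#' allowed only at existing nodes (no mid-edge splitting). Ties are
#' broken by the lowest carrier point index, then the earliest-attached
#' node. Carrier points coincident with an existing node are merged with
#' a warning.
#'
#' @param root numeric 3-vector: the tree root (conventionally the first
#'   branch point of the reference neuron).
#' @param carrierPoints n x 3 matrix of target points.
#' @param bf balancing factor >= 0.
#' @param label name for the grown geometry.
#' @return list of class \code{"MSTResult"}: \code{geometry}
#'   (a [NeuronGeometry-class] rooted at the root node), \code{bf},
#'   \code{totalCable} (micrometres), \code{branchPoints},
#'   \code{pathLengths}, \code{tortuosities}, \code{branchOrders}
#'   (per-branch-point), \code{rootPathLength} (per node).
#' @export
growMST <- function(root, carrierPoints, bf, label = "mst") {
  P <- as.matrix(carrierPoints)
  stopifnot(length(root) == 3, ncol(P) == 3, nrow(P) >= 1, bf >= 0)
  n <- nrow(P)
  nodes <- matrix(NA_real_, n + 1L, 3)
  nodes[1L, ] <- root
  parent <- rep(NA_integer_, n + 1L)
  PL <- numeric(n + 1L)
  nNodesNow <- 1L
  unatt <- seq_len(n)
  # best attachment cost/node per unattached point, updated incrementally
  # (PL of attached nodes never changes, so cached bests stay exact)
  d0 <- sqrt(colSums((t(P) - root)^2))
  bestCost <- d0 + bf * d0
  bestNode <- rep(1L, n)
  bestLen <- d0
  merged <- 0L
  for (step in seq_len(n)) {
    pick <- unatt[which.min(bestCost[unatt])]   # lowest index wins ties
    bn <- bestNode[pick]
    if (bestLen[pick] == 0) {
      merged <- merged + 1L
      # coincident point: contributes no node; nothing to update
      unatt <- setdiff(unatt, pick)
      next
    }
    nNodesNow <- nNodesNow + 1L
    nodes[nNodesNow, ] <- P[pick, ]
    parent[nNodesNow] <- bn
    PL[nNodesNow] <- PL[bn] + bestLen[pick]
    unatt <- setdiff(unatt, pick)
    if (length(unatt)) {
      dNew <- sqrt(colSums((t(P[unatt, , drop = FALSE]) -
                              nodes[nNodesNow, ])^2))
      cNew <- dNew + bf * (PL[nNodesNow] + dNew)
      better <- cNew < bestCost[unatt]
      bestCost[unatt][better] <- cNew[better]
      bestNode[unatt][better] <- nNodesNow
      bestLen[unatt][better] <- dNew[better]
    }
  }
  if (merged > 0)
    warning("merged ", merged, " carrier point(s) coincident with ",
            "existing nodes")
  nodes <- nodes[seq_len(nNodesNow), , drop = FALSE]
  parent <- parent[seq_len(nNodesNow)]
  g <- NeuronGeometry(
    data.frame(id = seq_len(nNodesNow), x = nodes[, 1], y = nodes[, 2],
               z = nodes[, 3], parent = parent),
    label = label, cellType = "synthetic")
  paths <- suppressWarnings(somaPaths(g, excludeAxons = FALSE))
  bo <- branchOrders(g)
  structure(list(
    geometry = g,
    bf = bf,
    totalCable = totalWiring(g, excludeAxons = FALSE),
    branchPoints = nrow(bo),
    pathLengths = paths$pathLength,
    tortuosities = paths$tortuosity[is.finite(paths$tortuosity)],
    branchOrders = bo$order,
    rootPathLength = .pathDistances(g)   # aligned with nodeTable order
  ), class = "MSTResult")
}

#' @export
print.MSTResult <- function(x, ...) {
  cat("MSTResult (bf = ", x$bf, "): ", nNodes(x$geometry), " nodes, ",
      x$branchPoints, " branch points, cable ",
      signif(x$totalCable, 6), " um\n", sep = "")
  invisible(x)
}

# root of a reference neuron for MST growth: coordinates of the first
# branch point relative to the soma (the branch point with the smallest
# somatofugal path distance); soma coordinates if no branch point exists
.mstRoot <- function(g) {
  bpr <- .branchPointRows(g)
  xyz <- .coords(g)
  if (!length(bpr)) return(xyz[1L, ])
  pd <- .pathDistances(g)
  xyz[bpr[which.min(pd[bpr])], ]
}

#' Tune the carrier-point count
#'
#' Monotone (bracketing + bisection) search over the number of carrier
#' points until a tree grown at \code{bfTune} has a branch point count
#' within \code{tolerance} of the reference neuron's. The returned count
#' is then reused across a whole bf sweep. Carriers are resampled from
#' the reference's bounding ellipsoid at every evaluation under the same
#' seed.
#'
#' @param g the reference [NeuronGeometry-class] (>= 1 branch point).
#' @param bfTune balancing factor used during tuning (default 0).
#' @param tolerance relative branch-point tolerance (default 0.20).
#' @param seed integer RNG seed for carrier sampling.
#' @param coverage bounding-ellipsoid coverage (default 0.95).
#' @param maxSteps search budget (default 30); exhausted -> error naming
#'   the best count found.
#' @return integer carrier count; attributes \code{"branchPoints"} (the
#'   achieved count) and \code{"reference"} (the target).
#' @export
tuneCarrierPoints <- function(g, bfTune = 0, tolerance = 0.20, seed = 1,
                              coverage = 0.95, maxSteps = 30) {
  refBp <- length(.branchPointRows(g))
  if (refBp < 1L) stop("reference neuron has no branch points")
  vol <- fitBoundingEllipsoid(g, coverage)
  evalBp <- function(nc) {
    pts <- sampleCarrierPoints(vol, nc, seed)
    suppressWarnings(growMST(.mstRoot(g), pts, bfTune))$branchPoints
  }
  ok <- function(bp) abs(bp - refBp) / refBp <= tolerance
  steps <- 0L
  n <- max(2L, 2L * refBp)
  bp <- evalBp(n); steps <- steps + 1L
  best <- c(n = n, bp = bp)
  if (ok(bp)) return(structure(n, branchPoints = bp, reference = refBp))
  lo <- hi <- n; bpLo <- bpHi <- bp
  while (bpHi < refBp && steps < maxSteps) {
    lo <- hi; bpLo <- bpHi
    hi <- hi * 2L; bpHi <- evalBp(hi); steps <- steps + 1L
    if (abs(bpHi - refBp) < abs(best["bp"] - refBp))
      best <- c(n = hi, bp = bpHi)
    if (ok(bpHi)) return(structure(hi, branchPoints = bpHi,
                                   reference = refBp))
  }
  while (bpLo > refBp && steps < maxSteps) {
    hi <- lo; bpHi <- bpLo
    lo <- max(2L, lo %/% 2L); bpLo <- evalBp(lo); steps <- steps + 1L
    if (abs(bpLo - refBp) < abs(best["bp"] - refBp))
      best <- c(n = lo, bp = bpLo)
    if (ok(bpLo)) return(structure(lo, branchPoints = bpLo,
                                   reference = refBp))
  }
  while (steps < maxSteps && hi - lo > 1L) {
    mid <- (lo + hi) %/% 2L
    bpMid <- evalBp(mid); steps <- steps + 1L
    if (abs(bpMid - refBp) < abs(best["bp"] - refBp))
      best <- c(n = mid, bp = bpMid)
    if (ok(bpMid)) return(structure(mid, branchPoints = bpMid,
                                    reference = refBp))
    if (bpMid < refBp) { lo <- mid } else { hi <- mid }
  }
  stop("carrier tuning did not converge in ", maxSteps,
       " steps; best count ", best["n"], " gave ", best["bp"],
       " branch points (target ", refBp, ")")
}

#' Balancing-factor sweep
#'
#' Grows one minimal spanning tree per balancing factor on a single
#' shared carrier-point set (sampled once from the reference's bounding
#' ellipsoid), so trees differ only in bf.
#'
#' @param g the reference [NeuronGeometry-class].
#' @param bfValues balancing factors (default \code{seq(0, 0.6, 0.1)}).
#' @param seed integer RNG seed for carrier sampling (and tuning).
#' @param carrierCount carrier points to use; tuned with
#'   [tuneCarrierPoints()] when NULL.
#' @param coverage bounding-ellipsoid coverage.
#' @return list of \code{"MSTResult"}, one per bf, with attributes
#'   \code{"carrierCount"} and \code{"seed"}.
#' @export
bfSweep <- function(g, bfValues = seq(0, 0.6, 0.1), seed = 1,
                    carrierCount = NULL, coverage = 0.95) {
  if (is.null(carrierCount))
    carrierCount <- tuneCarrierPoints(g, seed = seed, coverage = coverage)
  vol <- fitBoundingEllipsoid(g, coverage)
  pts <- sampleCarrierPoints(vol, as.integer(carrierCount), seed)
  root <- .mstRoot(g)
  out <- lapply(bfValues, function(bf)
    suppressWarnings(growMST(root, pts, bf,
                             label = sprintf("%s_mst_bf%.1f", g@label, bf))))
  attr(out, "carrierCount") <- as.integer(carrierCount)
  attr(out, "seed") <- seed
  out
}

# max-normalised histogram over fixed breaks
.normHist <- function(v, breaks) {
  h <- graphics::hist(v[is.finite(v)], breaks = breaks, plot = FALSE)$counts
  if (max(h) > 0) h / max(h) else h
}

#' Compare morphometric distributions of reference and synthetic trees
#'
#' For each metric (branch order, root-to-tip neurite length, tortuosity)
#' the reference and each synthetic tree are histogrammed on 50 shared
#' equal-width bins spanning the union range, each histogram is
#' normalised to its own maximum (so trees with different path counts are
#' comparable), and the divergence is the sum of absolute bin
#' differences. Total wiring and branch point counts are compared
#' directly, flagging synthetic trees within 20 percent of the reference
#' wiring.
#'
#' @param g the reference [NeuronGeometry-class] (axons excluded from its
#'   metrics).
#' @param sweep list of \code{"MSTResult"} from [bfSweep()].
#' @param nBins histogram bins (default 50).
#' @return data.frame with one row per bf: \code{bf}, \code{totalCable},
#'   \code{refWiring}, \code{cableWithin20}, \code{branchPoints},
#'   \code{refBranchPoints}, \code{divBranchOrder},
#'   \code{divNeuriteLength}, \code{divTortuosity}.
#' @export
compareDistributions <- function(g, sweep, nBins = 50) {
  refPaths <- suppressWarnings(somaPaths(g, excludeAxons = TRUE))
  refMetrics <- list(
    branchOrder = branchOrders(g)$order,
    neuriteLength = refPaths$pathLength,
    tortuosity = refPaths$tortuosity[is.finite(refPaths$tortuosity)])
  refWiring <- totalWiring(g, excludeAxons = TRUE)
  refBp <- length(.branchPointRows(g))
  rows <- lapply(sweep, function(m) {
    mstMetrics <- list(branchOrder = m$branchOrders,
                       neuriteLength = m$pathLengths,
                       tortuosity = m$tortuosities)
    div <- vapply(names(refMetrics), function(k) {
      a <- refMetrics[[k]]; b <- mstMetrics[[k]]
      rng <- range(c(a, b), finite = TRUE)
      if (diff(rng) == 0) rng <- rng + c(-0.5, 0.5)
      breaks <- seq(rng[1], rng[2], length.out = nBins + 1L)
      sum(abs(.normHist(a, breaks) - .normHist(b, breaks)))
    }, numeric(1))
    data.frame(bf = m$bf, totalCable = m$totalCable,
               refWiring = refWiring,
               cableWithin20 =
                 abs(m$totalCable - refWiring) / refWiring <= 0.20,
               branchPoints = m$branchPoints, refBranchPoints = refBp,
               divBranchOrder = div[["branchOrder"]],
               divNeuriteLength = div[["neuriteLength"]],
               divTortuosity = div[["tortuosity"]])
  })
  do.call(rbind, rows)
}
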