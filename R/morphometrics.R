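# Per-neuron morphometric battery: soma-to-tip paths, tortuosity, wiring,
# furcations, branch order, branch angles, symmetry index, Rall power,
# diameters by order, hair-like neurites and the one-row summary.

#' Enumerate soma-to-tip paths
#'
#' One record per terminating tip (axon leaves excluded): the full
#' somatofugal traversal with its path length (sum of consecutive
#' inter-node distances), straight-line soma-to-tip distance, tortuosity
#' and branch order at the tip.
#'
#' @param g a [NeuronGeometry-class]
#' @param excludeAxons drop paths ending at tagged axon tips (default
#'   TRUE; path statistics conventionally exclude axons).
#' @return data.frame with columns \code{tipId}, \code{pathLength},
#'   \code{euclidean}, \code{tortuosity} (\code{NA} when the tip
#'   coincides with the soma), \code{branchOrder} (number of branch
#'   points strictly between soma and tip) and list column \code{nodeIds}
#'   (soma first).
#' @export
somaPaths <- function(g, excludeAxons = TRUE) {
  stopifnot(is(g, "NeuronGeometry"))
  nd <- g@nodes
  pd <- .pathDistances(g)
  xyz <- .coords(g)
  bp <- logical(nNodes(g)); bp[.branchPointRows(g)] <- TRUE
  leafRows <- .leafRows(g)
  tipRows <- leafRows[!nd$id[leafRows] %in%
                        c(g@somaId, if (excludeAxons) g@axonTips)]
  if (!length(tipRows)) {
    warning("geometry has no terminating tips")
    return(data.frame(tipId = integer(), pathLength = numeric(),
                      euclidean = numeric(), tortuosity = numeric(),
                      branchOrder = integer()))
  }
  recs <- lapply(tipRows, function(r) {
    rows <- .pathRows(g, r)
    eu <- sqrt(sum((xyz[r, ] - xyz[1L, ])^2))
    list(tipId = nd$id[r], pathLength = pd[r], euclidean = eu,
         tortuosity = if (eu > 0) pd[r] / eu else NA_real_,
         branchOrder = sum(bp[rows]) - as.integer(bp[r]),
         nodeIds = nd$id[rows])
  })
  out <- data.frame(
    tipId = vapply(recs, `[[`, integer(1), "tipId"),
    pathLength = vapply(recs, `[[`, numeric(1), "pathLength"),
    euclidean = vapply(recs, `[[`, numeric(1), "euclidean"),
    tortuosity = vapply(recs, `[[`, numeric(1), "tortuosity"),
    branchOrder = vapply(recs, `[[`, integer(1), "branchOrder")
  )
  out$nodeIds <- lapply(recs, `[[`, "nodeIds")
  out
}

#' Tortuosity of a polyline path
#'
#' Path length divided by the Euclidean distance between the first and
#' last point. 1.0 indicates a perfectly straight path; larger values a
#' wandering one. A path returning to its origin (zero Euclidean
#' distance) is undefined and yields \code{NA} with a warning; such paths
#' are excluded from distributions.
#'
#' @param coords numeric matrix (n x 2 or n x 3) of ordered path points,
#'   soma first, in micrometres; at least two rows.
#' @return dimensionless tortuosity >= 1 (up to floating tolerance).
#' @examples
#' pathTortuosity(rbind(c(0, 0), c(1, 0), c(1, 1)))  # sqrt(2)
#' @export
pathTortuosity <- function(coords) {
  coords <- as.matrix(coords)
  stopifnot(nrow(coords) >= 2L)
  steps <- sqrt(rowSums((coords[-1L, , drop = FALSE] -
                           coords[-nrow(coords), , drop = FALSE])^2))
  eu <- sqrt(sum((coords[nrow(coords), ] - coords[1L, ])^2))
  if (eu == 0) {
    warning("path ends at its origin; tortuosity undefined")
    return(NA_real_)
  }
  sum(steps) / eu
}

#' Total wiring length
#'
#' Sum of all segment lengths in micrometres, omitting axon terminal
#' filaments by default (total wiring in the source preparations is
#' always reported excluding axons).
#'
#' @param g a [NeuronGeometry-class]
#' @param excludeAxons omit tagged axon filaments (default TRUE).
#' @return length in micrometres
#' @export
totalWiring <- function(g, excludeAxons = TRUE) {
  stopifnot(is(g, "NeuronGeometry"))
  el <- .edgeLengths(g)
  drop <- if (excludeAxons) .axonNodeRows(g) else integer()
  sum(el[setdiff(seq_len(nNodes(g))[-1L], drop)])
}

#' Furcation profile
#'
#' Daughter counts at every branch point (a non-soma node with two or
#' more children; primary filaments leaving the soma are not furcations)
#' and the per-neuron proportions of bi-, tri- and multi-furcations
#' (>= 4 daughters).
#'
#' @param g a [NeuronGeometry-class]
#' @return list with \code{counts} (data.frame \code{nodeId},
#'   \code{daughters}) and \code{proportions} (named numeric: \code{bi},
#'   \code{tri}, \code{multi}).
#' @export
furcationProfile <- function(g) {
  stopifnot(is(g, "NeuronGeometry"))
  nk <- .nChildren(g)
  bpr <- .branchPointRows(g)
  counts <- data.frame(nodeId = g@nodes$id[bpr], daughters = nk[bpr])
  d <- counts$daughters
  n <- max(1L, nrow(counts))
  list(counts = counts,
       proportions = c(bi = sum(d == 2L) / n,
                       tri = sum(d == 3L) / n,
                       multi = sum(d >= 4L) / n))
}

#' Branch orders
#'
#' Order of each branch point relative to the first branch point from the
#' soma: the first branch point on a lineage has order 0 and each deeper
#' branch point's order is the number of branch points strictly between
#' the soma and it along the unique path.
#'
#' @param g a [NeuronGeometry-class]
#' @return data.frame \code{nodeId}, \code{order}
#' @export
branchOrders <- function(g) {
  stopifnot(is(g, "NeuronGeometry"))
  pr <- .parentRow(g)
  bpr <- .branchPointRows(g)
  isBp <- logical(nNodes(g)); isBp[bpr] <- TRUE
  # count of branch points strictly above each node, one topological pass
  above <- integer(nNodes(g))
  for (i in seq_len(nNodes(g))[-1L])
    above[i] <- above[pr[i]] + as.integer(isBp[pr[i]])
  data.frame(nodeId = g@nodes$id[bpr], order = above[bpr])
}

#' Branch angle from three points
#'
#' The angle at a branch point between a daughter segment and the
#' hypothetical continuation of the parent segment. With \code{pMid} the
#' branch point, \code{p1} the far endpoint of the parent segment and
#' \code{p2} the distal endpoint of the daughter segment, the interior
#' angle theta at \code{pMid} of the triangle (p1, pMid, p2) comes from
#' the law of cosines and the reported branch angle is 180 - theta
#' degrees, in [0, 180]: a straight continuation scores 0, a right-angle
#' daughter 90.
#'
#' @param pMid,p1,p2 numeric 3-vectors (micrometres); must be pairwise
#'   distinct.
#' @return angle in degrees, or \code{NA} with a warning for a degenerate
#'   (zero-side) triangle.
#' @export
branchAngle <- function(pMid, p1, p2) {
  a <- sqrt(sum((p1 - pMid)^2))
  b <- sqrt(sum((p2 - pMid)^2))
  if (a == 0 || b == 0) {
    warning("degenerate branch-angle triangle (zero-length side)")
    return(NA_real_)
  }
  cc <- sum((p1 - pMid) * (p2 - pMid)) / (a * b)
  theta <- acos(max(-1, min(1, cc))) * 180 / pi
  180 - theta
}

#' Branch angles of a geometry
#'
#' One angle per (parent, daughter) segment pair at every branch point,
#' using the stored far endpoints of the tracer-defined segments adjacent
#' to the branch point. At multi-furcations the computation is repeated
#' for every daughter against the parent; daughter-daughter angles are
#' not reported. Degenerate zero-length segments are skipped.
#'
#' @param g a [NeuronGeometry-class]
#' @return data.frame \code{nodeId}, \code{daughterSeg}, \code{angle}
#'   (degrees)
#' @export
branchAngles <- function(g) {
  stopifnot(is(g, "NeuronGeometry"))
  segs <- neuronSegments(g)
  xyz <- .coords(g)
  idRow <- function(id) match(id, g@nodes$id)
  res <- list()
  for (i in seq_len(nrow(segs))) {
    parentSeg <- segs$parentSeg[i]
    if (is.na(parentSeg)) next               # departs the soma: no parent
    bpId <- segs$fromId[i]
    pMid <- xyz[idRow(bpId), ]
    p1 <- xyz[idRow(segs$fromId[parentSeg]), ]   # parent's far endpoint
    p2 <- xyz[idRow(segs$toId[i]), ]             # daughter's distal endpoint
    if (all(p1 == pMid) || all(p2 == pMid)) next
    ang <- suppressWarnings(branchAngle(pMid, p1, p2))
    if (is.na(ang)) next
    res[[length(res) + 1L]] <- data.frame(nodeId = bpId,
                                          daughterSeg = segs$segId[i],
                                          angle = ang)
  }
  if (!length(res))
    return(data.frame(nodeId = integer(), daughterSeg = integer(),
                      angle = numeric()))
  do.call(rbind, res)
}

#' Symmetry index of a bifurcation
#'
#' Ratio of the smaller to the larger summed downstream neurite length of
#' the two daughter branches: \code{min(d1, d2) / max(d1, d2)}. 1
#' indicates a perfectly symmetrical bifurcation; values near 0 a highly
#' asymmetrical one. Scale-invariant.
#'
#' @param d1,d2 summed downstream segment lengths (micrometres) of the
#'   two daughters; non-negative, not both zero.
#' @return value in [0, 1]; 0 (flagged with a warning) when one daughter
#'   has zero downstream length.
#' @export
symmetryIndex <- function(d1, d2) {
  stopifnot(d1 >= 0, d2 >= 0, d1 + d2 > 0)
  if (min(d1, d2) == 0) warning("daughter with zero downstream length")
  min(d1, d2) / max(d1, d2)
}

#' Symmetry indices of a geometry
#'
#' Symmetry index at every bifurcating branch point (multi-furcations are
#' excluded from SI distributions), where each daughter's weight is the
#' sum of the lengths of all its downstream segments.
#'
#' @param g a [NeuronGeometry-class]
#' @return data.frame \code{nodeId}, \code{d1}, \code{d2}, \code{si}
#' @export
symmetryIndices <- function(g) {
  stopifnot(is(g, "NeuronGeometry"))
  el <- .edgeLengths(g)
  kids <- .childrenList(g)
  # summed cable strictly below each node, one reverse topological pass
  below <- numeric(nNodes(g))
  for (i in rev(seq_len(nNodes(g)))) {
    ch <- kids[[i]]
    if (length(ch)) below[i] <- sum(below[ch] + el[ch])
  }
  bpr <- .branchPointRows(g)
  bif <- bpr[lengths(kids[bpr]) == 2L]
  if (!length(bif))
    return(data.frame(nodeId = integer(), d1 = numeric(), d2 = numeric(),
                      si = numeric()))
  d <- t(vapply(bif, function(r) {
    ch <- kids[[r]]
    sort(below[ch] + el[ch], decreasing = TRUE)
  }, numeric(2)))
  data.frame(nodeId = g@nodes$id[bif], d1 = d[, 1], d2 = d[, 2],
             si = ifelse(d[, 1] > 0, d[, 2] / d[, 1], NA_real_))
}

#' Rall power at a branch point
#'
#' The exponent X solving \code{parent^X = sum(daughters^X)} for the
#' parent and daughter radii of a branch point, found numerically by
#' minimising the residual of \code{parent^X = sum(daughters^X)} over a
#' wide clamped interval. X = 3/2 is the impedance-matching optimum for
#' current transfer. For numerical stability across the interval's
#' enormous dynamic range the residual is minimised on the log scale,
#' \code{|X log(parent) - log(sum(daughters^X))|}, which has the same
#' roots. When the residual has an interior sign change the root is
#' located to \code{tol}; otherwise the interior residual minimum is
#' refined from a coarse scan, or the endpoint with the smaller residual
#' is returned with \code{clamped = TRUE} (observed values cluster near
#' the bounds when daughters out- or under-size the parent for every
#' exponent).
#'
#' @param parentRadius parent radius, micrometres (> 0).
#' @param daughterRadii numeric vector (>= 2 entries) of daughter radii,
#'   micrometres (> 0).
#' @param lower,upper solver interval for X (defaults 1e-3, 20).
#' @param tol residual tolerance (default 1e-6).
#' @return list with \code{exponent}, \code{converged} (log-scale
#'   residual below \code{tol}), \code{clamped} (minimiser at an
#'   interval bound) and \code{residual} (log scale).
#' @examples
#' rallPower(2, c(1, 1))$exponent           # 1
#' rallPower(2^(2 / 3), c(1, 1))$exponent   # 3/2
#' @export
rallPower <- function(parentRadius, daughterRadii, lower = 1e-3,
                      upper = 20, tol = 1e-6) {
  if (parentRadius <= 0 || any(daughterRadii <= 0))
    stop("all radii must be positive")
  if (length(daughterRadii) < 2L)
    stop("need at least two daughter radii")
  h <- function(x) x * log(parentRadius) - log(sum(daughterRadii^x))
  hl <- h(lower); hu <- h(upper)
  if (is.finite(hl) && is.finite(hu) && sign(hl) * sign(hu) < 0) {
    root <- stats::uniroot(h, c(lower, upper), tol = tol / 10)$root
    res <- abs(h(root))
    return(list(exponent = root, converged = res < tol, clamped = FALSE,
                residual = res))
  }
  # no endpoint sign change: scan a coarse grid for either a hidden
  # root pair or an interior residual minimum, then refine
  grid <- seq(lower, upper, length.out = 512L)
  hg <- vapply(grid, h, numeric(1))
  sw <- which(diff(sign(hg)) != 0)
  if (length(sw)) {
    root <- stats::uniroot(h, grid[c(sw[1L], sw[1L] + 1L)],
                           tol = tol / 10)$root
    res <- abs(h(root))
    return(list(exponent = root, converged = res < tol, clamped = FALSE,
                residual = res))
  }
  i <- which.min(abs(hg))
  if (i > 1L && i < length(grid)) {
    opt <- stats::optimize(function(x) abs(h(x)),
                           c(grid[i - 1L], grid[i + 1L]), tol = tol / 10)
    if (opt$objective <= min(abs(hl), abs(hu)))
      return(list(exponent = opt$minimum,
                  converged = opt$objective < tol, clamped = FALSE,
                  residual = opt$objective))
  }
  pick <- if (abs(hl) <= abs(hu)) lower else upper
  list(exponent = pick, converged = abs(h(pick)) < tol, clamped = TRUE,
       residual = abs(h(pick)))
}

#' Rall powers across a geometry
#'
#' Rall power at every bifurcating branch point with radii on all three
#' participating nodes: the branch-point node's radius stands for the
#' parent and the first node of each daughter segment for the daughters
#' (the skeleton-annotation convention; radii measured from images are
#' outside this package's scope).
#'
#' @param g a [NeuronGeometry-class] with radii.
#' @param ... passed to [rallPower()].
#' @return data.frame \code{nodeId}, \code{exponent}, \code{converged},
#'   \code{clamped}
#' @export
rallPowers <- function(g, ...) {
  stopifnot(is(g, "NeuronGeometry"))
  if (all(is.na(g@nodes$radius)))
    stop("geometry has no radii; Rall power needs radius-annotated input")
  kids <- .childrenList(g)
  bpr <- .branchPointRows(g)
  rad <- g@nodes$radius
  res <- list()
  for (r in bpr) {
    ch <- kids[[r]]
    if (length(ch) != 2L) next
    pr <- rad[r]; dr <- rad[ch]
    if (is.na(pr) || anyNA(dr)) next
    rp <- rallPower(pr, dr, ...)
    res[[length(res) + 1L]] <- data.frame(
      nodeId = g@nodes$id[r], exponent = rp$exponent,
      converged = rp$converged, clamped = rp$clamped)
  }
  if (!length(res))
    return(data.frame(nodeId = integer(), exponent = numeric(),
                      converged = logical(), clamped = logical()))
  do.call(rbind, res)
}

#' Detect hair-like neurites
#'
#' Very thin neurites: maximal runs of connected cable whose diameter
#' (2 x radius) stays below \code{maxDiameter} along their full extent
#' and whose length, measured from the attachment point on the thicker
#' parent structure, exceeds \code{minLength}. Defaults follow the
#' field's definition of hair-like structures (< 1 micrometre diameter,
#' > 50 micrometres long).
#'
#' @param g a [NeuronGeometry-class]; radii must be present.
#' @param maxDiameter micrometres, default 1.
#' @param minLength micrometres, default 50.
#' @return data.frame with one row per flagged run: \code{rootId} (most
#'   proximal thin node), \code{length}, \code{nNodes}.
#' @export
detectHairlike <- function(g, maxDiameter = 1, minLength = 50) {
  stopifnot(is(g, "NeuronGeometry"))
  rad <- g@nodes$radius
  if (all(is.na(rad)))
    stop("geometry has no radii; hair-like detection needs ",
         "radius-annotated input")
  thin <- !is.na(rad) & 2 * rad < maxDiameter
  pr <- .parentRow(g)
  el <- .edgeLengths(g)
  # connected components of the thin-node induced forest
  comp <- integer(nNodes(g))
  nComp <- 0L
  for (i in seq_len(nNodes(g))) {
    if (!thin[i]) next
    p <- pr[i]
    if (!is.na(p) && thin[p]) comp[i] <- comp[p]
    else { nComp <- nComp + 1L; comp[i] <- nComp }
  }
  if (!nComp) return(data.frame(rootId = integer(), length = numeric(),
                                nNodes = integer()))
  res <- lapply(seq_len(nComp), function(k) {
    rows <- which(comp == k)
    # cable of every edge ending at a member, including the attachment
    # edge from the thicker parent structure
    inEdge <- rows[!is.na(pr[rows])]
    data.frame(rootId = g@nodes$id[rows[1L]],
               length = sum(el[inEdge]), nNodes = length(rows))
  })
  out <- do.call(rbind, res)
  out[out$length > minLength, , drop = FALSE]
}

#' Diameters by neurite order
#'
#' Per-class diameter samples for primary (the main path extending from
#' the soma to the axon), secondary (segments branching directly off the
#' primary), tertiary (branching off a secondary) and terminating-tip
#' segments. Each segment contributes the mean diameter (2 x radius) of
#' its non-junction nodes.
#'
#' @param g a [NeuronGeometry-class] with radii; axons should be tagged
#'   so the primary path is defined (otherwise the longest soma-to-tip
#'   path stands in, with a warning).
#' @return list with \code{samples} (data.frame \code{class} in
#'   \code{c("1","2","3","tip")}, \code{segId}, \code{diameter}) and
#'   \code{stats} (per-class mean, SD, CV, n).
#' @export
diameterByOrder <- function(g) {
  stopifnot(is(g, "NeuronGeometry"))
  if (all(is.na(g@nodes$radius)))
    stop("geometry has no radii; diameter analysis needs ",
         "radius-annotated input")
  segs <- neuronSegments(g)
  mpSegs <- tryCatch(mainPath(g)$segIds, error = function(e) NULL)
  if (is.null(mpSegs)) {
    warning("no tagged axon; using the longest soma-to-tip path as primary")
    paths <- somaPaths(g, excludeAxons = FALSE)
    tip <- paths$tipId[which.max(paths$pathLength)]
    rows <- match(paths$nodeIds[[which.max(paths$pathLength)]], g@nodes$id)
    mpSegs <- segs$segId[vapply(segs$rows, function(r)
      all(r %in% rows), logical(1))]
  }
  cls <- rep(NA_character_, nrow(segs))
  cls[segs$segId %in% mpSegs] <- "1"
  parentCls <- cls[match(segs$parentSeg, segs$segId)]
  cls[is.na(cls) & !is.na(parentCls) & parentCls == "1"] <- "2"
  parentCls <- cls[match(segs$parentSeg, segs$segId)]
  cls[is.na(cls) & !is.na(parentCls) & parentCls == "2"] <- "3"
  cls[segs$terminal & !segs$axon] <- "tip"
  cls[segs$axon] <- NA_character_
  rad <- g@nodes$radius
  diam <- vapply(seq_len(nrow(segs)), function(i) {
    rr <- segs$rows[[i]][-1L]           # exclude the proximal junction
    mean(2 * rad[rr], na.rm = TRUE)
  }, numeric(1))
  keep <- !is.na(cls) & is.finite(diam)
  samples <- data.frame(class = cls[keep], segId = segs$segId[keep],
                        diameter = diam[keep])
  stats <- do.call(rbind, lapply(c("1", "2", "3", "tip"), function(k) {
    v <- samples$diameter[samples$class == k]
    data.frame(class = k, n = length(v),
               mean = if (length(v)) mean(v) else NA_real_,
               sd = if (length(v) > 1) stats::sd(v) else NA_real_,
               cv = if (length(v) > 1 && mean(v) > 0)
                 stats::sd(v) / mean(v) else NA_real_)
  }))
  list(samples = samples, stats = stats)
}

#' One-row morphometric summary
#'
#' The per-neuron anatomical summary: soma-to-tip path count, branch
#' point count, subtree count (when axons are tagged), total wiring
#' excluding axons, tortuosity and soma-to-tip length means with SDs,
#' and neurite diameters by order when radii are available. Writable as
#' one CSV row.
#'
#' @param g a [NeuronGeometry-class]
#' @return one-row data.frame
#' @export
neuronSummary <- function(g) {
  stopifnot(is(g, "NeuronGeometry"))
  paths <- suppressWarnings(somaPaths(g))
  fp <- furcationProfile(g)
  nSub <- if (length(g@axonTips))
    nrow(subtreeTable(g)) else NA_integer_
  tort <- paths$tortuosity[is.finite(paths$tortuosity)]
  dio <- if (any(!is.na(g@nodes$radius)))
    suppressWarnings(diameterByOrder(g)$stats) else NULL
  pick <- function(k, col) {
    if (is.null(dio)) return(NA_real_)
    v <- dio[[col]][dio$class == k]
    if (length(v)) v else NA_real_
  }
  data.frame(
    label = g@label,
    cellType = g@cellType,
    somaToTipPaths = nrow(paths),
    branchPoints = nrow(fp$counts),
    subtrees = nSub,
    totalWiring = totalWiring(g, excludeAxons = TRUE),
    tortuosityMean = if (length(tort)) mean(tort) else NA_real_,
    tortuositySD = if (length(tort) > 1) stats::sd(tort) else NA_real_,
    pathLengthMean = if (nrow(paths)) mean(paths$pathLength) else NA_real_,
    pathLengthSD = if (nrow(paths) > 1) stats::sd(paths$pathLength)
                   else NA_real_,
    diam1 = pick("1", "mean"),
    diam2Mean = pick("2", "mean"), diam2SD = pick("2", "sd"),
    diam3Mean = pick("3", "mean"), diam3SD = pick("3", "sd"),
    diamTipMean = pick("tip", "mean"), diamTipSD = pick("tip", "sd")
  )
}
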