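# Low-level tree helpers shared by every analysis. All work on row indices
# into the topologically sorted node table; ids are arbitrary labels.

.coords <- function(g) as.matrix(g@nodes[, c("x", "y", "z")])

.parentRow <- function(g) match(g@nodes$parent, g@nodes$id)

.childrenList <- function(g) {
  n <- nNodes(g)
  pr <- .parentRow(g)
  unname(split(seq_len(n), factor(pr, levels = seq_len(n))))
}

# Euclidean length of the edge above each node (NA for root)
.edgeLengths <- function(g) {
  xyz <- .coords(g)
  pr <- .parentRow(g)
  d <- rep(NA_real_, nNodes(g))
  ok <- !is.na(pr)
  d[ok] <- sqrt(rowSums((xyz[ok, , drop = FALSE] -
                           xyz[pr[ok], , drop = FALSE])^2))
  d
}

# cumulative path length from the soma, per node (somatofugal distance)
.pathDistances <- function(g) {
  pr <- .parentRow(g)
  el <- .edgeLengths(g)
  d <- numeric(nNodes(g))
  for (i in seq_len(nNodes(g))[-1L]) d[i] <- d[pr[i]] + el[i]
  d
}

.leafRows <- function(g) {
  which(!g@nodes$id %in% g@nodes$parent)
}

# branch point = non-root node with >= 2 children
.branchPointRows <- function(g) {
  pr <- .parentRow(g)
  tab <- tabulate(pr[!is.na(pr)], nbins = nNodes(g))
  setdiff(which(tab >= 2L), 1L)
}

.nChildren <- function(g) {
  pr <- .parentRow(g)
  tabulate(pr[!is.na(pr)], nbins = nNodes(g))
}

# rows along the unique path root -> row (inclusive, root first)
.pathRows <- function(g, row) {
  pr <- .parentRow(g)
  out <- integer()
  while (!is.na(row)) { out <- c(row, out); row <- pr[row] }
  out
}

#' Segment decomposition of a skeleton
#'
#' Splits the tree into segments: maximal unbranched chains whose interior
#' nodes have exactly one child, so topological events (the root, branch
#' points, leaves) occur only at segment ends. Each segment runs from a
#' junction node (its proximal end, shared with the parent structure) to
#' the next junction or leaf.
#'
#' @param g a [NeuronGeometry-class]
#' @return data.frame with one row per segment: \code{segId},
#'   \code{fromId}/\code{toId} (proximal/distal node ids), \code{length}
#'   (micrometres, sum of consecutive inter-node distances), \code{nNodes},
#'   \code{parentSeg} (segment id whose distal node is this segment's
#'   proximal node; \code{NA} for root-attached segments), \code{terminal}
#'   (ends at a leaf) and \code{axon} (terminal filament of a tagged axon
#'   tip). The node rows of each segment are in the list column
#'   \code{rows} (proximal junction first).
#' @export
neuronSegments <- function(g) {
  stopifnot(is(g, "NeuronGeometry"))
  kids <- .childrenList(g)
  el <- .edgeLengths(g)
  nKids <- lengths(kids)
  junctions <- sort(unique(c(1L, .branchPointRows(g))))
  segRows <- list(); segFrom <- integer(); segTo <- integer()
  segLen <- numeric(); fromJunction <- integer()
  for (j in junctions) {
    for (c0 in kids[[j]]) {
      rows <- c(j, c0)
      len <- el[c0]
      cur <- c0
      while (nKids[cur] == 1L) {
        cur <- kids[[cur]][1L]
        rows <- c(rows, cur)
        len <- len + el[cur]
      }
      segRows[[length(segRows) + 1L]] <- rows
      segFrom <- c(segFrom, j); segTo <- c(segTo, cur)
      segLen <- c(segLen, len); fromJunction <- c(fromJunction, j)
    }
  }
  ids <- seq_along(segRows)
  parentSeg <- ids[match(fromJunction, segTo)]
  leafRows <- .leafRows(g)
  terminal <- segTo %in% leafRows
  axon <- g@nodes$id[segTo] %in% g@axonTips
  out <- data.frame(
    segId = ids,
    fromId = g@nodes$id[segFrom],
    toId = g@nodes$id[segTo],
    length = segLen,
    nNodes = lengths(segRows),
    parentSeg = parentSeg,
    terminal = terminal,
    axon = axon
  )
  out$rows <- segRows
  out
}

# rows of nodes belonging to axon terminal filaments (junction excluded)
.axonNodeRows <- function(g) {
  if (!length(g@axonTips)) return(integer())
  segs <- neuronSegments(g)
  unlist(lapply(segs$rows[segs$axon], function(r) r[-1L]), use.names = FALSE)
}

#' Terminating tip ids
#'
#' Leaves of the skeleton that are neither the soma nor tagged axon
#' terminals.
#'
#' @param g a [NeuronGeometry-class]
#' @return integer node ids
#' @export
terminatingTips <- function(g) {
  stopifnot(is(g, "NeuronGeometry"))
  setdiff(g@nodes$id[.leafRows(g)], c(g@somaId, g@axonTips))
}

# re-root the node table at the given id by reversing parent links along
# the old-root -> new-root path
.rerootAt <- function(nodes, newRootId) {
  path <- integer()
  cur <- newRootId
  repeat {
    path <- c(path, cur)
    p <- nodes$parent[match(cur, nodes$id)]
    if (is.na(p)) break
    cur <- p
  }
  # path[1] = new root ... path[n] = old root; parents now point toward
  # the new root
  for (k in seq_along(path)) {
    r <- match(path[k], nodes$id)
    nodes$parent[r] <- if (k == 1L) NA_integer_ else path[k - 1L]
  }
  nodes
}
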