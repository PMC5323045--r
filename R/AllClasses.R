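#' @import methods
NULL

#' NeuronGeometry: a rooted 3D skeletal reconstruction
#'
#' The universal substrate of every analysis in the package: a rooted,
#' acyclic tree of 3D nodes in micrometres with optional per-node radii,
#' a tagged soma (the root) and zero or more tagged axon terminal
#' filaments. Unipolar neurons (soma offset from the arborising neuropil,
#' connected through a primary neurite) are the intended use case, but any
#' single-rooted skeleton is accepted.
#'
#' @slot nodes data.frame with columns \code{id} (integer label, arbitrary),
#'   \code{type} (\code{"soma"}, \code{"axon"} or \code{"neurite"}),
#'   \code{x}, \code{y}, \code{z} (numeric, micrometres), \code{radius}
#'   (numeric, micrometres, \code{NA} when unmeasured) and \code{parent}
#'   (integer id, \code{NA} for the root). Rows are stored in topological
#'   order (every parent precedes its children).
#' @slot somaId integer id of the soma node; always the root.
#' @slot axonTips integer ids of leaf nodes tagged as axon terminals. The
#'   axon terminal filament of a tip is the maximal unbranched segment
#'   ending at it.
#' @slot label character neuron name.
#' @slot cellType one of \code{"GM"}, \code{"LG"}, \code{"LP"},
#'   \code{"PD"}, \code{"synthetic"}, \code{"other"}.
#'
#' @seealso [parseSWC()], [parseHoc()], [validateGeometry()],
#'   [neuronSummary()]
#' @export
setClass("NeuronGeometry",
  representation(
    nodes    = "data.frame",
    somaId   = "integer",
    axonTips = "integer",
    label    = "character",
    cellType = "character"
  ),
  prototype(
    nodes    = data.frame(),
    somaId   = NA_integer_,
    axonTips = integer(),
    label    = "neuron",
    cellType = "other"
  )
)

.NODE_COLS <- c("id", "type", "x", "y", "z", "radius", "parent")
.CELL_TYPES <- c("GM", "LG", "LP", "PD", "synthetic", "other")

setValidity("NeuronGeometry", function(object) {
  nd <- object@nodes
  msg <- character()
  if (!all(.NODE_COLS %in% names(nd)))
    msg <- c(msg, paste("nodes must have columns:",
                        paste(.NODE_COLS, collapse = ", ")))
  if (length(object@somaId) != 1L)
    msg <- c(msg, "somaId must be a single id")
  if (length(object@label) != 1L)
    msg <- c(msg, "label must be a single string")
  if (length(object@cellType) != 1L ||
      !object@cellType %in% .CELL_TYPES)
    msg <- c(msg, paste("cellType must be one of:",
                        paste(.CELL_TYPES, collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' Construct a NeuronGeometry from a node table
#'
#' Normalises a raw node table into a validated geometry: rows are sorted
#' topologically from the root, duplicate consecutive nodes (zero-length
#' edges, a tracing artifact) are merged with a warning, and non-positive
#' radii are replaced by \code{NA} with a warning. Structural defects
#' (multiple roots, cycles, disconnected nodes, duplicate ids) are errors;
#' use [validateGeometry()] to obtain a report instead.
#'
#' @param nodes data.frame with columns \code{id}, \code{x}, \code{y},
#'   \code{z}, \code{parent} and optionally \code{type} and \code{radius}.
#'   \code{parent} is \code{NA} (or \code{-1}) for the root.
#' @param axonTips integer ids of leaves to tag as axon terminals.
#' @param label neuron name.
#' @param cellType cell-type label, default \code{"other"}.
#' @param mergeZeroEdges merge consecutive coincident nodes (default TRUE).
#' @return a [NeuronGeometry-class] object.
#' @export
NeuronGeometry <- function(nodes, axonTips = integer(), label = "neuron",
                           cellType = "other", mergeZeroEdges = TRUE) {
  stopifnot(is.data.frame(nodes))
  if (!"type" %in% names(nodes)) nodes$type <- "neurite"
  if (!"radius" %in% names(nodes)) nodes$radius <- NA_real_
  nodes$id <- as.integer(nodes$id)
  nodes$parent <- suppressWarnings(as.integer(nodes$parent))
  nodes$parent[!is.na(nodes$parent) & nodes$parent < 0] <- NA_integer_
  for (cc in c("x", "y", "z", "radius")) nodes[[cc]] <- as.double(nodes[[cc]])
  nodes <- nodes[.NODE_COLS]

  if (anyDuplicated(nodes$id))
    stop("duplicate node id(s): ",
         paste(unique(nodes$id[duplicated(nodes$id)]), collapse = ", "))
  if (!all(is.finite(nodes$x) & is.finite(nodes$y) & is.finite(nodes$z)))
    stop("non-finite node coordinates")
  bad <- !is.na(nodes$radius) & nodes$radius <= 0
  if (any(bad)) {
    warning(sum(bad), " non-positive radii set to NA")
    nodes$radius[bad] <- NA_real_
  }
  rootRows <- which(is.na(nodes$parent))
  if (length(rootRows) == 0L) stop("no root node (all nodes have parents)")
  if (length(rootRows) > 1L)
    stop("more than one root node: ids ",
         paste(nodes$id[rootRows], collapse = ", "))
  missingPar <- setdiff(nodes$parent[!is.na(nodes$parent)], nodes$id)
  if (length(missingPar))
    stop("parent id(s) not defined in node table: ",
         paste(missingPar, collapse = ", "))

  nodes <- .topoSort(nodes)
  if (mergeZeroEdges) nodes <- .mergeZeroEdges(nodes)
  soma <- nodes$id[1L]
  nodes$type[1L] <- "soma"
  nodes$type[-1L][nodes$type[-1L] == "soma"] <- "neurite"

  axonTips <- as.integer(axonTips)
  if (length(axonTips)) {
    leaves <- setdiff(nodes$id, nodes$parent)
    bad <- setdiff(axonTips, leaves)
    if (length(bad))
      stop("axon tip id(s) not leaf nodes: ", paste(bad, collapse = ", "))
  }
  new("NeuronGeometry", nodes = nodes, somaId = soma,
      axonTips = sort(unique(axonTips)), label = label, cellType = cellType)
}

# breadth-first topological sort; errors on cycles / disconnected nodes
.topoSort <- function(nodes) {
  n <- nrow(nodes)
  idx <- seq_len(n)
  names(idx) <- as.character(nodes$id)
  parRow <- idx[as.character(nodes$parent)]
  kids <- split(idx, factor(parRow, levels = idx))
  root <- which(is.na(nodes$parent))
  order <- integer(n); order[1L] <- root; got <- 1L; head <- 1L
  while (head <= got) {
    ch <- kids[[order[head]]]
    if (length(ch)) {
      order[(got + 1L):(got + length(ch))] <- ch
      got <- got + length(ch)
    }
    head <- head + 1L
  }
  if (got < n) {
    left <- nodes$id[setdiff(idx, order[seq_len(got)])]
    stop("disconnected or cyclic structure; unreachable node id(s): ",
         paste(utils::head(left, 10L), collapse = ", "))
  }
  nodes <- nodes[order, , drop = FALSE]
  rownames(nodes) <- NULL
  nodes
}

# merge child nodes coincident with their parent (zero-length edges)
.mergeZeroEdges <- function(nodes) {
  repeat {
    pr <- match(nodes$parent, nodes$id)
    dup <- which(!is.na(pr) &
                 nodes$x == nodes$x[pr] & nodes$y == nodes$y[pr] &
                 nodes$z == nodes$z[pr])
    if (!length(dup)) return(nodes)
    d <- dup[1L]
    warning("merged zero-length edge at node id ", nodes$id[d],
            " into parent id ", nodes$parent[d])
    nodes$parent[!is.na(nodes$parent) & nodes$parent == nodes$id[d]] <-
      nodes$parent[d]
    nodes <- nodes[-d, , drop = FALSE]
  }
}

#' @describeIn NeuronGeometry-class compact description of the skeleton
#' @param object a NeuronGeometry
#' @export
setMethod("show", "NeuronGeometry", function(object) {
  nd <- object@nodes
  leaves <- setdiff(nd$id, nd$parent)
  tips <- setdiff(leaves, c(object@somaId, object@axonTips))
  cat("NeuronGeometry '", object@label, "' (", object@cellType, ")\n",
      sep = "")
  cat("  ", nrow(nd), " nodes, ", length(tips), " terminating tips, ",
      length(object@axonTips), " axon(s)\n", sep = "")
  cat("  total cable ", format(round(totalWiring(object, FALSE), 1)),
      " um (", format(round(totalWiring(object, TRUE), 1)),
      " um excluding axons)\n", sep = "")
  if (any(!is.na(nd$radius))) cat("  radii present\n")
  invisible(object)
})
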