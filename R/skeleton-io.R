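#' Parse an SWC skeleton
#'
#' Reads the standard whitespace-delimited 7-column SWC format (id, type,
#' x, y, z, radius, parent; \code{#} comments allowed). SWC type 1 marks
#' the soma, type 2 axon, all other types neurite. Coordinates and radii
#' are taken as micrometres; no unit inference is performed. Leaves of
#' type 2 are tagged as axon tips. If the structural root is not a type-1
#' node but a type-1 node exists, the tree is re-rooted at the type-1 node
#' closest to the root (deposited files vary in convention); if no type-1
#' node exists the root is taken as the soma with a warning.
#'
#' @param text character: SWC content (single string or vector of lines),
#'   or the path of a file when \code{isFile = TRUE}.
#' @param label neuron name; defaults to the file name when reading a
#'   file.
#' @param cellType cell-type label.
#' @param isFile read \code{text} as a file path.
#' @return a [NeuronGeometry-class]
#' @examples
#' g <- parseSWC(c("1 1 0 0 0 5 -1", "2 3 3 4 0 1 1", "3 3 3 4 5 1 2"))
#' totalWiring(g)  # 10: a 3-4-5 construction
#' @export
parseSWC <- function(text, label = NULL, cellType = "other",
                     isFile = FALSE) {
  if (isFile) {
    if (is.null(label))
      label <- tools::file_path_sans_ext(basename(text))
    text <- readLines(text, warn = FALSE)
  }
  if (is.null(label)) label <- "neuron"
  lines <- unlist(strsplit(text, "\n", fixed = TRUE))
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("empty SWC input")
  fields <- strsplit(lines, "[ \t]+")
  bad <- which(lengths(fields) != 7L)
  if (length(bad))
    stop("SWC format error: row ", bad[1L], " ('", lines[bad[1L]],
         "') does not have 7 columns")
  m <- matrix(suppressWarnings(as.numeric(unlist(fields))),
              ncol = 7L, byrow = TRUE)
  if (anyNA(m))
    stop("SWC format error: non-numeric field at row ",
         which(rowSums(is.na(m)) > 0)[1L])
  id <- as.integer(m[, 1L]); swcType <- as.integer(m[, 2L])
  parent <- as.integer(m[, 7L])
  if (anyDuplicated(id))
    stop("SWC format error: duplicate node id ",
         id[duplicated(id)][1L])
  orphan <- which(parent != -1L & !parent %in% id)
  if (length(orphan))
    stop("SWC format error: row ", orphan[1L], " references parent id ",
         parent[orphan[1L]], " absent from the file")
  if (sum(parent == -1L) > 1L)
    stop("SWC structure error: more than one root row")
  nodes <- data.frame(
    id = id,
    type = c("soma", "axon")[match(swcType, 1:2)],
    x = m[, 3L], y = m[, 4L], z = m[, 5L],
    radius = m[, 6L],
    parent = ifelse(parent == -1L, NA_integer_, parent)
  )
  nodes$type[is.na(nodes$type)] <- "neurite"
  nodes$radius[nodes$radius <= 0] <- NA_real_

  rootId <- nodes$id[is.na(nodes$parent)]
  somaIds <- nodes$id[nodes$type == "soma"]
  if (!length(somaIds)) {
    warning("no type-1 (soma) node; using the root as soma")
  } else if (!rootId %in% somaIds) {
    # re-root at the type-1 node fewest hops from the current root
    hops <- vapply(somaIds, function(s) {
      k <- 0L; cur <- s
      repeat {
        p <- nodes$parent[match(cur, nodes$id)]
        if (is.na(p)) return(k)
        cur <- p; k <- k + 1L
      }
    }, integer(1))
    pick <- somaIds[which.min(hops)]
    warning("root is not a soma node; re-rooting at type-1 node id ", pick)
    nodes <- .rerootAt(nodes, pick)
  }
  leaves <- setdiff(nodes$id, nodes$parent)
  tips2 <- intersect(nodes$id[nodes$type == "axon"], leaves)
  NeuronGeometry(nodes, axonTips = tips2, label = label,
                 cellType = cellType)
}

#' Serialize a geometry to SWC text
#'
#' Emits standard 7-column SWC with the soma as id 1 and every parent
#' preceding its children. Nodes of axon terminal filaments are written as
#' type 2, the soma as type 1, all others as type 3. Radii that were never
#' measured are written as 1.0 (the conventional placeholder).
#'
#' @param g a valid [NeuronGeometry-class]; invalid geometries are refused.
#' @param file optional path; when given the text is also written there.
#' @return character vector of SWC lines, invisibly when \code{file} is
#'   given.
#' @export
writeSWC <- function(g, file = NULL) {
  rep <- validateGeometry(g)
  if (length(rep))
    stop("refusing to serialize an invalid geometry: ",
         paste(rep, collapse = "; "))
  nd <- g@nodes
  newId <- seq_len(nrow(nd))            # topological order, soma first
  parentNew <- newId[match(nd$parent, nd$id)]
  parentNew[is.na(parentNew)] <- -1L
  axRows <- .axonNodeRows(g)
  swcType <- rep(3L, nrow(nd))
  swcType[axRows] <- 2L
  swcType[1L] <- 1L
  rad <- ifelse(is.na(nd$radius), 1.0, nd$radius)
  lines <- sprintf("%d %d %.10g %.10g %.10g %.10g %d",
                   newId, swcType, nd$x, nd$y, nd$z, rad, parentNew)
  lines <- c(paste0("# ", g@label, " (", g@cellType, ") written by stgmorph"),
             lines)
  if (!is.null(file)) {
    writeLines(lines, file)
    return(invisible(lines))
  }
  lines
}

#' Report axon candidates
#'
#' Terminal filaments (maximal unbranched segments ending at a leaf) that
#' do not branch for at least \code{minLength} micrometres are candidate
#' axons. Candidates are only reported, never silently tagged: in the
#' original preparations axons were identified manually, so tagging is
#' opt-in (see [tagAxons()]).
#'
#' @param g a [NeuronGeometry-class]
#' @param minLength minimum unbranched terminal length in micrometres
#'   (default 20).
#' @return data.frame of candidate terminal filaments: \code{tipId},
#'   \code{length}, \code{alreadyTagged}.
#' @export
axonCandidates <- function(g, minLength = 20) {
  segs <- neuronSegments(g)
  cand <- segs[segs$terminal & segs$length >= minLength &
                 segs$toId != g@somaId, , drop = FALSE]
  data.frame(tipId = cand$toId, length = cand$length,
             alreadyTagged = cand$toId %in% g@axonTips)
}

#' Tag axon terminal filaments
#'
#' Adds manually selected tips (always tagged, regardless of length) and,
#' when \code{autoTag = TRUE}, every candidate reported by
#' [axonCandidates()] to the geometry's axon set.
#'
#' @param g a [NeuronGeometry-class]
#' @param manualIds integer leaf ids to tag; each must terminate a
#'   terminal filament (be a leaf), otherwise an error is raised.
#' @param minLength candidate threshold in micrometres (default 20).
#' @param autoTag also tag all auto-detected candidates (default FALSE).
#' @return the geometry with updated axon tips; the candidate table is
#'   attached as attribute \code{"candidates"}.
#' @export
tagAxons <- function(g, manualIds = integer(), minLength = 20,
                     autoTag = FALSE) {
  leaves <- setdiff(g@nodes$id, g@nodes$parent)
  bad <- setdiff(as.integer(manualIds), leaves)
  if (length(bad))
    stop("manual axon id(s) are not terminal filaments (leaves): ",
         paste(bad, collapse = ", "))
  cand <- axonCandidates(g, minLength)
  tips <- union(g@axonTips, as.integer(manualIds))
  if (autoTag) tips <- union(tips, cand$tipId)
  g@axonTips <- sort(as.integer(tips))
  attr(g, "candidates") <- cand
  g
}

#' Validate a geometry and report violations
#'
#' Report-only check of every NeuronGeometry invariant: a single root
#' (the soma), connected acyclic structure, finite coordinates, positive
#' radii where present, axon tags on leaves. An empty report means the
#' geometry is valid.
#'
#' @param g a [NeuronGeometry-class]
#' @return character vector of findings; \code{character(0)} if valid.
#' @export
validateGeometry <- function(g) {
  findings <- character()
  nd <- g@nodes
  if (anyDuplicated(nd$id))
    findings <- c(findings, "duplicate node ids")
  if (!all(is.finite(nd$x) & is.finite(nd$y) & is.finite(nd$z)))
    findings <- c(findings, "non-finite coordinates")
  if (any(!is.na(nd$radius) & nd$radius <= 0))
    findings <- c(findings, "non-positive radii")
  roots <- which(is.na(nd$parent))
  if (length(roots) != 1L)
    findings <- c(findings, paste0(length(roots), " roots (expected 1)"))
  if (length(roots) >= 1L && !g@somaId %in% nd$id[roots])
    findings <- c(findings, "soma is not the root")
  # reachability from the first root: detects disconnection and cycles
  if (length(roots) >= 1L) {
    pr <- match(nd$parent, nd$id)
    reached <- rep(FALSE, nrow(nd))
    reached[roots[1L]] <- TRUE
    for (pass in seq_len(nrow(nd))) {
      newly <- !reached & !is.na(pr) & reached[pr]
      if (!any(newly)) break
      reached[newly] <- TRUE
    }
    if (!all(reached)) {
      unreached <- which(!reached)
      # a cycle: unreached nodes whose ancestry never reaches the root
      onCycle <- any(vapply(unreached, function(i) {
        seen <- integer(); cur <- i
        while (!is.na(cur)) {
          if (cur %in% seen) return(TRUE)
          seen <- c(seen, cur); cur <- pr[cur]
        }
        FALSE
      }, logical(1)))
      findings <- c(findings,
                    if (onCycle) "cycle detected" else NULL,
                    "disconnected: unreachable nodes present")
    }
  }
  leaves <- setdiff(nd$id, nd$parent)
  if (length(setdiff(g@axonTips, leaves)))
    findings <- c(findings, "axon tip not a leaf")
  findings
}

#' Normalize soma positions to the neuropil center
#'
#' Translates the soma coordinates of each preparation so that the
#' preparation's neuropil center sits at the origin, putting preparations
#' into a common frame. The orientation convention (anterior nerve up,
#' posterior nerve down) is carried as a metadata flag; no rotation is
#' computed.
#'
#' @param positions data.frame with columns \code{preparation},
#'   \code{somaX}, \code{somaY}, \code{centerX}, \code{centerY} and
#'   optionally \code{somaZ}/\code{centerZ}, all micrometres.
#' @return the data.frame with soma coordinates translated by minus the
#'   preparation's center and centers at the origin; attribute
#'   \code{"orientation"} set to \code{"anterior-up"}.
#' @export
normalizeSomaPositions <- function(positions) {
  need <- c("preparation", "somaX", "somaY", "centerX", "centerY")
  stopifnot(all(need %in% names(positions)))
  if (anyNA(positions$centerX) || anyNA(positions$centerY))
    stop("missing neuropil center for preparation(s): ",
         paste(unique(positions$preparation[
           is.na(positions$centerX) | is.na(positions$centerY)]),
           collapse = ", "))
  out <- positions
  out$somaX <- positions$somaX - positions$centerX
  out$somaY <- positions$somaY - positions$centerY
  out$centerX <- 0; out$centerY <- 0
  if (all(c("somaZ", "centerZ") %in% names(positions))) {
    if (anyNA(positions$centerZ)) stop("missing neuropil center z")
    out$somaZ <- positions$somaZ - positions$centerZ
    out$centerZ <- 0
  }
  attr(out, "orientation") <- "anterior-up"
  out
}
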