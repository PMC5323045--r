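#' Parse a NEURON hoc skeleton
#'
#' Reads the skeleton subset of the hoc dialect in which traced
#' reconstructions are deposited: \code{create} section declarations,
#' \code{pt3dadd(x, y, z, diam)} 3D point statements inside
#' \code{section \{ ... \}} blocks, and
#' \code{connect child(p), parent(p)} statements. Diameters are halved to
#' radii; all coordinates are micrometres. Any other hoc statement is
#' ignored with a single summary warning (the deposits are pure
#' skeletons). Sections whose name contains \code{soma}
#' (case-insensitive) provide the soma: the tree is rooted at the soma
#' section's first point. Terminal sections whose name contains
#' \code{axon} are tagged as axons. A \code{connect} whose sections form a
#' loop is a structure error; a \code{connect} naming an undeclared
#' section is a format error.
#'
#' @param text hoc content (single string or vector of lines), or a file
#'   path when \code{isFile = TRUE}.
#' @param label neuron name.
#' @param cellType cell-type label.
#' @param isFile read \code{text} as a file path.
#' @return a [NeuronGeometry-class]
#' @export
parseHoc <- function(text, label = NULL, cellType = "other",
                     isFile = FALSE) {
  if (isFile) {
    if (is.null(label))
      label <- tools::file_path_sans_ext(basename(text))
    text <- readLines(text, warn = FALSE)
  }
  if (is.null(label)) label <- "neuron"
  lines <- unlist(strsplit(text, "\n", fixed = TRUE))
  lines <- sub("//.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]

  secPoints <- list()     # name -> matrix x,y,z,diam
  secParent <- list()     # name -> list(parent, parentPos, childPos)
  current <- NULL
  ignored <- character()
  numRe <- "[-+]?[0-9]*\\.?[0-9]+(?:[eE][-+]?[0-9]+)?"

  declare <- function(names) {
    for (nm in names) {
      nm <- trimws(nm)
      br <- regmatches(nm, regexec("^([A-Za-z_][A-Za-z0-9_]*)\\[([0-9]+)\\]$",
                                   nm))[[1]]
      if (length(br)) {
        base <- br[2]; n <- as.integer(br[3])
        for (i in seq_len(n) - 1L)
          secPoints[paste0(base, "[", i, "]")] <<- list(NULL)
      } else {
        secPoints[nm] <<- list(NULL)
      }
    }
  }

  for (ln in lines) {
    rest <- ln
    while (nzchar(rest)) {
      rest <- trimws(rest)
      if (!nzchar(rest)) break
      if (is.null(current)) {
        if (grepl("^create\\s+", rest)) {
          declare(strsplit(sub("^create\\s+", "", rest), ",")[[1]])
          rest <- ""
        } else if (grepl("^connect\\s+", rest)) {
          m <- regmatches(rest, regexec(paste0(
            "^connect\\s+([A-Za-z_][A-Za-z0-9_]*(?:\\[[0-9]+\\])?)\\s*\\(\\s*(",
            numRe, ")\\s*\\)\\s*,\\s*([A-Za-z_][A-Za-z0-9_]*(?:\\[[0-9]+\\])?)",
            "\\s*\\(\\s*(", numRe, ")\\s*\\)"), rest))[[1]]
          if (!length(m))
            stop("hoc format error: unparsable connect statement: ", rest)
          child <- m[2]; childPos <- as.numeric(m[3])
          parent <- m[4]; parentPos <- as.numeric(m[5])
          for (s in c(child, parent))
            if (!s %in% names(secPoints))
              stop("hoc format error: connect references unknown section '",
                   s, "'")
          if (!is.null(secParent[[child]]))
            stop("hoc structure error: section '", child,
                 "' connected more than once")
          secParent[[child]] <- list(parent = parent,
                                     parentPos = parentPos,
                                     childPos = childPos)
          rest <- ""
        } else {
          m <- regmatches(rest, regexec(
            "^([A-Za-z_][A-Za-z0-9_]*(?:\\[[0-9]+\\])?)\\s*\\{(.*)$",
            rest))[[1]]
          if (length(m)) {
            if (!m[2] %in% names(secPoints))
              stop("hoc format error: block for unknown section '", m[2], "'")
            current <- m[2]
            rest <- m[3]
          } else {
            ignored <- c(ignored, rest)
            rest <- ""
          }
        }
      } else {
        if (grepl("^\\}", rest)) {
          current <- NULL
          rest <- sub("^\\}", "", rest)
          next
        }
        m <- regmatches(rest, regexec(paste0(
          "^pt3dadd\\s*\\(\\s*(", numRe, ")\\s*,\\s*(", numRe,
          ")\\s*,\\s*(", numRe, ")\\s*,\\s*(", numRe, ")\\s*\\)"), rest))[[1]]
        if (length(m)) {
          pt <- as.numeric(m[2:5])
          secPoints[[current]] <- rbind(secPoints[[current]], pt)
          rest <- sub("^pt3dadd\\s*\\([^)]*\\)", "", rest)
        } else if (grepl("^pt3dclear\\s*\\(\\s*\\)", rest)) {
          secPoints[[current]] <- NULL
          secPoints[current] <- list(NULL)
          rest <- sub("^pt3dclear\\s*\\(\\s*\\)", "", rest)
        } else {
          # unknown in-block statement: drop the first token
          ignored <- c(ignored, strsplit(rest, "\\s+")[[1]][1])
          rest <- sub("^\\S+", "", rest)
        }
      }
    }
  }
  if (length(ignored))
    warning("ignored ", length(ignored), " non-skeleton hoc statement(s): ",
            paste(utils::head(unique(ignored), 5L), collapse = ", "))

  secNames <- names(secPoints)
  filled <- secNames[!vapply(secPoints, is.null, logical(1))]
  if (!length(filled)) stop("hoc format error: no pt3dadd points found")
  secNames <- filled

  # cycle check on the section graph before materialising nodes
  for (s in secNames) {
    seen <- character(); cur <- s
    while (!is.null(secParent[[cur]])) {
      if (cur %in% seen)
        stop("hoc structure error: connect statements form a loop through '",
             cur, "'")
      seen <- c(seen, cur)
      cur <- secParent[[cur]]$parent
    }
  }

  # materialise nodes; global ids per section point
  nextId <- 1L
  secIds <- list()
  rows <- list()
  for (s in secNames) {
    pts <- secPoints[[s]]
    ids <- seq.int(nextId, length.out = nrow(pts))
    nextId <- nextId + nrow(pts)
    secIds[[s]] <- ids
    rows[[s]] <- data.frame(
      id = ids,
      type = if (grepl("soma", s, ignore.case = TRUE)) "soma"
             else if (grepl("axon", s, ignore.case = TRUE)) "axon"
             else "neurite",
      x = pts[, 1], y = pts[, 2], z = pts[, 3],
      radius = pts[, 4] / 2,
      parent = c(NA_integer_, ids[-length(ids)])
    )
  }
  posIndex <- function(s, pos) {
    n <- length(secIds[[s]])
    max(1L, min(n, as.integer(round(pos * (n - 1L))) + 1L))
  }
  for (s in secNames) {
    cp <- secParent[[s]]
    if (is.null(cp)) next
    if (!cp$parent %in% secNames)
      stop("hoc format error: connect references empty section '",
           cp$parent, "'")
    attachId <- secIds[[cp$parent]][posIndex(cp$parent, cp$parentPos)]
    if (cp$childPos > 0.5) {        # child attaches by its 1-end: flip it
      ids <- secIds[[s]]
      r <- rows[[s]]
      r[, c("x", "y", "z", "radius")] <-
        r[rev(seq_len(nrow(r))), c("x", "y", "z", "radius")]
      rows[[s]] <- r
    }
    rows[[s]]$parent[1L] <- attachId
  }
  nodes <- do.call(rbind, rows)

  nRoots <- sum(is.na(nodes$parent))
  if (nRoots > 1L) {
    rootSecs <- secNames[vapply(secNames,
                                function(s) is.null(secParent[[s]]),
                                logical(1))]
    stop("hoc structure error: ", nRoots,
         " unconnected root sections: ",
         paste(rootSecs, collapse = ", "))
  }
  somaRows <- nodes$id[nodes$type == "soma"]
  if (length(somaRows)) {
    rootId <- nodes$id[is.na(nodes$parent)]
    somaSec <- secNames[grepl("soma", secNames, ignore.case = TRUE)][1]
    somaHead <- secIds[[somaSec]][1L]
    if (rootId != somaHead) nodes <- .rerootAt(nodes, somaHead)
  }
  leaves <- setdiff(nodes$id, nodes$parent)
  axTips <- intersect(nodes$id[nodes$type == "axon"], leaves)
  NeuronGeometry(nodes, axonTips = axTips, label = label,
                 cellType = cellType)
}
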