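# Fixtures and independent oracles, all built in code.

# straight chain along +x with given inter-node spacing
chainGeometry <- function(n, spacing = 1, radius = NA_real_) {
  NeuronGeometry(data.frame(
    id = seq_len(n), x = spacing * (seq_len(n) - 1), y = 0, z = 0,
    radius = radius, parent = c(NA, seq_len(n - 1))))
}

# Y: soma -> stem -> bifurcation -> two tips
yGeometry <- function() {
  NeuronGeometry(data.frame(
    id = 1:4,
    x = c(0, 10, 20, 20), y = c(0, 0, 10, -10), z = 0,
    parent = c(NA, 1, 2, 2)))
}

# full binary tree of given depth (every internal node bifurcates)
binaryTreeGeometry <- function(depth) {
  id <- 1L; rows <- list()
  add <- function(parent, x, y, d) {
    me <- id; id <<- id + 1L
    rows[[me]] <<- data.frame(id = me, x = x, y = y, z = 0,
                              parent = parent)
    if (d > 0) {
      add(me, x + 10, y + 10 / d, d - 1)
      add(me, x + 10, y - 10 / d, d - 1)
    }
  }
  add(NA_integer_, 0, 0, 0)          # soma
  rows[[1]]$parent <- NA_integer_
  add(1L, 10, 0, depth)              # stem then tree
  NeuronGeometry(do.call(rbind, rows))
}

# comb: a backbone of nBranch nested branch points, each sprouting a tooth
combGeometry <- function(nBranch) {
  n <- nBranch + 2L
  backbone <- data.frame(id = seq_len(n), x = seq_len(n) - 1, y = 0,
                         z = 0, parent = c(NA, seq_len(n - 1)))
  teeth <- data.frame(id = n + seq_len(nBranch),
                      x = 1 + seq_len(nBranch) - 1, y = 1, z = 0,
                      parent = 1 + seq_len(nBranch))
  NeuronGeometry(rbind(backbone, teeth))
}

# independent Sholl oracle: climb to the root for every edge, half-open
# interval check per sampled distance (tolerance absorbs the different
# floating-point summation order of the independent distance computation)
bruteSholl <- function(g, dists, tol = 1e-7) {
  nd <- nodeTable(g)
  distToSoma <- function(id) {
    tot <- 0
    while (TRUE) {
      r <- match(id, nd$id)
      p <- nd$parent[r]
      if (is.na(p)) return(tot)
      pr <- match(p, nd$id)
      tot <- tot + sqrt(sum((unlist(nd[r, c("x", "y", "z")]) -
                               unlist(nd[pr, c("x", "y", "z")]))^2))
      id <- p
    }
  }
  ax <- integer(0)
  if (length(axonTips(g))) {
    segs <- neuronSegments(g)
    ax <- unlist(lapply(segs$rows[segs$axon], function(r) r[-1]))
  }
  edges <- which(!is.na(nd$parent))
  edges <- setdiff(edges, ax)
  vapply(dists, function(D) {
    sum(vapply(edges, function(r) {
      dc <- distToSoma(nd$id[r])
      dp <- distToSoma(nd$parent[r])
      dp <= D + tol && D < dc - tol
    }, logical(1)))
  }, integer(1))
}

# independent MST oracle: full cost recomputation at every step, no
# incremental caching; same tie-break (lowest carrier index, earliest node)
naiveMST <- function(root, P, bf) {
  P <- as.matrix(P)
  nodes <- rbind(root)
  PL <- 0
  parent <- NA_integer_
  unatt <- seq_len(nrow(P))
  nodeOf <- integer(0)                # carrier index -> node row
  while (length(unatt)) {
    best <- NULL
    for (pi in unatt) {
      for (ni in seq_len(nrow(nodes))) {
        d <- sqrt(sum((P[pi, ] - nodes[ni, ])^2))
        cost <- d + bf * (PL[ni] + d)
        if (is.null(best) || cost < best$cost) {
          best <- list(pi = pi, ni = ni, d = d, cost = cost)
        }
      }
    }
    nodes <- rbind(nodes, P[best$pi, ])
    PL <- c(PL, PL[best$ni] + best$d)
    parent <- c(parent, best$ni)
    nodeOf <- c(nodeOf, best$pi)
    unatt <- setdiff(unatt, best$pi)
  }
  list(nodes = nodes, parent = parent, cable = sum(
    sqrt(rowSums((nodes[-1, , drop = FALSE] -
                    nodes[parent[-1], , drop = FALSE])^2))))
}

# canonical edge-set key of a tree over coordinates (order-free)
edgeSetKey <- function(coords, parent) {
  ch <- which(!is.na(parent))
  keys <- vapply(ch, function(i) paste(
    paste(sprintf("%.6f", coords[parent[i], ]), collapse = ","),
    paste(sprintf("%.6f", coords[i, ]), collapse = ","), sep = "->"),
    character(1))
  sort(keys)
}

mstEdgeKey <- function(mstResult) {
  nd <- nodeTable(mstResult$geometry)
  edgeSetKey(as.matrix(nd[, c("x", "y", "z")]),
             match(nd$parent, nd$id))
}

# brute-force Rall exponent: dense grid argmin of the (log-scale)
# residual of parent^X = sum(daughters^X)
rallGridScan <- function(parentRadius, daughters, lower = 1e-3,
                         upper = 20, step = 1e-4) {
  xs <- seq(lower, upper, by = step)
  res <- abs(xs * log(parentRadius) -
               log(daughters[1]^xs + daughters[2]^xs))
  xs[which.min(res)]
}

# spherical Ellipsoid helper for overlap tests
sphereField <- function(center, r) {
  structure(list(center = center, axes = rep(r, 3), rotation = diag(3),
                 sphere = TRUE), class = "Ellipsoid")
}

# relabel nodes with random ids and shuffle row order
reindexGeometry <- function(g, seed = 99) {
  set.seed(seed)
  nd <- nodeTable(g)
  newIds <- sample(10000L:99999L, nrow(nd))
  map <- stats::setNames(newIds, nd$id)
  nd$id <- unname(map[as.character(nd$id)])
  nd$parent <- unname(map[as.character(nd$parent)])
  nd <- nd[sample(nrow(nd)), ]
  NeuronGeometry(nd, axonTips = unname(map[as.character(axonTips(g))]),
                 label = neuronLabel(g), cellType = cellType(g))
}
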