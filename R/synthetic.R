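# Synthetic unipolar skeleton generator with full ground truth: the
# testbed for every pipeline stage. Emulates the study conditions:
# unipolar topology (soma offset from the arborising neuropil), 1-5
# axons, soma-to-tip paths mostly 200-800 um, tortuosities in the 1-7
# range, a bifurcation-dominated furcation mix (~10% or fewer tri/multi)
# and subtree tip clusters that tile space, with optional tapered radii.

#' Specification for a synthetic unipolar neuron
#'
#' Defaults are the study conditions the generator emulates; see the
#' methods vignette for the reasoning behind each value.
#'
#' @param seed integer RNG seed.
#' @param somaOffset micrometres of unbranched primary neurite between
#'   the soma and the neuropil entry (default 80).
#' @param nAxons number of axons, 1-5 (default 1).
#' @param primaryLength micrometres of primary neurite inside the
#'   neuropil along which subtrees attach (default 200).
#' @param nSubtrees number of subtrees (default 8).
#' @param tipsPerSubtree tips per subtree; scalar or vector of length
#'   \code{nSubtrees} (default 5).
#' @param subtreeLayout \code{"tiled"} (field centers on an alternating
#'   grid flanking the primary, spacing \code{tileSpacing}) or
#'   \code{"random"}.
#' @param fieldDispersion SD (micrometres) of tip scatter around each
#'   field center (default 10).
#' @param tileSpacing lateral grid spacing in micrometres (default 60);
#'   must be positive for the tiled layout.
#' @param tortuosityFactor random-walk jitter amplitude as a multiple of
#'   \code{stepLength}; 0 yields exactly straight segments. The jitter is
#'   applied perpendicular to each leg at interior nodes only, so
#'   junctions, field centers and tip positions are unchanged
#'   (default 1, giving pooled tortuosities near the observed 2-4).
#' @param furcationMix probabilities over daughter counts 2, 3, >= 4
#'   (default \code{c(bi = 0.9, tri = 0.08, multi = 0.02)}).
#' @param taper diameters (micrometres) by order: primary, secondary,
#'   tertiary, tip (default \code{c(18, 6, 3, 1.5)}).
#' @param taperNoise sigma of multiplicative log-normal diameter noise
#'   (default 0; the observed within-class CVs of 0.6-1.4 correspond to
#'   sigma near 0.5-1).
#' @param radii emit per-node radii (default TRUE).
#' @param stepLength node spacing along legs in micrometres (default 8).
#' @param targetPathLengthRange micrometres; designed (straight-line)
#'   soma-to-tip lengths are checked against it (default
#'   \code{c(200, 800)} for the measured, jittered paths at the default
#'   tortuosity factor).
#' @param label,cellType labels for the emitted geometry.
#' @return list of class \code{"SyntheticNeuronSpec"}.
#' @export
syntheticNeuronSpec <- function(seed = 1, somaOffset = 80, nAxons = 1,
                                primaryLength = 200, nSubtrees = 8,
                                tipsPerSubtree = 5,
                                subtreeLayout = c("tiled", "random"),
                                fieldDispersion = 10, tileSpacing = 60,
                                tortuosityFactor = 1,
                                furcationMix = c(bi = 0.9, tri = 0.08,
                                                 multi = 0.02),
                                taper = c(18, 6, 3, 1.5), taperNoise = 0,
                                radii = TRUE, stepLength = 8,
                                targetPathLengthRange = c(200, 800),
                                label = NULL, cellType = "synthetic") {
  subtreeLayout <- match.arg(subtreeLayout)
  stopifnot(nAxons >= 1, nAxons <= 5, nSubtrees >= 1,
            somaOffset > 0, primaryLength > 0, stepLength > 0,
            fieldDispersion >= 0, tortuosityFactor >= 0,
            length(furcationMix) == 3, all(furcationMix >= 0),
            length(taper) == 4, all(taper > 0), taperNoise >= 0)
  if (abs(sum(furcationMix) - 1) > 1e-9)
    stop("furcationMix probabilities must sum to 1")
  if (subtreeLayout == "tiled" && tileSpacing <= 0)
    stop("tiled layout needs a positive tileSpacing")
  tips <- rep_len(as.integer(tipsPerSubtree), nSubtrees)
  stopifnot(all(tips >= 1))
  if (is.null(label)) label <- paste0("synth_seed", seed)
  structure(list(
    seed = as.integer(seed), somaOffset = somaOffset, nAxons = nAxons,
    primaryLength = primaryLength, nSubtrees = as.integer(nSubtrees),
    tipsPerSubtree = tips, subtreeLayout = subtreeLayout,
    fieldDispersion = fieldDispersion, tileSpacing = tileSpacing,
    tortuosityFactor = tortuosityFactor, furcationMix = furcationMix,
    taper = taper, taperNoise = taperNoise, radii = radii,
    stepLength = stepLength,
    targetPathLengthRange = targetPathLengthRange,
    label = label, cellType = cellType), class = "SyntheticNeuronSpec")
}

#' Generate a synthetic unipolar neuron
#'
#' Builds soma, primary neurite, subtree roots spaced along the primary,
#' subtree arbors grown toward designated field centers with jittered
#' random-walk legs, and unbranched axon filaments of at least 20
#' micrometres. Output passes [validateGeometry()] and, under the same
#' seed, is bit-identical.
#'
#' @param spec a [syntheticNeuronSpec()].
#' @return list with \code{geometry} (a [NeuronGeometry-class]) and
#'   \code{groundTruth}: \code{subtreeTips} (tip node ids per subtree),
#'   \code{fieldCenters} (matrix), \code{designedPathLengths} (per tip,
#'   straight-leg chord sums), \code{designedWiring} (total chord cable,
#'   axons excluded), \code{axonTipIds}, \code{furcationCounts}
#'   (realised daughter counts at created branch nodes),
#'   \code{radiusByClass} (diameters used), \code{spec}.
#' @export
generateNeuron <- function(spec) {
  stopifnot(inherits(spec, "SyntheticNeuronSpec"))
  set.seed(spec$seed)
  env <- new.env()
  env$x <- env$y <- env$z <- env$radius <- numeric(0)
  env$parent <- integer(0); env$type <- character(0)
  addNode <- function(p, parent, type = "neurite", radius = NA_real_) {
    env$x <- c(env$x, p[1]); env$y <- c(env$y, p[2]); env$z <- c(env$z, p[3])
    env$parent <- c(env$parent, parent)
    env$type <- c(env$type, type)
    env$radius <- c(env$radius, radius)
    length(env$x)
  }
  jitterSd <- spec$tortuosityFactor * spec$stepLength
  # straight leg from the node `from` to point `to`, subdivided at
  # stepLength with perpendicular jitter at interior nodes; returns the
  # id of the node at `to` and the chord length
  leg <- function(from, to, radius, type = "neurite", jitter = TRUE) {
    a <- c(env$x[from], env$y[from], env$z[from])
    v <- to - a
    L <- sqrt(sum(v^2))
    if (L == 0) stop("degenerate zero-length leg")
    n <- max(1L, ceiling(L / spec$stepLength))
    u <- v / L
    # orthonormal frame perpendicular to u
    ref <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    e1 <- ref - sum(ref * u) * u; e1 <- e1 / sqrt(sum(e1^2))
    e2 <- c(u[2] * e1[3] - u[3] * e1[2],
            u[3] * e1[1] - u[1] * e1[3],
            u[1] * e1[2] - u[2] * e1[1])
    cur <- from
    for (k in seq_len(n)) {
      p <- a + v * (k / n)
      if (jitter && jitterSd > 0 && k < n) {
        p <- p + stats::rnorm(1, 0, jitterSd) * e1 +
          stats::rnorm(1, 0, jitterSd) * e2
      }
      cur <- addNode(p, cur, type, radius)
    }
    list(end = cur, chord = L)
  }
  classRadius <- function(cls) {
    if (!spec$radii) return(NA_real_)
    d <- spec$taper[cls]
    if (spec$taperNoise > 0)
      d <- d * exp(stats::rnorm(1, 0, spec$taperNoise) -
                     spec$taperNoise^2 / 2)
    d / 2
  }

  soma <- addNode(c(0, 0, 0), NA_integer_, "soma",
                  if (spec$radii) 40 else NA_real_)

  # primary neurite along +x with junction nodes at subtree-root and
  # axon-origin positions
  dxi <- spec$primaryLength / (spec$nSubtrees + 1)
  rootX <- spec$somaOffset + dxi * seq_len(spec$nSubtrees)
  xEnd <- spec$somaOffset + spec$primaryLength
  axonX <- xEnd - 15 * (seq_len(spec$nAxons) - 1L)
  stationX <- sort(unique(c(rootX, axonX)))
  cur <- soma; prevX <- 0; rootNode <- integer(spec$nSubtrees)
  axonFrom <- integer(spec$nAxons)
  chordToStation <- numeric(length(stationX))
  acc <- 0
  for (si in seq_along(stationX)) {
    r1 <- classRadius(1L)
    lg <- leg(cur, c(stationX[si], 0, 0), r1, jitter = TRUE)
    cur <- lg$end; acc <- acc + lg$chord
    chordToStation[si] <- acc
    k <- which(rootX == stationX[si])
    if (length(k)) rootNode[k] <- cur
    j <- which(axonX == stationX[si])
    if (length(j)) axonFrom[j] <- cur
  }
  # the chain beyond the most distal branch point belongs to the most
  # distal axon's terminal filament, so it is not counted as (non-axon)
  # designed wiring
  designedPrimary <- if (length(stationX) >= 2L)
    chordToStation[length(stationX) - 1L] else 0

  # field centers
  centers <- matrix(NA_real_, spec$nSubtrees, 3)
  if (spec$subtreeLayout == "tiled") {
    side <- rep_len(c(1, -1), spec$nSubtrees)
    centers[, 1] <- rootX
    centers[, 2] <- side * spec$tileSpacing
    centers[, 3] <- 0
  } else {
    centers[, 1] <- stats::runif(spec$nSubtrees, spec$somaOffset, xEnd)
    centers[, 2] <- stats::runif(spec$nSubtrees, -1.5, 1.5) *
      max(spec$tileSpacing, 1)
    centers[, 3] <- stats::runif(spec$nSubtrees, -0.5, 0.5) *
      max(spec$tileSpacing, 1)
  }

  furcCounts <- integer(0)
  subtreeTips <- vector("list", spec$nSubtrees)
  designedPL <- numeric(0)      # per tip, chord path length from soma
  designedWiring <- designedPrimary
  rootChord <- chordToStation[match(rootX, stationX)]

  drawDaughters <- function(nTips) {
    if (nTips <= 2L) return(min(2L, nTips))
    probs <- spec$furcationMix
    cnts <- c(2L, 3L, 4L)
    ok <- cnts <= nTips
    d <- sample(cnts[ok], 1L, prob = probs[ok])
    d
  }
  # recursive arbor: attach tip set S (coord matrix) below node `at`
  grow <- function(at, S, depth, chordSoFar, k) {
    if (nrow(S) == 1L) {
      lg <- leg(at, S[1, ], classRadius(4L), jitter = TRUE)
      designedWiring <<- designedWiring + lg$chord
      designedPL <<- c(designedPL, chordSoFar + lg$chord)
      subtreeTips[[k]] <<- c(subtreeTips[[k]], lg$end)
      return(invisible(NULL))
    }
    d <- drawDaughters(nrow(S))
    ctr <- colMeans(S)
    here <- c(env$x[at], env$y[at], env$z[at])
    b <- here + 0.6 * (ctr - here)
    cls <- if (depth <= 1L) 2L else 3L
    lg <- leg(at, b, classRadius(cls), jitter = TRUE)
    designedWiring <<- designedWiring + lg$chord
    furcCounts <<- c(furcCounts, d)
    groups <- if (d < nrow(S)) {
      stats::cutree(stats::hclust(stats::dist(S), method = "average"), d)
    } else seq_len(nrow(S))
    for (gi in sort(unique(groups)))
      grow(lg$end, S[groups == gi, , drop = FALSE], depth + 1L,
           chordSoFar + lg$chord, k)
    invisible(NULL)
  }
  for (k in seq_len(spec$nSubtrees)) {
    tipsK <- matrix(stats::rnorm(3 * spec$tipsPerSubtree[k],
                                 mean = rep(centers[k, ],
                                            each = spec$tipsPerSubtree[k]),
                                 sd = spec$fieldDispersion),
                    spec$tipsPerSubtree[k], 3)
    grow(rootNode[k], tipsK, depth = 1L, chordSoFar = rootChord[k], k = k)
  }

  # axons: straight unbranched terminal filaments >= 20 um
  axonTipIds <- integer(spec$nAxons)
  for (j in seq_len(spec$nAxons)) {
    dir <- c(cos(0.35 * (j - 1L)), 0, sin(0.35 * (j - 1L)))
    from <- axonFrom[j]
    to <- c(env$x[from], env$y[from], env$z[from]) + 60 * dir
    lg <- leg(from, to, if (spec$radii) 1.5 else NA_real_,
              type = "axon", jitter = FALSE)
    axonTipIds[j] <- lg$end
  }

  nodes <- data.frame(id = seq_along(env$x), type = env$type,
                      x = env$x, y = env$y, z = env$z,
                      radius = env$radius, parent = env$parent)
  g <- NeuronGeometry(nodes, axonTips = axonTipIds, label = spec$label,
                      cellType = spec$cellType)
  rng <- range(designedPL)
  if (rng[1] < spec$targetPathLengthRange[1] / 4 ||
      rng[2] > spec$targetPathLengthRange[2] * 2)
    warning("designed path lengths (", round(rng[1]), "-", round(rng[2]),
            " um) far outside the target range")
  list(geometry = g,
       groundTruth = list(
         subtreeTips = subtreeTips,
         fieldCenters = centers,
         designedPathLengths = designedPL,
         designedWiring = designedWiring,
         axonTipIds = axonTipIds,
         furcationCounts = furcCounts,
         radiusByClass = spec$taper,
         spec = spec))
}

#' Generate a population of synthetic neurons
#'
#' Independent neurons with sub-seeds derived deterministically from the
#' master seed; parameters optionally jittered multiplicatively to
#' emulate animal-to-animal variability.
#'
#' @param template a [syntheticNeuronSpec()] used as the base.
#' @param n population size.
#' @param seed master seed.
#' @param perturb SD of multiplicative log-normal jitter applied to
#'   \code{somaOffset}, \code{primaryLength} and \code{tileSpacing}
#'   (default 0).
#' @return list of \code{generateNeuron()} results.
#' @export
generatePopulation <- function(template, n, seed = 1, perturb = 0) {
  stopifnot(inherits(template, "SyntheticNeuronSpec"), n >= 1)
  set.seed(seed)
  subSeeds <- sample.int(.Machine$integer.max - 1L, n)
  jit <- if (perturb > 0)
    matrix(exp(stats::rnorm(3 * n, 0, perturb)), n, 3) else
      matrix(1, n, 3)
  lapply(seq_len(n), function(i) {
    sp <- template
    sp$seed <- subSeeds[i]
    sp$somaOffset <- template$somaOffset * jit[i, 1]
    sp$primaryLength <- template$primaryLength * jit[i, 2]
    sp$tileSpacing <- template$tileSpacing * jit[i, 3]
    sp$label <- paste0(template$label, "_", i)
    generateNeuron(sp)
  })
}

#' Cell-type-like generator templates
#'
#' Qualitative templates mirroring the four cell classes: GM-like
#' neurons are multi-axon with many subtrees; LG-, LP- and PD-like are
#' single-axon with progressively fewer subtrees.
#'
#' @param type one of \code{"GM"}, \code{"LG"}, \code{"LP"}, \code{"PD"}.
#' @param seed seed stored in the template.
#' @return a [syntheticNeuronSpec()]
#' @export
cellTemplate <- function(type = c("GM", "LG", "LP", "PD"), seed = 1) {
  type <- match.arg(type)
  switch(type,
    GM = syntheticNeuronSpec(seed = seed, nAxons = 3, nSubtrees = 14,
                             primaryLength = 300, cellType = "synthetic",
                             label = paste0("GMlike_", seed)),
    LG = syntheticNeuronSpec(seed = seed, nSubtrees = 10,
                             label = paste0("LGlike_", seed)),
    LP = syntheticNeuronSpec(seed = seed, nSubtrees = 8,
                             label = paste0("LPlike_", seed)),
    PD = syntheticNeuronSpec(seed = seed, nSubtrees = 4,
                             label = paste0("PDlike_", seed)))
}

#' Scrambled twin of a tiled synthetic neuron
#'
#' Re-distributes the tip coordinates into the same number of, but
#' different, subtrees: tip leaf coordinates are permuted across the
#' whole neuron while per-subtree tip counts and subtree root positions
#' stay fixed. The twin is the bootstrap's negative control: its tip
#' assignment is itself random, so [scrambleTips()] should not reject
#' the null on it.
#'
#' @param neuron result of [generateNeuron()] (tiled ground truth).
#' @param seed permutation seed.
#' @return list with \code{geometry} and updated \code{groundTruth}.
#' @export
scrambledTwin <- function(neuron, seed = 1) {
  gt <- neuron$groundTruth
  g <- neuron$geometry
  tipIds <- unlist(gt$subtreeTips)
  rows <- match(tipIds, g@nodes$id)
  set.seed(seed)
  perm <- sample(seq_along(rows))
  nd <- g@nodes
  nd[rows, c("x", "y", "z")] <- nd[rows[perm], c("x", "y", "z")]
  g@nodes <- nd
  gt$scrambleSeed <- seed
  list(geometry = g, groundTruth = gt)
}
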