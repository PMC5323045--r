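test_that("generated neurons satisfy every geometry invariant", {
  for (tpl in c("GM", "LG", "LP", "PD")) {
    nn <- generateNeuron(cellTemplate(tpl, seed = 3))
    expect_length(validateGeometry(nn$geometry), 0L)
    expect_gte(length(axonTips(nn$geometry)), 1L)
    # axons are unbranched terminal filaments of at least 20 um
    cand <- axonCandidates(nn$geometry)
    expect_true(all(axonTips(nn$geometry) %in% cand$tipId))
  }
})

test_that("construction parameters are recovered from the geometry", {
  sp <- syntheticNeuronSpec(seed = 17, nSubtrees = 6, tipsPerSubtree = 4,
                            taperNoise = 0)
  nn <- generateNeuron(sp)
  g <- nn$geometry
  expect_length(detectSubtrees(g), 6L)
  expect_equal(nrow(somaPaths(g)), 24L)
  # furcation multiset: arbor branch nodes plus the primary junctions
  fp <- furcationProfile(g)
  expected <- sort(c(nn$groundTruth$furcationCounts,
                     rep(2L, sp$nSubtrees + sp$nAxons - 1L)))
  expect_equal(sort(fp$counts$daughters), expected)
})

test_that("zero tortuosity factor yields exactly straight segments", {
  nn <- generateNeuron(syntheticNeuronSpec(seed = 23,
                                           tortuosityFactor = 0))
  g <- nn$geometry
  segs <- neuronSegments(g)
  nd <- nodeTable(g)
  for (i in seq_len(nrow(segs))) {
    rows <- segs$rows[[i]]
    chord <- sqrt(sum((unlist(nd[rows[length(rows)], c("x", "y", "z")]) -
                         unlist(nd[rows[1], c("x", "y", "z")]))^2))
    expect_equal(segs$length[i], chord, tolerance = 1e-9)
  }
  # designed and measured path lengths coincide
  p <- somaPaths(g)
  expect_equal(sort(p$pathLength),
               sort(nn$groundTruth$designedPathLengths),
               tolerance = 1e-9)
  expect_equal(totalWiring(g), nn$groundTruth$designedWiring,
               tolerance = 1e-9)
})

test_that("jitter increases tortuosity monotonically on average", {
  tf <- c(0, 0.5, 1, 2)
  med <- vapply(tf, function(f) {
    nn <- generateNeuron(syntheticNeuronSpec(seed = 31,
                                             tortuosityFactor = f))
    stats::median(somaPaths(nn$geometry)$tortuosity)
  }, numeric(1))
  expect_true(all(diff(med) > 0))
  expect_gt(med[1], 1)     # piecewise-straight paths still bend at junctions
  expect_lt(med[1], 1.6)
})

test_that("same seed gives bit-identical output", {
  sp <- syntheticNeuronSpec(seed = 77, taperNoise = 0.3)
  a <- generateNeuron(sp); b <- generateNeuron(sp)
  expect_identical(writeSWC(a$geometry), writeSWC(b$geometry))
  expect_identical(a$groundTruth$designedPathLengths,
                   b$groundTruth$designedPathLengths)
})

test_that("populations derive distinct, reproducible sub-seeds", {
  tpl <- syntheticNeuronSpec(label = "pop")
  pop <- generatePopulation(tpl, 8, seed = 4, perturb = 0.05)
  expect_length(pop, 8L)
  labels <- vapply(pop, function(x) neuronLabel(x$geometry), "")
  expect_length(unique(labels), 8L)
  wir <- vapply(pop, function(x) totalWiring(x$geometry), numeric(1))
  expect_length(unique(round(wir, 6)), 8L)   # genuinely different neurons
  pop2 <- generatePopulation(tpl, 8, seed = 4, perturb = 0.05)
  expect_identical(wir, vapply(pop2, function(x)
    totalWiring(x$geometry), numeric(1)))
})

test_that("pooled population path lengths land in the target range", {
  pop <- generatePopulation(syntheticNeuronSpec(), 8, seed = 2)
  pl <- unlist(lapply(pop, function(x) somaPaths(x$geometry)$pathLength))
  h <- hist(pl, breaks = seq(0, max(pl) + 50, 50), plot = FALSE)
  mode <- h$mids[which.max(h$counts)]
  expect_gte(mode, 200); expect_lte(mode, 800)
  expect_gte(mean(pl >= 200 & pl <= 800), 0.75)
})

test_that("scrambled twins keep counts but break the tiling", {
  nn <- generateNeuron(syntheticNeuronSpec(seed = 41))
  tw <- scrambledTwin(nn, seed = 6)
  expect_length(validateGeometry(tw$geometry), 0L)
  stO <- detectSubtrees(nn$geometry)
  stT <- detectSubtrees(tw$geometry)
  expect_equal(vapply(stT, function(s) length(s$tipIds), integer(1)),
               vapply(stO, function(s) length(s$tipIds), integer(1)))
  # the coordinate multiset of tips is preserved
  coO <- do.call(rbind, lapply(stO, `[[`, "tipCoords"))
  coT <- do.call(rbind, lapply(stT, `[[`, "tipCoords"))
  expect_equal(coO[order(coO[, 1]), ], coT[order(coT[, 1]), ],
               tolerance = 1e-12, ignore_attr = TRUE)
  # scrambling inflates the mean cluster radius of a tiled neuron
  rO <- mean(vapply(stO, `[[`, numeric(1), "clusterRadius"))
  rT <- mean(vapply(stT, `[[`, numeric(1), "clusterRadius"))
  expect_gt(rT, rO)
})

test_that("infeasible specs are rejected", {
  expect_error(syntheticNeuronSpec(subtreeLayout = "tiled",
                                   tileSpacing = 0), "tileSpacing")
  expect_error(syntheticNeuronSpec(furcationMix = c(1, 1, 1)), "sum to 1")
  expect_error(syntheticNeuronSpec(nAxons = 9))
})
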