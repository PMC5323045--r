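test_that("main path connects soma to every axon", {
  nn <- generateNeuron(syntheticNeuronSpec(seed = 1))
  mp <- mainPath(nn$geometry)
  expect_equal(mp$nPaths, 1L)
  expect_true(somaId(nn$geometry) %in% mp$nodeIds)
  # no terminating tips live on the main path
  expect_length(intersect(terminatingTips(nn$geometry), mp$nodeIds), 0L)
  gm <- generateNeuron(syntheticNeuronSpec(seed = 1, nAxons = 3))
  mp3 <- mainPath(gm$geometry)
  expect_equal(mp3$nPaths, 3L)
  # the three main paths share the proximal trunk
  expect_true(all(mp$nodeIds[1:5] %in% mp3$nodeIds[1:5]))
  expect_error(mainPath(chainGeometry(3)), "no tagged axon")
})

test_that("subtrees are detected one per qualifying secondary branch", {
  nn <- generateNeuron(syntheticNeuronSpec(seed = 9, nSubtrees = 5))
  st <- detectSubtrees(nn$geometry)
  expect_length(st, 5L)
  # subtree tips partition the terminating tips
  allTips <- sort(unlist(lapply(st, `[[`, "tipIds")))
  expect_equal(allTips, sort(terminatingTips(nn$geometry)))
  # a secondary branch leading only to an axon is not a subtree
  one <- generateNeuron(syntheticNeuronSpec(seed = 9, nSubtrees = 5,
                                            tipsPerSubtree = 1))
  tipToKill <- detectSubtrees(one$geometry)[[3]]$tipIds
  g2 <- tagAxons(one$geometry, manualIds = tipToKill)
  expect_length(detectSubtrees(g2), 4L)
})

test_that("wiring is conserved under the subtree decomposition", {
  nn <- generateNeuron(syntheticNeuronSpec(seed = 12))
  g <- nn$geometry
  segs <- neuronSegments(g)
  mp <- mainPath(g)
  st <- detectSubtrees(g)
  pieces <- sum(segs$length[segs$segId %in% mp$segIds]) +
    sum(vapply(st, function(s)
      sum(segs$length[segs$segId %in% s$segIds]), numeric(1)))
  expect_equal(pieces, totalWiring(g, excludeAxons = TRUE),
               tolerance = 1e-9)
})

test_that("tip center of mass and cluster radius are analytic", {
  expect_equal(tipCenterOfMass(rbind(c(0, 0, 0), c(2, 0, 0))),
               c(1, 0, 0))
  expect_equal(tipCenterOfMass(rbind(c(3, 1, 2))), c(3, 1, 2))
  tips <- rbind(c(0, 0, 0), c(4, 0, 0))
  expect_equal(clusterRadius(tips), 2)
  expect_equal(clusterRadius(rbind(c(5, 5, 5))), 0)
  four <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0))
  expect_equal(clusterRadius(four), 1.0)
  # translation equivariance
  v <- c(7, -3, 2)
  expect_equal(tipCenterOfMass(sweep(four, 2, -v)),
               tipCenterOfMass(four) + v)
})

test_that("neuritic field fit recovers Gaussian cloud axes", {
  set.seed(21)
  n <- 500
  tips <- cbind(rnorm(n, sd = 10), rnorm(n, sd = 5), rnorm(n, sd = 2))
  f <- fitNeuriticField(tips)
  expect_false(f$sphere)
  expect_equal(f$axes, c(20, 10, 4), tolerance = 0.1)
  # two tips: sphere fallback at the cluster radius
  two <- rbind(c(0, 0, 0), c(4, 0, 0))
  f2 <- fitNeuriticField(two)
  expect_true(f2$sphere)
  expect_equal(f2$axes, rep(clusterRadius(two), 3))
  # rigid rotation rotates the fitted orientation identically
  R <- qr.Q(qr(matrix(rnorm(9), 3)))
  fr <- fitNeuriticField(tips %*% t(R))
  expect_equal(fr$axes, f$axes, tolerance = 1e-6)
  expect_equal(abs(det(crossprod(fr$rotation, R %*% f$rotation))), 1,
               tolerance = 1e-6)
})

test_that("overlap counting matches analytic circle arrangements", {
  far <- list(sphereField(c(0, 0, 0), 1), sphereField(c(10, 0, 0), 1))
  expect_equal(as.integer(countOverlaps(far)), 0L)
  conc <- list(sphereField(c(0, 0, 0), 2), sphereField(c(0, 0, 0), 1))
  expect_equal(as.integer(countOverlaps(conc)), 1L)
  grid <- list()
  for (i in 0:2) for (j in 0:2)
    grid[[length(grid) + 1]] <- sphereField(c(4 * i, 4 * j, 0), 1)
  expect_equal(as.integer(countOverlaps(grid)), 0L)
  touchAll <- list(sphereField(c(0, 0, 0), 3), sphereField(c(4, 0, 0), 3),
                   sphereField(c(2, 3, 0), 3))
  ov <- countOverlaps(touchAll)
  expect_equal(as.integer(ov), 3L)
  expect_equal(attr(ov, "subtreesOverlapping"), 3L)
})

test_that("overlap count is invariant under in-plane rigid motion", {
  nn <- generateNeuron(syntheticNeuronSpec(seed = 14))
  g <- nn$geometry
  obs <- function(gg) {
    st <- detectSubtrees(gg)
    as.integer(countOverlaps(lapply(st, fitNeuriticField)))
  }
  th <- 0.7
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  nd <- nodeTable(g)
  rot <- as.matrix(nd[, c("x", "y", "z")]) %*% t(R)
  nd$x <- rot[, 1] + 50; nd$y <- rot[, 2] - 20; nd$z <- rot[, 3]
  g2 <- NeuronGeometry(nd, axonTips = axonTips(g))
  expect_equal(obs(g2), obs(g))
})

test_that("tip scrambling preserves counts and coordinates", {
  nn <- generateNeuron(syntheticNeuronSpec(seed = 3, nSubtrees = 4,
                                           tipsPerSubtree = 3))
  sc <- scrambleTips(nn$geometry, nIterations = 50, seed = 7,
                     computeOverlaps = FALSE)
  expect_equal(sc$tipCounts, rep(3L, 4))
  expect_equal(sc$nIterations, 50L)
  expect_length(sc$scrambledMeanRadius, 50L)
  expect_gt(sc$pRadius, 0)
  expect_lte(sc$pRadius, 1)
  # bit reproducibility under the seed
  sc2 <- scrambleTips(nn$geometry, nIterations = 50, seed = 7,
                      computeOverlaps = FALSE)
  expect_identical(sc$scrambledMeanRadius, sc2$scrambledMeanRadius)
  # single subtree: the null is undefined
  one <- generateNeuron(syntheticNeuronSpec(seed = 3, nSubtrees = 1))
  expect_error(scrambleTips(one$geometry), "at least two subtrees")
})

test_that("singleton subtrees give zero radii and p = 1", {
  nn <- generateNeuron(syntheticNeuronSpec(seed = 5, nSubtrees = 5,
                                           tipsPerSubtree = 1))
  sc <- scrambleTips(nn$geometry, nIterations = 100, seed = 2,
                     computeOverlaps = FALSE)
  expect_equal(sc$observedMeanRadius, 0)
  expect_true(all(sc$scrambledMeanRadius == 0))
  expect_equal(sc$pRadius, 1)
})

test_that("iteration count shrinks to the number of distinct assignments", {
  # 2 subtrees x 1 tip: only 2 distinct assignments
  nn <- generateNeuron(syntheticNeuronSpec(seed = 5, nSubtrees = 2,
                                           tipsPerSubtree = 1))
  sc <- scrambleTips(nn$geometry, nIterations = 2000, seed = 1,
                     computeOverlaps = FALSE)
  expect_equal(sc$nIterations, 2L)
})

test_that("a tiled neuron is more compact than its scrambles", {
  nn <- generateNeuron(syntheticNeuronSpec(seed = 10))
  sc <- scrambleTips(nn$geometry, nIterations = 200, seed = 4,
                     computeOverlaps = FALSE)
  expect_lt(sc$observedMeanRadius, mean(sc$scrambledMeanRadius))
})

test_that("field report is consistent and reproducible", {
  nn <- generateNeuron(syntheticNeuronSpec(seed = 16, nSubtrees = 5))
  out <- tempfile(fileext = ".json")
  fr <- fieldReport(nn$geometry, nIterations = 30, seed = 9,
                    jsonFile = out)
  expect_equal(nrow(fr$table), 5L)
  st <- detectSubtrees(nn$geometry)
  expect_equal(fr$table$radius,
               vapply(st, `[[`, numeric(1), "clusterRadius"))
  expect_true(file.exists(out))
  fr2 <- fieldReport(nn$geometry, nIterations = 30, seed = 9)
  expect_identical(fr$bootstrap$scrambledMeanRadius,
                   fr2$bootstrap$scrambledMeanRadius)
})
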