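test_that("soma-to-tip paths are enumerated per terminating tip", {
  expect_equal(nrow(somaPaths(chainGeometry(3))), 1L)
  y <- somaPaths(yGeometry())
  expect_equal(nrow(y), 2L)
  # both records share the pre-bifurcation prefix
  expect_equal(y$nodeIds[[1]][1:2], y$nodeIds[[2]][1:2])
  nn <- generateNeuron(syntheticNeuronSpec(seed = 2))
  p <- somaPaths(nn$geometry)
  expect_equal(nrow(p), length(terminatingTips(nn$geometry)))
  expect_false(any(axonTips(nn$geometry) %in% p$tipId))
  # triangle inequality: path length >= Euclidean distance
  expect_true(all(p$pathLength >= p$euclidean - 1e-9))
})

test_that("tortuosity follows the path/Euclidean definition", {
  expect_equal(pathTortuosity(rbind(c(0, 0, 0), c(5, 0, 0),
                                    c(20, 0, 0))), 1.0)
  expect_equal(pathTortuosity(rbind(c(0, 0), c(1, 0), c(1, 1))),
               sqrt(2))
  expect_warning(v <- pathTortuosity(rbind(c(0, 0), c(1, 0), c(0, 0))),
                 "undefined")
  expect_true(is.na(v))
  # tortuosity >= 1 for every non-degenerate path, = 1 iff collinear
  nn <- generateNeuron(syntheticNeuronSpec(seed = 8))
  tt <- somaPaths(nn$geometry)$tortuosity
  expect_true(all(tt >= 1 - 1e-9))
})

test_that("total wiring sums segment lengths and can exclude axons", {
  g <- chainGeometry(3, spacing = 5)
  expect_equal(totalWiring(g), 10)
  gAx <- tagAxons(g, manualIds = 3L)
  expect_equal(totalWiring(gAx, excludeAxons = TRUE), 0)
  expect_equal(totalWiring(gAx, excludeAxons = FALSE), 10)
})

test_that("furcation profile classifies daughter counts", {
  fb <- furcationProfile(binaryTreeGeometry(3))
  expect_true(all(fb$counts$daughters == 2L))
  expect_equal(unname(fb$proportions["bi"]), 1)
  # one trifurcation among four bifurcations -> 80/20/0
  nd <- data.frame(id = 1:13, x = 0, y = 0, z = 0, parent = NA)
  nd$x <- c(0, 1, 2, 2, 3, 3, 4, 4, 5, 5, 6, 6, 6)
  nd$y <- c(0, 0, 1, -1, 2, -2, 3, -3, 4, -4, 5, 6, 7)
  nd$parent <- c(NA, 1, 2, 2, 3, 3, 5, 5, 7, 7, 9, 9, 9)
  g <- NeuronGeometry(nd)
  fp <- furcationProfile(g)
  expect_equal(unname(fp$proportions), c(0.8, 0.2, 0))
  # the soma with several primary filaments is not a furcation
  star <- NeuronGeometry(data.frame(id = 1:4, x = c(0, 1, -1, 0),
                                    y = c(0, 0, 0, 1), z = 0,
                                    parent = c(NA, 1, 1, 1)))
  expect_equal(nrow(furcationProfile(star)$counts), 0L)
})

test_that("branch orders count branch points from the first", {
  expect_equal(branchOrders(yGeometry())$order, 0L)
  nested <- combGeometry(3)
  expect_equal(sort(branchOrders(nested)$order), 0:2)
  deep <- combGeometry(101)
  expect_equal(max(branchOrders(deep)$order), 100L)
})

test_that("branch angle follows the 180-minus-theta convention", {
  expect_equal(branchAngle(c(1, 0, 0), c(0, 0, 0), c(2, 0, 0)), 0)
  expect_equal(branchAngle(c(1, 0, 0), c(0, 0, 0), c(1, 1, 0)), 90)
  expect_equal(branchAngle(c(1, 0, 0), c(0, 0, 0),
                           c(0.5, sqrt(3) / 2, 0)), 120)
  expect_warning(v <- branchAngle(c(0, 0, 0), c(0, 0, 0), c(1, 0, 0)),
                 "degenerate")
  expect_true(is.na(v))
})

test_that("branch angle is symmetric and rigid-motion invariant", {
  set.seed(42)
  R <- qr.Q(qr(matrix(rnorm(9), 3)))
  for (k in 1:20) {
    pts <- matrix(rnorm(9, sd = 5), 3)
    a0 <- branchAngle(pts[1, ], pts[2, ], pts[3, ])
    expect_equal(branchAngle(pts[1, ], pts[3, ], pts[2, ]), a0)
    shift <- rnorm(3)
    moved <- t(R %*% t(pts)) + rep(shift, each = 3)
    expect_equal(branchAngle(moved[1, ], moved[2, ], moved[3, ]), a0,
                 tolerance = 1e-9)
  }
})

test_that("geometry-level branch angles use adjacent segment endpoints", {
  ang <- branchAngles(yGeometry())
  # both daughters leave the straight stem at 45 degrees
  expect_equal(nrow(ang), 2L)
  expect_equal(ang$angle, c(45, 45))
})

test_that("symmetry index is min/max of downstream lengths", {
  expect_equal(symmetryIndex(120, 120), 1.0)
  expect_equal(symmetryIndex(10, 40), 0.25)
  # scale invariance
  set.seed(1)
  for (k in 1:20) {
    d <- runif(2, 0.1, 100); c0 <- runif(1, 0.01, 50)
    expect_equal(symmetryIndex(d[1] * c0, d[2] * c0),
                 symmetryIndex(d[1], d[2]), tolerance = 1e-12)
  }
  g <- yGeometry()   # both daughters 10*sqrt(2) downstream
  si <- symmetryIndices(g)
  expect_equal(si$si, 1.0)
  expect_equal(si$d1, sqrt(200))
})

test_that("Rall power solves the parent-daughter radius equation", {
  r <- rallPower(2, c(1, 1))
  expect_equal(r$exponent, 1, tolerance = 1e-6)
  expect_true(r$converged); expect_false(r$clamped)
  r <- rallPower(2^(2 / 3), c(1, 1))
  expect_equal(r$exponent, 1.5, tolerance = 1e-6)
  # parent equal to one daughter: sum always exceeds parent -> clamped low
  r <- rallPower(1, c(1, 1))
  expect_true(r$clamped)
  expect_equal(r$exponent, 1e-3)
  expect_error(rallPower(-1, c(1, 1)), "positive")
  expect_error(rallPower(1, 1), "two daughter")
})

test_that("Rall solver agrees with a coarse grid scan", {
  set.seed(7)
  for (k in 1:50) {
    pr <- runif(1, 0.5, 6); dr <- runif(2, 0.3, 4)
    got <- rallPower(pr, dr)$exponent
    ref <- rallGridScan(pr, dr, step = 1e-3)
    expect_lt(abs(got - ref), 2e-3)
  }
})

test_that("geometry-level Rall powers use branch point radii", {
  nd <- data.frame(id = 1:5, x = c(0, 10, 20, 30, 30),
                   y = c(0, 0, 0, 5, -5), z = 0,
                   radius = c(5, 3, 2^(2 / 3), 1, 1),
                   parent = c(NA, 1, 2, 3, 3))
  g <- NeuronGeometry(nd)
  rp <- rallPowers(g)
  expect_equal(nrow(rp), 1L)
  expect_equal(rp$exponent, 1.5, tolerance = 1e-6)
  expect_error(rallPowers(chainGeometry(3)), "no radii")
})

test_that("linearized Sholl counts crossings on analytic cases", {
  g <- chainGeometry(11, spacing = 10)   # single 100 um path
  s <- linearizedSholl(g, nDistances = 21)
  expect_equal(s$crossings[1], 1L)           # one primary filament
  expect_true(all(s$crossings[s$distance > 0 & s$distance < 100] == 1L))
  expect_equal(s$crossings[21], 0L)          # nothing beyond the last node
  # bifurcation at half length doubles the distal counts
  y <- yGeometry()                            # splits at 10 of ~24.1
  sy <- linearizedSholl(y, nDistances = 50)
  expect_true(all(sy$crossings[sy$distance < 10 & sy$distance > 0] == 1L))
  expect_true(all(sy$crossings[sy$distance > 10.01 &
                                 sy$distance < 24] == 2L))
  expect_equal(max(sy$normCount), 1)
  expect_equal(max(sy$normDistance), 1)
})

test_that("spatial density is a max-1 KDE that tracks point density", {
  set.seed(3)
  cluster <- matrix(rnorm(40, sd = 2), 20, 2)
  pts <- rbind(c(0, 0), cluster, c(200, 200))
  nd <- data.frame(id = seq_len(nrow(pts)), x = pts[, 1], y = pts[, 2],
                   z = 0, parent = c(NA, rep(1, nrow(pts) - 1)))
  g <- NeuronGeometry(nd, mergeZeroEdges = FALSE)
  d <- spatialDensity(g)
  expect_equal(max(d$density), 1.0)
  expect_true(all(d$density >= 0))
  # the distant outlier is the sparsest point
  expect_equal(which.min(d$density), nrow(pts))
  expect_error(spatialDensity(chainGeometry(2)), "at least 3")
})

test_that("hair-like neurites need thin diameter and > 50 um length", {
  mk <- function(r, n) {
    nd <- data.frame(id = seq_len(n + 1),
                     x = c(0, seq_len(n)) * 10, y = 0, z = 0,
                     radius = c(5, rep(r, n)),
                     parent = c(NA, seq_len(n)))
    NeuronGeometry(nd)
  }
  expect_equal(nrow(detectHairlike(mk(0.4, 6))), 1L)   # 60 um at 0.8 um
  expect_equal(nrow(detectHairlike(mk(1.0, 6))), 0L)   # 2 um diameter
  expect_equal(nrow(detectHairlike(mk(0.4, 1))), 0L)   # only 10 um
  expect_error(detectHairlike(chainGeometry(3)), "no radii")
})

test_that("diameters by order recover the generator taper exactly", {
  nn <- generateNeuron(syntheticNeuronSpec(seed = 4, taperNoise = 0))
  dio <- diameterByOrder(nn$geometry)
  means <- setNames(dio$stats$mean, dio$stats$class)
  expect_equal(unname(means[c("1", "2", "3")]), c(18, 6, 3),
               tolerance = 1e-9)
  expect_equal(unname(means["tip"]), 1.5, tolerance = 1e-9)
  expect_equal(dio$stats$cv[dio$stats$class == "1"], 0)
  expect_true(means["1"] > means["tip"])    # monotone taper
})

test_that("neuron summary mirrors ground truth and survives re-indexing", {
  nn <- generateNeuron(syntheticNeuronSpec(seed = 6, taperNoise = 0))
  g <- nn$geometry
  s <- neuronSummary(g)
  expect_equal(s$somaToTipPaths, sum(lengths(nn$groundTruth$subtreeTips)))
  expect_equal(s$subtrees, nn$groundTruth$spec$nSubtrees)
  expect_equal(s$totalWiring, totalWiring(g))
  s2 <- neuronSummary(reindexGeometry(g))
  for (col in setdiff(names(s), c("label", "cellType")))
    expect_equal(s2[[col]], s[[col]], tolerance = 1e-9, label = col)
})
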