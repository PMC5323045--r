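test_that("SWC parsing builds validated geometries", {
  g <- parseSWC(c("# a comment", "1 1 0 0 0 5 -1", "2 3 3 4 0 1 1",
                  "3 3 3 4 5 1 2"))
  expect_s4_class(g, "NeuronGeometry")
  expect_equal(nNodes(g), 3L)
  expect_length(terminatingTips(g), 1L)
  expect_equal(totalWiring(g), 10)      # 3-4-5 construction
  expect_equal(nodeTable(g)$radius[1], 5)
  expect_length(validateGeometry(g), 0L)
})

test_that("SWC format errors are caught and name the offence", {
  expect_error(parseSWC(c("1 1 0 0 0 1 -1", "2 3 1 0 0 1 7")),
               "parent id 7")
  expect_error(parseSWC(c("1 1 0 0 0 1 -1", "1 3 1 0 0 1 1")),
               "duplicate")
  expect_error(parseSWC(c("1 1 0 0 0 1 -1", "2 3 1 0 0 1 -1")),
               "root")
  expect_error(parseSWC("1 1 0 0 0 1"), "7 columns")
})

test_that("SWC round trip preserves topology, coordinates and radii", {
  nn <- generateNeuron(syntheticNeuronSpec(seed = 11, taperNoise = 0.4))
  g <- nn$geometry
  txt1 <- writeSWC(g)
  g2 <- parseSWC(txt1)
  expect_equal(nNodes(g2), nNodes(g))
  expect_equal(length(axonTips(g2)), length(axonTips(g)))
  expect_equal(totalWiring(g2), totalWiring(g), tolerance = 1e-9)
  expect_equal(sort(somaPaths(g2)$pathLength),
               sort(somaPaths(g)$pathLength), tolerance = 1e-9)
  # writeSWC canonicalises ids, so a second round trip is bit-identical
  # (data rows; the header comment carries the label)
  expect_identical(writeSWC(parseSWC(txt1))[-1], txt1[-1])
})

test_that("single-node and axon-tagged geometries serialize correctly", {
  g1 <- NeuronGeometry(data.frame(id = 1, x = 0, y = 0, z = 0,
                                  parent = NA))
  rows <- writeSWC(g1)
  expect_match(rows[2], "^1 1 .* -1$")
  g <- chainGeometry(5, spacing = 10)
  g <- tagAxons(g, manualIds = 5L)
  rows <- writeSWC(g)
  types <- as.integer(vapply(strsplit(rows[-1], " "), `[[`, "", 2))
  # the terminal filament back to the soma-adjacent junction is axonal
  expect_equal(types, c(1L, rep(2L, 4)))
})

test_that("axon candidates respect the 20 um unbranched rule", {
  # terminal filament of 25 um -> candidate; 10 um -> not
  long <- chainGeometry(7, spacing = 5)
  nd <- nodeTable(long)
  nd <- rbind(nd, data.frame(id = 8, type = "neurite", x = 5, y = 10,
                             z = 0, radius = NA, parent = 2))
  g <- NeuronGeometry(nd)    # node 2 is now a branch point
  cand <- axonCandidates(g)
  expect_true(7L %in% cand$tipId)                # 25 um beyond node 2
  expect_false(8L %in% cand$tipId)               # 10 um tooth
  # manual ids are tagged regardless of length
  gm <- tagAxons(g, manualIds = 8L)
  expect_true(8L %in% axonTips(gm))
  expect_error(tagAxons(g, manualIds = 2L), "not terminal")
  # opt-in auto tagging
  ga <- tagAxons(g, autoTag = TRUE)
  expect_true(7L %in% axonTips(ga))
})

test_that("validateGeometry reports disconnection and cycles", {
  good <- chainGeometry(4)
  expect_length(validateGeometry(good), 0L)
  orphan <- new("NeuronGeometry", nodes = data.frame(
    id = 1:4, type = "neurite", x = as.numeric(1:4), y = 0, z = 0,
    radius = NA_real_, parent = c(NA, 1L, NA, 3L)),
    somaId = 1L, axonTips = integer(), label = "bad", cellType = "other")
  expect_true(any(grepl("root", validateGeometry(orphan))))
  cyc <- new("NeuronGeometry", nodes = data.frame(
    id = 1:4, type = "neurite", x = as.numeric(1:4), y = 0, z = 0,
    radius = NA_real_, parent = c(NA, 1L, 4L, 3L)),
    somaId = 1L, axonTips = integer(), label = "bad", cellType = "other")
  f <- validateGeometry(cyc)
  expect_true(any(grepl("cycle", f)))
})

test_that("hoc parsing handles sections, connects and diameters", {
  hoc <- c("create soma, dend",
           "soma { pt3dadd(0, 0, 0, 10) pt3dadd(5, 0, 0, 8) }",
           "dend { pt3dadd(5, 0, 0, 4) pt3dadd(5, 5, 0, 2) }",
           "connect dend(0), soma(1)")
  g <- suppressWarnings(parseHoc(hoc))
  # the duplicated junction point is merged away
  expect_equal(nNodes(g), 3L)
  expect_equal(totalWiring(g), 10)
  expect_equal(nodeTable(g)$radius[1], 5)   # diameters halved
  expect_equal(somaId(g), nodeTable(g)$id[1])
})

test_that("hoc structural defects are errors", {
  loop <- c("create a, b",
            "a { pt3dadd(0,0,0,1) pt3dadd(1,0,0,1) }",
            "b { pt3dadd(1,0,0,1) pt3dadd(2,0,0,1) }",
            "connect b(0), a(1)",
            "connect a(0), b(1)")
  expect_error(parseHoc(loop), "loop")
  expect_error(parseHoc(c("create a",
                          "a { pt3dadd(0,0,0,1) }",
                          "connect ghost(0), a(1)")),
               "unknown section")
})

test_that("non-skeleton hoc statements are ignored with a warning", {
  hoc <- c("objref nil", "create a",
           "a { pt3dadd(0,0,0,2) pt3dadd(4,0,0,2) }",
           "access a")
  expect_warning(g <- parseHoc(hoc), "ignored")
  expect_equal(nNodes(g), 2L)
})

test_that("soma positions normalize to the neuropil origin", {
  df <- data.frame(preparation = c("p1", "p1", "p2"),
                   somaX = c(100, 120, 40), somaY = c(50, 60, 10),
                   centerX = c(100, 100, 30), centerY = c(50, 50, 5))
  out <- normalizeSomaPositions(df)
  expect_equal(out$somaX, c(0, 20, 10))
  expect_equal(out$somaY, c(0, 10, 5))
  expect_true(all(out$centerX == 0))
  # translation is an isometry within a preparation
  d0 <- dist(df[df$preparation == "p1", c("somaX", "somaY")])
  d1 <- dist(out[out$preparation == "p1", c("somaX", "somaY")])
  expect_equal(as.numeric(d0), as.numeric(d1))
  df$centerX[1] <- NA
  expect_error(normalizeSomaPositions(df), "missing neuropil center")
})

test_that("total cable is invariant under node re-indexing", {
  nn <- generateNeuron(syntheticNeuronSpec(seed = 5))
  g <- nn$geometry
  g2 <- reindexGeometry(g)
  expect_equal(totalWiring(g2), totalWiring(g), tolerance = 1e-9)
  expect_equal(totalWiring(g2, FALSE), totalWiring(g, FALSE),
               tolerance = 1e-9)
})
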