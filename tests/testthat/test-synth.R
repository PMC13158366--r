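test_that("the same seed reproduces a scene bit for bit", {
  sp <- sceneSpec(nPunctates = 6, nRods = 4, nNetworks = 2, rngSeed = 31)
  g1 <- generateScene(sp)
  g2 <- generateScene(sp)
  expect_identical(pixels(g1$image), pixels(g2$image))
  expect_identical(g1$truth@objects, g2$truth@objects)
  # a different seed gives a different image
  g3 <- generateScene(sceneSpec(nPunctates = 6, nRods = 4, nNetworks = 2,
                                rngSeed = 32))
  expect_false(identical(pixels(g1$image), pixels(g3$image)))
})

test_that("a punctate-only noiseless scene yields exactly its components", {
  sp <- sceneSpec(nPunctates = 5, nRods = 0, nNetworks = 0,
                  noiseModel = "none", illuminationAmplitude = 0,
                  rngSeed = 8)
  gen <- generateScene(sp)
  res <- analyzeImage(gen$image)
  v <- metricValues(res$metrics)
  expect_equal(v[["punctate_count"]], 5)
  expect_equal(v[["rod_count"]], 0)
  expect_equal(v[["network_count"]], 0)
})

test_that("a single network's branch count is recovered", {
  sp <- sceneSpec(nPunctates = 0, nRods = 0, nNetworks = 1,
                  branchesPerNetworkRange = c(4L, 4L),
                  noiseModel = "none", illuminationAmplitude = 0,
                  rngSeed = 12)
  gen <- generateScene(sp)
  expect_equal(gen$truth@objects[[1]]$branchCount, 4L)
  v <- metricValues(analyzeImage(gen$image)$metrics)
  expect_equal(v[["network_count"]], 1)
  expect_equal(v[["total_network_branch_count"]], 4)
})

test_that("ground-truth lengths equal the generating polyline geometry", {
  gen <- quickScene(3, nP = 2, nR = 5, nN = 1)
  for (o in gen$truth@objects) {
    geom <- sum(vapply(o$polylines, function(P) {
      if (nrow(P) < 2) 0 else sum(sqrt(rowSums(diff(P)^2)))
    }, 0))
    expect_equal(o$length, geom, tolerance = 1e-9)
  }
})

test_that("rendered rod length is close to geometric truth", {
  relErr <- vapply(1:10, function(s) {
    sp <- sceneSpec(nPunctates = 6, nRods = 10, nNetworks = 1,
                    rodLengthRange = c(25, 55), rngSeed = 400 + s)
    gen <- generateScene(sp)
    v <- metricValues(analyzeImage(gen$image)$metrics)
    truth <- mean(vapply(
      Filter(function(o) o$class == "rod", gen$truth@objects),
      function(o) o$length, 0))
    abs(v[["mean_rod_length"]] - truth) / truth
  }, 0)
  expect_lt(max(relErr), 0.15)
})

test_that("fccp transform at zero fragmentation is the identity spec", {
  gen <- quickScene(5)
  sp2 <- fccpTransform(gen$truth, 0)
  expect_identical(sp2, gen$truth@sourceSpec)
})

test_that("full fragmentation splits every rod into 2+ punctates", {
  sp <- sceneSpec(nPunctates = 0, nRods = 10, nNetworks = 0, rngSeed = 9)
  gen <- generateScene(sp)
  sp2 <- fccpTransform(gen$truth, 1)
  cls <- vapply(sp2@objects, function(o) o$class, "")
  expect_gte(sum(cls == "punctate"), 20)
  expect_equal(sum(cls == "rod"), 0)
})

test_that("fragmentation lowers the mean object length in truth", {
  gen <- quickScene(11, nP = 5, nR = 8, nN = 3)
  sp2 <- fccpTransform(gen$truth, 0.6)
  len0 <- mean(vapply(gen$truth@objects, function(o) o$length, 0))
  len1 <- mean(vapply(sp2@objects, function(o) o$length, 0))
  expect_lt(len1, len0)
})

test_that("networks keep at least three branches after fragmentation", {
  sp <- sceneSpec(nPunctates = 0, nRods = 0, nNetworks = 4,
                  branchesPerNetworkRange = c(4L, 5L), rngSeed = 13)
  gen <- generateScene(sp)
  sp2 <- fccpTransform(gen$truth, 1)
  nets <- Filter(function(o) o$class == "network", sp2@objects)
  expect_true(all(vapply(nets, function(o) o$branchCount, 0L) >= 3L))
  # detached branches reappear as rods with conserved length
  rods <- Filter(function(o) o$class == "rod", sp2@objects)
  expect_gt(length(rods), 0L)
})

test_that("a fragmented spec renders and the direction shows in metrics", {
  gen <- quickScene(17, nP = 6, nR = 8, nN = 2)
  v0 <- metricValues(analyzeImage(gen$image)$metrics)
  sp2 <- fccpTransform(gen$truth, 0.5)
  gen2 <- generateScene(sp2)
  v1 <- metricValues(analyzeImage(gen2$image)$metrics)
  expect_gt(v1[["punctate_count"]], v0[["punctate_count"]])
  expect_lt(v1[["mean_length_all_branches"]], v0[["mean_length_all_branches"]])
})

test_that("multicell fields carry consistent truth and channels", {
  gen <- generateMulticellField(3, cellSceneSpec(),
                                withNuclei = TRUE, rngSeed = 4)
  expect_equal(gen$truth@nNuclei, 3L)
  expect_equal(nrow(gen$truth@cellCenters), 3L)
  expect_identical(gen$nuclei@channel, "nuclei")
  expect_equal(countNuclei(gen$nuclei), 3L)
  cells <- vapply(gen$truth@objects, function(o) o$cell, 0L)
  expect_setequal(unique(cells), 1:3)
  # zero cells -> blank field
  blank <- generateMulticellField(0, sceneSpec(), rngSeed = 1)
  expect_warning(seg <- identifyPrimaryObjects(blank$image),
                 "blank|no objects")
  expect_equal(nCells(seg), 0L)
})

test_that("scene spec validity catches inconsistent optics", {
  expect_error(sceneSpec(minSeparation = 2, psfSigma = 2), "minSeparation")
  expect_error(sceneSpec(rodLengthRange = c(-5, 10)), "rodLengthRange")
  expect_error(sceneSpec(noiseModel = "salt"), "noiseModel")
})
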