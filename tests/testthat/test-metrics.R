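# A hand-built skeleton with 2 rods (lengths 7 and 9) and one T network
# whose 3 branches measure 4, 4 and 7: every parameter below follows from
# the definitional formulas by hand.
tShape <- function() {
  m <- matrix(FALSE, 40, 40)
  m[5, 3:10] <- TRUE            # rod, length 7
  m[10, 3:12] <- TRUE           # rod, length 9
  m[20:28, 25] <- TRUE          # T network
  m[20, 20:30] <- TRUE
  m
}

test_that("the 18 parameters follow the definitional formulas", {
  met <- computeMetrics(buildGraph(skeletonImage(tShape())))
  v <- metricValues(met)
  expect_equal(v[["punctate_count"]], 0)
  expect_equal(v[["rod_count"]], 2)
  expect_equal(v[["network_count"]], 1)
  expect_equal(v[["rod_length"]], 16)
  expect_equal(v[["mean_rod_length"]], 8)
  expect_equal(v[["network_length"]], 15)
  expect_equal(v[["total_network_branch_count"]], 3)
  expect_equal(v[["mean_network_branch_count"]], 3)
  expect_equal(v[["mean_network_branch_length"]], 5)
  expect_equal(v[["mean_network_length"]], 15)
  expect_equal(v[["all_branch_count"]], 5)                 # 0 + 2 + 3
  expect_equal(v[["mean_length_all_branches"]], 31 / 5)
  expect_equal(v[["mean_network_and_rod_length"]], 31 / 3)
  expect_equal(v[["punctate_pct"]], 0)
  expect_equal(v[["rod_pct"]], 200 / 3)
  expect_equal(v[["network_pct"]], 100 / 3)
  expect_equal(v[["skeleton_area"]], sum(tShape()))
})

test_that("an empty skeleton yields zero counts and missing means", {
  v <- metricValues(computeMetrics(buildGraph(skeletonImage(
    matrix(FALSE, 5, 5)))))
  expect_equal(unname(v[c("skeleton_area", "punctate_count", "rod_count",
                          "network_count", "all_branch_count")]),
               rep(0, 5))
  expect_true(all(is.na(v[c("mean_rod_length", "mean_network_length",
                            "mean_network_branch_count",
                            "mean_network_branch_length",
                            "mean_length_all_branches",
                            "mean_network_and_rod_length")])))
})

test_that("a single punctate gives a pure punctate percentage split", {
  m <- matrix(FALSE, 5, 5); m[3, 3] <- TRUE
  v <- metricValues(computeMetrics(buildGraph(skeletonImage(m))))
  expect_equal(v[["punctate_pct"]], 100)
  expect_equal(v[["rod_pct"]], 0)
  expect_equal(v[["network_pct"]], 0)
})

test_that("percentages sum to 100 and identities hold on pipeline output", {
  for (s in c(3, 14)) {
    gen <- quickScene(s, nP = 6, nR = 5, nN = 2)
    v <- metricValues(analyzeImage(gen$image)$metrics)
    expect_equal(v[["punctate_pct"]] + v[["rod_pct"]] + v[["network_pct"]],
                 100, tolerance = 1e-9)
    expect_equal(v[["mean_network_branch_count"]] * v[["network_count"]],
                 v[["total_network_branch_count"]])
    expect_equal(v[["mean_network_branch_length"]] *
                   v[["total_network_branch_count"]],
                 v[["network_length"]])
    expect_equal(v[["all_branch_count"]],
                 v[["punctate_count"]] + v[["rod_count"]] +
                   v[["total_network_branch_count"]])
  }
})

test_that("normalization divides extensive fields only and inverts", {
  met <- computeMetrics(buildGraph(skeletonImage(tShape())))
  v0 <- metricValues(met)
  n1 <- normalizeMetrics(met, "cell_area", 1)
  expect_equal(metricValues(n1), v0)                 # value 1 = identity
  A <- 1234.5
  nA <- normalizeMetrics(met, "cell_area", A)
  vA <- metricValues(nA)
  ext <- mitomorph:::.extensiveParameterNames()
  expect_equal(vA[ext], v0[ext] / A)
  intens <- setdiff(morphologyParameterNames(), ext)
  expect_equal(vA[intens], v0[intens])
  # round trip within 1e-12
  back <- metricValues(normalizeMetrics(nA, "cell_area", 1 / A))
  expect_equal(unname(back[ext]), unname(v0[ext]), tolerance = 1e-12)
  expect_error(normalizeMetrics(met, "cell_area", 0), "positive")
  expect_error(normalizeMetrics(met, "nuclei_count", -3), "positive")
})

test_that("physical pixel size scales lengths and areas correctly", {
  g <- buildGraph(skeletonImage(tShape()))
  vpx <- metricValues(computeMetrics(g))
  vum <- metricValues(computeMetrics(g, pixelSize = 0.25))
  expect_equal(vum[["mean_rod_length"]], vpx[["mean_rod_length"]] * 0.25)
  expect_equal(vum[["skeleton_area"]], vpx[["skeleton_area"]] * 0.25^2)
  expect_equal(vum[["rod_pct"]], vpx[["rod_pct"]])
})

test_that("batch analysis over a directory yields one record per field", {
  root <- tempfile(); dir.create(root)
  for (s in 1:3) {
    gen <- quickScene(30 + s, nP = 4, nR = 3, nN = 1)
    writeRawImage(gen$image, file.path(root, sprintf("field%d.tif", s)))
  }
  recs <- analyzeBatch(root, mode = "aggregate")
  expect_length(recs, 3L)
  expect_true(all(vapply(recs, function(r) r@normalizerKind, "") == "none"))
  ids <- vapply(recs, sourceId, "")
  expect_identical(ids, sort(ids))
  # unreadable files are skipped with a warning, not an error
  writeLines("junk", file.path(root, "broken.tif"))
  expect_warning(recs2 <- analyzeBatch(root, mode = "aggregate"),
                 "skipping unreadable")
  expect_length(recs2, 3L)
  # an empty directory warns and returns an empty list
  empty <- tempfile(); dir.create(empty)
  expect_warning(expect_length(analyzeBatch(empty), 0L), "no images")
})

test_that("aggregate batch normalizes by nuclei when the channel exists", {
  root <- tempfile(); dir.create(root)
  gen <- generateMulticellField(3, cellSceneSpec(),
                                withNuclei = TRUE, rngSeed = 5)
  writeRawImage(gen$image, file.path(root, "f1.tif"))
  writeRawImage(gen$nuclei, file.path(root, "f1_nuclei.tif"))
  recs <- analyzeBatch(root, mode = "aggregate")
  expect_length(recs, 1L)
  expect_identical(recs[[1]]@normalizerKind, "nuclei_count")
  expect_equal(recs[[1]]@normalizerValue, 3)
})
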