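test_that("CLAHE maps a constant image to a constant image", {
  img <- rawImage(matrix(37L, 30, 30))
  out <- claheCorrect(img)
  expect_equal(length(unique(as.vector(pixels(out)))), 1L)
  expect_identical(dim(pixels(out)), dim(pixels(img)))
  expect_identical(bitDepth(out), bitDepth(img))
})

test_that("CLAHE is deterministic (bitwise repeatable)", {
  set.seed(11)
  img <- rawImage(matrix(sample(0:255, 3600, replace = TRUE), 60, 60))
  expect_identical(pixels(claheCorrect(img)), pixels(claheCorrect(img)))
})

test_that("CLAHE flattens an illumination gradient over sparse spots", {
  # 2x linear gradient; bright spots of equal true brightness throughout
  set.seed(3)
  H <- 80L
  base <- matrix(20, H, H)
  gradient <- 1 + (col(base) - 1) / (H - 1)   # 1x .. 2x left to right
  spots <- expand.grid(r = seq(10, 70, by = 12), c = seq(10, 70, by = 12))
  for (i in seq_len(nrow(spots)))
    base[spots$r[i] + (-1:1), spots$c[i] + (-1:1)] <- 100
  img <- rawImage(matrix(as.integer(round(base * gradient)), H, H))
  spotMean <- function(px, cols) {
    sel <- spots[spots$c %in% cols, ]
    mean(vapply(seq_len(nrow(sel)), function(i)
      max(px[sel$r[i] + (-1:1), sel$c[i] + (-1:1)]), 0))
  }
  rawRatio <- spotMean(pixels(img), c(58, 70)) /
              spotMean(pixels(img), c(10, 22))
  eq <- claheCorrect(img)
  eqRatio <- spotMean(pixels(eq), c(58, 70)) /
             spotMean(pixels(eq), c(10, 22))
  expect_gt(rawRatio, 1.3)
  expect_lt(abs(eqRatio - 1), abs(rawRatio - 1))
})

test_that("CLAHE rejects invalid parameters", {
  img <- rawImage(matrix(0:99, 10, 10))
  expect_error(claheCorrect(img, kernelSize = c(50, 50)), "larger than")
  expect_error(claheCorrect(img, clipLimit = 0), "clipLimit")
  expect_error(claheCorrect(img, kernelSize = c(8, 8), nBins = 1), "nBins")
})

test_that("global Otsu equals the brute-force oracle on random histograms", {
  set.seed(101)
  for (i in 1:60) {
    n <- sample(50:400, 1)
    # mixture histograms with varied separation and ties
    v <- c(sample(0:120, n, replace = TRUE),
           sample(sample(60:255, 1) + 0:30, n, replace = TRUE))
    v <- pmin(pmax(v, 0L), 255L)
    img <- rawImage(matrix(v[seq_len(2 * floor(length(v) / 2))],
                           nrow = 2))
    mask <- otsuThreshold(img, mode = "global")
    expect_identical(otsuLevel(mask),
                     bruteOtsu(as.vector(pixels(img)), 255L))
  }
})

test_that("Otsu separates a clean bimodal image exactly", {
  img <- rawImage(matrix(c(rep(10L, 100), rep(200L, 100)), 20, 10))
  mask <- otsuThreshold(img)
  expect_equal(sum(pixels(mask)), 100L)
  expect_true(otsuLevel(mask) >= 10 && otsuLevel(mask) < 200)
})

test_that("Otsu rejects constant images as degenerate", {
  expect_error(otsuThreshold(rawImage(matrix(5L, 10, 10))), "degenerate")
})

test_that("Otsu foreground is invariant to adding a constant", {
  set.seed(5)
  v <- sample(0:200, 400, replace = TRUE)
  img1 <- rawImage(matrix(v, 20, 20))
  img2 <- rawImage(matrix(v + 30L, 20, 20))
  expect_identical(unname(pixels(otsuThreshold(img1)) * 1),
                   unname(pixels(otsuThreshold(img2)) * 1))
})

test_that("adaptive Otsu recovers objects under a strong gradient", {
  gen <- quickScene(77, nP = 4, nR = 4, nN = 1)
  maskA <- otsuThreshold(claheCorrect(gen$image), mode = "adaptive",
                         window = 48)
  # every true rod center must be foreground
  for (o in gen$truth@objects) {
    if (o$class != "rod") next
    ctr <- round(o$center)
    expect_true(any(pixels(maskA)[ctr[1] + (-1:1), ctr[2] + (-1:1)]))
  }
})

test_that("denoise_and_blur with zeroed parameters is the identity", {
  set.seed(1)
  img <- rawImage(matrix(sample(0:255, 400, replace = TRUE), 20, 20))
  expect_identical(pixels(denoiseAndBlur(img, 0, 0)), pixels(img))
})

test_that("opening suppresses an isolated bright speck", {
  m <- matrix(30L, 21, 21)
  m[11, 11] <- 250L
  out <- denoiseAndBlur(rawImage(m), minFeature = 2, sigma = 0)
  expect_lt(pixels(out)[11, 11], 40)
})

test_that("blurring a two-cell field leaves two regional maxima", {
  m <- matrix(10, 60, 60)
  m[15 + (-3:3), 15 + (-3:3)] <- 200
  m[45 + (-3:3), 45 + (-3:3)] <- 200
  sm <- pixels(denoiseAndBlur(rawImage(matrix(as.integer(m), 60, 60)),
                              minFeature = 0, sigma = 3))
  # count local maxima above background
  isMax <- sm > 50
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    sh <- matrix(0, 60, 60)
    rs <- max(1, 1 + dr):min(60, 60 + dr)
    cs <- max(1, 1 + dc):min(60, 60 + dc)
    sh[rs, cs] <- sm[rs - dr, cs - dc]
    isMax <- isMax & (sm >= sh)
  }
  expect_equal(countComponents8(isMax), 2L)
})

test_that("speck removal and gap closing behave as documented", {
  m <- matrix(FALSE, 20, 20)
  m[5, 5] <- TRUE                    # 1-px speck
  m[10, 3:9] <- TRUE                 # 7-px line
  m[15, 3:8] <- TRUE; m[15, 10:15] <- TRUE  # line with a 1-px gap
  bm <- binaryMask(m)
  cleaned <- removeSpecks(bm, minArea = 5)
  expect_false(pixels(cleaned)[5, 5])
  expect_true(all(pixels(cleaned)[10, 3:9]))
  closed <- closeGaps(bm, radius = 1)
  expect_true(pixels(closed)[15, 9])
})
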