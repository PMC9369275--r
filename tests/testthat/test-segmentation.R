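test_that("sacPercent is the documented pixel ratio", {
  m <- matrix(FALSE, 1024, 1360)
  m[seq_len(476672)] <- TRUE
  expect_equal(sacPercent(m), 100 * 476672 / 1392640)  # 34.2279 %SAC
  expect_equal(sacPercent(new("BinaryMask", pixels = m, provenance = "t")),
               sacPercent(m))
  expect_error(sacPercent(matrix(1, 2, 2)))
})

test_that("noise-free platelet recovery is near-exact", {
  tr <- fieldTruth(fieldSize = testField, seed = 31)
  bf <- renderBrightfield(tr, noiseSD = 0, seed = 32)
  mask <- segmentPlatelets(bf)
  truth <- truthMasks(tr)$platelet
  expect_gte(jaccard(mask@pixels, truth), 0.95)
  expect_lt(abs(sacPercent(mask) - 100 * mean(truth)), 1)
})

test_that("default-noise recovery stays accurate and blank fields are empty", {
  tr <- fieldTruth(fieldSize = testField, seed = 41)
  bf <- renderBrightfield(tr, noiseSD = 0.02, seed = 42)
  mask <- segmentPlatelets(bf)
  truth <- truthMasks(tr)$platelet
  expect_gte(jaccard(mask@pixels, truth), 0.9)
  expect_lt(abs(sacPercent(mask) - 100 * mean(truth)), 2)

  set.seed(43)
  blankBF <- intensityImage(
    matrix(0.85 + rnorm(prod(testField), 0, 0.02), testField[1]),
    "brightfield")
  expect_equal(sacPercent(segmentPlatelets(blankBF)), 0)
  blankFL <- intensityImage(
    matrix(abs(rnorm(prod(testField), 0.06, 0.02)), testField[1]), "PS")
  expect_equal(sacPercent(segmentFluorPositive(blankFL)), 0)
})

test_that("automatic masks are invariant to detector gain", {
  tr <- fieldTruth(fieldSize = testField, seed = 51)
  fl <- renderFluorescence(tr, "PS", noiseSD = 0.02, seed = 52)
  m1 <- segmentFluorPositive(fl)
  scaled <- intensityImage(fl@pixels * 0.4, "PS")
  m2 <- segmentFluorPositive(scaled)
  expect_identical(m1@pixels, m2@pixels)
})

test_that("fixed thresholds and degenerate images behave as documented", {
  px <- matrix(0.9, 20, 20); px[5:10, 5:10] <- 0.4
  img <- intensityImage(px, "brightfield")
  m <- segmentPlatelets(img, method = "fixed", threshold = 0.6)
  expect_equal(sum(m@pixels), 36)
  expect_error(segmentPlatelets(img, method = "fixed"), "threshold")
  expect_warning(e <- segmentPlatelets(
    intensityImage(matrix(0.5, 10, 10), "brightfield")), "constant")
  expect_false(any(e@pixels))
  expect_error(segmentPlatelets(intensityImage(px, "PS")), "brightfield")
  expect_error(segmentFluorPositive(img), "channel")
})

test_that("TIFF round trip preserves geometry and intensities", {
  tr <- fieldTruth(fieldSize = c(128L, 96L), seed = 61)
  img <- renderFluorescence(tr, "fibrinogen", noiseSD = 0.01, seed = 62)
  f <- tempfile(fileext = ".tiff")
  writeIntensityImage(img, f)
  back <- readIntensityImage(f, channel = "fibrinogen")
  expect_identical(dim(back@pixels), dim(img@pixels))
  expect_lt(max(abs(back@pixels - pmin(pmax(img@pixels, 0), 1))), 1 / 65535)
})

test_that("aggregate masks are platelet subsets above the area floor", {
  tr <- fieldTruth(fieldSize = testField, seed = 71)
  bf <- renderBrightfield(tr, noiseSD = 0.02, seed = 72)
  plt <- segmentPlatelets(bf)
  agg <- segmentAggregates(bf, plt)
  expect_true(all(plt@pixels[agg@pixels]))     # subset of the platelet mask
  expect_lte(sacPercent(agg), sacPercent(plt)) # P2 never exceeds P1
  truth <- truthMasks(tr)
  expect_lt(abs(sacPercent(agg) - 100 * mean(truth$aggregate)), 3)
  # every retained component is at least the minimum aggregate area
  lab <- EBImage::bwlabel(EBImage::Image(agg@pixels))
  sizes <- tabulate(as.integer(EBImage::imageData(lab)))
  sizes <- sizes[sizes > 0]
  if (length(sizes) > 0)
    expect_true(all(sizes * tr@pixelSize^2 >= tr@minAggregateArea))
  bad <- new("BinaryMask", pixels = matrix(FALSE, 2, 2), provenance = "t")
  expect_error(segmentAggregates(bf, bad), "dimensions")
})

test_that("fluorescence coverage recovery is accurate per channel", {
  tr <- fieldTruth(fieldSize = testField, seed = 81)
  for (ch in c("PS", "P-selectin", "fibrinogen")) {
    fl <- renderFluorescence(tr, ch, noiseSD = 0.02, seed = 82)
    est <- sacPercent(segmentFluorPositive(fl))
    expect_lt(abs(est - 100 * tr@channelFractions[[ch]]), 1.5, label = ch)
  }
})
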