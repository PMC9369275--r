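feat <- function(agg = 0, ml = 0, sol = NA_real_, n = 10L, largest = 50)
  new("MorphologyFeatures", nObjects = n, largestObjectArea = largest,
      aggregateAreaFraction = agg, multilayerAreaFraction = ml,
      meanSolidityLarge = sol)

test_that("rubric configuration is validated", {
  expect_s4_class(rubricConfig(), "RubricConfig")
  expect_error(rubricConfig(aggregateCuts = c(0.3, 0.1)), "increasing")
  expect_error(rubricConfig(multilayerCuts = c(0.1, 0.1, 0.2)), "increasing")
  expect_error(rubricConfig(solidityCuts = c(0.5, 0.7, 1.2)), "lie in")
  expect_error(rubricConfig(sacFloor = -1), "sacFloor")
})

test_that("fields below the adhesion floor score zero everywhere", {
  s <- scoreImage(feat(agg = 0.5, ml = 0.3, sol = 0.99), P1 = 0.2)
  expect_identical(s, c(morphology = 0L, multilayer = 0L, contraction = 0L))
})

test_that("score tiers follow the documented cut-points", {
  # sparse adhesion, no aggregates
  s0 <- scoreImage(feat(), P1 = 5)
  expect_identical(s0, c(morphology = 1L, multilayer = 0L, contraction = 0L))
  # small loose aggregates
  s1 <- scoreImage(feat(agg = 0.06, ml = 0.05, sol = 0.75), P1 = 20)
  expect_identical(s1, c(morphology = 2L, multilayer = 1L, contraction = 1L))
  # extensive, multilayered, contracted field reaches the top tiers
  s5 <- scoreImage(feat(agg = 0.40, ml = 0.25, sol = 0.96), P1 = 40)
  expect_identical(s5, c(morphology = 5L, multilayer = 3L, contraction = 3L))
  # values equal to a cut-point take the higher tier
  r <- rubricConfig()
  sEq <- scoreImage(feat(agg = r@aggregateCuts[1], ml = r@multilayerCuts[1],
                         sol = r@solidityCuts[1]), P1 = 20)
  expect_identical(sEq[["morphology"]], 3L)
  expect_identical(sEq[["multilayer"]], 1L)
  expect_identical(sEq[["contraction"]], 1L)
  # unknown solidity (no large aggregate) blocks contraction tiers only
  sNA <- scoreImage(feat(agg = 0.2, ml = 0.1, sol = NA_real_), P1 = 20)
  expect_identical(sNA[["contraction"]], 0L)
  expect_gt(sNA[["morphology"]], 1L)
})

test_that("scores are monotone in each feature", {
  r <- rubricConfig()
  grid <- expand.grid(agg = c(0, 0.05, 0.12, 0.3, 0.6),
                      ml = c(0, 0.05, 0.15, 0.25),
                      sol = c(0.65, 0.8, 0.9, 0.97))
  sc <- t(apply(grid, 1, function(g)
    scoreImage(feat(agg = g[1], ml = g[2], sol = g[3]), P1 = 20, rubric = r)))
  for (v in c("agg", "ml", "sol")) {
    for (i in seq_len(nrow(grid))) {
      larger <- which(grid[[v]] > grid[[v]][i] &
        colSums(abs(t(grid[setdiff(names(grid), v)]) -
                      unlist(grid[i, setdiff(names(grid), v)]))) == 0)
      for (j in larger)
        expect_true(all(sc[j, ] >= sc[i, ]),
                    label = sprintf("monotone in %s (row %d vs %d)", v, i, j))
    }
  }
})

test_that("extractFeatures measures mask geometry", {
  tr <- fieldTruth(fieldSize = testField, seed = 91)
  bf <- renderBrightfield(tr, noiseSD = 0.02, seed = 92)
  plt <- segmentPlatelets(bf)
  agg <- segmentAggregates(bf, plt)
  f <- extractFeatures(bf, plt, agg)
  expect_s4_class(f, "MorphologyFeatures")
  expect_gt(f@nObjects, 0L)
  expect_true(f@aggregateAreaFraction >= 0 && f@aggregateAreaFraction <= 1)
  expect_true(is.na(f@meanSolidityLarge) ||
                (f@meanSolidityLarge > 0 && f@meanSolidityLarge <= 1))
  truthF <- thromboflow:::.shapeFeatures(
    truthMasks(tr)$platelet, truthMasks(tr)$aggregate,
    truthMasks(tr)$multilayer, tr@pixelSize, tr@minAggregateArea)
  expect_lt(abs(f@aggregateAreaFraction - truthF@aggregateAreaFraction), 0.05)
})

test_that("measured scores reproduce the generator's intended tiers", {
  for (seed in c(101, 102)) {
    tr <- fieldTruth(fieldSize = c(512L, 680L), seed = seed)
    bf <- renderBrightfield(tr, noiseSD = 0.02, seed = seed + 1000)
    mb <- measureBrightfield(bf)
    expect_identical(as.integer(round(mb[c("P3", "P4", "P5")])),
                     unname(tr@intendedScores), label = paste("seed", seed))
  }
})
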