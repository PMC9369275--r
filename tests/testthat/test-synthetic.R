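test_that("ground truth obeys the mask hierarchy invariants", {
  tr <- fieldTruth(fieldSize = testField, seed = 201)
  m <- truthMasks(tr)
  expect_true(all(m$platelet[m$aggregate]))
  expect_true(all(m$platelet[m$multilayer]))
  for (ch in names(m$channels))
    expect_true(all(m$platelet[m$channels[[ch]]]), label = ch)
  expect_lte(tr@aggregateFraction, tr@plateletFraction)
  expect_true(all(tr@channelFractions <= tr@plateletFraction))
  # recorded fractions are the pixel-counted values of the recorded geometry
  expect_equal(tr@plateletFraction, mean(m$platelet))
  expect_equal(tr@aggregateFraction, mean(m$aggregate))
  expect_identical(names(tr@channelFractions),
                   c("PS", "P-selectin", "fibrinogen"))
  expect_identical(length(tr@intendedScores), 3L)
})

test_that("achieved coverage tracks the requested targets", {
  tr <- fieldTruth(plateletFraction = 0.3, aggregateFraction = 0.1,
                   fieldSize = testField, seed = 211)
  expect_lt(abs(tr@plateletFraction - 0.3), 0.02)
  expect_lt(abs(tr@aggregateFraction - 0.1), 0.02)
  lo <- fieldTruth(plateletFraction = 0.08, aggregateFraction = 0.02,
                   channelFractions = c(PS = 0.01, `P-selectin` = 0.03,
                                        fibrinogen = 0.02),
                   fieldSize = testField, seed = 212)
  expect_lt(abs(lo@plateletFraction - 0.08), 0.02)
  expect_error(fieldTruth(plateletFraction = 1.2), "\\[0, 1\\]")
})

test_that("field generation is seed-deterministic", {
  a <- fieldTruth(fieldSize = testField, seed = 221)
  b <- fieldTruth(fieldSize = testField, seed = 221)
  c <- fieldTruth(fieldSize = testField, seed = 222)
  expect_identical(a@discTable, b@discTable)
  expect_identical(a@intendedScores, b@intendedScores)
  expect_false(identical(a@discTable, c@discTable))
})

test_that("rendering is deterministic and bounded", {
  tr <- fieldTruth(fieldSize = testField, seed = 231)
  b1 <- renderBrightfield(tr, noiseSD = 0.02, seed = 7)
  b2 <- renderBrightfield(tr, noiseSD = 0.02, seed = 7)
  b3 <- renderBrightfield(tr, noiseSD = 0.02, seed = 8)
  expect_identical(b1@pixels, b2@pixels)
  expect_false(identical(b1@pixels, b3@pixels))
  expect_true(all(b1@pixels >= 0 & b1@pixels <= 1))
  f1 <- renderFluorescence(tr, "P-selectin", noiseSD = 0.02, seed = 7)
  expect_true(all(f1@pixels >= 0 & f1@pixels <= 1))
  expect_identical(f1@channel, "P-selectin")
  # brightfield deposits are darker, fluorescence signal brighter
  plt <- truthMasks(tr)$platelet
  expect_lt(mean(b1@pixels[plt]), mean(b1@pixels[!plt]))
  ps <- truthMasks(tr)$channels[["P-selectin"]]
  expect_gt(mean(f1@pixels[ps]), mean(f1@pixels[!ps]))
})

test_that("condition specs validate multiplier names and shear coverage", {
  cs <- conditionSpec("pep", multipliers = c(seeding = 0.6))
  expect_s4_class(cs, "ConditionSpec")
  expect_error(conditionSpec("bad", multipliers = c(foo = 2)), "unknown")
  expect_error(experimentDesign(
    shearRates = c(1000, 150),
    conditions = list(conditionSpec("control", shearRates = 1000))),
    "shear")
  expect_warning(experimentDesign(donors = 2), "donors")
  expect_error(suppressWarnings(experimentDesign(donors = 1)), "donors|2")
})

test_that("generated experiments have the designed shape and determinism", {
  des <- suppressWarnings(experimentDesign(
    donors = 2, runsPerCondition = 1, microspots = "collagen-I",
    shearRates = 1000,
    conditions = list(conditionSpec("control", shearRates = 1000)),
    imagesBrightfield = 1, imagesFluorescence = 1,
    fieldSize = c(128L, 96L), seed = 9))
  exp1 <- generateExperiment(des)
  # per field: 1 brightfield image + 3 channels per fluorescence field
  expect_identical(nrow(exp1@images), 2L * 1L * 1L * 1L * (1L + 3L))
  expect_identical(length(exp1@truths),
                   length(unique(exp1@images$truthId)))
  gt <- exp1@groundTruthTable
  expect_true(all(c("donor", "condition", "plateletFraction") %in% names(gt)))
  exp2 <- generateExperiment(des)
  expect_identical(exp1@groundTruthTable, exp2@groundTruthTable)
  expect_identical(exp1@images$imageSeed, exp2@images$imageSeed)
})

test_that("condition multipliers shift the generated ground truth", {
  des <- experimentDesign(
    donors = 3, runsPerCondition = 1, microspots = "collagen-I",
    shearRates = 1000,
    conditions = list(
      conditionSpec("control", shearRates = 1000),
      conditionSpec("inhibitor", multipliers = c(seeding = 0.5),
                    shearRates = 1000)),
    imagesBrightfield = 1, imagesFluorescence = 1,
    fieldSize = c(128L, 96L), seed = 10)
  exp <- generateExperiment(des)
  gt <- exp@groundTruthTable
  ctl <- mean(gt$plateletFraction[gt$condition == "control"])
  inh <- mean(gt$plateletFraction[gt$condition == "inhibitor"])
  expect_lt(inh, ctl)
  expect_lt(abs(inh / ctl - 0.5), 0.2)
})

test_that("simulateDonorValues produces a paired no-effect/effect layout", {
  sim <- simulateDonorValues(nDonors = 4, effect = 1, seed = 301)
  expect_s3_class(sim, "data.frame")
  expect_identical(nrow(sim), 4L)
  expect_identical(names(sim), c("donor", "control", "treated"))
  sim2 <- simulateDonorValues(nDonors = 4, effect = 1, seed = 301)
  expect_identical(sim, sim2)
  eff <- simulateDonorValues(nDonors = 50, effect = 0.5, seed = 302)
  expect_lt(mean(eff$treated), mean(eff$control))
})
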