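test_that("image-to-run averaging respects parameter provenance", {
  img <- data.frame(
    role = c("brightfield", "brightfield", "fluorescence"),
    P1 = c(30, 34, NA), P2 = c(10, 12, NA), P3 = c(4, 5, NA),
    P4 = c(2, 2, NA), P5 = c(3, 2, NA),
    P6 = c(NA, NA, 6), P7 = c(NA, NA, 15), P8 = c(NA, NA, 10))
  run <- averageImagesToRun(img)
  expect_equal(run$P1, 32)
  expect_equal(run$P3, 4.5)   # discrete scores become fractional
  expect_equal(run$P6, 6)
  expect_identical(run$nBrightfield, 2L)
  # a parameter with no contributing image is NA, never zero
  noFl <- averageImagesToRun(img[img$role == "brightfield", ])
  expect_true(is.na(noFl$P6))
  expect_equal(noFl$P1, 32)
})

test_that("run-to-donor averaging refuses mixed keys", {
  runs <- data.frame(donor = "d1", condition = c("a", "b"),
                     microspot = "m", shear_s1 = 1000,
                     P1 = c(1, 2), P2 = 0, P3 = 0, P4 = 0, P5 = 0,
                     P6 = 0, P7 = 0, P8 = 0)
  expect_error(averageRunsToDonor(runs), "mixed")
  one <- runs[runs$condition == "a", ]
  one2 <- rbind(one, one)
  one2$P1 <- c(10, 20)
  out <- averageRunsToDonor(one2)
  expect_equal(out$P1, 15)
  expect_identical(out$nRuns, 2L)
  expect_error(averageRunsToDonor(one2[, setdiff(names(one2), "donor")]),
               "missing key")
})

test_that("summarize helpers are order-invariant", {
  set.seed(3)
  img <- expand.grid(donor = c("d1", "d2"), condition = c("ctrl", "trt"),
                     microspot = "m", shear_s1 = 1000, run = 1:2,
                     role = "brightfield", stringsAsFactors = FALSE)
  for (p in paste0("P", 1:5)) img[[p]] <- runif(nrow(img), 0, 50)
  for (p in paste0("P", 6:8)) img[[p]] <- NA_real_
  a <- summarizeImagesToRuns(img)
  b <- summarizeImagesToRuns(img[sample(nrow(img)), ])
  expect_equal(a, b)
  da <- summarizeRunsToDonors(a)
  expect_equal(nrow(da), 4)  # 2 donors x 2 conditions
  expect_identical(unique(da$nRuns), 2L)
})

test_that("univariate scaling maps the frame to [0, 10]", {
  s <- scaleUnivariate(c(2, 4, 6))
  expect_equal(s$values, c(0, 5, 10))
  expect_equal(s$frame, c(2, 6))
  expect_warning(z <- scaleUnivariate(c(3, 3, 3)), "constant")
  expect_equal(z$values, c(0, 0, 0))
  # fixed frame: the assay reference range for platelet adhesion
  f <- scaleUnivariate(35.85, mode = "fixed", frame = c(0, 71.7))
  expect_equal(f$values, 5)
  expect_warning(cl <- scaleUnivariate(c(-5, 80), mode = "fixed",
                                       frame = c(0, 71.7)), "clipped")
  expect_equal(cl$values, c(0, 10))
  expect_error(scaleUnivariate(1, mode = "fixed"), "frame")
})

test_that("matrix scaling and cumulative sums honour the 0-80 bound", {
  m <- matrix(c(2, 4, 6), 3, 8, dimnames = list(c("a", "b", "c"),
                                                paste0("P", 1:8)))
  sm <- scaleMatrix(m)
  expect_s4_class(sm, "ScaledMatrix")
  expect_true(all(sm@values >= 0 & sm@values <= 10))
  cs <- cumulativeScaled(sm)
  expect_equal(unname(cs["c"]), 80)  # maximal condition saturates the bound
  expect_equal(unname(cs["a"]), 0)
  expect_true(all(cs >= 0 & cs <= 80))
  v <- stats::setNames(rep(10, 8), paste0("P", 1:8))
  expect_equal(cumulativeScaled(v), 80)
  expect_error(cumulativeScaled(v[-3]), "P3")
  # fixed mode needs a frame for every parameter
  expect_error(scaleMatrix(matrix(1, 1, 1, dimnames = list("a", "PX")),
                           mode = "fixed"), "PX")
})

test_that("paired t-test matches the closed form and stats::t.test", {
  r <- pairedTTest(c(0, 0, 0), c(1, 2, 3))
  expect_equal(r@tStatistic, 2 * sqrt(3), tolerance = 1e-6)  # 3.4641
  expect_equal(r@df, 2)
  expect_equal(r@pValue, 2 * stats::pt(-2 * sqrt(3), df = 2),
               tolerance = 1e-9)
  expect_equal(r@meanDifference, 2)

  set.seed(11)
  x <- rnorm(8, 10); y <- rnorm(8, 11)
  ours <- pairedTTest(x, y)
  ref <- stats::t.test(y, x, paired = TRUE)
  expect_equal(ours@tStatistic, unname(ref$statistic))
  expect_equal(ours@pValue, ref$p.value)

  z <- pairedTTest(c(5, 6, 7), c(5, 6, 7))
  expect_equal(z@tStatistic, 0)
  expect_equal(z@pValue, 1)
  expect_warning(inf <- pairedTTest(c(1, 2), c(2, 3)), "infinite")
  expect_equal(inf@pValue, 0)

  expect_error(pairedTTest(1, 2), "at least 2")
  expect_error(pairedTTest(c(a = 1, b = 2), c(b = 2, a = 3)), "misaligned")
  expect_error(pairedTTest(c(1, NA), c(2, 3)), "complete")
})

test_that("subtraction heatmap filters by significance", {
  set.seed(21)
  donors <- paste0("d", 1:4)
  mk <- function(cond, shift) {
    df <- data.frame(donor = donors, condition = cond, microspot = "m",
                     shear_s1 = 1000)
    for (p in paste0("P", 1:8)) df[[p]] <- rnorm(4, 20, 0.5)
    df$P1 <- df$P1 + shift    # strong real effect on P1 only
    df
  }
  ds <- rbind(mk("control", 0), mk("treated", -12))
  hm <- subtractionHeatmap(ds, control = "control")
  expect_s4_class(hm, "SubtractionHeatmap")
  expect_true(hm@significant["treated", "P1"])
  expect_lt(hm@delta["treated", "P1"], 0)
  tab <- as.data.frame(hm)
  expect_identical(nrow(tab), 8L)
  expect_true(all(c("condition", "parameter", "delta", "pValue",
                    "significant") %in% names(tab)))
  # BH adjustment can only reduce the significant set
  hmBH <- subtractionHeatmap(ds, control = "control", adjust = "BH")
  expect_true(all(hm@significant | !hmBH@significant))
  expect_error(subtractionHeatmap(ds, control = "nope"), "not found")
})
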