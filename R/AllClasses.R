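#' @import methods
NULL

.CHANNELS <- c("brightfield", "PS", "P-selectin", "fibrinogen")
.FLUOR_CHANNELS <- c("PS", "P-selectin", "fibrinogen")
.PARAMS <- paste0("P", 1:8)

#' Single-channel microscopy image
#'
#' A grayscale pixel grid with a channel tag and a physical pixel size.
#' Intensities are on an arbitrary non-negative scale; images read from
#' 8/16-bit TIFF are mapped to \[0, 1\].
#'
#' @slot pixels Numeric matrix of non-negative, finite intensities; rows are
#'   image rows (top to bottom), columns are image columns (left to right),
#'   origin at the top-left pixel.
#' @slot channel One of `"brightfield"`, `"PS"`, `"P-selectin"`,
#'   `"fibrinogen"`.
#' @slot pixelSize Pixel edge length in micrometres per pixel.
#' @export
setClass("IntensityImage",
  representation(pixels = "matrix", channel = "character",
                 pixelSize = "numeric"),
  validity = function(object) {
    p <- object@pixels
    if (length(p) == 0L) return("pixel grid is empty")
    if (!is.numeric(p)) return("pixels must be numeric")
    if (any(!is.finite(p))) return("pixel intensities must be finite")
    if (any(p < 0)) return("pixel intensities must be non-negative")
    if (length(object@channel) != 1L || !object@channel %in% .CHANNELS)
      return(sprintf("channel must be one of: %s",
                     paste(.CHANNELS, collapse = ", ")))
    if (length(object@pixelSize) != 1L || !is.finite(object@pixelSize) ||
        object@pixelSize <= 0)
      return("pixelSize must be a single positive number")
    TRUE
  })

#' Binary segmentation mask
#'
#' A logical pixel grid with the same shape as the image it was derived
#' from, plus a provenance tag naming the operation that produced it.
#'
#' @slot pixels Logical matrix.
#' @slot provenance Character scalar, e.g. `"segmentPlatelets"`.
#' @export
setClass("BinaryMask",
  representation(pixels = "matrix", provenance = "character"),
  validity = function(object) {
    if (!is.logical(object@pixels)) return("mask pixels must be logical")
    if (length(object@pixels) == 0L) return("mask is empty")
    if (anyNA(object@pixels)) return("mask must not contain NA")
    TRUE
  })

#' Per-field synthetic ground truth
#'
#' Records what a synthetic microscopy field truly contains: pixel-counted
#' coverage fractions, the object geometry (every platelet is a disc; an
#' aggregate is a cluster of discs with an optional darker multilayer core),
#' per-channel positive sub-regions, and the score triple implied by the
#' default rubric. All masks are reconstructed deterministically from
#' `discTable`, so rendering with different noise seeds reuses an identical
#' underlying geometry.
#'
#' @slot plateletFraction Fraction of field pixels covered by platelets.
#' @slot aggregateFraction Fraction of field pixels in multilayered
#'   aggregates (connected platelet components above the minimum aggregate
#'   area that contain multilayer pixels).
#' @slot multilayerFraction Multilayer pixels as a fraction of platelet
#'   pixels.
#' @slot channelFractions Named fraction of field pixels positive per
#'   fluorescence channel (`PS`, `P-selectin`, `fibrinogen`).
#' @slot discTable One row per rendered disc: object id, type, centre
#'   (row/col), radius, multilayer core radius, and per-channel positive
#'   sub-radius (all in pixels).
#' @slot objectTable One row per placed object: centroid, equivalent radius
#'   in micrometres, layer count, solidity.
#' @slot intendedScores Integer triple (morphology, multilayer, contraction)
#'   obtained by applying the default rubric to the noise-free masks.
#' @slot fieldSize Integer c(rows, cols).
#' @slot pixelSize Micrometres per pixel.
#' @slot minAggregateArea Minimum aggregate area (square micrometres) used
#'   when deriving the aggregate mask.
#' @export
setClass("GroundTruth",
  representation(plateletFraction = "numeric", aggregateFraction = "numeric",
                 multilayerFraction = "numeric", channelFractions = "numeric",
                 discTable = "data.frame", objectTable = "data.frame",
                 intendedScores = "integer", fieldSize = "integer",
                 pixelSize = "numeric", minAggregateArea = "numeric"),
  validity = function(object) {
    fr <- c(object@plateletFraction, object@aggregateFraction,
            object@channelFractions)
    if (any(fr < 0 | fr > 1)) return("all coverage fractions must be in [0, 1]")
    if (object@multilayerFraction < 0 || object@multilayerFraction > 1)
      return("multilayerFraction must be in [0, 1]")
    if (object@aggregateFraction > object@plateletFraction + 1e-12)
      return("aggregateFraction cannot exceed plateletFraction")
    if (any(object@channelFractions > object@plateletFraction + 1e-12))
      return("channel fractions cannot exceed plateletFraction")
    if (!identical(sort(names(object@channelFractions)),
                   sort(.FLUOR_CHANNELS)))
      return("channelFractions must be named PS, P-selectin, fibrinogen")
    if (length(object@fieldSize) != 2L || any(object@fieldSize < 1L))
      return("fieldSize must be two positive integers")
    if (length(object@intendedScores) != 3L)
      return("intendedScores must be an integer triple")
    TRUE
  })

#' Condition specification for the synthetic generator
#'
#' Encodes a treatment as multiplicative factors on the generative
#' intensities, one factor set per wall-shear rate. Factor names:
#' `seeding` (platelet seeding density), `aggregate` (aggregate coverage),
#' `multilayer` (multilayer fraction within aggregates), and one per
#' fluorescence channel (`PS`, `P-selectin`, `fibrinogen`).
#'
#' @slot name Condition label.
#' @slot multipliers Numeric matrix, rows named by shear rate (as character),
#'   columns `seeding`, `aggregate`, `multilayer`, `PS`, `P-selectin`,
#'   `fibrinogen`; all entries >= 0.
#' @slot donorSD Standard deviation of the per-donor lognormal random effect
#'   (log scale).
#' @slot noiseSD Pixel-noise standard deviation on the \[0, 1\] intensity
#'   scale.
#' @export
setClass("ConditionSpec",
  representation(name = "character", multipliers = "matrix",
                 donorSD = "numeric", noiseSD = "numeric"),
  validity = function(object) {
    m <- object@multipliers
    want <- c("seeding", "aggregate", "multilayer", .FLUOR_CHANNELS)
    if (!identical(colnames(m), want))
      return(sprintf("multiplier columns must be: %s",
                     paste(want, collapse = ", ")))
    if (any(m < 0)) return("multipliers must be >= 0")
    if (is.null(rownames(m))) return("multiplier rows must be named by shear rate")
    if (object@donorSD < 0 || object@noiseSD < 0)
      return("donorSD and noiseSD must be >= 0")
    TRUE
  })

#' Design of a synthetic flow experiment
#'
#' Mirrors the study design of a microfluidic thrombus-formation assay:
#' several donors, duplicate runs per condition, a set of collagen
#' microspots, and one or more wall-shear rates; per run a fixed number of
#' brightfield fields and of multicolour fluorescence fields.
#'
#' @slot donors Number of donors (>= 2; a warning is issued below 3).
#' @slot runsPerCondition Duplicate runs per condition.
#' @slot microspots Character vector of collagen labels.
#' @slot shearRates Wall-shear rates in 1/s.
#' @slot conditions List of [ConditionSpec-class]; the first with all-unit
#'   multipliers is treated as the control.
#' @slot imagesBrightfield Brightfield fields captured per run.
#' @slot imagesFluorescence Multicolour fluorescence fields per run.
#' @slot fieldSize Integer c(rows, cols) of each field.
#' @slot pixelSize Micrometres per pixel.
#' @slot seed Integer seed; the full experiment is reproducible from
#'   (design, seed).
#' @export
setClass("ExperimentDesign",
  representation(donors = "integer", runsPerCondition = "integer",
                 microspots = "character", shearRates = "numeric",
                 conditions = "list", imagesBrightfield = "integer",
                 imagesFluorescence = "integer", fieldSize = "integer",
                 pixelSize = "numeric", seed = "integer"),
  validity = function(object) {
    cnt <- c(object@donors, object@runsPerCondition,
             object@imagesBrightfield, object@imagesFluorescence)
    if (any(cnt < 1L)) return("all counts must be positive")
    if (object@donors < 2L)
      return("at least 2 donors are required for paired comparisons")
    if (length(object@conditions) < 1L)
      return("at least one condition is required")
    if (!all(vapply(object@conditions, is, logical(1), "ConditionSpec")))
      return("conditions must be ConditionSpec objects")
    if (any(object@shearRates <= 0)) return("shear rates must be positive")
    for (cs in object@conditions) {
      if (!all(as.character(object@shearRates) %in% rownames(cs@multipliers)))
        return(sprintf(
          "condition '%s' lacks multipliers for every design shear rate",
          cs@name))
    }
    if (length(object@fieldSize) != 2L || any(object@fieldSize < 16L))
      return("fieldSize must be two integers >= 16")
    TRUE
  })

#' Scoring rubric configuration
#'
#' Cut-points turning morphology features into the discrete thrombus scores:
#' morphology (0-5), multilayer (0-3), contraction (0-3). A value equal to a
#' cut-point takes the higher tier. All cut-point vectors must be strictly
#' increasing.
#'
#' @slot sacFloor Platelet adhesion (%SAC) below which the field counts as
#'   essentially platelet-free and scores (0, 0, 0).
#' @slot aggregateCuts Two increasing cut-points on the aggregate area
#'   fraction (aggregate pixels / platelet pixels) separating moderate and
#'   extensive aggregation tiers of the morphology score.
#' @slot multilayerCuts Three increasing cut-points on the multilayer area
#'   fraction (multilayer pixels / platelet pixels) defining multilayer
#'   tiers 1-3.
#' @slot solidityCuts Three increasing cut-points on the mean solidity of
#'   large objects defining contraction tiers 1-3.
#' @slot topMultilayer Multilayer fraction and
#' @slot topSolidity solidity required (jointly, with the upper aggregate
#'   cut) for the maximal morphology tier 5: a large, contracted,
#'   multilayered aggregate field.
#' @export
setClass("RubricConfig",
  representation(sacFloor = "numeric", aggregateCuts = "numeric",
                 multilayerCuts = "numeric", solidityCuts = "numeric",
                 topMultilayer = "numeric", topSolidity = "numeric"),
  validity = function(object) {
    mono <- function(x) length(x) > 0 && !is.unsorted(x, strictly = TRUE)
    if (object@sacFloor < 0) return("sacFloor must be >= 0")
    if (length(object@aggregateCuts) != 2L || !mono(object@aggregateCuts))
      return("aggregateCuts must be 2 strictly increasing values")
    if (length(object@multilayerCuts) != 3L || !mono(object@multilayerCuts))
      return("multilayerCuts must be 3 strictly increasing values")
    if (length(object@solidityCuts) != 3L || !mono(object@solidityCuts))
      return("solidityCuts must be 3 strictly increasing values")
    if (any(c(object@aggregateCuts, object@multilayerCuts) < 0) ||
        any(c(object@aggregateCuts, object@multilayerCuts) > 1))
      return("fraction cut-points must lie in [0, 1]")
    if (any(object@solidityCuts <= 0) || any(object@solidityCuts > 1))
      return("solidity cut-points must lie in (0, 1]")
    TRUE
  })

#' Result of a paired comparison
#'
#' @slot tStatistic Paired Student t statistic on the per-donor differences.
#' @slot df Degrees of freedom (number of pairs minus one).
#' @slot pValue Two-sided p-value.
#' @slot nPairs Number of donor pairs.
#' @slot meanDifference Mean of (treated - control) differences.
#' @export
setClass("ComparisonResult",
  representation(tStatistic = "numeric", df = "numeric", pValue = "numeric",
                 nPairs = "integer", meanDifference = "numeric"),
  validity = function(object) {
    if (object@nPairs < 2L) return("a paired comparison needs >= 2 pairs")
    if (object@df != object@nPairs - 1L) return("df must equal nPairs - 1")
    if (!is.na(object@pValue) && (object@pValue < 0 || object@pValue > 1))
      return("pValue must lie in [0, 1]")
    TRUE
  })

#' Univariate 0-10 scaled condition-by-parameter matrix
#'
#' @slot values Numeric matrix, conditions in rows, parameters (P1-P8) in
#'   columns, every entry in \[0, 10\].
#' @slot frame Data frame with the per-parameter `min` and `max` mapped to 0
#'   and 10.
#' @slot mode `"dataset"` (frame taken from the data) or `"fixed"`
#'   (caller-supplied frame, e.g. the assay's reference ranges).
#' @slot microspot,shearRate Grouping labels the matrix belongs to (may be
#'   `NA`).
#' @export
setClass("ScaledMatrix",
  representation(values = "matrix", frame = "data.frame", mode = "character",
                 microspot = "character", shearRate = "numeric"),
  validity = function(object) {
    v <- object@values
    if (any(v < -1e-9 | v > 10 + 1e-9, na.rm = TRUE))
      return("scaled values must lie in [0, 10]")
    if (!all(c("parameter", "min", "max") %in% names(object@frame)))
      return("frame needs columns parameter, min, max")
    TRUE
  })

#' Significance-filtered subtraction heatmap
#'
#' Control-subtracted 0-10 scaled parameter values per condition, with a
#' matching grid of paired-test p-values and a boolean significance mask
#' (p below the filter threshold). Masked (non-significant) cells keep their
#' raw delta in the export table; only the rendering neutralises them.
#'
#' @slot delta Numeric matrix (condition x parameter) of scaled differences
#'   versus the control, in \[-10, 10\].
#' @slot pValue Matching matrix of two-sided paired-test p-values.
#' @slot significant Logical matrix, `TRUE` where `pValue < alpha`.
#' @slot alpha Significance filter threshold (default 0.05).
#' @slot control Name of the control condition.
#' @slot frame Scaling frame used (per-parameter min/max).
#' @slot microspot,shearRate Grouping labels.
#' @export
setClass("SubtractionHeatmap",
  representation(delta = "matrix", pValue = "matrix", significant = "matrix",
                 alpha = "numeric", control = "character", frame = "data.frame",
                 microspot = "character", shearRate = "numeric"),
  validity = function(object) {
    if (!identical(dim(object@delta), dim(object@pValue)) ||
        !identical(dim(object@delta), dim(object@significant)))
      return("delta, pValue and significant must have identical dimensions")
    if (any(object@delta < -10 - 1e-9 | object@delta > 10 + 1e-9, na.rm = TRUE))
      return("deltas must lie in [-10, 10]")
    if (object@alpha <= 0 || object@alpha >= 1)
      return("alpha must lie in (0, 1)")
    ok <- object@significant == (object@pValue < object@alpha)
    if (any(!ok[!is.na(object@pValue)]))
      return("significant must equal (pValue < alpha)")
    TRUE
  })

#' Parsed peptide sequence
#'
#' @slot residues Character vector of one-letter codes (standard 20 amino
#'   acids, upper case).
#' @slot nTerm `"free"` or `"acetyl"`.
#' @slot cTerm `"acid"` (free carboxylic acid) or `"amide"`.
#' @export
setClass("PeptideSequence",
  representation(residues = "character", nTerm = "character",
                 cTerm = "character"),
  validity = function(object) {
    if (length(object@residues) == 0L) return("peptide must be non-empty")
    bad <- !object@residues %in% names(.RESIDUE_MASS)
    if (any(bad))
      return(sprintf("unknown residue '%s' at position %d",
                     object@residues[which(bad)[1]], which(bad)[1]))
    if (!object@nTerm %in% c("free", "acetyl")) return("invalid nTerm")
    if (!object@cTerm %in% c("acid", "amide")) return("invalid cTerm")
    TRUE
  })

setMethod("show", "IntensityImage", function(object) {
  cat(sprintf("IntensityImage: %d x %d px, channel '%s', %.3g um/px\n",
              nrow(object@pixels), ncol(object@pixels), object@channel,
              object@pixelSize))
  cat(sprintf("  intensity range [%.4g, %.4g]\n",
              min(object@pixels), max(object@pixels)))
})

setMethod("show", "BinaryMask", function(object) {
  cat(sprintf("BinaryMask: %d x %d px, %.2f%% positive (from %s)\n",
              nrow(object@pixels), ncol(object@pixels),
              100 * mean(object@pixels), object@provenance))
})

setMethod("show", "GroundTruth", function(object) {
  cat(sprintf("GroundTruth: %d x %d px field (%.3g um/px)\n",
              object@fieldSize[1], object@fieldSize[2], object@pixelSize))
  cat(sprintf("  platelet %.2f%%, aggregate %.2f%%, multilayer %.2f%% of platelet\n",
              100 * object@plateletFraction, 100 * object@aggregateFraction,
              100 * object@multilayerFraction))
  cat(sprintf("  channels (%% field): %s\n",
              paste(sprintf("%s %.2f", names(object@channelFractions),
                            100 * object@channelFractions), collapse = ", ")))
  cat(sprintf("  %d objects, intended scores (%s)\n", nrow(object@objectTable),
              paste(object@intendedScores, collapse = ", ")))
})

setMethod("show", "ExperimentDesign", function(object) {
  cat(sprintf(paste0("ExperimentDesign: %d donors x %d runs x %d microspots",
                     " x %d shear rates x %d conditions\n"),
              object@donors, object@runsPerCondition,
              length(object@microspots), length(object@shearRates),
              length(object@conditions)))
  cat(sprintf("  %d brightfield + %d fluorescence fields per run, %d x %d px\n",
              object@imagesBrightfield, object@imagesFluorescence,
              object@fieldSize[1], object@fieldSize[2]))
})

setMethod("show", "ComparisonResult", function(object) {
  cat(sprintf("Paired t: t = %.4f, df = %d, p = %.4g (n = %d, mean diff %.4g)\n",
              object@tStatistic, as.integer(object@df), object@pValue,
              object@nPairs, object@meanDifference))
})

setMethod("show", "SubtractionHeatmap", function(object) {
  cat(sprintf("SubtractionHeatmap vs '%s' (alpha = %g)", object@control,
              object@alpha))
  if (!is.na(object@microspot))
    cat(sprintf(" [%s, %g /s]", object@microspot, object@shearRate))
  cat("\n")
  cat(sprintf("  %d condition(s) x %d parameter(s), %d significant cell(s)\n",
              nrow(object@delta), ncol(object@delta),
              sum(object@significant, na.rm = TRUE)))
})

setMethod("show", "PeptideSequence", function(object) {
  cat(sprintf("PeptideSequence: %s (%d aa), N-term %s, C-term %s\n",
              paste(object@residues, collapse = ""), length(object@residues),
              object@nTerm, object@cTerm))
})
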