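#' @include AllClasses.R segmentation.R
NULL

#' Morphology features of a segmented thrombus field
#'
#' Measurable quantities from which the discrete thrombus scores are
#' derived.
#'
#' @slot nObjects Number of connected platelet components.
#' @slot largestObjectArea Area of the largest platelet component (square
#'   micrometres).
#' @slot aggregateAreaFraction Aggregate pixels / platelet pixels.
#' @slot multilayerAreaFraction Multilayer-tier pixels / platelet pixels.
#' @slot meanSolidityLarge Mean solidity (component area / convex-hull area)
#'   over aggregate components above the minimum aggregate area; `NA` when
#'   there is none.
#' @export
setClass("MorphologyFeatures",
  representation(nObjects = "integer", largestObjectArea = "numeric",
                 aggregateAreaFraction = "numeric",
                 multilayerAreaFraction = "numeric",
                 meanSolidityLarge = "numeric"),
  validity = function(object) {
    fr <- c(object@aggregateAreaFraction, object@multilayerAreaFraction)
    if (any(fr < 0 | fr > 1)) return("area fractions must lie in [0, 1]")
    s <- object@meanSolidityLarge
    if (!is.na(s) && (s <= 0 || s > 1)) return("solidity must lie in (0, 1]")
    if (object@nObjects < 0L) return("nObjects must be >= 0")
    TRUE
  })

setMethod("show", "MorphologyFeatures", function(object) {
  cat(sprintf(paste0("MorphologyFeatures: %d objects, largest %.1f um^2, ",
                     "aggregate %.3f, multilayer %.3f, solidity %s\n"),
              object@nObjects, object@largestObjectArea,
              object@aggregateAreaFraction, object@multilayerAreaFraction,
              ifelse(is.na(object@meanSolidityLarge), "NA",
                     sprintf("%.3f", object@meanSolidityLarge))))
})

# feature extraction from binary masks; shared by the measurement path
# (segmented masks) and the synthetic generator (noise-free truth masks)
.shapeFeatures <- function(plt, agg, ml, pixelSize, minAggregateArea = 20) {
  pxArea <- pixelSize^2
  nPlt <- sum(plt)
  if (nPlt == 0L)
    return(new("MorphologyFeatures", nObjects = 0L, largestObjectArea = 0,
               aggregateAreaFraction = 0, multilayerAreaFraction = 0,
               meanSolidityLarge = NA_real_))
  lab <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(plt)))
  sizes <- tabulate(as.integer(lab))
  sol <- NA_real_
  if (any(agg)) {
    alab <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(agg)))
    alabv <- as.integer(alab)
    asizes <- tabulate(alabv)
    big <- which(asizes * pxArea >= minAggregateArea)
    if (length(big) > 0L) {
      H <- nrow(plt)
      idx <- which(alabv %in% big)
      rows <- ((idx - 1L) %% H) + 1L
      cols <- ((idx - 1L) %/% H) + 1L
      sol <- mean(vapply(big, function(b) {
        sel <- alabv[idx] == b
        .solidity(rows[sel], cols[sel])
      }, numeric(1)))
    }
  }
  new("MorphologyFeatures",
      nObjects = length(sizes[sizes > 0L]),
      largestObjectArea = max(sizes) * pxArea,
      aggregateAreaFraction = sum(agg) / nPlt,
      multilayerAreaFraction = sum(ml & plt) / nPlt,
      meanSolidityLarge = sol)
}

#' Extract morphology features from a brightfield image and its masks
#'
#' @param image Brightfield [IntensityImage-class].
#' @param plateletMask,aggregateMask [BinaryMask-class] objects from
#'   [segmentPlatelets()] and [segmentAggregates()] on the same image.
#' @param pixelSize Micrometres per pixel (defaults to the image's).
#' @param minAggregateArea Minimum aggregate area in square micrometres.
#' @param multilayerFactor,multilayerOffset Multilayer-tier rule, as in
#'   [segmentAggregates()].
#' @param blurSigma,downsample,backgroundRadius Background-correction
#'   settings, as in [segmentPlatelets()].
#' @return A [MorphologyFeatures-class] object.
#' @export
extractFeatures <- function(image, plateletMask, aggregateMask,
                            pixelSize = NULL, minAggregateArea = 20,
                            multilayerFactor = 1.4, multilayerOffset = NULL,
                            blurSigma = 40, downsample = 8,
                            backgroundRadius = 64) {
  stopifnot(is(image, "IntensityImage"), is(plateletMask, "BinaryMask"),
            is(aggregateMask, "BinaryMask"))
  if (!identical(dim(image@pixels), dim(plateletMask@pixels)) ||
      !identical(dim(image@pixels), dim(aggregateMask@pixels)))
    stop("image and mask dimensions do not match")
  if (is.null(pixelSize)) pixelSize <- image@pixelSize
  plt <- plateletMask@pixels
  corr <- .correctBackground(image@pixels, "dark", blurSigma, downsample,
                             backgroundRadius)
  ml <- .multilayerPixels(corr, plt, multilayerFactor, multilayerOffset)
  .shapeFeatures(plt, aggregateMask@pixels, ml, pixelSize, minAggregateArea)
}

#' Scoring rubric with documented default cut-points
#'
#' Defaults are calibrated against the synthetic generator's geometry so
#' that its intended score tiers are reproduced on noise-free fields; they
#' are fully exposed here and serialisable through the pipeline
#' configuration. A feature value equal to a cut-point takes the higher
#' tier.
#'
#' @param sacFloor %SAC below which a field counts as essentially free of
#'   platelets and scores (0, 0, 0). Default 0.5%.
#' @param aggregateCuts Aggregate-area-fraction cut-points for morphology
#'   tiers 3 and 4.
#' @param multilayerCuts Multilayer-area-fraction cut-points for multilayer
#'   tiers 1-3.
#' @param solidityCuts Mean-solidity cut-points for contraction tiers 1-3.
#' @param topMultilayer,topSolidity Joint requirements (with the upper
#'   aggregate cut) for morphology tier 5.
#' @return A [RubricConfig-class].
#' @export
rubricConfig <- function(sacFloor = 0.5, aggregateCuts = c(0.11, 0.25),
                         multilayerCuts = c(0.04, 0.13, 0.21),
                         solidityCuts = c(0.70, 0.87, 0.94),
                         topMultilayer = 0.13, topSolidity = 0.87) {
  new("RubricConfig", sacFloor = sacFloor, aggregateCuts = aggregateCuts,
      multilayerCuts = multilayerCuts, solidityCuts = solidityCuts,
      topMultilayer = topMultilayer, topSolidity = topSolidity)
}

#' Assign the discrete thrombus scores from morphology features
#'
#' Deterministic rubric replacing visual comparison against reference
#' images: the morphology score (0-5) grows with the presence and extent of
#' aggregation and reaches its top tier only for extensively aggregated,
#' multilayered, contracted fields; the multilayer score (0-3) tiers the
#' multilayer area fraction; the contraction score (0-3) tiers the mean
#' solidity of large aggregates. A field whose platelet adhesion is below
#' the rubric floor scores (0, 0, 0); each score is monotone non-decreasing
#' in every feature.
#'
#' @param features A [MorphologyFeatures-class].
#' @param P1 Platelet adhesion (%SAC) of the same image.
#' @param rubric A [RubricConfig-class].
#' @return Named integer vector `c(morphology =, multilayer =,
#'   contraction =)`.
#' @export
scoreImage <- function(features, P1, rubric = rubricConfig()) {
  stopifnot(is(features, "MorphologyFeatures"), is(rubric, "RubricConfig"))
  validObject(rubric)
  if (P1 < rubric@sacFloor)
    return(c(morphology = 0L, multilayer = 0L, contraction = 0L))
  agg <- features@aggregateAreaFraction
  ml <- features@multilayerAreaFraction
  sol <- features@meanSolidityLarge
  solOK <- function(cut) !is.na(sol) && sol >= cut
  morph <- 1L + (agg > 0) + (agg >= rubric@aggregateCuts[1]) +
    (agg >= rubric@aggregateCuts[2]) +
    (agg >= rubric@aggregateCuts[2] && ml >= rubric@topMultilayer &&
       solOK(rubric@topSolidity))
  multi <- if (agg > 0) sum(ml >= rubric@multilayerCuts) else 0L
  contr <- if (agg > 0) sum(vapply(rubric@solidityCuts, solOK, logical(1)))
           else 0L
  c(morphology = min(5L, as.integer(morph)),
    multilayer = as.integer(multi), contraction = as.integer(contr))
}
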