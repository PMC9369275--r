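#' @include AllClasses.R scoring.R segmentation.R
NULL

# generative intensity tiers of the renderer, on the [0, 1] scale; the
# multilayer core of an aggregate is rendered darker than the monolayer by
# .BF_MULTILAYER_DROP (brightfield) and positive fluorescence regions
# brighter than background by .FL_SIGNAL
.BF_BACKGROUND <- 0.85
.BF_PLATELET_DROP <- 0.25
.BF_MULTILAYER_DROP <- 0.20
.FL_BACKGROUND <- 0.06
.FL_SIGNAL <- 0.50

# run-to-run and field-to-field lognormal jitter (log-scale sd) shared by
# all parameters of a run/field; deliberately run-dominated so that the
# eight parameters of one run co-vary, as repeated flow runs do
.RUN_SD <- 0.05
.IMG_SD <- 0.03

.MULT_NAMES <- c("seeding", "aggregate", "multilayer", .FLUOR_CHANNELS)

#' Specify a synthetic treatment condition
#'
#' A condition acts on the generator through multiplicative factors on the
#' generative intensities, one factor set per wall-shear rate: `seeding`
#' (platelet seeding density), `aggregate` (aggregate coverage),
#' `multilayer` (multilayer fraction within aggregates) and one factor per
#' fluorescence channel. The control condition has all factors equal to 1 at
#' every shear rate.
#'
#' @param name Condition label.
#' @param multipliers Either a named numeric vector applied at every shear
#'   rate, or a named list keyed by shear rate (as character) of named
#'   numeric vectors. Unnamed factors default to 1. Valid names:
#'   `seeding`, `aggregate`, `multilayer`, `PS`, `P-selectin`, `fibrinogen`.
#' @param shearRates Shear rates the condition must cover (1/s).
#' @param donorSD Log-scale SD of the per-donor lognormal random effect.
#' @param noiseSD Pixel-noise SD on the \[0, 1\] intensity scale.
#' @return A [ConditionSpec-class].
#' @examples
#' conditionSpec("control")
#' conditionSpec("inhibitor",
#'   multipliers = list(`1000` = c(seeding = 0.6), `150` = c(seeding = 1)))
#' @export
conditionSpec <- function(name, multipliers = numeric(0),
                          shearRates = c(1000, 150), donorSD = 0.15,
                          noiseSD = 0.02) {
  fill <- function(v) {
    out <- stats::setNames(rep(1, length(.MULT_NAMES)), .MULT_NAMES)
    if (length(v) > 0) {
      bad <- setdiff(names(v), .MULT_NAMES)
      if (length(bad) > 0)
        stop(sprintf("unknown multiplier name(s): %s",
                     paste(bad, collapse = ", ")))
      out[names(v)] <- v
    }
    out
  }
  keys <- as.character(shearRates)
  if (is.list(multipliers)) {
    rows <- lapply(keys, function(k) {
      fill(if (k %in% names(multipliers)) multipliers[[k]] else numeric(0))
    })
  } else {
    rows <- rep(list(fill(multipliers)), length(keys))
  }
  m <- do.call(rbind, rows)
  rownames(m) <- keys
  new("ConditionSpec", name = name, multipliers = m, donorSD = donorSD,
      noiseSD = noiseSD)
}

.isControlSpec <- function(cs) all(cs@multipliers == 1)

#' Design a synthetic flow experiment
#'
#' Defaults mirror a typical whole-blood microspot flow study: 3 donors,
#' duplicate runs per condition, three collagen microspots, arterial
#' (1000/s) and venous (150/s) shear, two brightfield and three multicolour
#' fluorescence fields per run, 1360 x 1024 pixel fields at 0.2 um/pixel.
#'
#' @param donors Number of donors (>= 2; warns below 3, since paired
#'   comparisons in this assay conventionally use at least three).
#' @param runsPerCondition Duplicate runs per condition.
#' @param microspots Collagen labels.
#' @param shearRates Wall-shear rates in 1/s.
#' @param conditions List of [ConditionSpec-class] (default: control only).
#' @param imagesBrightfield,imagesFluorescence Fields per run.
#' @param fieldSize c(rows, cols) in pixels.
#' @param pixelSize Micrometres per pixel.
#' @param seed Integer seed governing the whole experiment.
#' @return An [ExperimentDesign-class].
#' @export
experimentDesign <- function(donors = 3, runsPerCondition = 2,
                             microspots = c("collagen-I", "collagen-III",
                                            "collagen-IV"),
                             shearRates = c(1000, 150),
                             conditions = list(
                               conditionSpec("control",
                                             shearRates = shearRates)),
                             imagesBrightfield = 2, imagesFluorescence = 3,
                             fieldSize = c(1024, 1360), pixelSize = 0.2,
                             seed = 1) {
  if (donors < 3)
    warning("fewer than 3 donors: paired comparisons will be fragile")
  new("ExperimentDesign", donors = as.integer(donors),
      runsPerCondition = as.integer(runsPerCondition),
      microspots = microspots, shearRates = shearRates,
      conditions = conditions,
      imagesBrightfield = as.integer(imagesBrightfield),
      imagesFluorescence = as.integer(imagesFluorescence),
      fieldSize = as.integer(fieldSize), pixelSize = pixelSize,
      seed = as.integer(seed))
}

# baseline generative levels per microspot and shear regime: coverage
# declines from collagen I to IV (decreasing GPVI engagement) and at venous
# shear; channel positivity scales with platelet coverage
.baseLevels <- function(microspot, shear) {
  plt <- switch(microspot, "collagen-I" = 0.35, "collagen-III" = 0.28,
                "collagen-IV" = 0.22, 0.28)
  low <- shear <= 300
  if (low) plt <- plt * 0.6
  list(platelet = plt,
       aggregate = plt * (if (low) 0.20 else 0.34),
       multilayer = 0.35,
       channels = c(PS = 0.18, `P-selectin` = 0.42,
                    fibrinogen = 0.30) * plt,
       contraction = 1.2)
}

# --- field placement ---------------------------------------------------

# rasterise all discs of a disc table onto a logical field, selecting the
# radius column to draw (r, coreR, or a channel sub-radius)
.rasterDiscs <- function(discs, H, W, radiusCol = "r") {
  mask <- logical(H * W)
  if (nrow(discs) > 0) {
    rr <- discs[[radiusCol]]
    sel <- which(rr > 0)
    for (i in sel)
      mask[.discIndex(discs$y[i], discs$x[i], rr[i], H, W)] <- TRUE
  }
  matrix(mask, H, W)
}

#' Generate the ground truth of one synthetic microscopy field
#'
#' Places platelets as 2-4 um discs: isolated single platelets plus
#' Gaussian-clustered disc groups merged into aggregate blobs, whose cores
#' carry a second, darker multilayer tier. Placement continues until the
#' pixel-counted coverage reaches the requested fractions (within a fraction
#' of a percentage point); the recorded truth is the pixel-counted coverage
#' of the placed geometry, and all masks are reconstructed deterministically
#' from the recorded disc table. Channel-positive regions are drawn as
#' sub-regions of the platelet discs, so channel masks are always subsets of
#' the platelet mask.
#'
#' @param plateletFraction Target fraction of field pixels covered by
#'   platelets.
#' @param aggregateFraction Target fraction of field pixels inside
#'   multilayered aggregates (must not exceed `plateletFraction`).
#' @param multilayerFraction Multilayer core area as a fraction of aggregate
#'   area.
#' @param channelFractions Named target fractions of field pixels positive
#'   per channel; each must not exceed `plateletFraction`.
#' @param contraction Cluster spread of aggregates in units of the mean disc
#'   radius: small values give tight, contracted, high-solidity blobs; large
#'   values loose, ragged aggregates. Default 1.2.
#' @param fieldSize c(rows, cols) in pixels.
#' @param pixelSize Micrometres per pixel.
#' @param minAggregateArea Minimum aggregate area (um^2) used when deriving
#'   the aggregate mask and intended scores.
#' @param rubric Rubric used to derive the intended score triple.
#' @param seed Optional integer seed; when `NULL` the current RNG stream is
#'   used.
#' @return A [GroundTruth-class].
#' @export
fieldTruth <- function(plateletFraction = 0.35, aggregateFraction = 0.12,
                       multilayerFraction = 0.35,
                       channelFractions = c(PS = 0.06, `P-selectin` = 0.15,
                                            fibrinogen = 0.10),
                       contraction = 1.2, fieldSize = c(1024, 1360),
                       pixelSize = 0.2, minAggregateArea = 20,
                       rubric = rubricConfig(), seed = NULL) {
  if (plateletFraction < 0 || plateletFraction > 1)
    stop("requested platelet coverage must lie in [0, 1]")
  if (aggregateFraction < 0 || aggregateFraction > plateletFraction)
    stop("requested aggregate coverage must lie in [0, plateletFraction]")
  if (multilayerFraction < 0 || multilayerFraction > 1)
    stop("multilayerFraction must lie in [0, 1]")
  if (!identical(sort(names(channelFractions)), sort(.FLUOR_CHANNELS)))
    stop("channelFractions must be named PS, P-selectin, fibrinogen")
  if (any(channelFractions < 0 | channelFractions > plateletFraction))
    stop("channel fractions must lie in [0, plateletFraction]")
  channelFractions <- channelFractions[.FLUOR_CHANNELS]

  .withSeed(seed, {
    H <- as.integer(fieldSize[1]); W <- as.integer(fieldSize[2])
    N <- as.numeric(H) * W
    platelet <- logical(N)
    core <- logical(N)
    halo <- logical(N)
    dObj <- list(); dType <- list(); dY <- list(); dX <- list()
    dR <- list(); dCore <- list()
    objId <- 0L
    pltPx <- 0
    coreScale <- sqrt(multilayerFraction)

    addObject <- function(ys, xs, rs, type, coreRs) {
      objId <<- objId + 1L
      for (i in seq_along(ys)) {
        idx <- .discIndex(ys[i], xs[i], rs[i], H, W)
        pltPx <<- pltPx + sum(!platelet[idx])
        platelet[idx] <<- TRUE
        if (coreRs[i] > 0)
          core[.discIndex(ys[i], xs[i], coreRs[i], H, W)] <<- TRUE
        halo[.discIndex(ys[i], xs[i], rs[i] + 3, H, W)] <<- TRUE
      }
      k <- length(dObj) + 1L
      dObj[[k]] <<- rep(objId, length(ys)); dType[[k]] <<- rep(type, length(ys))
      dY[[k]] <<- ys; dX[[k]] <<- xs; dR[[k]] <<- rs; dCore[[k]] <<- coreRs
    }

    # aggregates first: clusters of discs added disc-by-disc so the target
    # coverage is approached without overshooting by more than one disc
    targetAgg <- aggregateFraction * N
    tries <- 0L
    while (pltPx < targetAgg - 0.002 * N && tries < 400L) {
      tries <- tries + 1L
      n <- sample(8:22, 1)
      rs <- sample(5:9, n, replace = TRUE)
      mR <- mean(rs)
      marY <- min(6 * mR, floor(H / 3)); marX <- min(6 * mR, floor(W / 3))
      cy <- stats::runif(1, 1 + marY, H - marY)
      cx <- stats::runif(1, 1 + marX, W - marX)
      ys <- stats::rnorm(n, cy, contraction * mR)
      xs <- stats::rnorm(n, cx, contraction * mR)
      idxs <- lapply(seq_len(n), function(i)
        .discIndex(ys[i], xs[i], rs[i], H, W))
      if (any(halo[unique(unlist(idxs))])) next  # keep aggregates separated
      keep <- integer(0)
      accAdd <- 0
      unionIdx <- integer(0)
      for (i in seq_len(n)) {
        newIdx <- setdiff(idxs[[i]], unionIdx)
        add <- length(newIdx)
        if (pltPx + accAdd + add > targetAgg + 0.004 * N && length(keep) >= 3L)
          break
        keep <- c(keep, i)
        accAdd <- accAdd + add
        unionIdx <- c(unionIdx, newIdx)
        if (pltPx + accAdd >= targetAgg) break
      }
      if (length(keep) < 3L) next
      coreRs <- if (coreScale > 0) pmax(2L, round(rs[keep] * coreScale))
                else rep(0L, length(keep))
      addObject(ys[keep], xs[keep], rs[keep], "aggregate", coreRs)
    }

    # single platelets fill the remaining coverage; kept off aggregates so
    # aggregate components stay what the aggregate placement defined
    targetPlt <- plateletFraction * N
    iter <- 0L
    maxIter <- max(4000L, as.integer(10 * targetPlt / 150))
    while (pltPx < targetPlt - 5e-4 * N && iter < maxIter) {
      iter <- iter + 1L
      r <- sample(5:10, 1)
      y <- sample.int(H, 1); x <- sample.int(W, 1)
      idx <- .discIndex(y, x, r, H, W)
      if (any(halo[idx])) next
      addObject(y, x, r, "single", 0L)
    }

    discTable <- if (length(dObj) > 0)
      data.frame(object = unlist(dObj), type = unlist(dType),
                 y = unlist(dY), x = unlist(dX), r = unlist(dR),
                 coreR = unlist(dCore))
    else
      data.frame(object = integer(0), type = character(0), y = numeric(0),
                 x = numeric(0), r = numeric(0), coreR = numeric(0))

    # object-level metadata: aggregates get exact rasterised footprints and
    # hull solidity; singles are discs (solidity 1, analytic footprint)
    objects <- lapply(split(seq_len(nrow(discTable)),
                            factor(discTable$object,
                                   levels = unique(discTable$object))),
      function(ii) {
        type <- discTable$type[ii[1]]
        if (type == "single") {
          r <- discTable$r[ii[1]]
          npx <- length(.discOffsets(as.integer(round(r)))$dy)
          data.frame(object = discTable$object[ii[1]], type = type,
                     centroidY = discTable$y[ii[1]],
                     centroidX = discTable$x[ii[1]],
                     equivalentRadius = sqrt(npx / pi) * pixelSize,
                     layerCount = 1L, solidity = 1)
        } else {
          idx <- unique(unlist(lapply(ii, function(i)
            .discIndex(discTable$y[i], discTable$x[i], discTable$r[i], H, W))))
          rows <- ((idx - 1L) %% H) + 1L
          cols <- ((idx - 1L) %/% H) + 1L
          data.frame(object = discTable$object[ii[1]], type = type,
                     centroidY = mean(rows), centroidX = mean(cols),
                     equivalentRadius = sqrt(length(idx) / pi) * pixelSize,
                     layerCount = if (any(discTable$coreR[ii] > 0)) 2L else 1L,
                     solidity = .solidity(rows, cols))
        }
      })

    # channel positivity: whole discs positive, in random order, until the
    # target is reached; the final disc is shrunk to a concentric sub-disc
    nd <- nrow(discTable)
    chCols <- c(PS = "chPS", `P-selectin` = "chPsel", fibrinogen = "chFib")
    for (cn in .FLUOR_CHANNELS) discTable[[chCols[[cn]]]] <- 0
    pltPx <- sum(platelet)
    for (cn in .FLUOR_CHANNELS) {
      target <- min(channelFractions[[cn]] * N, 0.95 * pltPx)
      if (target <= 0 || nd == 0) next
      chMask <- logical(N)
      ord <- sample.int(nd)
      got <- 0
      for (d in ord) {
        if (got >= target - 5e-4 * N) break
        idx <- .discIndex(discTable$y[d], discTable$x[d], discTable$r[d], H, W)
        add <- sum(!chMask[idx])
        if (add == 0) next
        if (got + add <= target + 5e-4 * N) {
          chMask[idx] <- TRUE
          discTable[[chCols[[cn]]]][d] <- discTable$r[d]
          got <- got + add
        } else {
          rr <- max(1, floor(discTable$r[d] * sqrt((target - got) / add)))
          sidx <- .discIndex(discTable$y[d], discTable$x[d], rr, H, W)
          addS <- sum(!chMask[sidx])
          chMask[sidx] <- TRUE
          discTable[[chCols[[cn]]]][d] <- rr
          got <- got + addS
          break
        }
      }
      channelFractions[[cn]] <- got / N
    }

    pltM <- matrix(platelet, H, W)
    coreM <- matrix(core, H, W)
    aggM <- .aggregateFromComponents(pltM, coreM, pixelSize, minAggregateArea)
    feats <- .shapeFeatures(pltM, aggM, coreM, pixelSize, minAggregateArea)
    p1 <- 100 * mean(pltM)
    scores <- scoreImage(feats, p1, rubric)

    objectTable <- if (length(objects) > 0) do.call(rbind, objects) else
      data.frame(object = integer(0), type = character(0),
                 centroidY = numeric(0), centroidX = numeric(0),
                 equivalentRadius = numeric(0), layerCount = integer(0),
                 solidity = numeric(0))

    new("GroundTruth",
        plateletFraction = mean(pltM),
        aggregateFraction = mean(aggM),
        multilayerFraction = if (any(pltM)) sum(coreM) / sum(pltM) else 0,
        channelFractions = channelFractions,
        discTable = discTable, objectTable = objectTable,
        intendedScores = unname(scores), fieldSize = c(H, W),
        pixelSize = pixelSize, minAggregateArea = minAggregateArea)
  })
}

#' Noise-free masks implied by a ground-truth record
#'
#' Reconstructed deterministically from the recorded disc geometry; these
#' are the oracles the measurement pipeline is validated against.
#'
#' @param truth A [GroundTruth-class].
#' @return A [BinaryMask-class].
#' @export
plateletMask <- function(truth) {
  stopifnot(is(truth, "GroundTruth"))
  m <- .rasterDiscs(truth@discTable, truth@fieldSize[1], truth@fieldSize[2], "r")
  new("BinaryMask", pixels = m, provenance = "groundTruth")
}

#' @rdname plateletMask
#' @export
multilayerMask <- function(truth) {
  stopifnot(is(truth, "GroundTruth"))
  m <- .rasterDiscs(truth@discTable, truth@fieldSize[1], truth@fieldSize[2],
                    "coreR")
  new("BinaryMask", pixels = m, provenance = "groundTruth")
}

#' @rdname plateletMask
#' @export
aggregateMask <- function(truth) {
  stopifnot(is(truth, "GroundTruth"))
  agg <- .aggregateFromComponents(plateletMask(truth)@pixels,
                                  multilayerMask(truth)@pixels,
                                  truth@pixelSize, truth@minAggregateArea)
  new("BinaryMask", pixels = agg, provenance = "groundTruth")
}

#' @rdname plateletMask
#' @param channel `"PS"`, `"P-selectin"` or `"fibrinogen"`.
#' @export
channelMask <- function(truth, channel) {
  stopifnot(is(truth, "GroundTruth"))
  col <- switch(channel, PS = "chPS", `P-selectin` = "chPsel",
                fibrinogen = "chFib",
                stop(sprintf("unknown channel '%s'", channel)))
  m <- .rasterDiscs(truth@discTable, truth@fieldSize[1], truth@fieldSize[2], col)
  new("BinaryMask", pixels = m, provenance = "groundTruth")
}

#' Intended score triple of a synthetic field
#'
#' @param truth A [GroundTruth-class].
#' @return Named integer vector (morphology, multilayer, contraction).
#' @export
intendedScores <- function(truth) {
  stopifnot(is(truth, "GroundTruth"))
  stats::setNames(truth@intendedScores,
                  c("morphology", "multilayer", "contraction"))
}

# --- experiment generation ---------------------------------------------

#' Container for a generated synthetic experiment
#'
#' @slot design The [ExperimentDesign-class] it was generated from.
#' @slot images Data frame with one row per image file: donor, condition,
#'   microspot, shear_s1, run, field, role, channel, truthId, imageSeed,
#'   noiseSD, image (file name).
#' @slot truths Named list of [GroundTruth-class], keyed by truthId (one per
#'   field).
#' @slot groundTruthTable Data frame of per-field true fractions and
#'   intended scores.
#' @export
setClass("ThrombusExperiment",
  representation(design = "ExperimentDesign", images = "data.frame",
                 truths = "list", groundTruthTable = "data.frame"))

setMethod("show", "ThrombusExperiment", function(object) {
  cat(sprintf("ThrombusExperiment: %d fields, %d image(s)\n",
              length(object@truths), nrow(object@images)))
  show(object@design)
})

#' Generate a complete synthetic experiment
#'
#' Produces one image set per (donor, condition, microspot, shear rate, run):
#' `imagesBrightfield` brightfield fields plus `imagesFluorescence`
#' multicolour fluorescence fields (each contributing one image per
#' channel), every field backed by a [GroundTruth-class] record. A per-donor
#' lognormal effect is drawn once and shared across all of that donor's
#' runs; run- and field-level lognormal jitter act on top; condition effects
#' enter as the shear-specific multipliers of each [ConditionSpec-class].
#' The full experiment, including all per-image rendering seeds, is
#' reproducible from (design, seed). Images are rendered lazily: use
#' [writeExperimentImages()] or [renderBrightfield()] /
#' [renderFluorescence()].
#'
#' @param design An [ExperimentDesign-class].
#' @return A [ThrombusExperiment-class].
#' @export
generateExperiment <- function(design) {
  stopifnot(is(design, "ExperimentDesign"))
  validObject(design)
  .withSeed(design@seed, {
    ctrlIdx <- which(vapply(design@conditions, .isControlSpec, logical(1)))
    donorSD <- if (length(ctrlIdx) > 0)
      design@conditions[[ctrlIdx[1]]]@donorSD else design@conditions[[1]]@donorSD
    dEff <- stats::rlnorm(design@donors, 0, donorSD)
    names(dEff) <- paste0("donor", seq_len(design@donors))

    imgRows <- list(); truths <- list(); gtRows <- list()
    tid <- 0L
    for (d in seq_len(design@donors)) {
      for (cs in design@conditions) {
        for (spot in design@microspots) {
          for (shear in design@shearRates) {
            base <- .baseLevels(spot, shear)
            m <- cs@multipliers[as.character(shear), ]
            for (run in seq_len(design@runsPerCondition)) {
              runJ <- stats::rlnorm(1, 0, .RUN_SD)
              nBF <- design@imagesBrightfield
              nFL <- design@imagesFluorescence
              for (f in seq_len(nBF + nFL)) {
                imgJ <- stats::rlnorm(1, 0, .IMG_SD)
                g <- dEff[d] * runJ * imgJ
                plt <- min(0.75, base$platelet * m[["seeding"]] * g)
                agg <- min(0.9 * plt,
                           base$aggregate * m[["seeding"]] * m[["aggregate"]] * g)
                ml <- min(0.85, base$multilayer * m[["multilayer"]])
                ch <- pmin(0.9 * plt,
                           base$channels * m[["seeding"]] *
                             m[.FLUOR_CHANNELS] * g)
                names(ch) <- .FLUOR_CHANNELS
                truth <- fieldTruth(plateletFraction = plt,
                                    aggregateFraction = agg,
                                    multilayerFraction = ml,
                                    channelFractions = ch,
                                    contraction = base$contraction,
                                    fieldSize = design@fieldSize,
                                    pixelSize = design@pixelSize)
                tid <- tid + 1L
                key <- sprintf("field%05d", tid)
                truths[[key]] <- truth
                role <- if (f <= nBF) "brightfield" else "fluorescence"
                fieldNo <- if (f <= nBF) f else f - nBF
                chans <- if (role == "brightfield") NA_character_ else
                  .FLUOR_CHANNELS
                for (chan in chans) {
                  stemChan <- if (is.na(chan)) "bf" else gsub("[^A-Za-z]", "",
                                                              chan)
                  imgRows[[length(imgRows) + 1L]] <- data.frame(
                    donor = names(dEff)[d], condition = cs@name,
                    microspot = spot, shear_s1 = shear, run = run,
                    field = fieldNo, role = role, channel = chan,
                    truthId = key,
                    imageSeed = sample.int(.Machine$integer.max - 1L, 1),
                    noiseSD = cs@noiseSD,
                    image = sprintf("%s_%s_%s_%g_r%d_f%d_%s.tif",
                                    names(dEff)[d], cs@name, spot, shear,
                                    run, fieldNo, stemChan))
                }
                gtRows[[length(gtRows) + 1L]] <- data.frame(
                  truthId = key, donor = names(dEff)[d], condition = cs@name,
                  microspot = spot, shear_s1 = shear, run = run,
                  field = fieldNo, role = role,
                  plateletFraction = truth@plateletFraction,
                  aggregateFraction = truth@aggregateFraction,
                  multilayerFraction = truth@multilayerFraction,
                  PS = truth@channelFractions[["PS"]],
                  Pselectin = truth@channelFractions[["P-selectin"]],
                  fibrinogen = truth@channelFractions[["fibrinogen"]],
                  morphology = truth@intendedScores[1],
                  multilayer = truth@intendedScores[2],
                  contraction = truth@intendedScores[3])
              }
            }
          }
        }
      }
    }
    new("ThrombusExperiment", design = design,
        images = do.call(rbind, imgRows), truths = truths,
        groundTruthTable = do.call(rbind, gtRows))
  })
}

#' Render and write all images of a generated experiment
#'
#' Writes one 16-bit grayscale TIFF per image row, plus `metadata.csv` (one
#' row per image: donor, condition, microspot, shear_s1, run, field, role,
#' channel, image path) and `ground_truth.csv` (per-field true fractions and
#' intended scores). Rendering uses the per-image seeds fixed at generation
#' time, so output is reproducible from (design, seed).
#'
#' @param experiment A [ThrombusExperiment-class].
#' @param dir Output directory (created if needed).
#' @return The metadata data.frame, invisibly.
#' @export
writeExperimentImages <- function(experiment, dir) {
  stopifnot(is(experiment, "ThrombusExperiment"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  md <- experiment@images
  for (i in seq_len(nrow(md))) {
    truth <- experiment@truths[[md$truthId[i]]]
    img <- if (md$role[i] == "brightfield")
      renderBrightfield(truth, noiseSD = md$noiseSD[i], seed = md$imageSeed[i])
    else
      renderFluorescence(truth, md$channel[i], noiseSD = md$noiseSD[i],
                         seed = md$imageSeed[i])
    writeIntensityImage(img, file.path(dir, md$image[i]))
  }
  utils::write.csv(md, file.path(dir, "metadata.csv"), row.names = FALSE)
  utils::write.csv(experiment@groundTruthTable,
                   file.path(dir, "ground_truth.csv"), row.names = FALSE)
  invisible(md)
}

#' Donor-level parameter values under the generator's statistical model
#'
#' Samples donor-summary values of a continuous coverage parameter directly
#' from the generator's effect model (shared lognormal donor effect, run- and
#' field-level lognormal jitter, images averaged to runs and runs to donors)
#' without rendering any pixels. Useful for calibrating the paired-test
#' machinery: with `effect = 1` the two conditions are exchangeable and the
#' paired test's rejection rate estimates its type-I error.
#'
#' @param nDonors,nRuns,nImages Design counts.
#' @param base Baseline parameter value.
#' @param effect Multiplicative treatment effect (1 = null).
#' @param donorSD,runSD,imageSD Lognormal SDs (log scale).
#' @param seed Optional seed.
#' @return Data frame with columns donor, control, treated.
#' @export
simulateDonorValues <- function(nDonors = 3, nRuns = 2, nImages = 2,
                                base = 35, effect = 1, donorSD = 0.15,
                                runSD = .RUN_SD, imageSD = .IMG_SD,
                                seed = NULL) {
  .withSeed(seed, {
    oneCondition <- function(d, eff) {
      runs <- vapply(seq_len(nRuns), function(r) {
        rj <- stats::rlnorm(1, 0, runSD)
        mean(base * eff * d * rj * stats::rlnorm(nImages, 0, imageSD))
      }, numeric(1))
      mean(runs)
    }
    dEff <- stats::rlnorm(nDonors, 0, donorSD)
    data.frame(donor = paste0("donor", seq_len(nDonors)),
               control = vapply(dEff, oneCondition, numeric(1), eff = 1),
               treated = vapply(dEff, oneCondition, numeric(1), eff = effect))
  })
}
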