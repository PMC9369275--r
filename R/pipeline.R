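#' @include heatmap.R scoring.R segmentation.R
NULL

#' Default pipeline configuration
#'
#' A plain, YAML-serialisable list holding every tunable of the measurement
#' and statistics pipeline: segmentation settings, rubric cut-points,
#' scaling mode, significance filter, control condition and seed. See the
#' individual functions for the meaning and defaults of each entry.
#'
#' @return Named list (class `thromboflowConfig`).
#' @export
defaultPipelineConfig <- function() {
  structure(list(
    version = 1L,
    control = "control",
    alpha = 0.05,
    adjust = "none",
    scalingMode = "dataset",
    segmentation = list(method = "otsu", polarity = "dark", blurSigma = 40,
                        downsample = 8, noiseFloor = 6, backgroundRadius = 64,
                        fixedThreshold = NULL, minAggregateArea = 20,
                        multilayerFactor = 1.4, multilayerOffset = NULL),
    rubric = list(sacFloor = 0.5, aggregateCuts = c(0.11, 0.25),
                  multilayerCuts = c(0.04, 0.13, 0.21),
                  solidityCuts = c(0.70, 0.87, 0.94),
                  topMultilayer = 0.13, topSolidity = 0.87),
    figures = FALSE,
    seed = 1L
  ), class = c("thromboflowConfig", "list"))
}

.validateConfig <- function(config) {
  if (is.null(config$alpha) || config$alpha <= 0 || config$alpha >= 1)
    stop("configuration error: alpha must lie in (0, 1)")
  if (!config$scalingMode %in% c("dataset", "fixed"))
    stop("configuration error: scalingMode must be 'dataset' or 'fixed'")
  if (!config$adjust %in% c("none", "BH"))
    stop("configuration error: adjust must be 'none' or 'BH'")
  # rubric cut-points are checked by the RubricConfig validity method
  invisible(.configRubric(config))
}

.configRubric <- function(config) {
  r <- config$rubric
  rubricConfig(sacFloor = r$sacFloor, aggregateCuts = r$aggregateCuts,
               multilayerCuts = r$multilayerCuts,
               solidityCuts = r$solidityCuts,
               topMultilayer = r$topMultilayer, topSolidity = r$topSolidity)
}

#' Read / write a pipeline configuration as YAML
#'
#' @param path YAML file path.
#' @return The configuration list (read) or `path` invisibly (write).
#' @export
readPipelineConfig <- function(path) {
  cfg <- utils::modifyList(defaultPipelineConfig(), yaml::read_yaml(path))
  class(cfg) <- c("thromboflowConfig", "list")
  .validateConfig(cfg)
  cfg
}

#' @rdname readPipelineConfig
#' @param config Configuration list.
#' @export
writePipelineConfig <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Measure the brightfield parameters of one image
#'
#' Runs segmentation, feature extraction and the scoring rubric: platelet
#' adhesion P1 (%SAC), aggregate coverage P2 (%SAC) and the morphology /
#' multilayer / contraction scores P3-P5.
#'
#' @param image Brightfield [IntensityImage-class].
#' @param config Pipeline configuration list.
#' @return Named numeric vector P1-P5 with attributes `thresholdPlatelet`
#'   and `features`.
#' @export
measureBrightfield <- function(image, config = defaultPipelineConfig()) {
  s <- config$segmentation
  det <- .segmentCoverage(image, s$polarity, s$method, s$fixedThreshold,
                          s$blurSigma, s$downsample, s$noiseFloor,
                          s$backgroundRadius,
                          provenance = "segmentPlatelets")
  plt <- det$mask
  agg <- segmentAggregates(image, plt, minAggregateArea = s$minAggregateArea,
                           multilayerFactor = s$multilayerFactor,
                           multilayerOffset = s$multilayerOffset,
                           blurSigma = s$blurSigma, downsample = s$downsample,
                           backgroundRadius = s$backgroundRadius)
  feats <- extractFeatures(image, plt, agg,
                           minAggregateArea = s$minAggregateArea,
                           multilayerFactor = s$multilayerFactor,
                           multilayerOffset = s$multilayerOffset,
                           blurSigma = s$blurSigma, downsample = s$downsample,
                           backgroundRadius = s$backgroundRadius)
  p1 <- sacPercent(plt)
  scores <- scoreImage(feats, p1, .configRubric(config))
  out <- c(P1 = p1, P2 = sacPercent(agg), P3 = as.numeric(scores[1]),
           P4 = as.numeric(scores[2]), P5 = as.numeric(scores[3]))
  attr(out, "thresholdPlatelet") <- det$threshold
  attr(out, "features") <- feats
  out
}

#' Measure the fluorescence parameters of one multicolour field
#'
#' @param images Named list of the field's channel images (names or channel
#'   tags `PS`, `P-selectin`, `fibrinogen`).
#' @param config Pipeline configuration list.
#' @return Named numeric vector P6 (PS exposure), P7 (P-selectin
#'   expression), P8 (fibrinogen binding), all %SAC.
#' @export
measureFluorescenceSet <- function(images, config = defaultPipelineConfig()) {
  s <- config$segmentation
  chans <- vapply(images, function(im) im@channel, character(1))
  pOf <- c(PS = "P6", `P-selectin` = "P7", fibrinogen = "P8")
  out <- c(P6 = NA_real_, P7 = NA_real_, P8 = NA_real_)
  for (i in seq_along(images)) {
    mask <- segmentFluorPositive(images[[i]], method = s$method,
                                 threshold = s$fixedThreshold,
                                 blurSigma = s$blurSigma,
                                 downsample = s$downsample,
                                 noiseFloor = s$noiseFloor,
                                 backgroundRadius = s$backgroundRadius)
    out[pOf[[chans[i]]]] <- sacPercent(mask)
  }
  out
}

#' Run the full measurement and statistics pipeline
#'
#' From a run-metadata table and an image directory to per-image parameters,
#' run and donor summaries, 0-10 scaled condition-by-parameter matrices and
#' significance-filtered subtraction heatmaps per (microspot, shear) group,
#' written as CSV alongside a machine-readable provenance record. Reruns
#' with an identical configuration produce byte-identical CSV output.
#'
#' @param metadata Data frame or CSV path with one row per image and columns
#'   `donor`, `condition`, `microspot`, `shear_s1`, `run`, `field`, `role`
#'   (`"brightfield"`/`"fluorescence"`), `channel` (`NA` for brightfield)
#'   and `image` (file name relative to `imageDir`), as written by
#'   [writeExperimentImages()].
#' @param imageDir Directory holding the image files.
#' @param config Pipeline configuration (see [defaultPipelineConfig()]).
#' @param outputDir Directory for CSV/JSON (and optional figure) output;
#'   created if needed.
#' @param pixelSize Micrometres per pixel of the input images.
#' @return Invisibly, a list with elements `imageParams`, `runParams`,
#'   `donorSummary`, `scaled` (list of [ScaledMatrix-class]), `heatmaps`
#'   (list of [SubtractionHeatmap-class]) and `provenance`.
#' @export
runPipeline <- function(metadata, imageDir = ".",
                        config = defaultPipelineConfig(),
                        outputDir = file.path(imageDir, "results"),
                        pixelSize = 0.2) {
  if (is.character(metadata)) metadata <- utils::read.csv(metadata)
  if (!is.data.frame(metadata) || nrow(metadata) == 0)
    stop("empty metadata table: nothing to analyse")
  need <- c("donor", "condition", "microspot", "shear_s1", "run", "field",
            "role", "channel", "image")
  miss <- setdiff(need, names(metadata))
  if (length(miss) > 0)
    stop(sprintf("metadata lacks column(s): %s", paste(miss, collapse = ", ")))
  .validateConfig(config)
  paths <- file.path(imageDir, metadata$image)
  gone <- !file.exists(paths)
  if (any(gone))
    stop(sprintf("missing image file(s):\n%s",
                 paste(paths[gone], collapse = "\n")))
  if (!config$control %in% metadata$condition)
    stop(sprintf("control condition '%s' absent from metadata",
                 config$control))
  if (!dir.exists(outputDir)) dir.create(outputDir, recursive = TRUE)

  cfgPath <- file.path(outputDir, "config.yaml")
  writePipelineConfig(config, cfgPath)
  hash <- unname(tools::md5sum(cfgPath))

  # per-image (brightfield) / per-field (fluorescence) measurement
  rows <- list()
  grp <- interaction(metadata$donor, metadata$condition, metadata$microspot,
                     metadata$shear_s1, metadata$run, metadata$field,
                     metadata$role, drop = TRUE)
  for (sub in split(seq_len(nrow(metadata)), grp)) {
    md <- metadata[sub, , drop = FALSE]
    key <- md[1, c("donor", "condition", "microspot", "shear_s1", "run",
                   "field", "role")]
    vals <- c(P1 = NA_real_, P2 = NA_real_, P3 = NA_real_, P4 = NA_real_,
              P5 = NA_real_, P6 = NA_real_, P7 = NA_real_, P8 = NA_real_)
    thr <- NA_real_
    if (key$role == "brightfield") {
      img <- readIntensityImage(file.path(imageDir, md$image[1]),
                                channel = "brightfield",
                                pixelSize = pixelSize)
      m <- measureBrightfield(img, config)
      vals[names(m)] <- m
      thr <- attr(m, "thresholdPlatelet")
    } else {
      imgs <- lapply(seq_len(nrow(md)), function(i)
        readIntensityImage(file.path(imageDir, md$image[i]),
                           channel = md$channel[i], pixelSize = pixelSize))
      m <- measureFluorescenceSet(imgs, config)
      vals[names(m)] <- m
    }
    rows[[length(rows) + 1L]] <- cbind(
      key, as.data.frame(as.list(vals)), threshold = thr,
      images = paste(md$image, collapse = ";"), row.names = NULL)
  }
  imageParams <- do.call(rbind, rows)
  imageParams <- imageParams[order(imageParams$donor, imageParams$condition,
                                   imageParams$microspot,
                                   imageParams$shear_s1, imageParams$run,
                                   imageParams$role, imageParams$field), ,
                             drop = FALSE]
  rownames(imageParams) <- NULL

  runParams <- summarizeImagesToRuns(imageParams)
  donorSummary <- summarizeRunsToDonors(runParams)

  scaled <- list(); heatmaps <- list()
  groups <- unique(donorSummary[c("microspot", "shear_s1")])
  for (i in seq_len(nrow(groups))) {
    spot <- groups$microspot[i]; shear <- groups$shear_s1[i]
    gkey <- sprintf("%s_%g", spot, shear)
    ds <- .filterGroup(donorSummary, spot, shear)
    means <- .conditionMeans(ds)
    sm <- tryCatch(
      scaleMatrix(means, mode = config$scalingMode, microspot = spot,
                  shearRate = shear),
      warning = function(w) {
        warning(sprintf("[%s] %s", gkey, conditionMessage(w)))
        suppressWarnings(scaleMatrix(means, mode = config$scalingMode,
                                     microspot = spot, shearRate = shear))
      })
    scaled[[gkey]] <- sm
    nCond <- length(unique(ds$condition))
    nDon <- length(unique(ds$donor))
    if (nCond >= 2 && nDon >= 2) {
      heatmaps[[gkey]] <- subtractionHeatmap(
        ds, control = config$control, microspot = spot, shearRate = shear,
        mode = config$scalingMode, alpha = config$alpha,
        adjust = config$adjust)
    }
  }

  stamp <- function(df) cbind(df, configHash = hash)
  utils::write.csv(stamp(imageParams),
                   file.path(outputDir, "image_parameters.csv"),
                   row.names = FALSE)
  utils::write.csv(stamp(runParams),
                   file.path(outputDir, "run_parameters.csv"),
                   row.names = FALSE)
  utils::write.csv(stamp(donorSummary),
                   file.path(outputDir, "donor_summary.csv"),
                   row.names = FALSE)
  for (g in names(scaled)) {
    sv <- as.data.frame(scaled[[g]]@values)
    sv <- cbind(condition = rownames(scaled[[g]]@values), sv)
    utils::write.csv(stamp(sv),
                     file.path(outputDir, sprintf("scaled_%s.csv", g)),
                     row.names = FALSE)
  }
  for (g in names(heatmaps)) {
    utils::write.csv(stamp(as.data.frame(heatmaps[[g]])),
                     file.path(outputDir, sprintf("heatmap_%s.csv", g)),
                     row.names = FALSE)
    if (isTRUE(config$figures) && capabilities("png"))
      try(plotSubtractionHeatmap(heatmaps[[g]],
                                 file = file.path(outputDir,
                                                  sprintf("heatmap_%s.png", g))),
          silent = TRUE)
  }
  provenance <- list(configHash = hash, seed = config$seed,
                     package = "thromboflow",
                     packageVersion = as.character(
                       utils::packageVersion("thromboflow")),
                     rVersion = paste(R.version$major, R.version$minor,
                                      sep = "."),
                     nImages = nrow(metadata))
  jsonlite::write_json(provenance, file.path(outputDir, "provenance.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(imageParams = imageParams, runParams = runParams,
                 donorSummary = donorSummary, scaled = scaled,
                 heatmaps = heatmaps, provenance = provenance))
}
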