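#' @include AllClasses.R AllGenerics.R
NULL

#' Construct an IntensityImage
#'
#' @param pixels Numeric matrix of intensities (rows top-to-bottom).
#' @param channel `"brightfield"`, `"PS"`, `"P-selectin"` or `"fibrinogen"`.
#' @param pixelSize Micrometres per pixel.
#' @return An [IntensityImage-class].
#' @export
intensityImage <- function(pixels, channel = "brightfield", pixelSize = 0.2) {
  new("IntensityImage", pixels = pixels, channel = channel,
      pixelSize = pixelSize)
}

#' Read / write a grayscale TIFF as an IntensityImage
#'
#' 8/16-bit grayscale TIFF intensities are mapped to \[0, 1\]. Multi-frame
#' files are not supported; the first frame of an RGB file is used with a
#' warning.
#'
#' @param path File path.
#' @param channel Channel tag to attach.
#' @param pixelSize Micrometres per pixel.
#' @return [IntensityImage-class] (read) or the path, invisibly (write).
#' @export
readIntensityImage <- function(path, channel = "brightfield",
                               pixelSize = 0.2) {
  img <- EBImage::readImage(path)
  d <- EBImage::imageData(img)
  if (length(dim(d)) > 2L) {
    warning("multi-channel image; using the first plane")
    d <- d[, , 1]
  }
  intensityImage(t(d), channel = channel, pixelSize = pixelSize)
}

#' @rdname readIntensityImage
#' @param image An [IntensityImage-class] with intensities in \[0, 1\].
#' @export
writeIntensityImage <- function(image, path) {
  stopifnot(is(image, "IntensityImage"))
  px <- pmin(pmax(image@pixels, 0), 1)
  EBImage::writeImage(EBImage::Image(t(px)), path, type = "tiff",
                      bits.per.sample = 16L)
  invisible(path)
}

#' @rdname pixels
#' @export
setMethod("pixels", "IntensityImage", function(x) x@pixels)

#' @rdname pixels
#' @export
setMethod("pixels", "BinaryMask", function(x) x@pixels)

#' @rdname pixelSize
#' @export
setMethod("pixelSize", "IntensityImage", function(x) x@pixelSize)

#' @rdname sacPercent
#' @export
setMethod("sacPercent", "BinaryMask", function(mask) 100 * mean(mask@pixels))

#' @rdname sacPercent
#' @export
setMethod("sacPercent", "matrix", function(mask) {
  stopifnot(is.logical(mask))
  100 * mean(mask)
})

# flat-field correction: estimate the smooth background on a downsampled
# copy of the image, remove the objects from the estimate with a grayscale
# closing (dark objects) or opening (bright objects) whose structuring
# element exceeds the largest expected object, smooth, upsample, and
# subtract in the direction that makes objects positive
.correctBackground <- function(px, polarity = c("dark", "bright"),
                               blurSigma = 40, downsample = 8,
                               backgroundRadius = 64) {
  polarity <- match.arg(polarity)
  H <- nrow(px); W <- ncol(px)
  img <- EBImage::Image(px)
  ds <- max(1L, as.integer(downsample))
  small <- EBImage::resize(img, w = max(8L, ceiling(H / ds)),
                           h = max(8L, ceiling(W / ds)))
  # filters may not exceed the (downsampled) image: gblur uses a kernel of
  # 2*ceiling(3*sigma)+1 pixels, the rank filters a brush of 2*rad+1
  maxSigma <- ((min(dim(small)) - 1L) %/% 2L) / 3
  maxRad <- (min(dim(small)) - 1L) %/% 2L
  # denoise before the rank filters so they track the background, not the
  # noise extremes
  small <- EBImage::gblur(small, sigma = min(2, maxSigma),
                          boundary = "replicate")
  rad <- min(maxRad, max(3L, ceiling(backgroundRadius / ds)))
  br <- EBImage::makeBrush(2L * rad + 1L, shape = "disc")
  flat <- if (polarity == "dark")
    EBImage::erode(EBImage::dilate(small, br), br)
  else
    EBImage::dilate(EBImage::erode(small, br), br)
  sm <- EBImage::gblur(flat, sigma = min(max(1, blurSigma / ds), maxSigma),
                       boundary = "replicate")
  bg <- EBImage::imageData(EBImage::resize(sm, w = H, h = W))
  if (polarity == "dark") bg - px else px - bg
}

# robust background-noise sigma of a corrected image: objects live in the
# positive tail, so the spread of the negative deviations from the median
# estimates the background noise alone (half-normal MAD, scaled to sigma)
.backgroundSigma <- function(corr) {
  d <- corr - stats::median(corr)
  neg <- d[d < 0]
  if (length(neg) == 0) return(0)
  1.4826 * stats::median(-neg)
}

# automatic thresholding of a background-corrected image: Otsu on the
# max-normalised corrected intensities, plus an emptiness guard: the mask is
# kept only when the foreground/background mean separation exceeds
# `noiseFloor` background-noise sigmas, so pure-noise fields (where Otsu
# merely splits the noise distribution in half) come back empty. Both terms
# scale linearly with detector gain, so the mask is invariant to a global
# intensity scaling.
.autoThreshold <- function(corr, noiseFloor = 6) {
  empty <- list(threshold = Inf, mask = corr > Inf)
  mx <- max(corr)
  if (mx <= 0) return(empty)
  norm <- pmin(pmax(corr / mx, 0), 1)
  tOtsu <- EBImage::otsu(EBImage::Image(norm)) * mx
  mask <- corr > tOtsu
  if (!any(mask) || all(mask)) return(empty)
  bg <- corr[!mask]
  sep <- mean(corr[mask]) - mean(bg)
  if (sep < noiseFloor * .backgroundSigma(bg)) return(empty)
  list(threshold = tOtsu, mask = mask)
}

.segmentCoverage <- function(image, polarity, method = "otsu",
                             threshold = NULL, blurSigma = 40,
                             downsample = 8, noiseFloor = 6,
                             backgroundRadius = 64,
                             provenance = "segment") {
  px <- image@pixels
  if (identical(method, "fixed")) {
    if (is.null(threshold))
      stop("method = 'fixed' requires a threshold")
    m <- if (polarity == "dark") px <= threshold else px >= threshold
    return(list(mask = new("BinaryMask", pixels = m, provenance = provenance),
                threshold = threshold))
  }
  if (diff(range(px)) == 0) {
    warning(sprintf("constant image: %s returns an empty mask", provenance))
    m <- matrix(FALSE, nrow(px), ncol(px))
    return(list(mask = new("BinaryMask", pixels = m, provenance = provenance),
                threshold = NA_real_))
  }
  corr <- .correctBackground(px, polarity, blurSigma, downsample,
                             backgroundRadius)
  at <- .autoThreshold(corr, noiseFloor)
  list(mask = new("BinaryMask", pixels = at$mask, provenance = provenance),
       threshold = at$threshold)
}

#' Segment platelet-covered pixels in a brightfield image
#'
#' Default method: flat-field correction (subtract a large-radius smoothed
#' background estimate) followed by Otsu thresholding of the corrected image
#' with dark-object polarity, plus a robust noise floor so that fields
#' without deposits yield an empty mask. A fixed-threshold override is
#' available for images where automatic thresholding is unsuitable.
#' `sacPercent()` of the result is the platelet adhesion parameter (P1).
#'
#' @param image Brightfield [IntensityImage-class].
#' @param method `"otsu"` (automatic, default) or `"fixed"`.
#' @param polarity `"dark"` (platelets darker than background, default) or
#'   `"bright"`.
#' @param threshold Intensity threshold for `method = "fixed"`.
#' @param blurSigma Gaussian sigma (pixels, full scale) of the background
#'   estimate.
#' @param downsample Downsampling factor used when estimating the background.
#' @param noiseFloor Emptiness guard: the automatic mask is kept only when
#'   the foreground/background mean separation of the corrected image exceeds
#'   this many background-noise sigmas; otherwise the field is called empty.
#' @param backgroundRadius Radius (pixels, full scale) of the structuring
#'   element used to remove objects from the background estimate; must exceed
#'   half the largest expected object.
#' @return A [BinaryMask-class]. A constant image under automatic
#'   thresholding returns an empty mask with a warning.
#' @export
segmentPlatelets <- function(image, method = c("otsu", "fixed"),
                             polarity = c("dark", "bright"), threshold = NULL,
                             blurSigma = 40, downsample = 8, noiseFloor = 6,
                             backgroundRadius = 64) {
  stopifnot(is(image, "IntensityImage"))
  if (image@channel != "brightfield")
    stop("segmentPlatelets expects a brightfield image")
  method <- match.arg(method)
  polarity <- match.arg(polarity)
  .segmentCoverage(image, polarity, method, threshold, blurSigma, downsample,
                   noiseFloor, backgroundRadius,
                   provenance = "segmentPlatelets")$mask
}

#' Segment positively stained pixels in a fluorescence image
#'
#' Bright-object counterpart of [segmentPlatelets()] (background-corrected
#' Otsu with a noise floor; fixed-threshold override). `sacPercent()` of the
#' result gives the activation-marker parameters: PS exposure (P6),
#' P-selectin expression (P7) or fibrinogen binding (P8), depending on the
#' channel.
#'
#' @inheritParams segmentPlatelets
#' @param image Fluorescence [IntensityImage-class] (channel `"PS"`,
#'   `"P-selectin"` or `"fibrinogen"`).
#' @return A [BinaryMask-class].
#' @export
segmentFluorPositive <- function(image, method = c("otsu", "fixed"),
                                 threshold = NULL, blurSigma = 40,
                                 downsample = 8, noiseFloor = 6,
                                 backgroundRadius = 64) {
  stopifnot(is(image, "IntensityImage"))
  if (!image@channel %in% .FLUOR_CHANNELS)
    stop(sprintf("unknown fluorescence channel '%s' (expected %s)",
                 image@channel, paste(.FLUOR_CHANNELS, collapse = ", ")))
  method <- match.arg(method)
  .segmentCoverage(image, "bright", method, threshold, blurSigma, downsample,
                   noiseFloor, backgroundRadius,
                   provenance = "segmentFluorPositive")$mask
}

# pixels of the platelet mask belonging to the darker multilayer tier:
# corrected intensity at least `offset` above the corrected platelet median
# (absolute offset), or at least `factor` times the median (relative rule,
# used when offset is NULL; invariant to detector gain)
.multilayerPixels <- function(corr, plt, factor = 1.4, offset = NULL) {
  if (!any(plt)) return(plt & FALSE)
  med <- stats::median(corr[plt])
  thr <- if (!is.null(offset)) med + offset else med * factor
  plt & corr >= thr
}

# aggregate mask: connected platelet components that exceed the minimum
# aggregate area and contain at least one multilayer pixel
.aggregateFromComponents <- function(plt, ml, pixelSize, minAggregateArea) {
  out <- matrix(FALSE, nrow(plt), ncol(plt))
  if (!any(plt) || !any(ml)) return(out)
  lab <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(plt)))
  labv <- as.integer(lab)
  sizes <- tabulate(labv)
  mlLabs <- unique(labv[as.logical(ml) & labv > 0L])
  keep <- intersect(which(sizes * pixelSize^2 >= minAggregateArea), mlLabs)
  if (length(keep) == 0L) return(out)
  out[] <- labv %in% keep
  out
}

#' Segment multilayered platelet aggregates
#'
#' Returns the subset of the platelet mask made of connected components that
#' (a) exceed `minAggregateArea` and (b) contain a multilayer core: pixels
#' darker than the corrected platelet median by at least `multilayerOffset`
#' (or, by default, by the gain-invariant relative rule
#' `corrected >= multilayerFactor * median`). `sacPercent()` of the result is
#' the platelet aggregate coverage parameter (P2); it can never exceed P1.
#'
#' @inheritParams segmentPlatelets
#' @param plateletMask [BinaryMask-class] from [segmentPlatelets()] on the
#'   same image.
#' @param minAggregateArea Minimum aggregate area in square micrometres
#'   (default 20, several platelet footprints).
#' @param multilayerFactor Relative multilayer rule: multilayer pixels have
#'   corrected intensity at least this multiple of the platelet median.
#' @param multilayerOffset Absolute offset alternative (corrected-intensity
#'   units); overrides the relative rule when given.
#' @return A [BinaryMask-class], always a subset of `plateletMask`.
#' @export
segmentAggregates <- function(image, plateletMask, minAggregateArea = 20,
                              multilayerFactor = 1.4, multilayerOffset = NULL,
                              blurSigma = 40, downsample = 8,
                              backgroundRadius = 64) {
  stopifnot(is(image, "IntensityImage"), is(plateletMask, "BinaryMask"))
  if (!identical(dim(image@pixels), dim(plateletMask@pixels)))
    stop("platelet mask does not match the image dimensions")
  plt <- plateletMask@pixels
  corr <- .correctBackground(image@pixels, "dark", blurSigma, downsample,
                             backgroundRadius)
  ml <- .multilayerPixels(corr, plt, multilayerFactor, multilayerOffset)
  agg <- .aggregateFromComponents(plt, ml, image@pixelSize, minAggregateArea)
  new("BinaryMask", pixels = agg, provenance = "segmentAggregates")
}
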