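#' @include AllClasses.R
NULL

#' Pixel data of an image or mask
#'
#' @param x An [IntensityImage-class] or [BinaryMask-class] object.
#' @return A numeric (image) or logical (mask) matrix, rows = image rows
#'   (top to bottom), columns = image columns (left to right).
#' @export
setGeneric("pixels", function(x) standardGeneric("pixels"))

#' Physical pixel size
#'
#' @param x An object carrying a pixel calibration.
#' @return Pixel edge length in micrometres per pixel.
#' @export
setGeneric("pixelSize", function(x) standardGeneric("pixelSize"))

#' Surface-area coverage of a mask
#'
#' Percentage of the imaged field occupied by the positive pixels of a mask
#' (SAC, in percent). This is the common currency of the continuous thrombus
#' parameters: platelet adhesion, aggregate coverage, and the positive-area
#' fractions of the three activation markers.
#'
#' @param mask A [BinaryMask-class] or a logical matrix.
#' @return A single number in \[0, 100\].
#' @examples
#' sacPercent(matrix(c(TRUE, FALSE, TRUE, FALSE), 2, 2))
#' @export
setGeneric("sacPercent", function(mask) standardGeneric("sacPercent"))
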