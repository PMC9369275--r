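#' @include synthetic.R
NULL

#' Render a synthetic brightfield image from ground truth
#'
#' Bright background with darker platelet objects: monolayer pixels sit
#' 0.25 intensity units below the 0.85 background and multilayer cores a
#' further 0.20 below (on the \[0, 1\] scale), under a deterministic mild
#' illumination gradient, with additive Gaussian pixel noise. The underlying
#' geometry depends only on the ground truth, so two seeds give different
#' noise fields over an identical object mask.
#'
#' @param truth A [GroundTruth-class].
#' @param noiseSD Gaussian pixel-noise SD (intensity units).
#' @param seed Optional seed for the noise field.
#' @return A brightfield [IntensityImage-class].
#' @export
renderBrightfield <- function(truth, noiseSD = 0.02, seed = NULL) {
  stopifnot(is(truth, "GroundTruth"))
  validObject(truth)
  H <- truth@fieldSize[1]; W <- truth@fieldSize[2]
  plt <- plateletMask(truth)@pixels
  ml <- multilayerMask(truth)@pixels
  base <- (.BF_BACKGROUND - .BF_PLATELET_DROP * plt -
             .BF_MULTILAYER_DROP * ml) * .illumination(H, W)
  px <- .withSeed(seed, base + if (noiseSD > 0)
    matrix(stats::rnorm(H * W, 0, noiseSD), H, W) else 0)
  intensityImage(pmin(pmax(px, 0), 1), channel = "brightfield",
                 pixelSize = truth@pixelSize)
}

#' Render a synthetic fluorescence channel image from ground truth
#'
#' Dark background with bright positive regions drawn as the ground truth's
#' channel mask (a subset of the platelet mask), under the same illumination
#' gradient, noise and determinism contract as [renderBrightfield()].
#'
#' @inheritParams renderBrightfield
#' @param channel `"PS"`, `"P-selectin"` or `"fibrinogen"`.
#' @return A fluorescence [IntensityImage-class].
#' @export
renderFluorescence <- function(truth, channel, noiseSD = 0.02, seed = NULL) {
  stopifnot(is(truth, "GroundTruth"))
  if (!channel %in% .FLUOR_CHANNELS)
    stop(sprintf("unknown channel '%s' (expected %s)", channel,
                 paste(.FLUOR_CHANNELS, collapse = ", ")))
  H <- truth@fieldSize[1]; W <- truth@fieldSize[2]
  ch <- channelMask(truth, channel)@pixels
  base <- (.FL_BACKGROUND + .FL_SIGNAL * ch) * .illumination(H, W)
  px <- .withSeed(seed, base + if (noiseSD > 0)
    matrix(stats::rnorm(H * W, 0, noiseSD), H, W) else 0)
  intensityImage(pmin(pmax(px, 0), 1), channel = channel,
                 pixelSize = truth@pixelSize)
}
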