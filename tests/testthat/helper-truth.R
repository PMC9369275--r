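# Reconstruct the noise-free truth masks of a GroundTruth object from its
# disc table (the generator's deterministic geometry record).
truthMasks <- function(tr) {
  dt <- tr@discTable
  H <- tr@fieldSize[1]
  W <- tr@fieldSize[2]
  raster <- thromboflow:::.rasterDiscs
  plt <- raster(dt, H, W, "r")
  ml <- raster(dt[dt$coreR > 0, , drop = FALSE], H, W, "coreR")
  # the truth's aggregate mask is derived exactly like the measurement's:
  # platelet components above the area floor that contain multilayer pixels
  agg <- thromboflow:::.aggregateFromComponents(plt, ml & plt, tr@pixelSize,
                                                tr@minAggregateArea)
  ch <- lapply(c(PS = "chPS", `P-selectin` = "chPsel", fibrinogen = "chFib"),
               function(col) raster(dt[dt[[col]] > 0, , drop = FALSE],
                                    H, W, col))
  list(platelet = plt, aggregate = agg & plt, multilayer = ml & plt,
       channels = ch)
}

jaccard <- function(a, b) sum(a & b) / sum(a | b)

# Small field size used throughout the unit tests to keep them fast; the
# acceptance tests use the full default field.
testField <- c(340L, 256L)

# The published peptide notations (printed sequences; pCIB is line-wrapped)
PCIB <- "Ace-LVLAMWKVGFFKRNRPP LEEDDEEGQ-OH"
PCIBM <- "Ace-LVRKMWQVGFYKRNRYPLEEDDEEGQ-OH"
PGRP <- "TYFAVLM"
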