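#' @include stats.R
NULL

# condition-by-parameter matrix of donor means for one (microspot, shear)
.conditionMeans <- function(donorSummary, parameters = .PARAMS) {
  conds <- unique(donorSummary$condition)
  m <- matrix(NA_real_, length(conds), length(parameters),
              dimnames = list(conds, parameters))
  for (cn in conds) {
    sub <- donorSummary[donorSummary$condition == cn, , drop = FALSE]
    for (p in parameters) m[cn, p] <- mean(sub[[p]])
  }
  m
}

.filterGroup <- function(donorSummary, microspot, shearRate) {
  if (!is.na(microspot))
    donorSummary <- donorSummary[donorSummary$microspot == microspot, ,
                                 drop = FALSE]
  if (!is.na(shearRate))
    donorSummary <- donorSummary[donorSummary$shear_s1 == shearRate, ,
                                 drop = FALSE]
  donorSummary
}

#' Significance-filtered subtraction heatmap versus a control condition
#'
#' For each non-control condition and each parameter, the cell value is the
#' 0-10 scaled condition mean minus the scaled control mean (scaling frames
#' per parameter, by default from the data of this microspot/shear group).
#' p-values come from per-donor paired t-tests on the unscaled donor
#' summaries (the t statistic is invariant to the affine scaling, so testing
#' the unscaled values pins the convention without changing the answer for
#' dataset frames). Cells with p below `alpha` are marked significant;
#' non-significant cells keep their delta in the object and export table and
#' are only neutralised when rendered.
#'
#' @param donorSummary Donor-summary table from [summarizeRunsToDonors()],
#'   one row per (donor, condition) within one microspot/shear group (or
#'   pass `microspot` / `shearRate` to filter).
#' @param control Name of the control condition.
#' @param microspot,shearRate Optional filters and labels.
#' @param mode,frame Scaling mode and fixed frame, as in [scaleMatrix()].
#' @param alpha Significance filter (default 0.05).
#' @param adjust `"none"` (default, a conventional unadjusted 0.05 filter)
#'   or `"BH"` for Benjamini-Hochberg adjustment across the heatmap.
#' @param parameters Parameter columns to include.
#' @return A [SubtractionHeatmap-class].
#' @export
subtractionHeatmap <- function(donorSummary, control = "control",
                               microspot = NA_character_,
                               shearRate = NA_real_,
                               mode = c("dataset", "fixed"), frame = NULL,
                               alpha = 0.05, adjust = c("none", "BH"),
                               parameters = .PARAMS) {
  mode <- match.arg(mode)
  adjust <- match.arg(adjust)
  ds <- .filterGroup(donorSummary, microspot, shearRate)
  if (nrow(ds) == 0) stop("no donor summaries for the requested group")
  if (!control %in% ds$condition)
    stop(sprintf("control condition '%s' not found", control))
  means <- .conditionMeans(ds, parameters)
  sm <- scaleMatrix(means, mode = mode, frame = frame,
                    microspot = microspot, shearRate = shearRate)
  conds <- setdiff(rownames(means), control)
  if (length(conds) == 0) stop("no non-control condition to compare")
  delta <- sm@values[conds, , drop = FALSE] -
    matrix(sm@values[control, ], length(conds), length(parameters),
           byrow = TRUE, dimnames = list(conds, parameters))
  p <- matrix(NA_real_, length(conds), length(parameters),
              dimnames = list(conds, parameters))
  ctrl <- ds[ds$condition == control, , drop = FALSE]
  ctrl <- ctrl[order(ctrl$donor), , drop = FALSE]
  for (cn in conds) {
    trt <- ds[ds$condition == cn, , drop = FALSE]
    trt <- trt[order(trt$donor), , drop = FALSE]
    if (!identical(ctrl$donor, trt$donor))
      stop(sprintf("donors of '%s' and '%s' are misaligned", control, cn))
    for (pp in parameters) {
      x <- stats::setNames(ctrl[[pp]], ctrl$donor)
      y <- stats::setNames(trt[[pp]], trt$donor)
      if (anyNA(x) || anyNA(y)) next
      p[cn, pp] <- pairedTTest(x, y)@pValue
    }
  }
  if (adjust == "BH") p[] <- stats::p.adjust(as.vector(p), method = "BH")
  sig <- !is.na(p) & p < alpha
  new("SubtractionHeatmap", delta = delta, pValue = p, significant = sig,
      alpha = alpha, control = control, frame = sm@frame,
      microspot = microspot, shearRate = shearRate)
}

#' Export a subtraction heatmap as a table
#'
#' One row per (condition, parameter) cell; non-significant cells keep their
#' raw delta.
#'
#' @param x A [SubtractionHeatmap-class].
#' @param row.names,optional Ignored (S3 compatibility).
#' @param ... Ignored.
#' @return Data frame with columns condition, parameter, delta, pValue,
#'   significant.
#' @export
as.data.frame.SubtractionHeatmap <- function(x, row.names = NULL,
                                             optional = FALSE, ...) {
  conds <- rownames(x@delta); pars <- colnames(x@delta)
  data.frame(condition = rep(conds, times = length(pars)),
             parameter = rep(pars, each = length(conds)),
             delta = as.vector(x@delta), pValue = as.vector(x@pValue),
             significant = as.vector(x@significant))
}

#' Render a subtraction heatmap
#'
#' Decreases versus control are drawn in green, increases in red, and
#' non-significant cells in neutral grey, on a symmetric -10..10 colour
#' scale.
#'
#' @param x A [SubtractionHeatmap-class].
#' @param file Optional PNG path; when `NULL` draws on the current device.
#' @param ... Passed to [pheatmap::pheatmap()].
#' @return The pheatmap object, invisibly.
#' @export
plotSubtractionHeatmap <- function(x, file = NULL, ...) {
  stopifnot(is(x, "SubtractionHeatmap"))
  disp <- x@delta
  disp[!x@significant] <- NA
  main <- sprintf("vs %s%s", x@control,
                  if (!is.na(x@microspot))
                    sprintf(" (%s, %g /s)", x@microspot, x@shearRate) else "")
  args <- list(
    disp, cluster_rows = FALSE, cluster_cols = FALSE,
    color = grDevices::colorRampPalette(c("darkgreen", "white", "red3"))(101),
    breaks = seq(-10, 10, length.out = 102), na_col = "grey88",
    main = main, ...)
  if (!is.null(file)) args$filename <- file
  invisible(do.call(pheatmap::pheatmap, args))
}

#' Cumulative bar plot of scaled parameters per condition
#'
#' Stacked bars of the 0-10 scaled parameters P1-P8, one bar per condition;
#' bar heights are the cumulative sums (bounded by 80).
#'
#' @param x A [ScaledMatrix-class].
#' @param file Optional PNG path.
#' @param ... Passed to [graphics::barplot()].
#' @return Invisibly, the cumulative sums per condition.
#' @export
plotCumulative <- function(x, file = NULL, ...) {
  stopifnot(is(x, "ScaledMatrix"))
  if (!is.null(file)) {
    grDevices::png(file, width = 900, height = 700, res = 150)
    on.exit(grDevices::dev.off())
  }
  cols <- grDevices::hcl.colors(ncol(x@values), "Spectral")
  graphics::barplot(t(x@values), col = cols, las = 2,
                    ylab = "cumulative scaled parameters (0-80)",
                    legend.text = colnames(x@values),
                    args.legend = list(x = "topright", bty = "n", cex = 0.7),
                    ...)
  invisible(cumulativeScaled(x))
}
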