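#' @include AllClasses.R
NULL

.KEYS <- c("donor", "condition", "microspot", "shear_s1")
.BF_PARAMS <- paste0("P", 1:5)
.FL_PARAMS <- paste0("P", 6:8)

#' Reference parameter ranges of the assay
#'
#' Measured value ranges of the eight thrombus parameters: platelet adhesion
#' 0-71.7 %SAC (P1), aggregate coverage 0-29.8 %SAC (P2), morphology score
#' 0-4.75 (P3), multilayer score 0-2.75 (P4), contraction score 0-2.75 (P5),
#' PS exposure 0-22.2 %SAC (P6), P-selectin expression 0-71.7 %SAC (P7),
#' fibrinogen binding 0-45.7 %SAC (P8). Score ranges are fractional because
#' they apply after averaging over images and runs. These ranges serve as
#' the fixed scaling frame (`mode = "fixed"`).
#'
#' @return Data frame with columns parameter, min, max.
#' @export
defaultParameterRanges <- function() {
  data.frame(parameter = .PARAMS, min = 0,
             max = c(71.7, 29.8, 4.75, 2.75, 2.75, 22.2, 71.7, 45.7))
}

#' Average per-image parameter sets into one run-level parameter set
#'
#' Brightfield-borne parameters (P1-P5) are averaged over the run's
#' brightfield images and fluorescence-borne parameters (P6-P8) over its
#' fluorescence fields. Discrete scores become fractional after averaging. A
#' parameter with no contributing image is flagged missing (`NA`), never
#' zero.
#'
#' @param imageParams Data frame of per-image rows with a `role` column
#'   (`"brightfield"` / `"fluorescence"`) and columns P1-P8 (`NA` where a
#'   row does not carry a parameter).
#' @return One-row data frame with P1-P8 plus the image counts averaged.
#' @export
averageImagesToRun <- function(imageParams) {
  stopifnot(is.data.frame(imageParams), nrow(imageParams) >= 1,
            "role" %in% names(imageParams))
  out <- stats::setNames(as.list(rep(NA_real_, 8)), .PARAMS)
  bf <- imageParams[imageParams$role == "brightfield", , drop = FALSE]
  fl <- imageParams[imageParams$role == "fluorescence", , drop = FALSE]
  for (p in .BF_PARAMS)
    if (p %in% names(bf) && any(!is.na(bf[[p]])))
      out[[p]] <- mean(bf[[p]], na.rm = TRUE)
  for (p in .FL_PARAMS)
    if (p %in% names(fl) && any(!is.na(fl[[p]])))
      out[[p]] <- mean(fl[[p]], na.rm = TRUE)
  cbind(as.data.frame(out),
        nBrightfield = nrow(bf), nFluorescence = nrow(fl))
}

#' Average run-level parameter sets into one donor summary row
#'
#' All runs must share the same (donor, condition, microspot, shear) key;
#' mixing keys is an error. Parameters are averaged over runs (`NA` runs
#' propagate unless every run carries the value).
#'
#' @param runParams Data frame of run rows with the key columns `donor`,
#'   `condition`, `microspot`, `shear_s1` and columns P1-P8.
#' @return One-row data frame: key, P1-P8, number of runs averaged.
#' @export
averageRunsToDonor <- function(runParams) {
  stopifnot(is.data.frame(runParams), nrow(runParams) >= 1)
  miss <- setdiff(.KEYS, names(runParams))
  if (length(miss) > 0)
    stop(sprintf("missing key column(s): %s", paste(miss, collapse = ", ")))
  key <- unique(runParams[.KEYS])
  if (nrow(key) != 1)
    stop("runs with mixed (donor, condition, microspot, shear) keys")
  vals <- lapply(.PARAMS, function(p) {
    v <- runParams[[p]]
    if (is.null(v) || all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  })
  cbind(key, stats::setNames(as.data.frame(vals), .PARAMS),
        nRuns = nrow(runParams), row.names = NULL)
}

#' Aggregate a per-image parameter table to runs and to donor summaries
#'
#' Convenience wrappers applying [averageImagesToRun()] per (donor,
#' condition, microspot, shear, run) group and [averageRunsToDonor()] per
#' (donor, condition, microspot, shear) group. Aggregation is
#' order-invariant.
#'
#' @param imageParams Per-image parameter table with key columns plus `run`,
#'   `role` and P1-P8.
#' @return Data frame of run-level (or donor-level) parameter sets.
#' @export
summarizeImagesToRuns <- function(imageParams) {
  g <- interaction(imageParams$donor, imageParams$condition,
                   imageParams$microspot, imageParams$shear_s1,
                   imageParams$run, drop = TRUE)
  rows <- lapply(split(imageParams, g), function(df) {
    cbind(unique(df[c(.KEYS, "run")]), averageImagesToRun(df),
          row.names = NULL)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$donor, out$condition, out$microspot, out$shear_s1, out$run), ,
      drop = FALSE]
}

#' @rdname summarizeImagesToRuns
#' @param runParams Run-level table from [summarizeImagesToRuns()].
#' @export
summarizeRunsToDonors <- function(runParams) {
  g <- interaction(runParams$donor, runParams$condition, runParams$microspot,
                   runParams$shear_s1, drop = TRUE)
  out <- do.call(rbind, lapply(split(runParams, g), averageRunsToDonor))
  rownames(out) <- NULL
  out[order(out$donor, out$condition, out$microspot, out$shear_s1), ,
      drop = FALSE]
}

#' Univariate 0-10 scaling of a parameter across conditions
#'
#' Affine map sending the frame minimum to 0 and maximum to 10. With
#' `mode = "dataset"` (default) the frame is the range of `values`
#' themselves; a constant vector maps to all zeros with a warning (so a
#' parameter with no signal anywhere stays visually empty). With
#' `mode = "fixed"` a caller-supplied frame `c(min, max)` is used and values
#' outside it are clipped to \[0, 10\] with a warning.
#'
#' @param values Numeric vector (one value per condition).
#' @param mode `"dataset"` or `"fixed"`.
#' @param frame Length-2 numeric frame, required for `mode = "fixed"`.
#' @return List with `values` (scaled vector) and `frame` (c(min, max)).
#' @examples
#' scaleUnivariate(c(2, 4, 6))  # 0, 5, 10
#' @export
scaleUnivariate <- function(values, mode = c("dataset", "fixed"),
                            frame = NULL) {
  mode <- match.arg(mode)
  stopifnot(is.numeric(values), length(values) >= 1)
  if (mode == "dataset") {
    frame <- range(values, na.rm = TRUE)
    if (diff(frame) == 0) {
      warning("constant parameter vector: scaled to all zeros")
      return(list(values = rep(0, length(values)) + 0 * values, frame = frame))
    }
  } else {
    if (is.null(frame) || length(frame) != 2 || frame[2] <= frame[1])
      stop("mode = 'fixed' requires frame = c(min, max) with max > min")
  }
  sc <- 10 * (values - frame[1]) / (frame[2] - frame[1])
  if (any(sc < 0 | sc > 10, na.rm = TRUE)) {
    warning("values outside the fixed frame were clipped to [0, 10]")
    sc <- pmin(pmax(sc, 0), 10)
  }
  list(values = sc, frame = frame)
}

#' Scale a condition-by-parameter matrix univariately to 0-10
#'
#' Applies [scaleUnivariate()] column by column (one frame per parameter).
#'
#' @param mat Numeric matrix, conditions in rows, parameters in columns.
#' @param mode `"dataset"` or `"fixed"`.
#' @param frame For `mode = "fixed"`: data frame with columns parameter,
#'   min, max (default [defaultParameterRanges()]).
#' @param microspot,shearRate Optional grouping labels carried along.
#' @return A [ScaledMatrix-class].
#' @export
scaleMatrix <- function(mat, mode = c("dataset", "fixed"), frame = NULL,
                        microspot = NA_character_, shearRate = NA_real_) {
  mode <- match.arg(mode)
  stopifnot(is.matrix(mat), !is.null(colnames(mat)))
  if (mode == "fixed" && is.null(frame)) frame <- defaultParameterRanges()
  out <- mat
  fr <- data.frame(parameter = colnames(mat), min = NA_real_, max = NA_real_)
  for (j in seq_len(ncol(mat))) {
    f <- if (mode == "fixed") {
      r <- frame[frame$parameter == colnames(mat)[j], ]
      if (nrow(r) != 1)
        stop(sprintf("no fixed frame for parameter %s", colnames(mat)[j]))
      c(r$min, r$max)
    } else NULL
    s <- scaleUnivariate(mat[, j], mode = mode, frame = f)
    out[, j] <- s$values
    fr$min[j] <- s$frame[1]; fr$max[j] <- s$frame[2]
  }
  new("ScaledMatrix", values = out, frame = fr, mode = mode,
      microspot = microspot, shearRate = shearRate)
}

#' Cumulative sum of the eight scaled parameters for one condition
#'
#' Summarises a condition as the sum of its 0-10 scaled parameters, bounded
#' by 80. All eight parameters must be present and non-missing.
#'
#' @param x Named numeric vector containing P1-P8, or a [ScaledMatrix-class]
#'   (returns one sum per condition row).
#' @return Numeric sum(s) in \[0, 80\].
#' @export
cumulativeScaled <- function(x) {
  if (is(x, "ScaledMatrix")) {
    return(vapply(rownames(x@values), function(r)
      cumulativeScaled(x@values[r, ]), numeric(1)))
  }
  miss <- setdiff(.PARAMS, names(x))
  if (length(miss) > 0)
    stop(sprintf("missing parameter(s): %s", paste(miss, collapse = ", ")))
  v <- x[.PARAMS]
  if (anyNA(v))
    stop(sprintf("missing parameter value(s): %s",
                 paste(.PARAMS[is.na(v)], collapse = ", ")))
  sum(v)
}

#' Paired Student t-test on donor-aligned condition values
#'
#' Two-sided paired t-test of treated versus control values, one pair per
#' donor. If both vectors are named the names must agree (donor alignment).
#' If every pairwise difference is exactly zero the result is t = 0, p = 1
#' by convention (identical measurements carry no evidence either way); a
#' non-zero constant difference yields an infinite t and p = 0 with a
#' warning.
#'
#' @param control,treated Equal-length numeric vectors, donor-aligned,
#'   n >= 2.
#' @return A [ComparisonResult-class]; `meanDifference` is
#'   mean(treated - control).
#' @examples
#' pairedTTest(c(0, 0, 0), c(1, 2, 3))  # t = 3.4641, df = 2
#' @export
pairedTTest <- function(control, treated) {
  if (length(control) != length(treated))
    stop("control and treated must have equal length")
  if (length(control) < 2)
    stop("paired test requires at least 2 pairs")
  if (!is.null(names(control)) && !is.null(names(treated)) &&
      !identical(names(control), names(treated)))
    stop("misaligned donors: names of control and treated differ")
  if (anyNA(control) || anyNA(treated))
    stop("paired test requires complete pairs")
  d <- treated - control
  n <- length(d)
  if (stats::sd(d) == 0) {
    if (all(d == 0)) {
      t <- 0; p <- 1
    } else {
      warning("constant non-zero differences: t is infinite")
      t <- sign(mean(d)) * Inf; p <- 0
    }
  } else {
    tt <- stats::t.test(treated, control, paired = TRUE)
    t <- unname(tt$statistic); p <- tt$p.value
  }
  new("ComparisonResult", tStatistic = t, df = n - 1, pValue = p,
      nPairs = as.integer(n), meanDifference = mean(d))
}
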