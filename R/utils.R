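# Low-level helpers shared by the synthetic generator and the measurement
# code. Pixel grids are plain R matrices (rows top-to-bottom, columns
# left-to-right); linear indices are column-major.

.discCache <- new.env(parent = emptyenv())

# (dy, dx) offsets of all pixels within integer radius r of a centre pixel
.discOffsets <- function(r) {
  key <- as.character(r)
  if (!is.null(.discCache[[key]])) return(.discCache[[key]])
  s <- seq(-r, r)
  g <- expand.grid(dy = s, dx = s)
  g <- g[g$dy^2 + g$dx^2 <= r^2, , drop = FALSE]
  out <- list(dy = g$dy, dx = g$dx)
  .discCache[[key]] <- out
  out
}

# column-major linear indices of a disc clipped to the field
.discIndex <- function(cy, cx, r, H, W) {
  off <- .discOffsets(as.integer(round(r)))
  y <- as.integer(round(cy)) + off$dy
  x <- as.integer(round(cx)) + off$dx
  keep <- y >= 1L & y <= H & x >= 1L & x <= W
  (x[keep] - 1L) * H + y[keep]
}

# convex-hull area of a set of pixels given by (row, col) coordinates,
# via the shoelace formula on the hull vertices of the pixel centres
.hullArea <- function(rows, cols) {
  n <- length(rows)
  if (n < 3L) return(as.numeric(n))
  h <- grDevices::chull(cols, rows)
  xs <- cols[h]; ys <- rows[h]
  m <- length(h)
  if (m < 3L) return(as.numeric(n))
  j <- c(m, seq_len(m - 1L))
  abs(sum(xs * ys[j] - xs[j] * ys)) / 2
}

# solidity of a pixel set: area / convex-hull area, capped at 1 (pixelation
# makes the hull of pixel centres slightly smaller than the true footprint)
.solidity <- function(rows, cols) {
  ha <- .hullArea(rows, cols)
  if (ha <= 0) return(1)
  min(1, length(rows) / ha)
}

# run expr with a fixed RNG seed, restoring the caller's RNG state
.withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

# deterministic mild illumination plane, fixed per field geometry
.illumination <- function(H, W) {
  ry <- (seq_len(H) / H - 0.5) * 0.03
  rx <- (seq_len(W) / W - 0.5) * 0.04
  1 + outer(ry, rx, `+`)
}

.asMatrix <- function(x) {
  if (is(x, "BinaryMask") || is(x, "IntensityImage")) x@pixels else x
}
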