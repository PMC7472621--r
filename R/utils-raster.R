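# Shared raster helpers. Images are plain numeric matrices, row 1 at the top,
# intensities on the 0..255 scale (uint8 values stored as doubles).

# Direction-index convention used throughout the package:
# index 0 = east, increasing counter-clockwise in 45-degree steps
# (0=E, 1=NE, 2=N, 3=NW, 4=W, 5=SW, 6=S, 7=SE). The same indices name the
# compass-mask directions and the 8-neighbourhood, so that the neighbour in
# direction i and the neighbour in direction (i+4) mod 8 are geometrically
# opposite. In matrix coordinates (row grows downward) the offsets are:
dir_offsets <- function() {
  matrix(c( 0L,  1L,   # E
           -1L,  1L,   # NE
           -1L,  0L,   # N
           -1L, -1L,   # NW
            0L, -1L,   # W
            1L, -1L,   # SW
            1L,  0L,   # S
            1L,  1L),  # SE
         ncol = 2L, byrow = TRUE,
         dimnames = list(c("E","NE","N","NW","W","SW","S","SE"),
                         c("drow", "dcol")))
}

#' @keywords internal
assert_image <- function(image) {
  if (!is.matrix(image) || !is.numeric(image) || length(image) == 0L)
    stop("`image` must be a non-empty numeric matrix", call. = FALSE)
  if (any(image < 0, na.rm = TRUE))
    stop("image intensities must be non-negative", call. = FALSE)
  invisible(image)
}

# out[r, c] = image[clamp(r + drow), clamp(c + dcol)] -- replicate padding.
shift_replicate <- function(image, drow, dcol) {
  nr <- nrow(image); nc <- ncol(image)
  ri <- pmin(pmax(seq_len(nr) + drow, 1L), nr)
  ci <- pmin(pmax(seq_len(nc) + dcol, 1L), nc)
  image[ri, ci, drop = FALSE]
}

# The 8 replicate-padded neighbour rasters, in direction-index order 0..7,
# returned as an (npix x 8) matrix of column-major flattened rasters.
neighbor_matrix <- function(image) {
  off <- dir_offsets()
  vapply(seq_len(8L),
         function(i) as.vector(shift_replicate(image, off[i, 1L], off[i, 2L])),
         numeric(length(image)))
}

# Exact sliding-window correlation (no kernel flip) with replicate padding.
# Accumulation is a fixed-order shift-and-add so that integer-valued images
# and kernels give exact integer results (bit-identical to a per-pixel loop).
correlate_replicate <- function(image, kernel) {
  k <- nrow(kernel)
  stopifnot(k == ncol(kernel), k %% 2L == 1L)
  half <- (k - 1L) %/% 2L
  out <- matrix(0, nrow(image), ncol(image))
  for (a in seq_len(k)) {
    for (b in seq_len(k)) {
      w <- kernel[a, b]
      if (w != 0)
        out <- out + w * shift_replicate(image, a - 1L - half, b - 1L - half)
    }
  }
  out
}

# Exact 90-degree counter-clockwise rotation of a raster.
rot90_ccw <- function(image) t(image)[ncol(image):1, , drop = FALSE]

# 180-degree rotation (point reflection).
rot180 <- function(image) image[nrow(image):1, ncol(image):1, drop = FALSE]

clip_uint8 <- function(x) {
  x <- round(x)
  x[x < 0] <- 0
  x[x > 255] <- 255
  x
}
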