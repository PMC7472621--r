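#' Eight-direction compass mask banks
#'
#' A mask bank is a set of eight square convolution kernels, one per compass
#' direction, obtained by rotating a base edge kernel through 45-degree steps.
#' Three classical families are provided: Kirsch (the 5/-3 compass masks),
#' Sobel and Prewitt (first-derivative kernels and their diagonal rotations).
#'
#' Direction indexing is fixed package-wide: index 0 points east and indices
#' increase counter-clockwise in 45-degree steps (0=E, 1=NE, 2=N, 3=NW, 4=W,
#' 5=SW, 6=S, 7=SE). Kernel `i + 4` is always the 180-degree rotation of
#' kernel `i`, so opposite directions carry point-reflected kernels. The same
#' indices name the 8-neighbourhood of a pixel, which is what makes the
#' opposite-neighbour intensity differences of the structure code geometrically
#' meaningful.
#'
#' Sizes larger than 3 are built by the compass construction: the axis-aligned
#' kernels are the standard separable n-by-n Sobel/Prewitt derivative kernels
#' (binomial respectively uniform smoothing), and each 45-degree step circularly
#' shifts every concentric ring of border coefficients by its ring radius.
#' Kirsch kernels at size n place, on the ring of radius r (8r cells), an arc of
#' 3r coefficients equal to +5 centred on the kernel direction and -3 elsewhere,
#' which keeps every kernel zero-sum at every size.
#'
#' @param family One of `"kirsch"`, `"sobel"`, `"prewitt"`.
#' @param size Odd kernel side length, one of 3, 5, 7, 9.
#'
#' @return An object of class `mask_bank`: a list with elements `family`,
#'   `size`, `kernels` (list of 8 matrices, direction indices 0..7) and
#'   `direction_angles` (degrees, `c(0, 45, ..., 315)`).
#'
#' @examples
#' b <- kirsch_bank()
#' b$kernels[[1]]          # east kernel
#' sum(b$kernels[[3]])     # Kirsch kernels are zero-sum
#' mask_bank("sobel", 5)
#' @export
mask_bank <- function(family = c("kirsch", "sobel", "prewitt"), size = 3L) {
  family <- match.arg(family)
  size <- as.integer(size)
  if (!size %in% c(3L, 5L, 7L, 9L))
    stop("unsupported mask size ", size, "; must be one of 3, 5, 7, 9",
         call. = FALSE)
  kernels <- switch(family,
    kirsch  = kirsch_kernels(size),
    sobel   = derivative_kernels(size, smooth = choose(size - 1L, 0:(size - 1L))),
    prewitt = derivative_kernels(size, smooth = rep(1, size))
  )
  structure(
    list(family = family, size = size, kernels = kernels,
         direction_angles = 45 * (0:7)),
    class = "mask_bank")
}

#' @rdname mask_bank
#' @export
kirsch_bank <- function() mask_bank("kirsch", 3L)

#' @export
print.mask_bank <- function(x, ...) {
  cat(sprintf("<mask_bank> %s %dx%d, 8 directions (0=E, counter-clockwise)\n",
              x$family, x$size, x$size))
  labs <- rownames(dir_offsets())
  for (i in 1:8) {
    cat(sprintf("# direction %d (%s, %d deg)\n", i - 1L, labs[i],
                x$direction_angles[i]))
    utils::write.table(format(x$kernels[[i]]), row.names = FALSE,
                       col.names = FALSE, quote = FALSE)
  }
  invisible(x)
}

#' Export a mask bank as plain-text CSV blocks
#'
#' Writes the eight kernels one after another, blank-line separated, each as a
#' CSV grid, so users can inspect or substitute the exact coefficients.
#'
#' @param bank A [mask_bank()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_mask_bank_csv <- function(bank, path) {
  stopifnot(inherits(bank, "mask_bank"))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in 1:8) {
    writeLines(sprintf("# family=%s size=%d direction=%d angle=%d",
                       bank$family, bank$size, i - 1L,
                       bank$direction_angles[i]), con)
    utils::write.table(bank$kernels[[i]], con, sep = ",", row.names = FALSE,
                       col.names = FALSE)
    writeLines("", con)
  }
  invisible(path)
}

# --- construction -----------------------------------------------------------

# Cells of the concentric ring at Chebyshev radius r, ordered counter-clockwise
# starting at due east, as (row, col) indices. The cell lying exactly in
# compass direction i sits at walk position i * r, and a 90-degree rotation of
# the grid shifts walk positions by exactly 2r.
ring_walk <- function(size, r) {
  ctr <- (size + 1L) %/% 2L
  cells <- which(
    outer(seq_len(size), seq_len(size),
          function(rr, cc) pmax(abs(rr - ctr), abs(cc - ctr)) == r),
    arr.ind = TRUE)
  ang <- atan2(ctr - cells[, 1L], cells[, 2L] - ctr) %% (2 * pi)
  cells[order(ang), , drop = FALSE]
}

# Kirsch compass kernels at any supported size: per ring of 8r cells, +5 on the
# 3r-cell arc centred on the kernel direction, -3 elsewhere (zero-sum: 15r - 15r).
kirsch_kernels <- function(size) {
  rmax <- (size - 1L) %/% 2L
  lapply(0:7, function(i) {
    k <- matrix(0, size, size)
    for (r in seq_len(rmax)) {
      walk <- ring_walk(size, r)
      n <- 8L * r
      vals <- rep(-3, n)
      arc <- (i * r - ((3L * r - 1L) %/% 2L)) + seq_len(3L * r) - 1L
      vals[(arc %% n) + 1L] <- 5
      k[walk] <- vals
    }
    k
  })
}

# Sobel/Prewitt compass kernels: separable north kernel (positive weights on the
# top rows), other directions by ring-wise circular shift of r cells per
# 45-degree step. 90-degree multiples reproduce the exact separable rotations.
derivative_kernels <- function(size, smooth) {
  deriv <- if (all(smooth == choose(size - 1L, 0:(size - 1L)))) {
    convolve_seq(c(1, -1), choose(size - 2L, 0:(size - 2L)))  # Sobel family
  } else {
    ((size - 1L) / 2):(-(size - 1L) / 2)             # Prewitt ramp
  }
  north <- outer(deriv, smooth)                       # rows top-to-bottom
  rmax <- (size - 1L) %/% 2L
  lapply(0:7, function(i) {
    k <- matrix(0, size, size)
    for (r in seq_len(rmax)) {
      walk <- ring_walk(size, r)
      n <- 8L * r
      base <- north[walk]                             # walk values of north (index 2)
      # kernel i value at walk position p = north value at p - (i - 2) * r
      idx <- ((seq_len(n) - 1L - (i - 2L) * r) %% n) + 1L
      k[walk] <- base[idx]
    }
    k
  })
}

# Full (zero-padded) discrete convolution of two coefficient vectors.
convolve_seq <- function(a, b) {
  out <- numeric(length(a) + length(b) - 1L)
  for (i in seq_along(a)) {
    out[i + seq_along(b) - 1L] <- out[i + seq_along(b) - 1L] + a[i] * b
  }
  out
}
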