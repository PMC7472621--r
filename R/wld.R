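#' Parameters for the baseline Weber local descriptor
#'
#' The baseline WLD descriptor quantizes each pixel's differential excitation
#' into `M * S` bins and its gradient orientation into `T` bins, then builds a
#' `T x (M * S)` joint histogram. Two presets are provided:
#'
#' * `"classic"` — T = 8, M = 6, S = 5, one global histogram (240 values),
#'   the same excitation quantization as WTLD.
#' * `"table5"` — T = 8, M = 4, S = 1, computed on each cell of a 4x4 block
#'   grid: 32 bins per block, 512 values on a 100x100 image. This is the
#'   compact configuration used when WLD serves as the dimension-matched
#'   comparison baseline; the exact sub-quantization behind that published
#'   dimension is not recoverable, so this preset reproduces the dimension,
#'   not necessarily the original binning.
#'
#' @param preset `"classic"` or `"table5"`, or `NULL` to set fields directly.
#' @param T Orientation bins (even, at least 2).
#' @param M,S Excitation bands and intervals per band.
#' @param epsilon Zero-centre guard for the Weber ratio.
#' @param block_grid `"global"` for one histogram, or an integer vector
#'   `c(rows, cols)` of sub-blocks.
#' @return An object of class `wld_params`.
#' @export
wld_params <- function(preset = NULL, T = 8L, M = 6L, S = 5L,
                       epsilon = 1e-6, block_grid = "global") {
  if (!is.null(preset)) {
    preset <- match.arg(preset, c("classic", "table5"))
    if (preset == "table5") {
      T <- 8L; M <- 4L; S <- 1L; block_grid <- c(4L, 4L)
    } else {
      T <- 8L; M <- 6L; S <- 5L; block_grid <- "global"
    }
  }
  T <- as.integer(T); M <- as.integer(M); S <- as.integer(S)
  stopifnot(T >= 2L, T %% 2L == 0L, M >= 1L, S >= 1L, epsilon > 0)
  structure(list(T = T, M = M, S = S, epsilon = epsilon,
                 block_grid = block_grid),
            class = "wld_params")
}

#' @rdname wld_params
#' @export
wld_excitation <- function(image, params = wld_params()) {
  differential_excitation(image, params$epsilon)
}

#' WLD gradient orientation
#'
#' Quantized orientation of the local gray gradient, computed from the
#' differences of opposite 4-neighbours: the horizontal component is
#' east-minus-west and the vertical component north-minus-south. The angle is
#' the two-argument arctangent of (vertical, horizontal), mapped to
#' \eqn{[0, 2\pi)} and uniformly quantized into `T` bins; a zero gradient maps
#' to bin 0 by convention.
#'
#' @param image Numeric intensity matrix.
#' @param T Number of orientation bins.
#' @return Integer matrix of bin indices in `0..T-1`.
#' @export
wld_orientation <- function(image, T = 8L) {
  assert_image(image)
  gh <- shift_replicate(image, 0L, 1L) - shift_replicate(image, 0L, -1L)
  gv <- shift_replicate(image, -1L, 0L) - shift_replicate(image, 1L, 0L)
  theta <- atan2(gv, gh) %% (2 * pi)     # atan2(0, 0) = 0 -> bin 0
  bin <- floor(theta * T / (2 * pi))
  matrix(pmin(as.integer(bin), T - 1L), nrow(image), ncol(image))
}

#' Baseline WLD feature vector
#'
#' Joint histogram of (orientation bin, excitation bin), flattened
#' orientation-major; with a block grid the histogram is computed per block and
#' the blocks are concatenated row-major. Default normalization rescales each
#' block segment to unit L1 mass.
#'
#' @param image Numeric intensity matrix (dimensions divisible by the block
#'   grid, if one is set).
#' @param params A [wld_params()].
#' @param normalization `"l1"`, `"l2"` or `"none"`.
#' @return Numeric feature vector of length
#'   `T * M * S * prod(block_grid)` with attribute `layout`.
#' @examples
#' img <- matrix(sample(0:255, 1e4, TRUE), 100, 100)
#' length(wld_feature(img, wld_params("table5")))   # 512
#' @export
wld_feature <- function(image, params = wld_params(),
                        normalization = c("l1", "l2", "none")) {
  normalization <- match.arg(normalization)
  stopifnot(inherits(params, "wld_params"))
  assert_image(image)
  nbins <- params$M * params$S
  gb <- quantize_excitation(wld_excitation(image, params), params$M, params$S)
  ob <- wld_orientation(image, params$T)
  joint <- as.vector(ob) * nbins + as.vector(gb)     # orientation-major
  ncell <- params$T * nbins
  if (identical(params$block_grid, "global")) {
    out <- tabulate(joint + 1L, nbins = ncell)
    segs <- list(out)
  } else {
    bid <- block_index(dim(image), params$block_grid)
    segs <- lapply(seq_len(prod(params$block_grid)), function(b)
      tabulate(joint[bid == b] + 1L, nbins = ncell))
    out <- unlist(segs, use.names = FALSE)
  }
  out <- normalize_segments(out, vapply(segs, length, 1L), normalization)
  attr(out, "layout") <- list(descriptor = "wld", T = params$T,
                              M = params$M, S = params$S,
                              block_grid = params$block_grid)
  out
}
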