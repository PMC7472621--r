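#' Parameters for the Weber texture local descriptor
#'
#' Bundles the tunable quantities of the WTLD pixel coding. The direction count
#' is fixed at 8 (one per compass mask) and the number of main directions
#' entering the adaptive threshold is fixed at 4.
#'
#' @param mask_family,mask_size Compass-mask bank used for directional
#'   filtering; see [mask_bank()].
#' @param M Number of equal bands the differential-excitation range
#'   \eqn{(-\pi/2, \pi/2)} is divided into.
#' @param S Number of uniform intervals per band, giving `M * S` excitation
#'   bins in total.
#' @param epsilon Guard added to the centre pixel in the Weber ratio so a zero
#'   centre intensity stays finite. Default `1e-6`, negligible against the
#'   minimum positive intensity 1 of 8-bit images.
#' @param sigma_rule How the adaptive threshold averages the main-direction
#'   intensity differences: `"over_n"` (default) averages all four absolute
#'   differences, `"over_n_minus_1"` averages only the three strongest. Both
#'   coincide whenever the four absolute differences are equal.
#'
#' @return An object of class `wtld_params`.
#' @export
wtld_params <- function(mask_family = "kirsch", mask_size = 3L,
                        M = 6L, S = 5L, epsilon = 1e-6,
                        sigma_rule = c("over_n", "over_n_minus_1")) {
  sigma_rule <- match.arg(sigma_rule)
  M <- as.integer(M); S <- as.integer(S)
  stopifnot(M >= 1L, S >= 1L, epsilon > 0)
  structure(
    list(mask_family = mask_family, mask_size = as.integer(mask_size),
         M = M, S = S, T = 8L, N = 4L,
         epsilon = epsilon, sigma_rule = sigma_rule),
    class = "wtld_params")
}

#' @export
print.wtld_params <- function(x, ...) {
  cat(sprintf(
    "<wtld_params> %s %dx%d mask, M=%d bands x S=%d intervals, sigma rule '%s'\n",
    x$mask_family, x$mask_size, x$mask_size, x$M, x$S, x$sigma_rule))
  invisible(x)
}

#' Weber differential excitation
#'
#' Per-pixel arctangent of the summed relative differences between a pixel and
#' its eight neighbours,
#' \deqn{\gamma(x_c) = \arctan\left[\sum_{i=0}^{7} \frac{x_i - x_c}{x_c + \epsilon}\right],}
#' the Weber-law salience measure shared by WLD and WTLD. Border neighbours are
#' obtained by replicate padding; values lie in \eqn{(-\pi/2, \pi/2)}.
#'
#' @param image Numeric matrix of non-negative intensities (0..255 scale).
#' @param epsilon Zero-centre guard added to the denominator.
#' @return Matrix of excitation values (radians), same shape as `image`.
#' @examples
#' differential_excitation(matrix(128, 5, 5))   # constant image -> all zero
#' @export
differential_excitation <- function(image, epsilon = 1e-6) {
  assert_image(image)
  xc <- as.vector(image)
  nb <- neighbor_matrix(image)
  s <- numeric(length(xc))
  for (i in 1:8) s <- s + (nb[, i] - xc) / (xc + epsilon)
  matrix(atan(s), nrow(image), ncol(image))
}

#' Absolute compass-mask responses
#'
#' Correlates the image with each of the eight directional kernels of a mask
#' bank and takes absolute values: `R[[i]] = |I * M_i|`. Borders are replicate
#' padded so every raster keeps the image size.
#'
#' @param image Numeric intensity matrix.
#' @param bank A [mask_bank()].
#' @return List of 8 non-negative response matrices, direction indices 0..7.
#' @export
directional_responses <- function(image, bank) {
  assert_image(image)
  stopifnot(inherits(bank, "mask_bank"))
  lapply(bank$kernels, function(k) abs(correlate_replicate(image, k)))
}

#' Main direction numbers
#'
#' Per pixel, the indices of the four largest directional responses:
#' `D1 = argmax_i R_i`, then the second, third and fourth largest. Ties are
#' broken deterministically in favour of the smallest direction index, so a
#' pixel where all responses coincide gets D1..D4 = 0, 1, 2, 3.
#'
#' @param R List of 8 response matrices from [directional_responses()].
#' @return List of 4 integer matrices with values in 0..7 (`D1` to `D4`),
#'   pairwise distinct at every pixel.
#' @export
main_directions <- function(R) {
  stopifnot(is.list(R), length(R) == 8L)
  dims <- dim(R[[1]])
  m <- vapply(R, as.vector, numeric(prod(dims)))
  if (is.null(dim(m))) m <- matrix(m, nrow = 1L)   # 1-pixel image
  out <- vector("list", 4L)
  idx <- seq_len(nrow(m))
  for (k in 1:4) {
    top <- max.col(m, ties.method = "first")
    out[[k]] <- matrix(top - 1L, dims[1], dims[2])
    m[cbind(idx, top)] <- -Inf
  }
  names(out) <- paste0("D", 1:4)
  out
}

#' Main-direction intensity differences
#'
#' For each of the four main directions, the signed difference between the
#' pixel's neighbour in that direction and the diametrically opposite
#' neighbour: `C_i = N[D_i] - N[D_i opposite]`, with the opposite index
#' `(D_i + 4) mod 8`. Captures how steeply intensity changes across the pixel
#' along its dominant local orientations.
#'
#' @param image Numeric intensity matrix.
#' @param D List of 4 direction matrices from [main_directions()].
#' @return List of 4 signed difference matrices (`C1` to `C4`), intensity units.
#' @export
intensity_differences <- function(image, D) {
  assert_image(image)
  stopifnot(is.list(D), length(D) == 4L)
  nb <- neighbor_matrix(image)
  idx <- seq_len(length(image))
  out <- lapply(D, function(d) {
    dv <- as.vector(d)
    ci <- nb[cbind(idx, dv + 1L)] - nb[cbind(idx, ((dv + 4L) %% 8L) + 1L)]
    matrix(ci, nrow(image), ncol(image))
  })
  names(out) <- paste0("C", 1:4)
  out
}

#' Adaptive-threshold binarization of the intensity differences
#'
#' The per-pixel threshold is the average absolute main-direction intensity
#' difference: with the default `"over_n"` rule
#' \eqn{\sigma = (|C_1|+|C_2|+|C_3|+|C_4|)/4}; the `"over_n_minus_1"` rule
#' averages only the first three, \eqn{(|C_1|+|C_2|+|C_3|)/3}, ignoring the
#' weakest direction. The two rules coincide whenever the four absolute
#' differences are equal. Each difference is then
#' binarized by strict comparison, `M_i = 1` if `|C_i| > sigma`, else 0 — so a
#' flat pixel (all differences zero) codes as all zeros, and scaling all
#' intensities by a positive constant leaves every bit unchanged.
#'
#' @param C List of 4 difference matrices from [intensity_differences()].
#' @param sigma_rule `"over_n"` or `"over_n_minus_1"`; see [wtld_params()].
#' @return List with `sigma` (matrix) and `Mbits` (list of 4 binary matrices).
#' @export
adaptive_threshold <- function(C, sigma_rule = c("over_n", "over_n_minus_1")) {
  sigma_rule <- match.arg(sigma_rule)
  stopifnot(is.list(C), length(C) == 4L)
  a <- lapply(C, abs)
  sigma <- if (sigma_rule == "over_n") {
    (a[[1]] + a[[2]] + a[[3]] + a[[4]]) / 4
  } else {
    (a[[1]] + a[[2]] + a[[3]]) / 3
  }
  Mbits <- lapply(a, function(ai) (ai > sigma) + 0L)
  names(Mbits) <- paste0("M", 1:4)
  list(sigma = sigma, Mbits = Mbits)
}

#' Structure code
#'
#' Fuses the main direction number and the binarized main-direction intensity
#' difference into a 4-bit code, `L = 2 * D1 + M1`, values 0..15. With
#' `M2` supplied the two-direction variant `L = 4 * D1 + 2 * M1 + M2`
#' (values 0..31) is returned instead; the one-direction code is the default
#' descriptor.
#'
#' @param D1 Matrix of main directions (0..7).
#' @param M1 Binary matrix from [adaptive_threshold()].
#' @param M2 Optional second binary matrix for the two-direction code.
#' @return Integer code matrix.
#' @export
structure_code <- function(D1, M1, M2 = NULL) {
  if (is.null(M2)) 2L * D1 + M1 else 4L * D1 + 2L * M1 + M2
}

#' Full per-pixel WTLD maps
#'
#' Runs the whole pixel-level pipeline — differential excitation, directional
#' filtering, main directions, intensity differences, adaptive threshold and
#' structure code — and returns every intermediate raster.
#'
#' @param image Numeric intensity matrix (0..255 scale).
#' @param params A [wtld_params()].
#' @return An object of class `wtld_pixel_maps`: list with `gamma`, `R` (8
#'   response matrices), `D` (4 direction matrices), `C` (4 difference
#'   matrices), `sigma`, `Mbits` (4 binary matrices) and `L` (codes 0..15).
#' @examples
#' pm <- wtld_pixel_maps(matrix(sample(0:255, 64, TRUE), 8, 8))
#' table(pm$L)
#' @export
wtld_pixel_maps <- function(image, params = wtld_params()) {
  stopifnot(inherits(params, "wtld_params"))
  assert_image(image)
  bank <- mask_bank(params$mask_family, params$mask_size)
  gamma <- differential_excitation(image, params$epsilon)
  R <- directional_responses(image, bank)
  D <- main_directions(R)
  C <- intensity_differences(image, D)
  thr <- adaptive_threshold(C, params$sigma_rule)
  L <- structure_code(D[[1]], thr$Mbits[[1]])
  structure(
    list(gamma = gamma, R = R, D = D, C = C,
         sigma = thr$sigma, Mbits = thr$Mbits, L = L, params = params),
    class = "wtld_pixel_maps")
}

#' @export
print.wtld_pixel_maps <- function(x, ...) {
  cat(sprintf("<wtld_pixel_maps> %d x %d pixels, %s %dx%d mask\n",
              nrow(x$L), ncol(x$L),
              x$params$mask_family, x$params$mask_size, x$params$mask_size))
  cat("structure code counts:\n")
  print(table(factor(x$L, levels = 0:15)))
  invisible(x)
}

#' Directional image
#'
#' The main-direction raster rescaled to the 0..255 display range — the
#' direction map one inspects to see how much directional detail the
#' descriptor extracts from an animal's back texture.
#'
#' @param image Numeric intensity matrix.
#' @param bank A [mask_bank()].
#' @return Matrix with values in 0..255 (`D1` scaled by 255/7).
#' @export
directional_image <- function(image, bank = kirsch_bank()) {
  D <- main_directions(directional_responses(image, bank))
  round(D[[1]] * (255 / 7))
}

#' Correlation coefficient of two rasters
#'
#' Pearson product-moment correlation of two equally shaped rasters,
#' \deqn{r = \frac{\sum_{mn}(A_{mn}-\bar A)(E_{mn}-\bar E)}
#'   {\sqrt{\sum_{mn}(A_{mn}-\bar A)^2 \sum_{mn}(E_{mn}-\bar E)^2}},}
#' used as the diagnostic that directional images of different individuals are
#' less correlated under WTLD than under WLD.
#'
#' @param A,E Numeric matrices of identical shape, neither constant.
#' @return Scalar in \eqn{[-1, 1]}.
#' @export
correlation_coefficient <- function(A, E) {
  if (!all(dim(A) == dim(E)))
    stop("A and E must have identical dimensions", call. = FALSE)
  a <- as.vector(A) - mean(A)
  e <- as.vector(E) - mean(E)
  den <- sqrt(sum(a^2) * sum(e^2))
  if (den == 0)
    stop("correlation undefined for a constant raster", call. = FALSE)
  sum(a * e) / den
}
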