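#' Quantize differential excitation into uniform bins
#'
#' The excitation range \eqn{[-\pi/2, \pi/2]} is partitioned into `M` equal
#' bands and each band into `S` equal sub-intervals, giving `M * S` uniform
#' bins. The bin index is `floor((gamma + pi/2) / (pi / (M * S)))`, clamped to
#' the top bin at the upper edge.
#'
#' @param gamma Matrix of excitation values in \eqn{(-\pi/2, \pi/2)}.
#' @param M,S Bands and intervals per band.
#' @return Integer matrix of bin indices in `0 .. M*S - 1`.
#' @examples
#' quantize_excitation(matrix(0), M = 6, S = 5)   # 15, first bin of band 3
#' @export
quantize_excitation <- function(gamma, M = 6L, S = 5L) {
  nbins <- as.integer(M) * as.integer(S)
  bin <- floor((gamma + pi / 2) / (pi / nbins))
  m <- matrix(pmax(pmin(as.integer(bin), nbins - 1L), 0L),
              nrow(gamma), ncol(gamma))
  m
}

#' Joint excitation/direction histogram
#'
#' Counts of (main direction, excitation bin) pairs over the whole image,
#' flattened direction-major into a vector of length `T * M * S`. This is the
#' global segment of the WTLD feature vector.
#'
#' @param gamma_bins Integer matrix from [quantize_excitation()].
#' @param D1 Main-direction matrix (values `0 .. T-1`).
#' @param T Direction bins (8 for the compass banks).
#' @param M,S Excitation quantization, matching `gamma_bins`.
#' @return Integer count vector of length `T * M * S`; sums to the pixel count.
#' @export
excitation_direction_histogram <- function(gamma_bins, D1, T = 8L,
                                           M = 6L, S = 5L) {
  stopifnot(all(dim(gamma_bins) == dim(D1)))
  nbins <- as.integer(M) * as.integer(S)
  joint <- as.vector(D1) * nbins + as.vector(gamma_bins)
  tabulate(joint + 1L, nbins = as.integer(T) * nbins)
}

#' Per-block structure-code histograms
#'
#' Divides the code raster into a regular grid of equally sized sub-blocks and
#' tabulates the 16 structure codes within each; block histograms are
#' concatenated row-major. Sub-blocking preserves the coarse spatial layout of
#' the texture (where on the back a pattern occurs), which a single global
#' histogram would discard.
#'
#' @param L Integer code matrix (values 0..15).
#' @param grid Integer vector `c(rows, cols)`; image dimensions must be
#'   divisible by it.
#' @return Integer count vector of length `prod(grid) * 16`.
#' @export
block_structure_histogram <- function(L, grid = c(4L, 4L)) {
  bid <- block_index(dim(L), grid)
  unlist(lapply(seq_len(prod(grid)), function(b)
    tabulate(L[bid == b] + 1L, nbins = 16L)), use.names = FALSE)
}

#' WTLD feature vector
#'
#' Assembles the final descriptor of an image: the global `T x (M * S)`
#' excitation/direction histogram cascaded with the per-block 16-bin
#' structure-code histograms. At the defaults (T = 8, M = 6, S = 5, 4x4
#' blocks on a 100x100 image) the vector has 240 + 256 = 496 entries drawn
#' from 256 distinct histogram cells. Each of the two segments is L1
#' normalized by default so images of different sizes are comparable under an
#' SVM; raw counts are available with `normalization = "none"`.
#'
#' @param image Numeric intensity matrix (0..255 scale), dimensions divisible
#'   by `grid`.
#' @param params A [wtld_params()].
#' @param grid Sub-block grid `c(rows, cols)`.
#' @param normalization `"l1"`, `"l2"` or `"none"`.
#' @return Numeric vector of class `wtld_feature` with attribute `layout`
#'   naming the two segments.
#' @examples
#' img <- matrix(sample(0:255, 1e4, TRUE), 100, 100)
#' length(wtld_feature(img))   # 496
#' @export
wtld_feature <- function(image, params = wtld_params(), grid = c(4L, 4L),
                         normalization = c("l1", "l2", "none")) {
  normalization <- match.arg(normalization)
  pm <- wtld_pixel_maps(image, params)
  gb <- quantize_excitation(pm$gamma, params$M, params$S)
  seg1 <- excitation_direction_histogram(gb, pm$D[[1]], params$T,
                                         params$M, params$S)
  seg2 <- block_structure_histogram(pm$L, grid)
  out <- normalize_segments(c(seg1, seg2), c(length(seg1), length(seg2)),
                            normalization)
  structure(out,
            layout = list(descriptor = "wtld",
                          excitation_direction = length(seg1),
                          structure_blocks = length(seg2),
                          grid = as.integer(grid),
                          normalization = normalization),
            class = "wtld_feature")
}

#' Extract a feature table from an image dataset
#'
#' Maps a descriptor over every image of a dataset tibble (as returned by
#' [generate_dataset()] or [load_images()]) and returns one row per image:
#' `filename`, `label`, then one numeric column per feature entry. Feature
#' columns are named `ed_*` (excitation/direction segment) and `sc_*`
#' (structure-code blocks) for WTLD, `wld_*` for the baseline.
#'
#' @param data Tibble with columns `filename`, `label` and list-column `image`.
#' @param descriptor `"wtld"`, `"wld"` or `"pixels"` (flattened raw
#'   intensities rescaled to 0..1, the no-descriptor baseline).
#' @param params A [wtld_params()] or [wld_params()] matching the descriptor.
#' @param grid WTLD sub-block grid.
#' @param normalization Passed to the descriptor.
#' @return A tibble of `nrow(data)` feature rows.
#' @examples
#' \donttest{
#' ds <- generate_dataset(synth_config(n_classes = 2, images_per_class = 3))
#' extract_features(ds)
#' }
#' @export
extract_features <- function(data,
                             descriptor = c("wtld", "wld", "pixels"),
                             params = NULL, grid = c(4L, 4L),
                             normalization = "l1") {
  descriptor <- match.arg(descriptor)
  stopifnot(is.data.frame(data), "image" %in% names(data))
  if (nrow(data) == 0L) stop("no images to extract features from", call. = FALSE)
  feats <- switch(descriptor,
    wtld = {
      p <- params %||% wtld_params()
      lapply(data$image, function(img)
        as.numeric(wtld_feature(img, p, grid, normalization)))
    },
    wld = {
      p <- params %||% wld_params("table5")
      lapply(data$image, function(img)
        as.numeric(wld_feature(img, p, normalization)))
    },
    pixels = lapply(data$image, function(img) as.vector(img) / 255)
  )
  len <- unique(vapply(feats, length, 1L))
  if (length(len) != 1L)
    stop("images produced feature vectors of differing lengths", call. = FALSE)
  mat <- do.call(rbind, feats)
  colnames(mat) <- feature_names(descriptor, len,
                                 params %||% switch(descriptor,
                                                    wtld = wtld_params(),
                                                    wld = wld_params("table5"),
                                                    pixels = NULL),
                                 grid)
  out <- tibble::tibble(
    filename = if ("filename" %in% names(data)) data$filename
               else sprintf("img%04d", seq_len(nrow(data))),
    label = data$label)
  dplyr::bind_cols(out, tibble::as_tibble(mat))
}

#' Write a feature table to CSV
#'
#' Plain-text companion of [extract_features()]: `filename`, `label`, then the
#' feature columns, plus a JSON sidecar describing the layout.
#'
#' @param features Tibble from [extract_features()].
#' @param path CSV output path; the sidecar is written to `paste0(path, ".json")`.
#' @return `path`, invisibly.
#' @export
write_feature_csv <- function(features, path) {
  readr::write_csv(features, path)
  layout <- list(
    n_images = nrow(features),
    n_features = ncol(features) - 2L,
    columns = names(features))
  jsonlite::write_json(layout, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

# --- internals --------------------------------------------------------------

feature_names <- function(descriptor, len, params, grid) {
  if (descriptor == "wtld") {
    n1 <- params$T * params$M * params$S
    c(sprintf("ed_%03d", seq_len(n1)), sprintf("sc_%03d", seq_len(len - n1)))
  } else if (descriptor == "wld") {
    sprintf("wld_%03d", seq_len(len))
  } else {
    sprintf("px_%05d", seq_len(len))
  }
}

# Row-major block id (1-based) of every pixel for an r x c sub-block grid.
block_index <- function(dims, grid) {
  grid <- as.integer(grid)
  stopifnot(length(grid) == 2L, all(grid >= 1L))
  if (any(dims %% grid != 0L))
    stop(sprintf(
      "image dimensions %dx%d are not divisible by the %dx%d block grid; normalize images first",
      dims[1], dims[2], grid[1], grid[2]), call. = FALSE)
  br <- (seq_len(dims[1]) - 1L) %/% (dims[1] %/% grid[1])
  bc <- (seq_len(dims[2]) - 1L) %/% (dims[2] %/% grid[2])
  outer(br, bc, function(r, c) r * grid[2] + c + 1L)
}

normalize_segments <- function(x, seg_lengths, normalization) {
  if (normalization == "none") return(as.numeric(x))
  ends <- cumsum(seg_lengths)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  x <- as.numeric(x)
  for (i in seq_along(seg_lengths)) {
    seg <- x[starts[i]:ends[i]]
    nrm <- if (normalization == "l1") sum(seg) else sqrt(sum(seg^2))
    if (nrm > 0) x[starts[i]:ends[i]] <- seg / nrm
  }
  x
}

`%||%` <- function(a, b) if (is.null(a)) b else a
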