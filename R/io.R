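#' Load a labelled image dataset from disk
#'
#' Reads the images listed in a `filename,label` CSV manifest, converts them
#' to 8-bit grayscale (ITU-R BT.601 luma for colour inputs) and resizes them
#' to the working resolution by bilinear interpolation. Rows are returned in
#' manifest order. PNG, JPEG and TIFF inputs are supported.
#'
#' @param dir Directory containing the image files.
#' @param labels_csv Path to the manifest; defaults to `labels.csv` inside
#'   `dir`. Must have a header with columns `filename` and `label`.
#' @param size Target `c(rows, cols)`; `NULL` keeps native resolution.
#' @return Tibble with columns `filename`, `label` (factor) and list-column
#'   `image` (numeric matrices, 0..255).
#' @export
load_images <- function(dir, labels_csv = file.path(dir, "labels.csv"),
                        size = c(100L, 100L)) {
  if (!dir.exists(dir)) stop("image directory not found: ", dir, call. = FALSE)
  if (!file.exists(labels_csv))
    stop("labels manifest not found: ", labels_csv, call. = FALSE)
  man <- readr::read_csv(labels_csv, show_col_types = FALSE)
  if (!all(c("filename", "label") %in% names(man)))
    stop("labels manifest must have columns `filename` and `label`",
         call. = FALSE)
  if (nrow(man) == 0L) stop("labels manifest is empty", call. = FALSE)
  dup <- man$filename[duplicated(man$filename)]
  if (length(dup))
    stop("duplicate filename(s) in manifest: ",
         paste(unique(dup), collapse = ", "), call. = FALSE)
  images <- lapply(seq_len(nrow(man)), function(i) {
    path <- file.path(dir, man$filename[i])
    if (!file.exists(path))
      stop(sprintf("manifest row %d: file not found: %s", i, path),
           call. = FALSE)
    img <- tryCatch(read_gray_image(path),
                    error = function(e)
                      stop(sprintf("manifest row %d: cannot read %s (%s)",
                                   i, path, conditionMessage(e)),
                           call. = FALSE))
    if (!is.null(size)) img <- resize_gray(img, size)
    img
  })
  tibble::tibble(filename = man$filename,
                 label = factor(man$label),
                 image = images)
}

#' Read one image file as an 8-bit grayscale matrix
#'
#' Colour images are converted with the BT.601 luma weights
#' (0.299 R + 0.587 G + 0.114 B) and rounded to integers on the 0..255 scale.
#'
#' @param path Image file (PNG/JPEG/TIFF).
#' @return Numeric matrix, rows = image rows, values 0..255.
#' @export
read_gray_image <- function(path) {
  e <- EBImage::readImage(path)
  d <- EBImage::imageData(e) * 255          # [x, y(, channel)]
  if (length(dim(d)) == 3L) {
    nch <- dim(d)[3]
    d <- if (nch >= 3L) {
      0.299 * d[, , 1] + 0.587 * d[, , 2] + 0.114 * d[, , 3]
    } else d[, , 1]
  }
  clip_uint8(t(d))
}

#' Resize a grayscale matrix by bilinear interpolation
#'
#' @param img Numeric matrix (0..255).
#' @param size Target `c(rows, cols)`.
#' @return Resized integer-valued matrix.
#' @export
resize_gray <- function(img, size = c(100L, 100L)) {
  size <- as.integer(size)
  if (all(dim(img) == size)) return(img)
  e <- EBImage::resize(EBImage::Image(t(img) / 255),
                       w = size[2], h = size[1])
  clip_uint8(t(EBImage::imageData(e)) * 255)
}
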