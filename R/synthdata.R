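#' Configuration for the synthetic back-texture generator
#'
#' Builds labelled synthetic analogues of segmented top-view animal images.
#' Each class (individual) is defined by a base coat intensity, an oriented
#' sinusoidal stripe field standing in for hair-growth direction and spacing,
#' a set of elliptical intensity spots standing in for skin blemishes and coat
#' patches, a smooth linear illumination gradient, and additive Gaussian
#' sensor noise. These are exactly the cue families (hair, skin lines, spots)
#' that texture descriptors exploit for individual identification.
#'
#' Per-class parameters default to a deterministic spread: stripe angles
#' evenly spaced over 180 degrees, stripe frequencies cycling through
#' 6/9/12/15 cycles per image, stripe contrast 25, mean spot counts cycling
#' 2..5, spot intensity deltas alternating +-40, base intensities cycling
#' 100..140. A custom `class_params` tibble (one row per class with columns
#' `stripe_angle`, `stripe_freq`, `stripe_contrast`, `spot_count`,
#' `spot_radius_min`, `spot_radius_max`, `spot_delta`, `base_intensity`)
#' overrides the defaults.
#'
#' @param n_classes Number of individuals (at least 2).
#' @param images_per_class Images generated per individual.
#' @param image_size `c(rows, cols)` of the output rasters.
#' @param noise_sd Standard deviation of the additive Gaussian noise,
#'   intensity units (0..255 scale).
#' @param illumination_range Peak-to-trough amplitude range of the linear
#'   illumination gradient, intensity units.
#' @param seed Integer seed; the same seed reproduces the dataset bytewise.
#' @param class_params Optional per-class parameter tibble (see Details).
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(n_classes = 10L, images_per_class = 50L,
                         image_size = c(100L, 100L), noise_sd = 10,
                         illumination_range = c(5, 20), seed = 1L,
                         class_params = NULL) {
  n_classes <- as.integer(n_classes)
  if (n_classes < 2L) stop("n_classes must be at least 2", call. = FALSE)
  if (is.null(class_params)) {
    k <- seq_len(n_classes) - 1L
    class_params <- tibble::tibble(
      stripe_angle    = k * 180 / n_classes,
      stripe_freq     = c(6, 9, 12, 15)[k %% 4L + 1L],
      stripe_contrast = 25,
      spot_count      = k %% 4L + 2L,
      spot_radius_min = 3,
      spot_radius_max = 8,
      spot_delta      = ifelse(k %% 2L == 0L, 40, -40),
      base_intensity  = c(100, 110, 120, 130, 140)[k %% 5L + 1L])
  }
  stopifnot(nrow(class_params) == n_classes)
  degenerate <- nrow(dplyr::distinct(class_params)) < n_classes &&
    all(class_params$stripe_contrast == 0) && all(class_params$spot_count == 0)
  if (degenerate)
    warning("classes share identical parameters with zero contrast and no spots; dataset is not separable")
  structure(
    list(n_classes = n_classes,
         images_per_class = as.integer(images_per_class),
         image_size = as.integer(image_size), noise_sd = noise_sd,
         illumination_range = illumination_range, seed = as.integer(seed),
         class_params = class_params),
    class = "synth_config")
}

#' Generate a labelled synthetic texture dataset
#'
#' Draws `images_per_class` images for each class under a fixed seed. Every
#' image is the class's base intensity plus its oriented stripe field (random
#' phase per image), randomly placed elliptical spots (Poisson-distributed
#' count around the class mean), a random-direction linear illumination
#' gradient and Gaussian noise, clipped and rounded to 8-bit intensities.
#'
#' @param config A [synth_config()].
#' @param out_dir Optional directory; when given, images are written as PNG
#'   files along with a `labels.csv` manifest (columns `filename,label`) and a
#'   `config.json` record of the resolved configuration.
#' @return Tibble with columns `filename`, `label` (factor `class01`, ...)
#'   and list-column `image` (integer matrices, 0..255).
#' @examples
#' ds <- generate_dataset(synth_config(n_classes = 2, images_per_class = 2))
#' dim(ds$image[[1]])
#' @export
generate_dataset <- function(config = synth_config(), out_dir = NULL) {
  stopifnot(inherits(config, "synth_config"))
  nr <- config$image_size[1]; nc <- config$image_size[2]
  rows <- vector("list", config$n_classes * config$images_per_class)
  old <- local_seed(config$seed)
  on.exit(restore_seed(old), add = TRUE)
  n <- 0L
  for (k in seq_len(config$n_classes)) {
    cp <- config$class_params[k, ]
    for (j in seq_len(config$images_per_class)) {
      n <- n + 1L
      img <- synth_image(nr, nc, cp, config$noise_sd,
                         config$illumination_range)
      rows[[n]] <- list(
        filename = sprintf("class%02d_img%03d.png", k, j),
        label = sprintf("class%02d", k), image = img)
    }
  }
  out <- tibble::tibble(
    filename = vapply(rows, `[[`, "", "filename"),
    label = factor(vapply(rows, `[[`, "", "label")),
    image = lapply(rows, `[[`, "image"))
  if (!is.null(out_dir)) write_dataset(out, config, out_dir)
  out
}

#' Degrade images to stress-test descriptor robustness
#'
#' Applies seeded random rotations, rescalings and occluding bars to every
#' image of a dataset, emulating free posture and partial visibility of the
#' animal under the camera.
#'
#' @param data Dataset tibble with an `image` list-column.
#' @param rotation_range Either a single non-negative number `r` (angles drawn
#'   uniformly from `[-r, r]` degrees) or a vector of discrete angles sampled
#'   uniformly. Multiples of 90 are applied exactly; other angles use bilinear
#'   resampling with the image mean as background.
#' @param scale_range `c(min, max)` multiplicative scale factors; the rescaled
#'   image is centre-cropped or mean-padded back to the original size.
#' @param occlusion_fraction Fraction of image rows covered by a flat bar at
#'   the image's mean intensity (1 blanks the whole image).
#' @param seed Integer seed.
#' @return The dataset tibble with transformed images.
#' @export
degrade <- function(data, rotation_range = 0, scale_range = c(1, 1),
                    occlusion_fraction = 0, seed = 1L) {
  stopifnot(is.data.frame(data), "image" %in% names(data),
            occlusion_fraction >= 0, occlusion_fraction <= 1)
  old <- local_seed(as.integer(seed))
  on.exit(restore_seed(old), add = TRUE)
  data$image <- lapply(data$image, function(img) {
    angle <- if (length(rotation_range) > 1L) {
      sample(rotation_range, 1L)
    } else if (rotation_range > 0) {
      stats::runif(1, -rotation_range, rotation_range)
    } else 0
    s <- if (diff(range(scale_range)) > 0)
      stats::runif(1, scale_range[1], scale_range[2]) else scale_range[1]
    img <- rotate_image(img, angle)
    img <- rescale_image(img, s)
    occlude_rows(img, occlusion_fraction)
  })
  data
}

# --- internals --------------------------------------------------------------

synth_image <- function(nr, nc, cp, noise_sd, illum_range) {
  y <- matrix(seq_len(nr), nr, nc)            # row coordinate, top down
  x <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  img <- matrix(cp$base_intensity, nr, nc)
  # oriented hair stripes: sinusoid along the class direction, random phase
  th <- cp$stripe_angle * pi / 180
  phase <- stats::runif(1, 0, 2 * pi)
  u <- (x * cos(th) + y * sin(th)) / max(nr, nc)
  img <- img + cp$stripe_contrast * sin(2 * pi * cp$stripe_freq * u + phase)
  # elliptical skin spots, Poisson count around the class mean
  nspots <- stats::rpois(1, cp$spot_count)
  for (s in seq_len(nspots)) {
    cy <- stats::runif(1, 1, nr); cx <- stats::runif(1, 1, nc)
    ry <- stats::runif(1, cp$spot_radius_min, cp$spot_radius_max)
    rx <- stats::runif(1, cp$spot_radius_min, cp$spot_radius_max)
    rot <- stats::runif(1, 0, pi)
    dy <- y - cy; dx <- x - cx
    ex <- ((dx * cos(rot) + dy * sin(rot)) / rx)^2 +
          ((-dx * sin(rot) + dy * cos(rot)) / ry)^2
    img <- img + cp$spot_delta * (ex <= 1)
  }
  # smooth linear illumination gradient in a random direction
  amp <- stats::runif(1, illum_range[1], illum_range[2])
  dirg <- stats::runif(1, 0, 2 * pi)
  g <- (x * cos(dirg) + y * sin(dirg))
  g <- (g - min(g)) / max(max(g) - min(g), 1)
  img <- img + amp * (g - 0.5)
  img <- img + stats::rnorm(nr * nc, 0, noise_sd)
  clip_uint8(img)
}

write_dataset <- function(data, config, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_len(nrow(data))) {
    png::writePNG(data$image[[i]] / 255,
                  file.path(out_dir, data$filename[i]))
  }
  readr::write_csv(
    tibble::tibble(filename = data$filename,
                   label = as.character(data$label)),
    file.path(out_dir, "labels.csv"))
  cfg <- unclass(config)
  cfg$class_params <- as.data.frame(cfg$class_params)
  jsonlite::write_json(cfg, file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

rotate_image <- function(img, angle) {
  angle <- angle %% 360
  if (angle == 0) return(img)
  if (angle %% 90 == 0) {
    for (i in seq_len(angle %/% 90)) img <- rot90_ccw(img)
    return(img)
  }
  bg <- mean(img)
  e <- EBImage::rotate(EBImage::Image(t(img) / 255), -angle,  # CCW-positive
                       output.dim = c(ncol(img), nrow(img)),
                       bg.col = bg / 255)
  clip_uint8(t(EBImage::imageData(e)) * 255)
}

rescale_image <- function(img, s) {
  if (s == 1) return(img)
  nr <- nrow(img); nc <- ncol(img)
  e <- EBImage::resize(EBImage::Image(t(img) / 255),
                       w = max(2L, round(nc * s)), h = max(2L, round(nr * s)))
  out <- t(EBImage::imageData(e)) * 255
  res <- matrix(mean(img), nr, nc)
  rr <- min(nr, nrow(out)); cc <- min(nc, ncol(out))
  r0 <- (nr - rr) %/% 2L; c0 <- (nc - cc) %/% 2L
  sr0 <- (nrow(out) - rr) %/% 2L; sc0 <- (ncol(out) - cc) %/% 2L
  res[r0 + seq_len(rr), c0 + seq_len(cc)] <-
    out[sr0 + seq_len(rr), sc0 + seq_len(cc)]
  clip_uint8(res)
}

occlude_rows <- function(img, fraction) {
  if (fraction <= 0) return(img)
  nr <- nrow(img)
  h <- min(nr, ceiling(fraction * nr))
  top <- if (h >= nr) 1L else sample.int(nr - h + 1L, 1L)
  img[top:(top + h - 1L), ] <- round(mean(img))
  img
}

# Seed handling: install a reproducible RNG state and hand back the previous
# one so library calls never perturb the caller's stream.
local_seed <- function(seed) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  old
}

restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible()
}
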