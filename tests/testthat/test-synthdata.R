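test_that("the generator is seeded, shaped and 8-bit clean", {
  cfg <- synth_config(n_classes = 4, images_per_class = 3, seed = 42)
  d1 <- generate_dataset(cfg)
  d2 <- generate_dataset(cfg)
  expect_identical(d1, d2)                      # same seed, bytewise identical
  expect_equal(nrow(d1), 12)
  expect_equal(levels(d1$label), sprintf("class%02d", 1:4))
  expect_true(all(vapply(d1$image, function(i)
    all(dim(i) == c(100, 100)), TRUE)))
  rng <- range(unlist(d1$image))
  expect_gte(rng[1], 0); expect_lte(rng[2], 255)
  expect_true(all(unlist(d1$image) == round(unlist(d1$image))))
  d3 <- generate_dataset(synth_config(n_classes = 4, images_per_class = 3,
                                      seed = 43))
  expect_false(identical(d1$image, d3$image))   # different seed, different data
})

test_that("degenerate identical-class configurations warn, not error", {
  cp <- tibble::tibble(stripe_angle = c(0, 0), stripe_freq = c(8, 8),
                       stripe_contrast = c(0, 0), spot_count = c(0, 0),
                       spot_radius_min = 3, spot_radius_max = 5,
                       spot_delta = 0, base_intensity = 120)
  expect_warning(synth_config(n_classes = 2, images_per_class = 2,
                              class_params = cp), "not separable")
})

test_that("noise-free orthogonal stripe classes are perfectly separable", {
  cp <- tibble::tibble(stripe_angle = c(0, 90), stripe_freq = 10,
                       stripe_contrast = 40, spot_count = 0,
                       spot_radius_min = 3, spot_radius_max = 5,
                       spot_delta = 0, base_intensity = 120)
  ds <- generate_dataset(synth_config(n_classes = 2, images_per_class = 10,
                                      noise_sd = 0,
                                      illumination_range = c(0, 0),
                                      seed = 5, class_params = cp))
  ev <- crossval_evaluate(extract_features(ds), kernel = "linear", seed = 1)
  expect_equal(ev$mean_accuracy, 1.0)
})

test_that("accuracy does not improve as sensor noise rises", {
  accs <- sapply(c(0, 10, 30, 60), function(sd) {
    mean(sapply(1:3, function(s) {
      ds <- generate_dataset(synth_config(n_classes = 5, images_per_class = 8,
                                          noise_sd = sd, seed = 100 + s))
      crossval_evaluate(extract_features(ds), kernel = "rbf", C = 100,
                        seed = s)$mean_accuracy
    }))
  })
  # non-increasing up to one small inversion
  inversions <- diff(accs) > 0.01
  expect_lte(sum(inversions), 1)
  expect_lt(accs[4], accs[1] + 0.01)
})

test_that("collapsing two classes onto identical parameters confuses them", {
  cp <- tibble::tibble(stripe_angle = c(30, 30), stripe_freq = 9,
                       stripe_contrast = 25, spot_count = 2,
                       spot_radius_min = 3, spot_radius_max = 6,
                       spot_delta = 30, base_intensity = 120)
  ds <- generate_dataset(synth_config(n_classes = 2, images_per_class = 15,
                                      noise_sd = 10, seed = 77,
                                      class_params = cp))
  ev <- crossval_evaluate(extract_features(ds), kernel = "rbf", C = 100,
                          seed = 3)
  diag_pct <- diag(ev$confusion_pct)
  expect_true(all(diag_pct > 15 & diag_pct < 85))
})

test_that("degrade applies identity, exact right angles and full occlusion", {
  ds <- tiny_dataset(n_classes = 2, images_per_class = 2, seed = 50)
  same <- degrade(ds, rotation_range = 0, scale_range = c(1, 1),
                  occlusion_fraction = 0)
  expect_identical(same$image, ds$image)
  # right-angle rotation set: images are exact grid rotations
  rot <- degrade(ds, rotation_range = c(90, 180, 270), seed = 13)
  img <- ds$image[[1]]; got <- rot$image[[1]]
  candidates <- list(wtld:::rot90_ccw(img),
                     wtld:::rot180(img),
                     wtld:::rot90_ccw(wtld:::rot180(img)))
  expect_true(any(vapply(candidates, identical, TRUE, y = got)))
  # full occlusion flattens the image
  occ <- degrade(ds, occlusion_fraction = 1, seed = 3)
  expect_true(all(vapply(occ$image, function(i) length(unique(c(i))) == 1, TRUE)))
  # seeded: reproducible
  r1 <- degrade(ds, rotation_range = 20, scale_range = c(0.8, 1.2), seed = 9)
  r2 <- degrade(ds, rotation_range = 20, scale_range = c(0.8, 1.2), seed = 9)
  expect_identical(r1$image, r2$image)
})

test_that("right-angle rotated data stays classifiable above chance", {
  ds <- generate_dataset(synth_config(n_classes = 4, images_per_class = 10,
                                      noise_sd = 10, seed = 60))
  rot <- degrade(ds, rotation_range = c(90, 180, 270), seed = 8)
  both <- dplyr::bind_rows(ds, rot)
  ev <- crossval_evaluate(extract_features(both), kernel = "rbf", C = 100,
                          seed = 2)
  expect_gt(ev$mean_accuracy, 0.5)   # chance is 0.25
})
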