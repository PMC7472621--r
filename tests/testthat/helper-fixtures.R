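random_uint8 <- function(nr, nc, seed) {
  set.seed(seed)
  matrix(sample(0:255, nr * nc, replace = TRUE), nr, nc)
}

# pixels whose maximum directional response is strictly unique (the rotation
# covariance of the argmax only holds where no tie-break is involved)
strict_argmax_mask <- function(img, bank) {
  arr <- simplify2array(directional_responses(img, bank))
  mx <- apply(arr, c(1, 2), max)
  apply(arr == array(mx, dim(arr)), c(1, 2), sum) == 1
}

# small, fast synthetic dataset for classifier-level tests
tiny_dataset <- function(n_classes = 3, images_per_class = 8, seed = 11,
                         noise_sd = 10) {
  generate_dataset(synth_config(n_classes = n_classes,
                                images_per_class = images_per_class,
                                noise_sd = noise_sd, seed = seed))
}
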