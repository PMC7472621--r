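test_that("differential excitation handles the canonical patches", {
  expect_true(all(differential_excitation(matrix(200, 5, 5)) == 0))
  # symmetric neighbourhood cancels exactly
  img <- matrix(c(60, 40, 40, 60, 50, 40, 60, 60, 40), 3)
  expect_equal(differential_excitation(img)[2, 2], 0)
  # centre 100, all eight neighbours 90
  img2 <- matrix(90, 3, 3); img2[2, 2] <- 100
  expect_equal(differential_excitation(img2)[2, 2], atan(-0.8),
               tolerance = 1e-6)
})

test_that("directional responses locate a vertical step edge on the E/W kernels", {
  img <- cbind(matrix(0, 5, 2), matrix(200, 5, 3))
  R <- directional_responses(img, kirsch_bank())
  resp <- vapply(R, function(r) r[3, 3], 1)   # pixel on the bright edge column
  expect_true(which.max(resp) %in% c(1, 5))   # east or west kernel
  # constant image: all responses zero
  R0 <- directional_responses(matrix(9, 4, 4), kirsch_bank())
  expect_true(all(vapply(R0, function(r) all(r == 0), TRUE)))
})

test_that("responses commute with point reflection of the image", {
  img <- random_uint8(10, 12, seed = 17)
  b <- kirsch_bank()
  R <- directional_responses(img, b)
  Rr <- directional_responses(img[10:1, 12:1], b)
  for (i in 1:8) {
    opp <- ((i - 1 + 4) %% 8) + 1
    expect_equal(R[[i]], Rr[[opp]][10:1, 12:1], info = paste("dir", i - 1))
  }
})

test_that("main directions agree with a full-sort oracle and break ties low", {
  mk <- function(v) lapply(v, function(x) matrix(x, 1, 1))
  D <- main_directions(mk(c(5, 1, 1, 1, 1, 1, 1, 1)))
  expect_equal(D[[1]][1, 1], 0)
  expect_equal(vapply(main_directions(mk(rep(2, 8))), function(m) m[1, 1], 1L),
               c(D1 = 0L, D2 = 1L, D3 = 2L, D4 = 3L))
  set.seed(31)
  for (rep in 1:25) {
    v <- sample(0:9, 8, replace = TRUE)        # replicates force ties
    D <- main_directions(mk(v))
    got <- vapply(D, function(m) m[1, 1], 1L)
    expect_equal(unname(got), order(v, decreasing = TRUE)[1:4] - 1L)
  }
})

test_that("intensity differences use the geometrically opposite neighbour", {
  img <- matrix(100, 3, 3)
  img[1, 2] <- 200   # north neighbour of the centre
  img[3, 2] <- 50    # south neighbour
  Dn <- lapply(c(2L, 0L, 1L, 3L), function(d) matrix(d, 3, 3))
  C <- intensity_differences(img, Dn)
  expect_equal(C[[1]][2, 2], 150)              # D = north: N - S
  Ds <- lapply(c(6L, 0L, 1L, 3L), function(d) matrix(d, 3, 3))
  expect_equal(intensity_differences(img, Ds)[[1]][2, 2], -150)  # D = south
  C0 <- intensity_differences(matrix(7, 3, 3), Dn)
  expect_true(all(vapply(C0, function(m) all(m == 0), TRUE)))
})

test_that("adaptive threshold averages and binarizes strictly", {
  mk <- function(v) lapply(v, function(x) matrix(x, 1, 1))
  # all zero differences: sigma 0, strict inequality keeps all bits 0
  thr0 <- adaptive_threshold(mk(c(0, 0, 0, 0)))
  expect_equal(thr0$sigma[1, 1], 0)
  expect_true(all(vapply(thr0$Mbits, function(m) m[1, 1], 1L) == 0L))
  # |C| = (8, 4, 2, 2): sigma 4, only the first difference exceeds it
  thr <- adaptive_threshold(mk(c(8, -4, 2, -2)))
  expect_equal(thr$sigma[1, 1], 4)
  expect_equal(vapply(thr$Mbits, function(m) m[1, 1], 1L),
               c(M1 = 1L, M2 = 0L, M3 = 0L, M4 = 0L))
  # threshold is homogeneous: scaling differences leaves bits unchanged
  for (k in c(0.5, 2, 3)) {
    thrk <- adaptive_threshold(mk(k * c(8, -4, 2, -2)))
    expect_equal(thrk$Mbits, thr$Mbits)
  }
})

test_that("both sigma rules are valid and coincide for equal differences", {
  img <- random_uint8(12, 12, seed = 23)
  for (rule in c("over_n", "over_n_minus_1")) {
    pm <- wtld_pixel_maps(img, wtld_params(sigma_rule = rule))
    expect_true(all(vapply(pm$Mbits, function(m) all(m %in% 0:1), TRUE)))
    expect_true(all(pm$L >= 0 & pm$L <= 15))
  }
  mk <- function(v) lapply(v, function(x) matrix(x, 2, 2))
  eq <- mk(c(6, -6, 6, -6))
  a <- adaptive_threshold(eq, "over_n")
  b <- adaptive_threshold(eq, "over_n_minus_1")
  expect_equal(a$sigma, b$sigma)
  expect_equal(a$Mbits, b$Mbits)
})

test_that("structure code composes direction and bit", {
  expect_equal(structure_code(0L, 0L), 0L)
  expect_equal(structure_code(7L, 1L), 15L)
  expect_equal(structure_code(3L, 1L), 7L)
  D1 <- matrix(0:7, 2); M1 <- matrix(rep(0:1, 4), 2)
  expect_true(all(structure_code(D1, M1) == 2L * D1 + M1))
  # optional two-direction code spans 0..31
  expect_equal(structure_code(7L, 1L, M2 = 1L), 31L)
})

test_that("vectorized pixel maps match the naive per-pixel reference", {
  for (seed in c(1, 2, 3)) {
    img <- random_uint8(16, 16, seed = seed)
    for (rule in c("over_n", "over_n_minus_1")) {
      p <- wtld_params(sigma_rule = rule)
      pm <- wtld_pixel_maps(img, p)
      or <- oracle_pixel_maps(img, p)
      expect_identical(pm$gamma, or$gamma)
      expect_identical(pm$R, or$R)
      expect_identical(pm$D, or$D)
      expect_identical(pm$C, or$C)
      expect_identical(pm$Mbits, or$Mbits)
      expect_identical(pm$L, or$L)
    }
  }
})

test_that("the full pipeline is invariant to intensity scaling", {
  img <- random_uint8(20, 20, seed = 41) + 1
  base <- wtld_pixel_maps(img)
  for (k in c(0.5, 2, 3)) {
    pm <- wtld_pixel_maps(k * img)
    expect_identical(pm$L, base$L, label = paste("k =", k))
    expect_identical(pm$D, base$D)
    expect_identical(pm$Mbits, base$Mbits)
  }
})

test_that("directional images behave under ties, duplication and negation", {
  expect_true(all(directional_image(matrix(5, 6, 6)) == 0))   # ties -> index 0
  img <- random_uint8(15, 15, seed = 8)
  d1 <- directional_image(img)
  expect_equal(correlation_coefficient(d1, directional_image(img)), 1.0)
  # zero-sum kernels: the negative image has identical absolute responses
  expect_identical(directional_image(255 - img), d1)
})

test_that("correlation coefficient matches its definition", {
  A <- matrix(c(1, 2, 3, 4, 5, 6, 7, 8, 10), 3)
  E <- matrix(c(2, 1, 4, 3, 6, 5, 8, 7, 9), 3)
  expect_equal(correlation_coefficient(A, E),
               stats::cor(as.vector(A), as.vector(E)))
  expect_equal(correlation_coefficient(A, A), 1.0)
  expect_equal(correlation_coefficient(A, 2 * mean(A) - A), -1.0)
  expect_error(correlation_coefficient(A, matrix(1, 3, 3)), "constant")
  expect_error(correlation_coefficient(A, matrix(1, 2, 2)), "dimensions")
})
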