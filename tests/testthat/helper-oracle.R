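# Independent naive reference for the per-pixel coding: explicit double loops
# over pixels (and kernel cells), no vectorization. Used to validate the
# package's raster implementation bit for bit.

oracle_clamp <- function(i, n) min(max(i, 1L), n)

# neighbour value in direction d (0..7) with replicate padding
oracle_neighbor <- function(img, r, c, d) {
  off <- wtld:::dir_offsets()
  img[oracle_clamp(r + off[d + 1L, 1L], nrow(img)),
      oracle_clamp(c + off[d + 1L, 2L], ncol(img))]
}

oracle_pixel_maps <- function(img, params = wtld_params()) {
  bank <- mask_bank(params$mask_family, params$mask_size)
  nr <- nrow(img); nc <- ncol(img)
  gamma <- matrix(0, nr, nc)
  R <- lapply(1:8, function(i) matrix(0, nr, nc))
  D <- lapply(1:4, function(i) matrix(0L, nr, nc))
  C <- lapply(1:4, function(i) matrix(0, nr, nc))
  Mb <- lapply(1:4, function(i) matrix(0L, nr, nc))
  L <- matrix(0L, nr, nc)
  half <- (params$mask_size - 1L) %/% 2L
  for (r in seq_len(nr)) {
    for (c in seq_len(nc)) {
      xc <- img[r, c]
      s <- 0
      for (d in 0:7) s <- s + (oracle_neighbor(img, r, c, d) - xc) / (xc + params$epsilon)
      gamma[r, c] <- atan(s)
      resp <- numeric(8)
      for (i in 1:8) {
        k <- bank$kernels[[i]]
        acc <- 0
        for (a in seq_len(params$mask_size)) {
          for (b in seq_len(params$mask_size)) {
            acc <- acc + k[a, b] *
              img[oracle_clamp(r + a - 1L - half, nr),
                  oracle_clamp(c + b - 1L - half, nc)]
          }
        }
        resp[i] <- abs(acc)
      }
      for (i in 1:8) R[[i]][r, c] <- resp[i]
      ord <- order(resp, decreasing = TRUE) - 1L   # stable: smallest index first
      for (i in 1:4) D[[i]][r, c] <- ord[i]
      cs <- numeric(4)
      for (i in 1:4) {
        d1 <- ord[i]
        cs[i] <- oracle_neighbor(img, r, c, d1) -
          oracle_neighbor(img, r, c, (d1 + 4L) %% 8L)
        C[[i]][r, c] <- cs[i]
      }
      sigma <- if (params$sigma_rule == "over_n") {
        (abs(cs[1]) + abs(cs[2]) + abs(cs[3]) + abs(cs[4])) / 4
      } else {
        (abs(cs[1]) + abs(cs[2]) + abs(cs[3])) / 3
      }
      for (i in 1:4) Mb[[i]][r, c] <- as.integer(abs(cs[i]) > sigma)
      L[r, c] <- 2L * D[[1]][r, c] + Mb[[1]][r, c]
    }
  }
  names(D) <- paste0("D", 1:4)
  names(C) <- paste0("C", 1:4)
  names(Mb) <- paste0("M", 1:4)
  list(gamma = gamma, R = R, D = D, C = C, Mbits = Mb, L = L)
}

# brute-force joint tally of (direction, excitation-bin) pairs
oracle_joint_histogram <- function(gamma_bins, D1, T, M, S) {
  h <- integer(T * M * S)
  for (r in seq_len(nrow(D1))) {
    for (c in seq_len(ncol(D1))) {
      idx <- D1[r, c] * (M * S) + gamma_bins[r, c] + 1L
      h[idx] <- h[idx] + 1L
    }
  }
  h
}

# brute-force per-block 16-bin tally, blocks row-major
oracle_block_histogram <- function(L, grid) {
  bh <- nrow(L) %/% grid[1]; bw <- ncol(L) %/% grid[2]
  out <- integer(0)
  for (br in seq_len(grid[1])) {
    for (bc in seq_len(grid[2])) {
      h <- integer(16)
      for (r in (br - 1L) * bh + seq_len(bh)) {
        for (c in (bc - 1L) * bw + seq_len(bw)) {
          h[L[r, c] + 1L] <- h[L[r, c] + 1L] + 1L
        }
      }
      out <- c(out, h)
    }
  }
  out
}
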