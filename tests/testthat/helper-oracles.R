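# Brute-force reference implementations, written as explicit per-pixel loops
# and kept deliberately naive. They are the independent oracles the fast
# vectorised descriptor code is checked against.

oracle_gradients <- function(img) {
  nr <- nrow(img)
  nc <- ncol(img)
  ix <- iy <- g <- th <- matrix(0, nr, nc)
  clamp <- function(i, n) min(max(i, 1L), n)
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      ix[i, j] <- img[i, clamp(j + 1L, nc)] - img[i, clamp(j - 1L, nc)]
      iy[i, j] <- img[clamp(i + 1L, nr), j] - img[clamp(i - 1L, nr), j]
      g[i, j] <- sqrt(ix[i, j]^2 + iy[i, j]^2)
      a <- atan2(iy[i, j], ix[i, j]) * 180 / pi
      a <- a %% 180
      if (a >= 180) a <- 0
      if (g[i, j] == 0) a <- 0
      th[i, j] <- a
    }
  }
  list(ix = ix, iy = iy, magnitude = g, orientation = th)
}

oracle_hog <- function(img, n_bins = 9, n_blocks = 9, overlap = 0.5,
                       epsilon = 1e-5) {
  gr <- oracle_gradients(img)
  n <- ncol(img)
  w <- n / (1 + (n_blocks - 1) * (1 - overlap))
  out <- numeric(0)
  for (b in seq_len(n_blocks)) {
    lo <- floor((b - 1) * (1 - overlap) * w) + 1
    hi <- floor(((b - 1) * (1 - overlap) + 1) * w)
    hist <- numeric(n_bins)
    for (i in seq_len(nrow(img))) {
      for (j in lo:hi) {
        bin <- min(floor(gr$orientation[i, j] / (180 / n_bins)), n_bins - 1) + 1
        hist[bin] <- hist[bin] + gr$magnitude[i, j]
      }
    }
    out <- c(out, hist / sqrt(sum(hist^2) + epsilon^2))
  }
  out
}

oracle_lbp <- function(img) {
  counts <- numeric(256)
  offs <- list(c(-1, -1), c(-1, 0), c(-1, 1), c(0, 1),
               c(1, 1), c(1, 0), c(1, -1), c(0, -1))
  for (i in 2:(nrow(img) - 1)) {
    for (j in 2:(ncol(img) - 1)) {
      code <- 0
      for (k in seq_along(offs)) {
        nb <- img[i + offs[[k]][1], j + offs[[k]][2]]
        if (nb >= img[i, j]) code <- code + 2^(k - 1)
      }
      counts[code + 1] <- counts[code + 1] + 1
    }
  }
  counts
}
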