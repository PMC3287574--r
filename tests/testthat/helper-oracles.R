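# Independent oracles used across test files. These deliberately avoid the
# package's own kernels: the flood oracle is a plain linear-scan simulation,
# the stencil/summation oracles are direct loops.

# Brute-force marker flood: exhaustive level-by-level expansion. Keeps every
# frontier entry in flat vectors and rescans for the minimal
# (height, insertion counter) each step; expansion enqueues 8-neighbours in
# row-major window order at max(own height, popped height).
flood_oracle <- function(grad, markers) {
  nr <- nrow(grad); nc <- ncol(grad)
  lab <- matrix(0L, nr, nc)
  qh <- numeric(0); qc <- integer(0); qr <- integer(0); qcl <- integer(0)
  qlb <- integer(0)
  cnt <- 0L
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    if (markers[r, c] != 0L) {
      lab[r, c] <- markers[r, c]
      qh <- c(qh, grad[r, c]); qc <- c(qc, cnt); qr <- c(qr, r)
      qcl <- c(qcl, c); qlb <- c(qlb, markers[r, c])
      cnt <- cnt + 1L
    }
  }
  off <- rbind(c(-1L, -1L), c(-1L, 0L), c(-1L, 1L), c(0L, -1L),
               c(0L, 1L), c(1L, -1L), c(1L, 0L), c(1L, 1L))
  while (length(qh) > 0L) {
    lev <- min(qh)
    at <- which(qh == lev)
    i <- at[which.min(qc[at])]
    h <- qh[i]; r <- qr[i]; c <- qcl[i]; l <- qlb[i]
    qh <- qh[-i]; qc <- qc[-i]; qr <- qr[-i]; qcl <- qcl[-i]; qlb <- qlb[-i]
    for (k in 1:8) {
      rr <- r + off[k, 1L]; cc <- c + off[k, 2L]
      if (rr < 1L || rr > nr || cc < 1L || cc > nc) next
      if (lab[rr, cc] == 0L) {
        lab[rr, cc] <- l
        qh <- c(qh, max(grad[rr, cc], h)); qc <- c(qc, cnt)
        qr <- c(qr, rr); qcl <- c(qcl, cc); qlb <- c(qlb, l)
        cnt <- cnt + 1L
      }
    }
  }
  lab
}

# random small watershed instance: gradient heights on a coarse integer
# scale (to exercise ties), 2-4 markers at distinct positions
random_flood_instance <- function(seed) {
  set.seed(seed)
  nr <- sample(2:8, 1L); nc <- sample(2:8, 1L)
  grad <- matrix(sample(0:5, nr * nc, replace = TRUE), nr, nc)
  k <- sample(2:4, 1L)
  pos <- sample(nr * nc, min(k, nr * nc))
  markers <- matrix(0L, nr, nc)
  markers[pos] <- seq_along(pos)
  list(grad = grad, markers = markers)
}

# direct 3x3 Sobel at an interior pixel, edge handling irrelevant
sobel_at <- function(img, r, c) {
  kx <- matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, 3, byrow = TRUE)
  ky <- t(kx)
  win <- img[(r - 1):(r + 1), (c - 1):(c + 1)]
  sqrt(sum(kx * win)^2 + sum(ky * win)^2)
}

# the printed confusion counts and their published 2-dp ratios
published_cases <- function() {
  data.frame(
    case = c("0046", "0051", "0069", "0074", "0123", "0161", "0226", "0274"),
    tp = c(4517, 3235, 2913, 12912, 7419, 4339, 18834, 1583),
    fp = c(635, 370, 1475, 2611, 1452, 2050, 890, 704),
    fn = c(825, 179, 140, 4654, 2566, 858, 575, 80),
    hitting = c(0.85, 0.95, 0.95, 0.74, 0.74, 0.83, 0.97, 0.95),
    missing = c(0.15, 0.05, 0.05, 0.26, 0.26, 0.17, 0.03, 0.05),
    over_hitting = c(0.12, 0.11, 0.48, 0.15, 0.15, 0.39, 0.05, 0.42),
    relative_hitting = c(0.88, 0.90, 0.66, 0.83, 0.84, 0.68, 0.95, 0.69),
    relative_missing = c(0.16, 0.05, 0.03, 0.30, 0.29, 0.13, 0.03, 0.03),
    kappa = c(0.86, 0.92, 0.78, 0.78, 0.79, 0.75, 0.96, 0.80),
    stringsAsFactors = FALSE
  )
}

# a clean two-level disk phantom (no texture, no noise, hard edge)
two_level_disk <- function(side = 64L, radius = 18, lo = 50, hi = 200,
                           seed = 1L) {
  generate_phantom(phantom_spec(height = side, width = side, radius = radius,
                                contrast = hi - lo, softness = 0,
                                background_level = lo, texture_sigma = 0,
                                noise_sigma = 0, seed = seed))
}
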