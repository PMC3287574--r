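test_that("signed-distance init: signs, inverse thresholding, half-plane distances", {
  m <- matrix(0L, 9, 9); m[5, 5] <- 1L
  phi <- init_from_mask(m)
  expect_lt(phi[5, 5], 0)
  expect_true(all(phi[m == 0L] > 0))
  # phi grows with distance from the single mask pixel: d - 1/2 outside
  d <- sqrt(outer((1:9 - 5)^2, (1:9 - 5)^2, `+`))
  expect_equal(phi[m == 0L], d[m == 0L] - 0.5, tolerance = 1e-9)
  expect_equal(phi[5, 5], -0.5)

  # half-plane: |phi| = distance to nearest opposite pixel - 1/2,
  # checked against an exhaustive nearest-boundary search
  hp <- matrix(0L, 8, 12); hp[, 1:5] <- 1L
  phi2 <- init_from_mask(hp)
  for (r in c(1, 4, 8)) for (c in c(1, 5, 6, 12)) {
    opp <- which(hp != hp[r, c], arr.ind = TRUE)
    dmin <- min(sqrt((opp[, 1] - r)^2 + (opp[, 2] - c)^2))
    expect_equal(abs(phi2[r, c]), dmin - 0.5, tolerance = 1e-9)
  }

  # threshold inverse
  set.seed(3)
  rndm <- matrix(rbinom(100, 1, 0.4), 10, 10)
  if (any(rndm == 1) && any(rndm == 0))
    expect_identical(matrix(as.integer(init_from_mask(rndm) < 0), 10, 10), rndm)
  expect_error(init_from_mask(matrix(1L, 4, 4)), "inside and outside")
})

test_that("region means are the per-region averages", {
  img <- matrix(7.5, 6, 6)
  phi <- matrix(1, 6, 6); phi[3:4, 3:4] <- -1
  expect_equal(region_means(img, phi), c(c1 = 7.5, c2 = 7.5))
  img2 <- matrix(50, 6, 6); img2[3:4, 3:4] <- 200
  expect_equal(region_means(img2, phi), c(c1 = 200, c2 = 50))
  set.seed(8)
  img3 <- matrix(runif(36, 0, 255), 6, 6)
  phi3 <- matrix(rnorm(36), 6, 6)
  want <- c(c1 = sum(img3[phi3 < 0]) / sum(phi3 < 0),
            c2 = sum(img3[phi3 >= 0]) / sum(phi3 >= 0))
  expect_equal(region_means(img3, phi3), want)
  expect_error(region_means(img3, abs(phi3)), "degenerate")
})

test_that("energy: zero data terms on an exact partition, brute-force sums, co-area length", {
  img <- matrix(50, 8, 8); img[3:6, 3:6] <- 200
  mask <- matrix(0L, 8, 8); mask[3:6, 3:6] <- 1L
  phi <- init_from_mask(mask)
  e_mu0 <- chan_vese_energy(img, phi, mu = 0)
  expect_equal(e_mu0, 0)
  e_len <- chan_vese_energy(img, phi, lambda1 = 0, lambda2 = 0, mu = 1)
  expect_equal(chan_vese_energy(img, phi, mu = 0.3), 0.3 * e_len)

  # mu = 0: energy equals the two summed squared residuals, by direct loops
  set.seed(21)
  img5 <- matrix(runif(25, 0, 1), 5, 5)
  phi5 <- matrix(rnorm(25), 5, 5)
  c1 <- mean(img5[phi5 < 0]); c2 <- mean(img5[phi5 >= 0])
  want <- sum((img5[phi5 < 0] - c1)^2) + sum((img5[phi5 >= 0] - c2)^2)
  expect_equal(chan_vese_energy(img5, phi5, mu = 0), want, tolerance = 1e-12)

  # co-area length of a large centred disk approximates its circumference
  m <- matrix(0L, 128, 128)
  d <- sqrt(outer((1:128 - 64.5)^2, (1:128 - 64.5)^2, `+`))
  m[d <= 30] <- 1L
  len <- chan_vese_energy(matrix(1, 128, 128), init_from_mask(m),
                          lambda1 = 0, lambda2 = 0, mu = 1)
  expect_lt(abs(len - 2 * pi * 30) / (2 * pi * 30), 0.10)
})

test_that("evolution recovers a piecewise-constant disk exactly from a crude mask", {
  ph <- two_level_disk()
  m0 <- matrix(0L, 64, 64); m0[20:48, 28:56] <- 1L  # overlaps disk and background
  fit <- chan_vese(ph$image, m0)
  expect_identical(fit$mask, ph$mask)
  expect_false(fit$degenerate)
})

test_that("an exact two-region partition is a fixed point under mu = 0", {
  img <- matrix(40, 20, 20); img[6:14, 6:14] <- 210
  mask <- matrix(0L, 20, 20); mask[6:14, 6:14] <- 1L
  fit <- chan_vese(img, mask, mu = 0)
  expect_identical(fit$mask, mask)
  expect_lte(fit$iterations_run, 5L)
})

test_that("constant images yield a degenerate flag or an unchanged mask", {
  img <- matrix(120, 24, 24)
  m0 <- matrix(0L, 24, 24); m0[8:16, 8:16] <- 1L
  fit <- chan_vese(img, m0)
  expect_true(fit$degenerate || identical(fit$mask, m0))
})

test_that("energy history is non-increasing within tolerance on the disk fixture", {
  ph <- two_level_disk()
  m0 <- matrix(0L, 64, 64); m0[20:48, 28:56] <- 1L
  fit <- chan_vese(ph$image, m0)
  eh <- fit$energy_history
  expect_true(all(diff(eh) <= pmax(abs(eh[-length(eh)]) * 1e-6, 1e-9)))
  # and the returned mask is exactly the phi < 0 set
  expect_identical(fit$mask,
                   matrix(as.integer(fit$phi < 0), nrow(fit$phi), ncol(fit$phi)))
})

test_that("level-set refinement does not degrade the watershed mask on phantoms", {
  better <- 0L
  seeds <- 0:4
  for (s in seeds) {
    ph <- generate_phantom(phantom_spec(seed = s))
    fit <- suppressWarnings(segment_mass(ph$image))
    d0 <- dice(ph$mask, fit$coarse_mask)
    d1 <- dice(ph$mask, fit$final_mask)
    if (d1 >= d0) better <- better + 1L
  }
  expect_gte(better, ceiling(0.9 * length(seeds)) - 1L)
})
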