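test_that("mean filter averages the window and replicates edges", {
  expect_identical(mean_filter(matrix(1:9, 3, 3), 1L), matrix(1:9, 3, 3))
  img <- matrix(10, 3, 3); img[2, 2] <- 100
  expect_equal(mean_filter(img, 3L)[2, 2], (8 * 10 + 100) / 9)
  expect_equal(mean_filter(matrix(5, 6, 6), 5L), matrix(5, 6, 6))
  # corner pixel: replicated edges weight the corner value
  img2 <- matrix(0, 4, 4); img2[1, 1] <- 9
  expect_equal(mean_filter(img2, 3L)[1, 1], 4 * 9 / 9)
  expect_error(mean_filter(img, 2L), "odd")
})

test_that("gaussian filter is normalized and matches its kernel on an impulse", {
  expect_equal(gaussian_filter(matrix(3.5, 8, 8), 1.5), matrix(3.5, 8, 8),
               tolerance = 1e-9)
  side <- 2L * ceiling(4 * 1) + 1L
  n <- 2L * side + 1L
  img <- matrix(0, n, n); img[side + 1L, side + 1L] <- 1
  got <- gaussian_filter(img, 1)
  k <- gaussian_kernel(1)
  ctr <- side + 1L; r <- (side - 1L) %/% 2L
  expect_equal(got[(ctr - r):(ctr + r), (ctr - r):(ctr + r)], k,
               tolerance = 1e-9)
  expect_error(gaussian_filter(img, 0), "sigma")
})

test_that("larger sigma never increases intensity variance", {
  set.seed(11)
  img <- matrix(runif(900, 0, 255), 30, 30)
  vars <- sapply(c(0.5, 1, 2, 4), function(s) var(as.vector(gaussian_filter(img, s))))
  expect_true(all(diff(vars) <= 1e-9))
})

test_that("anisotropic diffusion: identity cases and the single-step stencil", {
  img <- matrix(runif(100, 0, 255), 10, 10)
  expect_identical(anisotropic_diffusion(img, iterations = 0L), img)
  expect_equal(anisotropic_diffusion(matrix(42, 7, 7), 25L), matrix(42, 7, 7))
  # 1x3 fixture, one step, exponential conduction, by direct stencil arithmetic
  g <- function(s) exp(-(s / 30)^2)
  got <- anisotropic_diffusion(matrix(c(0, 100, 0), 1), iterations = 1L,
                               kappa = 30, rate = 0.25)
  want <- c(0 + 0.25 * g(100) * 100,
            100 + 0.25 * 2 * g(100) * (-100),
            0 + 0.25 * g(100) * 100)
  expect_equal(as.vector(got), want)
  # rational conduction uses its own g
  g2 <- function(s) 1 / (1 + (s / 30)^2)
  got2 <- anisotropic_diffusion(matrix(c(0, 100, 0), 1), iterations = 1L,
                                conduction = "rational")
  expect_equal(got2[1, 2], 100 - 0.25 * 2 * g2(100) * 100)
  expect_error(anisotropic_diffusion(img, rate = 0.3), "rate")
})

test_that("diffusion conserves total intensity and respects extremum bounds", {
  set.seed(99)
  for (i in 1:10) {
    img <- matrix(runif(20 * 20, 0, 255), 20, 20)
    out <- anisotropic_diffusion(img, iterations = 50L)
    expect_equal(sum(out), sum(img), tolerance = 1e-6)
    expect_gte(min(out), min(img) - 1e-9)
    expect_lte(max(out), max(img) + 1e-9)
  }
})

test_that("diffusion preserves a high-contrast step better than a Gaussian blur", {
  img <- matrix(0, 32, 32); img[, 17:32] <- 200   # contrast 200 >> kappa 30
  ad <- anisotropic_diffusion(img, iterations = 20L)
  gs <- gaussian_filter(img, 2)
  step_ad <- abs(ad[16, 17] - ad[16, 16])
  step_gs <- abs(gs[16, 17] - gs[16, 16])
  expect_gt(step_ad, step_gs)
  expect_gt(step_ad, 0.9 * 200)  # edge essentially intact
})

test_that("denoise dispatcher routes to the right filter", {
  img <- matrix(runif(64, 0, 255), 8, 8)
  expect_identical(denoise(img, "none"), img)
  expect_equal(denoise(img, "mean", size = 3L), mean_filter(img, 3L))
  expect_equal(denoise(img, "gaussian", sigma = 1), gaussian_filter(img, 1))
  expect_equal(denoise(img, "anisotropic", iterations = 3L),
               anisotropic_diffusion(img, iterations = 3L))
})
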