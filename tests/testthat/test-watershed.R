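test_that("gradient magnitude: zero on constants, symmetric on a step, exact Sobel", {
  expect_equal(gradient_magnitude(matrix(9, 6, 6)), matrix(0, 6, 6))
  img <- matrix(0, 8, 8); img[, 5:8] <- 255
  g <- gradient_magnitude(img)
  expect_true(all(g[, 4:5] > 0))
  expect_equal(g[, 1:2], matrix(0, 8, 2))
  expect_equal(g[, 7:8], matrix(0, 8, 2))
  expect_equal(g[2:7, 4], g[2:7, 5])   # mirror symmetry across the step
  set.seed(5)
  rnd <- matrix(runif(49, 0, 255), 7, 7)
  for (r in 3:5) for (c in 3:5)
    expect_equal(gradient_magnitude(rnd)[r, c], sobel_at(rnd, r, c),
                 tolerance = 1e-9)
})

test_that("marker extraction finds one marker per bright blob", {
  # one soft blob on a dark background
  ph <- generate_phantom(phantom_spec(96, 96, center = c(48, 48), radius = 20,
                                      contrast = 150, softness = 4,
                                      background_level = 30, texture_sigma = 0,
                                      noise_sigma = 0, seed = 1))
  mk <- extract_markers(ph$image)
  fg <- sort(unique(mk[mk >= 2L]))
  expect_length(fg, 1L)
  expect_true(all(ph$mask[mk == 2L] == 1L))          # marker inside the blob
  expect_true(all(ph$mask[mk == 1L] == 0L))          # background avoids it
  expect_gt(sum(mk == 1L), 0L)

  # two well-separated blobs -> two foreground markers, one inside each
  d1 <- sqrt(outer((1:128 - 34)^2, (1:128 - 34)^2, `+`))
  d2 <- sqrt(outer((1:128 - 94)^2, (1:128 - 94)^2, `+`))
  img <- 30 + 150 / (1 + exp(-(16 - d1) / 3)) + 150 / (1 + exp(-(16 - d2) / 3))
  mk2 <- extract_markers(img)
  fg2 <- sort(unique(mk2[mk2 >= 2L]))
  expect_length(fg2, 2L)
  expect_true(all((d1 <= 16)[mk2 == fg2[1]]) || all((d2 <= 16)[mk2 == fg2[1]]))
})

test_that("constant image falls back to a single-pixel marker and border background", {
  expect_message(mk <- extract_markers(matrix(80, 40, 40)), "fall")
  expect_equal(sum(mk >= 2L), 1L)
  expect_gt(sum(mk == 1L), 0L)
  border <- matrix(FALSE, 40, 40)
  border[c(1, 40), ] <- TRUE; border[, c(1, 40)] <- TRUE
  expect_true(all(border[mk == 1L]))
})

test_that("marker maps have disjoint connected nonzero components", {
  ph <- generate_phantom(phantom_spec(seed = 4))
  mk <- extract_markers(anisotropic_diffusion(ph$image))
  for (l in sort(unique(mk[mk >= 2L]))) {
    comp <- mammoseg:::cpp_label8(matrix(as.integer(mk == l), nrow(mk), ncol(mk)))
    expect_equal(max(comp), 1L)   # each foreground marker is 8-connected
  }
})

test_that("priority flood matches the hand-traced 1x5 example", {
  g <- matrix(c(0, 1, 5, 1, 0), 1)
  m <- matrix(c(1L, 0L, 0L, 0L, 2L), 1)
  # ridge pixel joins the earlier-inserted (left) flood under the FIFO rule
  expect_identical(marker_watershed(g, m), matrix(c(1L, 1L, 1L, 2L, 2L), 1))
  expect_identical(marker_watershed(g, matrix(c(0L, 0L, 3L, 0L, 0L), 1)),
                   matrix(3L, 1, 5))
  expect_error(marker_watershed(g, matrix(0L, 1, 5)), "marker")
})

test_that("priority flood equals the brute-force flood oracle on random grids", {
  for (seed in 1:200) {
    inst <- random_flood_instance(seed)
    got <- marker_watershed(inst$grad, inst$markers)
    want <- flood_oracle(inst$grad, inst$markers)
    expect_identical(got, want, info = paste("seed", seed))
  }
})

test_that("watershed labelings are connected partitions preserving markers", {
  for (seed in c(3, 17, 42, 101)) {
    inst <- random_flood_instance(seed)
    lab <- marker_watershed(inst$grad, inst$markers)
    expect_true(all(lab > 0L))
    expect_true(all(lab %in% unique(inst$markers[inst$markers > 0L])))
    expect_true(all(lab[inst$markers > 0L] == inst$markers[inst$markers > 0L]))
    for (l in unique(as.vector(lab))) {
      comp <- mammoseg:::cpp_label8(matrix(as.integer(lab == l),
                                           nrow(lab), ncol(lab)))
      expect_equal(max(comp), 1L)
    }
  }
})

test_that("watershed reruns are bit-identical", {
  ph <- generate_phantom(phantom_spec(seed = 2))
  den <- anisotropic_diffusion(ph$image)
  g <- gradient_magnitude(den)
  mk <- extract_markers(den)
  expect_identical(marker_watershed(g, mk), marker_watershed(g, mk))
})

test_that("mass region selection maximizes mean intensity with area tie-break", {
  labels <- matrix(2L, 4, 4); labels[, 3:4] <- 3L
  markers <- matrix(0L, 4, 4); markers[1, 1] <- 2L; markers[1, 3] <- 3L
  img <- matrix(90, 4, 4); img[, 3:4] <- 180
  got <- select_mass_region(labels, markers, img)
  expect_identical(got, matrix(as.integer(labels == 3L), 4, 4))

  # equal means: larger area wins
  labels2 <- matrix(3L, 5, 5); labels2[1, 1] <- 2L
  markers2 <- matrix(0L, 5, 5); markers2[1, 1] <- 2L; markers2[3, 3] <- 3L
  img2 <- matrix(100, 5, 5)
  expect_identical(select_mass_region(labels2, markers2, img2),
                   matrix(as.integer(labels2 == 3L), 5, 5))

  # single foreground marker: its whole catchment comes back
  labels3 <- matrix(2L, 3, 3)
  markers3 <- matrix(0L, 3, 3); markers3[2, 2] <- 2L
  expect_identical(select_mass_region(labels3, markers3, img2[1:3, 1:3]),
                   matrix(1L, 3, 3))
  expect_error(select_mass_region(matrix(1L, 3, 3), matrix(1L, 3, 3),
                                  matrix(0, 3, 3)), "foreground")
})

test_that("denoising shrinks uncontrolled watershed region counts on phantoms", {
  for (s in 0:2) {
    ph <- generate_phantom(phantom_spec(seed = s))
    n_raw <- watershed_region_count(ph$image)
    n_den <- watershed_region_count(anisotropic_diffusion(ph$image))
    expect_lt(n_den, n_raw)
  }
})
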