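test_that("noise-free vessel masking recovers the vessel raster exactly", {
  ph <- generate_phantom(small_phantom_config(seed = 2L, noise_sd = 0))
  sup <- extract_slab(ph$volume, ph$surfaces, slab_preset("superficial"),
                      "decorrelation")
  vm <- vessel_mask(sup)
  expect_identical(vm$mask, ph$truth$vessel_mask)
})

test_that("a constant-zero angiogram cannot be binarized", {
  expect_error(vessel_mask(matrix(0, 16, 16)), "constant image")
})

test_that("vessel masking on noisy phantoms overlaps truth with Dice >= 0.95", {
  for (s in 1:3) {
    ph <- generate_phantom(small_phantom_config(seed = s))
    sup <- extract_slab(ph$volume, ph$surfaces, slab_preset("superficial"),
                        "decorrelation")
    vm <- vessel_mask(sup)
    dice <- 2 * sum(vm$mask & ph$truth$vessel_mask) /
      (sum(vm$mask) + sum(ph$truth$vessel_mask))
    expect_gte(dice, 0.95)
  }
})

test_that("projection removal is the set difference of foci and vessels", {
  set.seed(31)
  foci <- binary_mask(matrix(runif(400) < 0.25, 20, 20), "isodata", 100L)
  vessels <- binary_mask(matrix(runif(400) < 0.3, 20, 20), "isodata", 80L)
  ret <- remove_projection(foci, vessels)
  expect_identical(ret$mask, foci$mask & !vessels$mask)
  expect_identical(sum(ret$mask),
                   sum(foci$mask) - sum(foci$mask & vessels$mask))
  # empty vessel mask: identity
  none <- binary_mask(matrix(FALSE, 20, 20), "isodata", 10L)
  expect_identical(remove_projection(foci, none)$mask, foci$mask)
  # dimension mismatch
  small <- binary_mask(matrix(FALSE, 10, 10), "isodata", 10L)
  expect_error(remove_projection(foci, small), "dimensions")
})

test_that("vessel dilation widens the exclusion zone", {
  foci <- binary_mask(matrix(TRUE, 9, 9), "isodata", 0L)
  vessels <- binary_mask(matrix(FALSE, 9, 9), "isodata", 0L)
  vessels$mask[5, 5] <- TRUE
  expect_identical(sum(remove_projection(foci, vessels)$mask), 80L)
  expect_identical(sum(remove_projection(foci, vessels, 1)$mask), 76L)
})

test_that("the retained mask contains no projected pixel on noise-free phantoms", {
  ph <- generate_phantom(small_phantom_config(seed = 9L, noise_sd = 0))
  q <- quantify_eye(ph$volume, ph$surfaces)
  expect_false(any(q$retained$mask & ph$truth$projection_mask_hfl))
})

test_that("intensity is the histogram mean of retained pixels", {
  img <- matrix(0, 4, 4)
  mask <- matrix(FALSE, 4, 4)
  mask[1, 1:4] <- TRUE
  img[1, 1:4] <- c(10, 20, 30, 40)
  res <- decorrelation_intensity(img, binary_mask(mask, "manual"))
  expect_identical(res$intensity, 25)
  expect_identical(res$n_pixels, 4L)
  expect_identical(sum(res$histogram), 4L)
  expect_identical(res$histogram[c(10, 20, 30, 40) + 1], rep(1L, 4))
  # all-zero retained pixels give intensity 0
  res0 <- decorrelation_intensity(matrix(0, 4, 4),
                                  binary_mask(mask, "manual"))
  expect_identical(res0$intensity, 0)
  # histogram-mean identity on arbitrary data
  set.seed(5)
  img2 <- matrix(runif(400, 0, 255), 20, 20)
  m2 <- binary_mask(matrix(runif(400) < 0.4, 20, 20), "manual")
  r2 <- decorrelation_intensity(img2, m2)
  expect_equal(r2$intensity, sum((0:255) * r2$histogram) / sum(r2$histogram))
  expect_equal(r2$intensity, mean(round(img2[m2$mask])))
})

test_that("an empty retained mask is an error, not a zero", {
  img <- matrix(50, 8, 8)
  expect_error(
    decorrelation_intensity(img, binary_mask(matrix(FALSE, 8, 8), "manual")),
    "no foci pixels")
})

test_that("projection removal can only lower the measured intensity", {
  for (s in 1:3) {
    ph <- generate_phantom(small_phantom_config(seed = s, noise_sd = 0))
    q <- quantify_eye(ph$volume, ph$surfaces)
    without <- decorrelation_intensity(q$hfl_angio, q$foci)
    expect_lte(q$result$intensity, without$intensity)
  }
})

test_that("noise-free pipelines recover the true intensity exactly", {
  for (s in 4:6) {
    ph <- generate_phantom(small_phantom_config(seed = s, noise_sd = 0))
    q <- quantify_eye(ph$volume, ph$surfaces)
    expect_identical(q$result$intensity, ph$truth$true_intensity)
  }
})

test_that("the subtraction display utility clips at zero", {
  a <- matrix(c(100, 10), 2, 2)
  b <- matrix(c(30, 50), 2, 2)
  expect_identical(subtract_projection_image(a, b),
                   matrix(c(70, 0), 2, 2))
})
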