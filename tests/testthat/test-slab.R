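test_that("the three slab presets carry the published offsets", {
  sup <- slab_preset("superficial")
  expect_identical(sup$inner_reference, "ilm")
  expect_identical(sup$inner_offset, 3)
  expect_identical(sup$outer_reference, "ipl")
  expect_identical(sup$outer_offset, 15)
  inl <- slab_preset("inl")
  expect_identical(inl$inner_reference, "ipl")
  expect_identical(c(inl$inner_offset, inl$outer_offset), c(38, 47))
  hfl <- slab_preset("hfl")
  expect_identical(hfl$inner_reference, "bm")
  expect_identical(c(hfl$inner_offset, hfl$outer_offset), c(-100, -91))
})

test_that("micrometre-to-voxel conversion selects the overlapping rows", {
  # flat BM at 300 um, 3 um voxels: [200, 209) um covers 0-based rows 66..69
  surf <- flat_surfaces(4, 4, ilm = 30, ipl = 100, bm = 300)
  vol <- array(0, c(4, 4, 110))
  vol[, , 67:70] <- 100   # 1-based rows for 0-based 66..69
  slab <- extract_slab(vol, surf, slab_preset("hfl"), axial_step = 3)
  expect_true(all(slab$image == 100))
  vol2 <- array(100, c(4, 4, 110))
  vol2[, , 67:70] <- 0    # only the selected rows are read
  slab2 <- extract_slab(vol2, surf, slab_preset("hfl"), axial_step = 3)
  expect_true(all(slab2$image == 0))
})

test_that("projection of a constant volume is that constant", {
  surf <- flat_surfaces()
  vol <- array(100, c(20, 20, 130))
  for (p in c("mean", "max")) {
    slab <- extract_slab(vol, surf, slab_preset("inl", projection = p),
                         axial_step = 3)
    expect_true(all(slab$image == 100))
  }
})

test_that("slab extraction matches a brute-force voxel loop", {
  set.seed(42)
  ny <- 6; nx <- 5; nz <- 60
  vol <- array(runif(ny * nx * nz, 0, 255), c(ny, nx, nz))
  ilm <- matrix(runif(ny * nx, 10, 25), ny, nx)
  ipl <- ilm + runif(ny * nx, 30, 45)
  bm <- ipl + runif(ny * nx, 60, 80)
  surf <- boundary_surfaces(ilm, ipl, bm, lateral_step = 40)
  spec <- slab_spec("ipl", 5, "ipl", 21, projection = "mean")
  slab <- extract_slab(vol, surf, spec, axial_step = 3)
  for (i in seq_len(ny)) for (j in seq_len(nx)) {
    inner <- ipl[i, j] + 5; outer <- ipl[i, j] + 21
    rows <- (floor(inner / 3) + 1):ceiling(outer / 3)
    expect_equal(slab$image[i, j], mean(vol[i, j, rows]))
    expect_gte(slab$image[i, j], min(vol[i, j, rows]))
    expect_lte(slab$image[i, j], max(vol[i, j, rows]))
  }
  spec_max <- slab_spec("bm", -40, "bm", -10, projection = "max")
  slab_max <- extract_slab(vol, surf, spec_max, axial_step = 3)
  for (i in seq_len(ny)) for (j in seq_len(nx)) {
    rows <- (floor((bm[i, j] - 40) / 3) + 1):ceiling((bm[i, j] - 10) / 3)
    expect_equal(slab_max$image[i, j], max(vol[i, j, rows]))
  }
})

test_that("slab extraction commutes with lateral cropping", {
  ph <- generate_phantom(small_phantom_config(seed = 8L))
  spec <- slab_preset("hfl")
  full <- extract_slab(ph$volume, ph$surfaces, spec, "structural")
  keep_i <- 10:40; keep_j <- 5:60
  cropped_surf <- boundary_surfaces(ph$surfaces$ilm[keep_i, keep_j],
                                    ph$surfaces$ipl[keep_i, keep_j],
                                    ph$surfaces$bm[keep_i, keep_j],
                                    ph$surfaces$lateral_step)
  cropped_vol <- ph$volume$structural[keep_i, keep_j, , drop = FALSE]
  crop_then_extract <- extract_slab(cropped_vol, cropped_surf, spec,
                                    axial_step = ph$volume$axial_step)
  expect_identical(full$image[keep_i, keep_j], crop_then_extract$image)
})

test_that("out-of-bounds slabs and crossed surfaces are rejected", {
  surf <- flat_surfaces(4, 4, ilm = 10, ipl = 60, bm = 290)
  vol <- array(0, c(4, 4, 50))  # only 150 um deep
  expect_error(extract_slab(vol, surf, slab_preset("hfl"), axial_step = 3),
               "exits volume bounds")
  expect_error(boundary_surfaces(matrix(100, 2, 2), matrix(50, 2, 2),
                                 matrix(300, 2, 2), 40),
               "crossed")
  expect_error(extract_slab(vol, surf, slab_spec("ipl", 10, "ipl", 5),
                            axial_step = 3),
               "cross|inner boundary")
})

test_that("CSF thickness over a flat retina is the constant thickness", {
  surf <- flat_surfaces(41, 41, ilm = 50, ipl = 150, bm = 350,
                        lateral_step = 50)
  expect_identical(compute_csf_thickness(surf, c(21, 21)), 300)
})

test_that("CSF thickness only sees pixels inside the central disc", {
  ny <- nx <- 41; step <- 50
  ilm <- matrix(50, ny, nx)
  ipl <- matrix(150, ny, nx)
  bm <- matrix(450, ny, nx)           # thickness 400 outside
  ii <- matrix(seq_len(ny), ny, nx)
  jj <- matrix(seq_len(nx), ny, nx, byrow = TRUE)
  inside <- step * sqrt((ii - 21)^2 + (jj - 21)^2) <= 500
  bm[inside] <- 300                   # thickness 250 inside the 1 mm disc
  surf <- boundary_surfaces(ilm, ipl, bm, step)
  expect_identical(compute_csf_thickness(surf, c(21, 21)), 250)
})

test_that("CSF thickness over the foveal pit matches an exhaustive pixel loop", {
  ph <- generate_phantom(small_phantom_config(seed = 12L))
  surf <- ph$surfaces
  center <- find_fovea(surf)
  got <- compute_csf_thickness(surf, center)
  step <- surf$lateral_step
  acc <- c()
  for (i in seq_len(nrow(surf$ilm))) for (j in seq_len(ncol(surf$ilm)))
    if (step * sqrt((i - center[1])^2 + (j - center[2])^2) <= 500)
      acc <- c(acc, surf$bm[i, j] - surf$ilm[i, j])
  expect_equal(got, mean(acc))
})

test_that("the measurement disc must fit inside the field", {
  surf <- flat_surfaces(10, 10, lateral_step = 50)
  expect_error(compute_csf_thickness(surf, c(2, 2)), "exceeds the lateral field")
})
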