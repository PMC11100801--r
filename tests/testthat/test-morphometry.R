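test_that("thinning preserves 1-pixel lines and shrinks a disc to its core", {
  line <- matrix(FALSE, 15, 15)
  line[8, 3:13] <- TRUE
  expect_identical(skeletonize_cell(line), line)

  disc <- matrix(FALSE, 41, 41)
  yy <- outer((1:41 - 21)^2, (1:41 - 21)^2, "+")
  disc[yy <= 15^2] <- TRUE
  sk <- skeletonize_cell(disc)
  expect_lte(sum(sk), 8)                       # tiny central cluster
  expect_true(all(which(sk) %in% which(disc))) # skeleton subset of mask
  ctr <- which(sk, arr.ind = TRUE)
  expect_true(all(abs(ctr - 21) <= 2))

  expect_error(skeletonize_cell(matrix(FALSE, 5, 5)), "empty")
})

test_that("skeleton is always a subset of the mask", {
  set.seed(31)
  for (rep in 1:5) {
    blob <- matrix(runif(40 * 40) < 0.4, 40, 40)
    blob[1, ] <- FALSE; blob[, 1] <- FALSE; blob[40, ] <- FALSE; blob[, 40] <- FALSE
    if (!any(blob)) next
    sk <- skeletonize_cell(blob)
    expect_true(all(!(sk & !blob)))
  }
})

test_that("star phantoms yield exactly k intersections inside the arm extent", {
  for (k in c(1, 3, 6)) {
    ph <- generate_sholl_phantom(k, arm_length = 18, pixel_size = 0.5, soma_radius = 5)
    m <- matrix(ph$image$data[1, 1, , ] > 128,
                dim(ph$image$data)[3], dim(ph$image$data)[4])
    sk <- skeletonize_cell(binary_mask(m, ph$image$voxel_size))
    pr <- sholl_profile(sk, ph$truth$center_um, ring_spacing = 1,
                        start_radius = 7, max_radius = 16)
    expect_true(all(pr$intersections == k))
    # beyond the arms: zero
    pr2 <- sholl_profile(sk, ph$truth$center_um, ring_spacing = 1,
                         start_radius = 20, max_radius = 21)
    expect_true(all(pr2$intersections == 0))
  }
})

test_that("sholl profiles match the brute-force distance-bin oracle exactly", {
  for (s in 1:8) {
    phan <- random_walk_skeleton(seed = 100 + s)
    radii <- seq(2, 40, by = 2)
    mine <- sholl_profile(phan$img, phan$center_um, ring_spacing = 2,
                          start_radius = 2, max_radius = 40,
                          pixel_size = phan$pixel_size)
    orc <- oracle_sholl(phan$img, phan$pixel_size, phan$center_um, radii)
    expect_identical(mine$intersections, orc)
  }
})

test_that("sholl profile is invariant under whole-image translation", {
  phan <- random_walk_skeleton(seed = 55, size_px = 150)
  big <- matrix(FALSE, 220, 220)
  big[31:180, 31:180] <- phan$img
  p1 <- sholl_profile(phan$img, phan$center_um, ring_spacing = 2,
                      start_radius = 2, max_radius = 30, pixel_size = 0.5)
  p2 <- sholl_profile(big, phan$center_um + 30 * 0.5, ring_spacing = 2,
                      start_radius = 2, max_radius = 30, pixel_size = 0.5)
  expect_identical(p1$intersections, p2$intersections)
})

test_that("rings beyond the border are flagged, off-image centres rejected", {
  img <- matrix(FALSE, 21, 21)
  img[11, 1:21] <- TRUE
  pr <- sholl_profile(img, c(5, 5), ring_spacing = 2, start_radius = 2,
                      max_radius = 10, pixel_size = 1)
  expect_true(any(pr$clipped))
  expect_false(pr$clipped[pr$radius_um <= 5][1])
  expect_error(sholl_profile(img, c(-3, 5), pixel_size = 1), "outside")
  expect_error(sholl_profile(img, c(5, 5), ring_spacing = 0, pixel_size = 1),
               "ring_spacing")
})

test_that("cell volume is voxel count times voxel volume", {
  arr <- array(FALSE, c(10, 20, 20))
  arr[1:1000] <- TRUE
  expect_equal(cell_volume(binary_mask(arr, c(0.33, 0.1, 0.1))), 3.3)
  expect_identical(cell_volume(binary_mask(array(FALSE, c(2, 2, 2)), c(1, 1, 1))), 0)
  # digitized 5-um sphere lands within 5% of the analytic volume
  dim3 <- c(40, 120, 120)
  vox <- c(0.33, 0.1, 0.1)
  arr2 <- array(FALSE, dim3)
  arr2[microquant:::rasterize_sphere(dim3, vox, c(6, 6, 6), 5)] <- TRUE
  expect_equal(cell_volume(binary_mask(arr2, vox)), (4 / 3) * pi * 125,
               tolerance = 0.05)
})
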