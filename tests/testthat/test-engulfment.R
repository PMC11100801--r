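rand_mask <- function(p, dims = c(6, 10, 10), voxel = c(0.5, 0.2, 0.2)) {
  binary_mask(array(runif(prod(dims)) < p, dims), voxel)
}

make_cell <- function(mask) {
  structure(list(
    cell_id = 1L, animal_id = "a", image_id = "i",
    mask = mask$data,
    bbox = list(z = c(1L, dim(mask$data)[1]), y = c(1L, dim(mask$data)[2]),
                x = c(1L, dim(mask$data)[3])),
    voxel_size = mask$voxel_size,
    soma_centroid_um = c(0, 0, 0), soma_depth_um = 1,
    voxel_count = sum(mask$data),
    volume_um3 = mask_volume(mask)
  ), class = "cell_object")
}

test_that("mask_within is conjunction: absorption, disjointness, symmetry", {
  set.seed(41)
  outer_m <- rand_mask(0.5)
  inner_m <- binary_mask(outer_m$data & (array(runif(600) < 0.5, dim(outer_m$data))),
                         outer_m$voxel_size)
  expect_identical(mask_within(outer_m, inner_m)$data, inner_m$data)
  disj <- binary_mask(!outer_m$data, outer_m$voxel_size)
  expect_identical(sum(mask_within(outer_m, disj)$data), 0L)
  a <- rand_mask(0.4); b <- rand_mask(0.4)
  expect_identical(mask_within(a, b)$data, mask_within(b, a)$data)
  expect_identical(mask_within(a, a)$data, a$data)
  expect_error(mask_within(a, rand_mask(0.4, dims = c(5, 10, 10))), "lattice")
})

test_that("phagocytic capacity follows the stated formula", {
  cell_arr <- array(FALSE, c(10, 10, 10))
  cell_arr[1:1000 <= 1000] <- TRUE  # all 1000 voxels
  cell <- make_cell(binary_mask(cell_arr, c(1, 1, 1)))
  cd <- array(FALSE, c(10, 10, 10)); cd[1:50] <- TRUE
  expect_equal(phagocytic_capacity(cell, binary_mask(cd, c(1, 1, 1))), 5)
  expect_equal(phagocytic_capacity(cell, binary_mask(array(FALSE, c(10, 10, 10)), c(1, 1, 1))), 0)
  empty <- make_cell(binary_mask(array(FALSE, c(10, 10, 10)), c(1, 1, 1)))
  expect_error(phagocytic_capacity(empty, binary_mask(cd, c(1, 1, 1))), "empty")
})

test_that("fully nested and disjoint synaptic signal give exact volumes", {
  cell_arr <- array(FALSE, c(8, 12, 12)); cell_arr[2:7, 2:11, 2:11] <- TRUE
  cell <- make_cell(binary_mask(cell_arr, c(0.5, 0.2, 0.2)))
  cd <- array(FALSE, c(8, 12, 12)); cd[3:5, 4:8, 4:8] <- TRUE
  vg <- array(FALSE, c(8, 12, 12)); vg[4, 5:6, 5:6] <- TRUE  # inside lysosome
  rec <- engulfed_synaptic_volume(cell, binary_mask(cd, cell$voxel_size),
                                  binary_mask(vg, cell$voxel_size))
  expect_equal(rec$engulfed_synaptic_volume_um3, sum(vg) * 0.5 * 0.2 * 0.2)
  expect_equal(rec$engulfed_norm, sum(vg) / sum(cell_arr))
  vg2 <- array(FALSE, c(8, 12, 12)); vg2[1, 1, 1] <- TRUE    # outside the cell
  rec2 <- engulfed_synaptic_volume(cell, binary_mask(cd, cell$voxel_size),
                                   binary_mask(vg2, cell$voxel_size))
  expect_identical(rec2$engulfed_voxels, 0L)
})

test_that("nesting chain holds on adversarial random masks", {
  set.seed(42)
  for (rep in 1:100) {
    cellm <- rand_mask(runif(1, 0.05, 0.9))
    if (!any(cellm$data)) next
    cell <- make_cell(cellm)
    rec <- engulfed_synaptic_volume(cell, rand_mask(runif(1)), rand_mask(runif(1)))
    expect_lte(rec$engulfed_voxels, rec$lysosome_voxels)
    expect_lte(rec$lysosome_voxels, rec$cell_voxels)
    expect_gte(rec$phagocytic_capacity_pct, 0)
    expect_lte(rec$phagocytic_capacity_pct, 100)
    expect_gte(rec$engulfed_norm, 0)
    expect_lte(rec$engulfed_norm, 1)
  }
})

test_that("growing the CD68 mask never decreases capacity or engulfed volume", {
  set.seed(43)
  cellm <- rand_mask(0.6)
  cell <- make_cell(cellm)
  vg <- rand_mask(0.3)
  cd_small <- rand_mask(0.2)
  cd_big <- binary_mask(cd_small$data | (array(runif(600) < 0.3, dim(cd_small$data))),
                        cd_small$voxel_size)
  r1 <- engulfed_synaptic_volume(cell, cd_small, vg)
  r2 <- engulfed_synaptic_volume(cell, cd_big, vg)
  expect_gte(r2$phagocytic_capacity_pct, r1$phagocytic_capacity_pct)
  expect_gte(r2$engulfed_voxels, r1$engulfed_voxels)
})

test_that("bounding-box measurement equals whole-field measurement", {
  g <- generate_microglia_volume(tiny_mg_config(6))
  seg <- suppressMessages(segment_microglia(g$volume))
  eng <- measure_engulfment(g$volume, seg)
  # recompute on the full lattice without cropping
  cd68 <- threshold_channel(g$volume, "CD68", method = "midpoint")
  vglut2 <- threshold_channel(g$volume, "VGlut2", method = "midpoint")
  for (k in seq_along(seg$cells)) {
    cell <- seg$cells[[k]]
    full <- array(FALSE, dim(seg$labels$labels))
    full[seg$labels$labels == k] <- TRUE
    lyso <- full & cd68$data
    engv <- lyso & vglut2$data
    expect_identical(eng$lysosome_voxels[k], sum(lyso))
    expect_identical(eng$engulfed_voxels[k], sum(engv))
  }
})
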