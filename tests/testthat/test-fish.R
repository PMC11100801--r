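test_that("cell-type calls follow the margin rule", {
  expect_identical(call_cell_type(10, 1, 3), "glutamatergic")
  expect_identical(call_cell_type(2, 2, 3), "ambiguous")
  expect_identical(call_cell_type(1, 9, 3), "GABAergic")
  expect_identical(call_cell_type(c(5, 0), c(0, 5), 3),
                   c("glutamatergic", "GABAergic"))
  expect_error(call_cell_type(1, 1, 0), "min_margin")
})

test_that("Fos calls use a strict, size-adjusted threshold", {
  # exactly 6 puncta at the median volume is NOT active
  expect_identical(call_fos_state(6, 100, 100), "Fos-")
  expect_identical(call_fos_state(7, 100, 100), "Fos+")
  # doubling the cell size doubles the threshold
  expect_identical(call_fos_state(7, 200, 100), "Fos-")
  expect_identical(call_fos_state(13, 200, 100), "Fos+")
  expect_error(call_fos_state(5, 100, 0), "median_volume")
  # monotone in count, antitone in volume
  counts <- 0:20
  st <- call_fos_state(counts, 100, 100)
  expect_true(all(diff(st == "Fos+") >= 0))
  vols <- seq(50, 300, by = 10)
  st2 <- call_fos_state(10, vols, 100)
  expect_true(all(diff(st2 == "Fos+") <= 0))
})

test_that("puncta are assigned by centroid containment with conservation", {
  # two nuclei, three puncta: one in each nucleus, one in background
  lab <- array(0L, c(3, 20, 20))
  lab[2, 3:6, 3:6] <- 1L
  lab[2, 12:15, 12:15] <- 2L
  nuclei <- list(labels = lab, n = 2L,
                 objects = data.frame(volume_um3 = c(16, 16) * 1),
                 voxel_size = c(1, 1, 1))
  puncta <- list(table = data.frame(
    centroid_z_um = c(1, 1, 1),
    centroid_y_um = c(4, 13, 18),
    centroid_x_um = c(4, 13, 18)
  ))
  asg <- assign_puncta(puncta, nuclei)
  expect_identical(asg$counts, c(1L, 1L))
  expect_identical(asg$n_unassigned, 1L)
  expect_identical(sum(asg$counts) + asg$n_unassigned, 3L)
})

test_that("nucleus segmentation recovers planted nuclei and volumes", {
  f <- generate_fish_field(config_fish(40, seed = 8))
  nuclei <- suppressMessages(segment_nuclei(f$volume))
  expect_identical(count_cells(nuclei), 40L)
  # match measured to truth by centroid lookup in the truth grid
  idx <- cbind(
    round(nuclei$objects$centroid_z_um / f$volume$voxel_size[1]) + 1L,
    round(nuclei$objects$centroid_y_um / f$volume$voxel_size[2]) + 1L,
    round(nuclei$objects$centroid_x_um / f$volume$voxel_size[3]) + 1L
  )
  tid <- f$truth$nucleus_grid[idx]
  expect_true(all(tid > 0L))
  expect_equal(nuclei$objects$volume_um3,
               f$truth$nuclei$dapi_volume_um3[tid], tolerance = 0.05)
})

test_that("per-cell puncta counts are recovered exactly on a clean field", {
  f <- generate_fish_field(config_fish(40, seed = 12))
  rec <- suppressMessages(quantify_fish(f$volume, animal_id = "a1"))
  nuclei <- suppressMessages(segment_nuclei(f$volume))
  idx <- cbind(
    round(nuclei$objects$centroid_z_um / f$volume$voxel_size[1]) + 1L,
    round(nuclei$objects$centroid_y_um / f$volume$voxel_size[2]) + 1L,
    round(nuclei$objects$centroid_x_um / f$volume$voxel_size[3]) + 1L
  )
  tid <- f$truth$nucleus_grid[idx]
  tr <- f$truth$nuclei[tid, ]
  expect_gte(mean(rec$count_IL34 == tr$IL34), 0.95)
  expect_gte(mean(rec$count_VGlut1 == tr$VGlut1), 0.95)
  # type calls against truth: no cross-type confusion
  called <- rec$cell_type
  wrong <- (called == "glutamatergic" & tr$cell_type == "GABAergic") |
    (called == "GABAergic" & tr$cell_type == "glutamatergic")
  expect_lte(mean(wrong), 0.02)
})

test_that("type averages exclude ambiguous cells and are order-invariant", {
  rec <- data.frame(
    nucleus_id = 1:5, animal_id = "a1",
    cell_type = c("glutamatergic", "glutamatergic", "GABAergic", "ambiguous", "GABAergic"),
    target_density_per_um3 = c(0.2, 0.4, 0.1, 9, 0.3)
  )
  agg <- il34_by_type(rec)
  expect_identical(nrow(agg), 2L)
  expect_equal(agg$mean_density[agg$cell_type == "glutamatergic"], 0.3)
  expect_equal(agg$mean_density[agg$cell_type == "GABAergic"], 0.2)
  expect_identical(agg$n_cells, c(2L, 2L))
  perm <- rec[c(5, 3, 1, 4, 2), ]
  expect_equal(il34_by_type(perm)$mean_density, agg$mean_density)
  # single cell: its own density
  one <- rec[1, ]
  expect_equal(il34_by_type(one)$mean_density, 0.2)
  # all ambiguous: empty with a warning
  amb <- rec; amb$cell_type <- "ambiguous"
  expect_warning(empty <- il34_by_type(amb), "no non-ambiguous")
  expect_identical(nrow(empty), 0L)
})

test_that("density scales inversely with DAPI volume", {
  rec <- data.frame(count = c(10, 10), vol = c(100, 200))
  d <- rec$count / rec$vol
  expect_equal(d[1] / d[2], 2)
  # multiplying all volumes by c divides all densities by c
  d2 <- rec$count / (3 * rec$vol)
  expect_equal(d2, d / 3)
})
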