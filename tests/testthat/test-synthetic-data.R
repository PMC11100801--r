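# The generators define the study conditions; these tests pin their
# determinism, their exact-by-construction ground truth, and the
# degenerate cases.

test_that("generator config validation rejects bad inputs", {
  expect_error(generator_config(lysosome_fraction = 1.2), "fractions")
  expect_error(generator_config(engulfed_fraction = -0.1), "fractions")
  expect_error(generator_config(voxel_size = c(0, 0.1, 0.1)), "positive")
  expect_error(generator_config(fish_type_means = list(a = c(X = 0), b = c(X = 1))),
               "positive")
})

test_that("a fixed seed reproduces every generator bit-exactly", {
  a <- generate_microglia_volume(tiny_mg_config(7))
  b <- generate_microglia_volume(tiny_mg_config(7))
  expect_identical(a$volume$data, b$volume$data)
  expect_identical(a$truth$cells, b$truth$cells)
  expect_identical(a$truth$puncta, b$truth$puncta)

  f1 <- generate_fish_field(config_fish(30, seed = 3))
  f2 <- generate_fish_field(config_fish(30, seed = 3))
  expect_identical(f1$volume$data, f2$volume$data)
  expect_identical(f1$truth$nuclei, f2$truth$nuclei)

  s1 <- generate_synapse_field(config_synapse(seed = 4, n_pre = 40, n_post = 40))
  s2 <- generate_synapse_field(config_synapse(seed = 4, n_pre = 40, n_post = 40))
  expect_identical(s1$volume$data, s2$volume$data)
  expect_identical(s1$truth$pre_centers, s2$truth$pre_centers)

  t1 <- generate_assay_table(seed = 5)
  t2 <- generate_assay_table(seed = 5)
  expect_identical(t1, t2)
})

test_that("microglia truth is exact and nested by construction", {
  g <- generate_microglia_volume(tiny_mg_config(11, n_cells = 3L,
                                                field_shape = c(20L, 330L, 330L)))
  tr <- g$truth
  # brute-force voxel counting over the emitted label grids equals truth
  for (i in seq_len(tr$n_cells)) {
    expect_identical(sum(tr$label_grid == i), tr$cells$voxel_count[i])
    expect_identical(sum(tr$lysosome_grid == i), tr$cells$lysosome_voxels[i])
  }
  # nesting chain
  expect_true(all(tr$cells$engulfed_voxels <= tr$cells$lysosome_voxels))
  expect_true(all(tr$cells$lysosome_voxels <= tr$cells$voxel_count))
  # every lysosome voxel lies inside its cell's mask
  lv <- which(tr$lysosome_grid > 0L)
  expect_true(all(tr$label_grid[lv] == tr$lysosome_grid[lv]))
  # engulfed puncta count is exact
  n_eng <- round(tr$config$engulfed_fraction * tr$config$n_synaptic_puncta)
  expect_identical(sum(tr$puncta$engulfed), as.integer(n_eng))
  # engulfed puncta centroids really are inside lysosomes
  dims <- dim(tr$label_grid)
  eng <- tr$puncta[tr$puncta$engulfed, ]
  idx <- cbind(round(eng$z_um / tr$voxel_size[1]) + 1L,
               round(eng$y_um / tr$voxel_size[2]) + 1L,
               round(eng$x_um / tr$voxel_size[3]) + 1L)
  expect_true(all(tr$lysosome_grid[idx] > 0L))
})

test_that("degenerate microglia configs behave as stated", {
  g0 <- generate_microglia_volume(tiny_mg_config(3, n_cells = 0L))
  expect_identical(g0$truth$n_cells, 0L)
  expect_identical(nrow(g0$truth$cells), 0L)
  expect_true(all(g0$truth$label_grid == 0L))

  ge <- generate_microglia_volume(tiny_mg_config(3, engulfed_fraction = 0))
  expect_true(all(ge$truth$cells$engulfed_voxels == 0L))

  # overcrowded field errors explicitly
  expect_error(
    generate_microglia_volume(tiny_mg_config(3, n_cells = 40L)),
    "too crowded"
  )
})

test_that("true engulfed volume is monotone in engulfed_fraction at fixed seed", {
  for (s in 1:3) {
    tot <- vapply(c(0, 0.25, 0.5), function(f) {
      g <- generate_microglia_volume(tiny_mg_config(s, n_cells = 3L,
                                                    field_shape = c(20L, 330L, 330L),
                                                    engulfed_fraction = f))
      sum(g$truth$cells$engulfed_volume_um3)
    }, numeric(1))
    expect_true(all(diff(tot) >= 0))
    expect_identical(tot[1], 0)
  }
})

test_that("fish truth realizes the configured two-fold type means", {
  f <- generate_fish_field(config_fish(200, seed = 9))
  tr <- f$truth$nuclei
  m <- tapply(tr$IL34, tr$cell_type, mean)
  expect_equal(unname(m["glutamatergic"] / m["GABAergic"]), 2, tolerance = 0.2)
  # balanced types
  expect_equal(unname(table(tr$cell_type)["glutamatergic"]), 100)
})

test_that("fish counts approach Poisson in the infinite-dispersion limit", {
  f <- generate_fish_field(config_fish(150, seed = 10, fish_dispersion = Inf))
  nt <- f$truth$nuclei
  x <- nt$IL34[nt$cell_type == "glutamatergic"]
  expect_gt(var(x) / mean(x), 0.6)
  expect_lt(var(x) / mean(x), 1.5)
})

test_that("synapse truth pins the colocalized pair count exactly", {
  s <- generate_synapse_field(config_synapse(seed = 2, n_pre = 50, n_post = 50,
                                             coloc_probability = 1))
  expect_identical(s$truth$colocalized_pair_count, 50)
  s0 <- generate_synapse_field(config_synapse(seed = 2, n_pre = 30, n_post = 30,
                                              coloc_probability = 0))
  expect_identical(s0$truth$colocalized_pair_count, 0)
  # non-paired puncta keep the enforced separation
  pc <- rbind(as.matrix(s0$truth$pre_centers), as.matrix(s0$truth$post_centers))
  dd <- as.matrix(dist(pc))
  diag(dd) <- Inf
  expect_gte(min(dd), s0$truth$min_sep - 1e-9)
})

test_that("sholl phantom geometry and bounds checks hold", {
  ph <- generate_sholl_phantom(6, arm_length = 15)
  expect_identical(ph$truth$n_arms, 6L)
  img <- ph$image$data[1, 1, , ]
  expect_true(all(img %in% c(0, 255)))
  expect_error(generate_sholl_phantom(3, arm_length = 10, margin = -8), "exceed")
  expect_error(generate_sholl_phantom(0, arm_length = 10), "n_arms")
  expect_error(generate_sholl_phantom(3, arm_length = 4, soma_radius = 5),
               "exceed")
})

test_that("assay generator recovers fold changes exactly at zero noise", {
  tb <- generate_assay_table(seed = 1, between_sd = 0, replicate_sd = 0,
                             fold_changes = c(control = 1, treated = 4))
  res <- ddct_table(tb, control_group = "control")
  expect_equal(unname(tapply(res$ddct, res$group, mean)[["treated"]]), -2)
  expect_equal(unname(tapply(res$fold_change, res$group, mean)[["treated"]]), 4)
  expect_equal(unname(tapply(res$fold_change, res$group, mean)[["control"]]), 1,
               tolerance = 1e-12)
})

test_that("intensity mixture generator produces labelled classes at stated means", {
  mx <- generate_intensity_mixture(seed = 2, n_per_class = 50)
  expect_identical(nrow(mx), 150L)
  m <- tapply(mx$value, mx$true_class, mean)
  expect_equal(as.numeric(m[c("Lo", "Mid", "Hi")]), c(0.5, 1.0, 1.5),
               tolerance = 0.1)
})
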