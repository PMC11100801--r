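test_that("puncta detection finds planted puncta and applies the size window", {
  s <- generate_synapse_field(config_synapse(seed = 21, n_pre = 50, n_post = 50,
                                             coloc_probability = 0))
  pre <- suppressMessages(detect_puncta(s$volume, "VGlut2", size_window = c(2, 200)))
  expect_identical(nrow(pre$table), 50L)
  # an all-background channel with a fixed threshold above the noise: nothing
  bg <- volume_image(array(5, c(1, 1, 40, 40)) + array(round(abs(rnorm(1600))), c(1, 1, 40, 40)),
                     c(1, 0.1, 0.1), "empty")
  none <- detect_puncta(bg, "empty", threshold_method = "fixed", t = 50)
  expect_identical(nrow(none$table), 0L)
  # an oversized blob is rejected and logged
  arr <- array(0, c(1, 1, 60, 60))
  arr[1, 1, 10:40, 10:40] <- 200   # 961 px blob
  arr[1, 1, 50:51, 50:51] <- 200   # 4 px punctum
  v <- volume_image(arr, c(1, 0.1, 0.1), "ch")
  ps <- suppressMessages(detect_puncta(v, "ch", threshold_method = "fixed",
                                       t = 100, size_window = c(2, 100)))
  expect_identical(nrow(ps$table), 1L)
  expect_identical(ps$n_rejected, 1L)
  expect_error(detect_puncta(v, "ch", size_window = c(5, 5)), "size_window")
})

test_that("identical puncta sets colocalize completely; distant sets not at all", {
  s <- generate_synapse_field(config_synapse(seed = 22, n_pre = 30, n_post = 30,
                                             coloc_probability = 0))
  pre <- suppressMessages(detect_puncta(s$volume, "VGlut2", size_window = c(2, 200)))
  co_self <- count_colocalized(pre, pre, "overlap")
  expect_identical(co_self$n_colocalized, nrow(pre$table))
  post <- suppressMessages(detect_puncta(s$volume, "PSD95", size_window = c(2, 200)))
  # planted with min separation 3 um and no pairs: nothing within r = 1
  co0 <- count_colocalized(pre, post, "centroid", r = 1)
  expect_identical(co0$n_colocalized, 0L)
  expect_error(count_colocalized(pre, post, "centroid"), "radius")
})

test_that("colocalization counts are symmetric, bounded, and monotone in r", {
  s <- generate_synapse_field(config_synapse(seed = 23, n_pre = 60, n_post = 40,
                                             coloc_probability = 0.5))
  pre <- suppressMessages(detect_puncta(s$volume, "VGlut2", size_window = c(2, 200)))
  post <- suppressMessages(detect_puncta(s$volume, "PSD95", size_window = c(2, 200)))
  ab <- count_colocalized(pre, post, "overlap")
  ba <- count_colocalized(post, pre, "overlap")
  expect_identical(ab$n_colocalized, ba$n_colocalized)
  expect_lte(ab$n_colocalized, min(ab$n_pre, ab$n_post))
  last <- -1L
  for (r in c(0.2, 0.5, 1, 2)) {
    cnt <- count_colocalized(pre, post, "centroid", r = r)$n_colocalized
    expect_gte(cnt, last)
    last <- cnt
  }
})

test_that("matcher equals the exhaustive brute-force oracle on random fields", {
  for (s in 1:6) {
    cfg <- config_synapse(seed = 300 + s,
                          n_pre = 20 + 5 * s, n_post = 25 + 3 * s,
                          coloc_probability = runif(1, 0.2, 0.8))
    f <- generate_synapse_field(cfg)
    pre <- suppressMessages(detect_puncta(f$volume, "VGlut2", size_window = c(2, 200)))
    post <- suppressMessages(detect_puncta(f$volume, "PSD95", size_window = c(2, 200)))
    expect_identical(count_colocalized(pre, post, "overlap")$n_colocalized,
                     oracle_coloc_overlap(pre, post))
    expect_identical(count_colocalized(pre, post, "centroid", r = 0.8)$n_colocalized,
                     oracle_coloc_centroid(pre, post, 0.8))
  }
})

test_that("planted colocalization fraction is recovered", {
  f <- generate_synapse_field(config_synapse(seed = 31, n_pre = 100, n_post = 100,
                                             coloc_probability = 0.4))
  pre <- suppressMessages(detect_puncta(f$volume, "VGlut2", size_window = c(2, 200)))
  post <- suppressMessages(detect_puncta(f$volume, "PSD95", size_window = c(2, 200)))
  co <- count_colocalized(pre, post, "overlap")
  expect_equal(co$n_colocalized / co$n_pre, 0.4, tolerance = 0.125)
  expect_gt(co$density_per_100um2, 0)
})
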