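test_that("scene generation is seed-deterministic", {
  s1 <- generate_scene(small_scene_params(2))
  s2 <- generate_scene(small_scene_params(2))
  expect_identical(s1$image$pixels, s2$image$pixels)
  expect_identical(s1$annotations, s2$annotations)
  s3 <- generate_scene(small_scene_params(3))
  expect_false(identical(s1$image$pixels, s3$image$pixels))
})

test_that("the generator honours its declared constraints", {
  p <- small_scene_params(6, n_ma = 6L)
  scene <- generate_scene(p)
  ann <- scene$annotations
  expect_equal(nrow(ann), 6L)
  S <- p$image_size
  ctr <- S / 2 + 0.5
  r <- sqrt((ann$y + 1 - ctr)^2 + (ann$x + 1 - ctr)^2)
  expect_true(all(r < p$fov_radius_frac * S))          # inside FOV
  expect_false(any(scene$vessel_mask[cbind(ann$y + 1, ann$x + 1)]))
  if (nrow(ann) > 1) {
    dd <- as.matrix(stats::dist(cbind(ann$x, ann$y)))
    expect_gte(min(dd[upper.tri(dd)]), p$min_separation)
  }
})

test_that("MA centres are darker than matched background controls", {
  scene <- generate_scene(small_scene_params(10, n_ma = 6L))
  g <- scene$green
  ann <- scene$annotations
  ma_vals <- g[cbind(ann$y + 1, ann$x + 1)]
  # controls: shift each centre 15 px (clear of the lesion, same bg field)
  ctrl_vals <- g[cbind(ann$y + 1, pmin(ann$x + 16, ncol(g)))]
  expect_lt(mean(ma_vals), mean(ctrl_vals))
})

test_that("multiscale response at implanted centres beats matched
           controls nearly always", {
  scene <- generate_scene(small_scene_params(29, n_ma = 6L))
  cfg <- ma_config(working_resolution = 220L)
  pre <- preprocess_image(scene$image, cfg)
  resp <- multiscale_response(pre$image, cfg, pre$fov)$response
  ann <- scene$annotations
  at_ma <- resp[cbind(ann$y + 1, ann$x + 1)]
  at_ctrl <- resp[cbind(ann$y + 1, pmin(ann$x + 16, ncol(resp)))]
  expect_gte(mean(at_ma > at_ctrl), 0.95)
})

test_that("patch datasets are balanced, reproducible and centred on
           local minima of the smoothed lesion", {
  p <- small_scene_params(40, n_ma = 8L)
  cfg <- ma_config(working_resolution = 220L)
  ds <- generate_patch_dataset(p, n_per_class = 20L, cfg = cfg)
  expect_length(ds$stacks, 40L)
  expect_equal(sum(ds$labels == 1L), 20L)
  expect_equal(sum(ds$labels == 2L), 20L)
  expect_true(all(vapply(ds$stacks, function(s)
    all(dim(s) == c(121L, 8L)), TRUE)))

  ds2 <- generate_patch_dataset(p, n_per_class = 20L, cfg = cfg)
  expect_identical(ds$stacks, ds2$stacks)

  # disjoint seeds -> disjoint patch locations
  ds3 <- generate_patch_dataset(small_scene_params(400, n_ma = 8L),
                                n_per_class = 20L, cfg = cfg)
  k1 <- paste(ds$centers$image_id, ds$centers$x, ds$centers$y)
  k3 <- paste(ds3$centers$image_id, ds3$centers$x, ds3$centers$y)
  expect_length(intersect(k1, k3), 0L)

  # every MA patch's centre is the minimum of its smoothed 11x11 window
  scene <- generate_scene(p)
  S <- p$image_size
  fov <- (matrix(seq_len(S), S, S) - (S / 2 + 0.5))^2 +
    (t(matrix(seq_len(S), S, S)) - (S / 2 + 0.5))^2 <=
    (p$fov_radius_frac * S)^2
  enh <- enhance(scene$green, fov, cfg)
  sm <- fundusMA:::conv2_reflect(enh, fundusMA:::gaussian_kernel(1, 2L))
  ma_rows <- ds$centers[ds$centers$label == "MA" &
                        ds$centers$image_id == scene$image$image_id, ]
  for (i in seq_len(nrow(ma_rows))) {
    w <- extract_patch(sm, c(ma_rows$y[i] + 1L, ma_rows$x[i] + 1L))$window
    expect_equal(which.min(w), 61L)   # centre of the 11x11 window
  }
})

test_that("oversized dark distractors grow past the size cap and every
           retained candidate respects it", {
  p <- small_scene_params(55, n_ma = 4L, n_large_dark = 2L)
  scene <- generate_scene(p)
  cfg <- ma_config(working_resolution = 220L)
  # on the clean green channel, growing from a large-blob centre exceeds
  # the 120-pixel cap, so the size filter (not thresholding) removes it
  big <- scene$distractors[scene$distractors$type == "large_dark", ]
  g <- scene$green
  for (i in seq_len(nrow(big))) {
    seed <- (big$x[i]) * nrow(g) + big$y[i] + 1L
    tgrow <- adaptive_threshold(g[seed],
                                fundusMA:::box_mean(g, 25L)[seed], 0.5)
    grown <- region_grow(g, seed, tgrow, max_pixels = 1200L)
    expect_gt(length(grown), cfg$max_region_area)
  }
  pre <- preprocess_image(scene$image, cfg)
  tab <- candidates_table(extract_candidates(pre, cfg))
  expect_true(all(tab$area <= cfg$max_region_area))
})

test_that("scene writing produces the declared files and byte-identical
           reruns", {
  dir1 <- withr::local_tempdir(); dir2 <- withr::local_tempdir()
  scene <- generate_scene(small_scene_params(8))
  f1 <- write_scene(scene, dir1)
  f2 <- write_scene(generate_scene(small_scene_params(8)), dir2)
  expect_true(all(file.exists(f1)))
  for (k in seq_along(f1)) {
    expect_identical(readBin(f1[k], "raw", 5e6), readBin(f2[k], "raw", 5e6))
  }
})
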