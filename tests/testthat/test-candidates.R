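test_that("correlation map equals a brute-force Pearson computation", {
  set.seed(101)
  img <- matrix(stats::runif(32 * 32), 32, 32)
  for (sigma in c(1.1, 1.3, 1.5)) {
    got <- correlation_map(img, sigma, window_half = 4L)
    want <- pearson_map_oracle(img, sigma, 4L)
    expect_lt(max(abs(got - want)), 1e-10)
  }
})

test_that("an affine copy of the template correlates to exactly 1", {
  half <- 4L
  tmpl <- fundusMA:::gaussian_template(1.2, half)
  img <- matrix(0.5, 31, 31)
  # place a*G+b as a *dark* blob so the inverted image is an affine copy
  img[12:20, 12:20] <- 0.9 - 0.3 * tmpl
  r <- correlation_map(img, 1.2, half)
  expect_equal(r[16, 16], 1, tolerance = 1e-12)
})

test_that("constant images give an all-zero response (zero-variance rule)", {
  r <- correlation_map(matrix(0.5, 16, 16), 1.2, window_half = 4L)
  expect_true(all(r == 0))
  expect_error(correlation_map(matrix(0.5, 8, 8), 1.2, window_half = 4L),
               "window larger")
})

test_that("multiscale max is the elementwise maximum and dominates
           every scale", {
  maps <- list(matrix(0.2, 4, 4), matrix(0.5, 4, 4), matrix(0.4, 4, 4),
               matrix(0.1, 4, 4), matrix(0.3, 4, 4))
  expect_equal(multiscale_max(maps), matrix(0.5, 4, 4))
  expect_error(multiscale_max(list(matrix(0, 2, 2), matrix(0, 3, 3))))

  set.seed(7)
  img <- matrix(stats::runif(40 * 40, 0.4, 0.6), 40, 40)
  ms <- multiscale_response(img, ma_config(), keep_scales = TRUE)
  for (m in ms$per_scale) expect_true(all(ms$response >= m))
})

test_that("an implanted blob at sigma 1.3 peaks at its own scale", {
  half <- 4L
  img <- matrix(0.6, 41, 41)
  d2 <- outer((-20:20)^2, (-20:20)^2, `+`)
  img <- img - 0.25 * exp(-d2 / (2 * 1.3^2))
  centre <- sapply(c(1.1, 1.2, 1.3, 1.4, 1.5), function(s)
    correlation_map(img, s, half)[21, 21])
  expect_true(all(centre[3] >= centre))
})

test_that("threshold is inclusive and candidates decrease monotonically", {
  resp <- matrix(0, 20, 20)
  resp[5, 5] <- 0.59; resp[5, 10] <- 0.60; resp[5, 15] <- 0.61
  seeds <- threshold_candidates(resp, 0.6)
  expect_length(seeds, 2L)

  # on a smooth unimodal response (the realistic case) raising the
  # threshold never increases the number of seed regions, and the set of
  # retained pixels always shrinks
  resp2 <- matrix(0, 60, 60)
  for (ctr in list(c(15, 15), c(15, 45), c(45, 30))) {
    d2 <- outer((seq_len(60) - ctr[1])^2, (seq_len(60) - ctr[2])^2, `+`)
    resp2 <- pmax(resp2, exp(-d2 / 30))
  }
  counts <- sapply(seq(0.1, 0.9, 0.1), function(th)
    length(threshold_candidates(resp2, th)))
  expect_true(all(diff(counts) <= 0))
  px <- lapply(seq(0.1, 0.9, 0.1), function(th)
    sort(unlist(threshold_candidates(resp2, th))))
  for (i in seq_len(8)) expect_true(all(px[[i + 1]] %in% px[[i]]))
})

test_that("vessel exclusion removes on-vessel blobs; pass-through mask
           removes nothing", {
  resp <- matrix(0, 30, 30)
  resp[10:12, 10:12] <- 0.9
  vess <- matrix(FALSE, 30, 30); vess[8:14, 8:14] <- TRUE
  expect_length(threshold_candidates(resp, 0.6, vessels = vess), 0L)
  expect_length(threshold_candidates(resp, 0.6,
                                     vessels = matrix(FALSE, 30, 30)), 1L)
  expect_error(threshold_candidates(resp, 0.6,
                                    vessels = matrix(FALSE, 10, 10)),
               "shape")
})

test_that("vessel heuristic keeps curves, drops MA-scale blobs", {
  cfg <- ma_config()
  S <- 200
  g <- matrix(0.6, S, S)
  for (i in 1:180) {
    r <- 10 + i; c <- round(100 + 30 * sin(i / 25))
    if (r <= S && c >= 2 && c <= S - 1) g[r, c + (-1:1)] <- 0.3
  }
  g <- fundusMA:::conv2_reflect(g, fundusMA:::gaussian_kernel(1, 2L))
  g[60:62, 160:162] <- 0.35
  vm <- vessel_mask(g, cfg)
  on_curve <- vm[cbind(41:160, round(100 + 30 * sin((31:150) / 25)))]
  expect_gt(mean(on_curve), 0.9)
  expect_false(any(vm[58:64, 158:164]))
})

test_that("adaptive threshold follows the dynamics formula", {
  expect_equal(adaptive_threshold(0.2, 0.6, 0.5), 0.4)
  expect_equal(adaptive_threshold(0.2, 0.6, 0), 0.2)   # darkest only
  expect_equal(adaptive_threshold(0.2, 0.6, 1), 0.6)   # up to background
  expect_error(adaptive_threshold(0.2, 0.6, 1.5))
})

test_that("region growing matches the naive flood-fill oracle", {
  # dark disk of known pixel count
  g <- matrix(0.8, 60, 60)
  d2 <- outer((-29:30)^2, (-29:30)^2, `+`)
  g[d2 <= 11.5] <- 0.1                    # 37-pixel digital disk
  seed <- which.min(g)
  px <- region_grow(g, seed, 0.4)
  expect_length(px, 37L)
  expect_setequal(px, flood_oracle(g <= 0.4, seed))

  # singleton: all 8 neighbours above t
  g2 <- matrix(0.9, 20, 20); g2[10, 10] <- 0.1
  expect_length(region_grow(g2, which.min(g2), 0.4), 1L)

  # bridge joins two disks into one region
  g3 <- matrix(0.9, 40, 80)
  d2a <- outer((20 - seq_len(40))^2, (20 - seq_len(80))^2, `+`)
  d2b <- outer((20 - seq_len(40))^2, (60 - seq_len(80))^2, `+`)
  g3[d2a <= 16 | d2b <= 16] <- 0.1
  g3[20, 20:60] <- 0.1
  px3 <- region_grow(g3, which.min(g3), 0.4)
  expect_setequal(px3, flood_oracle(g3 <= 0.4, which.min(g3)))
  expect_true(any((px3 - 1) %/% 40 + 1 > 40))  # reaches the second disk

  # seed above threshold -> empty-region signal
  expect_length(region_grow(g2, 1L, 0.4), 0L)
})

test_that("region growing on random blob fields equals the oracle", {
  set.seed(33)
  for (rep in 1:8) {
    g <- matrix(stats::runif(45 * 45, 0.5, 0.9), 45, 45)
    n_blob <- sample(2:4, 1)
    for (b in seq_len(n_blob)) {
      r0 <- sample(8:38, 1); c0 <- sample(8:38, 1)
      rad2 <- sample(4:20, 1)
      d2 <- outer((seq_len(45) - r0)^2, (seq_len(45) - c0)^2, `+`)
      g[d2 <= rad2] <- stats::runif(1, 0.05, 0.2)
    }
    seed <- which.min(g)
    t <- adaptive_threshold(g[seed], mean(g), 0.5)
    expect_setequal(region_grow(g, seed, t), flood_oracle(g <= t, seed))
  }
})

test_that("size filter discards regions above 120 pixels and keeps 120", {
  mk <- function(a) list(pixels = seq_len(a), area = a, score = 0.7)
  out <- filter_by_size(list(mk(121L), mk(120L), mk(119L)), 120L)
  expect_equal(vapply(out, `[[`, 0L, "area"), c(120L, 119L))
  expect_length(filter_by_size(list(), 120L), 0L)
})

test_that("8-connected labelling counts diagonal and separated blobs", {
  m <- matrix(FALSE, 10, 10)
  m[2, 2] <- TRUE; m[3, 3] <- TRUE        # diagonal pair: one component
  comps <- fundusMA:::label_components8(m)
  expect_length(comps, 1L)
  m[8, 8] <- TRUE
  expect_length(fundusMA:::label_components8(m), 2L)
  resp <- matrix(0, 40, 40)
  resp[10, 10] <- 0.9; resp[10, 30] <- 0.9   # 20 px apart
  expect_length(threshold_candidates(resp, 0.6), 2L)
})

test_that("candidate extraction end-to-end finds implanted blobs and
           excludes the oversized", {
  scene <- generate_scene(small_scene_params(17))
  cfg <- ma_config(working_resolution = 220L)
  pre <- preprocess_image(scene$image, cfg)
  cands <- extract_candidates(pre, cfg)
  tab <- candidates_table(cands)
  expect_true(all(tab$area <= cfg$max_region_area))
  expect_true(all(tab$score >= cfg$correlation_threshold - 1e-12))
  ann <- scene$annotations
  hit <- vapply(seq_len(nrow(ann)), function(i)
    any(sqrt((tab$x - ann$x[i])^2 + (tab$y - ann$y[i])^2) <= 5), TRUE)
  expect_gte(mean(hit), 0.75)
})
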