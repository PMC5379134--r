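# Independent oracles and small fixture builders shared by the tests.
# These are deliberately naive implementations (double loops, literal
# definitional sums) kept separate from the package's code paths.

# Literal per-pixel Pearson correlation of the inverted image against a
# Gaussian template, clamped to [0,1]; border pixels (window leaves the
# image) are 0, zero-variance windows are 0.
pearson_map_oracle <- function(image, sigma, half) {
  inv <- 1 - image
  H <- nrow(image); W <- ncol(image)
  tmpl <- as.vector(outer(exp(-(-half:half)^2 / (2 * sigma^2)),
                          exp(-(-half:half)^2 / (2 * sigma^2))))
  out <- matrix(0, H, W)
  for (i in (half + 1):(H - half)) {
    for (j in (half + 1):(W - half)) {
      w <- as.vector(inv[(i - half):(i + half), (j - half):(j + half)])
      r <- suppressWarnings(stats::cor(w, tmpl))
      if (is.na(r) || r < 0) r <- 0
      out[i, j] <- min(r, 1)
    }
  }
  out
}

# Naive 8-connected flood fill: repeated neighbourhood scans until the
# region stops growing. Returns sorted linear indices.
flood_oracle <- function(include_mat, seed) {
  H <- nrow(include_mat); W <- ncol(include_mat)
  region <- matrix(FALSE, H, W)
  region[seed] <- include_mat[seed]
  if (!region[seed]) return(integer(0))
  repeat {
    grown <- region
    idx <- which(region)
    r <- (idx - 1L) %% H + 1L
    c <- (idx - 1L) %/% H + 1L
    for (dr in -1:1) for (dc in -1:1) {
      rr <- r + dr; cc <- c + dc
      ok <- rr >= 1 & rr <= H & cc >= 1 & cc <= W
      grown[cbind(rr[ok], cc[ok])] <-
        grown[cbind(rr[ok], cc[ok])] | include_mat[cbind(rr[ok], cc[ok])]
    }
    if (identical(grown, region)) break
    region <- grown
  }
  sort(which(region))
}

# Definitional between/within scatter sums over feature stacks.
scatter_oracle <- function(stacks, labels) {
  K <- ncol(stacks[[1]])
  N <- length(stacks)
  Xbar <- Reduce(`+`, stacks) / N
  Sb <- matrix(0, K, K); Sw <- matrix(0, K, K)
  for (cl in sort(unique(labels))) {
    idx <- which(labels == cl)
    Xc <- Reduce(`+`, stacks[idx]) / length(idx)
    Sb <- Sb + length(idx) * t(Xc - Xbar) %*% (Xc - Xbar)
    for (i in idx) Sw <- Sw + t(stacks[[i]] - Xc) %*% (stacks[[i]] - Xc)
  }
  list(Sb = Sb, Sw = Sw)
}

# Bright disk on a dark surround (value/background in [0,1]).
make_disk_image <- function(S = 200, radius = 80, value = 0.6, bg = 0.02) {
  ctr <- (S + 1) / 2
  d2 <- (matrix(seq_len(S), S, S) - ctr)^2 +
        (t(matrix(seq_len(S), S, S)) - ctr)^2
  g <- matrix(bg, S, S)
  g[d2 <= radius^2] <- value
  g
}

# Small, quick-to-generate scene parameters for unit tests.
small_scene_params <- function(seed, ...) {
  defaults <- list(image_size = 220L, n_vessels = 3L, n_ma = 4L,
                   n_bright = 1L, n_large_dark = 1L, seed = seed)
  args <- utils::modifyList(defaults, list(...))
  do.call(simulation_params, args)
}

# Random labelled feature stacks with a class-mean shift on channel 1.
random_stacks <- function(n_per_class, p = 30, K = 4, shift = 1.5) {
  s1 <- lapply(seq_len(n_per_class),
               function(i) matrix(stats::rnorm(p * K), p, K))
  s2 <- lapply(seq_len(n_per_class), function(i)
    matrix(stats::rnorm(p * K), p, K) +
      outer(rep(1, p), c(shift, rep(0, K - 1))) / sqrt(p))
  list(stacks = c(s1, s2), labels = rep(1:2, each = n_per_class))
}
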