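# Candidate extraction: multiscale Gaussian correlation filtering,
# response thresholding, vessel exclusion, adaptive-threshold region
# growing and the size filter.

# ---- 8-connected pixel utilities (linear indices, column-major) --------

# Vectorized 8-connected breadth-first flood fill over a logical inclusion
# vector. Returns the linear indices of the filled region.
flood_fill8 <- function(include, seed, H, W, max_pixels = Inf) {
  visited <- logical(H * W)
  if (!include[seed]) return(integer(0))
  visited[seed] <- TRUE
  pixels <- seed
  frontier <- seed
  while (length(frontier) && length(pixels) <= max_pixels) {
    r <- (frontier - 1L) %% H + 1L
    c <- (frontier - 1L) %/% H + 1L
    nb <- integer(0)
    for (dr in -1L:1L) for (dc in -1L:1L) {
      if (dr == 0L && dc == 0L) next
      rr <- r + dr; cc <- c + dc
      ok <- rr >= 1L & rr <= H & cc >= 1L & cc <= W
      if (any(ok)) nb <- c(nb, (cc[ok] - 1L) * H + rr[ok])
    }
    nb <- unique(nb)
    nb <- nb[!visited[nb] & include[nb]]
    visited[nb] <- TRUE
    pixels <- c(pixels, nb)
    frontier <- nb
  }
  pixels
}

# 8-connected components of a logical matrix as a list of linear-index
# vectors: 4-connected labelling (EBImage) followed by union-find over
# the diagonal adjacencies.
label_components8 <- function(mask) {
  if (!any(mask)) return(list())
  H <- nrow(mask); W <- ncol(mask)
  lab <- t(EBImage::imageData(EBImage::bwlabel(EBImage::Image(t(mask)))))
  storage.mode(lab) <- "integer"
  n <- max(lab)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  a1 <- lab[seq_len(H - 1L), seq_len(W - 1L)]
  b1 <- lab[2:H, 2:W]
  a2 <- lab[2:H, seq_len(W - 1L)]
  b2 <- lab[seq_len(H - 1L), 2:W]
  keep1 <- a1 > 0L & b1 > 0L & a1 != b1
  keep2 <- a2 > 0L & b2 > 0L & a2 != b2
  pairs <- unique(rbind(cbind(a1[keep1], b1[keep1]),
                        cbind(a2[keep2], b2[keep2])))
  for (k in seq_len(nrow(pairs))) {
    ra <- find(pairs[k, 1L]); rb <- find(pairs[k, 2L])
    if (ra != rb) parent[rb] <- ra
  }
  roots <- vapply(seq_len(n), find, 0L)
  pix <- which(lab > 0L)
  unname(split(pix, roots[lab[pix]]))
}

# Chebyshev dilation of a set of linear indices by `by` pixels.
dilate_indices <- function(idx, H, W, by = 2L) {
  r <- (idx - 1L) %% H + 1L
  c <- (idx - 1L) %/% H + 1L
  out <- integer(0)
  for (dr in -by:by) for (dc in -by:by) {
    rr <- r + dr; cc <- c + dc
    ok <- rr >= 1L & rr <= H & cc >= 1L & cc <= W
    out <- c(out, (cc[ok] - 1L) * H + rr[ok])
  }
  unique(out)
}

# Mean filter with an edge-clipped square window (integral-image based).
box_mean <- function(mat, w) {
  h <- (w - 1L) %/% 2L
  H <- nrow(mat); W <- ncol(mat)
  ii <- matrix(0, H + 1L, W + 1L)
  ii[-1L, -1L] <- apply(apply(mat, 2L, cumsum), 1L, cumsum) |> t()
  r1 <- pmax(seq_len(H) - h, 1L); r2 <- pmin(seq_len(H) + h, H)
  c1 <- pmax(seq_len(W) - h, 1L); c2 <- pmin(seq_len(W) + h, W)
  S <- ii[r2 + 1L, c2 + 1L] - ii[r1, c2 + 1L] -
       ii[r2 + 1L, c1] + ii[r1, c1]
  n <- outer(r2 - r1 + 1L, c2 - c1 + 1L)
  S / n
}

# ---- multiscale correlation filtering ----------------------------------

# Window sums of a matrix and its square over the full (2h+1)^2 window,
# computed by exact shift accumulation (no FFT, no integral-image
# cancellation); border pixels whose window leaves the image are invalid.
window_sums <- function(mat, half) {
  H <- nrow(mat); W <- ncol(mat)
  P <- matrix(0, H + 2L * half, W + 2L * half)
  P[half + seq_len(H), half + seq_len(W)] <- mat
  P2 <- P * P
  S1 <- matrix(0, H, W); S2 <- matrix(0, H, W)
  for (di in 0:(2L * half)) for (dj in 0:(2L * half)) {
    S1 <- S1 + P[di + seq_len(H), dj + seq_len(W)]
    S2 <- S2 + P2[di + seq_len(H), dj + seq_len(W)]
  }
  list(S1 = S1, S2 = S2)
}

# Correlation numerator sum( (G - mean(G)) * window ) by shift accumulation.
template_cross <- function(mat, tmpl, half) {
  H <- nrow(mat); W <- ncol(mat)
  P <- matrix(0, H + 2L * half, W + 2L * half)
  P[half + seq_len(H), half + seq_len(W)] <- mat
  w <- tmpl - mean(tmpl)
  num <- matrix(0, H, W)
  for (di in 0:(2L * half)) for (dj in 0:(2L * half)) {
    num <- num + w[di + 1L, dj + 1L] * P[di + seq_len(H), dj + seq_len(W)]
  }
  num
}

mscf_single <- function(inv, sums, tmpl, half, valid) {
  n <- (2L * half + 1L)^2
  num <- template_cross(inv, tmpl, half)
  sxx <- sum((tmpl - mean(tmpl))^2)
  vy <- sums$S2 - sums$S1^2 / n
  r <- matrix(0, nrow(inv), ncol(inv))
  ok <- valid & vy > 1e-12
  r[ok] <- num[ok] / sqrt(sxx * vy[ok])
  r[r < 0] <- 0
  pmin(r, 1)
}

#' Single-scale Gaussian correlation map
#'
#' At each pixel, the Pearson correlation coefficient between a Gaussian
#' template of scale \code{sigma} and the local window of the
#' intensity-inverted image (microaneurysms are dark, the template is
#' bright; inversion keeps the response in [0,1]). Negative correlations
#' and zero-variance windows map to 0, as do border pixels whose window
#' leaves the image and, when given, pixels outside the FOV.
#'
#' @param image H x W matrix in [0,1] (preprocessed working image).
#' @param sigma Gaussian template scale in pixels.
#' @param window_half Half-width of the square correlation window.
#' @param fov Optional logical FOV mask.
#' @return H x W response matrix in [0,1].
#' @export
correlation_map <- function(image, sigma, window_half = 4L, fov = NULL) {
  H <- nrow(image); W <- ncol(image)
  if (2L * window_half + 1L > min(H, W))
    stop("correlation window larger than image")
  inv <- 1 - image
  sums <- window_sums(inv, window_half)
  valid <- matrix(FALSE, H, W)
  valid[(window_half + 1L):(H - window_half),
        (window_half + 1L):(W - window_half)] <- TRUE
  if (!is.null(fov)) valid <- valid & fov
  tmpl <- gaussian_template(sigma, window_half)
  mscf_single(inv, sums, tmpl, window_half, valid)
}

#' Elementwise maximum over single-scale response maps
#' @param maps List of H x W response matrices sharing one shape.
#' @return H x W matrix of per-pixel maxima.
#' @export
multiscale_max <- function(maps) {
  stopifnot(length(maps) >= 1L)
  d <- dim(maps[[1]])
  out <- maps[[1]]
  for (m in maps[-1]) {
    if (!all(dim(m) == d)) stop("response maps differ in shape")
    out <- pmax(out, m)
  }
  out
}

#' Multiscale correlation response
#'
#' Runs \code{correlation_map} at every scale of the configuration's
#' sigma grid (window sums are shared across scales) and combines the
#' responses by elementwise maximum.
#'
#' @param image Preprocessed working image.
#' @param cfg An \code{ma_config}.
#' @param fov Optional logical FOV mask.
#' @param keep_scales Keep the per-scale maps in the result?
#' @return List with \code{response} (the max map) and, if requested,
#'   \code{per_scale} (named by sigma).
#' @export
multiscale_response <- function(image, cfg = ma_config(), fov = NULL,
                                keep_scales = FALSE) {
  half <- cfg$window_half
  H <- nrow(image); W <- ncol(image)
  if (2L * half + 1L > min(H, W)) stop("correlation window larger than image")
  inv <- 1 - image
  sums <- window_sums(inv, half)
  valid <- matrix(FALSE, H, W)
  valid[(half + 1L):(H - half), (half + 1L):(W - half)] <- TRUE
  if (!is.null(fov)) valid <- valid & fov
  maps <- lapply(sigma_grid(cfg), function(s)
    mscf_single(inv, sums, gaussian_template(s, half), half, valid))
  names(maps) <- as.character(sigma_grid(cfg))
  out <- list(response = multiscale_max(maps))
  if (keep_scales) out$per_scale <- maps
  out
}

# ---- vessel exclusion --------------------------------------------------

# Eccentricity of a pixel set from its second central moments.
pixel_eccentricity <- function(idx, H) {
  r <- (idx - 1L) %% H + 1L
  c <- (idx - 1L) %/% H + 1L
  if (length(idx) < 3L) return(0)
  cv <- stats::cov(cbind(r, c))
  ev <- eigen(cv, symmetric = TRUE, only.values = TRUE)$values
  if (ev[1] <= 0) return(0)
  sqrt(max(0, 1 - ev[2] / ev[1]))
}

#' Heuristic vessel mask
#'
#' Marks elongated dark structures so candidates lying on the vasculature
#' can be removed. A morphological bottom-hat with a disc larger than the
#' microaneurysm scale highlights dark structures; thresholding it and
#' dropping components that are small and compact enough to be MA-like
#' leaves the vessel tree. A user-supplied mask (e.g. from a dedicated
#' vessel segmenter) can be passed downstream instead.
#'
#' @param image Preprocessed working image.
#' @param cfg An \code{ma_config} (disc radius and bottom-hat threshold).
#' @param fov Optional logical FOV mask.
#' @return H x W logical matrix, TRUE on vessels.
#' @export
vessel_mask <- function(image, cfg = ma_config(), fov = NULL) {
  r <- cfg$vessel_disc_radius
  brush <- EBImage::makeBrush(2L * r + 1L, shape = "disc")
  closed <- t(EBImage::imageData(
    EBImage::closing(EBImage::Image(t(image)), brush)))
  bh <- closed - image
  m <- bh > cfg$vessel_threshold
  if (!is.null(fov)) m <- m & fov
  H <- nrow(m)
  out <- matrix(FALSE, H, ncol(m))
  for (px in label_components8(m)) {
    ma_like <- length(px) <= cfg$max_region_area &&
      pixel_eccentricity(px, H) < 0.95
    tiny <- length(px) < 20L
    if (!ma_like && !tiny) out[px] <- TRUE
  }
  out
}

# ---- thresholding, region growing, size filter -------------------------

#' Seed regions from a thresholded response map
#'
#' Pixels with response >= threshold (inclusive), inside the FOV and off
#' the vessel mask, grouped into 8-connected components.
#'
#' @param response H x W response matrix.
#' @param threshold Response threshold in (0,1).
#' @param vessels Optional logical vessel mask (TRUE = excluded).
#' @param fov Optional logical FOV mask.
#' @return List of integer vectors of linear pixel indices, one per seed
#'   component (possibly empty).
#' @export
threshold_candidates <- function(response, threshold, vessels = NULL,
                                 fov = NULL) {
  stopifnot(threshold > 0, threshold < 1)
  bw <- response >= threshold
  if (!is.null(fov)) bw <- bw & fov
  if (!is.null(vessels)) {
    if (!all(dim(vessels) == dim(response)))
      stop("vessel mask shape does not match response map")
    bw <- bw & !vessels
  }
  label_components8(bw)
}

#' Adaptive region-growing threshold
#'
#' The growing threshold interpolates between the darkest candidate
#' intensity and the local background level:
#' \code{t = i_darkest - beta * (i_darkest - i_bg)}, so \code{beta = 0}
#' grows nothing beyond the darkest intensity and \code{beta = 1} grows up
#' to the background.
#'
#' @param i_darkest Lowest green-channel intensity in the candidate
#'   locality.
#' @param i_bg Mean-filtered background intensity at the seed.
#' @param beta Dynamics weight in [0,1].
#' @return The threshold t.
#' @export
adaptive_threshold <- function(i_darkest, i_bg, beta = 0.5) {
  stopifnot(beta >= 0, beta <= 1)
  i_darkest - beta * (i_darkest - i_bg)
}

#' Grow a candidate region from its darkest pixel
#'
#' 8-connected flood fill from the seed, including pixels with intensity
#' <= t (microaneurysms are dark).
#'
#' @param green H x W intensity matrix.
#' @param seed Linear index of the starting pixel.
#' @param t Growing threshold.
#' @param max_pixels Safety cap on region size; growth stops once the
#'   region exceeds it (such regions are discarded by the size filter).
#' @return Integer vector of linear pixel indices; empty if the seed
#'   itself is above t.
#' @export
region_grow <- function(green, seed, t, max_pixels = Inf) {
  H <- nrow(green); W <- ncol(green)
  r0 <- (seed - 1L) %% H + 1L
  c0 <- (seed - 1L) %/% H + 1L
  # grow inside an expanding local window: regions are small (they are
  # capped anyway), so the fill rarely needs the full image
  half <- 16L
  repeat {
    r1 <- max(1L, r0 - half); r2 <- min(H, r0 + half)
    c1 <- max(1L, c0 - half); c2 <- min(W, c0 + half)
    sub <- green[r1:r2, c1:c2, drop = FALSE] <= t
    h <- nrow(sub); w <- ncol(sub)
    sseed <- (c0 - c1) * h + (r0 - r1 + 1L)
    px <- flood_fill8(as.vector(sub), sseed, h, w, max_pixels = max_pixels)
    if (length(px) == 0L) return(integer(0))
    rr <- (px - 1L) %% h + r1
    cc <- (px - 1L) %/% h + c1
    touches <- (any(rr == r1) && r1 > 1L) || (any(rr == r2) && r2 < H) ||
               (any(cc == c1) && c1 > 1L) || (any(cc == c2) && c2 < W)
    if (!touches || length(px) > max_pixels ||
        (r1 == 1L && r2 == H && c1 == 1L && c2 == W)) {
      return((cc - 1L) * H + rr)
    }
    half <- half * 2L
  }
}

#' Discard regions larger than the microaneurysm size cap
#'
#' A region whose area exceeds \code{max_area} pixels is too large to be a
#' microaneurysm and is removed; regions of exactly \code{max_area} pixels
#' are kept.
#'
#' @param regions List of candidate regions (each with an \code{area}).
#' @param max_area Size cap in pixels (default 120).
#' @return The filtered list.
#' @export
filter_by_size <- function(regions, max_area = 120L) {
  Filter(function(r) r$area <= max_area, regions)
}

#' Extract microaneurysm candidate regions from a preprocessed image
#'
#' The full candidate stage: multiscale correlation response, threshold at
#' \code{cfg$correlation_threshold}, vessel exclusion, adaptive-threshold
#' region growing from each seed component's darkest pixel, and the
#' 120-pixel size filter.
#'
#' @param pre Output of \code{preprocess_image} (or a list with
#'   \code{image}, \code{fov}, \code{image_id}).
#' @param cfg An \code{ma_config}.
#' @param vessels Logical vessel mask, or NULL to compute the built-in
#'   heuristic mask.
#' @param response Optional precomputed multiscale response map.
#' @param threshold Response threshold (defaults to the configured one).
#' @return List of class \code{"ma_candidates"}: candidate regions, each a
#'   list with \code{pixels} (linear indices), \code{seed}, \code{area},
#'   \code{score} (peak response), \code{centroid} (row, col, 1-based) and
#'   \code{image_id}; the response map is attached as an attribute.
#' @export
extract_candidates <- function(pre, cfg = ma_config(), vessels = NULL,
                               response = NULL,
                               threshold = cfg$correlation_threshold) {
  img <- pre$image
  H <- nrow(img); W <- ncol(img)
  if (is.null(vessels)) vessels <- vessel_mask(img, cfg, pre$fov)
  if (is.null(response))
    response <- multiscale_response(img, cfg, pre$fov)$response
  seeds <- threshold_candidates(response, threshold, vessels, pre$fov)
  bg <- box_mean(img, cfg$bg_window)
  gvec <- as.vector(img)
  rvec <- as.vector(response)
  cap <- 10L * cfg$max_region_area
  regions <- list()
  for (comp in seeds) {
    loc <- dilate_indices(comp, H, W, by = 2L)
    seed <- loc[which.min(gvec[loc])]
    i_dark <- gvec[seed]
    i_bg <- bg[seed]
    tgrow <- adaptive_threshold(i_dark, i_bg, cfg$beta)
    px <- region_grow(img, seed, tgrow, max_pixels = cap)
    if (length(px) == 0L) next
    r <- (px - 1L) %% H + 1L
    c <- (px - 1L) %/% H + 1L
    regions[[length(regions) + 1L]] <- list(
      pixels = px, seed = seed, area = length(px),
      # peak response over the grown region and its seed component, so
      # the score ranks candidates by the MSCF evidence that raised them
      score = max(rvec[px], rvec[comp]),
      centroid = c(round(mean(r)), round(mean(c))),
      image_id = pre$image_id)
  }
  regions <- filter_by_size(regions, cfg$max_region_area)
  structure(regions, class = "ma_candidates", response = response)
}

#' Convert candidate regions to a detection-style table
#' @param cands An \code{"ma_candidates"} list.
#' @return data.frame with image_id, x, y (0-based), area, score.
#' @export
candidates_table <- function(cands) {
  if (length(cands) == 0L)
    return(data.frame(image_id = character(), x = integer(), y = integer(),
                      area = integer(), score = numeric(),
                      stringsAsFactors = FALSE))
  data.frame(
    image_id = vapply(cands, `[[`, "", "image_id"),
    x = vapply(cands, function(r) r$centroid[2] - 1L, 0) |> as.integer(),
    y = vapply(cands, function(r) r$centroid[1] - 1L, 0) |> as.integer(),
    area = vapply(cands, `[[`, 0L, "area"),
    score = vapply(cands, `[[`, 0, "score"),
    stringsAsFactors = FALSE)
}
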