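# Preprocessing: green channel, field-of-view mask, contrast enhancement,
# smoothing, and bicubic resize to the square working resolution.
# Images are numeric [H, W] matrices in [0,1], row = y, col = x.

#' Extract the normalized green channel
#'
#' Microaneurysms show the highest contrast against the background in the
#' green plane of a color fundus photograph.
#'
#' @param image A \code{"fundus_image"}.
#' @return H x W numeric matrix in [0,1].
#' @export
extract_green <- function(image) {
  stopifnot(inherits(image, "fundus_image"))
  image$pixels[, , 2] / 255
}

#' Extract the field-of-view mask
#'
#' The FOV is the illuminated circular region carrying retinal
#' information. A coarse mask is obtained by Otsu thresholding of the
#' green channel; morphological opening then closing with a disc-shaped
#' structuring element of radius 2 removes misclassified specks, and the
#' largest connected component is retained.
#'
#' @param green H x W matrix in [0,1].
#' @return H x W logical matrix, TRUE inside the FOV.
#' @export
extract_fov <- function(green) {
  if (diff(range(green)) < 1e-8)
    stop("degenerate input: image is constant, no foreground/background split")
  img <- EBImage::Image(t(green))
  th <- EBImage::otsu(img)
  mask <- img > th
  brush <- EBImage::makeBrush(5L, shape = "disc")  # radius-2 disc
  mask <- EBImage::closing(EBImage::opening(mask, brush), brush)
  lab <- EBImage::bwlabel(mask)
  tab <- tabulate(as.integer(EBImage::imageData(lab)))
  if (length(tab) == 0L || max(tab) == 0L)
    stop("degenerate input: empty field of view after cleanup")
  keep <- which.max(tab)
  t(EBImage::imageData(lab) == keep)
}

# Discrete Gaussian kernel on a (2h+1)^2 grid, normalized to unit sum.
gaussian_kernel <- function(sigma, half) {
  x <- -half:half
  k1 <- exp(-x^2 / (2 * sigma^2))
  k <- outer(k1, k1)
  k / sum(k)
}

# Unnormalized Gaussian template used by correlation filtering (Pearson
# correlation is invariant to the template's scale and offset).
gaussian_template <- function(sigma, half) {
  x <- -half:half
  k1 <- exp(-x^2 / (2 * sigma^2))
  outer(k1, k1)
}

# 2-D convolution with symmetric (half-sample reflection) boundary.
conv2_reflect <- function(mat, kernel) {
  kh <- (nrow(kernel) - 1L) %/% 2L
  kw <- (ncol(kernel) - 1L) %/% 2L
  H <- nrow(mat); W <- ncol(mat)
  ri <- c(rev(seq_len(kh)), seq_len(H), H - seq_len(kh) + 1L)
  ci <- c(rev(seq_len(kw)), seq_len(W), W - seq_len(kw) + 1L)
  pad <- mat[ri, ci, drop = FALSE]
  out <- matrix(0, H, W)
  for (i in seq_len(nrow(kernel))) {
    for (j in seq_len(ncol(kernel))) {
      if (kernel[i, j] == 0) next
      out <- out + kernel[i, j] *
        pad[(i - 1L) + seq_len(H), (j - 1L) + seq_len(W), drop = FALSE]
    }
  }
  out
}

#' Contrast enhancement and smoothing
#'
#' Applies contrast-limited adaptive histogram equalization (CLAHE) to the
#' green channel, then a 5x5 Gaussian smoothing filter with standard
#' deviation 1 to suppress amplified noise. Pixels outside the FOV are set
#' to zero and the output is clipped to [0,1]. A flat field (no dynamic
#' range inside the FOV) is passed through CLAHE unchanged.
#'
#' @param green H x W matrix in [0,1].
#' @param fov H x W logical FOV mask.
#' @param cfg An \code{ma_config} (CLAHE tile grid and clip limit).
#' @return H x W matrix in [0,1].
#' @export
enhance <- function(green, fov, cfg = ma_config()) {
  stopifnot(all(dim(green) == dim(fov)))
  rng <- range(green[fov])
  if (diff(rng) > 1e-8) {
    # CLAHE tiles must divide the image extent: replicate-pad to the next
    # multiple, equalize, crop back. The limit is relative to the mean
    # histogram bin height; the configured clip is on the [0,1] scale
    # with 256 bins.
    H <- nrow(green); W <- ncol(green)
    nt <- cfg$clahe_tiles
    Hp <- nt * ceiling(H / nt); Wp <- nt * ceiling(W / nt)
    gp <- green[c(seq_len(H), rep(H, Hp - H)),
                c(seq_len(W), rep(W, Wp - W)), drop = FALSE]
    eq <- EBImage::clahe(EBImage::Image(t(gp)), nx = nt, ny = nt,
                         bins = 256L, limit = cfg$clahe_clip * 256)
    g <- t(EBImage::imageData(eq))[seq_len(H), seq_len(W), drop = FALSE]
  } else {
    g <- green
  }
  g <- conv2_reflect(g, gaussian_kernel(1, 2L))
  g[!fov] <- 0
  pmin(pmax(g, 0), 1)
}

# Catmull-Rom cubic interpolation weight (the classic bicubic kernel,
# a = -0.5).
cubic_weight <- function(t) {
  t <- abs(t)
  ifelse(t <= 1, 1.5 * t^3 - 2.5 * t^2 + 1,
         ifelse(t < 2, -0.5 * t^3 + 2.5 * t^2 - 4 * t + 2, 0))
}

# Dense (out x in) row-resampling matrix for separable bicubic resize,
# pixel-centre aligned, edge-clamped.
bicubic_weights <- function(n_in, n_out) {
  s <- ((seq_len(n_out) - 0.5) * n_in / n_out) - 0.5   # 0-based source coord
  base <- floor(s)
  W <- matrix(0, n_out, n_in)
  for (k in -1:2) {
    idx <- base + k
    w <- cubic_weight(s - idx)
    idx <- pmin(pmax(idx, 0), n_in - 1L)               # clamp at edges
    W[cbind(seq_len(n_out), idx + 1L)] <-
      W[cbind(seq_len(n_out), idx + 1L)] + w
  }
  W / rowSums(W)
}

#' Resize a grayscale image to the working resolution
#'
#' Bicubic (Catmull-Rom) interpolation to an S x S raster, S =
#' \code{working_resolution}. An input already at the target size is
#' returned unchanged.
#'
#' @param image H x W numeric matrix.
#' @param size Target side length (default from \code{ma_config()}).
#' @return size x size numeric matrix.
#' @export
resize_working <- function(image, size = ma_config()$working_resolution) {
  H <- nrow(image); W <- ncol(image)
  if (H == size && W == size) return(image)
  Wr <- bicubic_weights(H, size)
  Wc <- bicubic_weights(W, size)
  Wr %*% image %*% t(Wc)
}

#' Rescale annotation coordinates with a resize
#'
#' Maps 0-based pixel-centred coordinates from an n_from raster to the
#' corresponding positions on an n_to raster (the same pixel-centre
#' alignment \code{resize_working} uses).
#'
#' @param coord Numeric vector of 0-based coordinates.
#' @param n_from,n_to Source and target raster extents along that axis.
#' @return Rescaled coordinates, rounded to integers.
#' @export
rescale_coords <- function(coord, n_from, n_to) {
  as.integer(round((coord + 0.5) * n_to / n_from - 0.5))
}

#' Full preprocessing of a fundus photograph
#'
#' Green channel, FOV extraction, CLAHE + Gaussian smoothing, then bicubic
#' resize to the square working resolution (FOV resized nearest-neighbour).
#'
#' @param image A \code{"fundus_image"}.
#' @param cfg An \code{ma_config}.
#' @return List with \code{image} (S x S matrix in [0,1]), \code{fov}
#'   (S x S logical), \code{orig_dim} (c(H, W)) and \code{image_id}.
#' @export
preprocess_image <- function(image, cfg = ma_config()) {
  green <- extract_green(image)
  fov <- extract_fov(green)
  enh <- enhance(green, fov, cfg)
  S <- cfg$working_resolution
  out <- resize_working(enh, S)
  # nearest-neighbour resize of the mask via the same centre alignment
  ri <- pmin(pmax(round((seq_len(S) - 0.5) * nrow(fov) / S + 0.5), 1L),
             nrow(fov))
  ci <- pmin(pmax(round((seq_len(S) - 0.5) * ncol(fov) / S + 0.5), 1L),
             ncol(fov))
  fov_s <- fov[ri, ci, drop = FALSE]
  out[!fov_s] <- 0
  list(image = pmin(pmax(out, 0), 1), fov = fov_s,
       orig_dim = dim(green), image_id = image$image_id)
}
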