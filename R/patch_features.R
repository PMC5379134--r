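# Per-candidate 11x11 patch extraction and the eight-channel feature
# representation used by the fusion dictionary (F1 raw, F2 equalized,
# F3/F4 Canny edges, F5 close, F6 open, F7 gradient, F8 wavelet-denoised).

# Half-sample symmetric index reflection (edge duplicated).
reflect_index <- function(i, n) {
  i <- ifelse(i < 1L, 1L - i, i)
  i <- ifelse(i > n, 2L * n + 1L - i, i)
  pmin(pmax(i, 1L), n)
}

l2_normalize <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < 1e-12) v else v / n
}

#' Extract a square patch centred on a pixel
#'
#' Cuts the \code{size} x \code{size} window around \code{center}
#' (1-based row, col), reflection-padding where the window leaves the
#' image, and flattens it to a unit l2-norm column vector.
#'
#' @param image H x W numeric matrix.
#' @param center Integer (row, col), 1-based, inside the image.
#' @param size Odd window side (default 11).
#' @return List of class \code{"ma_patch"}: \code{window} (size x size),
#'   \code{center}, \code{vector} (length size^2, unit norm unless the
#'   window is all-zero).
#' @export
extract_patch <- function(image, center, size = 11L) {
  H <- nrow(image); W <- ncol(image)
  r0 <- as.integer(center[1]); c0 <- as.integer(center[2])
  if (r0 < 1L || r0 > H || c0 < 1L || c0 > W)
    stop("patch center outside image")
  h <- (size - 1L) %/% 2L
  ri <- reflect_index(r0 + (-h:h), H)
  ci <- reflect_index(c0 + (-h:h), W)
  win <- image[ri, ci, drop = FALSE]
  structure(list(window = win, center = c(r0, c0),
                 vector = l2_normalize(as.vector(win))),
            class = "ma_patch")
}

# ---- individual feature channels ---------------------------------------

# Global 256-bin histogram equalization of a [0,1] window.
hist_equalize <- function(win) {
  b <- pmin(pmax(floor(win * 255), 0), 255)
  cdf <- cumsum(tabulate(as.vector(b) + 1L, nbins = 256L))
  matrix(cdf[b + 1L] / length(win), nrow(win), ncol(win))
}

# Erosion / dilation with the radius-1 disc (3x3 cross), replicate border.
cross_morph <- function(win, op) {
  H <- nrow(win); W <- ncol(win)
  pad <- win[reflect_index(0:(H + 1L), H), reflect_index(0:(W + 1L), W)]
  f <- if (op == "min") pmin else pmax
  f(pad[2:(H + 1L), 2:(W + 1L)],
    pad[1:H, 2:(W + 1L)], pad[3:(H + 2L), 2:(W + 1L)],
    pad[2:(H + 1L), 1:W], pad[2:(H + 1L), 3:(W + 2L)])
}

morph_open <- function(win) cross_morph(cross_morph(win, "min"), "max")
morph_close <- function(win) cross_morph(cross_morph(win, "max"), "min")

# Sobel gradients, replicate border.
sobel_xy <- function(win) {
  kx <- matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3L, 3L, byrow = TRUE)
  list(gx = conv2_reflect(win, kx), gy = conv2_reflect(win, t(kx)))
}

sobel_magnitude <- function(win) {
  g <- sobel_xy(win)
  sqrt(g$gx^2 + g$gy^2)
}

# Compact Canny edge detector: Gaussian smoothing (sigma 1), Sobel
# gradient, 4-direction non-maximum suppression, hysteresis with
# thresholds at fixed fractions of the gradient-magnitude range.
canny_edges <- function(win, lo_frac = 0.4, hi_frac = 0.8) {
  H <- nrow(win); W <- ncol(win)
  sm <- conv2_reflect(win, gaussian_kernel(1, 2L))
  g <- sobel_xy(sm)
  mag <- sqrt(g$gx^2 + g$gy^2)
  mmax <- max(mag)
  if (mmax < 1e-12) return(matrix(0, H, W))
  ang <- atan2(g$gy, g$gx)                # gy along rows, gx along cols
  sector <- (round(ang / (pi / 4)) %% 4L) # 0:E-W 1:NE-SW 2:N-S 3:NW-SE
  off <- list(c(0L, 1L), c(1L, 1L), c(1L, 0L), c(1L, -1L))
  at <- function(r, c) {
    v <- mag[cbind(as.vector(pmin(pmax(r, 1L), H)),
                   as.vector(pmin(pmax(c, 1L), W)))]
    matrix(v, H, W)
  }
  rr <- row(mag); cc <- col(mag)
  nms <- matrix(0, H, W)
  for (s in 0:3) {
    d <- off[[s + 1L]]
    sel <- sector == s
    keep <- mag >= at(rr + d[1], cc + d[2]) &
            mag >= at(rr - d[1], cc - d[2])
    nms[sel & keep] <- mag[sel & keep]
  }
  hi <- hi_frac * mmax; lo <- lo_frac * mmax
  strong <- nms >= hi
  weak <- nms >= lo
  if (!any(strong)) return(matrix(0, H, W))
  # keep weak pixels 8-connected to a strong one
  out <- matrix(FALSE, H, W)
  for (px in label_components8(weak)) {
    if (any(strong[px])) out[px] <- TRUE
  }
  out + 0
}

# Daubechies-2 (4-tap) periodized orthonormal analysis matrix, n even.
db2_matrix <- function(n) {
  s3 <- sqrt(3)
  h <- c(1 + s3, 3 + s3, 3 - s3, 1 - s3) / (4 * sqrt(2))
  g <- c(h[4], -h[3], h[2], -h[1])
  Wm <- matrix(0, n, n)
  for (i in seq_len(n %/% 2L)) {
    pos <- ((2L * (i - 1L) + 0:3) %% n) + 1L
    Wm[i, pos] <- Wm[i, pos] + h
    Wm[n %/% 2L + i, pos] <- Wm[n %/% 2L + i, pos] + g
  }
  Wm
}

# Single-level db2 wavelet denoising: soft threshold on detail
# coefficients at the universal threshold, noise scale from the MAD of
# the diagonal detail band. Odd windows are edge-padded to even length.
wavelet_denoise <- function(win) {
  H <- nrow(win); W <- ncol(win)
  n1 <- H + H %% 2L; n2 <- W + W %% 2L
  X <- win[c(seq_len(H), rep(H, n1 - H)), c(seq_len(W), rep(W, n2 - W))]
  Wr <- db2_matrix(n1); Wc <- db2_matrix(n2)
  C <- Wr %*% X %*% t(Wc)
  a1 <- seq_len(n1 %/% 2L); a2 <- seq_len(n2 %/% 2L)
  detail <- matrix(TRUE, n1, n2)
  detail[a1, a2] <- FALSE
  hh <- C[-a1, -a2]
  sigma <- stats::median(abs(hh)) / 0.6745
  thr <- sigma * sqrt(2 * log(n1 * n2))
  Cd <- C
  Cd[detail] <- sign(C[detail]) * pmax(abs(C[detail]) - thr, 0)
  Y <- t(Wr) %*% Cd %*% Wc
  Y[seq_len(H), seq_len(W), drop = FALSE]
}

#' Eight-feature representation of a candidate patch
#'
#' Computes the eight per-patch feature images — F1 raw grayscale, F2
#' histogram-equalized, F3 Canny edges of F1, F4 Canny edges of F2, F5
#' morphological closing, F6 morphological opening, F7 Sobel gradient
#' magnitude, F8 wavelet-denoised — each flattened and l2-normalized into
#' one column of a p x K matrix (p = size^2, K = 8). All-zero channels
#' (e.g. edges of a constant window) are left as zero columns.
#'
#' @param window size x size numeric matrix in [0,1].
#' @return p x K numeric matrix, columns named F1..F8.
#' @export
compute_features <- function(window) {
  feats <- list(
    F1 = window,
    F2 = hist_equalize(window),
    F3 = canny_edges(window),
    F4 = canny_edges(hist_equalize(window)),
    F5 = morph_close(window),
    F6 = morph_open(window),
    F7 = sobel_magnitude(window),
    F8 = wavelet_denoise(window)
  )
  out <- vapply(feats, function(f) l2_normalize(as.vector(f)),
                numeric(length(window)))
  colnames(out) <- names(feats)
  out
}

#' Feature stack of the patch centred on a pixel
#' @inheritParams extract_patch
#' @return p x K feature matrix (see \code{compute_features}).
#' @export
patch_feature_stack <- function(image, center, size = 11L) {
  compute_features(extract_patch(image, center, size)$window)
}
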