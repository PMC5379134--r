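# Detection scoring: one-to-one centre matching, sensitivity / FPPI /
# precision, and FROC readout at fixed FPPI points.

#' Match detections against ground-truth centres
#'
#' Greedy nearest-first one-to-one matching per image: the closest
#' unmatched detection/ground-truth pair within \code{radius} pixels is
#' matched first, repeatedly. Leftover detections are false positives,
#' leftover ground truths false negatives.
#'
#' @param dets Detection data.frame (image_id, x, y, ...); typically only
#'   rows labeled "MA".
#' @param gt Annotation data.frame (image_id, x, y).
#' @param radius Match radius in pixels (Euclidean).
#' @param n_images Number of images evaluated; defaults to the images
#'   named in either table (pass the true count when some images have
#'   neither detections nor lesions).
#' @return List of class \code{"ma_match"}: TP, FP, FN, pairs
#'   (data.frame of matched coordinates and distances), n_images.
#' @export
match_detections <- function(dets, gt, radius = 5,
                             n_images = length(unique(c(dets$image_id,
                                                        gt$image_id)))) {
  if (radius < 0) stop("match radius must be nonnegative")
  TP <- 0L; FP <- 0L; FN <- 0L
  pairs <- list()
  for (id in unique(c(dets$image_id, gt$image_id))) {
    d <- dets[dets$image_id == id, , drop = FALSE]
    g <- gt[gt$image_id == id, , drop = FALSE]
    if (nrow(d) == 0L) { FN <- FN + nrow(g); next }
    if (nrow(g) == 0L) { FP <- FP + nrow(d); next }
    D <- outer(d$x, g$x, `-`)^2 + outer(d$y, g$y, `-`)^2
    D <- sqrt(D)
    d_free <- rep(TRUE, nrow(d)); g_free <- rep(TRUE, nrow(g))
    repeat {
      D_open <- D
      D_open[!d_free, ] <- Inf
      D_open[, !g_free] <- Inf
      best <- which.min(D_open)
      if (length(best) == 0L || D_open[best] > radius) break
      di <- (best - 1L) %% nrow(d) + 1L
      gi <- (best - 1L) %/% nrow(d) + 1L
      d_free[di] <- FALSE; g_free[gi] <- FALSE
      TP <- TP + 1L
      pairs[[length(pairs) + 1L]] <- data.frame(
        image_id = id, det_x = d$x[di], det_y = d$y[di],
        gt_x = g$x[gi], gt_y = g$y[gi], dist = D[di, gi])
    }
    FP <- FP + sum(d_free)
    FN <- FN + sum(g_free)
  }
  structure(list(TP = TP, FP = FP, FN = FN,
                 pairs = if (length(pairs)) do.call(rbind, pairs)
                         else NULL,
                 n_images = n_images),
            class = "ma_match")
}

#' Detection metrics
#'
#' \code{sensitivity} = TP / (TP + FN); \code{fppi} = FP / number of
#' images; \code{precision} = TP / (TP + FP). Conventions for empty
#' denominators: sensitivity is 1 when there is neither ground truth nor
#' any detection and 0 when there are detections but no ground truth;
#' precision is NaN (with a warning) when there are no detections.
#'
#' @param match An \code{"ma_match"}.
#' @return A single number.
#' @export
sensitivity <- function(match) {
  if (match$TP + match$FN == 0L)
    return(if (match$FP == 0L) 1 else 0)
  match$TP / (match$TP + match$FN)
}

#' @rdname sensitivity
#' @export
fppi <- function(match) {
  if (match$n_images <= 0L) stop("n_images must be positive")
  match$FP / match$n_images
}

#' @rdname sensitivity
#' @export
precision <- function(match) {
  if (match$TP + match$FP == 0L) {
    warning("no detections: precision undefined")
    return(NaN)
  }
  match$TP / (match$TP + match$FP)
}

#' @export
print.ma_match <- function(x, ...) {
  cat(sprintf("detection match over %d image(s): TP %d, FP %d, FN %d\n",
              x$n_images, x$TP, x$FP, x$FN))
  cat(sprintf("  sensitivity %.4f, FPPI %.3f\n",
              sensitivity(x), fppi(x)))
  invisible(x)
}

#' FROC curve and fixed-FPPI sensitivity readout
#'
#' Builds the free-response ROC curve from per-threshold match results,
#' reads the sensitivity at fixed FPPI points by linear interpolation
#' between bracketing measured points (clamped to the nearest endpoint
#' outside the measured range), and averages the readouts.
#'
#' @param matches List of \code{"ma_match"} results, one per operating
#'   point (e.g. one per candidate threshold).
#' @param thresholds Optional vector labelling the operating points.
#' @param fppi_points FPPI values at which sensitivity is read out
#'   (default 1, 2, 4, 8, 12, 16, 20).
#' @return List of class \code{"ma_froc"}: \code{points} (data.frame
#'   threshold, sensitivity, fppi sorted by fppi), \code{at_fppi} (named
#'   sensitivity vector), \code{average} (their unweighted mean).
#' @export
froc_curve <- function(matches, thresholds = seq_along(matches),
                       fppi_points = c(1, 2, 4, 8, 12, 16, 20)) {
  stopifnot(length(matches) >= 2L)
  pts <- data.frame(
    threshold = thresholds,
    sensitivity = vapply(matches, sensitivity, 0),
    fppi = vapply(matches, fppi, 0))
  pts <- pts[order(pts$fppi, pts$sensitivity), ]
  # collapse duplicate FPPI values to their best sensitivity
  uf <- tapply(pts$sensitivity, pts$fppi, max)
  xs <- as.numeric(names(uf)); ys <- as.numeric(uf)
  at <- if (length(xs) >= 2L) {
    stats::approx(xs, ys, xout = fppi_points, rule = 2)$y
  } else {
    rep(ys[1], length(fppi_points))
  }
  names(at) <- fppi_points
  structure(list(points = pts, at_fppi = at, average = mean(at)),
            class = "ma_froc")
}

#' @export
print.ma_froc <- function(x, ...) {
  cat("FROC readout (sensitivity at fixed FPPI):\n")
  print(round(x$at_fppi, 4))
  cat(sprintf("  average sensitivity over %d points: %.4f\n",
              length(x$at_fppi), x$average))
  invisible(x)
}

#' Plot an FROC curve
#' @param x An \code{"ma_froc"}.
#' @param ... Passed to \code{plot}.
#' @export
plot.ma_froc <- function(x, ...) {
  graphics::plot(x$points$fppi, x$points$sensitivity, type = "b",
                 xlab = "false positives per image",
                 ylab = "sensitivity", ylim = c(0, 1), ...)
  graphics::points(as.numeric(names(x$at_fppi)), x$at_fppi, pch = 4)
}
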