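# Synthetic fundus scenes: circular field of view, smooth bright
# background, dark curvilinear vessels, small dark Gaussian
# microaneurysms with ground-truth centres, plus distractors (bright
# spots, over-sized dark blobs). Not anatomically realistic -- built to
# exercise every pipeline stage with known truth.

#' Parameters of the synthetic fundus generator
#'
#' @param image_size Square image side in pixels.
#' @param fov_radius_frac FOV radius as a fraction of the image side.
#' @param bg_base Mean green-channel background intensity inside the FOV.
#' @param bg_gradient_amp Amplitude of the smooth low-frequency
#'   background modulation.
#' @param n_vessels Number of vessel random walks.
#' @param vessel_width Range (min, max) of vessel widths in pixels.
#' @param vessel_darkness Intensity drop on the vessel centreline.
#' @param n_ma Microaneurysms per image.
#' @param ma_sigma Range of MA Gaussian scales (pixels); matches the
#'   correlation filter's scale grid.
#' @param ma_contrast Range of MA centre intensity drops.
#' @param n_bright Bright-spot distractors (test polarity handling).
#' @param n_large_dark Large dark blob distractors (area well above the
#'   120-pixel cap; test the size filter).
#' @param noise_sd Additive Gaussian pixel noise, intensity units.
#' @param min_separation Minimum pairwise distance between MA centres
#'   (default 2 x 11-pixel patch size).
#' @param seed RNG seed for the scene.
#' @return List of class \code{"sim_params"}.
#' @export
simulation_params <- function(image_size = 850L,
                              fov_radius_frac = 0.47,
                              bg_base = 0.55,
                              bg_gradient_amp = 0.08,
                              n_vessels = 8L,
                              vessel_width = c(2, 5),
                              vessel_darkness = 0.25,
                              n_ma = 10L,
                              ma_sigma = c(1.1, 1.5),
                              ma_contrast = c(0.15, 0.3),
                              n_bright = 2L,
                              n_large_dark = 2L,
                              noise_sd = 0.01,
                              min_separation = 22,
                              seed = 1L) {
  p <- list(image_size = as.integer(image_size),
            fov_radius_frac = fov_radius_frac, bg_base = bg_base,
            bg_gradient_amp = bg_gradient_amp,
            n_vessels = as.integer(n_vessels),
            vessel_width = vessel_width,
            vessel_darkness = vessel_darkness,
            n_ma = as.integer(n_ma), ma_sigma = ma_sigma,
            ma_contrast = ma_contrast,
            n_bright = as.integer(n_bright),
            n_large_dark = as.integer(n_large_dark),
            noise_sd = noise_sd, min_separation = min_separation,
            seed = as.integer(seed))
  stopifnot(p$image_size >= 64L, p$fov_radius_frac > 0,
            p$fov_radius_frac <= 0.5, all(p$ma_contrast > 0),
            p$n_ma >= 0L)
  class(p) <- "sim_params"
  p
}

# Stamp a radially symmetric profile centred at (r0, c0) into g.
# plateau > 1 saturates the Gaussian into a flat-topped disk (used for
# oversized dark distractors, whose grown area must exceed the size cap).
stamp_blob <- function(g, r0, c0, sigma, amp, extent = ceiling(4 * sigma),
                       plateau = 1) {
  S <- nrow(g)
  ri <- max(1L, round(r0) - extent):min(S, round(r0) + extent)
  ci <- max(1L, round(c0) - extent):min(S, round(c0) + extent)
  d2 <- outer((ri - r0)^2, (ci - c0)^2, `+`)
  g[ri, ci] <- g[ri, ci] + amp * pmin(1, plateau * exp(-d2 / (2 * sigma^2)))
  g
}

# Random-walk vessel path stamped as a thick dark curve; returns the
# updated intensity image and the boolean centre mask.
stamp_vessel <- function(g, vmask, start, dir0, width, darkness) {
  S <- nrow(g)
  pos <- start
  ang <- dir0
  half <- max(1L, round(width / 2))
  steps <- 0L
  while (steps < 2L * S) {
    r <- round(pos[1]); c <- round(pos[2])
    if (r < 1L || r > S || c < 1L || c > S) break
    ri <- max(1L, r - half):min(S, r + half)
    ci <- max(1L, c - half):min(S, c + half)
    d2 <- outer((ri - pos[1])^2, (ci - pos[2])^2, `+`)
    prof <- exp(-d2 / (2 * (width / 2.355)^2))   # FWHM = width
    g[ri, ci] <- g[ri, ci] - darkness * prof
    vmask[ri, ci] <- vmask[ri, ci] | (d2 <= (width / 2)^2 + 0.5)
    ang <- ang + stats::rnorm(1L, 0, 0.15)
    pos <- pos + 1.5 * c(sin(ang), cos(ang))
    steps <- steps + 1L
  }
  list(g = g, vmask = vmask)
}

# Rejection-sample points inside the FOV margin, off the (dilated)
# vessel mask, with pairwise separation; errors out after bounded tries.
sample_clear_points <- function(n, S, fov_r, centre, clear, min_sep,
                                margin = 20, max_tries = 4000L) {
  pts <- matrix(numeric(0), 0L, 2L)
  tries <- 0L
  while (nrow(pts) < n) {
    tries <- tries + 1L
    if (tries > max_tries)
      stop("could not place all lesions; reduce n_ma or distractors")
    ang <- stats::runif(1L, 0, 2 * pi)
    rad <- sqrt(stats::runif(1L)) * (fov_r - margin)
    r <- centre[1] + rad * sin(ang)
    c <- centre[2] + rad * cos(ang)
    ri <- round(r); ci <- round(c)
    if (clear[ri, ci]) next
    if (nrow(pts) > 0L &&
        min(sqrt((pts[, 1] - r)^2 + (pts[, 2] - c)^2)) < min_sep) next
    pts <- rbind(pts, c(r, c))
  }
  pts
}

#' Generate a synthetic fundus scene
#'
#' Builds the green-channel intensity field (bright FOV disk, smooth
#' background, dark vessels, implanted Gaussian microaneurysms,
#' distractors, pixel noise), assembles an RGB fundus image with the
#' lesion/vessel structure dominant in the green plane, and returns the
#' ground truth alongside.
#'
#' @param params A \code{"sim_params"} object.
#' @return List of class \code{"synthetic_scene"}: \code{image}
#'   (\code{"fundus_image"}), \code{green} (clean working-scale green
#'   matrix), \code{vessel_mask} (logical), \code{annotations}
#'   (data.frame image_id, x, y; 0-based), \code{distractors}
#'   (data.frame with type, x, y), \code{params}.
#' @export
generate_scene <- function(params = simulation_params()) {
  stopifnot(inherits(params, "sim_params"))
  set.seed(params$seed)
  S <- params$image_size
  centre <- c(S, S) / 2 + 0.5
  fov_r <- params$fov_radius_frac * S
  rr <- matrix(seq_len(S), S, S)
  cc <- t(rr)
  d2c <- (rr - centre[1])^2 + (cc - centre[2])^2
  fov <- d2c <= fov_r^2

  # smooth background: base + a few low-frequency cosine modes
  g <- matrix(params$bg_base, S, S)
  for (k in 1:3) {
    fr <- stats::runif(2L, 0.5, 1.5) / S
    ph <- stats::runif(2L, 0, 2 * pi)
    g <- g + (params$bg_gradient_amp / 3) *
      cos(2 * pi * fr[1] * rr + ph[1]) * cos(2 * pi * fr[2] * cc + ph[2])
  }

  # vessels: random walks entering from the FOV rim, aimed inward
  vmask <- matrix(FALSE, S, S)
  for (v in seq_len(params$n_vessels)) {
    a <- stats::runif(1L, 0, 2 * pi)
    start <- centre + (fov_r - 2) * c(sin(a), cos(a))
    dir0 <- a + pi + stats::rnorm(1L, 0, 0.4)  # roughly inward
    w <- stats::runif(1L, params$vessel_width[1], params$vessel_width[2])
    sv <- stamp_vessel(g, vmask, start, dir0, w, params$vessel_darkness)
    g <- sv$g; vmask <- sv$vmask
  }

  # keep lesions off vessels (with clearance) and inside the FOV margin
  clear <- dilate_mask_cheb(vmask, 8L)

  distractors <- data.frame(type = character(), x = integer(),
                            y = integer(), stringsAsFactors = FALSE)
  ma_xy <- NULL
  if (params$n_ma > 0L) {
    ma_xy <- sample_clear_points(params$n_ma, S, fov_r, centre, clear,
                                 params$min_separation)
    for (i in seq_len(params$n_ma)) {
      sg <- stats::runif(1L, params$ma_sigma[1], params$ma_sigma[2])
      ct <- stats::runif(1L, params$ma_contrast[1], params$ma_contrast[2])
      g <- stamp_blob(g, ma_xy[i, 1], ma_xy[i, 2], sg, -ct, extent = 8L)
    }
  }
  occupied <- clear
  if (!is.null(ma_xy)) {
    for (i in seq_len(nrow(ma_xy)))
      occupied[max(1, round(ma_xy[i, 1]) - 25):min(S, round(ma_xy[i, 1]) + 25),
               max(1, round(ma_xy[i, 2]) - 25):min(S, round(ma_xy[i, 2]) + 25)] <- TRUE
  }
  if (params$n_bright > 0L) {
    bx <- sample_clear_points(params$n_bright, S, fov_r, centre, occupied,
                              params$min_separation)
    for (i in seq_len(params$n_bright)) {
      g <- stamp_blob(g, bx[i, 1], bx[i, 2], 2.5, +0.2, extent = 10L)
      distractors <- rbind(distractors, data.frame(
        type = "bright", x = round(bx[i, 2]) - 1L, y = round(bx[i, 1]) - 1L))
    }
  }
  if (params$n_large_dark > 0L) {
    dx <- sample_clear_points(params$n_large_dark, S, fov_r, centre,
                              occupied, 60)
    for (i in seq_len(params$n_large_dark)) {
      # flat-cored dark disk, ~300 px below the growing threshold: larger
      # than any MA, so only the size filter can remove it
      g <- stamp_blob(g, dx[i, 1], dx[i, 2], 6, -0.25, extent = 20L,
                      plateau = 2)
      distractors <- rbind(distractors, data.frame(
        type = "large_dark", x = round(dx[i, 2]) - 1L,
        y = round(dx[i, 1]) - 1L))
    }
  }

  g <- g + matrix(stats::rnorm(S * S, 0, params$noise_sd), S, S)
  g[!fov] <- 0.02
  g <- pmin(pmax(g, 0), 1)

  px <- array(0L, dim = c(S, S, 3L))
  px[, , 1] <- as.integer(round(pmin(0.6 * g + 0.35, 1) * 255))
  px[, , 2] <- as.integer(round(g * 255))
  px[, , 3] <- as.integer(round(0.3 * g * 255))
  px[, , 1][!fov] <- 5L; px[, , 3][!fov] <- 5L
  id <- sprintf("synthetic_%04d", params$seed)
  ann <- if (is.null(ma_xy) || nrow(ma_xy) == 0L) {
    data.frame(image_id = character(), x = integer(), y = integer())
  } else {
    data.frame(image_id = id, x = as.integer(round(ma_xy[, 2]) - 1L),
               y = as.integer(round(ma_xy[, 1]) - 1L))
  }
  structure(list(image = fundus_image(px, id), green = g,
                 vessel_mask = vmask, annotations = ann,
                 distractors = distractors, params = params),
            class = "synthetic_scene")
}

# Chebyshev dilation of a logical mask (separable running max).
dilate_mask_cheb <- function(mask, by) {
  H <- nrow(mask); W <- ncol(mask)
  out <- mask
  for (d in seq_len(by)) {
    out[1:(H - 1), ] <- out[1:(H - 1), ] | out[2:H, ]
    out[2:H, ] <- out[2:H, ] | out[1:(H - 1), ]
  }
  for (d in seq_len(by)) {
    out[, 1:(W - 1)] <- out[, 1:(W - 1)] | out[, 2:W]
    out[, 2:W] <- out[, 2:W] | out[, 1:(W - 1)]
  }
  out
}

#' Write a synthetic scene to disk
#' @param scene A \code{"synthetic_scene"}.
#' @param dir Output directory (created if needed).
#' @return Named character vector of the files written, invisibly.
#' @export
write_scene <- function(scene, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  id <- scene$image$image_id
  img <- file.path(dir, paste0(id, ".png"))
  msk <- file.path(dir, paste0(id, "_vessels.png"))
  ann <- file.path(dir, paste0(id, "_annotations.csv"))
  prm <- file.path(dir, paste0(id, "_params.json"))
  write_fundus_image(scene$image, img)
  write_fundus_image(scene$vessel_mask + 0, msk)
  write_annotations(scene$annotations, ann)
  jsonlite::write_json(unclass(scene$params), prm, auto_unbox = TRUE,
                       digits = NA)
  invisible(c(image = img, vessels = msk, annotations = ann, params = prm))
}

#' Generate a labeled patch training set
#'
#' Cuts microaneurysm patches at implanted centres and non-MA patches at
#' random off-MA, off-vessel FOV locations plus distractor centres, from
#' as many synthetic scenes (CLAHE-enhanced, as the detection pipeline
#' sees them) as needed for balanced classes.
#'
#' @param params A \code{"sim_params"}; its seed starts the scene
#'   sequence, one scene per consecutive seed.
#' @param n_per_class Patches per class.
#' @param cfg An \code{ma_config} (patch size, CLAHE settings).
#' @return List of class \code{"ma_patchset"}: \code{stacks} (list of
#'   p x K feature matrices), \code{labels} (1 = MA, 2 = non-MA),
#'   \code{centers} (data.frame image_id, x, y, label).
#' @export
generate_patch_dataset <- function(params = simulation_params(),
                                   n_per_class = 100L,
                                   cfg = ma_config()) {
  stopifnot(n_per_class >= 1L)
  stacks <- list(); labels <- integer(0)
  centers <- list()
  n_ma_have <- 0L; n_bg_have <- 0L
  scene_seed <- params$seed
  guard <- 0L
  while (n_ma_have < n_per_class || n_bg_have < n_per_class) {
    guard <- guard + 1L
    if (guard > 20L + 4L * ceiling(n_per_class / max(params$n_ma, 1L)))
      stop("insufficient valid patch locations; increase n_ma or scenes")
    sp <- params; sp$seed <- scene_seed
    scene <- generate_scene(sp)
    scene_seed <- scene_seed + 1L
    S <- params$image_size
    fov <- (matrix(seq_len(S), S, S) - (S / 2 + 0.5))^2 +
           (t(matrix(seq_len(S), S, S)) - (S / 2 + 0.5))^2 <=
           (params$fov_radius_frac * S)^2
    enh <- enhance(scene$green, fov, cfg)
    id <- scene$image$image_id
    # MA patches at implanted centres
    for (i in seq_len(nrow(scene$annotations))) {
      if (n_ma_have >= n_per_class) break
      r <- scene$annotations$y[i] + 1L; c <- scene$annotations$x[i] + 1L
      stacks[[length(stacks) + 1L]] <-
        patch_feature_stack(enh, c(r, c), cfg$patch_size)
      labels <- c(labels, 1L)
      centers[[length(centers) + 1L]] <-
        data.frame(image_id = id, x = c - 1L, y = r - 1L, label = "MA")
      n_ma_have <- n_ma_have + 1L
    }
    # non-MA patches: distractor centres, then clear background spots
    keep_out <- dilate_mask_cheb(scene$vessel_mask, 6L)
    for (i in seq_len(nrow(scene$annotations))) {
      r <- scene$annotations$y[i] + 1L; c <- scene$annotations$x[i] + 1L
      keep_out[max(1, r - 15):min(S, r + 15),
               max(1, c - 15):min(S, c + 15)] <- TRUE
    }
    bg_pts <- rbind(
      as.matrix(data.frame(r = scene$distractors$y + 1L,
                           c = scene$distractors$x + 1L)),
      sample_clear_points(max(params$n_ma, 4L), S,
                          params$fov_radius_frac * S,
                          c(S, S) / 2 + 0.5, keep_out, 15))
    for (i in seq_len(nrow(bg_pts))) {
      if (n_bg_have >= n_per_class) break
      r <- round(bg_pts[i, 1]); c <- round(bg_pts[i, 2])
      stacks[[length(stacks) + 1L]] <-
        patch_feature_stack(enh, c(r, c), cfg$patch_size)
      labels <- c(labels, 2L)
      centers[[length(centers) + 1L]] <-
        data.frame(image_id = id, x = c - 1L, y = r - 1L, label = "non-MA")
      n_bg_have <- n_bg_have + 1L
    }
  }
  structure(list(stacks = stacks, labels = labels,
                 centers = do.call(rbind, centers)),
            class = "ma_patchset")
}
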