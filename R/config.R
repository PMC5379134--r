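#' Pipeline configuration
#'
#' Builds the configuration object consumed by every stage of the
#' microaneurysm detection pipeline. Defaults follow the published study
#' conditions where those are stated (Gaussian scale grid, candidate
#' threshold, region-growing \code{beta}, 120-pixel size cap, 11x11
#' patches, working resolution 850) and documented package choices
#' elsewhere.
#'
#' @param sigma_min,sigma_max,sigma_step Gaussian template scale grid for
#'   multiscale correlation filtering (pixels at working resolution).
#' @param window_half Half-width of the square correlation window; the
#'   window is \code{(2*window_half+1)^2} pixels.
#' @param correlation_threshold Threshold on the multiscale correlation
#'   response used to seed candidates, in (0,1).
#' @param beta Region-growing dynamics weight in [0,1]: the adaptive
#'   threshold is \code{t = I_darkest - beta*(I_darkest - I_bg)}.
#' @param max_region_area Regions larger than this many pixels are
#'   discarded as too large to be a microaneurysm.
#' @param bg_window Side of the square mean filter estimating the local
#'   background intensity \code{I_bg} (odd).
#' @param patch_size Side of the square candidate patch (odd).
#' @param n_features Number of per-patch feature channels K.
#' @param fused_dim Number of Fisher-fused channels M (\code{<= n_features}).
#' @param atoms_per_subdictionary Atoms d in each K-SVD subdictionary.
#' @param omp_sparsity Maximum atoms T used by orthogonal matching pursuit.
#' @param ksvd_iterations Alternations of sparse coding and atom updates.
#' @param working_resolution Square working image side after bicubic resize.
#' @param match_radius Euclidean distance (pixels at working resolution)
#'   within which a detection matches a ground-truth centre.
#' @param clahe_tiles,clahe_clip CLAHE tile grid (per side) and clip limit
#'   on the [0,1] intensity scale.
#' @param vessel_disc_radius Disc radius of the bottom-hat used by the
#'   built-in vessel heuristic (pixels; larger than the MA scale).
#' @param vessel_threshold Bottom-hat response above which a pixel is
#'   provisionally vascular.
#' @param rng_seed Integer seed from which all stage seeds are derived.
#' @return An object of class \code{"ma_config"}: a validated named list.
#' @examples
#' cfg <- ma_config()
#' cfg$correlation_threshold
#' @export
ma_config <- function(sigma_min = 1.1, sigma_max = 1.5, sigma_step = 0.1,
                      window_half = 4L,
                      correlation_threshold = 0.6,
                      beta = 0.5,
                      max_region_area = 120L,
                      bg_window = 25L,
                      patch_size = 11L,
                      n_features = 8L,
                      fused_dim = 3L,
                      atoms_per_subdictionary = 128L,
                      omp_sparsity = 5L,
                      ksvd_iterations = 15L,
                      working_resolution = 850L,
                      match_radius = 5,
                      clahe_tiles = 8L,
                      clahe_clip = 0.01,
                      vessel_disc_radius = 6L,
                      vessel_threshold = 0.05,
                      rng_seed = 1L) {
  cfg <- list(
    sigma_min = sigma_min, sigma_max = sigma_max, sigma_step = sigma_step,
    window_half = as.integer(window_half),
    correlation_threshold = correlation_threshold,
    beta = beta,
    max_region_area = as.integer(max_region_area),
    bg_window = as.integer(bg_window),
    patch_size = as.integer(patch_size),
    n_features = as.integer(n_features),
    fused_dim = as.integer(fused_dim),
    atoms_per_subdictionary = as.integer(atoms_per_subdictionary),
    omp_sparsity = as.integer(omp_sparsity),
    ksvd_iterations = as.integer(ksvd_iterations),
    working_resolution = as.integer(working_resolution),
    match_radius = match_radius,
    clahe_tiles = as.integer(clahe_tiles),
    clahe_clip = clahe_clip,
    vessel_disc_radius = as.integer(vessel_disc_radius),
    vessel_threshold = vessel_threshold,
    rng_seed = as.integer(rng_seed)
  )
  class(cfg) <- "ma_config"
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  stopifnot(
    cfg$sigma_min > 0, cfg$sigma_max >= cfg$sigma_min, cfg$sigma_step > 0,
    cfg$window_half >= 1L,
    cfg$correlation_threshold > 0, cfg$correlation_threshold < 1,
    cfg$beta >= 0, cfg$beta <= 1,
    cfg$max_region_area >= 1L,
    cfg$bg_window %% 2L == 1L,
    cfg$patch_size %% 2L == 1L,
    cfg$fused_dim >= 1L, cfg$fused_dim <= cfg$n_features,
    cfg$omp_sparsity >= 1L,
    cfg$omp_sparsity <= cfg$atoms_per_subdictionary,
    cfg$working_resolution >= 64L,
    cfg$match_radius >= 0
  )
  invisible(cfg)
}

#' Sigma grid of a configuration
#' @param cfg An \code{ma_config}.
#' @return Numeric vector of Gaussian template scales, strictly increasing.
#' @export
sigma_grid <- function(cfg) {
  s <- seq(cfg$sigma_min, cfg$sigma_max, by = cfg$sigma_step)
  round(s, 10)
}

#' Resolve a configuration from defaults, a file, and overrides
#'
#' Precedence is override > file > built-in default, matching the
#' command-line contract (flag > config file > default).
#'
#' @param file Optional path to a JSON file of configuration fields.
#' @param overrides Named list of fields taking highest precedence.
#' @return An \code{ma_config}.
#' @export
resolve_config <- function(file = NULL, overrides = list()) {
  fields <- list()
  if (!is.null(file)) {
    if (!file.exists(file)) stop("config file not found: ", file)
    fields <- jsonlite::fromJSON(file, simplifyVector = TRUE)
    fields <- fields[names(fields) %in% names(formals(ma_config))]
  }
  fields[names(overrides)] <- overrides
  do.call(ma_config, fields)
}

#' @export
print.ma_config <- function(x, ...) {
  cat("Microaneurysm pipeline configuration\n")
  cat(sprintf("  MSCF scales: %s (window %dx%d), threshold %.2f\n",
              paste(sigma_grid(x), collapse = ", "),
              2L * x$window_half + 1L, 2L * x$window_half + 1L,
              x$correlation_threshold))
  cat(sprintf("  region growing: beta %.2f, size cap %d px, bg window %d\n",
              x$beta, x$max_region_area, x$bg_window))
  cat(sprintf("  patches: %dx%d, K = %d features, M = %d fused\n",
              x$patch_size, x$patch_size, x$n_features, x$fused_dim))
  cat(sprintf("  dictionary: d = %d atoms, T = %d, %d K-SVD iterations\n",
              x$atoms_per_subdictionary, x$omp_sparsity, x$ksvd_iterations))
  cat(sprintf("  working resolution %d, match radius %.1f px, seed %d\n",
              x$working_resolution, x$match_radius, x$rng_seed))
  invisible(x)
}

# Deterministic per-stage seed derivation from the single pipeline seed.
# Keeps every stage's RNG stream independent of the others' draw counts.
stage_seed <- function(cfg_or_seed, stage) {
  seed <- if (inherits(cfg_or_seed, "ma_config")) cfg_or_seed$rng_seed
          else as.integer(cfg_or_seed)
  offs <- c(simulate = 101L, train = 211L, dict = 307L, patches = 401L,
            detect = 503L, misc = 601L)
  if (!stage %in% names(offs)) stop("unknown stage: ", stage)
  (seed * 1009L + offs[[stage]]) %% 2147483563L
}
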