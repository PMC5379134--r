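# MA / non-MA decision by accumulated per-channel sparse reconstruction
# error against the per-class subdictionaries.

#' Classify one feature stack
#'
#' Fuses the stack (\code{Y = X W}), sparse-codes each fused channel m
#' against every class's subdictionary \code{Q[[c]][[m]]}, and assigns the
#' class with the lowest reconstruction error accumulated over the M
#' channels. Ties go to class 1 (MA), favouring screening sensitivity.
#'
#' @param X p x K feature stack.
#' @param model A trained \code{"ma_model"}.
#' @return List with \code{label} (1 = MA, 2 = non-MA),
#'   \code{per_class_error} (length C) and \code{per_feature_errors}
#'   (C x M matrix).
#' @export
classify_stack <- function(X, model) {
  if (ncol(X) != nrow(model$W))
    stop(sprintf("stack has %d feature channels but model expects %d",
                 ncol(X), nrow(model$W)))
  Y <- fuse(X, model$W)
  M <- ncol(model$W)
  Tspar <- model$config$omp_sparsity
  pf <- matrix(0, 2L, M)
  for (c in 1:2) for (m in seq_len(M)) {
    pf[c, m] <- sparse_code(Y[, m], model$dicts[[c]][[m]], Tspar)$residual2
  }
  per_class <- rowSums(pf)
  label <- which.min(per_class)   # which.min takes the first on ties -> MA
  list(label = label, per_class_error = per_class, per_feature_errors = pf)
}

#' Predict MA / non-MA labels for feature stacks
#'
#' @param object A trained \code{"ma_model"}.
#' @param newdata A single p x K feature stack or a list of them.
#' @param ... Unused.
#' @return data.frame with one row per stack: \code{label} (integer),
#'   \code{class} ("MA"/"non-MA") and the per-class accumulated errors
#'   \code{error_ma}, \code{error_nonma}.
#' @export
predict.ma_model <- function(object, newdata, ...) {
  if (is.matrix(newdata)) newdata <- list(newdata)
  res <- lapply(newdata, classify_stack, model = object)
  data.frame(
    label = vapply(res, `[[`, 0L, "label"),
    class = object$class_names[vapply(res, `[[`, 0L, "label")],
    error_ma = vapply(res, function(r) r$per_class_error[1], 0),
    error_nonma = vapply(res, function(r) r$per_class_error[2], 0),
    stringsAsFactors = FALSE)
}

#' Detect microaneurysms in a fundus image
#'
#' Runs the full pipeline on one image: preprocessing, candidate
#' extraction, per-candidate feature stacks at the region centroid, and
#' dictionary classification. Every candidate appears in the result with
#' its predicted label; rows labeled "MA" are the detections. The score
#' column carries the candidate's peak multiscale correlation response.
#'
#' @param image A \code{"fundus_image"} (or a path readable by
#'   \code{read_fundus_image}).
#' @param model A trained \code{"ma_model"}.
#' @param cfg An \code{ma_config}; must agree with the model's patch
#'   size and feature counts.
#' @param vessels Optional H x W logical vessel mask at working
#'   resolution (otherwise the built-in heuristic is used).
#' @param threshold Candidate response threshold (defaults to the
#'   configured one); exposed so FROC curves can sweep it.
#' @return Detection data.frame: image_id, x, y (0-based, working
#'   resolution), score, label.
#' @export
detect_image <- function(image, model, cfg = model$config, vessels = NULL,
                         threshold = cfg$correlation_threshold) {
  for (f in c("patch_size", "n_features", "fused_dim")) {
    if (!identical(cfg[[f]], model$config[[f]]))
      stop("config/model mismatch in field: ", f)
  }
  if (is.character(image)) image <- read_fundus_image(image)
  pre <- preprocess_image(image, cfg)
  cands <- extract_candidates(pre, cfg, vessels = vessels,
                              threshold = threshold)
  if (length(cands) == 0L) return(empty_detections())
  stacks <- lapply(cands, function(r)
    patch_feature_stack(pre$image, r$centroid, cfg$patch_size))
  pred <- predict(model, stacks)
  data.frame(
    image_id = vapply(cands, `[[`, "", "image_id"),
    x = vapply(cands, function(r) as.integer(r$centroid[2] - 1L), 0L),
    y = vapply(cands, function(r) as.integer(r$centroid[1] - 1L), 0L),
    score = vapply(cands, `[[`, 0, "score"),
    label = pred$class,
    stringsAsFactors = FALSE)
}
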