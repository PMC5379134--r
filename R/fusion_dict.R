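# Fisher-criterion feature fusion and the multifeature dictionary model.
#
# Each training sample is a p x K feature stack (p = 121 pixels, K = 8
# feature channels). The K x M fusion matrix W maximizes the Fisher
# criterion tr(W' Sb W) / tr(W' Sw W) over the K feature channels;
# per-class, per-fused-channel subdictionaries are then learned by K-SVD
# on the fused data y_i = X_i W.

#' Between- and within-class scatter of feature stacks
#'
#' Scatter is taken over the K feature channels: with stack means
#' \eqn{\bar X_c} (class) and \eqn{\bar X} (grand),
#' \eqn{S_b = \sum_c N_c (\bar X_c - \bar X)^T (\bar X_c - \bar X)} and
#' \eqn{S_w = \sum_c \sum_{i \in c} (X_i - \bar X_c)^T (X_i - \bar X_c)},
#' both K x K.
#'
#' @param stacks List of p x K feature matrices.
#' @param labels Integer class labels (1 = MA, 2 = non-MA), one per stack.
#' @return List with \code{Sb}, \code{Sw} (K x K symmetric PSD matrices)
#'   and the per-class counts \code{n_c}.
#' @export
scatter_matrices <- function(stacks, labels) {
  stopifnot(length(stacks) == length(labels))
  classes <- sort(unique(labels))
  if (length(classes) < 2L) stop("need at least two classes")
  K <- ncol(stacks[[1]])
  Xbar <- Reduce(`+`, stacks) / length(stacks)
  Sb <- matrix(0, K, K); Sw <- matrix(0, K, K)
  n_c <- integer(length(classes))
  for (ci in seq_along(classes)) {
    idx <- which(labels == classes[ci])
    n_c[ci] <- length(idx)
    Xc <- Reduce(`+`, stacks[idx]) / length(idx)
    Dc <- Xc - Xbar
    Sb <- Sb + length(idx) * crossprod(Dc)
    for (i in idx) {
      Di <- stacks[[i]] - Xc
      Sw <- Sw + crossprod(Di)
    }
  }
  list(Sb = (Sb + t(Sb)) / 2, Sw = (Sw + t(Sw)) / 2, n_c = n_c)
}

#' Fisher fusion matrix from a scatter pair
#'
#' Solves the generalized eigenvalue problem \eqn{S_b \phi = \lambda S_w
#' \phi} (with a small ridge on \eqn{S_w} for invertibility) and returns
#' the top-M eigenvectors as columns of W, ordered by decreasing
#' eigenvalue, normalized so \eqn{\phi^T (S_w + \epsilon I) \phi = 1},
#' signs fixed so each column's largest-magnitude entry is positive.
#'
#' @param scatter List with \code{Sb} and \code{Sw} (from
#'   \code{scatter_matrices}).
#' @param M Number of fused channels (<= K).
#' @return List of class \code{"fusion_matrix"}: \code{W} (K x M),
#'   \code{eigenvalues} (length M, decreasing), \code{epsilon} (ridge
#'   used).
#' @export
fisher_fusion <- function(scatter, M) {
  Sb <- scatter$Sb; Sw <- scatter$Sw
  K <- ncol(Sb)
  if (M > K) stop("M must not exceed the number of feature channels K")
  eps <- 1e-6 * sum(diag(Sw)) / K
  if (eps <= 0) eps <- 1e-8
  Swr <- Sw + diag(eps, K)
  Rc <- chol(Swr)
  Rinv <- backsolve(Rc, diag(K))
  A <- t(Rinv) %*% Sb %*% Rinv
  es <- eigen((A + t(A)) / 2, symmetric = TRUE)
  W <- Rinv %*% es$vectors[, seq_len(M), drop = FALSE]
  W <- apply(W, 2L, fix_sign)
  structure(list(W = W, eigenvalues = es$values[seq_len(M)], epsilon = eps),
            class = "fusion_matrix")
}

#' Fuse a feature stack
#'
#' Projects the K feature channels onto the M fused channels:
#' \code{fused = X \%*\% W}.
#'
#' @param X p x K feature stack.
#' @param W K x M fusion matrix (or a \code{"fusion_matrix"} object).
#' @return p x M fused matrix.
#' @export
fuse <- function(X, W) {
  if (inherits(W, "fusion_matrix")) W <- W$W
  if (ncol(X) != nrow(W)) stop("feature stack and fusion matrix disagree")
  X %*% W
}

#' Fit the multifeature fusion dictionary model
#'
#' The fitting function of the package: learns the Fisher fusion matrix
#' from labeled patch feature stacks and then, for each class c (1 = MA,
#' 2 = non-MA) and fused channel m, a K-SVD subdictionary on the m-th
#' fused column of the class-c samples. Classification of a new stack is
#' by the class with the lowest reconstruction error accumulated over the
#' M fused channels (see \code{predict.ma_model}).
#'
#' @param stacks List of p x K feature stacks (see
#'   \code{patch_feature_stack}).
#' @param labels Integer labels, 1 = MA, 2 = non-MA.
#' @param cfg An \code{ma_config}; \code{fused_dim},
#'   \code{atoms_per_subdictionary}, \code{omp_sparsity},
#'   \code{ksvd_iterations} and \code{rng_seed} control the fit.
#' @return Object of class \code{"ma_model"}: \code{W} (K x M),
#'   \code{eigenvalues}, \code{dicts} (dicts[[c]][[m]] = p x d matrix),
#'   \code{objectives} (K-SVD error traces), \code{config},
#'   \code{n_per_class}, \code{class_names}.
#' @examples
#' \donttest{
#' ds <- generate_patch_dataset(simulation_params(image_size = 256,
#'                              n_ma = 8, n_vessels = 3, seed = 1),
#'                              n_per_class = 40)
#' fit <- ma_train(ds$stacks, ds$labels,
#'                 ma_config(atoms_per_subdictionary = 24,
#'                           ksvd_iterations = 5))
#' fit
#' }
#' @export
ma_train <- function(stacks, labels, cfg = ma_config()) {
  labels <- as.integer(labels)
  counts <- table(factor(labels, levels = 1:2))
  if (any(counts == 0L))
    stop(sprintf("both classes required: %d MA, %d non-MA samples",
                 counts[1], counts[2]))
  sc <- scatter_matrices(stacks, labels)
  fm <- fisher_fusion(sc, cfg$fused_dim)
  fused <- lapply(stacks, fuse, W = fm$W)
  set.seed(stage_seed(cfg, "dict"))
  dicts <- list(); objectives <- list()
  for (c in 1:2) {
    idx <- which(labels == c)
    dicts[[c]] <- list(); objectives[[c]] <- list()
    for (m in seq_len(cfg$fused_dim)) {
      Y <- vapply(fused[idx], function(f) f[, m], numeric(nrow(fused[[1]])))
      kd <- ksvd_learn(Y, cfg$atoms_per_subdictionary, cfg$omp_sparsity,
                       cfg$ksvd_iterations)
      dicts[[c]][[m]] <- kd$dictionary
      objectives[[c]][[m]] <- kd$objective
    }
  }
  structure(list(W = fm$W, eigenvalues = fm$eigenvalues, dicts = dicts,
                 objectives = objectives, config = cfg,
                 n_per_class = as.integer(counts),
                 class_names = c("MA", "non-MA")),
            class = "ma_model")
}

#' @export
print.ma_model <- function(x, ...) {
  cfg <- x$config
  cat("Multifeature fusion dictionary model for microaneurysm detection\n")
  cat(sprintf("  trained on %d MA / %d non-MA patch stacks (%dx%d patches)\n",
              x$n_per_class[1], x$n_per_class[2],
              cfg$patch_size, cfg$patch_size))
  cat(sprintf("  fusion: K = %d channels -> M = %d (eigenvalues %s)\n",
              nrow(x$W), ncol(x$W),
              paste(signif(x$eigenvalues, 3), collapse = ", ")))
  cat(sprintf("  subdictionaries: %d x %d grid, %d atoms each, T = %d\n",
              length(x$dicts), ncol(x$W),
              ncol(x$dicts[[1]][[1]]), cfg$omp_sparsity))
  invisible(x)
}

#' @export
summary.ma_model <- function(object, ...) {
  print(object)
  cat("  final K-SVD representation errors:\n")
  for (c in 1:2) {
    errs <- vapply(object$objectives[[c]],
                   function(o) o[length(o)], 0)
    cat(sprintf("    class %d (%s): %s\n", c, object$class_names[c],
                paste(signif(errs, 4), collapse = ", ")))
  }
  invisible(object)
}

#' @export
coef.ma_model <- function(object, ...) object$W

#' Persist / restore a trained model
#'
#' The model directory holds the fusion matrix, every subdictionary and
#' the training configuration as plain text (CSV + JSON).
#'
#' @param model An \code{"ma_model"}.
#' @param dir Directory to create/read.
#' @return \code{save_model}: \code{dir} invisibly; \code{load_model}:
#'   the restored \code{"ma_model"}.
#' @export
save_model <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(model$W, file.path(dir, "fusion_matrix.csv"),
                   row.names = FALSE)
  for (c in 1:2) for (m in seq_len(ncol(model$W))) {
    utils::write.csv(model$dicts[[c]][[m]],
                     file.path(dir, sprintf("dict_c%d_m%d.csv", c, m)),
                     row.names = FALSE)
  }
  meta <- unclass(model$config)
  meta$eigenvalues <- model$eigenvalues
  meta$n_per_class <- model$n_per_class
  jsonlite::write_json(meta, file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname save_model
#' @export
load_model <- function(dir) {
  cfg_path <- file.path(dir, "config.json")
  if (!file.exists(cfg_path)) stop("not a model directory: ", dir)
  meta <- jsonlite::fromJSON(cfg_path)
  eig <- meta$eigenvalues; npc <- meta$n_per_class
  meta$eigenvalues <- NULL; meta$n_per_class <- NULL
  cfg <- do.call(ma_config, meta[names(meta) %in% names(formals(ma_config))])
  W <- as.matrix(utils::read.csv(file.path(dir, "fusion_matrix.csv")))
  dimnames(W) <- NULL
  dicts <- list()
  for (c in 1:2) {
    dicts[[c]] <- list()
    for (m in seq_len(ncol(W))) {
      D <- as.matrix(utils::read.csv(
        file.path(dir, sprintf("dict_c%d_m%d.csv", c, m))))
      dimnames(D) <- NULL
      dicts[[c]][[m]] <- D
    }
  }
  structure(list(W = W, eigenvalues = eig, dicts = dicts,
                 objectives = NULL, config = cfg,
                 n_per_class = as.integer(npc),
                 class_names = c("MA", "non-MA")),
            class = "ma_model")
}
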