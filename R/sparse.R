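# Orthogonal matching pursuit and K-SVD dictionary learning.

#' Sparse-code a vector against a subdictionary by OMP
#'
#' Greedy orthogonal matching pursuit: at each step the atom with the
#' largest absolute correlation with the current residual is added to the
#' support and the coefficients are re-fit by least squares on the
#' selected atoms, until \code{sparsity} atoms are used or the residual
#' vanishes.
#'
#' @param y Length-p signal vector.
#' @param Q p x d dictionary with (ideally) unit-norm atoms.
#' @param sparsity Maximum number of atoms T.
#' @return List of class \code{"sparse_code"}: \code{beta} (length-d
#'   coefficient vector), \code{support} (selected atom indices),
#'   \code{residual2} (squared l2 reconstruction error).
#' @export
sparse_code <- function(y, Q, sparsity) {
  stopifnot(sparsity >= 1L)
  if (all(abs(Q) < 1e-14)) stop("dictionary is all-zero")
  d <- ncol(Q)
  support <- integer(0)
  beta_s <- numeric(0)
  r <- y
  for (s in seq_len(min(sparsity, d))) {
    cors <- crossprod(Q, r)
    cors[support] <- 0
    j <- which.max(abs(cors))
    if (abs(cors[j]) < 1e-12) break
    support <- c(support, j)
    Qs <- Q[, support, drop = FALSE]
    beta_s <- qr.coef(qr(Qs), y)
    beta_s[is.na(beta_s)] <- 0
    r <- y - Qs %*% beta_s
  }
  beta <- numeric(d)
  beta[support] <- beta_s
  structure(list(beta = beta, support = support,
                 residual2 = sum(r^2)),
            class = "sparse_code")
}

# Coefficient matrix (d x n) for all columns of Y.
omp_code_matrix <- function(Y, Q, sparsity) {
  B <- matrix(0, ncol(Q), ncol(Y))
  for (i in seq_len(ncol(Y))) {
    B[, i] <- sparse_code(Y[, i], Q, sparsity)$beta
  }
  B
}

# Fix atom sign so the largest-magnitude entry is positive.
fix_sign <- function(v) {
  j <- which.max(abs(v))
  if (v[j] < 0) -v else v
}

#' Learn a subdictionary by K-SVD
#'
#' Alternates OMP sparse coding of all training vectors with sequential
#' SVD-based atom updates. Atoms are kept at unit l2 norm; an atom used by
#' no signal after a sweep is replaced by the training vector with the
#' largest current residual. The dictionary is initialized from a random
#' sample of the training vectors (driven by R's RNG state, so seed the
#' session for reproducibility).
#'
#' @param Y p x n matrix of training vectors (columns).
#' @param d Number of atoms; reduced (with a warning) if n < d.
#' @param sparsity OMP sparsity T.
#' @param iterations Number of coding/update alternations.
#' @return List of class \code{"ksvd_dict"}: \code{dictionary} (p x d,
#'   unit-norm atoms), \code{objective} (total squared representation
#'   error after each iteration's atom updates), \code{codes} (d x n
#'   final coefficients).
#' @export
ksvd_learn <- function(Y, d, sparsity, iterations = 15L) {
  p <- nrow(Y); n <- ncol(Y)
  if (n < 1L) stop("no training vectors")
  if (n < d) {
    warning(sprintf("only %d training vectors; reducing atoms from %d", n, d))
    d <- n
  }
  stopifnot(sparsity <= d)
  init <- sample.int(n, d)
  Q <- apply(Y[, init, drop = FALSE], 2L, function(v) {
    nv <- sqrt(sum(v^2))
    if (nv < 1e-12) stats::rnorm(p) / sqrt(p) else v / nv
  })
  Q <- apply(Q, 2L, fix_sign)
  objective <- numeric(iterations)
  B <- NULL
  for (it in seq_len(iterations)) {
    B <- omp_code_matrix(Y, Q, sparsity)
    R <- Y - Q %*% B
    for (k in seq_len(d)) {
      omega <- which(abs(B[k, ]) > 0)
      if (length(omega) == 0L) {
        # dead atom: replace by the worst-represented training vector
        res <- colSums(R^2)
        j <- which.max(res)
        v <- Y[, j]
        nv <- sqrt(sum(v^2))
        Q[, k] <- fix_sign(if (nv < 1e-12) stats::rnorm(p) / sqrt(p)
                           else v / nv)
        next
      }
      Ek <- R[, omega, drop = FALSE] + Q[, k] %o% B[k, omega]
      sv <- svd(Ek, nu = 1L, nv = 1L)
      atom <- fix_sign(sv$u[, 1])
      sgn <- if (all(atom == sv$u[, 1])) 1 else -1
      coef <- sgn * sv$d[1] * sv$v[, 1]
      Q[, k] <- atom
      B[k, omega] <- coef
      R[, omega] <- Ek - atom %o% coef
    }
    objective[it] <- sum((Y - Q %*% B)^2)
  }
  structure(list(dictionary = Q, objective = objective, codes = B),
            class = "ksvd_dict")
}
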