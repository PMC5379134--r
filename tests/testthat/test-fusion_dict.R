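test_that("scatter matrices match the definitional summation oracle", {
  set.seed(42)
  rs <- random_stacks(15, p = 20, K = 4)
  got <- scatter_matrices(rs$stacks, rs$labels)
  want <- scatter_oracle(rs$stacks, rs$labels)
  expect_lt(max(abs(got$Sb - want$Sb)), 1e-10)
  expect_lt(max(abs(got$Sw - want$Sw)), 1e-10)
  expect_error(scatter_matrices(rs$stacks, rep(1L, 30)), "two classes")
})

test_that("scatter edge cases: equal class means and one-sample classes", {
  X <- matrix(1:12 / 12, 4, 3)
  sc <- scatter_matrices(list(X, X, X, X), c(1, 1, 2, 2))
  expect_equal(sc$Sb, matrix(0, 3, 3))
  X2 <- matrix(stats::rnorm(12), 4, 3)
  sc2 <- scatter_matrices(list(X, X2), c(1, 2))
  expect_equal(sc2$Sw, matrix(0, 3, 3))
})

test_that("Sb + Sw equals the total scatter", {
  set.seed(8)
  rs <- random_stacks(20, p = 15, K = 5)
  sc <- scatter_matrices(rs$stacks, rs$labels)
  Xbar <- Reduce(`+`, rs$stacks) / length(rs$stacks)
  St <- Reduce(`+`, lapply(rs$stacks, function(X) crossprod(X - Xbar)))
  expect_lt(max(abs(sc$Sb + sc$Sw - St)), 1e-8)
})

test_that("the leading fused direction matches the two-class LDA closed
           form and satisfies the generalized eigen equation", {
  set.seed(19)
  rs <- random_stacks(40, p = 30, K = 4, shift = 2)
  sc <- scatter_matrices(rs$stacks, rs$labels)
  fm <- fisher_fusion(sc, 3L)
  expect_error(fisher_fusion(sc, 5L), "exceed")

  # residuals of Sb phi = lambda (Sw + eps I) phi
  Swr <- sc$Sw + diag(fm$epsilon, 4)
  for (m in 1:3) {
    res <- sc$Sb %*% fm$W[, m] - fm$eigenvalues[m] * Swr %*% fm$W[, m]
    expect_lt(sqrt(sum(res^2)), 1e-8)
    expect_equal(drop(t(fm$W[, m]) %*% Swr %*% fm$W[, m]), 1,
                 tolerance = 1e-10)
  }
  expect_true(all(diff(fm$eigenvalues) <= 1e-12))

  # closed form: with C = 2 the only discriminative direction is
  # solve(Sw, delta) for the K-space mean difference acting through Sb
  idx1 <- which(rs$labels == 1)
  X1 <- Reduce(`+`, rs$stacks[idx1]) / length(idx1)
  X2 <- Reduce(`+`, rs$stacks[-idx1]) / (length(rs$stacks) - length(idx1))
  D <- X1 - X2                                  # p x K
  # Sb = (N/2) * (D/2)'(D/2) * 2; its column space is spanned by D'D
  lead <- Re(eigen(solve(Swr, crossprod(D)))$vectors[, 1])
  cosang <- abs(sum(lead * fm$W[, 1])) /
    sqrt(sum(lead^2) * sum(fm$W[, 1]^2))
  expect_gt(cosang, 0.99)
})

test_that("Rayleigh quotient of the leading direction beats random
           directions", {
  set.seed(77)
  rs <- random_stacks(25, p = 20, K = 6, shift = 1)
  sc <- scatter_matrices(rs$stacks, rs$labels)
  fm <- fisher_fusion(sc, 2L)
  rq <- function(v) drop(t(v) %*% sc$Sb %*% v) /
    drop(t(v) %*% (sc$Sw + diag(fm$epsilon, 6)) %*% v)
  best <- rq(fm$W[, 1])
  rand <- replicate(1000, {
    v <- stats::rnorm(6); rq(v / sqrt(sum(v^2)))
  })
  expect_gte(best, max(rand))
})

test_that("fusion picks out a single separating feature component", {
  set.seed(55)
  p <- 25; K <- 5
  s1 <- lapply(1:40, function(i) matrix(stats::rnorm(p * K, sd = 0.3), p, K))
  s2 <- lapply(1:40, function(i) {
    X <- matrix(stats::rnorm(p * K, sd = 0.3), p, K)
    X[, 1] <- X[, 1] + 1
    X
  })
  sc <- scatter_matrices(c(s1, s2), rep(1:2, each = 40))
  fm <- fisher_fusion(sc, 2L)
  expect_gte(abs(fm$W[1, 1]) / sqrt(sum(fm$W[, 1]^2)), 0.9)
})

test_that("fuse is the plain matrix product", {
  X <- matrix(stats::rnorm(40), 10, 4)
  expect_equal(fuse(X, diag(4)), X)
  expect_equal(fuse(matrix(0, 10, 4), matrix(1, 4, 2)), matrix(0, 10, 2))
  W <- matrix(stats::rnorm(8), 4, 2)
  expect_equal(fuse(3 * X, W), 3 * fuse(X, W))
  expect_error(fuse(X, matrix(0, 5, 2)), "disagree")
})

test_that("K-SVD: rank-1 fixed point, monotone objective, dead-atom
           handling and a reduced-dictionary warning", {
  set.seed(12)
  v <- stats::rnorm(20); v <- v / sqrt(sum(v^2))
  Y <- v %o% stats::runif(10, 0.5, 2)
  kd <- ksvd_learn(Y, 1L, 1L, 3L)
  expect_equal(abs(sum(kd$dictionary[, 1] * v)), 1, tolerance = 1e-10)
  expect_lt(kd$objective[3], 1e-20)

  Yr <- matrix(stats::rnorm(30 * 60), 30, 60)
  kd2 <- ksvd_learn(Yr, 20L, 3L, 10L)
  expect_true(all(diff(kd2$objective) <= 1e-8 * kd2$objective[1]))
  expect_equal(sqrt(colSums(kd2$dictionary^2)), rep(1, 20),
               tolerance = 1e-10)

  expect_warning(ksvd_learn(Yr[, 1:5], 10L, 2L, 2L), "reducing")
})

test_that("training produces the M x C subdictionary grid and is
           seed-deterministic", {
  set.seed(4)
  rs <- random_stacks(25, p = 20, K = 4)
  cfg <- ma_config(fused_dim = 3L, atoms_per_subdictionary = 8L,
                   ksvd_iterations = 3L, omp_sparsity = 2L, rng_seed = 5L)
  fit1 <- ma_train(rs$stacks, rs$labels, cfg)
  fit2 <- ma_train(rs$stacks, rs$labels, cfg)
  expect_length(fit1$dicts, 2L)                 # classes
  expect_length(fit1$dicts[[1]], 3L)            # fused channels
  expect_equal(dim(fit1$dicts[[2]][[3]]), c(20L, 8L))
  expect_identical(fit1$W, fit2$W)
  expect_identical(fit1$dicts, fit2$dicts)
  expect_error(ma_train(rs$stacks, rep(1L, length(rs$stacks)), cfg),
               "both classes")
})
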