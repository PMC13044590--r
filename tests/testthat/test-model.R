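test_that("gram_matrix matches the elementwise loop oracle", {
  set.seed(41)
  M <- matrix(rnorm(70), 10, 7,
              dimnames = list(sprintf("i%02d", 1:10), paste0("f", 1:7)))
  K <- gram_matrix(M, "transcriptome", scale_features = FALSE)
  Mc <- scale(M, scale = FALSE)
  oracle <- matrix(0, 10, 10)
  for (i in 1:10) for (j in 1:10)
    oracle[i, j] <- sum(Mc[i, ] * Mc[j, ])
  expect_lt(max(abs(unclass(K) - oracle)), 1e-10)

  Ks <- gram_matrix(M, "transcriptome", scale_features = TRUE)
  expect_lt(max(abs(unclass(Ks) - oracle / 7)), 1e-10)
  expect_equal(attr(Ks, "n_features"), 7L)
})

test_that("single-feature Gram is the rank-one outer product", {
  z <- c(-1, 0, 1, 2, -2)
  M <- matrix(z, 5, 1, dimnames = list(letters[1:5], "f"))
  K <- gram_matrix(M, "genome")
  zc <- z - mean(z)
  expect_lt(max(abs(unclass(K) - tcrossprod(zc))), 1e-12)
  expect_equal(qr(unclass(K))$rank, 1L)
  expect_error(gram_matrix(matrix(1, 4, 2), "genome"), "non-constant")
})

test_that("implied covariance has the Markov-chain structure on a grid", {
  expect_equal(implied_covariance(0, 0), diag(3),
               ignore_attr = TRUE)
  expect_equal(det(implied_covariance(0.5, 0.3)), 0.6825)
  grid <- seq(-0.95, 0.95, length.out = 21)
  for (a in grid) for (b in grid) {
    S <- implied_covariance(a, b)
    expect_lt(abs(solve(S)[1, 3]), 1e-10)
    expect_lt(abs(det(S) - (1 - a^2) * (1 - b^2)), 1e-12)
  }
  expect_error(implied_covariance(1, 0), "inside")
})

test_that("negative log-likelihood matches the explicit-inverse oracle", {
  expect_equal(negative_log_likelihood(diag(3), 0, 0), 3)
  S <- implied_covariance(0.5, 0.3)
  expect_equal(negative_log_likelihood(S, 0.5, 0.3), 3 + log(0.6825))

  set.seed(42)
  for (i in 1:20) {
    r <- exact_cor_scores(runif(1, -0.7, 0.7), runif(1, -0.7, 0.7),
                          runif(1, -0.4, 0.4), n = 50, seed = i)
    Sr <- cor(cbind(r$g, r$t, r$p))
    a <- runif(1, -0.9, 0.9); b <- runif(1, -0.9, 0.9)
    oracle <- sum(diag(Sr %*% solve(implied_covariance(a, b)))) +
      log(det(implied_covariance(a, b)))
    expect_lt(abs(negative_log_likelihood(Sr, a, b) - oracle), 1e-12)
  }
})

test_that("the generating parameters minimize the likelihood over a grid", {
  a0 <- 0.6; b0 <- -0.4
  S <- implied_covariance(a0, b0)
  ref <- negative_log_likelihood(S, a0, b0)
  grid <- seq(-0.9, 0.9, length.out = 21)
  for (a in grid) for (b in grid)
    expect_gte(negative_log_likelihood(S, a, b), ref - 1e-12)
})

test_that("structural half-step recovers exact generating parameters", {
  sp <- fit_structural_params(diag(3))
  expect_lt(abs(sp$alpha), 1e-6)
  expect_lt(abs(sp$beta), 1e-6)
  for (ab in list(c(0.5, 0.3), c(0.85, 0.34), c(-0.7, 0.2))) {
    sp <- fit_structural_params(implied_covariance(ab[1], ab[2]))
    # closed form: for unit-diagonal S the MLE is (S12, S23)
    expect_lt(abs(sp$alpha - ab[1]), 1e-5)
    expect_lt(abs(sp$beta - ab[2]), 1e-5)
  }
})

test_that("connection weights are the negated off-diagonal precision", {
  W <- connection_weights(0.5, 0.3)
  expect_equal(W[1, 2], 2 / 3)
  expect_equal(W[2, 3], 0.3 / 0.91)
  expect_identical(W[1, 3], 0)
  expect_equal(connection_weights(0, 0), matrix(0, 3, 3),
               ignore_attr = TRUE)
  # agrees with -offdiag(solve(Sigma)) for random parameters
  set.seed(5)
  for (i in 1:10) {
    a <- runif(1, -0.9, 0.9); b <- runif(1, -0.9, 0.9)
    Om <- solve(implied_covariance(a, b))
    W <- connection_weights(a, b)
    expect_lt(abs(W[1, 2] + Om[1, 2]), 1e-10)
    expect_lt(abs(W[2, 3] + Om[2, 3]), 1e-10)
  }
})

test_that("trait PCA variance fractions match the eigen oracle", {
  set.seed(6)
  u <- rnorm(20); v <- rnorm(4)
  P1 <- u %*% t(v)  # rank 1
  expect_equal(trait_pca_variance(P1, 1), 1)
  P <- matrix(rnorm(20 * 5), 20, 5)
  expect_equal(trait_pca_variance(P, 5), 1)
  ev <- eigen(cov(scale(P, scale = FALSE)), symmetric = TRUE,
              only.values = TRUE)$values
  expect_lt(abs(trait_pca_variance(P, 2) - sum(ev[1:2]) / sum(ev)), 1e-10)
  expect_error(trait_pca_variance(P, 9), "rank")
})
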