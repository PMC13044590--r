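test_that("score normalization is exact and idempotent", {
  s <- normalize_score(c(1, 2, 3))
  expect_lt(abs(mean(s)), 1e-12)
  expect_equal(var(s), 1)
  expect_lt(max(abs(normalize_score(s) - s)), 1e-12)
  set.seed(3)
  x <- rnorm(50, 4, 9)
  nx <- normalize_score(x)
  # two-pass oracle
  expect_lt(abs(sum((nx - mean(nx))^2) / 49 - 1), 1e-12)
  expect_error(normalize_score(rep(2, 5)), "zero variance")
})

test_that("a shared eigenvector across identical blocks is a sweep fixed
           point", {
  Ks <- noise_grams(n = 20, p = 6, seed = 1)
  K <- Ks$K_G
  e <- eigen(unclass(K), symmetric = TRUE)
  v <- e$vectors[, 1]
  W <- connection_weights(0.5, 0.5)
  for (scheme in c("covariance", "correlation")) {
    sw <- gcca_sweep(K, K, K, W, list(v, v, v), scheme = scheme)
    for (j in 1:3)
      expect_lt(max(abs(normalize_score(sw$scores[[j]]) -
                          normalize_score(v))), 1e-8)
  }
})

test_that("zero connection weights leave scores unchanged with a warning", {
  Ks <- noise_grams(n = 15, p = 4, seed = 2)
  sc <- lapply(1:3, function(j) rnorm(15))
  W <- connection_weights(0, 0)
  w <- capture_warnings(sw <- gcca_sweep(Ks$K_G, Ks$K_T, Ks$K_P, W, sc))
  expect_length(w, 3)
  expect_match(w, "orthogonal", all = TRUE)
  # kept scores, up to the scheme normalization applied on entry
  for (j in 1:3)
    expect_gt(abs(cor(sw$scores[[j]], sc[[j]])), 1 - 1e-10)
})

test_that("repeated sweeps never decrease the weighted-covariance
           objective", {
  for (scheme in c("covariance", "correlation")) {
    for (seed in 1:50) {
      Ks <- noise_grams(n = 15, p = 5, seed = seed)
      set.seed(seed + 1000)
      sc <- lapply(1:3, function(j) rnorm(15))
      W <- connection_weights(0.6, 0.4)
      s1 <- gcca_sweep(Ks$K_G, Ks$K_T, Ks$K_P, W, sc, scheme = scheme)
      s2 <- gcca_sweep(Ks$K_G, Ks$K_T, Ks$K_P, W, s1$scores, s1$loadings,
                       scheme = scheme)
      expect_gte(s2$objective, s1$objective - 1e-10)
    }
  }
})

test_that("null data with low-dimensional blocks yields near-zero paths", {
  # rank-1 blocks: the purest no-signal case, no room for the fit to
  # align block subspaces
  for (seed in 1:20) {
    Ks <- noise_grams(n = 300, p = 1, seed = 100 + seed)
    fit <- fit_hdma(Ks$K_G, Ks$K_T, Ks$K_P)
    expect_lt(abs(fit$alpha), 0.2)
    expect_lt(abs(fit$beta), 0.2)
  }
  # rank-2 blocks: subspace alignment inflates the null paths somewhat;
  # they stay small on average
  ab <- sapply(1:20, function(seed) {
    Ks <- noise_grams(n = 300, p = 2, seed = 100 + seed)
    fit <- fit_hdma(Ks$K_G, Ks$K_T, Ks$K_P)
    c(fit$alpha, fit$beta)
  })
  expect_lt(mean(abs(ab)), 0.2)
})

test_that("fits are deterministic, sign-conventional, variance-normalized
           and monotone in NLL", {
  r1 <- fit_small(101)
  r2 <- fit_small(101)
  expect_identical(r1$fit$nll_trace, r2$fit$nll_trace)
  expect_identical(r1$fit$scores, r2$fit$scores)
  for (seed in 102:106) {
    f <- fit_small(seed)$fit
    expect_gte(f$alpha, 0)
    expect_gte(f$beta, 0)
    expect_true(all(diff(f$nll_trace) <= 1e-9))
    for (s in f$scores) {
      expect_lt(abs(var(s) - 1), 1e-6)
      expect_lt(abs(mean(s)), 1e-8)
    }
  }
})

test_that("permuting individuals permutes scores and preserves the fit", {
  r <- fit_small(120, n = 60)
  b <- r$blocks
  f1 <- r$fit
  set.seed(77)
  perm <- sample(60)
  Xp <- expression_matrix(unclass(b$X)[perm, , drop = FALSE],
                          stage = "standardized")
  Pp <- b$P[perm, , drop = FALSE]
  attr(Pp, "column_kind") <- attr(b$P, "column_kind")
  f2 <- fit_hdma(b$K_G[perm, perm], unclass(b$K_T)[perm, perm],
                 unclass(b$K_P)[perm, perm], X = Xp, P = Pp)
  expect_lt(abs(f1$alpha - f2$alpha), 1e-8)
  expect_lt(abs(f1$beta - f2$beta), 1e-8)
  expect_lt(max(abs(f2$gene_loadings - f1$gene_loadings)), 1e-8)
  for (s in c("g", "t", "p"))
    expect_lt(max(abs(unname(f2$scores[[s]]) -
                        unname(f1$scores[[s]])[perm])), 1e-6)
})

test_that("mismatched individual ids are rejected", {
  Ks <- noise_grams(n = 10, p = 3, seed = 4)
  Kbad <- unclass(Ks$K_T)
  rownames(Kbad) <- rev(rownames(Kbad))
  expect_error(fit_hdma(Ks$K_G, Kbad, Ks$K_P), "ids")
})

test_that("gene loadings are correlations with the mediator score", {
  r <- fit_small(110)
  X <- r$blocks$X
  t_ <- r$fit$scores$t
  gl <- gene_loadings(X, t_)
  expect_true(all(abs(gl) <= 1))
  # covariance-formula oracle
  oracle <- apply(unclass(X), 2, function(col)
    cov(col, t_) / (sd(col) * sd(t_)))
  expect_lt(max(abs(gl - oracle)), 1e-10)

  # exact endpoints: a gene identical to the score
  X2 <- unclass(X)
  X2[, 1] <- normalize_score(unname(t_))
  X2[, 2] <- -X2[, 1]
  X2 <- expression_matrix(scale(X2), stage = "standardized")
  gl2 <- gene_loadings(X2, unname(t_))
  expect_equal(unname(gl2[1]), 1)
  expect_equal(unname(gl2[2]), -1)
})

test_that("phenotype loadings exclude constant columns with a warning", {
  set.seed(13)
  p_ <- rnorm(30)
  P <- cbind(a = p_, b = rnorm(30), c = rep(1, 30))
  expect_warning(pl <- phenotype_loadings(P, p_), "c")
  expect_equal(names(pl), c("a", "b"))
  expect_equal(unname(pl["a"]), 1)
})

test_that("score correlations report the mediation identity", {
  s <- exact_cor_scores(0.85, 0.34, 0.38, n = 477)
  sc <- score_correlations(s)
  expect_equal(sc$r_gt, 0.85)
  expect_equal(sc$r_tp, 0.34)
  expect_equal(sc$r_expected, 0.85 * 0.34)
  expect_true(sc$direct_effect)

  x <- rnorm(30)
  same <- list(g = x, t = x, p = x)
  sc2 <- score_correlations(same)
  expect_equal(sc2$r_gt, 1)
  expect_equal(sc2$r_expected, 1)

  # textbook oracle on random scores
  set.seed(21)
  rs <- list(g = rnorm(40), t = rnorm(40), p = rnorm(40))
  sc3 <- score_correlations(rs)
  ct <- cor.test(rs$g, rs$t)
  expect_lt(abs(sc3$r_gt - unname(ct$estimate)), 1e-12)
  expect_lt(abs(sc3$p_values[["gt"]] - ct$p.value), 1e-12)
})
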