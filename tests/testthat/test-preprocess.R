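test_that("log transform matches the scalar oracle and guards its domain", {
  x <- toy_counts(5, 4, seed = 9)
  lt <- log_transform(x, pseudocount = 1)
  expect_identical(expr_stage(lt), "log")
  # scalar-loop oracle
  for (i in 1:5) for (j in 1:4)
    expect_equal(lt[i, j], log2(unclass(x)[i, j] + 1))

  one <- expression_matrix(matrix(c(0, 3), 1, 2,
                                  dimnames = list("a", c("g1", "g2"))),
                           stage = "counts")
  lt1 <- log_transform(one, 1)
  expect_equal(unname(unclass(lt1)[1, ]), c(0, 2))
  expect_error(log_transform(lt1), "stage")
  expect_error(log_transform(one, pseudocount = 0), "pseudocount")
})

test_that("covariate adjustment residualizes exactly", {
  n <- 30
  C <- toy_covariates(n, seed = 4)
  set.seed(8)
  X <- matrix(rnorm(n * 6), n, 6,
              dimnames = list(C$individual_id, paste0("g", 1:6)))
  # column exactly linear in a covariate -> zero residual
  X[, 1] <- 2 * C$age_at_death + 5
  Xl <- expression_matrix(X, stage = "log")
  adj <- adjust_covariates(Xl, C)
  expect_lt(max(abs(adj[, 1])), 1e-10)

  # normal-equations oracle, gene by gene
  D <- cbind(1, C$sex, C$education_years, C$age_at_death)
  beta <- solve(t(D) %*% D) %*% t(D) %*% X
  expect_lt(max(abs(unclass(adj) - (X - D %*% beta))), 1e-8)
  # residuals orthogonal to every design column
  expect_lt(max(abs(t(D) %*% unclass(adj))), 1e-7)
})

test_that("a column already orthogonal to the design is unchanged", {
  n <- 24
  C <- toy_covariates(n, seed = 5)
  D <- cbind(1, C$sex, C$education_years, C$age_at_death)
  set.seed(10)
  y <- rnorm(n)
  y <- qr.resid(qr(D), y)  # orthogonal, mean zero
  X <- matrix(y, n, 1, dimnames = list(C$individual_id, "g1"))
  adj <- adjust_covariates(expression_matrix(X, stage = "log"), C)
  expect_lt(max(abs(unclass(adj)[, 1] - y)), 1e-10)
})

test_that("rank-deficient designs fail naming the collinear column", {
  C <- toy_covariates(10, seed = 6)
  C$edu_copy <- C$education_years
  X <- expression_matrix(matrix(rnorm(10), 10, 1,
                                dimnames = list(C$individual_id, "g1")),
                         stage = "log")
  expect_error(adjust_covariates(X, C), "edu_copy")
})

test_that("standardization hits exact moments, is idempotent, drops
           constants", {
  X <- expression_matrix(matrix(c(1, 2, 3, 5, 5, 5), 3, 2,
                                dimnames = list(letters[1:3],
                                                c("g1", "g2"))),
                         stage = "adjusted")
  expect_warning(st <- standardize_columns(X), "g2")
  expect_equal(attr(st, "dropped_genes"), "g2")
  expect_equal(unname(unclass(st)[, 1]), c(-1, 0, 1))

  st2 <- standardize_columns(st)
  expect_lt(max(abs(unclass(st2) - unclass(st))), 1e-10)

  set.seed(3)
  R <- expression_matrix(matrix(rnorm(40), 10, 4,
                                dimnames = list(sprintf("i%02d", 1:10),
                                                paste0("g", 1:4))),
                         stage = "adjusted")
  sR <- standardize_columns(R)
  expect_lt(max(abs(colMeans(sR))), 1e-8)
  expect_lt(max(abs(apply(unclass(sR), 2, sd) - 1)), 1e-8)
})

test_that("adjust + standardize leaves columns orthogonal to covariates", {
  n <- 40
  C <- toy_covariates(n, seed = 7)
  set.seed(12)
  X <- expression_matrix(
    matrix(rpois(n * 5, 80), n, 5,
           dimnames = list(C$individual_id, paste0("g", 1:5))),
    stage = "counts")
  st <- standardize_columns(adjust_covariates(log_transform(X), C))
  D <- cbind(C$sex, C$education_years, C$age_at_death)
  Dc <- scale(D, scale = FALSE)
  Dn <- sweep(Dc, 2, sqrt(colSums(Dc^2)), "/")
  expect_lt(max(abs(crossprod(Dn, unclass(st)))), 1e-6)
})

test_that("individual alignment is a sorted set intersection", {
  expect_equal(align_individuals(c("a", "b", "c"), c("c", "b", "d")),
               c("b", "c"))
  expect_equal(align_individuals(letters[1:3], letters[1:3]), letters[1:3])
  expect_error(align_individuals(c("a"), c("b")), "common")

  set.seed(20)
  for (i in 1:10) {
    l1 <- sample(letters, 15)
    l2 <- sample(letters, 15)
    l3 <- sample(letters, 15)
    expect_equal(align_individuals(l1, l2, l3),
                 sort(intersect(intersect(l1, l2), l3)))
  }
})
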