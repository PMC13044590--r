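# independent running-sum oracle: explicit position-by-position loop
es_loop_oracle <- function(ids, set, w) {
  N <- length(ids)
  hit <- ids %in% set
  m <- sum(hit)
  stat <- if (w == 0) rep(1, N) else N:1
  denom_hit <- sum(stat[hit]^w)
  run <- 0
  best <- 0
  path <- numeric(N)
  for (i in seq_len(N)) {
    if (hit[i]) run <- run + stat[i]^w / denom_hit
    else run <- run - 1 / (N - m)
    path[i] <- run
  }
  path[which.max(abs(path))]
}

test_that("enrichment score equals the hand loop on a 10-gene toy", {
  ids <- letters[1:10]
  set <- c("b", "e", "i")
  for (w in c(0, 1)) {
    es <- enrichment_score(ids, set, weight_exponent = w)
    expect_equal(es$es, es_loop_oracle(ids, set, w))
  }
  # leading edge lies inside set intersect list
  es0 <- enrichment_score(ids, set, 0)
  expect_true(all(es0$leading_edge %in% set))
})

test_that("extreme sets give the boundary enrichment scores", {
  ids <- sprintf("g%03d", 1:100)
  top <- ids[1:10]
  es <- enrichment_score(ids, top, weight_exponent = 0)
  expect_equal(es$es, 1)
  expect_equal(es$position, 10L)
  expect_equal(sort(es$leading_edge), sort(top))

  bottom <- ids[91:100]
  esb <- enrichment_score(ids, bottom, weight_exponent = 0)
  expect_lte(esb$es, 0)
  expect_error(enrichment_score(ids, c("zz1", "zz2")), "intersect")
})

test_that("w=0 scores stay in [-1,1] and depend only on hit positions", {
  set.seed(71)
  ids <- sprintf("g%03d", 1:80)
  for (i in 1:50) {
    set <- sample(ids, sample(3:20, 1))
    es <- enrichment_score(ids, set, 0)$es
    expect_gte(es, -1)
    expect_lte(es, 1)
    # relabel all genes, keep hit positions: same score
    ids2 <- sprintf("h%03d", 1:80)
    set2 <- ids2[ids %in% set]
    expect_equal(enrichment_score(ids2, set2, 0)$es, es)
  }
})

test_that("weighted scores agree with the fgsea implementation", {
  set.seed(72)
  N <- 200
  ids <- sprintf("g%03d", 1:N)
  stats <- setNames(as.numeric(N:1), ids)
  for (i in 1:10) {
    set <- sample(ids, 15)
    ours <- enrichment_score(ids, set, weight_exponent = 1)$es
    ref <- fgsea::calcGseaStat(stats, selectedStats = which(ids %in% set),
                               gseaParam = 1, returnLeadingEdge = FALSE)
    expect_lt(abs(ours - ref), 1e-12)
  }
})

test_that("permutation p-values are deterministic, extreme for planted
           sets, and calibrated under the null", {
  set.seed(73)
  N <- 400
  ids <- sprintf("g%03d", 1:N)
  planted <- list(planted = ids[1:20])
  r1 <- permutation_nes(ids, planted, B = 199, seed = 42)
  r2 <- permutation_nes(ids, planted, B = 199, seed = 42)
  expect_identical(r1, r2)
  expect_equal(r1$p_value, 1 / 200)
  expect_gt(r1$nes, 1)

  sets <- lapply(1:200, function(i) sample(ids, 15))
  names(sets) <- sprintf("null_%03d", 1:200)
  res <- permutation_nes(ids, sets, B = 199, weight_exponent = 0,
                         seed = 7)
  frac <- mean(res$p_value < 0.05)
  expect_gte(frac, 0.01)
  expect_lte(frac, 0.10)
  # BH adjustment is monotone in the raw p ordering
  ord <- order(res$p_value)
  expect_true(all(diff(res$p_adjust[ord]) >= -1e-12))
  expect_true(all(res$p_adjust >= res$p_value - 1e-12))
})
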