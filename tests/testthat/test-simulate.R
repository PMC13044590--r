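test_that("genotype simulation is deterministic and respects the
           relatedness structure", {
  G1 <- simulate_genotypes(50, 200, family_block_size = 1, seed = 5)
  G2 <- simulate_genotypes(50, 200, family_block_size = 1, seed = 5)
  expect_identical(unclass(G1), unclass(G2))
  expect_error(simulate_genotypes(10, 10, maf_range = c(0.01, 0.4),
                                  seed = 1), "maf_range")

  # unrelated cohort: mean off-diagonal GRM kinship ~ 0
  G <- simulate_genotypes(200, 1000, family_block_size = 1, seed = 6)
  K <- unclass(compute_kinship(G, "grm"))
  expect_lt(abs(mean(K[upper.tri(K)])), 0.02)
})

test_that("family blocks elevate within-block kinship over between-block",
          {
  for (seed in 1:20) {
    G <- simulate_genotypes(80, 400, family_block_size = 4, seed = seed)
    K <- unclass(compute_kinship(G, "grm"))
    fam <- rep(seq_len(20), each = 4)
    same <- outer(fam, fam, "==") & upper.tri(K)
    diff_ <- outer(fam, fam, "!=") & upper.tri(K)
    expect_gt(mean(K[same]), mean(K[diff_]))
  }
})

test_that("generated latents realize the structural equations", {
  # null chain: no genome -> transcriptome -> phenome paths
  sim0 <- simulate_dataset(small_config(seed = 8, n = 477, alpha = 0,
                                        beta = 0))
  expect_lt(abs(cor(sim0$truth$g_star, sim0$truth$t_star)), 0.1)
  expect_lt(abs(cor(sim0$truth$t_star, sim0$truth$p_star)), 0.1)

  # mediated chain at the study scale
  r <- sapply(1:20, function(seed) {
    sim <- simulate_dataset(small_config(seed = 200 + seed, n = 477))
    cor(sim$truth$g_star, sim$truth$t_star)
  })
  expect_lt(abs(mean(r) - 0.85), 0.05)
})

test_that("a zero loading fraction leaves expression independent of the
           mediator", {
  cfg <- synthetic_config(n = 120, n_snps = 150, n_genes = 250,
                          n_causal_snps = 25, loading_fraction = 0,
                          seed = 33)
  sim <- simulate_dataset(cfg)
  X <- standardize_columns(log_transform(sim$counts))
  r <- abs(cor(unclass(X), sim$truth$t_star))
  # Bonferroni bound on the max null correlation (Fisher z scale)
  bound <- tanh(qnorm(1 - 0.025 / ncol(X)) / sqrt(120 - 3))
  expect_lt(max(r), bound)
})

test_that("ordinal outcomes track latent severity with the clinical sign
           pattern", {
  for (seed in 41:45) {
    sim <- simulate_dataset(small_config(seed = seed, n = 300))
    p_ <- sim$truth$p_star
    expect_gt(cor(p_, sim$phenotypes$braak, method = "spearman"), 0)
    expect_gt(cor(p_, sim$phenotypes$cog_lv, method = "spearman"), 0)
    expect_gt(cor(p_, sim$phenotypes$cog_death, method = "spearman"), 0)
    expect_lt(cor(p_, sim$phenotypes$cerad, method = "spearman"), 0)
    expect_lt(cor(p_, sim$phenotypes$mmse, method = "spearman"), 0)
  }
})

test_that("full dataset simulation is deterministic under a fixed seed", {
  s1 <- simulate_dataset(small_config(seed = 55))
  s2 <- simulate_dataset(small_config(seed = 55))
  expect_identical(unclass(s1$counts), unclass(s2$counts))
  expect_identical(s1$phenotypes, s2$phenotypes)
  expect_identical(s1$truth, s2$truth)
})
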