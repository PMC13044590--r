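# Fixture builders shared across the suite. Everything is generated in
# code under fixed seeds; no data files.

toy_genotypes <- function(n = 20, m = 100, seed = 1, maf = 0.3) {
  set.seed(seed)
  genotype_matrix(matrix(rbinom(n * m, 2, maf), n, m),
                  individual_ids = sprintf("i%03d", seq_len(n)),
                  snp_ids = sprintf("s%03d", seq_len(m)))
}

toy_counts <- function(n = 12, g = 6, seed = 2) {
  set.seed(seed)
  expression_matrix(matrix(rpois(n * g, 50), n, g,
                           dimnames = list(sprintf("i%03d", seq_len(n)),
                                           sprintf("g%02d", seq_len(g)))),
                    stage = "counts")
}

toy_covariates <- function(n = 12, seed = 3) {
  set.seed(seed)
  covariate_table(sprintf("i%03d", seq_len(n)),
                  sex = rbinom(n, 1, 0.5),
                  education_years = sample(8:25, n, replace = TRUE),
                  age_at_death = runif(n, 65, 100))
}

# three pure-noise Gram blocks over the same individuals
noise_grams <- function(n, p, seed) {
  set.seed(seed)
  src <- c("genome", "transcriptome", "phenome")
  out <- lapply(1:3, function(j) {
    M <- matrix(rnorm(n * p), n, p)
    rownames(M) <- sprintf("i%04d", seq_len(n))
    gram_matrix(M, source = src[j])
  })
  names(out) <- c("K_G", "K_T", "K_P")
  out
}

# Score triple with exact sample correlations, built from an orthonormal
# (under the sample inner product) mean-zero basis.
exact_cor_scores <- function(r_gt, r_tp, r_gp, n = 100, seed = 11) {
  set.seed(seed)
  M <- scale(matrix(rnorm(n * 3), n, 3), scale = FALSE)
  Q <- qr.Q(qr(M)) * sqrt(n - 1)  # cor(Q) = I, var = 1, mean = 0
  g <- Q[, 1]
  t_ <- r_gt * Q[, 1] + sqrt(1 - r_gt^2) * Q[, 2]
  b <- (r_tp - r_gt * r_gp) / sqrt(1 - r_gt^2)
  stopifnot(r_gp^2 + b^2 < 1)
  p <- r_gp * Q[, 1] + b * Q[, 2] + sqrt(1 - r_gp^2 - b^2) * Q[, 3]
  list(g = g, t = t_, p = p)
}

# small synthetic study for fast fits
small_config <- function(seed, n = 100, n_genes = 200, n_snps = 200,
                         ...) {
  synthetic_config(n = n, n_genes = n_genes, n_snps = n_snps,
                   n_causal_snps = 30, seed = seed, ...)
}

fit_small <- function(seed, n = 100, ...) {
  sim <- simulate_dataset(small_config(seed, n = n))
  b <- suppressMessages(prepare_blocks(sim$counts, sim$covariates,
                                       sim$phenotypes,
                                       genotypes = sim$genotypes))
  list(fit = fit_hdma(b$K_G, b$K_T, b$K_P, X = b$X, P = b$P, ...),
       blocks = b, sim = sim)
}
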