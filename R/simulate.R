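#' Configuration for the synthetic cohort generator
#'
#' Defines a ROSMAP-like study: a cohort with some close relatives, a
#' heritable latent mediator carried by a sparse transcriptomic signature,
#' and five correlated clinical outcomes (four ordinal scales plus MMSE).
#' Defaults realize the mediation chain at the scale the fit is meant to
#' recover: 477 individuals, path coefficients \eqn{\alpha = 0.85} and
#' \eqn{\beta = 0.34}, 2000 genes of which 10% load on the mediator.
#'
#' @param n Cohort size.
#' @param n_snps Number of genotyped SNPs.
#' @param n_genes Number of genes.
#' @param n_causal_snps SNPs contributing to the latent genetic score.
#' @param alpha,beta True structural path coefficients in (-1, 1).
#' @param loading_fraction Share of genes with non-zero true loading.
#' @param loading_scale Upper bound of the non-zero |loading| range; the
#'   non-zero loadings are drawn uniformly from
#'   `(loading_scale/2, loading_scale)` with random sign.
#' @param covariate_effects Named sd of the per-gene covariate effects
#'   (on the standardized covariates), for `sex`, `education_years`,
#'   `age_at_death`.
#' @param ordinal_reliability Correlation of each clinical variable's
#'   latent copy with the phenome latent `p*`.
#' @param thresholds Named list of strictly increasing quantile cut
#'   points for the ordinal scales (defaults: evenly spaced).
#' @param family_block_size Individuals per sibship; 1 = unrelated cohort.
#' @param nb_dispersion Negative-binomial dispersion of the counts
#'   (`size = 1/nb_dispersion`).
#' @param base_log_mean_range Range of per-gene baseline log count means.
#' @param maf_range Minor allele frequency range, inside (0.05, 0.5).
#' @param seed Mandatory integer seed.
#' @return A validated `synthetic_config` list.
#' @export
synthetic_config <- function(n = 477, n_snps = 1000, n_genes = 2000,
                             n_causal_snps = 100, alpha = 0.85, beta = 0.34,
                             loading_fraction = 0.10, loading_scale = 0.8,
                             covariate_effects = c(sex = 0.2,
                                                   education_years = 0.02,
                                                   age_at_death = 0.01),
                             ordinal_reliability = 0.7,
                             thresholds = NULL,
                             family_block_size = 4, nb_dispersion = 0.1,
                             base_log_mean_range = log(c(50, 500)),
                             maf_range = c(0.1, 0.4), seed) {
  stop_if(missing(seed) || is.null(seed), "seed is mandatory")
  if (is.null(thresholds))
    thresholds <- list(braak = (1:6) / 7, cerad = (1:3) / 4,
                       cog_lv = (1:5) / 6, cog_death = (1:5) / 6)
  cfg <- list(n = n, n_snps = n_snps, n_genes = n_genes,
              n_causal_snps = n_causal_snps, alpha = alpha, beta = beta,
              loading_fraction = loading_fraction,
              loading_scale = loading_scale,
              covariate_effects = covariate_effects,
              ordinal_reliability = ordinal_reliability,
              thresholds = thresholds,
              family_block_size = family_block_size,
              nb_dispersion = nb_dispersion,
              base_log_mean_range = base_log_mean_range,
              maf_range = maf_range, seed = as.integer(seed))
  stop_if(abs(alpha) >= 1 || abs(beta) >= 1,
          "alpha and beta must lie in (-1, 1)")
  for (f in c("loading_scale", "ordinal_reliability"))
    stop_if(cfg[[f]] <= 0 || cfg[[f]] > 1, f, " must be in (0, 1]")
  stop_if(loading_fraction < 0 || loading_fraction > 1,
          "loading_fraction must be in [0, 1] (0 = no mediating signature)")
  stop_if(n_causal_snps > n_snps, "n_causal_snps cannot exceed n_snps")
  stop_if(maf_range[1] < 0.05 || maf_range[2] > 0.5 ||
            maf_range[1] >= maf_range[2],
          "maf_range must be increasing inside (0.05, 0.5)")
  for (v in names(cfg$thresholds))
    stop_if(any(diff(cfg$thresholds[[v]]) <= 0),
            "thresholds for ", v, " must be strictly increasing")
  structure(cfg, class = "synthetic_config")
}

#' Simulate a genotype dosage matrix with optional family structure
#'
#' Baseline dosages are Binomial(2, maf) per SNP. With
#' `family_block_size > 1` the cohort is partitioned into sibships: each
#' block draws four parental haplotypes and every member inherits one
#' allele per parent, so realized kinship is elevated within blocks
#' (expected GRM kinship ~0.5 between full sibs on the relationship
#' scale) and ~0 between blocks.
#'
#' @param n Individuals.
#' @param m SNPs.
#' @param maf_range Minor allele frequency range inside (0.05, 0.5).
#' @param family_block_size Sibship size (1 = unrelated).
#' @param seed Integer seed.
#' @return A [genotype_matrix()].
#' @export
simulate_genotypes <- function(n, m, maf_range = c(0.1, 0.4),
                               family_block_size = 1, seed) {
  stop_if(maf_range[1] < 0.05 || maf_range[2] > 0.5 ||
            maf_range[1] >= maf_range[2],
          "maf_range must be increasing inside (0.05, 0.5)")
  with_seed(seed, sim_genotypes_impl(n, m, maf_range, family_block_size))
}

sim_genotypes_impl <- function(n, m, maf_range, family_block_size) {
  maf <- stats::runif(m, maf_range[1], maf_range[2])
  G <- matrix(0L, n, m)
  b <- max(1L, as.integer(family_block_size))
  starts <- seq(1L, n, by = b)
  for (s in starts) {
    members <- s:min(s + b - 1L, n)
    if (length(members) == 1L || b == 1L) {
      for (i in members)
        G[i, ] <- stats::rbinom(m, 2L, maf)
    } else {
      # four parental haplotypes; each sib inherits one allele per parent,
      # transmission independent per SNP (no linkage is modeled)
      hp <- matrix(stats::rbinom(4L * m, 1L, rep(maf, each = 4L)), 4L, m)
      for (i in members) {
        pick1 <- stats::rbinom(m, 1L, 0.5)
        pick2 <- stats::rbinom(m, 1L, 0.5)
        a1 <- ifelse(pick1 == 1L, hp[1L, ], hp[2L, ])
        a2 <- ifelse(pick2 == 1L, hp[3L, ], hp[4L, ])
        G[i, ] <- a1 + a2
      }
    }
  }
  genotype_matrix(G,
                  individual_ids = sprintf("ind_%04d", seq_len(n)),
                  snp_ids = sprintf("snp_%05d", seq_len(m)))
}

#' Simulate a full synthetic cohort with ground truth
#'
#' Generates the four raw data tables the analysis consumes plus the
#' latent truth, realizing the structural equations of the mediation
#' model: a latent genetic score `g*` (standardized weighted sum of
#' causal SNP dosages), the mediator `t* = alpha g* + sqrt(1-alpha^2) e`,
#' gene-level log expression `w_j t* + sqrt(1-w_j^2) e_ij` plus covariate
#' effects realized as negative-binomial counts, the phenome latent
#' `p* = beta t* + sqrt(1-beta^2) d`, and clinical outcomes as
#' variable-specific noisy copies of `p*` cut at configured quantiles
#' (Braak, Cog LV, Cog death increasing with severity; CERAD and MMSE
#' inverted, matching their clinical coding).
#'
#' @param config A [synthetic_config()].
#' @return List with `genotypes`, `counts` (an `expression_matrix`),
#'   `phenotypes`, `covariates`, and `truth` (latents `g_star`, `t_star`,
#'   `p_star`, loading vector `w`, `alpha`, `beta`, `causal_snp_ids`).
#' @export
simulate_dataset <- function(config) {
  stop_if(!inherits(config, "synthetic_config"),
          "config must come from synthetic_config()")
  with_seed(config$seed, simulate_dataset_impl(config))
}

simulate_dataset_impl <- function(cfg) {
  n <- cfg$n
  G <- sim_genotypes_impl(n, cfg$n_snps, cfg$maf_range,
                          cfg$family_block_size)
  ids <- rownames(G)

  causal <- sort(sample.int(cfg$n_snps, cfg$n_causal_snps))
  u <- stats::rnorm(cfg$n_causal_snps)
  g_star <- normalize_score(as.vector(unclass(G)[, causal, drop = FALSE] %*% u))
  t_star <- cfg$alpha * g_star +
    sqrt(1 - cfg$alpha^2) * stats::rnorm(n)

  w <- numeric(cfg$n_genes)
  n_sig <- round(cfg$loading_fraction * cfg$n_genes)
  if (n_sig > 0L) {
    sig <- sample.int(cfg$n_genes, n_sig)
    w[sig] <- sample(c(-1, 1), n_sig, replace = TRUE) *
      stats::runif(n_sig, cfg$loading_scale / 2, cfg$loading_scale)
  }

  sex <- stats::rbinom(n, 1L, 0.5)
  edu <- pmax(0, round(stats::rnorm(n, 16, 3)))
  age <- pmin(pmax(stats::rnorm(n, 85, 6), 60), 105)
  cov_std <- scale(cbind(sex = sex, education_years = edu,
                         age_at_death = age))

  eff <- vapply(names(cfg$covariate_effects), function(cv)
    stats::rnorm(cfg$n_genes, 0, cfg$covariate_effects[[cv]]),
    numeric(cfg$n_genes))
  latent <- tcrossprod(t_star, w) +
    matrix(stats::rnorm(n * cfg$n_genes), n) %*%
      diag(sqrt(1 - w^2), cfg$n_genes) +
    cov_std %*% t(eff)

  b0 <- stats::runif(cfg$n_genes, cfg$base_log_mean_range[1],
                     cfg$base_log_mean_range[2])
  mu <- exp(sweep(latent, 2L, b0, "+"))
  counts <- matrix(stats::rnbinom(length(mu), mu = mu,
                                  size = 1 / cfg$nb_dispersion),
                   n, cfg$n_genes)
  dimnames(counts) <- list(ids, sprintf("gene_%05d", seq_len(cfg$n_genes)))

  p_star <- cfg$beta * t_star + sqrt(1 - cfg$beta^2) * stats::rnorm(n)
  rel <- cfg$ordinal_reliability
  noisy <- function() rel * p_star + sqrt(1 - rel^2) * stats::rnorm(n)
  cut_levels <- function(z, qs, levels)
    levels[findInterval(z, stats::qnorm(qs)) + 1L]

  braak <- cut_levels(noisy(), cfg$thresholds$braak, 0:6)
  cerad <- cut_levels(-noisy(), cfg$thresholds$cerad, 1:4)
  cog_lv <- cut_levels(noisy(), cfg$thresholds$cog_lv, 1:6)
  cog_death <- cut_levels(noisy(), cfg$thresholds$cog_death, 1:6)
  mmse <- round(pmin(pmax(25 - 5 * noisy(), 0), 30))

  list(genotypes = G,
       counts = expression_matrix(counts, stage = "counts"),
       phenotypes = phenotype_table(ids, mmse, braak, cerad, cog_lv,
                                    cog_death),
       covariates = covariate_table(ids, sex, edu, age),
       truth = list(g_star = stats::setNames(g_star, ids),
                    t_star = stats::setNames(t_star, ids),
                    p_star = stats::setNames(p_star, ids),
                    w = stats::setNames(w, colnames(counts)),
                    alpha = cfg$alpha, beta = cfg$beta,
                    causal_snp_ids = colnames(G)[causal]))
}
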