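#!/usr/bin/env Rscript
# Stage 5: parameter-recovery study.
#
# Repeats simulate -> preprocess -> fit over independent seeds at the
# default study conditions (n = 477, alpha = 0.85, beta = 0.34) and over
# weaker mediation settings, summarizing how well the fitted score
# correlations and gene loadings recover the generative truth. Writes
# results/recovery.tsv.

suppressPackageStartupMessages(library(hdmediate))

n_seeds <- 10L
settings <- list(c(alpha = 0.85, beta = 0.34),
                 c(alpha = 0.60, beta = 0.34),
                 c(alpha = 0.30, beta = 0.34))

rows <- list()
for (s in settings) {
  for (i in seq_len(n_seeds)) {
    cfg <- synthetic_config(alpha = s[["alpha"]], beta = s[["beta"]],
                            seed = 3000L + i)
    sim <- simulate_dataset(cfg)
    b <- suppressMessages(prepare_blocks(sim$counts, sim$covariates,
                                         sim$phenotypes,
                                         genotypes = sim$genotypes))
    fit <- fit_hdma(b$K_G, b$K_T, b$K_P, X = b$X, P = b$P)
    rows[[length(rows) + 1L]] <- data.frame(
      true_alpha = s[["alpha"]], true_beta = s[["beta"]], seed = cfg$seed,
      alpha_hat = fit$alpha, beta_hat = fit$beta,
      loading_recovery = unname(cor(fit$gene_loadings, sim$truth$w)))
  }
}
tab <- do.call(rbind, rows)
dir.create("results", showWarnings = FALSE)
write.table(tab, "results/recovery.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

agg <- aggregate(cbind(alpha_hat, beta_hat, loading_recovery) ~
                   true_alpha + true_beta, tab, mean)
cat("Mean recovery over", n_seeds, "seeds per setting:\n")
print(round(agg, 3), row.names = FALSE)
cat("\nGene-loading recovery stays high across settings. The fitted\n")
cat("genome-transcriptome correlation tracks the generative value at\n")
cat("strong mediation but is upward-biased when the true path is weak:\n")
cat("with kinship estimated from m SNPs, any score built through K_G\n")
cat("carries a geometric alignment floor of roughly 1/sqrt(1 + n/m)\n")
cat("(about 0.82 at n = 477, m = 1000) regardless of the true path.\n")
cat("Fitted score correlations should therefore be read as upper bounds\n")
cat("on mediated heritability, not unbiased estimates.\n")
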