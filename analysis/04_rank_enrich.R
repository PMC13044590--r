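#!/usr/bin/env Rscript
# Stage 4: gene ranking and preranked enrichment.
#
# Orders genes by transcript loading into descending (up-regulated with
# severity) and ascending (down-regulated) lists, writes RNK files and
# the top-150 query lists, and runs permutation enrichment against a
# small synthetic gene-set collection built from the generative truth
# (a real analysis would supply curated GMT collections here).

suppressPackageStartupMessages(library(hdmediate))

gl_tab <- read_matrix_tsv("results/run/fit/gene_loadings.tsv")
gl <- setNames(gl_tab[, "loading"], rownames(gl_tab))
truth <- jsonlite::read_json("results/run/sim/truth.json")

up <- rank_genes(gl, "descending")
down <- rank_genes(gl, "ascending")
dir.create("results/run/rank", showWarnings = FALSE, recursive = TRUE)
write_rnk(up, "results/run/rank/genes_descending.rnk")
write_rnk(down, "results/run/rank/genes_ascending.rnk")
write_grp(top_k(up, 150), "results/run/rank/top_up.grp")
write_grp(top_k(down, 150), "results/run/rank/top_down.grp")

# synthetic gene-set collection: the true up- and down-signature genes
# plus size-matched random sets as negative controls
sim <- simulate_dataset(synthetic_config(seed = 2026L))
w <- sim$truth$w
sets <- list(true_up_signature = names(w)[w > 0.4],
             true_down_signature = names(w)[w < -0.4])
set.seed(1)
for (i in 1:8)
  sets[[sprintf("random_%02d", i)]] <- sample(names(w), 60)
dir.create("results/run/enrich", showWarnings = FALSE, recursive = TRUE)
write_gmt(sets, "results/run/enrich/synthetic_sets.gmt")

res <- permutation_nes(up, sets, B = 1000, weight_exponent = 1,
                       seed = 2026)
write.table(res[, setdiff(names(res), "leading_edge")],
            "results/run/enrich/enrichment_up.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

cat("Enrichment of the descending (up-with-severity) list:\n")
print(res[order(res$p_value), c("set", "size", "es", "nes", "p_value",
                                "p_adjust")],
      row.names = FALSE, digits = 3)
cat("\nThe planted up-signature should lead with NES > 1 and minimal p;\n")
cat("random control sets should be non-significant after adjustment.\n")
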