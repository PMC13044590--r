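#' Prepare the three aligned similarity blocks from raw tables
#'
#' Runs the full preprocessing path: kinship (computed from genotypes or
#' supplied directly), expression log transform, covariate adjustment and
#' standardization, ordinal phenotype encoding, individual alignment
#' (sorted common ids; rows with missing values are rejected by the table
#' constructors upstream), and Gram construction for the transcriptome
#' and phenome blocks.
#'
#' @param counts An `expression_matrix` at stage `"counts"`.
#' @param covariates Covariate `data.frame` ([covariate_table()]).
#' @param phenotypes Phenotype `data.frame` ([phenotype_table()]).
#' @param genotypes Optional [genotype_matrix()] (used when `kinship` is
#'   not supplied).
#' @param kinship Optional pre-computed kinship matrix.
#' @param kinship_method Estimator passed to [compute_kinship()].
#' @param pseudocount,log_base Passed to [log_transform()].
#' @param encoding_spec Passed to [encode_phenotypes()].
#' @return List with `K_G`, `K_T`, `K_P`, the standardized expression
#'   `X`, encoded phenotypes `P`, and the aligned `individual_ids`.
#' @export
prepare_blocks <- function(counts, covariates, phenotypes,
                           genotypes = NULL, kinship = NULL,
                           kinship_method = "grm",
                           pseudocount = 1, log_base = 2,
                           encoding_spec = default_encoding_spec()) {
  stop_if(is.null(genotypes) && is.null(kinship),
          "supply either genotypes or a kinship matrix")
  if (is.null(kinship))
    kinship <- compute_kinship(genotypes, method = kinship_method)
  ids <- align_individuals(rownames(kinship), rownames(counts),
                           covariates$individual_id,
                           phenotypes$individual_id)
  n_in <- max(nrow(kinship), nrow(counts), nrow(covariates),
              nrow(phenotypes))
  if (length(ids) < n_in)
    message(length(ids), " individuals common to all blocks (",
            n_in - length(ids), " dropped)")
  K_G <- unclass(kinship)[ids, ids]
  counts <- expression_matrix(unclass(counts)[ids, , drop = FALSE],
                              stage = "counts")
  covariates <- covariates[match(ids, covariates$individual_id), ,
                           drop = FALSE]
  phenotypes <- phenotypes[match(ids, phenotypes$individual_id), ,
                           drop = FALSE]
  X <- standardize_columns(adjust_covariates(
    log_transform(counts, pseudocount = pseudocount, base = log_base),
    covariates))
  P <- encode_phenotypes(phenotypes, spec = encoding_spec)
  list(K_G = K_G,
       K_T = gram_matrix(unclass(X), source = "transcriptome"),
       K_P = gram_matrix(P, source = "phenome"),
       X = X, P = P, individual_ids = ids)
}

#' Default pipeline configuration
#'
#' @param out_dir Run directory (created if absent).
#' @param seed Integer seed echoed into every stage.
#' @param stages Stages to run, a subset of
#'   `c("simulate", "preprocess", "fit", "rank", "enrich")` in that order.
#' @param sim A [synthetic_config()] (defaults to
#'   `synthetic_config(seed = seed)`); ignored when `"simulate"` is not
#'   among the stages and input paths are given instead.
#' @param inputs Named list of input TSV paths (`genotypes` or `kinship`,
#'   `counts`, `covariates`, `phenotypes`) for runs that skip simulation.
#' @param kinship_method,pseudocount Preprocessing options.
#' @param scheme,tol,max_iter,ridge Fit options (see [fit_hdma()]).
#' @param top_k Size of the up/down query gene lists.
#' @param gmt Optional GMT path enabling the enrichment stage.
#' @param permutations,weight_exponent Enrichment options.
#' @return A `run_config` list.
#' @export
default_run_config <- function(out_dir, seed,
                               stages = c("simulate", "preprocess", "fit",
                                          "rank"),
                               sim = NULL, inputs = NULL,
                               kinship_method = "grm", pseudocount = 1,
                               scheme = "covariance", tol = 1e-8,
                               max_iter = 500, ridge = 1e-8,
                               top_k = 150, gmt = NULL,
                               permutations = 1000, weight_exponent = 1) {
  if (is.null(sim)) sim <- synthetic_config(seed = seed)
  structure(list(out_dir = out_dir, seed = as.integer(seed),
                 stages = stages, sim = sim, inputs = inputs,
                 kinship_method = kinship_method,
                 pseudocount = pseudocount, scheme = scheme, tol = tol,
                 max_iter = max_iter, ridge = ridge, top_k = top_k,
                 gmt = gmt, permutations = permutations,
                 weight_exponent = weight_exponent),
            class = "run_config")
}

#' Run the analysis pipeline
#'
#' Executes the configured stages in order — simulate, preprocess, fit,
#' rank, enrich — writing each stage's artifacts under its own
#' subdirectory of `config$out_dir` and a `manifest.json` listing every
#' artifact with its md5 content hash. Reruns with the same configuration
#' and seed reproduce identical hashes. A failing stage aborts with the
#' stage named; artifacts of completed stages are retained.
#'
#' @param config A `run_config` from [default_run_config()].
#' @return Invisibly, a list with the run directory, the manifest, and
#'   in-memory results of the stages that ran.
#' @export
run_pipeline <- function(config) {
  stop_if(!inherits(config, "run_config"),
          "config must come from default_run_config()")
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  state <- list()
  add <- function(path) files <<- c(files, path)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  if ("simulate" %in% config$stages) stage("simulate", {
    d <- file.path(config$out_dir, "sim")
    dir.create(d, showWarnings = FALSE)
    sim <- simulate_dataset(config$sim)
    add(write_matrix_tsv(unclass(sim$genotypes),
                         file.path(d, "genotypes.tsv")))
    add(write_matrix_tsv(unclass(sim$counts), file.path(d, "counts.tsv")))
    utils::write.table(sim$covariates, file.path(d, "covariates.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    add(file.path(d, "covariates.tsv"))
    utils::write.table(sim$phenotypes, file.path(d, "phenotypes.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    add(file.path(d, "phenotypes.tsv"))
    truth <- sim$truth
    jsonlite::write_json(
      list(alpha = truth$alpha, beta = truth$beta,
           causal_snp_ids = truth$causal_snp_ids,
           seed = config$sim$seed),
      file.path(d, "truth.json"), auto_unbox = TRUE, digits = NA)
    add(file.path(d, "truth.json"))
    state$sim <- sim
    state <<- state
  })

  if ("preprocess" %in% config$stages) stage("preprocess", {
    d <- file.path(config$out_dir, "prep")
    dir.create(d, showWarnings = FALSE)
    if (!is.null(state$sim)) {
      blocks <- prepare_blocks(state$sim$counts, state$sim$covariates,
                               state$sim$phenotypes,
                               genotypes = state$sim$genotypes,
                               kinship_method = config$kinship_method,
                               pseudocount = config$pseudocount)
    } else {
      inp <- config$inputs
      stop_if(is.null(inp), "no simulated data and no input paths")
      for (p in unlist(inp)) stop_if(!file.exists(p), "missing input: ", p)
      kin <- if (!is.null(inp$kinship)) read_kinship_tsv(inp$kinship)
      gen <- if (!is.null(inp$genotypes))
        genotype_matrix(read_matrix_tsv(inp$genotypes))
      cov_d <- utils::read.delim(inp$covariates, stringsAsFactors = FALSE)
      phe_d <- utils::read.delim(inp$phenotypes, stringsAsFactors = FALSE)
      blocks <- prepare_blocks(
        expression_matrix(read_matrix_tsv(inp$counts), stage = "counts"),
        covariate_table(cov_d$individual_id, cov_d$sex,
                        cov_d$education_years, cov_d$age_at_death),
        phenotype_table(phe_d$individual_id, phe_d$mmse, phe_d$braak,
                        phe_d$cerad, phe_d$cog_lv, phe_d$cog_death),
        genotypes = gen, kinship = kin,
        kinship_method = config$kinship_method,
        pseudocount = config$pseudocount)
    }
    add(write_matrix_tsv(blocks$K_G, file.path(d, "kinship.tsv")))
    add(write_matrix_tsv(unclass(blocks$X),
                         file.path(d, "expression_standardized.tsv")))
    add(write_matrix_tsv(blocks$P, file.path(d, "phenotypes_encoded.tsv")))
    state$blocks <- blocks
    state <<- state
  })

  if ("fit" %in% config$stages) stage("fit", {
    stop_if(is.null(state$blocks), "fit stage requires preprocess outputs")
    d <- file.path(config$out_dir, "fit")
    dir.create(d, showWarnings = FALSE)
    b <- state$blocks
    fit <- fit_hdma(b$K_G, b$K_T, b$K_P, scheme = config$scheme,
                    tol = config$tol, max_iter = config$max_iter,
                    ridge = config$ridge, seed = config$seed,
                    X = b$X, P = b$P)
    sc <- cbind(g = fit$scores$g, t = fit$scores$t, p = fit$scores$p)
    add(write_matrix_tsv(sc, file.path(d, "scores.tsv")))
    gl <- matrix(fit$gene_loadings, ncol = 1,
                 dimnames = list(names(fit$gene_loadings), "loading"))
    add(write_matrix_tsv(gl, file.path(d, "gene_loadings.tsv"),
                         id_name = "gene_id"))
    pl <- matrix(fit$phenotype_loadings, ncol = 1,
                 dimnames = list(names(fit$phenotype_loadings), "loading"))
    add(write_matrix_tsv(pl, file.path(d, "phenotype_loadings.tsv"),
                         id_name = "column"))
    cors <- score_correlations(fit)
    jsonlite::write_json(
      list(alpha = fit$alpha, beta = fit$beta,
           nll_trace = fit$nll_trace, converged = fit$converged,
           r_gt = cors$r_gt, r_tp = cors$r_tp, r_gp = cors$r_gp,
           r_expected = cors$r_expected,
           direct_effect = cors$direct_effect,
           seed = config$seed, options = fit$options),
      file.path(d, "fit_summary.json"), auto_unbox = TRUE, digits = NA)
    add(file.path(d, "fit_summary.json"))
    state$fit <- fit
    state <<- state
  })

  if ("rank" %in% config$stages) stage("rank", {
    stop_if(is.null(state$fit), "rank stage requires a fit")
    d <- file.path(config$out_dir, "rank")
    dir.create(d, showWarnings = FALSE)
    up <- rank_genes(state$fit$gene_loadings, "descending")
    down <- rank_genes(state$fit$gene_loadings, "ascending")
    add(write_rnk(up, file.path(d, "genes_descending.rnk")))
    add(write_rnk(down, file.path(d, "genes_ascending.rnk")))
    k <- min(config$top_k, nrow(up))
    add(write_grp(top_k(up, k), file.path(d, "top_up.grp")))
    add(write_grp(top_k(down, k), file.path(d, "top_down.grp")))
    state$rank <- list(up = up, down = down)
    state <<- state
  })

  if ("enrich" %in% config$stages) stage("enrich", {
    stop_if(is.null(state$rank), "enrich stage requires rankings")
    stop_if(is.null(config$gmt), "enrich stage requires a GMT path")
    d <- file.path(config$out_dir, "enrich")
    dir.create(d, showWarnings = FALSE)
    sets <- read_gmt(config$gmt)
    for (dir_ in c("up", "down")) {
      ranked <- if (dir_ == "up") state$rank$up else state$rank$down
      res <- permutation_nes(ranked, sets, B = config$permutations,
                             weight_exponent = config$weight_exponent,
                             seed = config$seed)
      f <- file.path(d, paste0("enrichment_", dir_, ".tsv"))
      utils::write.table(res, f, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      add(f)
    }
  })

  manifest <- list(seed = config$seed, stages = config$stages,
                   artifacts = lapply(stats::setNames(files, files),
                                      function(f) unname(tools::md5sum(f))))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(out_dir = config$out_dir, manifest = manifest,
                 state = state))
}
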