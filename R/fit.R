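#' Center and variance-normalize a score vector
#'
#' Scores are identified only up to scale, so each is reported with mean
#' zero and unit sample variance. For scores built from a column-centered
#' Gram matrix the centering is a no-op; it matters only for externally
#' supplied similarity matrices that are not row-centered.
#'
#' @param x Numeric score vector with non-zero variance.
#' @return Numeric vector with mean 0 (within 1e-10) and variance 1.
#' @export
normalize_score <- function(x) {
  stop_if(!is.numeric(x) || length(x) < 2L, "score must be a numeric vector")
  x <- x - mean(x)
  v <- var1(x)
  stop_if(v <= 0 || !is.finite(v), "score has zero variance")
  x / sqrt(v)
}

# --- internal sweep machinery -----------------------------------------------

ridge_lambda <- function(K, ridge) ridge * sum(diag(K)) / nrow(K)

# Recover a loading vector for a given score by the ridge-stabilized solve
# (K + lambda I) l = s. Exact up to the ridge when s lies in the column
# space of K.
recover_loading <- function(K, s, ridge = 1e-8) {
  solve(K + diag(ridge_lambda(K, ridge), nrow(K)), s)
}

#' One block-coordinate GCCA sweep
#'
#' Updates the three loading/score pairs in the fixed order genome,
#' transcriptome, phenome. Each block maximizes the weighted covariance of
#' its score with the weighted sum of the other blocks' current scores,
#' \eqn{z_j = \sum_k w_{jk} s_k}, under the scheme's normalization:
#'
#' * `"covariance"`: loading norm constraint \eqn{l^T K l = 1}, giving the
#'   update \eqn{s \propto K z} — the Horst/mode-A update of regularized
#'   generalized canonical correlation analysis. Directions are weighted by
#'   the block's variance spectrum, which keeps the fit well-posed when the
#'   Gram matrix is full rank.
#' * `"correlation"`: unit score variance with the score confined to the
#'   Gram column space, giving the ridge-stabilized projection
#'   \eqn{s \propto K (K + \lambda I)^{-1} z}. This is the exact
#'   per-block minimizer of the mediation likelihood, appropriate when the
#'   Gram matrices are low-rank relative to the cohort size.
#'
#' A block whose target is (numerically) orthogonal to its column space
#' keeps its previous score with a warning. The sweep never decreases its
#' weighted-covariance objective.
#'
#' @param K_G,K_T,K_P Column-centered symmetric similarity matrices over
#'   the same ordered individuals.
#' @param weights 3 x 3 connection weight matrix from
#'   [connection_weights()].
#' @param scores List of three score vectors `g`, `t`, `p`.
#' @param loadings Optional list of matching loading vectors; recovered by
#'   ridge solve when omitted.
#' @param scheme `"covariance"` or `"correlation"` (see above).
#' @param ridge Relative ridge for stabilized solves.
#' @return List with updated `scores`, `loadings`, and the
#'   weighted-covariance `objective`.
#' @export
gcca_sweep <- function(K_G, K_T, K_P, weights, scores, loadings = NULL,
                       scheme = c("covariance", "correlation"),
                       ridge = 1e-8) {
  scheme <- match.arg(scheme)
  Ks <- list(K_G, K_T, K_P)
  n <- nrow(K_G)
  if (is.null(loadings))
    loadings <- lapply(1:3, function(j) recover_loading(Ks[[j]], scores[[j]], ridge))
  # bring incoming state onto the scheme's normalization
  for (j in 1:3) {
    cj <- if (scheme == "covariance") {
      sqrt(max(sum(loadings[[j]] * scores[[j]]), .Machine$double.eps))
    } else {
      sd_ <- sqrt(var1(scores[[j]]))
      if (sd_ <= 0) 1 else sd_
    }
    scores[[j]] <- scores[[j]] / cj
    loadings[[j]] <- loadings[[j]] / cj
  }
  for (j in 1:3) {
    z <- numeric(n)
    for (k in 1:3) if (k != j) z <- z + weights[j, k] * scores[[k]]
    if (scheme == "covariance") {
      q <- sum(z * (Ks[[j]] %*% z))
      if (q <= n * .Machine$double.eps) {
        warning("block ", j, ": target orthogonal to block space; ",
                "keeping previous score")
        next
      }
      loadings[[j]] <- z / sqrt(q)
      scores[[j]] <- as.vector(Ks[[j]] %*% loadings[[j]])
    } else {
      u <- recover_loading(Ks[[j]], z, ridge)
      s_raw <- as.vector(Ks[[j]] %*% u)
      s_raw <- s_raw - mean(s_raw)
      v <- var1(s_raw)
      if (v <= n * .Machine$double.eps^2) {
        warning("block ", j, ": target orthogonal to block space; ",
                "keeping previous score")
        next
      }
      loadings[[j]] <- u / sqrt(v)
      scores[[j]] <- s_raw / sqrt(v)
    }
  }
  obj <- weights[1, 2] * sum(scores[[1]] * scores[[2]]) +
    weights[2, 3] * sum(scores[[2]] * scores[[3]]) +
    weights[1, 3] * sum(scores[[1]] * scores[[3]])
  list(scores = stats::setNames(scores, c("g", "t", "p")),
       loadings = stats::setNames(loadings, c("l_G", "l_T", "l_P")),
       objective = obj / (n - 1))
}

#' Fit the high-dimensional perfect-mediation model
#'
#' Alternates two half-steps until the negative log-likelihood
#' \eqn{L = \mathrm{tr}(S\Sigma^{-1}) + \log\det\Sigma} stabilizes:
#' (1) given the current score correlation matrix `S`, the structural
#' parameters \eqn{(\alpha, \beta)} are re-estimated by bounded
#' minimization ([fit_structural_params()]); (2) given
#' \eqn{(\alpha, \beta)}, the loading vectors are improved by one
#' generalized canonical correlation sweep ([gcca_sweep()]) with
#' connection weights \eqn{-\mathrm{offdiag}(\Sigma^{-1})}. A sweep that
#' would increase the likelihood criterion is rejected and the fit stops,
#' so the recorded `nll_trace` is nonincreasing by construction.
#'
#' Scores are initialized at the leading eigenvector of each centered
#' similarity matrix (sign-canonicalized, hence deterministic); optional
#' extra random restarts are drawn behind `seed` and the best final
#' likelihood is kept. On return the sign indeterminacy is resolved
#' deterministically (\eqn{\hat\alpha \ge 0}, \eqn{\hat\beta \ge 0}, and
#' the whole triple oriented so the phenome score increases with clinical
#' severity when `P` is supplied); scores are centered and scaled to unit
#' variance; and loadings are recovered by the ridge-stabilized solve
#' `K l = score`.
#'
#' @param K_G Kinship (genome similarity) matrix.
#' @param K_T Transcriptome Gram matrix.
#' @param K_P Phenome Gram matrix. All three must cover the same
#'   individuals in the same order.
#' @param scheme Loading update scheme, see [gcca_sweep()].
#' @param tol Relative NLL change declaring convergence.
#' @param max_iter Maximum outer iterations.
#' @param ridge Relative ridge for stabilized solves.
#' @param n_starts Number of starts (1 deterministic + `n_starts - 1`
#'   random).
#' @param seed Seed for the random restarts (required if `n_starts > 1`).
#' @param X Optional standardized expression matrix; populates
#'   `gene_loadings` via [gene_loadings()].
#' @param P Optional encoded phenotype matrix; populates
#'   `phenotype_loadings` via [phenotype_loadings()].
#' @return An object of class `hdma_fit`: list with `scores` (`g`, `t`,
#'   `p`; mean 0, variance 1), `loadings` (`l_G`, `l_T`, `l_P`), `alpha`,
#'   `beta`, `nll_trace`, `converged`, `n_iter`, `gene_loadings`,
#'   `phenotype_loadings`, and the options used.
#' @export
fit_hdma <- function(K_G, K_T, K_P,
                     scheme = c("covariance", "correlation"),
                     tol = 1e-8, max_iter = 500, ridge = 1e-8,
                     n_starts = 1, seed = NULL, X = NULL, P = NULL) {
  scheme <- match.arg(scheme)
  Ks <- lapply(list(K_G, K_T, K_P), as.matrix)
  n <- nrow(Ks[[1]])
  for (K in Ks) {
    stop_if(nrow(K) != ncol(K), "similarity matrices must be square")
    stop_if(nrow(K) != n, "similarity matrices must have equal dimensions")
  }
  ids <- rownames(Ks[[1]])
  if (!is.null(ids)) {
    for (K in Ks[2:3])
      stop_if(!identical(rownames(K), ids),
              "individual ids do not match across the three blocks")
  }
  Kc <- lapply(Ks, function(K) {
    K <- center_gram((K + t(K)) / 2)
    (K + t(K)) / 2
  })

  stop_if(n_starts > 1 && is.null(seed),
          "seed is required for random restarts")
  inits <- list(eigen_init(Kc))
  if (n_starts > 1) {
    extra <- with_seed(seed, lapply(seq_len(n_starts - 1), function(i)
      lapply(Kc, function(K) as.vector(K %*% stats::rnorm(n)))))
    inits <- c(inits, extra)
  }

  best <- NULL
  for (init in inits) {
    run <- hdma_run(Kc, init, scheme, tol, max_iter, ridge)
    if (is.null(best) || run$nll < best$nll) best <- run
  }

  scores <- best$scores
  # Resolve the sign indeterminacy. Flipping any single block's score and
  # loading leaves the likelihood unchanged (the (g,p) cell never enters),
  # so orient: alpha >= 0 (flip g against t), beta >= 0 (flip p against t),
  # and, when the encoded phenome block is available, the whole triple so
  # that the phenome score increases with clinical severity (rank sum over
  # the ordinal dummy columns).
  if (stats::cor(scores[[1]], scores[[2]]) < 0) scores[[1]] <- -scores[[1]]
  if (stats::cor(scores[[2]], scores[[3]]) < 0) scores[[3]] <- -scores[[3]]
  if (!is.null(P)) {
    kind <- attr(P, "column_kind")
    dum <- if (!is.null(kind)) which(kind == "dummy") else integer(0)
    if (length(dum) > 0L) {
      sev <- rowSums(as.matrix(P)[, dum, drop = FALSE])
      if (stats::sd(sev) > 0 && stats::cor(scores[[3]], sev) < 0)
        scores <- lapply(scores, function(s) -s)
    }
  }
  scores <- lapply(scores, normalize_score)
  loadings <- lapply(1:3, function(j) {
    l <- recover_loading(Kc[[j]], scores[[j]], ridge)
    if (!is.null(ids)) names(l) <- ids
    l
  })
  if (!is.null(ids)) scores <- lapply(scores, stats::setNames, ids)
  S <- stats::cor(cbind(g = scores[[1]], t = scores[[2]], p = scores[[3]]))
  sp <- fit_structural_params(S)

  fit <- structure(list(
    scores = stats::setNames(scores, c("g", "t", "p")),
    loadings = stats::setNames(loadings, c("l_G", "l_T", "l_P")),
    alpha = sp$alpha, beta = sp$beta,
    nll_trace = best$nll_trace, converged = best$converged,
    n_iter = best$n_iter,
    gene_loadings = NULL, phenotype_loadings = NULL,
    options = list(scheme = scheme, tol = tol, max_iter = max_iter,
                   ridge = ridge, n_starts = n_starts, seed = seed)),
    class = "hdma_fit")
  if (!is.null(X)) fit$gene_loadings <- gene_loadings(X, fit$scores$t)
  if (!is.null(P)) {
    # the all-ones lowest-level dummies are constant by construction;
    # drop them silently rather than re-warning on every fit
    Pm <- as.matrix(P)
    Pk <- Pm[, apply(Pm, 2L, stats::sd) > 0, drop = FALSE]
    fit$phenotype_loadings <- phenotype_loadings(Pk, fit$scores$p)
  }
  fit
}

# Leading-direction initialization by fixed-count power iteration from a
# permutation-equivariant start vector (squared row norms, centered).
# Unlike eigen(), whose output for near-degenerate spectra depends on the
# row order, this makes fits exactly equivariant under permutation of
# individuals up to floating-point noise.
eigen_init <- function(Kc, iterations = 60L) {
  lapply(Kc, function(K) {
    v <- rowSums(K^2)
    v <- v - mean(v)
    if (sqrt(sum(v^2)) < .Machine$double.eps * nrow(K))
      v <- K[, which.max(diag(K))]
    for (i in seq_len(iterations)) {
      v2 <- as.vector(K %*% v)
      nv <- sqrt(sum(v2^2))
      if (nv < .Machine$double.eps) break
      v <- v2 / nv
    }
    v * sign(v[which.max(abs(v))])  # permutation-stable sign fix
  })
}

hdma_run <- function(Kc, init, scheme, tol, max_iter, ridge) {
  scores <- lapply(init, function(s) normalize_score(s))
  loadings <- NULL
  nll_trace <- numeric(0)
  converged <- FALSE
  prev_state <- NULL
  iter <- 0L
  repeat {
    S <- stats::cor(cbind(scores[[1]], scores[[2]], scores[[3]]))
    sp <- fit_structural_params(S)
    if (length(nll_trace) > 0L && sp$nll > utils::tail(nll_trace, 1L) + 1e-12) {
      # monotone acceptance: reject the last sweep, keep the previous state
      scores <- prev_state$scores
      loadings <- prev_state$loadings
      sp <- prev_state$sp
      converged <- TRUE
      break
    }
    nll_trace <- c(nll_trace, sp$nll)
    if (length(nll_trace) >= 2L) {
      d <- abs(nll_trace[length(nll_trace) - 1L] - sp$nll)
      if (d / max(1, abs(sp$nll)) < tol) {
        converged <- TRUE
        break
      }
    }
    if (iter >= max_iter) break
    iter <- iter + 1L
    prev_state <- list(scores = scores, loadings = loadings, sp = sp)
    W <- connection_weights(sp$alpha, sp$beta)
    sw <- gcca_sweep(Kc[[1]], Kc[[2]], Kc[[3]], W, scores, loadings,
                     scheme = scheme, ridge = ridge)
    scores <- sw$scores
    loadings <- sw$loadings
  }
  list(scores = scores, loadings = loadings, nll = utils::tail(nll_trace, 1L),
       nll_trace = nll_trace, converged = converged, n_iter = iter)
}

#' @export
print.hdma_fit <- function(x, ...) {
  cat("High-dimensional mediation fit (", x$options$scheme, " scheme)\n",
      sep = "")
  cat(sprintf("  alpha (genome -> transcriptome): %.4f\n", x$alpha))
  cat(sprintf("  beta  (transcriptome -> phenome): %.4f\n", x$beta))
  cat(sprintf("  NLL: %.6f after %d iteration(s); converged: %s\n",
              utils::tail(x$nll_trace, 1L), x$n_iter, x$converged))
  invisible(x)
}

#' Per-gene transcript loadings
#'
#' The contribution of each gene to the transcriptome score, defined as
#' the Pearson correlation of the standardized gene column with the
#' fitted score `t`. On standardized expression this is
#' monotone-equivalent to the covariance definition; an option switches
#' to raw covariances for comparison.
#'
#' @param X An `expression_matrix` at stage `"standardized"`.
#' @param t_score Fitted transcriptome score over the same individuals.
#' @param type `"correlation"` (default) or `"covariance"`.
#' @return Named numeric vector, one loading per gene, in `[-1, 1]` for
#'   the correlation definition.
#' @export
gene_loadings <- function(X, t_score, type = c("correlation", "covariance")) {
  type <- match.arg(type)
  check_stage(X, "standardized")
  stop_if(nrow(X) != length(t_score),
          "expression matrix and score cover different individuals")
  if (!is.null(names(t_score)))
    check_same_ids(rownames(X), names(t_score), "expression and score")
  v <- unclass(X)
  out <- if (type == "correlation") as.vector(stats::cor(v, t_score))
  else as.vector(crossprod(v, t_score - mean(t_score))) / (nrow(v) - 1)
  stats::setNames(out, colnames(v))
}

#' Per-column phenotype loadings
#'
#' Pearson correlation of each encoded phenotype column with the fitted
#' phenome score. Constant columns (e.g. the all-ones lowest-level dummy)
#' carry no information and are excluded with a warning.
#'
#' @param P Encoded phenotype matrix ([encode_phenotypes()]).
#' @param p_score Fitted phenome score over the same individuals.
#' @return Named numeric vector over the non-constant columns.
#' @export
phenotype_loadings <- function(P, p_score) {
  P <- as.matrix(P)
  stop_if(nrow(P) != length(p_score),
          "phenotype matrix and score cover different individuals")
  if (!is.null(names(p_score)) && !is.null(rownames(P)))
    check_same_ids(rownames(P), names(p_score), "phenotypes and score")
  sdv <- apply(P, 2L, stats::sd)
  if (any(sdv == 0))
    warning("excluding constant phenotype column(s): ",
            paste(colnames(P)[sdv == 0], collapse = ", "))
  keep <- sdv > 0
  stats::setNames(as.vector(stats::cor(P[, keep, drop = FALSE], p_score)),
                  colnames(P)[keep])
}

#' Score correlations and the mediation consistency check
#'
#' Pairwise Pearson correlations among the fitted scores with two-sided
#' p-values, plus the correlation expected between genome and phenome
#' scores under perfect mediation, \eqn{r_{exp} = r_{gt} \cdot r_{tp}}.
#' An observed \eqn{r_{gp}} exceeding \eqn{r_{exp}} indicates direct
#' genome-phenome effects not carried by the transcriptome block.
#'
#' @param fit An `hdma_fit`, or a list with score vectors `g`, `t`, `p`.
#' @return List with `r_gt`, `r_tp`, `r_gp`, their `p_values`,
#'   `r_expected`, and logical `direct_effect` flag.
#' @export
score_correlations <- function(fit) {
  scores <- if (inherits(fit, "hdma_fit")) fit$scores else fit
  stop_if(!all(c("g", "t", "p") %in% names(scores)),
          "fit must carry scores g, t and p")
  ct <- function(a, b) stats::cor.test(scores[[a]], scores[[b]])
  gt <- ct("g", "t"); tp <- ct("t", "p"); gp <- ct("g", "p")
  r_gt <- unname(gt$estimate); r_tp <- unname(tp$estimate)
  r_gp <- unname(gp$estimate)
  r_expected <- r_gt * r_tp
  list(r_gt = r_gt, r_tp = r_tp, r_gp = r_gp,
       p_values = c(gt = gt$p.value, tp = tp$p.value, gp = gp$p.value),
       r_expected = r_expected,
       direct_effect = r_gp > r_expected)
}
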