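#' Construct a genotype dosage matrix
#'
#' Wraps an individuals-by-SNPs matrix of allele dosages (0, 1, 2, or `NA`
#' for a missing call) with validated row and column identifiers.
#'
#' @param dosages Numeric matrix, individuals in rows, SNPs in columns.
#' @param individual_ids Character vector of unique individual ids
#'   (defaults to `rownames(dosages)`).
#' @param snp_ids Character vector of unique SNP ids (defaults to
#'   `colnames(dosages)`).
#' @return A `genotype_matrix`: the dosage matrix with ids as dimnames.
#' @export
genotype_matrix <- function(dosages, individual_ids = rownames(dosages),
                            snp_ids = colnames(dosages)) {
  dosages <- as.matrix(dosages)
  individual_ids <- check_ids(individual_ids, "individual_ids")
  snp_ids <- check_ids(snp_ids, "snp_ids")
  stop_if(nrow(dosages) != length(individual_ids) ||
            ncol(dosages) != length(snp_ids),
          "id lists must match the dosage matrix dimensions")
  vals <- dosages[!is.na(dosages)]
  stop_if(!all(vals %in% c(0, 1, 2)),
          "non-missing dosages must be 0, 1 or 2")
  dimnames(dosages) <- list(individual_ids, snp_ids)
  structure(dosages, class = c("genotype_matrix", "matrix", "array"))
}

#' Estimate a kinship matrix from genotype dosages
#'
#' Two estimators of pairwise genetic similarity are provided.
#' `"grm"` (default) is the genomic relationship matrix
#' \eqn{K = Z Z^T / m'} where `Z` is the dosage matrix restricted to the
#' `m'` polymorphic SNPs, with each SNP column centered and scaled to unit
#' sample standard deviation (missing calls are mean-imputed, i.e. set to
#' zero after centering). `"king_robust"` is the pairwise
#' within-family-robust estimator
#' \eqn{\hat\phi_{ij} = (N_{het,het} - 2 N_{IBS0}) / (N_{het,i} + N_{het,j})}
#' computed over SNPs non-missing in both individuals, with the diagonal set
#' to 0.5. Pairs with no heterozygous sites have an undefined estimate; they
#' are recorded as unrelated (0) with a warning.
#'
#' Any symmetric user-supplied kinship matrix can be used downstream in
#' place of these estimators; [fit_hdma()] only needs a genetic similarity
#' matrix.
#'
#' @param G A [genotype_matrix()].
#' @param method `"grm"` or `"king_robust"`.
#' @return A symmetric `kinship_matrix` with individual ids as dimnames and
#'   attribute `n_snps_used`.
#' @export
compute_kinship <- function(G, method = c("grm", "king_robust")) {
  method <- match.arg(method)
  stop_if(!inherits(G, "genotype_matrix"), "G must be a genotype_matrix")
  stop_if(nrow(G) < 2L, "kinship needs at least 2 individuals")
  all_missing <- rowSums(!is.na(G)) == 0L
  stop_if(any(all_missing), "individual(s) with no genotype calls: ",
          paste(rownames(G)[all_missing], collapse = ", "))
  called <- colSums(!is.na(G)) >= 1L
  stop_if(!all(called), "SNP(s) with no calls: ",
          paste(colnames(G)[!called], collapse = ", "))
  K <- switch(method, grm = kinship_grm(G), king_robust = kinship_king(G))
  K <- (K + t(K)) / 2
  structure(K, class = c("kinship_matrix", "matrix", "array"))
}

kinship_grm <- function(G) {
  mu <- colMeans(G, na.rm = TRUE)
  sdv <- apply(G, 2L, stats::sd, na.rm = TRUE)
  poly <- !is.na(sdv) & sdv > 0
  stop_if(!any(poly), "no polymorphic SNPs: GRM is undefined")
  Z <- sweep(G[, poly, drop = FALSE], 2L, mu[poly], "-")
  Z <- sweep(Z, 2L, sdv[poly], "/")
  Z[is.na(Z)] <- 0
  K <- tcrossprod(Z) / sum(poly)
  attr(K, "n_snps_used") <- sum(poly)
  dimnames(K) <- list(rownames(G), rownames(G))
  K
}

kinship_king <- function(G) {
  M <- !is.na(G)
  het <- (!is.na(G) & G == 1) * 1
  a0 <- (!is.na(G) & G == 0) * 1
  a2 <- (!is.na(G) & G == 2) * 1
  storage.mode(M) <- "double"
  n_hethet <- tcrossprod(het)
  n_ibs0 <- tcrossprod(a0, a2) + tcrossprod(a2, a0)
  # heterozygote counts restricted to SNPs non-missing in both of the pair
  n_het_i <- tcrossprod(het, M)
  denom <- n_het_i + t(n_het_i)
  K <- (n_hethet - 2 * n_ibs0) / denom
  bad <- !is.finite(K)
  diag(bad) <- FALSE
  if (any(bad)) {
    warning(sum(bad) / 2, " pair(s) with no heterozygous sites; ",
            "kinship recorded as 0 (unrelated)")
    K[bad] <- 0
  }
  diag(K) <- 0.5
  attr(K, "n_snps_used") <- ncol(G)
  dimnames(K) <- list(rownames(G), rownames(G))
  K
}

#' Validate a square kinship matrix
#'
#' @param K Numeric square matrix with matching row/column ids.
#' @param tol Symmetry tolerance.
#' @return `K` with class `kinship_matrix`.
#' @export
as_kinship_matrix <- function(K, tol = 1e-10) {
  K <- as.matrix(K)
  stop_if(nrow(K) != ncol(K), "kinship matrix must be square")
  ids <- check_ids(rownames(K))
  stop_if(!identical(ids, as.character(colnames(K))),
          "kinship row and column ids must match")
  stop_if(!all(is.finite(K)), "kinship matrix contains non-finite values")
  stop_if(max(abs(K - t(K))) > tol, "kinship matrix is not symmetric")
  stop_if(any(diag(K) <= 0), "kinship diagonal must be strictly positive")
  structure(K, class = c("kinship_matrix", "matrix", "array"))
}
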