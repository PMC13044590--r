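#' Individual-by-individual Gram matrix of a feature block
#'
#' Builds \eqn{K = X_c X_c^T} from the column-centered feature matrix
#' (constant columns are dropped first), optionally scaled by the number
#' of retained features so that blocks of very different width sit on
#' comparable scales. Column centering makes the rows of `K` sum to zero,
#' so every score `K l` is automatically mean-centered.
#'
#' @param M Numeric matrix, individuals in rows, features in columns.
#' @param source Label for the block: `"genome"`, `"transcriptome"` or
#'   `"phenome"`.
#' @param scale_features Divide by the number of retained features
#'   (default `TRUE`). This changes only the conditioning, not the scores,
#'   which are variance-normalized downstream.
#' @return Symmetric `gram_matrix` with attributes `source` and
#'   `n_features`.
#' @export
gram_matrix <- function(M, source = c("genome", "transcriptome", "phenome"),
                        scale_features = TRUE) {
  source <- match.arg(source)
  M <- as.matrix(M)
  stop_if(nrow(M) < 2L, "need at least 2 individuals")
  stop_if(anyNA(M), "feature matrix contains missing values")
  Mc <- scale(M, center = TRUE, scale = FALSE)
  keep <- apply(Mc, 2L, function(x) any(x != 0))
  stop_if(!any(keep), "no non-constant features left for Gram construction")
  Mc <- Mc[, keep, drop = FALSE]
  K <- tcrossprod(Mc)
  if (scale_features) K <- K / ncol(Mc)
  K <- (K + t(K)) / 2
  dimnames(K) <- list(rownames(M), rownames(M))
  structure(K, source = source, n_features = ncol(Mc),
            class = c("gram_matrix", "matrix", "array"))
}

# Gower double-centering: projects the similarity matrix onto the space
# orthogonal to the constant vector, so scores K l have mean zero even for
# externally supplied kinship matrices (a Gram matrix built by
# gram_matrix() is already row-centered and passes through unchanged).
center_gram <- function(K) {
  n <- nrow(K)
  rm_ <- rowMeans(K)
  gm <- mean(K)
  K - matrix(rm_, n, n) - matrix(rm_, n, n, byrow = TRUE) + gm
}

#' Fraction of trait variance captured by leading principal components
#'
#' Eigendecomposes the column covariance of the (centered) encoded
#' phenotype matrix and returns the share of total variance carried by the
#' first `k` principal components — a summary of how strongly the clinical
#' traits covary.
#'
#' @param P Numeric matrix of encoded phenotypes (individuals x columns).
#' @param k Number of leading components.
#' @return Fraction in `[0, 1]`.
#' @export
trait_pca_variance <- function(P, k) {
  P <- as.matrix(P)
  Pc <- scale(P, center = TRUE, scale = FALSE)
  ev <- eigen(stats::cov(Pc), symmetric = TRUE, only.values = TRUE)$values
  ev <- pmax(ev, 0)
  r <- sum(ev > max(ev) * 1e-12)
  stop_if(k < 1L || k > r, "k must be between 1 and the matrix rank (", r, ")")
  sum(ev[seq_len(k)]) / sum(ev)
}
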