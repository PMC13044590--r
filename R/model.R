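#' Model-implied covariance of the perfect-mediation chain
#'
#' Under the structural equations \eqn{t = \alpha g + \epsilon_t},
#' \eqn{p = \beta t + \epsilon_p} with unit-variance scores, the implied
#' covariance of \eqn{(g, t, p)} is
#' \deqn{\Sigma = \begin{pmatrix} 1 & \alpha & \alpha\beta \\ \alpha & 1 &
#' \beta \\ \alpha\beta & \beta & 1 \end{pmatrix}}
#' with \eqn{\det\Sigma = (1-\alpha^2)(1-\beta^2)}. Its inverse has a zero
#' in the (g, p) cell: conditional on the mediator, genome and phenome
#' scores are independent — the defining property of a perfect mediator.
#'
#' @param alpha,beta Structural path coefficients, each in (-1, 1).
#' @return 3 x 3 matrix with dimnames `g`, `t`, `p`.
#' @export
implied_covariance <- function(alpha, beta) {
  stop_if(!is.finite(alpha) || !is.finite(beta) ||
            abs(alpha) >= 1 || abs(beta) >= 1,
          "structural parameters must lie strictly inside (-1, 1)")
  S <- matrix(c(1, alpha, alpha * beta,
                alpha, 1, beta,
                alpha * beta, beta, 1), 3L, 3L,
              dimnames = list(c("g", "t", "p"), c("g", "t", "p")))
  S
}

#' Negative log-likelihood of the perfect-mediation model
#'
#' Evaluates \eqn{L = \mathrm{tr}(S \Sigma^{-1}) + \log\det\Sigma} for the
#' sample covariance `S` of the unit-variance score triple and the
#' model-implied \eqn{\Sigma(\alpha, \beta)}. At \eqn{\alpha=\beta=0} this
#' is `tr(S) = 3`; at `S = Sigma(alpha, beta)` it is
#' `3 + log((1-alpha^2)(1-beta^2))`.
#'
#' @param S 3 x 3 symmetric sample covariance with unit diagonal
#'   (scores are pre-scaled to variance one).
#' @inheritParams implied_covariance
#' @return Scalar negative log-likelihood.
#' @export
negative_log_likelihood <- function(S, alpha, beta) {
  S <- as.matrix(S)
  stop_if(!all(dim(S) == 3L), "S must be 3 x 3")
  stop_if(!all(is.finite(S)), "S contains non-finite values")
  stop_if(max(abs(S - t(S))) > 1e-8, "S must be symmetric")
  # tr(S Omega) in closed form from the chain-structured precision matrix
  # (the (g,p) precision cell is exactly zero), plus log det Sigma.
  ia <- 1 / (1 - alpha^2)
  ib <- 1 / (1 - beta^2)
  S[1, 1] * ia + S[2, 2] * (ia + beta^2 * ib) + S[3, 3] * ib -
    2 * S[1, 2] * alpha * ia - 2 * S[2, 3] * beta * ib +
    log1p(-alpha^2) + log1p(-beta^2)
}

#' Maximum-likelihood structural parameters for a fixed score covariance
#'
#' The structural half-step of the alternating fit: minimizes
#' [negative_log_likelihood()] over \eqn{(\alpha, \beta) \in (-1, 1)^2}.
#' Because the chain-structured likelihood separates exactly into an
#' \eqn{\alpha} term and a \eqn{\beta} term, the two-dimensional problem
#' is solved by bounded one-dimensional minimization per coordinate,
#' which is robust even when the optimum sits near the box bound. When
#' `S` equals an exact \eqn{\Sigma(\alpha_0, \beta_0)} the minimizer is
#' \eqn{(\alpha_0, \beta_0)} (the sample covariances \eqn{S_{12}} and
#' \eqn{S_{23}} are the stationary points).
#'
#' @inheritParams negative_log_likelihood
#' @param bound Box half-width for the search (parameters are confined to
#'   `(-bound, bound)`).
#' @return List with elements `alpha`, `beta` and `nll`.
#' @export
fit_structural_params <- function(S, bound = 0.99) {
  S <- as.matrix(S)
  stop_if(!all(is.finite(S)), "S contains non-finite values")
  # exact separable terms of tr(S Omega) + log det Sigma
  f_alpha <- function(x)
    (S[1, 1] + S[2, 2] - 2 * x * S[1, 2]) / (1 - x^2) + log1p(-x^2)
  f_beta <- function(x)
    (S[2, 2] * x^2 + S[3, 3] - 2 * x * S[2, 3]) / (1 - x^2) + log1p(-x^2)
  alpha <- stats::optimize(f_alpha, c(-bound, bound), tol = 1e-10)$minimum
  beta <- stats::optimize(f_beta, c(-bound, bound), tol = 1e-10)$minimum
  list(alpha = alpha, beta = beta,
       nll = negative_log_likelihood(S, alpha, beta))
}

#' Connection weights of the likelihood-equivalent GCCA problem
#'
#' With the score variances fixed at one, \eqn{\mathrm{tr}(S\Sigma^{-1})}
#' is linear in the off-diagonal entries of `S`, so minimizing it over the
#' scores is equivalent to maximizing the weighted sum of score
#' covariances \eqn{\sum_{j<k} c_{jk}\,\mathrm{cov}(s_j, s_k)} with
#' \eqn{c = -\mathrm{offdiag}(\Sigma^{-1})}:
#' \eqn{c_{gt} = \alpha/(1-\alpha^2)}, \eqn{c_{tp} = \beta/(1-\beta^2)},
#' and \eqn{c_{gp} = 0} exactly, from the Markov structure of the chain.
#' This is a generalized canonical correlation problem connecting only
#' the genome-transcriptome and transcriptome-phenome block pairs.
#'
#' @inheritParams implied_covariance
#' @return Symmetric 3 x 3 weight matrix (zero diagonal).
#' @export
connection_weights <- function(alpha, beta) {
  implied_covariance(alpha, beta)  # validates the parameter range
  W <- matrix(0, 3L, 3L, dimnames = list(c("g", "t", "p"), c("g", "t", "p")))
  W[1, 2] <- W[2, 1] <- alpha / (1 - alpha^2)
  W[2, 3] <- W[3, 2] <- beta / (1 - beta^2)
  W
}
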