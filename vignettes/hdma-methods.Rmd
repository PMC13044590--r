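---
title: "High-dimensional mediation of genotype on clinical phenotype: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{High-dimensional mediation: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hdmediate)
```

## The scientific question

A genetic predisposition to a late-life disease must act through
intermediate molecular state. Given three blocks of data on the same
cohort — genotypes, post-mortem brain transcriptomes, and clinical
severity measures — we want a single transcriptomic axis that *mediates*
the effect of genetic background on clinical outcome: a score `t` such
that the phenome score `p` is (ideally) independent of the genome score
`g` once `t` is known. Genes are then ranked by their contribution to
this mediating axis and interrogated with gene-set enrichment.

## The model

Each block enters as an individual-by-individual similarity matrix: a
kinship matrix $K_G$ for the genome, and Gram matrices $K_T = X X^\top$
and $K_P = P P^\top$ for the (standardized) transcriptome $X$ and the
encoded phenome $P$. Scores are linear in similarity space,

$$g = K_G \ell_G, \qquad t = K_T \ell_T, \qquad p = K_P \ell_P,$$

each rescaled to unit variance (scale is not identified). The loading
vectors are chosen to maximize the Gaussian likelihood of the
perfect-mediation structural equations

$$t = \alpha g + \varepsilon_t, \qquad p = \beta t + \varepsilon_p,
\qquad |\alpha|, |\beta| < 1,$$

whose implied covariance for $(g, t, p)$ is
$\Sigma(\alpha, \beta) = \begin{pmatrix} 1 & \alpha & \alpha\beta \\
\alpha & 1 & \beta \\ \alpha\beta & \beta & 1\end{pmatrix}$, with
$\det\Sigma = (1-\alpha^2)(1-\beta^2)$ and, crucially, a zero in the
$(g,p)$ cell of $\Sigma^{-1}$: conditional independence of genome and
phenome given the mediator. The criterion minimized is

$$L(S; \alpha, \beta) = \operatorname{tr}(S\,\Sigma^{-1}) +
\log\det\Sigma,$$

with $S$ the sample covariance of the three unit-variance scores.

## The alternating fit

`fit_hdma()` alternates two half-steps:

1. **Structural half-step.** For fixed scores, $L$ separates exactly
   into an $\alpha$ term and a $\beta$ term, so each is minimized by
   bounded one-dimensional search on $(-0.99, 0.99)$
   (`fit_structural_params()`). For a unit-diagonal $S$ the stationary
   points are simply $S_{12}$ and $S_{23}$; the numerical search is kept
   because it is robust when the optimum sits against the bound.
2. **Loading half-step.** With the unit-variance constraint,
   $\operatorname{tr}(S\Sigma^{-1})$ is linear in the off-diagonal
   entries of $S$, so minimizing over the scores is the generalized
   canonical correlation problem of maximizing
   $c_{gt}\operatorname{cov}(g,t) + c_{tp}\operatorname{cov}(t,p)$ with
   weights $c = -\mathrm{offdiag}(\Sigma^{-1})$; the genome-phenome
   connection weight is exactly zero by the Markov structure. One
   block-coordinate sweep in the fixed order G, T, P updates each
   loading against its weighted target $z$ (`gcca_sweep()`).

Two update schemes are provided for the loading half-step, because the
two natural normalizations behave very differently in high dimension:

* **`scheme = "covariance"` (default).** The loading is normalized in
  feature space ($\ell^\top K \ell = 1$), giving the update
  $s \propto K z$. This is the Horst-scheme, mode-A update of
  regularized generalized canonical correlation analysis, the standard
  choice when blocks have many more features than individuals. Because
  the update weights directions by the block's variance spectrum, a
  full-rank Gram matrix does not let a score simply copy its target,
  and the fit remains well-posed at transcriptome scale.
* **`scheme = "correlation"`.** The score itself is variance-normalized
  and the update is the ridge-stabilized projection
  $s \propto K (K + \lambda I)^{-1} z$ — the exact per-block minimizer
  of $L$. This is the right tool when the similarity matrices are
  genuinely low-rank relative to the cohort (the package's tiny-instance
  optimality tests run in this scheme), but it degenerates on full-rank
  blocks: every vector lies in the column space, all score correlations
  can be driven towards one, and $L$ is unbounded below. That
  degeneracy is why the covariance scheme is the default.

**Monotone acceptance.** Under the correlation scheme every half-step
decreases $L$, so the recorded likelihood trace is nonincreasing by
construction. Under the covariance scheme the sweep ascends a
weighted-covariance surrogate rather than $L$ itself; the fit therefore
evaluates $L$ after each sweep and *rejects* a sweep that would increase
it, stopping there. In practice fits at the default conditions accept
two or three sweeps from the spectral initialization and stop — the
likelihood is used both as objective and as stopping rule.

**Initialization and determinism.** Scores start at the leading
variance direction of each centered similarity matrix, computed by a
fixed number (60) of power iterations from the centered squared row
norms rather than by `eigen()`: for near-degenerate spectra (typical of
kinship bulk eigenvalues) LAPACK eigenvectors depend on row order,
whereas the power-iteration start makes fits exactly equivariant under
permutation of individuals up to floating-point noise. The start vector
sign is fixed by making its largest-magnitude entry positive. Optional
random restarts (`n_starts`, seeded) guard against local optima in the
correlation scheme; the deterministic start alone is used by default.

**Sign conventions.** Flipping any single score (with its loading)
leaves $L$ unchanged, since the $(g,p)$ entry of $S$ never enters. The
returned fit is oriented deterministically: $\hat\alpha \ge 0$,
$\hat\beta \ge 0$, and — when the encoded phenome block is supplied —
the whole triple is flipped, if needed, so the phenome score increases
with clinical severity (measured by the rank sum over the ordinal dummy
columns). Without the convention, quantities compared across seeds
(e.g. gene-loading recovery) would carry arbitrary signs.

**Numerical parameters.** `ridge` (default `1e-8`, scaled by
`tr(K)/n`) stabilizes the projections and the final loading recovery
`solve(K + ridge, score)`; it affects conditioning, not the reported
scores. Convergence is declared at relative likelihood change below
`tol = 1e-8` or `max_iter = 500` outer iterations. Gram matrices are
column-centered (dropping constant features, e.g. the all-ones
lowest-level ordinal dummy) and scaled by the feature count so blocks of
very different width are comparably conditioned; centering makes every
score mean-zero exactly.

## Preprocessing choices

* **Kinship.** Two estimators are implemented: the centered-scaled GRM
  $Z Z^\top / m'$ over polymorphic SNPs (default; missing calls
  mean-imputed) and the KING-robust pairwise estimator
  $(N_{het,het} - 2N_{IBS0})/(N_{het,i} + N_{het,j})$ with diagonal 0.5.
  Pairs with no heterozygous sites have an undefined KING estimate and
  are recorded as unrelated (0) with a warning. Any user-supplied
  symmetric kinship matrix is accepted — the fit needs only a genetic
  similarity matrix.
* **Expression.** `log2(count + 1)` (base and pseudocount
  configurable), least-squares residualization on
  `[1, sex, education_years, age_at_death]` (any further numeric
  covariates in the table join the design), then per-transcript
  standardization with the sample (n − 1) standard deviation. Constant
  transcripts are dropped with a warning.
* **Ordinal encoding.** Each ordinal scale expands into cumulative
  binary dummies — ones up to the assigned level — so a Braak score of 3
  sets `braak>=0 ... braak>=3`. This preserves order without imposing
  equal spacing between levels. MMSE is treated as continuous (centered,
  unit sd), following its interval-scale use; the choice is
  configurable in the encoding specification. CERAD and MMSE are
  encoded as recorded (no direction reversal): the fitted phenotype
  loadings absorb their inverse clinical coding, and indeed come out
  negative on both when severity drives the phenome score.
* **Alignment.** Individuals common to all blocks, in sorted id order;
  the count dropped is reported.

## The synthetic cohort generator

`simulate_dataset()` realizes exactly the structure the model assumes,
with full ground truth for recovery tests: a latent genetic score `g*`
(standardized weighted sum of 100 causal SNPs out of 1000, cohort of
477 in sibships of 4 generated via shared parental haplotypes), the
mediator `t* = 0.85 g* + noise`, 2000 genes of which 10% load on `t*`
with loadings of magnitude 0.4–0.8, negative-binomial counts
(dispersion 0.1, baseline means 50–500), covariate effects on
expression, the phenome latent `p* = 0.34 t* + noise`, and five
clinical outcomes as noisy copies of `p*` (reliability 0.7) cut at
evenly spaced quantiles — Braak, Cog LV and Cog death increasing with
severity, CERAD and MMSE inverted to match their clinical coding. The
cohort size, gene count and path coefficients mirror the study
conditions the fit is meant to recover; the remaining settings are
fixed at values typical of a bulk-brain RNA-seq cohort of elderly
donors.

What the generator deliberately does **not** emulate: linkage
disequilibrium, population stratification, cell-type composition,
technical expression covariates (e.g. RIN), non-Gaussian latent
structure, or multiple mediating components. Passing recovery tests on
this generator therefore demonstrates that the estimator recovers the
model's own structure at realistic size and noise — not that real
cohorts satisfy that structure.

## Ranking and enrichment

Transcript loadings are the per-gene Pearson correlations with the
fitted mediator score (on standardized expression this is
monotone-equivalent to the covariance definition; an option switches to
covariances). Genes are ordered into descending (up-with-severity) and
ascending lists with stable id tie-breaks; the top 150 of each form the
signature-matching query files. Enrichment uses the classic running-sum
statistic on the order-based ranking: with weight exponent 1 hits are
weighted by their reverse-rank position, with exponent 0 uniformly;
misses decrement by $1/(N-m)$; the score is the extremum of largest
magnitude. Significance comes from size-matched gene-label permutations
(default 1000) with one-sided p-values, sign-matched NES normalization,
and Benjamini–Hochberg adjustment across sets. The gene-label null was
chosen because a phenotype-permutation null is not available to a
preranked analysis; it tests set concentration, not inter-gene
correlation structure.

## Known limitations

* **A geometric floor on fitted score correlations.** With kinship
  estimated from m SNPs, the genome update can align with *any* target
  at roughly $1/\sqrt{1 + n/m}$ (about 0.82 at n = 477, m = 1000) even
  in the absence of signal, because the bulk spectrum of the GRM is
  flat. The recovery study (`analysis/05_recovery_study.R`) shows the
  consequence: the fitted genome–transcriptome correlation tracks the
  generative value when mediation is strong, but is upward-biased when
  the true path is weak. Fitted score correlations should be read as
  upper bounds on mediated heritability; the same caveat applies to any
  score-based kinship analysis, including on real cohorts where the SNP
  panel is larger and the floor correspondingly higher.
* **Null inflation grows with block rank.** Pure-noise blocks of rank 1
  yield near-zero fitted paths; higher-rank noise blocks allow the
  alternating fit to align subspaces and inflate them. Model fit on
  full-rank blocks should always be compared against a matched null
  simulation.
* **No uncertainty quantification.** Standard errors or confidence
  intervals for the structural parameters are not provided; the
  permutation machinery covers only the enrichment stage.
* **Single mediating component.** The model extracts one axis per
  block; multi-component extensions are out of scope.

## Problem sizes used by the test suite

The suite exercises the full pipeline at the study scale (477
individuals, 2000 genes, 20 seeds) for parameter recovery, 100 fits at
n = 100 for the likelihood-trace property, rank-2 instances at n = 8
against an exhaustive angular-grid oracle, and 200 random gene sets for
permutation calibration. These sizes were chosen so that each property
is tested at the smallest scale at which it is informative.
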