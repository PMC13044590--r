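#' Construct a staged expression matrix
#'
#' Expression data move through four stages: `counts` (normalized read
#' counts, non-negative), `log` (log-transformed), `adjusted` (covariate
#' residuals), and `standardized` (column mean 0, sd 1). The stage is
#' carried as an attribute so each preprocessing step can assert it
#' receives the stage it expects.
#'
#' @param values Numeric matrix, individuals in rows, genes in columns.
#' @param stage One of `"counts"`, `"log"`, `"adjusted"`, `"standardized"`.
#' @param individual_ids,gene_ids Unique id vectors (default: dimnames).
#' @return An `expression_matrix` with a `stage` attribute.
#' @export
expression_matrix <- function(values,
                              stage = c("counts", "log", "adjusted",
                                        "standardized"),
                              individual_ids = rownames(values),
                              gene_ids = colnames(values)) {
  stage <- match.arg(stage)
  values <- as.matrix(values)
  individual_ids <- check_ids(individual_ids, "individual_ids")
  gene_ids <- check_ids(gene_ids, "gene_ids")
  stop_if(nrow(values) != length(individual_ids) ||
            ncol(values) != length(gene_ids),
          "id lists must match the expression matrix dimensions")
  stop_if(anyNA(values), "expression matrix contains missing values")
  if (stage == "counts") stop_if(any(values < 0), "counts must be >= 0")
  dimnames(values) <- list(individual_ids, gene_ids)
  structure(values, stage = stage,
            class = c("expression_matrix", "matrix", "array"))
}

#' @rdname expression_matrix
#' @param x An `expression_matrix`.
#' @export
expr_stage <- function(x) attr(x, "stage")

check_stage <- function(x, stage) {
  stop_if(!inherits(x, "expression_matrix"), "expected an expression_matrix")
  stop_if(!identical(expr_stage(x), stage),
          "expected stage '", stage, "', got '", expr_stage(x), "'")
  invisible(TRUE)
}

#' Log-transform normalized read counts
#'
#' Applies `log(value + pseudocount)` elementwise. Base 2 and a
#' pseudocount of 1 are the defaults; both are configurable.
#'
#' @param counts An `expression_matrix` at stage `"counts"`.
#' @param pseudocount Positive offset added before taking the log.
#' @param base Logarithm base.
#' @return An `expression_matrix` at stage `"log"`.
#' @export
log_transform <- function(counts, pseudocount = 1, base = 2) {
  check_stage(counts, "counts")
  stop_if(pseudocount <= 0, "pseudocount must be > 0")
  stop_if(any(counts < 0), "negative values in count matrix")
  out <- log(unclass(counts) + pseudocount, base = base)
  expression_matrix(out, stage = "log")
}

#' Construct a covariate table
#'
#' @param individual_ids Unique individual ids.
#' @param sex Binary (0/1) indicator.
#' @param education_years Non-negative years of education.
#' @param age_at_death Age at death in years.
#' @return A validated `data.frame` of covariates.
#' @export
covariate_table <- function(individual_ids, sex, education_years,
                            age_at_death) {
  individual_ids <- check_ids(individual_ids)
  d <- data.frame(individual_id = individual_ids, sex = as.numeric(sex),
                  education_years = as.numeric(education_years),
                  age_at_death = as.numeric(age_at_death),
                  stringsAsFactors = FALSE)
  stop_if(anyNA(d), "covariate table contains missing values")
  stop_if(!all(d$sex %in% c(0, 1)), "sex must be coded 0/1")
  stop_if(any(d$education_years < 0), "education_years must be >= 0")
  d
}

#' Residualize expression on covariates
#'
#' Replaces every gene column by its least-squares residual against the
#' design `[1, sex, education_years, age_at_death]`, removing non-genetic
#' drivers of expression variation before the mediation fit. Any covariate
#' data frame with the same individuals works; extra numeric columns are
#' included in the design.
#'
#' @param X An `expression_matrix` at stage `"log"`.
#' @param C A covariate `data.frame` with an `individual_id` column
#'   matching `X`'s rows in order.
#' @return An `expression_matrix` at stage `"adjusted"` whose columns are
#'   orthogonal to every design column.
#' @export
adjust_covariates <- function(X, C) {
  check_stage(X, "log")
  stop_if(!is.data.frame(C) || is.null(C$individual_id),
          "C must be a covariate data.frame with an individual_id column")
  check_same_ids(rownames(X), C$individual_id, "expression and covariates")
  D <- cbind(intercept = 1,
             as.matrix(C[, setdiff(names(C), "individual_id"), drop = FALSE]))
  qrD <- qr(D)
  if (qrD$rank < ncol(D)) {
    drop_cols <- colnames(D)[qrD$pivot[(qrD$rank + 1L):ncol(D)]]
    stop("covariate design is rank deficient; collinear column(s): ",
         paste(drop_cols, collapse = ", "), call. = FALSE)
  }
  res <- qr.resid(qrD, unclass(X))
  dimnames(res) <- dimnames(X)
  expression_matrix(res, stage = "adjusted")
}

#' Standardize expression columns
#'
#' Scales each transcript to mean zero and unit sample standard deviation
#' (`n - 1` denominator). Constant columns cannot be scaled; they are
#' dropped with a warning and their ids are recorded in the
#' `dropped_genes` attribute.
#'
#' @param X An `expression_matrix` at stage `"adjusted"` (or `"log"`, for
#'   workflows that skip covariate adjustment).
#' @return An `expression_matrix` at stage `"standardized"`.
#' @export
standardize_columns <- function(X) {
  stop_if(!inherits(X, "expression_matrix"), "expected an expression_matrix")
  stop_if(expr_stage(X) == "counts",
          "standardize after log transform, not on raw counts")
  v <- unclass(X)
  sdv <- apply(v, 2L, stats::sd)
  keep <- sdv > 0
  dropped <- colnames(v)[!keep]
  if (length(dropped) > 0L)
    warning("dropping ", length(dropped), " constant column(s): ",
            paste(utils::head(dropped, 5L), collapse = ", "),
            if (length(dropped) > 5L) ", ..." else "")
  v <- v[, keep, drop = FALSE]
  v <- scale(v)
  attr(v, "scaled:center") <- NULL
  attr(v, "scaled:scale") <- NULL
  out <- expression_matrix(v, stage = "standardized")
  attr(out, "dropped_genes") <- dropped
  out
}

#' Align individuals across data blocks
#'
#' Computes the deterministic (sorted) intersection of several individual
#' id vectors. All downstream matrices must be subset to this order before
#' entering the fit.
#'
#' @param ... Two or more character vectors of individual ids.
#' @return Sorted character vector of ids common to every input.
#' @export
align_individuals <- function(...) {
  lists <- list(...)
  stop_if(length(lists) < 1L, "supply at least one id vector")
  common <- Reduce(intersect, lapply(lists, as.character))
  stop_if(length(common) == 0L, "no individuals are common to all inputs")
  sort(common)
}
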