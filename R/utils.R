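#' @keywords internal
"_PACKAGE"

# Internal assertion helpers. These fail loudly with the offending names so
# that misaligned inputs never propagate silently.

stop_if <- function(cond, ...) {
  if (cond) stop(..., call. = FALSE)
}

check_ids <- function(ids, what = "individual_ids") {
  stop_if(is.null(ids) || length(ids) == 0L, what, " must be non-empty")
  stop_if(anyNA(ids), what, " contains NA")
  stop_if(anyDuplicated(ids) > 0L, what, " contains duplicates: ",
          paste(unique(ids[duplicated(ids)]), collapse = ", "))
  as.character(ids)
}

check_same_ids <- function(a, b, what = "inputs") {
  stop_if(length(a) != length(b) || !all(a == b),
          what, " must cover the same individuals in the same order")
  invisible(TRUE)
}

# Save/restore the global RNG state around seeded draws so that seeded
# package functions do not perturb the caller's random stream.
with_seed <- function(seed, expr) {
  stop_if(is.null(seed) || !is.finite(seed), "a finite seed is required")
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Sample variance (n - 1 denominator) of a vector, without dispatch overhead.
var1 <- function(x) {
  m <- mean(x)
  sum((x - m)^2) / (length(x) - 1)
}
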