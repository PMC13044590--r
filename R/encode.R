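#' Construct a clinical phenotype table
#'
#' Validated container for the five clinical outcomes: MMSE (mini-mental
#' state exam, 0-30, higher = better cognition), Braak stage (0-6, tau
#' tangle spread), CERAD score (1-4, higher = less amyloid pathology),
#' cognitive diagnosis at last visit (1-6) and at death (1-6).
#'
#' @param individual_ids Unique individual ids.
#' @param mmse,braak,cerad,cog_lv,cog_death Integer-valued clinical scores.
#' @return A validated `data.frame`.
#' @export
phenotype_table <- function(individual_ids, mmse, braak, cerad, cog_lv,
                            cog_death) {
  individual_ids <- check_ids(individual_ids)
  d <- data.frame(individual_id = individual_ids, mmse = as.numeric(mmse),
                  braak = as.numeric(braak), cerad = as.numeric(cerad),
                  cog_lv = as.numeric(cog_lv),
                  cog_death = as.numeric(cog_death),
                  stringsAsFactors = FALSE)
  stop_if(anyNA(d), "phenotype table contains missing values")
  rng <- list(mmse = c(0, 30), braak = c(0, 6), cerad = c(1, 4),
              cog_lv = c(1, 6), cog_death = c(1, 6))
  for (v in names(rng)) {
    bad <- d[[v]] < rng[[v]][1] | d[[v]] > rng[[v]][2]
    stop_if(any(bad), v, " out of range [", rng[[v]][1], ", ", rng[[v]][2],
            "] for individual(s): ",
            paste(d$individual_id[bad], collapse = ", "))
  }
  d
}

#' Cumulative dummy encoding of one ordinal value
#'
#' An ordinal score is expanded into one binary component per level, with
#' 1s filled in for every level up to and including the assigned score.
#' A score of 4 on a six-level 1..6 scale encodes as
#' `c(1, 1, 1, 1, 0, 0)`: the individual meets the criteria for all levels
#' up to four. The encoding preserves the order structure without
#' assigning equal weight to the gaps between levels.
#'
#' @param value A single value that must occur in `levels`.
#' @param levels Ordered vector of the scale's levels (ascending).
#' @return Binary vector of length `length(levels)`.
#' @export
encode_ordinal_value <- function(value, levels) {
  stop_if(length(value) != 1L || is.na(value), "value must be a single score")
  stop_if(!value %in% levels, "value ", value, " is not a declared level")
  as.numeric(levels <= value)
}

#' Default encoding specification for the clinical phenotypes
#'
#' Braak is ordinal with 7 levels (0-6), CERAD with 4 (1-4), Cog LV and
#' Cog death with 6 each (1-6); MMSE is treated as continuous (centered
#' and scaled), following its interval-scale interpretation. Override the
#' returned list to change level sets or reclassify variables.
#'
#' @return Named list; each element is either
#'   `list(kind = "ordinal", levels = <vector>)` or
#'   `list(kind = "continuous")`.
#' @export
default_encoding_spec <- function() {
  list(mmse = list(kind = "continuous"),
       braak = list(kind = "ordinal", levels = 0:6),
       cerad = list(kind = "ordinal", levels = 1:4),
       cog_lv = list(kind = "ordinal", levels = 1:6),
       cog_death = list(kind = "ordinal", levels = 1:6))
}

#' Encode a phenotype table into the numeric phenome block
#'
#' Ordinal variables are expanded with [encode_ordinal_value()] into
#' cumulative dummy columns labelled `"<var>>=<level>"`; continuous
#' variables are centered and scaled to unit sd. The lowest-level dummy
#' column of each ordinal variable is all ones by construction; it is
#' retained here and removed automatically by the constant-column drop
#' when the phenome Gram matrix is built.
#'
#' @param tab A [phenotype_table()]-style `data.frame` with an
#'   `individual_id` column.
#' @param spec Encoding specification, as from [default_encoding_spec()].
#' @return Numeric matrix (individuals x encoded columns) with a
#'   `column_kind` attribute (`"dummy"` or `"continuous"` per column).
#' @export
encode_phenotypes <- function(tab, spec = default_encoding_spec()) {
  stop_if(!is.data.frame(tab) || is.null(tab$individual_id),
          "tab must be a data.frame with an individual_id column")
  ids <- check_ids(tab$individual_id)
  vars <- names(spec)
  missing_vars <- setdiff(vars, names(tab))
  stop_if(length(missing_vars) > 0L, "phenotype table lacks column(s): ",
          paste(missing_vars, collapse = ", "))
  blocks <- list()
  kinds <- character(0)
  for (v in vars) {
    s <- spec[[v]]
    x <- tab[[v]]
    if (identical(s$kind, "ordinal")) {
      bad <- !x %in% s$levels
      stop_if(any(bad), "value outside declared levels for '", v,
              "' in row(s): ", paste(which(bad), collapse = ", "))
      block <- t(vapply(x, encode_ordinal_value, numeric(length(s$levels)),
                        levels = s$levels))
      colnames(block) <- paste0(v, ">=", s$levels)
      blocks[[v]] <- block
      kinds <- c(kinds, rep("dummy", length(s$levels)))
    } else if (identical(s$kind, "continuous")) {
      sdx <- stats::sd(x)
      if (is.na(sdx) || sdx == 0) {
        warning("continuous variable '", v,
                "' has no variation; centered only")
        sdx <- 1
      }
      block <- matrix((x - mean(x)) / sdx, ncol = 1L,
                      dimnames = list(NULL, v))
      blocks[[v]] <- block
      kinds <- c(kinds, "continuous")
    } else {
      stop("unknown kind for variable '", v, "'", call. = FALSE)
    }
  }
  P <- do.call(cbind, blocks)
  rownames(P) <- ids
  attr(P, "column_kind") <- stats::setNames(kinds, colnames(P))
  P
}
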