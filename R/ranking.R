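#' Rank genes by transcript loading
#'
#' Orders genes by their putative causal importance: the descending list
#' leads with the most up-regulated (most positive-loading) genes, the
#' ascending list with the most down-regulated. Ties are broken by gene
#' id, so the ordering is stable across platforms.
#'
#' @param gene_loadings Named numeric vector of per-gene loadings.
#' @param direction `"descending"` (default) or `"ascending"`.
#' @return A `ranked_genes` data frame with columns `gene_id` and
#'   `loading`, ordered per `direction`, with a `direction` attribute.
#' @export
rank_genes <- function(gene_loadings,
                       direction = c("descending", "ascending")) {
  direction <- match.arg(direction)
  ids <- names(gene_loadings)
  stop_if(is.null(ids), "gene_loadings must be a named vector")
  check_ids(ids, "gene ids")
  stop_if(!all(is.finite(gene_loadings)), "loadings must be finite")
  ord <- if (direction == "descending") order(-gene_loadings, ids)
  else order(gene_loadings, ids)
  out <- data.frame(gene_id = ids[ord],
                    loading = unname(gene_loadings[ord]),
                    stringsAsFactors = FALSE)
  structure(out, direction = direction,
            class = c("ranked_genes", "data.frame"))
}

#' Head of a ranked gene list
#'
#' The top `k` genes of a directional ranking — by default the top 150,
#' the size used for signature-matching queries against perturbational
#' databases.
#'
#' @param ranked A `ranked_genes` object from [rank_genes()].
#' @param k Number of genes to keep.
#' @return Character vector of the first `k` gene ids.
#' @export
top_k <- function(ranked, k = 150) {
  stop_if(!inherits(ranked, "ranked_genes"), "ranked must come from rank_genes()")
  stop_if(k < 1L || k > nrow(ranked), "k must be between 1 and ", nrow(ranked))
  ranked$gene_id[seq_len(k)]
}

#' Map gene ids through a two-column identifier table
#'
#' Translates e.g. Ensembl ids to common symbols using a user-supplied
#' map. Ids without a (non-empty) mapping are dropped; the number dropped
#' is reported in a message and in the `n_unmapped` attribute.
#'
#' @param ids Character vector of ids to translate.
#' @param map Data frame whose first column is the source id and second
#'   the target id.
#' @return Character vector of mapped ids (shorter than the input when
#'   some ids are unmapped).
#' @export
apply_id_map <- function(ids, map) {
  stop_if(!is.data.frame(map) || ncol(map) < 2L,
          "map must be a two-column data.frame")
  idx <- match(ids, as.character(map[[1L]]))
  out <- as.character(map[[2L]])[idx]
  keep <- !is.na(out) & nzchar(out)
  if (any(!keep))
    message("dropping ", sum(!keep), " id(s) without a mapped name")
  structure(out[keep], n_unmapped = sum(!keep))
}
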