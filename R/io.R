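# Plain-text I/O: TSV matrices with a leading id column, GMT gene-set
# collections, RNK ranked lists, GRP id lists. All writers produce
# canonical formatting so that read(write(x)) round-trips exactly.

#' Read / write a numeric matrix as TSV with an id column
#'
#' The first column holds row (individual) ids, the header row the column
#' ids; missing values are written as `NA`.
#'
#' @param path File path.
#' @param x Numeric matrix with dimnames.
#' @param id_name Header label for the id column.
#' @return `read_matrix_tsv` returns the matrix; `write_matrix_tsv`
#'   returns `path` invisibly.
#' @export
read_matrix_tsv <- function(path) {
  d <- utils::read.delim(path, check.names = FALSE,
                         stringsAsFactors = FALSE)
  ids <- check_ids(as.character(d[[1L]]), "row ids")
  m <- as.matrix(d[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  m
}

#' @rdname read_matrix_tsv
#' @export
write_matrix_tsv <- function(x, path, id_name = "individual_id") {
  x <- as.matrix(x)
  stop_if(is.null(rownames(x)) || is.null(colnames(x)),
          "matrix must carry row and column ids")
  d <- data.frame(rownames(x), x, check.names = FALSE,
                  stringsAsFactors = FALSE)
  names(d)[1L] <- id_name
  utils::write.table(d, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a square kinship matrix TSV
#'
#' @param path TSV with matching row/column ids.
#' @return A validated `kinship_matrix`.
#' @export
read_kinship_tsv <- function(path) {
  as_kinship_matrix(read_matrix_tsv(path))
}

#' Read a GMT gene-set collection
#'
#' Each line is `name TAB description TAB member1 TAB member2 ...`.
#' Duplicate set names and empty sets are rejected with the offending
#' line number.
#'
#' @param path GMT file path.
#' @return Named list of gene-id character vectors; descriptions in the
#'   `descriptions` attribute.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  stop_if(length(lines) == 0L, "empty GMT file: ", path)
  sets <- list()
  descs <- character(0)
  for (i in seq_along(lines)) {
    parts <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    stop_if(length(parts) < 3L,
            "malformed GMT line ", i, ": need name, description, members")
    members <- parts[-(1:2)]
    members <- members[nzchar(members)]
    stop_if(length(members) == 0L, "empty gene set at GMT line ", i)
    stop_if(parts[1L] %in% names(sets),
            "duplicate set name at GMT line ", i, ": ", parts[1L])
    sets[[parts[1L]]] <- members
    descs[parts[1L]] <- parts[2L]
  }
  structure(sets, descriptions = descs)
}

#' @rdname read_gmt
#' @param collection Named list of gene sets (optionally with a
#'   `descriptions` attribute).
#' @export
write_gmt <- function(collection, path) {
  stop_if(is.null(names(collection)), "collection must be named")
  descs <- attr(collection, "descriptions")
  lines <- vapply(names(collection), function(nm) {
    d <- if (!is.null(descs) && nm %in% names(descs)) descs[[nm]] else "na"
    paste(c(nm, d, collection[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Write a ranked list in RNK format
#'
#' Two tab-separated columns, gene id and ranking statistic, best rank
#' first — the input format of preranked enrichment tools.
#'
#' @param ranked A `ranked_genes` object.
#' @param path Output path.
#' @export
write_rnk <- function(ranked, path) {
  stop_if(!inherits(ranked, "ranked_genes"),
          "ranked must come from rank_genes()")
  writeLines(paste(ranked$gene_id,
                   formatC(ranked$loading, format = "g", digits = 15),
                   sep = "\t"), path)
  invisible(path)
}

#' @rdname write_rnk
#' @export
read_rnk <- function(path) {
  d <- utils::read.delim(path, header = FALSE,
                         col.names = c("gene_id", "loading"),
                         stringsAsFactors = FALSE)
  check_ids(d$gene_id, "gene ids")
  d
}

#' Write / read a GRP gene list (one id per line)
#'
#' The query-file format for signature-matching uploads.
#'
#' @param ids Character vector of gene ids.
#' @param path File path.
#' @export
write_grp <- function(ids, path) {
  writeLines(as.character(ids), path)
  invisible(path)
}

#' @rdname write_grp
#' @export
read_grp <- function(path) {
  out <- readLines(path)
  out[nzchar(out)]
}
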