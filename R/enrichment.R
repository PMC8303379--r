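#' Hypergeometric over-representation analysis
#'
#' One-sided test of overlap between a query gene list and each gene set:
#' `p = P[X >= k]` for `X ~ Hypergeometric(N, K, n)` with universe size `N`,
#' term size `K` (after intersection with the universe), query size `n` and
#' overlap `k`; computed with the stable upper-tail survival function and
#' Benjamini-Hochberg adjusted across retained terms.
#'
#' @param query character vector of gene ids; genes outside the universe are
#'   dropped with a warning.
#' @param universe character vector of background gene ids (e.g. expressed
#'   genes).
#' @param genesets a [signature_set()].
#' @param min_term,max_term retained term sizes (after universe intersection).
#' @return data.frame sorted by p ascending (ties by term id): `term_id`,
#'   `term_name`, `k`, `n`, `K`, `N`, `gene_ratio`, `p_value`, `p_adjusted`,
#'   `hit_genes` (comma-separated).
#' @export
ora <- function(query, universe, genesets, min_term = 3, max_term = 500) {
  stopifnot(inherits(genesets, "signature_set"))
  universe <- unique(universe)
  if (length(universe) == 0) stop("empty universe")
  query <- unique(query)
  outside <- setdiff(query, universe)
  if (length(outside) > 0) {
    warning(length(outside), " query gene(s) outside the universe dropped")
    query <- intersect(query, universe)
  }
  if (length(query) == 0) stop("empty query after universe filtering")
  N <- length(universe)
  n <- length(query)
  rows <- lapply(names(genesets$sets), function(term) {
    tg <- intersect(genesets$sets[[term]], universe)
    K <- length(tg)
    if (K < min_term || K > max_term) return(NULL)
    hits <- intersect(query, tg)
    k <- length(hits)
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(term_id = term,
               term_name = if (nzchar(genesets$description[[term]]))
                 genesets$description[[term]] else term,
               k = k, n = n, K = K, N = N, gene_ratio = k / n,
               p_value = p,
               hit_genes = paste(sort(hits), collapse = ","),
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0) {
    out <- data.frame(term_id = character(0), term_name = character(0),
                      k = integer(0), n = integer(0), K = integer(0),
                      N = integer(0), gene_ratio = numeric(0),
                      p_value = numeric(0), p_adjusted = numeric(0),
                      hit_genes = character(0))
    return(out)
  }
  out <- do.call(rbind, rows)
  out$p_adjusted <- stats::p.adjust(out$p_value, method = "BH")
  out <- out[order(out$p_value, out$term_id), ]
  out <- out[, c("term_id", "term_name", "k", "n", "K", "N", "gene_ratio",
                 "p_value", "p_adjusted", "hit_genes")]
  rownames(out) <- NULL
  out
}

#' Combine enrichment results into a long-format dot-plot table
#'
#' Union of terms across conditions, one row per (term, condition); cells for
#' term/condition pairs missing from a result set are explicit NAs.
#'
#' @param results named list of [ora()] result data.frames (one per
#'   condition, e.g. timepoint or comparison).
#' @param path optional TSV output path.
#' @return data.frame with `term_id`, `condition`, `gene_ratio`,
#'   `p_adjusted`, `k`.
#' @export
dotplot_table <- function(results, path = NULL) {
  if (length(results) == 0) stop("need at least one result set")
  if (is.null(names(results))) names(results) <- paste0("condition", seq_along(results))
  terms <- unique(unlist(lapply(results, function(r) r$term_id)))
  out <- do.call(rbind, lapply(names(results), function(cond) {
    r <- results[[cond]]
    idx <- match(terms, r$term_id)
    data.frame(term_id = terms, condition = cond,
               gene_ratio = r$gene_ratio[idx], p_adjusted = r$p_adjusted[idx],
               k = r$k[idx], stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  if (!is.null(path))
    utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  out
}
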