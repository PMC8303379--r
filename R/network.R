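# all-pairs Pearson correlations between the rows of two matrices sharing
# sample columns, with two-sided t-based p-values
row_correlations <- function(X, Y) {
  if (!identical(colnames(X), colnames(Y)))
    stop("matrices do not share sample columns")
  n <- ncol(X)
  if (n < 3) stop("need at least 3 samples")
  r <- suppressWarnings(stats::cor(t(X), t(Y)))
  list(r = r, p = cor_pvalue(r, n), n = n)
}

edge_frame <- function(r, p, edge_type, p_adjusted = NULL) {
  src <- rep(rownames(r), ncol(r))
  tgt <- rep(colnames(r), each = nrow(r))
  out <- data.frame(source = src, target = tgt, r = as.vector(r),
                    p_value = as.vector(p), stringsAsFactors = FALSE)
  out$p_adjusted <- if (is.null(p_adjusted))
    stats::p.adjust(out$p_value, method = "BH") else as.vector(p_adjusted)
  out$edge_type <- edge_type
  out
}

#' lncRNA-pcRNA co-expression edges
#'
#' All lncRNA x protein-coding Pearson correlations on shared samples, with
#' BH-adjusted p-values across all tested pairs; retains
#' `|r| > r_min` and `p_adjusted < padj_max`.
#'
#' @param lnc_expr,pc_expr genes x samples matrices (log2-CPM) with identical
#'   sample columns.
#' @param r_min correlation threshold (strict, on |r|).
#' @param padj_max BH-adjusted p threshold (strict).
#' @param positive_only restrict to r > 0 edges.
#' @return data.frame of retained edges: `source` (lncRNA), `target` (pcRNA),
#'   `r`, `p_value`, `p_adjusted`, `edge_type = "lnc_pc"`.
#' @export
lnc_pc_edges <- function(lnc_expr, pc_expr, r_min = 0.9, padj_max = 0.01,
                         positive_only = FALSE) {
  cc <- row_correlations(lnc_expr, pc_expr)
  ed <- edge_frame(cc$r, cc$p, "lnc_pc")
  keep <- is.finite(ed$r) & abs(ed$r) > r_min & ed$p_adjusted < padj_max
  if (positive_only) keep <- keep & ed$r > 0
  out <- ed[keep, ]
  rownames(out) <- NULL
  out
}

#' lncRNA-immunocyte correlation edges (the imm-lncRNA screen)
#'
#' lncRNA x cell-type Pearson correlations against normalized infiltration
#' scores, thresholded at `|r| > r_min` and unadjusted `p < p_max`. Retained
#' edges define the imm-lncRNA candidate set.
#'
#' @param lnc_expr genes x samples matrix (log2-CPM).
#' @param scores an [infiltration_scores()] object or a celltype x sample
#'   matrix of normalized scores with matching sample columns.
#' @param r_min correlation threshold (strict, on |r|).
#' @param p_max unadjusted p threshold (strict).
#' @param positive_only restrict to r > 0 edges.
#' @return data.frame of retained edges: `source` (lncRNA), `target`
#'   (cell type), `r`, `p_value`, `p_adjusted` (BH, reported only),
#'   `edge_type = "lnc_cell"`.
#' @export
lnc_cell_edges <- function(lnc_expr, scores, r_min = 0.75, p_max = 0.001,
                           positive_only = FALSE) {
  sc <- if (inherits(scores, "infiltration_scores")) scores$normalized
        else as.matrix(scores)
  sds <- apply(sc, 1, stats::sd)
  if (any(sds == 0)) {
    warning("zero-variance cell type(s) excluded: ",
            paste(rownames(sc)[sds == 0], collapse = ", "))
    sc <- sc[sds > 0, , drop = FALSE]
  }
  cc <- row_correlations(lnc_expr, sc)
  ed <- edge_frame(cc$r, cc$p, "lnc_cell")
  keep <- is.finite(ed$r) & abs(ed$r) > r_min & ed$p_value < p_max
  if (positive_only) keep <- keep & ed$r > 0
  out <- ed[keep, ]
  rownames(out) <- NULL
  out
}

#' Degree and hub category per lncRNA
#'
#' Degree is the number of retained edges incident to each lncRNA; categories
#' are terciles of the degree distribution (`low`/`mid`/`high`), ties at a
#' tercile boundary resolved toward the higher category.
#'
#' @param edges edge data.frame whose `source` column holds lncRNA ids.
#' @return data.frame with `lnc_id`, `degree`, `category`, sorted by degree
#'   descending.
#' @export
hub_rank <- function(edges) {
  if (nrow(edges) == 0) stop("empty edge list")
  deg <- table(edges$source)
  d <- as.vector(deg)
  q <- stats::quantile(d, c(1 / 3, 2 / 3))
  category <- ifelse(d >= q[2], "high", ifelse(d >= q[1], "mid", "low"))
  out <- data.frame(lnc_id = names(deg), degree = d, category = category,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$degree, out$lnc_id), ]
  rownames(out) <- NULL
  out
}

#' Assemble the multilayer lncRNA-immunocyte-GO network
#'
#' For each imm-lncRNA (a lncRNA with at least one cell edge), its correlated
#' protein-coding partners are tested for over-representation against the
#' supplied gene-set collection; terms with `p_adjusted < ora_padj_max` are
#' attached as lncRNA-to-GO attribution edges. imm-lncRNAs without correlated
#' pcRNAs are kept and flagged `no functional attribution`.
#'
#' @param cell_edges retained edges from [lnc_cell_edges()].
#' @param pc_edges retained edges from [lnc_pc_edges()].
#' @param genesets functional [signature_set()] (GO/KEGG-style collection).
#' @param universe background gene ids for the enrichment.
#' @param ora_padj_max adjusted-p threshold for attaching terms.
#' @param min_term,max_term term-size window passed to [ora()].
#' @return object of class `multilayer_network`: list with `nodes` (typed:
#'   lncRNA/pcRNA/immunocyte/go_term), `edges` (correlation edges), `go_edges`
#'   (lnc -> term attributions with the ora p and gene ratio), `hubs`
#'   (per-lncRNA degree/category over all correlation edges), `flags`.
#' @export
build_multilayer <- function(cell_edges, pc_edges, genesets, universe,
                             ora_padj_max = 0.05, min_term = 3,
                             max_term = 500) {
  imm_lnc <- unique(cell_edges$source)
  go_edges <- data.frame(source = character(0), target = character(0),
                         p_adjusted = numeric(0), gene_ratio = numeric(0),
                         stringsAsFactors = FALSE)
  flags <- character(0)
  for (l in imm_lnc) {
    partners <- pc_edges$target[pc_edges$source == l]
    if (length(partners) == 0) {
      flags[l] <- "no functional attribution"
      next
    }
    res <- tryCatch(ora(partners, universe, genesets, min_term = min_term,
                        max_term = max_term),
                    warning = function(w) suppressWarnings(
                      ora(partners, universe, genesets, min_term = min_term,
                          max_term = max_term)))
    hit <- res[res$p_adjusted < ora_padj_max, , drop = FALSE]
    if (nrow(hit) == 0) {
      flags[l] <- "no functional attribution"
      next
    }
    go_edges <- rbind(go_edges,
                      data.frame(source = l, target = hit$term_id,
                                 p_adjusted = hit$p_adjusted,
                                 gene_ratio = hit$gene_ratio,
                                 stringsAsFactors = FALSE))
  }
  all_edges <- rbind(cell_edges, pc_edges[pc_edges$source %in% imm_lnc, ,
                                          drop = FALSE])
  typed <- function(ids, type) data.frame(id = ids,
                                          type = rep(type, length(ids)),
                                          stringsAsFactors = FALSE)
  nodes <- rbind(typed(imm_lnc, "lncRNA"),
                 typed(unique(cell_edges$target), "immunocyte"),
                 typed(unique(pc_edges$target[pc_edges$source %in% imm_lnc]),
                       "pcRNA"),
                 typed(unique(go_edges$target), "go_term"))
  dup <- duplicated(nodes$id)
  if (any(dup))
    stop("node id(s) shared across layers: ",
         paste(unique(nodes$id[dup]), collapse = ", "),
         " (rename the functional gene-set collection)")
  hubs <- if (nrow(all_edges) > 0) hub_rank(all_edges) else
    data.frame(lnc_id = character(0), degree = integer(0),
               category = character(0))
  structure(list(nodes = nodes, edges = all_edges, go_edges = go_edges,
                 hubs = hubs, flags = flags),
            class = "multilayer_network")
}

#' @export
print.multilayer_network <- function(x, ...) {
  cat("multilayer_network:", nrow(x$nodes), "nodes (",
      paste(names(table(x$nodes$type)), table(x$nodes$type),
            collapse = ", "), "),",
      nrow(x$edges), "correlation edges,", nrow(x$go_edges),
      "GO attributions\n")
  invisible(x)
}

#' Sankey long-format table of the multilayer network
#'
#' One row per (lncRNA, immunocyte, GO term) path: every cell edge of a
#' lncRNA crossed with every attached term; link weights are `|r|` of the
#' cell edge and the term's gene ratio.
#'
#' @param net a [build_multilayer()] network.
#' @return data.frame with `lncRNA`, `immunocyte`, `go_term`, `cell_r`,
#'   `gene_ratio`.
#' @export
sankey_table <- function(net) {
  stopifnot(inherits(net, "multilayer_network"))
  cell <- net$edges[net$edges$edge_type == "lnc_cell", , drop = FALSE]
  out <- do.call(rbind, lapply(unique(cell$source), function(l) {
    ce <- cell[cell$source == l, , drop = FALSE]
    ge <- net$go_edges[net$go_edges$source == l, , drop = FALSE]
    if (nrow(ge) == 0) return(NULL)
    expand <- expand.grid(ci = seq_len(nrow(ce)), gi = seq_len(nrow(ge)))
    data.frame(lncRNA = l, immunocyte = ce$target[expand$ci],
               go_term = ge$target[expand$gi],
               cell_r = abs(ce$r[expand$ci]),
               gene_ratio = ge$gene_ratio[expand$gi],
               stringsAsFactors = FALSE)
  }))
  if (is.null(out))
    out <- data.frame(lncRNA = character(0), immunocyte = character(0),
                      go_term = character(0), cell_r = numeric(0),
                      gene_ratio = numeric(0))
  rownames(out) <- NULL
  out
}

#' Export a multilayer network
#'
#' Formats: `graphml` (typed nodes, r/p edge attributes; via igraph),
#' `edgelist` (TSV of all correlation and attribution edges), `sankey`
#' (long-format TSV from [sankey_table()]).
#'
#' @param net a [build_multilayer()] network.
#' @param format one of `"graphml"`, `"edgelist"`, `"sankey"`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
export_network <- function(net, format = c("graphml", "edgelist", "sankey"),
                           path) {
  stopifnot(inherits(net, "multilayer_network"))
  if (!format[1] %in% c("graphml", "edgelist", "sankey"))
    stop("unknown format '", format[1],
         "'; supported: graphml, edgelist, sankey")
  format <- match.arg(format)
  if (format == "graphml") {
    g <- multilayer_igraph(net)
    igraph::write_graph(g, path, format = "graphml")
  } else if (format == "edgelist") {
    ed <- net$edges
    ge <- net$go_edges
    if (nrow(ge) > 0)
      ed <- rbind(ed, data.frame(source = ge$source, target = ge$target,
                                 r = NA_real_, p_value = NA_real_,
                                 p_adjusted = ge$p_adjusted,
                                 edge_type = "lnc_go",
                                 stringsAsFactors = FALSE))
    utils::write.table(ed, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    utils::write.table(sankey_table(net), path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

#' Convert a multilayer network to an igraph object
#'
#' @param net a [build_multilayer()] network.
#' @return an undirected igraph graph with a `type` vertex attribute and
#'   `r`, `p_value`, `p_adjusted`, `edge_type` edge attributes.
#' @export
multilayer_igraph <- function(net) {
  stopifnot(inherits(net, "multilayer_network"))
  ed <- net$edges
  ge <- net$go_edges
  if (nrow(ge) > 0)
    ed <- rbind(ed[, c("source", "target", "r", "p_value", "p_adjusted",
                       "edge_type")],
                data.frame(source = ge$source, target = ge$target,
                           r = NA_real_, p_value = NA_real_,
                           p_adjusted = ge$p_adjusted, edge_type = "lnc_go",
                           stringsAsFactors = FALSE))
  igraph::graph_from_data_frame(ed, directed = FALSE,
                                vertices = unique(net$nodes))
}
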