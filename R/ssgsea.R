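#' Single-sample GSEA enrichment scores
#'
#' Per sample, all N genes are ranked by expression (highest expression gets
#' rank value N; ties break deterministically by gene id). Walking the ranked
#' list, a gene set G accumulates the weighted in-set empirical distribution
#' `P_in(i) = sum_{j <= i, j in G} r_j^alpha / sum_{j in G} r_j^alpha` against
#' the unweighted out-of-set one `P_out(i) = #{j <= i, j notin G} / (N - |G|)`;
#' the enrichment score is the sum of `P_in(i) - P_out(i)` over all N
#' positions.
#'
#' @param expr genes x samples real matrix (log2-CPM recommended, prior 1).
#' @param signatures a [signature_set()]; every set must intersect the matrix
#'   genes in at least 1 and at most N-1 genes.
#' @param alpha rank weighting exponent (standard ssGSEA weight 0.25).
#' @return celltype x sample matrix of raw enrichment scores.
#' @export
ssgsea_scores <- function(expr, signatures, alpha = 0.25) {
  stopifnot(inherits(signatures, "signature_set"))
  expr <- as.matrix(expr)
  N <- nrow(expr)
  if (N < 2) stop("need at least 2 genes")
  if (length(signatures) == 0) stop("empty signature set")
  if (is.null(rownames(expr))) stop("expression matrix must have gene ids")
  sets <- lapply(signatures$sets, function(g) intersect(g, rownames(expr)))
  empty <- names(sets)[lengths(sets) == 0]
  if (length(empty) > 0)
    stop("signature(s) with zero overlap with the matrix: ",
         paste(empty, collapse = ", "))
  full <- names(sets)[lengths(sets) == N]
  if (length(full) > 0)
    stop("signature(s) covering every gene are degenerate: ",
         paste(full, collapse = ", "))
  const <- apply(expr, 2, function(x) max(x) == min(x))
  if (any(const))
    stop("all-constant sample(s), ranking undefined: ",
         paste(colnames(expr)[const], collapse = ", "))
  es <- matrix(NA_real_, length(sets), ncol(expr),
               dimnames = list(names(sets), colnames(expr)))
  gene_ids <- rownames(expr)
  set_members <- lapply(sets, function(g) gene_ids %in% g)
  for (s in seq_len(ncol(expr))) {
    x <- expr[, s]
    ord <- order(-x, gene_ids)          # descending, ties by gene id
    r <- rev(seq_len(N))                # rank value at each ordered position
    w <- r^alpha
    for (k in seq_along(sets)) {
      ind <- set_members[[k]][ord]
      win <- w * ind
      p_in <- cumsum(win) / sum(win)
      p_out <- cumsum(!ind) / (N - sum(ind))
      es[k, s] <- sum(p_in - p_out)
    }
  }
  es
}

#' Min-max normalize raw enrichment scores
#'
#' `(x - min) / (max - min)` using the global minimum and maximum of the raw
#' matrix, mapping all scores into `[0, 1]`.
#'
#' @param raw_es celltype x sample matrix from [ssgsea_scores()].
#' @return normalized matrix of the same shape.
#' @export
normalize_scores <- function(raw_es) {
  rng <- range(raw_es)
  if (rng[1] == rng[2]) stop("constant score matrix cannot be normalized")
  (raw_es - rng[1]) / (rng[2] - rng[1])
}

#' Convert normalized scores to per-sample fractions
#'
#' Each sample column is divided by its column sum, so cell-type fractions
#' within a sample add to 1.
#'
#' @param normalized non-negative celltype x sample matrix.
#' @return matrix with columns summing to 1.
#' @export
score_fractions <- function(normalized) {
  if (any(normalized < 0)) stop("normalized scores must be non-negative")
  cs <- colSums(normalized)
  if (any(cs == 0))
    stop("all-zero sample column(s): ",
         paste(colnames(normalized)[cs == 0], collapse = ", "))
  sweep(normalized, 2, cs, `/`)
}

#' Full infiltration scoring of an expression matrix
#'
#' Convenience wrapper: raw ssGSEA scores, min-max normalized scores and
#' per-sample fractions in one object.
#'
#' @inheritParams ssgsea_scores
#' @return object of class `infiltration_scores`: list with `raw_es`,
#'   `normalized`, `fractions` (all celltype x sample matrices).
#' @export
infiltration_scores <- function(expr, signatures, alpha = 0.25) {
  raw <- ssgsea_scores(expr, signatures, alpha = alpha)
  norm <- normalize_scores(raw)
  structure(list(raw_es = raw, normalized = norm,
                 fractions = score_fractions(norm)),
            class = "infiltration_scores")
}

#' @export
print.infiltration_scores <- function(x, ...) {
  cat("infiltration_scores:", nrow(x$raw_es), "cell types x",
      ncol(x$raw_es), "samples\n")
  invisible(x)
}

#' Pairwise Pearson correlation of cell-type scores
#'
#' Correlations across samples with two-sided p-values from the t statistic
#' `r * sqrt(n - 2) / sqrt(1 - r^2)` on `n - 2` degrees of freedom; the
#' diagonal is `r = 1, p = 0` by convention. Zero-variance cell types give NA
#' with a warning.
#'
#' @param scores celltype x sample matrix (>= 3 samples), e.g. the
#'   `normalized` slot of [infiltration_scores()].
#' @return list with symmetric matrices `r` and `p`.
#' @export
celltype_correlation <- function(scores) {
  n <- ncol(scores)
  if (n < 3) stop("need at least 3 samples")
  sds <- apply(scores, 1, stats::sd)
  if (any(sds == 0))
    warning("zero-variance cell type(s) set to NA: ",
            paste(rownames(scores)[sds == 0], collapse = ", "))
  r <- suppressWarnings(stats::cor(t(scores)))
  p <- cor_pvalue(r, n)
  diag(r) <- 1
  diag(p) <- 0
  r[sds == 0, ] <- NA_real_; r[, sds == 0] <- NA_real_
  p[sds == 0, ] <- NA_real_; p[, sds == 0] <- NA_real_
  list(r = r, p = p)
}

# two-sided p-value for a Pearson correlation on n samples
cor_pvalue <- function(r, n) {
  t <- r * sqrt(n - 2) / sqrt(pmax(1 - r^2, .Machine$double.eps))
  2 * stats::pt(-abs(t), df = n - 2)
}

#' Tidy long-format score table for heatmap plotting
#'
#' @param scores an [infiltration_scores()] object.
#' @param samples optional sample metadata data.frame to join on `sample_id`.
#' @return data.frame with `celltype`, `sample_id`, `raw_es`, `normalized`,
#'   `fraction` and any metadata columns.
#' @export
scores_long <- function(scores, samples = NULL) {
  stopifnot(inherits(scores, "infiltration_scores"))
  out <- data.frame(
    celltype = rep(rownames(scores$raw_es), ncol(scores$raw_es)),
    sample_id = rep(colnames(scores$raw_es), each = nrow(scores$raw_es)),
    raw_es = as.vector(scores$raw_es),
    normalized = as.vector(scores$normalized),
    fraction = as.vector(scores$fractions),
    stringsAsFactors = FALSE)
  if (!is.null(samples))
    out <- merge(out, samples, by = "sample_id", sort = FALSE)
  out
}
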