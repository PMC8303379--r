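#' Trimmed mean of M-values (TMM) normalization factors
#'
#' Between-sample scale factors robust to asymmetric differential expression.
#' For each sample against a reference, per-gene log2 ratios M and mean log2
#' abundances A are computed over genes expressed in both; genes in the 30%
#' two-sided M tails or the 5% two-sided A tails are discarded and the factor
#' is 2^(precision-weighted mean of the retained M). Factors are rescaled so
#' their geometric mean is 1.
#'
#' @param mat an [expression_matrix()] or counts matrix (>= 2 samples).
#' @param ref_sample optional reference sample id; defaults to the sample
#'   whose upper-quartile CPM is closest to the mean upper quartile.
#' @param logratio_trim,abundance_trim two-sided trim fractions for M and A.
#' @return named numeric vector of per-sample factors (geometric mean 1).
#' @export
tmm_factors <- function(mat, ref_sample = NULL, logratio_trim = 0.3,
                        abundance_trim = 0.05) {
  counts <- if (inherits(mat, "expression_matrix")) mat$counts else as.matrix(mat)
  if (ncol(counts) < 2) stop("TMM needs at least 2 samples")
  lib <- colSums(counts)
  if (any(lib == 0))
    stop("sample(s) with all-zero counts: ",
         paste(colnames(counts)[lib == 0], collapse = ", "))
  if (is.null(ref_sample)) {
    uq <- apply(counts, 2, function(x) stats::quantile(x / sum(x), 0.75))
    ref_sample <- colnames(counts)[which.min(abs(uq - base::mean(uq)))]
  }
  if (!ref_sample %in% colnames(counts))
    stop("reference sample not found: ", ref_sample)
  yr <- counts[, ref_sample]
  nr <- lib[[ref_sample]]
  f <- vapply(colnames(counts), function(s) {
    if (s == ref_sample) return(1)
    ys <- counts[, s]
    ns <- lib[[s]]
    keep <- ys > 0 & yr > 0
    y1 <- ys[keep]; y2 <- yr[keep]
    M <- log2((y1 / ns) / (y2 / nr))
    A <- 0.5 * log2((y1 / ns) * (y2 / nr))
    if (length(M) == 0) return(1)
    if (max(abs(M)) < 1e-6) return(1)  # identical relative profiles
    n <- length(M)
    loM <- floor(n * logratio_trim) + 1; hiM <- n + 1 - loM
    loA <- floor(n * abundance_trim) + 1; hiA <- n + 1 - loA
    rM <- rank(M); rA <- rank(A)
    keep2 <- rM >= loM & rM <= hiM & rA >= loA & rA <= hiA
    if (!any(keep2)) return(1)
    # precision weights: inverse asymptotic variance of M (delta method)
    v <- (ns - y1) / (ns * y1) + (nr - y2) / (nr * y2)
    2^(sum(M[keep2] / v[keep2]) / sum(1 / v[keep2]))
  }, numeric(1))
  f <- f / exp(base::mean(log(f)))
  f
}

#' Method-of-moments negative-binomial dispersion estimates
#'
#' Per-gene dispersion `phi_g = max(0, (s^2 - m) / m^2)` on counts normalized
#' to a common effective library size, with within-group pooling of the
#' variance, shrunk toward the median dispersion with fixed weight
#' `lambda = 0.3`.
#'
#' @param mat an [expression_matrix()] or counts matrix.
#' @param groups factor/vector of group labels, one per sample; at least one
#'   group must have >= 2 replicates.
#' @param norm_factors optional TMM factors (default [tmm_factors()] when
#'   >= 2 samples, else 1).
#' @param lambda shrinkage weight toward the median dispersion.
#' @return named numeric vector of per-gene dispersions.
#' @export
estimate_dispersion <- function(mat, groups, norm_factors = NULL,
                                lambda = 0.3) {
  counts <- if (inherits(mat, "expression_matrix")) mat$counts else as.matrix(mat)
  if (ncol(counts) < 2) stop("dispersion estimation needs >= 2 samples")
  groups <- as.factor(groups)
  if (length(groups) != ncol(counts))
    stop("groups length must match sample count")
  if (max(table(groups)) < 2)
    stop("at least one group must have >= 2 replicates")
  if (is.null(norm_factors)) norm_factors <- tmm_factors(counts)
  eff <- colSums(counts) * norm_factors
  z <- sweep(counts, 2, base::mean(eff) / eff, `*`)
  m <- rowMeans(z)
  # pooled within-group variance
  ss <- matrix(0, nrow(counts), 1)
  df <- 0
  for (g in levels(groups)) {
    idx <- which(groups == g)
    if (length(idx) < 2) next
    zg <- z[, idx, drop = FALSE]
    ss <- ss + rowSums((zg - rowMeans(zg))^2)
    df <- df + length(idx) - 1
  }
  s2 <- as.vector(ss) / df
  phi <- ifelse(m > 0, pmax(0, (s2 - m) / m^2), 0)
  phi_common <- stats::median(phi[m > 0])
  if (!is.finite(phi_common)) phi_common <- 0
  out <- (1 - lambda) * phi + lambda * phi_common
  names(out) <- rownames(counts)
  out
}

# quantile-to-quantile NB map of counts from one mean to another at fixed
# per-gene dispersion (mid-probability mapping; Poisson branch for phi ~ 0)
q2q_nb <- function(y, mu_in, mu_out, phi) {
  out <- numeric(length(y))
  pois <- phi < 1e-8
  if (any(pois)) {
    p <- stats::ppois(y[pois] - 1, mu_in[pois]) +
      0.5 * stats::dpois(y[pois], mu_in[pois])
    out[pois] <- stats::qpois(pmin(pmax(p, 0), 1 - 1e-12), mu_out[pois])
  }
  if (any(!pois)) {
    size <- 1 / phi[!pois]
    p <- stats::pnbinom(y[!pois] - 1, mu = mu_in[!pois], size = size) +
      0.5 * stats::dnbinom(y[!pois], mu = mu_in[!pois], size = size)
    out[!pois] <- stats::qnbinom(pmin(pmax(p, 0), 1 - 1e-12),
                                 mu = mu_out[!pois], size = size)
  }
  out
}

# conditional two-sided exact NB p-value: given group totals (ya, yb) from
# (na, nb) equal-size libraries and dispersion phi, sum the probabilities of
# all splits of the total no more likely than the observed one
nb_exact_pvalue <- function(ya, yb, na, nb, phi) {
  t <- ya + yb
  if (t == 0) return(1)
  av <- 0:t
  if (phi < 1e-8) {
    lp <- stats::dbinom(av, t, na / (na + nb), log = TRUE)
  } else {
    m <- t / (na + nb)
    lp <- stats::dnbinom(av, mu = na * m, size = na / phi, log = TRUE) +
      stats::dnbinom(t - av, mu = nb * m, size = nb / phi, log = TRUE)
  }
  lmax <- max(lp)
  pr <- exp(lp - lmax)
  obs <- pr[ya + 1]
  sum(pr[pr <= obs * (1 + 1e-10)]) / sum(pr)
}

#' Exact negative-binomial test between two groups
#'
#' Per gene: counts are quantile-adjusted to a common effective library size
#' (the mean TMM-scaled library), group totals are conditioned on the overall
#' total, and the two-sided exact p-value is the summed probability of all
#' splits no more likely than the observed one under a shared-mean NB with the
#' gene's dispersion. Log2 fold changes come from normalized group means with
#' a prior count; p-values are Benjamini-Hochberg adjusted across genes.
#'
#' @param mat an [expression_matrix()] or counts matrix.
#' @param groupA,groupB disjoint non-empty vectors of sample ids; fold change
#'   is reported as B over A.
#' @param dispersions per-gene dispersion vector (default:
#'   [estimate_dispersion()] on the two groups).
#' @param norm_factors optional TMM factors for all samples in `mat`.
#' @param prior_count prior added to group means for the log2 fold change.
#' @param comparison,timepoint_days labels carried into the result table.
#' @return data.frame with columns `gene_id`, `log2fc`, `p_value`,
#'   `p_adjusted`, `mean_cpm`, `comparison`, `timepoint_days`.
#' @export
nb_exact_test <- function(mat, groupA, groupB, dispersions = NULL,
                          norm_factors = NULL, prior_count = 0.5,
                          comparison = "", timepoint_days = NA_integer_) {
  counts <- if (inherits(mat, "expression_matrix")) mat$counts else as.matrix(mat)
  if (length(intersect(groupA, groupB)) > 0)
    stop("groups must be disjoint")
  if (length(groupA) == 0 || length(groupB) == 0)
    stop("groups must be non-empty")
  miss <- setdiff(c(groupA, groupB), colnames(counts))
  if (length(miss) > 0)
    stop("unknown sample id(s): ", paste(miss, collapse = ", "))
  sub <- counts[, c(groupA, groupB), drop = FALSE]
  if (any(colSums(sub) == 0) || sum(sub[, groupA]) == 0 ||
      sum(sub[, groupB]) == 0)
    stop("a group has zero total counts")
  if (is.null(norm_factors)) {
    norm_factors <- tmm_factors(sub)
  } else {
    if (is.null(names(norm_factors))) {
      if (length(norm_factors) == ncol(sub)) {
        names(norm_factors) <- colnames(sub)
      } else if (length(norm_factors) == ncol(counts)) {
        names(norm_factors) <- colnames(counts)
      } else stop("norm_factors length does not match the samples")
    }
    norm_factors <- norm_factors[c(groupA, groupB)]
  }
  if (is.null(dispersions)) {
    grp <- c(rep("A", length(groupA)), rep("B", length(groupB)))
    dispersions <- estimate_dispersion(sub, grp, norm_factors = norm_factors)
  }
  dispersions <- dispersions[rownames(sub)]
  eff <- colSums(sub) * norm_factors
  common <- base::mean(eff)
  # per-gene common-scale abundance and pseudo-counts at equal library size
  p_g <- rowSums(sub) / sum(eff) * common
  pseudo <- sub
  for (j in seq_len(ncol(sub))) {
    pseudo[, j] <- q2q_nb(sub[, j], p_g * (eff[j] / common), p_g, dispersions)
  }
  na <- length(groupA); nb <- length(groupB)
  ya <- rowSums(pseudo[, groupA, drop = FALSE])
  yb <- rowSums(pseudo[, groupB, drop = FALSE])
  pv <- vapply(seq_len(nrow(sub)), function(i) {
    nb_exact_pvalue(ya[i], yb[i], na, nb, dispersions[i])
  }, numeric(1))
  z <- sweep(sub, 2, common / eff, `*`)
  mA <- rowMeans(z[, groupA, drop = FALSE])
  mB <- rowMeans(z[, groupB, drop = FALSE])
  lfc <- log2((mB + prior_count) / (mA + prior_count))
  mean_cpm <- rowMeans(cpm(sub, lib_sizes = eff))
  data.frame(gene_id = rownames(sub), log2fc = lfc, p_value = pv,
             p_adjusted = stats::p.adjust(pv, method = "BH"),
             mean_cpm = mean_cpm, comparison = comparison,
             timepoint_days = timepoint_days,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Filter genes by expression before testing
#'
#' Keep genes with CPM above `cpm_min` in at least `min_samples` samples.
#'
#' @param mat an [expression_matrix()] or counts matrix.
#' @param cpm_min CPM threshold.
#' @param min_samples minimum number of samples above threshold.
#' @return character vector of retained gene ids.
#' @export
filter_expressed <- function(mat, cpm_min = 1, min_samples = 2) {
  counts <- if (inherits(mat, "expression_matrix")) mat$counts else as.matrix(mat)
  keep <- rowSums(cpm(counts) > cpm_min) >= min_samples
  rownames(counts)[keep]
}

#' Call differentially expressed genes
#'
#' Applies the fold-change and p-value thresholds (|log2FC| >= 0.5 and
#' p < 0.05 by default, thresholds inclusive on the fold change) and labels
#' each gene `up`, `down` or `ns`.
#'
#' @param results data.frame from [nb_exact_test()].
#' @param lfc_threshold inclusive |log2FC| threshold.
#' @param p_threshold p-value threshold (strict).
#' @param use_adjusted use BH-adjusted p-values for calling instead of raw.
#' @return the input with a `direction` column; attribute `summary` holds
#'   `n_up`, `n_down`, `n_total = n_up + n_down`.
#' @export
call_degs <- function(results, lfc_threshold = 0.5, p_threshold = 0.05,
                      use_adjusted = FALSE) {
  if (nrow(results) == 0) {
    results$direction <- character(0)
    attr(results, "summary") <- c(n_up = 0, n_down = 0, n_total = 0)
    return(results)
  }
  p <- if (use_adjusted) results$p_adjusted else results$p_value
  dir <- rep("ns", nrow(results))
  dir[results$log2fc >= lfc_threshold & p < p_threshold] <- "up"
  dir[results$log2fc <= -lfc_threshold & p < p_threshold] <- "down"
  results$direction <- dir
  attr(results, "summary") <- c(n_up = sum(dir == "up"),
                                n_down = sum(dir == "down"),
                                n_total = sum(dir != "ns"))
  results
}

#' All intersection-region counts for up to five sets (Venn table)
#'
#' @param deg_sets named list (2-5 entries) of character id vectors.
#' @return data.frame with one row per non-empty region pattern: logical
#'   membership columns, `region` label, `count`; attribute `members` holds
#'   the ids per region.
#' @export
overlap_sets <- function(deg_sets) {
  k <- length(deg_sets)
  if (k < 2) stop("need at least 2 sets")
  if (k > 5) stop("more than 5 sets unsupported")
  if (is.null(names(deg_sets))) stop("sets must be named")
  universe <- unique(unlist(deg_sets))
  memb <- vapply(deg_sets, function(s) universe %in% s, logical(length(universe)))
  if (length(universe) == 1) memb <- matrix(memb, nrow = 1,
                                            dimnames = list(NULL, names(deg_sets)))
  patt <- expand.grid(rep(list(c(FALSE, TRUE)), k))[-1, , drop = FALSE]
  names(patt) <- names(deg_sets)
  key <- apply(memb, 1, function(r) paste(as.integer(r), collapse = ""))
  pkey <- apply(patt, 1, function(r) paste(as.integer(r), collapse = ""))
  counts <- vapply(pkey, function(pk) sum(key == pk), integer(1))
  members <- lapply(pkey, function(pk) universe[key == pk])
  region <- apply(patt, 1, function(r)
    paste(names(deg_sets)[as.logical(r)], collapse = "&"))
  out <- cbind(patt, data.frame(region = region, count = counts,
                                stringsAsFactors = FALSE))
  rownames(out) <- NULL
  names(members) <- region
  attr(out, "members") <- members
  out
}

# natural chromosome order: 1..n numerically, then X, Y, then the rest
natural_chrom_order <- function(chroms) {
  u <- unique(chroms)
  num <- suppressWarnings(as.numeric(u))
  lev <- c(u[!is.na(num)][order(num[!is.na(num)])],
           intersect(c("X", "Y"), u),
           sort(setdiff(u[is.na(num)], c("X", "Y"))))
  factor(chroms, levels = lev)
}

#' Export DEGs in chromosome order with per-timepoint fold-change columns
#'
#' Rows are the union of DEGs across the supplied tables, ordered by natural
#' chromosome sort (1..19, X, Y) then start position; one log2FC column per
#' timepoint. This is the data table behind a circos-style DEG plot.
#'
#' @param deg_tables list of called DEG tables (from [call_degs()]) with a
#'   `timepoint_days` column; only rows with direction != "ns" are used.
#' @param annotation annotation data.frame covering every DEG.
#' @param path optional TSV output path.
#' @return the ordered data.frame, invisibly written to `path` if given.
#' @export
circos_export <- function(deg_tables, annotation, path = NULL) {
  degs <- do.call(rbind, lapply(deg_tables, function(tb)
    tb[tb$direction != "ns", c("gene_id", "log2fc", "timepoint_days")]))
  ids <- unique(degs$gene_id)
  idx <- match(ids, annotation$gene_id)
  if (anyNA(idx))
    stop("unannotated DEG(s): ", paste(ids[is.na(idx)], collapse = ", "))
  out <- data.frame(gene_id = ids, chromosome = annotation$chromosome[idx],
                    start = annotation$start[idx], stringsAsFactors = FALSE)
  for (tp in sort(unique(degs$timepoint_days))) {
    col <- stats::setNames(degs$log2fc[degs$timepoint_days == tp],
                           degs$gene_id[degs$timepoint_days == tp])
    out[[paste0("log2fc_day", tp)]] <- unname(col[out$gene_id])
  }
  out <- out[order(natural_chrom_order(out$chromosome), out$start,
                   out$gene_id), ]
  rownames(out) <- NULL
  if (!is.null(path))
    utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out)
}

#' DEG bookkeeping summary across comparisons and timepoints
#'
#' Per (comparison, timepoint) up/down/total counts plus grand totals per
#' comparison (`timepoint_days = "all"`); totals are sums of the per-timepoint
#' parts and `n_total = n_up + n_down` everywhere.
#'
#' @param deg_tables list of called DEG tables (from [call_degs()]) carrying
#'   `comparison` and `timepoint_days` columns.
#' @return data.frame with columns `comparison`, `timepoint_days`, `n_up`,
#'   `n_down`, `n_total`.
#' @export
deg_summary <- function(deg_tables) {
  if (length(deg_tables) == 0) stop("need at least one DEG table")
  all <- do.call(rbind, lapply(deg_tables, function(tb)
    tb[, c("gene_id", "direction", "comparison", "timepoint_days")]))
  cells <- unique(all[, c("comparison", "timepoint_days")])
  cells <- cells[order(cells$comparison, cells$timepoint_days), ]
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    sel <- all$comparison == cells$comparison[i] &
      all$timepoint_days == cells$timepoint_days[i]
    data.frame(comparison = cells$comparison[i],
               timepoint_days = as.character(cells$timepoint_days[i]),
               n_up = sum(all$direction[sel] == "up"),
               n_down = sum(all$direction[sel] == "down"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  totals <- lapply(unique(out$comparison), function(cmp) {
    sel <- out$comparison == cmp
    data.frame(comparison = cmp, timepoint_days = "all",
               n_up = sum(out$n_up[sel]), n_down = sum(out$n_down[sel]),
               stringsAsFactors = FALSE)
  })
  out <- rbind(out, do.call(rbind, totals))
  out$n_total <- out$n_up + out$n_down
  rownames(out) <- NULL
  out
}
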