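#' Construct a validated expression matrix
#'
#' Bundles an integer count matrix (genes x samples) with per-sample metadata.
#' Counts must be non-negative integers; gene and sample identifiers must be
#' unique; the metadata rows must match the count columns one-to-one and in
#' order.
#'
#' @param counts numeric matrix of non-negative integer counts with gene ids as
#'   rownames and sample ids as colnames.
#' @param samples data.frame with columns `sample_id`, `genotype` (`"WT"` or
#'   `"KO"`), `treatment` (`"vehicle"` or `"histamine"`), `timepoint_days`
#'   (integer), `replicate` (integer >= 1). One row per count column, same
#'   order.
#' @return An object of class `expression_matrix`: a list with elements
#'   `counts` (integer matrix) and `samples` (the metadata data.frame).
#' @export
expression_matrix <- function(counts, samples) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts))) stop("counts must have gene ids as rownames")
  if (is.null(colnames(counts))) stop("counts must have sample ids as colnames")
  bad <- which(!is.finite(counts) | counts < 0 | counts != round(counts),
               arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf("non-integer or negative count for gene '%s', sample '%s'",
                 rownames(counts)[bad[1, 1]], colnames(counts)[bad[1, 2]]))
  }
  storage.mode(counts) <- "integer"
  dup <- unique(rownames(counts)[duplicated(rownames(counts))])
  if (length(dup) > 0)
    stop("duplicated gene id(s): ", paste(dup, collapse = ", "))
  if (anyDuplicated(colnames(counts)))
    stop("duplicated sample id(s): ",
         paste(unique(colnames(counts)[duplicated(colnames(counts))]),
               collapse = ", "))
  samples <- validate_sample_meta(samples)
  if (nrow(samples) != ncol(counts))
    stop("number of count columns (", ncol(counts),
         ") does not match number of metadata rows (", nrow(samples), ")")
  if (!identical(samples$sample_id, colnames(counts)))
    stop("sample ids in metadata do not match count column names (order matters)")
  structure(list(counts = counts, samples = samples),
            class = "expression_matrix")
}

validate_sample_meta <- function(samples) {
  req <- c("sample_id", "genotype", "treatment", "timepoint_days", "replicate")
  miss <- setdiff(req, names(samples))
  if (length(miss) > 0)
    stop("sample metadata missing column(s): ", paste(miss, collapse = ", "))
  samples$sample_id <- as.character(samples$sample_id)
  samples$genotype <- as.character(samples$genotype)
  samples$treatment <- as.character(samples$treatment)
  samples$timepoint_days <- as.integer(samples$timepoint_days)
  samples$replicate <- as.integer(samples$replicate)
  if (!all(samples$genotype %in% c("WT", "KO")))
    stop("genotype must be 'WT' or 'KO'")
  if (!all(samples$treatment %in% c("vehicle", "histamine")))
    stop("treatment must be 'vehicle' or 'histamine'")
  if (any(samples$replicate < 1)) stop("replicate must be >= 1")
  key <- paste(samples$genotype, samples$treatment, samples$timepoint_days,
               samples$replicate)
  if (anyDuplicated(key))
    stop("duplicated (genotype, treatment, timepoint, replicate) combination")
  rownames(samples) <- NULL
  samples
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat("expression_matrix:", nrow(x$counts), "genes x", ncol(x$counts),
      "samples\n")
  cat("  arms:", paste(sort(unique(paste0(x$samples$genotype, "-",
                                          x$samples$treatment))),
                       collapse = ", "), "\n")
  cat("  timepoints (days):",
      paste(sort(unique(x$samples$timepoint_days)), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.expression_matrix <- function(x) dim(x$counts)

#' Read a count matrix and sample metadata from TSV files
#'
#' The counts file is a TSV whose header row holds sample ids and whose first
#' column holds gene ids. The metadata file is a TSV with columns `sample_id`,
#' `genotype`, `treatment`, `timepoint_days`, `replicate`. Count columns are
#' reordered to follow the metadata row order.
#'
#' @param path path to the counts TSV.
#' @param metadata_path path to the sample metadata TSV.
#' @return An [expression_matrix()].
#' @export
read_counts <- function(path, metadata_path) {
  if (!file.exists(path)) stop("counts file not found: ", path)
  if (!file.exists(metadata_path))
    stop("metadata file not found: ", metadata_path)
  tab <- utils::read.delim(path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  gene_ids <- as.character(tab[[1]])
  counts <- as.matrix(tab[, -1, drop = FALSE])
  rownames(counts) <- gene_ids
  meta <- utils::read.delim(metadata_path, check.names = FALSE,
                            stringsAsFactors = FALSE)
  meta <- validate_sample_meta(meta)
  if (!setequal(colnames(counts), meta$sample_id))
    stop("sample ids differ between counts file and metadata: counts-only {",
         paste(setdiff(colnames(counts), meta$sample_id), collapse = ", "),
         "}, metadata-only {",
         paste(setdiff(meta$sample_id, colnames(counts)), collapse = ", "), "}")
  counts <- counts[, meta$sample_id, drop = FALSE]
  expression_matrix(counts, meta)
}

#' Read a count matrix in Matrix Market triplet format
#'
#' Alternative reader for MTX + separate gene/sample index files (one id per
#' line, order matching the MTX rows/columns).
#'
#' @param mtx_path path to the `.mtx` file.
#' @param genes_path,samples_path one-id-per-line index files.
#' @inheritParams read_counts
#' @return An [expression_matrix()].
#' @export
read_counts_mtx <- function(mtx_path, genes_path, samples_path, metadata_path) {
  m <- as.matrix(Matrix::readMM(mtx_path))
  rownames(m) <- readLines(genes_path)
  colnames(m) <- readLines(samples_path)
  meta <- utils::read.delim(metadata_path, check.names = FALSE,
                            stringsAsFactors = FALSE)
  meta <- validate_sample_meta(meta)
  if (!setequal(colnames(m), meta$sample_id))
    stop("sample ids differ between MTX index and metadata")
  expression_matrix(m[, meta$sample_id, drop = FALSE], meta)
}

#' Write an expression matrix (and optionally its metadata) to TSV
#'
#' Integer counts are written exactly, so `read_counts(write_counts(x))`
#' round-trips without drift.
#'
#' @param mat an [expression_matrix()].
#' @param path output counts TSV path.
#' @param metadata_path optional output path for the sample metadata TSV.
#' @return `path`, invisibly.
#' @export
write_counts <- function(mat, path, metadata_path = NULL) {
  stopifnot(inherits(mat, "expression_matrix"))
  df <- data.frame(gene_id = rownames(mat$counts), mat$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(metadata_path))
    utils::write.table(mat$samples, metadata_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  invisible(path)
}

#' Read a gene annotation table
#'
#' TSV with columns `gene_id`, `biotype` (`protein_coding` or `lncRNA`),
#' `chromosome`, `start` (0-based). Start coordinates are only used to order
#' the circos export.
#'
#' @param path annotation TSV path.
#' @return data.frame with one row per gene.
#' @export
read_annotation <- function(path) {
  ann <- utils::read.delim(path, stringsAsFactors = FALSE)
  req <- c("gene_id", "biotype", "chromosome", "start")
  miss <- setdiff(req, names(ann))
  if (length(miss) > 0)
    stop("annotation missing column(s): ", paste(miss, collapse = ", "))
  if (!all(ann$biotype %in% c("protein_coding", "lncRNA")))
    stop("biotype must be 'protein_coding' or 'lncRNA'")
  if (anyDuplicated(ann$gene_id))
    stop("duplicated gene id(s) in annotation: ",
         paste(unique(ann$gene_id[duplicated(ann$gene_id)]), collapse = ", "))
  ann
}

#' Read gene sets from a GMT file
#'
#' Standard GMT: one set per line, `name TAB description TAB gene TAB gene...`.
#' Duplicate genes within a line are dropped with a warning.
#'
#' @param path GMT file path.
#' @return A `signature_set`: list with `sets` (named list of character
#'   vectors) and `description` (named character vector).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  sets <- list()
  desc <- character(0)
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3)
      stop("GMT parse error at line ", i, ": fewer than 3 fields")
    genes <- f[-(1:2)]
    genes <- genes[nzchar(genes)]
    if (anyDuplicated(genes)) {
      warning("duplicate gene(s) in set '", f[1], "' deduplicated")
      genes <- unique(genes)
    }
    sets[[f[1]]] <- genes
    desc[f[1]] <- f[2]
  }
  signature_set(sets, desc)
}

#' Construct a signature set (named gene-set collection)
#'
#' @param sets named list of character vectors (gene ids); no empty set, no
#'   duplicated genes within a set.
#' @param description optional named character vector of set descriptions.
#' @return An object of class `signature_set`.
#' @export
signature_set <- function(sets, description = NULL) {
  if (length(sets) > 0) {
    if (is.null(names(sets)) || any(!nzchar(names(sets))))
      stop("all sets must be named")
    if (any(lengths(sets) == 0)) stop("empty gene set not allowed")
    dup_in <- vapply(sets, function(g) anyDuplicated(g) > 0, logical(1))
    if (any(dup_in))
      stop("duplicated genes within set(s): ",
           paste(names(sets)[dup_in], collapse = ", "))
  }
  if (is.null(description)) {
    description <- stats::setNames(rep("", length(sets)), names(sets))
  }
  structure(list(sets = sets, description = description),
            class = "signature_set")
}

#' @export
print.signature_set <- function(x, ...) {
  cat("signature_set with", length(x$sets), "set(s)\n")
  if (length(x$sets) > 0)
    cat("  sizes:", paste(utils::head(lengths(x$sets), 10), collapse = ", "),
        if (length(x$sets) > 10) "..." else "", "\n")
  invisible(x)
}

#' @export
length.signature_set <- function(x) length(x$sets)

#' Write a signature set to GMT
#'
#' @param sig a `signature_set`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sig, path) {
  stopifnot(inherits(sig, "signature_set"))
  lines <- vapply(names(sig$sets), function(nm) {
    paste(c(nm, sig$description[[nm]], sig$sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Split an expression matrix by gene biotype
#'
#' Partitions the genes of `mat` into protein-coding and lncRNA sub-matrices
#' according to the annotation. Every gene must be annotated.
#'
#' @param mat an [expression_matrix()].
#' @param ann annotation data.frame (see [read_annotation()]).
#' @return list with elements `pc` and `lnc`, both `expression_matrix`
#'   objects (possibly with zero rows).
#' @export
split_by_biotype <- function(mat, ann) {
  stopifnot(inherits(mat, "expression_matrix"))
  idx <- match(rownames(mat$counts), ann$gene_id)
  if (anyNA(idx))
    stop("unannotated gene(s): ",
         paste(rownames(mat$counts)[is.na(idx)], collapse = ", "))
  bt <- ann$biotype[idx]
  sub <- function(keep) {
    structure(list(counts = mat$counts[keep, , drop = FALSE],
                   samples = mat$samples),
              class = "expression_matrix")
  }
  list(pc = sub(bt == "protein_coding"), lnc = sub(bt == "lncRNA"))
}

#' Counts per million
#'
#' Scales each sample column to a library of one million; optionally returns
#' `log2(cpm + prior_count)`.
#'
#' @param mat an [expression_matrix()] or a plain counts matrix.
#' @param log if `TRUE`, return `log2(cpm + prior_count)`.
#' @param prior_count added before the log (default 1, so zero counts map to 0
#'   in an exactly 1e6-deep library).
#' @param lib_sizes optional effective library sizes (e.g. TMM-scaled);
#'   defaults to column sums.
#' @return real-valued matrix, genes x samples.
#' @export
cpm <- function(mat, log = FALSE, prior_count = 1, lib_sizes = NULL) {
  counts <- if (inherits(mat, "expression_matrix")) mat$counts else as.matrix(mat)
  if (is.null(lib_sizes)) lib_sizes <- colSums(counts)
  if (any(lib_sizes <= 0))
    stop("zero library size in sample(s): ",
         paste(colnames(counts)[lib_sizes <= 0], collapse = ", "))
  out <- sweep(counts, 2, 1e6 / lib_sizes, `*`)
  if (log) out <- log2(out + prior_count)
  out
}

#' Relative threshold-cycle (ddCt) fold change
#'
#' `2^-ddCt` with `ddCt = (Ct_target,case - Ct_ref,case) -
#' (Ct_target,ctrl - Ct_ref,ctrl)`: the qPCR fold change of a target gene in a
#' case sample relative to a control sample, each normalized to a reference
#' gene.
#'
#' @param ct_target_case,ct_ref_case,ct_target_ctrl,ct_ref_ctrl finite cycle
#'   numbers.
#' @return positive fold change.
#' @export
ddct_fold_change <- function(ct_target_case, ct_ref_case,
                             ct_target_ctrl, ct_ref_ctrl) {
  vals <- c(ct_target_case, ct_ref_case, ct_target_ctrl, ct_ref_ctrl)
  if (!all(is.finite(vals))) stop("non-finite Ct value")
  ddct <- (ct_target_case - ct_ref_case) - (ct_target_ctrl - ct_ref_ctrl)
  2^(-ddct)
}
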