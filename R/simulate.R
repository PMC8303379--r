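#' Default immunocyte panel used by the simulator
#'
#' Twenty-two immune cell types; the first six (myeloid populations and
#' T memory cells) are the condition-responsive set by default, mirroring the
#' populations that move after myocardial infarction under Hdc/histamine
#' perturbation.
#' @export
default_celltypes <- function() {
  c("Neutrophils", "Eosinophils", "MDSC", "Macrophages", "Monocytes",
    "T_memory_cells", "T_follicular_helper", "T_regulatory_cells",
    "T_helper_cells", "T_cytotoxic_cells", "T_gamma_delta", "NK_cells",
    "B_cells_naive", "B_cells_memory", "Plasma_cells", "Dendritic_cells",
    "Mast_cells", "Basophils", "T_cells_naive_CD4", "T_cells_naive_CD8",
    "NKT_cells", "Innate_lymphoid_cells")
}

#' Simulation configuration
#'
#' Parameters of the synthetic experiment generator. Defaults encode the study
#' design the pipeline targets: three arms (wild-type vehicle, knockout
#' vehicle, knockout + histamine) at 0/1/7 days with 3 replicates each,
#' negative-binomial counts with dispersion 0.1, 22 immunocyte signatures of
#' 10 markers, 30% planted differential genes at |log2FC| = 2, and six
#' lncRNAs coupled to cell abundances at a target Pearson r of 0.9.
#'
#' @param n_pc_genes,n_lnc_genes numbers of protein-coding and lncRNA genes.
#' @param n_celltypes number of immunocyte signatures (max 22 named types).
#' @param markers_per_celltype marker genes per cell type (0 disables the
#'   marker/abundance layer).
#' @param replicates replicates per arm x timepoint.
#' @param timepoints timepoints in days.
#' @param arms subset of `"WT-vehicle"`, `"KO-vehicle"`, `"KO-histamine"`.
#' @param dispersion NB dispersion phi (Var = m + phi m^2); `< 1e-8` switches
#'   to Poisson sampling.
#' @param frac_de fraction of genes planted as differential.
#' @param de_log2fc planted absolute log2 fold change.
#' @param abundance_effect scale (log2 units per unit-sd pattern) of the
#'   condition-driven latent cell-abundance variation.
#' @param marker_gain log2-expression shift per unit latent abundance (`b`).
#' @param n_responsive_celltypes how many cell types respond to condition.
#' @param n_imm_lnc number of lncRNAs coupled to cell abundances.
#' @param imm_lnc_r target Pearson correlation between a planted lncRNA's
#'   observed log2 expression and its cell type's latent abundance.
#' @param abundance_noise_sd per-(cell, sample) abundance noise sd.
#' @param lib_factor_range range of per-sample library depth factors.
#' @param seed integer RNG seed; identical configs give identical output.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_pc_genes = 2000, n_lnc_genes = 200,
                       n_celltypes = 22, markers_per_celltype = 10,
                       replicates = 3, timepoints = c(0, 1, 7),
                       arms = c("WT-vehicle", "KO-vehicle", "KO-histamine"),
                       dispersion = 0.1, frac_de = 0.3, de_log2fc = 2,
                       abundance_effect = 1, marker_gain = 1.5,
                       n_responsive_celltypes = 6, n_imm_lnc = 6,
                       imm_lnc_r = 0.9, abundance_noise_sd = 0.1,
                       lib_factor_range = c(0.7, 1.3), seed = 1) {
  cfg <- list(n_pc_genes = n_pc_genes, n_lnc_genes = n_lnc_genes,
              n_celltypes = n_celltypes,
              markers_per_celltype = markers_per_celltype,
              replicates = replicates, timepoints = timepoints, arms = arms,
              dispersion = dispersion, frac_de = frac_de,
              de_log2fc = de_log2fc, abundance_effect = abundance_effect,
              marker_gain = marker_gain,
              n_responsive_celltypes = n_responsive_celltypes,
              n_imm_lnc = n_imm_lnc, imm_lnc_r = imm_lnc_r,
              abundance_noise_sd = abundance_noise_sd,
              lib_factor_range = lib_factor_range, seed = seed)
  valid_arms <- c("WT-vehicle", "KO-vehicle", "KO-histamine")
  if (!all(arms %in% valid_arms))
    stop("arms must be a subset of: ", paste(valid_arms, collapse = ", "))
  if (markers_per_celltype * n_celltypes > n_pc_genes)
    stop("marker demand (", markers_per_celltype * n_celltypes,
         ") exceeds protein-coding gene pool (", n_pc_genes, ")")
  if (n_imm_lnc > n_lnc_genes)
    stop("n_imm_lnc exceeds n_lnc_genes")
  if (n_imm_lnc > n_responsive_celltypes)
    stop("n_imm_lnc exceeds n_responsive_celltypes (one linked cell type each)")
  if (n_responsive_celltypes > n_celltypes)
    stop("n_responsive_celltypes exceeds n_celltypes")
  if (n_celltypes > length(default_celltypes()))
    stop("at most ", length(default_celltypes()), " cell types supported")
  if (frac_de < 0 || frac_de > 1) stop("frac_de must be in [0, 1]")
  if (dispersion < 0) stop("dispersion must be >= 0")
  structure(cfg, class = "sim_config")
}

#' Negative-binomial draws in the (mean, dispersion) parameterization
#'
#' `Var = mean + dispersion * mean^2`; dispersion below 1e-8 falls back to
#' Poisson sampling.
#'
#' @param n number of draws.
#' @param mean vector of means (recycled).
#' @param dispersion scalar dispersion phi >= 0.
#' @return integer-valued numeric vector.
#' @export
nb_draws <- function(n, mean, dispersion) {
  if (dispersion < 1e-8) stats::rpois(n, mean)
  else stats::rnbinom(n, mu = mean, size = 1 / dispersion)
}

# Orthogonal unit-sd condition patterns for the responsive cell types.
# Column 1 is the canonical myeloid trajectory (up in KO-vehicle at days 1 and
# 7, reverted under histamine); the rest are Gram-Schmidt completions from
# Helmert contrasts, giving per-animal abundance variation uncorrelated across
# cell types.
abundance_patterns <- function(samples, n_responsive) {
  S <- nrow(samples)
  if (n_responsive == 0) return(matrix(0, S, 0))
  if (n_responsive >= S)
    stop("need more samples than responsive cell types for orthogonal patterns")
  canon <- as.numeric(samples$genotype == "KO" &
                        samples$treatment == "vehicle" &
                        samples$timepoint_days %in% c(1, 7))
  if (stats::sd(canon) == 0) {
    # design without KO-vehicle time structure: seed with first Helmert contrast
    canon <- stats::contr.helmert(S)[, 1]
  }
  canon <- canon - base::mean(canon)
  basis <- cbind(canon, stats::contr.helmert(S))
  q <- qr(basis)
  V <- qr.Q(q)[, seq_len(n_responsive), drop = FALSE]
  # fix signs so column 1 tracks the canonical pattern positively
  if (sum(V[, 1] * canon) < 0) V[, 1] <- -V[, 1]
  V * sqrt(S - 1)  # unit sample sd, zero mean
}

#' Simulate a synthetic experiment with planted ground truth
#'
#' Generative model (deterministic given `cfg$seed`):
#' \enumerate{
#'   \item per-gene baseline log2 mean `mu_g ~ Uniform(3, 10)`;
#'   \item latent cell abundance `a[c, s] = abundance_effect * v_c[s] + eps`,
#'     `eps ~ Normal(0, abundance_noise_sd)`, where the `v_c` are orthogonal
#'     unit-sd condition patterns for the responsive cell types (the first is
#'     the canonical myeloid pattern: raised in KO arms at days 1 and 7,
#'     reverted under histamine) and 0 for the rest;
#'   \item marker gene g of cell c has log2 mean `mu_g + marker_gain * a[c, s]`;
#'   \item planted differential genes get `+/- de_log2fc` in the affected arm
#'     (genotype-effect genes in all KO samples, histamine-effect genes in
#'     KO-histamine samples);
#'   \item a planted imm-lncRNA linked to cell c has log2 mean
#'     `mu_l + marker_gain * a[c, s] + Normal(0, sigma)`, sigma chosen so the
#'     observed log2 expression correlates with `a[c, ]` at `imm_lnc_r`
#'     (accounting for the NB counting-noise floor `(1/m + phi) / ln(2)^2`);
#'   \item counts `~ NB(mean = lib_factor_s * 2^log2mean, dispersion)`,
#'     `lib_factor_s ~ Uniform(lib_factor_range)`.
#' }
#'
#' @param cfg a [sim_config()].
#' @return list of class `lnc_sim` with elements `expr`
#'   ([expression_matrix()]), `annotation`, `signatures`
#'   ([signature_set()]), `truth` (planted DE table, latent abundance matrix,
#'   marker assignment, imm-lncRNA links) and `config`.
#' @export
simulate_experiment <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(cfg$seed)

  arms <- do.call(rbind, lapply(strsplit(cfg$arms, "-", fixed = TRUE),
                                function(x) data.frame(genotype = ifelse(x[1] == "WT", "WT", "KO"),
                                                       treatment = x[2])))
  samples <- do.call(rbind, lapply(seq_len(nrow(arms)), function(i) {
    do.call(rbind, lapply(cfg$timepoints, function(tp) {
      data.frame(sample_id = sprintf("%s_%s_d%d_r%d", arms$genotype[i],
                                     arms$treatment[i], tp,
                                     seq_len(cfg$replicates)),
                 genotype = arms$genotype[i], treatment = arms$treatment[i],
                 timepoint_days = tp, replicate = seq_len(cfg$replicates),
                 stringsAsFactors = FALSE)
    }))
  }))
  S <- nrow(samples)

  pc_ids <- sprintf("PC%04d", seq_len(cfg$n_pc_genes))
  lnc_ids <- sprintf("LNC%04d", seq_len(cfg$n_lnc_genes))
  gene_ids <- c(pc_ids, lnc_ids)
  G <- length(gene_ids)

  celltypes <- default_celltypes()[seq_len(cfg$n_celltypes)]
  n_resp <- min(cfg$n_responsive_celltypes, cfg$n_celltypes)

  # latent abundances
  V <- abundance_patterns(samples, n_resp)
  a <- matrix(stats::rnorm(cfg$n_celltypes * S, 0, cfg$abundance_noise_sd),
              nrow = cfg$n_celltypes, ncol = S,
              dimnames = list(celltypes, samples$sample_id))
  if (n_resp > 0)
    a[seq_len(n_resp), ] <- a[seq_len(n_resp), , drop = FALSE] +
      cfg$abundance_effect * t(V)

  # marker assignment: random protein-coding genes, disjoint across cell types
  n_mark <- cfg$markers_per_celltype * cfg$n_celltypes
  marker_genes <- if (n_mark > 0) sample(pc_ids, n_mark) else character(0)
  marker_assignment <- if (n_mark > 0)
    data.frame(gene_id = marker_genes,
               celltype = rep(celltypes, each = cfg$markers_per_celltype),
               stringsAsFactors = FALSE)
  else data.frame(gene_id = character(0), celltype = character(0))

  # planted imm-lncRNAs, one responsive cell type each
  imm_lnc <- if (cfg$n_imm_lnc > 0) sample(lnc_ids, cfg$n_imm_lnc) else character(0)

  mu <- stats::runif(G, 3, 10)
  names(mu) <- gene_ids
  L <- matrix(mu, nrow = G, ncol = S,
              dimnames = list(gene_ids, samples$sample_id))

  if (n_mark > 0) {
    idx <- match(marker_assignment$gene_id, gene_ids)
    L[idx, ] <- L[idx, ] + cfg$marker_gain * a[marker_assignment$celltype, ]
  }

  # planted DE genes among genes free of other structure
  eligible <- setdiff(gene_ids, c(marker_genes, imm_lnc))
  n_de <- min(round(cfg$frac_de * G), length(eligible))
  de_truth <- data.frame(gene_id = character(0), comparison = character(0),
                         true_log2fc = numeric(0))
  if (n_de > 0) {
    de_genes <- sample(eligible, n_de)
    has_hist <- "KO-histamine" %in% cfg$arms && "KO-vehicle" %in% cfg$arms
    has_geno <- "WT-vehicle" %in% cfg$arms &&
      any(c("KO-vehicle", "KO-histamine") %in% cfg$arms)
    comps <- c(if (has_geno) "KO_vs_WT", if (has_hist) "histamine_vs_vehicle")
    if (length(comps) == 0) comps <- "KO_vs_WT"
    comp_of <- rep(comps, length.out = n_de)
    signs <- rep(c(1, -1), length.out = n_de)
    de_truth <- data.frame(gene_id = de_genes, comparison = comp_of,
                           true_log2fc = signs * cfg$de_log2fc,
                           stringsAsFactors = FALSE)
    for (i in seq_len(n_de)) {
      aff <- if (comp_of[i] == "KO_vs_WT") samples$genotype == "KO"
             else samples$treatment == "histamine"
      L[de_genes[i], aff] <- L[de_genes[i], aff] + signs[i] * cfg$de_log2fc
    }
  }

  # planted imm-lncRNAs: couple to the linked cell's abundance, with noise
  # sized so the observed log2-expression correlation hits imm_lnc_r
  imm_links <- data.frame(lnc_id = character(0), celltype = character(0),
                          target_r = numeric(0), sigma = numeric(0))
  if (cfg$n_imm_lnc > 0) {
    for (i in seq_len(cfg$n_imm_lnc)) {
      ct <- celltypes[i]
      sig_sd <- cfg$marker_gain * stats::sd(a[ct, ])
      m_approx <- 2^mu[imm_lnc[i]]
      v_count <- (1 / m_approx + cfg$dispersion) / log(2)^2
      sigma2 <- max(0, sig_sd^2 * (1 / cfg$imm_lnc_r^2 - 1) - v_count)
      L[imm_lnc[i], ] <- L[imm_lnc[i], ] + cfg$marker_gain * a[ct, ] +
        stats::rnorm(S, 0, sqrt(sigma2))
      imm_links <- rbind(imm_links,
                         data.frame(lnc_id = imm_lnc[i], celltype = ct,
                                    target_r = cfg$imm_lnc_r,
                                    sigma = sqrt(sigma2)))
    }
  }

  lib_factor <- stats::runif(S, cfg$lib_factor_range[1], cfg$lib_factor_range[2])
  mean_mat <- sweep(2^L, 2, lib_factor, `*`)
  counts <- matrix(nb_draws(G * S, as.vector(mean_mat), cfg$dispersion),
                   nrow = G, ncol = S,
                   dimnames = list(gene_ids, samples$sample_id))

  expr <- expression_matrix(counts, samples)

  chroms <- c(as.character(1:19), "X", "Y")
  chrom_of <- rep_len(chroms, G)
  within <- stats::ave(seq_len(G), chrom_of, FUN = seq_along)
  annotation <- data.frame(
    gene_id = gene_ids,
    biotype = c(rep("protein_coding", cfg$n_pc_genes),
                rep("lncRNA", cfg$n_lnc_genes)),
    chromosome = chrom_of, start = as.integer(within * 10000L),
    stringsAsFactors = FALSE)

  signatures <- if (n_mark > 0)
    signature_set(split(marker_assignment$gene_id, marker_assignment$celltype)[celltypes])
  else signature_set(list())

  truth <- list(de_genes = de_truth, celltype_abundance = a,
                marker_assignment = marker_assignment,
                imm_lnc_links = imm_links, lib_factor = lib_factor,
                baseline_log2_mean = mu)
  structure(list(expr = expr, annotation = annotation,
                 signatures = signatures, truth = truth, config = cfg),
            class = "lnc_sim")
}

#' Simulate a null experiment (no planted structure)
#'
#' [simulate_experiment()] with `frac_de = 0`, `abundance_effect = 0` and
#' `n_imm_lnc = 0`; used for type-I error and permutation calibration.
#'
#' @param cfg a [sim_config()]; the three null overrides are applied on top.
#' @return an `lnc_sim` object with empty truth tables.
#' @export
simulate_null <- function(cfg = sim_config()) {
  cfg$frac_de <- 0
  cfg$abundance_effect <- 0
  cfg$n_imm_lnc <- 0
  simulate_experiment(cfg)
}

#' Write a simulated experiment to disk in the pipeline's input formats
#'
#' Counts/metadata/annotation as TSV, signatures as GMT, ground truth as JSON.
#'
#' @param sim an `lnc_sim` object.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  stopifnot(inherits(sim, "lnc_sim"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_counts(sim$expr, file.path(dir, "counts.tsv"),
               file.path(dir, "samples.tsv"))
  utils::write.table(sim$annotation, file.path(dir, "annotation.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (length(sim$signatures) > 0)
    write_gmt(sim$signatures, file.path(dir, "signatures.gmt"))
  truth <- sim$truth
  truth$celltype_abundance <- as.data.frame(truth$celltype_abundance)
  jsonlite::write_json(truth, file.path(dir, "truth.json"), digits = NA,
                       dataframe = "columns")
  invisible(dir)
}
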