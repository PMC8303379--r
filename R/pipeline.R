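#' Pipeline configuration
#'
#' Bundles input sources and all stage thresholds. Input is either a
#' [sim_config()] (simulate mode) or a named list of file paths
#' (`counts`, `metadata`, `annotation`, `signatures`, optionally `genesets`
#' for the functional collection; when absent the immunocyte signatures
#' double as the functional collection, as in the synthetic study).
#'
#' @param simulate a [sim_config()], or `NULL` when reading files.
#' @param input named list of input paths (ignored in simulate mode).
#' @param comparisons optional list of comparisons, each a list with `name`,
#'   `arm_a`, `arm_b` (arm labels like `"KO-vehicle"`) and `timepoint`;
#'   `NULL` derives the genotype and histamine contrasts per timepoint from
#'   the metadata.
#' @param lfc_threshold,p_threshold,use_adjusted DEG calling thresholds.
#' @param cpm_filter,min_samples expression filter (CPM > `cpm_filter` in at
#'   least `min_samples` samples).
#' @param r_min_pc,padj_max_pc lncRNA-pcRNA edge thresholds.
#' @param r_min_cell,p_max_cell lncRNA-immunocyte edge thresholds.
#' @param ora_padj_max adjusted-p cutoff for attaching GO terms.
#' @param alpha ssGSEA rank weight.
#' @param max_unit_change,n_permutations temporal clustering parameters.
#' @param positive_only restrict network edges to positive correlations.
#' @param seed master seed (simulation and permutation tests).
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(simulate = sim_config(), input = NULL,
                            comparisons = NULL, lfc_threshold = 0.5,
                            p_threshold = 0.05, use_adjusted = FALSE,
                            cpm_filter = 1, min_samples = 2,
                            r_min_pc = 0.9, padj_max_pc = 0.01,
                            r_min_cell = 0.75, p_max_cell = 0.001,
                            ora_padj_max = 0.05, alpha = 0.25,
                            max_unit_change = 2, n_permutations = 1000,
                            positive_only = FALSE, seed = 1) {
  if (is.null(simulate) && is.null(input))
    stop("either simulate or input must be given")
  if (!is.null(input)) {
    req <- c("counts", "metadata", "annotation", "signatures")
    miss <- setdiff(req, names(input))
    if (length(miss) > 0)
      stop("input paths missing: ", paste(miss, collapse = ", "))
  }
  structure(list(simulate = simulate, input = input,
                 comparisons = comparisons, lfc_threshold = lfc_threshold,
                 p_threshold = p_threshold, use_adjusted = use_adjusted,
                 cpm_filter = cpm_filter, min_samples = min_samples,
                 r_min_pc = r_min_pc, padj_max_pc = padj_max_pc,
                 r_min_cell = r_min_cell, p_max_cell = p_max_cell,
                 ora_padj_max = ora_padj_max, alpha = alpha,
                 max_unit_change = max_unit_change,
                 n_permutations = n_permutations,
                 positive_only = positive_only, seed = seed),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Top-level keys mirror the [pipeline_config()] arguments; a `simulate`
#' section is passed to [sim_config()].
#'
#' @param path YAML file path.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  y <- yaml::read_yaml(path)
  if (!is.null(y$simulate)) {
    y$simulate$timepoints <- unlist(y$simulate$timepoints)
    y$simulate$arms <- unlist(y$simulate$arms)
    y$simulate <- do.call(sim_config, y$simulate)
  }
  do.call(pipeline_config, y)
}

# derive the genotype and histamine contrasts per timepoint from metadata
default_comparisons <- function(samples) {
  arm <- paste0(samples$genotype, "-", samples$treatment)
  comps <- list()
  for (tp in sort(unique(samples$timepoint_days))) {
    if (all(c("WT-vehicle", "KO-vehicle") %in% arm[samples$timepoint_days == tp]))
      comps[[length(comps) + 1]] <- list(name = "KO_vs_WT",
                                         arm_a = "WT-vehicle",
                                         arm_b = "KO-vehicle", timepoint = tp)
    if (all(c("KO-vehicle", "KO-histamine") %in% arm[samples$timepoint_days == tp]))
      comps[[length(comps) + 1]] <- list(name = "histamine_vs_vehicle",
                                         arm_a = "KO-vehicle",
                                         arm_b = "KO-histamine",
                                         timepoint = tp)
  }
  comps
}

arm_samples <- function(samples, arm, timepoint = NULL) {
  sel <- paste0(samples$genotype, "-", samples$treatment) == arm
  if (!is.null(timepoint)) sel <- sel & samples$timepoint_days == timepoint
  samples$sample_id[sel]
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full pipeline
#'
#' Simulate (or load) the inputs, then: expression filtering and TMM
#' normalization, per-comparison/timepoint exact NB tests and DEG calling,
#' DEG bookkeeping (summary, overlaps, circos table), temporal profile
#' clustering of genotype DEGs, over-representation per timepoint, ssGSEA
#' infiltration scoring with cell-cell correlations, and the thresholded
#' correlation networks assembled into the multilayer lncRNA-immunocyte-GO
#' network. Every stage writes its TSV to `outdir` and a `manifest.json`
#' records the config hash and per-stage row counts. Deterministic given
#' `cfg$seed`.
#'
#' @param cfg a [pipeline_config()].
#' @param outdir output directory (created).
#' @return list of in-memory stage results (invisible); side effect: files
#'   under `outdir`.
#' @export
run_pipeline <- function(cfg, outdir) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  counts_n <- list()

  inp <- stage("input", {
    if (!is.null(cfg$simulate)) {
      sim <- simulate_experiment(cfg$simulate)
      # the synthetic functional layer is the marker programs; rename the
      # sets so GO-term nodes cannot collide with immunocyte nodes
      gs <- sim$signatures
      if (length(gs) > 0)
        gs <- signature_set(stats::setNames(gs$sets,
                                            paste0(names(gs$sets),
                                                   "_markers")))
      list(expr = sim$expr, annotation = sim$annotation,
           signatures = sim$signatures, genesets = gs,
           truth = sim$truth)
    } else {
      for (p in unlist(cfg$input))
        if (!file.exists(p)) stop("input path not found: ", p)
      expr <- read_counts(cfg$input$counts, cfg$input$metadata)
      gs <- if (!is.null(cfg$input$genesets)) read_gmt(cfg$input$genesets)
            else read_gmt(cfg$input$signatures)
      list(expr = expr, annotation = read_annotation(cfg$input$annotation),
           signatures = read_gmt(cfg$input$signatures), genesets = gs,
           truth = NULL)
    }
  })
  expr <- inp$expr

  norm <- stage("normalize", {
    expressed <- filter_expressed(expr, cfg$cpm_filter, cfg$min_samples)
    sub <- structure(list(counts = expr$counts[expressed, , drop = FALSE],
                          samples = expr$samples),
                     class = "expression_matrix")
    f <- tmm_factors(sub)
    eff <- colSums(sub$counts) * f
    list(expr = sub, factors = f, eff = eff,
         log2cpm = cpm(sub, log = TRUE, lib_sizes = eff))
  })

  comps <- cfg$comparisons
  if (is.null(comps)) comps <- default_comparisons(expr$samples)
  if (length(comps) == 0) stop("no comparisons derivable from the metadata")

  de <- stage("differential_expression", {
    tabs <- lapply(comps, function(cm) {
      ga <- arm_samples(expr$samples, cm$arm_a, cm$timepoint)
      gb <- arm_samples(expr$samples, cm$arm_b, cm$timepoint)
      res <- nb_exact_test(norm$expr, ga, gb, comparison = cm$name,
                           timepoint_days = cm$timepoint)
      call_degs(res, cfg$lfc_threshold, cfg$p_threshold, cfg$use_adjusted)
    })
    names(tabs) <- vapply(comps, function(cm)
      paste0(cm$name, "_d", cm$timepoint), character(1))
    for (nm in names(tabs))
      write_tsv(tabs[[nm]], file.path(outdir, paste0("de_", nm, ".tsv")))
    tabs
  })
  counts_n$de_tables <- sum(vapply(de, nrow, integer(1)))

  book <- stage("deg_bookkeeping", {
    summ <- deg_summary(de)
    write_tsv(summ, file.path(outdir, "deg_summary.tsv"))
    venns <- list()
    for (cmp in unique(vapply(comps, `[[`, character(1), "name"))) {
      sets <- lapply(de[grepl(paste0("^", cmp), names(de))], function(tb)
        tb$gene_id[tb$direction != "ns"])
      if (length(sets) >= 2) venns[[cmp]] <- overlap_sets(sets)
    }
    jsonlite::write_json(lapply(venns, function(v)
      v[, c("region", "count")]), file.path(outdir, "venn.json"),
      digits = NA)
    circ <- circos_export(de, inp$annotation,
                          file.path(outdir, "circos.tsv"))
    list(summary = summ, venns = venns, circos = circ)
  })

  clusters <- stage("temporal_clustering", {
    geno <- de[grepl("^KO_vs_WT", names(de))]
    if (length(geno) == 0) geno <- de
    degs <- unique(unlist(lapply(geno, function(tb)
      tb$gene_id[tb$direction != "ns"])))
    arm_b <- comps[[1]]$arm_b
    cols <- arm_samples(expr$samples, arm_b)
    if (length(degs) >= 2 && length(cols) >= 2 &&
        length(unique(expr$samples$timepoint_days[match(cols, expr$samples$sample_id)])) >= 3) {
      tps <- expr$samples$timepoint_days[match(cols, expr$samples$sample_id)]
      traj <- gene_trajectories(norm$log2cpm[intersect(degs, rownames(norm$log2cpm)),
                                             cols, drop = FALSE], tps)
      profs <- enumerate_profiles(ncol(traj), cfg$max_unit_change)
      asg <- assign_genes(traj, profs)
      sig <- profile_significance(asg, traj, profs,
                                  n_permutations = cfg$n_permutations,
                                  seed = cfg$seed)
      cs <- cluster_summary(asg, traj)
      write_tsv(sig, file.path(outdir, "profiles.tsv"))
      write_tsv(cs$members, file.path(outdir, "profile_members.tsv"))
      write_tsv(data.frame(profile_id = rownames(cs$summary), cs$summary),
                file.path(outdir, "profile_summary.tsv"))
      list(profiles = profs, assignment = asg, significance = sig,
           summary = cs)
    } else {
      write_tsv(data.frame(), file.path(outdir, "profiles.tsv"))
      NULL
    }
  })

  enr <- stage("enrichment", {
    universe <- rownames(norm$expr$counts)
    res <- list()
    for (nm in names(de)) {
      q <- de[[nm]]$gene_id[de[[nm]]$direction != "ns"]
      if (length(q) == 0) {
        res[[nm]] <- ora(universe[1], universe, inp$genesets)[0, ]
      } else {
        res[[nm]] <- suppressWarnings(ora(q, universe, inp$genesets))
      }
      write_tsv(res[[nm]], file.path(outdir, paste0("ora_", nm, ".tsv")))
    }
    dp <- dotplot_table(res, file.path(outdir, "ora_dotplot.tsv"))
    list(results = res, dotplot = dp)
  })

  infl <- stage("immune_infiltration", {
    if (length(inp$signatures) == 0) return(NULL)
    sc <- infiltration_scores(norm$log2cpm, inp$signatures, alpha = cfg$alpha)
    write_tsv(data.frame(celltype = rownames(sc$raw_es), sc$raw_es),
              file.path(outdir, "ssgsea_raw.tsv"))
    write_tsv(data.frame(celltype = rownames(sc$normalized), sc$normalized),
              file.path(outdir, "ssgsea_normalized.tsv"))
    write_tsv(data.frame(celltype = rownames(sc$fractions), sc$fractions),
              file.path(outdir, "ssgsea_fractions.tsv"))
    write_tsv(scores_long(sc, expr$samples),
              file.path(outdir, "ssgsea_long.tsv"))
    cc <- celltype_correlation(sc$normalized)
    write_tsv(data.frame(celltype = rownames(cc$r), cc$r),
              file.path(outdir, "celltype_correlation.tsv"))
    list(scores = sc, correlation = cc)
  })

  net <- stage("network", {
    if (is.null(infl)) return(NULL)
    split <- split_by_biotype(norm$expr, inp$annotation)
    if (nrow(split$lnc$counts) == 0) return(NULL)
    lnc_l2 <- norm$log2cpm[rownames(split$lnc$counts), , drop = FALSE]
    pc_l2 <- norm$log2cpm[rownames(split$pc$counts), , drop = FALSE]
    pe <- lnc_pc_edges(lnc_l2, pc_l2, cfg$r_min_pc, cfg$padj_max_pc,
                       cfg$positive_only)
    ce <- lnc_cell_edges(lnc_l2, infl$scores, cfg$r_min_cell, cfg$p_max_cell,
                         cfg$positive_only)
    ml <- build_multilayer(ce, pe, inp$genesets,
                           rownames(split$pc$counts),
                           ora_padj_max = cfg$ora_padj_max)
    write_tsv(pe, file.path(outdir, "lnc_pc_edges.tsv"))
    write_tsv(ce, file.path(outdir, "lnc_cell_edges.tsv"))
    write_tsv(ml$hubs, file.path(outdir, "hubs.tsv"))
    export_network(ml, "graphml", file.path(outdir, "network.graphml"))
    export_network(ml, "edgelist", file.path(outdir, "network_edges.tsv"))
    export_network(ml, "sankey", file.path(outdir, "sankey.tsv"))
    list(pc_edges = pe, cell_edges = ce, multilayer = ml)
  })

  manifest <- stage("manifest", {
    cfg_json <- file.path(outdir, "config.json")
    cfg_ser <- unclass(cfg)
    cfg_ser$simulate <- if (!is.null(cfg$simulate)) unclass(cfg$simulate)
    jsonlite::write_json(cfg_ser, cfg_json, digits = NA, auto_unbox = TRUE,
                         null = "null")
    man <- list(
      package_version = as.character(utils::packageVersion("lncImmNet")),
      r_version = paste(R.version$major, R.version$minor, sep = "."),
      seed = cfg$seed,
      config_md5 = unname(tools::md5sum(cfg_json)),
      n_genes_input = nrow(expr$counts),
      n_genes_expressed = nrow(norm$expr$counts),
      n_samples = ncol(expr$counts),
      de_rows = vapply(de, nrow, integer(1)),
      deg_counts = vapply(de, function(tb) sum(tb$direction != "ns"),
                          integer(1)),
      n_significant_profiles = if (!is.null(clusters))
        sum(clusters$significance$significant) else 0L,
      ora_rows = vapply(enr$results, nrow, integer(1)),
      n_celltypes = if (!is.null(infl)) nrow(infl$scores$raw_es) else 0L,
      n_pc_edges = if (!is.null(net)) nrow(net$pc_edges) else 0L,
      n_cell_edges = if (!is.null(net)) nrow(net$cell_edges) else 0L,
      n_go_edges = if (!is.null(net)) nrow(net$multilayer$go_edges) else 0L)
    jsonlite::write_json(man, file.path(outdir, "manifest.json"),
                         digits = NA, auto_unbox = TRUE)
    man
  })

  invisible(list(input = inp, norm = norm, de = de, bookkeeping = book,
                 clusters = clusters, enrichment = enr, infiltration = infl,
                 network = net, manifest = manifest, outdir = outdir))
}
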