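test_that("TMM factors are 1 for identical or depth-scaled samples", {
  set.seed(1)
  y <- matrix(rnbinom(2000, mu = 100, size = 10), 1000, 2,
              dimnames = list(sprintf("g%04d", 1:1000), c("a", "b")))
  y[, 2] <- y[, 1]
  expect_equal(unname(tmm_factors(y)), c(1, 1))

  y2 <- cbind(a = y[, 1], b = 2L * y[, 1])
  expect_equal(unname(tmm_factors(y2)), c(1, 1))

  y3 <- cbind(a = y[, 1], b = 0L * y[, 1])
  expect_error(tmm_factors(y3), "all-zero")
})

test_that("TMM factor matches the brute-force trim rule and edgeR", {
  set.seed(2)
  mu <- exp(runif(1000, 2, 7))
  a <- rnbinom(1000, mu = mu, size = 10)
  up <- sample(1000, 50)  # 5% of genes 8-fold up in B
  mu_b <- mu; mu_b[up] <- mu_b[up] * 8
  b <- rnbinom(1000, mu = mu_b, size = 10)
  y <- cbind(a = a, b = b)
  rownames(y) <- sprintf("g%04d", 1:1000)

  f <- tmm_factors(y, ref_sample = "a")
  f_oracle <- tmm_oracle(y[, "b"], y[, "a"])
  # compare unscaled B-vs-A factor: undo the geometric-mean rescale
  expect_lt(abs((f[["b"]] / f[["a"]]) / f_oracle - 1), 0.02)

  skip_if_not_installed("edgeR")
  f_edger <- edgeR::calcNormFactors(y, method = "TMM", refColumn = 1)
  expect_lt(abs(f[["b"]] / f[["a"]] - f_edger[2] / f_edger[1]), 0.02)
})

test_that("dispersion estimates recover truth and vanish for constant data", {
  set.seed(3)
  # Poisson data: phi ~ 0
  y <- matrix(rpois(3000 * 6, lambda = 200), 3000, 6,
              dimnames = list(sprintf("g%04d", 1:3000), paste0("s", 1:6)))
  phi <- estimate_dispersion(y, rep(c("A", "B"), each = 3))
  expect_lte(stats::median(phi), 0.05)

  # phi = 0.4 at 10 replicates
  y2 <- matrix(rnbinom(3000 * 10, mu = 200, size = 1 / 0.4), 3000, 10,
               dimnames = list(sprintf("g%04d", 1:3000), paste0("s", 1:10)))
  phi2 <- estimate_dispersion(y2, rep("A", 10), norm_factors = rep(1, 10))
  expect_gte(stats::median(phi2), 0.25)
  expect_lte(stats::median(phi2), 0.55)

  # constant counts within groups -> exactly zero
  y3 <- matrix(rep(c(10L, 20L), each = 4 * 3), 4, 6, byrow = TRUE,
               dimnames = list(paste0("g", 1:4), paste0("s", 1:6)))
  y3[] <- rep(c(10L, 20L), each = 3)[col(y3)]
  phi3 <- estimate_dispersion(y3, rep(c("A", "B"), each = 3),
                              norm_factors = rep(1, 6))
  expect_equal(unname(phi3), rep(0, 4))

  expect_error(estimate_dispersion(y[, 1, drop = FALSE], "A"), ">= 2")
})

test_that("exact test gives p = 1 for identical groups and matches the
           binomial split at phi = 0", {
  y <- matrix(c(10L, 10L, 10L, 10L, 40L, 40L, 40L, 40L), 2, 4, byrow = TRUE,
              dimnames = list(c("g1", "filler"), paste0("s", 1:4)))
  disp <- c(g1 = 0, filler = 0)
  res <- nb_exact_test(y, c("s1", "s2"), c("s3", "s4"), dispersions = disp,
                       norm_factors = rep(1, 4))
  expect_equal(res$log2fc[res$gene_id == "g1"], 0)
  expect_equal(res$p_value[res$gene_id == "g1"], 1)

  # totals A=0, B=20 at equal sizes: p = 2 * 0.5^20
  y2 <- matrix(c(0L, 0L, 10L, 10L, 50L, 50L, 40L, 40L), 2, 4, byrow = TRUE,
               dimnames = list(c("g1", "filler"), paste0("s", 1:4)))
  res2 <- nb_exact_test(y2, c("s1", "s2"), c("s3", "s4"), dispersions = disp,
                        norm_factors = rep(1, 4))
  expect_equal(res2$p_value[res2$gene_id == "g1"], 2 * 0.5^20,
               tolerance = 1e-9)
})

test_that("exact test equals brute-force conditional enumeration (2v2)", {
  for (phi in c(0, 0.05, 0.3)) {
    for (case in list(c(3, 11), c(0, 9), c(7, 7), c(14, 2))) {
      ya <- case[1]; yb <- case[2]
      lib <- 40L
      y <- rbind(g1 = c(floor(ya / 2), ceiling(ya / 2), floor(yb / 2),
                        ceiling(yb / 2)))
      y <- rbind(y, filler = lib - y[1, ])
      colnames(y) <- paste0("s", 1:4)
      res <- nb_exact_test(y, c("s1", "s2"), c("s3", "s4"),
                           dispersions = c(g1 = phi, filler = phi),
                           norm_factors = rep(1, 4))
      expect_equal(res$p_value[res$gene_id == "g1"],
                   exact_p_oracle(ya, yb, 2, 2, phi), tolerance = 1e-12)
    }
  }
})

test_that("swapping group labels negates log2fc and preserves p", {
  sim <- simulate_experiment(sim_config(n_pc_genes = 200, n_lnc_genes = 20,
                                        markers_per_celltype = 0,
                                        n_responsive_celltypes = 0,
                                        n_imm_lnc = 0, seed = 6,
                                        arms = c("WT-vehicle", "KO-vehicle")))
  fx <- full_dispersions(sim)
  s <- fx$samples
  ga <- s$sample_id[s$genotype == "WT" & s$timepoint_days == 1]
  gb <- s$sample_id[s$genotype == "KO" & s$timepoint_days == 1]
  r1 <- nb_exact_test(fx$counts, ga, gb, dispersions = fx$dispersions)
  r2 <- nb_exact_test(fx$counts, gb, ga, dispersions = fx$dispersions)
  expect_equal(r1$log2fc, -r2$log2fc, tolerance = 1e-12)
  expect_equal(r1$p_value, r2$p_value, tolerance = 1e-12)
})

test_that("DEG calling applies inclusive fold-change and strict p thresholds", {
  res <- data.frame(gene_id = c("a", "b", "c", "d"),
                    log2fc = c(0.5, 3, -0.5, 0.49),
                    p_value = c(0.049, 0.2, 0.01, 0.001),
                    p_adjusted = c(0.2, 0.5, 0.04, 0.01),
                    mean_cpm = 10, comparison = "x", timepoint_days = 0L)
  called <- call_degs(res)
  expect_equal(called$direction, c("up", "ns", "down", "ns"))
  expect_equal(attr(called, "summary"),
               c(n_up = 1, n_down = 1, n_total = 2))

  # adjusted-p mode flips the criterion
  called2 <- call_degs(res, use_adjusted = TRUE)
  expect_equal(called2$direction, c("ns", "ns", "down", "ns"))

  empty <- call_degs(res[0, ])
  expect_equal(nrow(empty), 0)
  expect_equal(unname(attr(empty, "summary")), c(0, 0, 0))
})

test_that("BH adjustment matches the reference step-up on random vectors", {
  set.seed(7)
  for (i in 1:50) {
    p <- runif(sample(5:200, 1))
    expect_equal(stats::p.adjust(p, method = "BH"), bh_oracle(p),
                 tolerance = 1e-14)
  }
})

test_that("overlap_sets reproduces brute-force Venn regions", {
  v <- overlap_sets(list(A = c("a", "b", "c"), B = c("b", "c", "d")))
  expect_equal(v$count[v$region == "A"], 1)
  expect_equal(v$count[v$region == "B"], 1)
  expect_equal(v$count[v$region == "A&B"], 2)
  expect_setequal(attr(v, "members")[["A&B"]], c("b", "c"))

  v2 <- overlap_sets(list(A = c("a"), B = c("b")))
  expect_equal(v2$count[v2$region == "A&B"], 0)

  set.seed(8)
  pool <- sprintf("g%04d", 1:1000)
  sets <- list(A = sample(pool, 100), B = sample(pool, 100),
               C = sample(pool, 100))
  v3 <- overlap_sets(sets)
  # brute-force membership tally
  for (i in seq_len(nrow(v3))) {
    inside <- Reduce(intersect, sets[unlist(v3[i, c("A", "B", "C")])])
    outside <- unique(unlist(sets[!unlist(v3[i, c("A", "B", "C")])]))
    expect_equal(v3$count[i], length(setdiff(inside, outside)))
  }
  expect_error(overlap_sets(sets[1]), "at least 2")
  expect_error(overlap_sets(rep(sets, 2)), "more than 5")
})

test_that("circos export orders by natural chromosome sort then start", {
  ann <- data.frame(gene_id = c("gA", "gB", "gC", "gD"),
                    biotype = "protein_coding",
                    chromosome = c("2", "1", "1", "10"),
                    start = c(100L, 500L, 200L, 1L))
  tb <- data.frame(gene_id = c("gA", "gB", "gC", "gD"),
                   log2fc = c(1, 2, 3, 4), p_value = 0.01, p_adjusted = 0.05,
                   mean_cpm = 10, comparison = "x",
                   timepoint_days = 0L, direction = "up")
  out <- circos_export(list(tb), ann)
  expect_equal(out$gene_id, c("gC", "gB", "gA", "gD"))  # chr1 < chr2 < chr10

  tb2 <- tb; tb2$timepoint_days <- 1L; tb2$direction <- c("up", "ns", "ns", "up")
  out2 <- circos_export(list(tb, tb2), ann)
  # row count equals the DEG union across timepoints
  expect_equal(nrow(out2), length(union(tb$gene_id[tb$direction != "ns"],
                                        tb2$gene_id[tb2$direction != "ns"])))
  expect_error(circos_export(list(tb), ann[1:2, ]), "unannotated")
})

test_that("deg_summary adds per-timepoint parts into comparison totals", {
  mk <- function(cmp, tp, up, dn) {
    data.frame(gene_id = sprintf("%s_%d_%d", cmp, tp, seq_len(up + dn)),
               direction = c(rep("up", up), rep("down", dn)),
               comparison = cmp, timepoint_days = tp)
  }
  tabs <- list(mk("KO_vs_WT", 0, 5, 2), mk("KO_vs_WT", 1, 3, 4),
               mk("KO_vs_WT", 7, 1, 1))
  s <- deg_summary(tabs)
  tot <- s[s$timepoint_days == "all", ]
  expect_equal(tot$n_up, 9)
  expect_equal(tot$n_down, 7)
  expect_equal(tot$n_total, 16)
  expect_true(all(s$n_total == s$n_up + s$n_down))

  # oracle recount on a simulated DE run
  sim <- simulate_experiment(sim_config(n_pc_genes = 150, n_lnc_genes = 20,
                                        markers_per_celltype = 0,
                                        n_responsive_celltypes = 0,
                                        n_imm_lnc = 0, seed = 9,
                                        arms = c("WT-vehicle", "KO-vehicle")))
  fx <- full_dispersions(sim)
  s2 <- fx$samples
  tabs2 <- lapply(c(0, 1), function(tp) {
    call_degs(nb_exact_test(fx$counts,
                            s2$sample_id[s2$genotype == "WT" &
                                           s2$timepoint_days == tp],
                            s2$sample_id[s2$genotype == "KO" &
                                           s2$timepoint_days == tp],
                            dispersions = fx$dispersions,
                            comparison = "KO_vs_WT", timepoint_days = tp))
  })
  summ <- deg_summary(tabs2)
  recount <- sum(vapply(tabs2, function(tb) sum(tb$direction != "ns"),
                        integer(1)))
  expect_equal(summ$n_total[summ$timepoint_days == "all"], recount)
})

test_that("null p-values are uniform where the conditional support is dense", {
  # the exact conditional p is discrete, so uniformity is judged on genes
  # with large group totals (dense support); 4 replicates give the moment
  # dispersion estimator enough residual df for sharp per-gene estimates
  sim <- simulate_null(sim_config(n_pc_genes = 4800, n_lnc_genes = 200,
                                  markers_per_celltype = 0,
                                  n_responsive_celltypes = 0,
                                  n_imm_lnc = 0, seed = 13, replicates = 4,
                                  arms = c("WT-vehicle", "KO-vehicle")))
  fx <- full_dispersions(sim)
  s <- fx$samples
  ga <- s$sample_id[s$genotype == "WT" & s$timepoint_days == 1]
  gb <- s$sample_id[s$genotype == "KO" & s$treatment == "vehicle" &
                      s$timepoint_days == 1]
  res <- nb_exact_test(fx$counts, ga, gb, dispersions = fx$dispersions)
  tot <- rowSums(fx$counts[, c(ga, gb)])
  p_dense <- res$p_value[tot >= 1000]
  expect_gt(length(p_dense), 1000)
  ks <- suppressWarnings(stats::ks.test(p_dense, "punif")$statistic)
  expect_lt(unname(ks), 0.03)
})
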