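test_that("exact-copy genes produce r = 1 edges; mismatch errors", {
  set.seed(40)
  lnc <- matrix(rnorm(3 * 9), 3, 9,
                dimnames = list(paste0("l", 1:3), paste0("s", 1:9)))
  pc <- matrix(rnorm(4 * 9), 4, 9,
               dimnames = list(paste0("p", 1:4), paste0("s", 1:9)))
  pc[1, ] <- lnc[1, ]
  ed <- lnc_pc_edges(lnc, pc)
  expect_true(any(ed$source == "l1" & ed$target == "p1" & ed$r > 0.999))

  colnames(pc) <- paste0("x", 1:9)
  expect_error(lnc_pc_edges(lnc, pc), "share sample")
})

test_that("edge lists equal a brute-force all-pairs loop", {
  set.seed(41)
  lnc <- matrix(rnorm(10 * 9), 10, 9,
                dimnames = list(paste0("l", 1:10), paste0("s", 1:9)))
  pc <- matrix(rnorm(20 * 9), 20, 9,
               dimnames = list(paste0("p", 1:20), paste0("s", 1:9)))
  ed <- lnc_pc_edges(lnc, pc, r_min = 0, padj_max = 1.1)
  expect_equal(nrow(ed), 200)
  for (i in sample(nrow(ed), 40)) {
    r_bf <- stats::cor(lnc[ed$source[i], ], pc[ed$target[i], ])
    expect_equal(ed$r[i], r_bf, tolerance = 1e-12)
    p_bf <- stats::cor.test(lnc[ed$source[i], ], pc[ed$target[i], ])$p.value
    expect_equal(ed$p_value[i], p_bf, tolerance = 1e-9)
  }
})

test_that("independent noise is almost entirely rejected at the default thresholds", {
  set.seed(42)
  lnc <- matrix(rnorm(50 * 18), 50, 18,
                dimnames = list(paste0("l", 1:50), paste0("s", 1:18)))
  pc <- matrix(rnorm(200 * 18), 200, 18,
               dimnames = list(paste0("p", 1:200), paste0("s", 1:18)))
  ed <- lnc_pc_edges(lnc, pc)
  expect_lte(nrow(ed), 0.01 * 50 * 200)
})

test_that("cell edges: thresholds, completeness, and zero-variance handling", {
  set.seed(43)
  sc <- matrix(runif(4 * 12), 4, 12,
               dimnames = list(paste0("c", 1:4), paste0("s", 1:12)))
  lnc <- matrix(rnorm(3 * 12), 3, 12,
                dimnames = list(paste0("l", 1:3), paste0("s", 1:12)))
  lnc[1, ] <- sc[2, ] + rnorm(12, 0, 0.01)
  ed <- lnc_cell_edges(lnc, sc)
  expect_true(any(ed$source == "l1" & ed$target == "c2" & ed$r > 0.99))

  ed_all <- lnc_cell_edges(lnc, sc, r_min = 0, p_max = 1.1)
  expect_equal(nrow(ed_all), 3 * 4)

  sc[4, ] <- 0.5
  expect_warning(ed2 <- lnc_cell_edges(lnc, sc, r_min = 0, p_max = 1.1),
                 "zero-variance")
  expect_equal(nrow(ed2), 3 * 3)
})

test_that("edge retention is monotone in the thresholds", {
  set.seed(44)
  lnc <- matrix(rnorm(20 * 10), 20, 10,
                dimnames = list(paste0("l", 1:20), paste0("s", 1:10)))
  pc <- matrix(rnorm(30 * 10), 30, 10,
               dimnames = list(paste0("p", 1:30), paste0("s", 1:10)))
  strict <- lnc_pc_edges(lnc, pc, r_min = 0.7, padj_max = 0.05)
  loose <- lnc_pc_edges(lnc, pc, r_min = 0.5, padj_max = 0.2)
  key <- function(e) paste(e$source, e$target)
  expect_true(all(key(strict) %in% key(loose)))
})

test_that("hub degrees and tercile categories follow the conventions", {
  ed <- data.frame(source = c("l1", "l1", "l1"), target = paste0("p", 1:3))
  h1 <- hub_rank(ed)
  expect_equal(h1$degree, 3)
  expect_equal(h1$category, "high")

  ed2 <- data.frame(
    source = rep(paste0("l", 1:6), times = c(1, 1, 5, 5, 9, 9)),
    target = paste0("p", 1:30))
  h2 <- hub_rank(ed2)
  expect_equal(h2$category[match(paste0("l", 1:6), h2$lnc_id)],
               c("low", "low", "mid", "mid", "high", "high"))

  set.seed(45)
  ed3 <- data.frame(source = sample(paste0("l", 1:8), 60, replace = TRUE),
                    target = sample(paste0("p", 1:40), 60, replace = TRUE))
  h3 <- hub_rank(ed3)
  for (l in h3$lnc_id)
    expect_equal(h3$degree[h3$lnc_id == l], sum(ed3$source == l))

  expect_error(hub_rank(ed2[0, ]), "empty")
})

test_that("multilayer assembly attaches ora terms compositionally", {
  uni <- sprintf("p%03d", 1:60)
  gs <- signature_set(list(term_hit = uni[1:10], term_other = uni[40:55]))
  pc_edges <- data.frame(source = "l1", target = uni[1:10], r = 0.95,
                         p_value = 1e-6, p_adjusted = 1e-5,
                         edge_type = "lnc_pc")
  cell_edges <- data.frame(source = "l1", target = "Macrophages", r = 0.9,
                           p_value = 1e-5, p_adjusted = 1e-4,
                           edge_type = "lnc_cell")
  net <- build_multilayer(cell_edges, pc_edges, gs, uni)
  expect_equal(net$go_edges$target, "term_hit")
  ref <- ora(uni[1:10], uni, gs)
  expect_equal(net$go_edges$p_adjusted,
               ref$p_adjusted[ref$term_id == "term_hit"])
  expect_setequal(net$nodes$type[net$nodes$id %in% c("l1", "Macrophages",
                                                     "term_hit")],
                  c("lncRNA", "immunocyte", "go_term"))

  # lncRNA without pc partners is kept but flagged
  cell2 <- rbind(cell_edges,
                 data.frame(source = "l2", target = "MDSC", r = 0.8,
                            p_value = 1e-4, p_adjusted = 1e-3,
                            edge_type = "lnc_cell"))
  net2 <- build_multilayer(cell2, pc_edges, gs, uni)
  expect_equal(unname(net2$flags["l2"]), "no functional attribution")

  # no cell edges -> empty but valid network
  net3 <- build_multilayer(cell_edges[0, ], pc_edges, gs, uni)
  expect_equal(nrow(net3$nodes), 0)
})

test_that("sankey rows count cell-edges x attached terms per lncRNA", {
  uni <- sprintf("p%03d", 1:60)
  gs <- signature_set(list(t1 = uni[1:10], t2 = uni[5:14]))
  pc_edges <- data.frame(source = "l1", target = uni[1:12], r = 0.95,
                         p_value = 1e-6, p_adjusted = 1e-5,
                         edge_type = "lnc_pc")
  cell_edges <- data.frame(source = rep("l1", 2),
                           target = c("Macrophages", "Monocytes"), r = 0.9,
                           p_value = 1e-5, p_adjusted = 1e-4,
                           edge_type = "lnc_cell")
  net <- build_multilayer(cell_edges, pc_edges, gs, uni)
  sk <- sankey_table(net)
  expect_equal(nrow(sk), 2 * nrow(net$go_edges))
})

test_that("graphml export round-trips nodes and edges", {
  uni <- sprintf("p%03d", 1:30)
  gs <- signature_set(list(t1 = uni[1:10]))
  pc_edges <- data.frame(source = "l1", target = uni[1:10], r = 0.95,
                         p_value = 1e-6, p_adjusted = 1e-5,
                         edge_type = "lnc_pc")
  cell_edges <- data.frame(source = "l1", target = "Macrophages", r = 0.9,
                           p_value = 1e-5, p_adjusted = 1e-4,
                           edge_type = "lnc_cell")
  net <- build_multilayer(cell_edges, pc_edges, gs, uni)
  f <- withr::local_tempfile(fileext = ".graphml")
  export_network(net, "graphml", f)
  g <- igraph::read_graph(f, format = "graphml")
  expect_setequal(igraph::V(g)$name, net$nodes$id)
  expect_equal(igraph::ecount(g),
               nrow(net$edges) + nrow(net$go_edges))

  # empty network still writes valid graphml
  empty <- build_multilayer(cell_edges[0, ], pc_edges, gs, uni)
  f2 <- withr::local_tempfile(fileext = ".graphml")
  export_network(empty, "graphml", f2)
  g2 <- igraph::read_graph(f2, format = "graphml")
  expect_equal(igraph::vcount(g2), 0)

  expect_error(export_network(net, "dot", f), "unknown format")

  f3 <- withr::local_tempfile(fileext = ".tsv")
  export_network(net, "sankey", f3)
  expect_equal(nrow(utils::read.delim(f3)), nrow(sankey_table(net)))
})

test_that("the end-to-end screen recovers planted links on default settings", {
  stats_by_seed <- vapply(1:5, function(seed) {
    scr <- run_screen(simulate_experiment(sim_config(seed = seed)))
    c(scr$recall, scr$precision_all)
  }, numeric(2))
  expect_gte(stats::median(stats_by_seed[1, ]), 0.8)
  expect_gte(stats::median(stats_by_seed[2, ]), 0.8)
})

test_that("marker-derived terms attach to planted lncRNAs end-to-end", {
  # attribution needs the lnc-marker correlation (the product of lnc-abundance
  # and marker-abundance correlations) to clear the 0.9 pc-edge threshold,
  # hence a strong-coupling configuration
  rate <- vapply(1:5, function(seed) {
    sim <- simulate_experiment(sim_config(seed = seed, imm_lnc_r = 0.97))
    keep <- filter_expressed(sim$expr)
    cts <- sim$expr$counts[keep, , drop = FALSE]
    l2 <- cpm(cts, log = TRUE, lib_sizes = colSums(cts) * tmm_factors(cts))
    em <- structure(list(counts = cts, samples = sim$expr$samples),
                    class = "expression_matrix")
    sp <- split_by_biotype(em, sim$annotation)
    sc <- infiltration_scores(l2, sim$signatures)
    lncm <- l2[rownames(sp$lnc$counts), , drop = FALSE]
    pcm <- l2[rownames(sp$pc$counts), , drop = FALSE]
    gs <- signature_set(stats::setNames(sim$signatures$sets,
                                        paste0(names(sim$signatures$sets),
                                               "_markers")))
    net <- build_multilayer(lnc_cell_edges(lncm, sc),
                            lnc_pc_edges(lncm, pcm), gs, rownames(pcm))
    tr <- sim$truth$imm_lnc_links
    base::mean(vapply(seq_len(nrow(tr)), function(i)
      any(net$go_edges$source == tr$lnc_id[i] &
            net$go_edges$target == paste0(tr$celltype[i], "_markers")),
      logical(1)))
  }, numeric(1))
  expect_gte(stats::median(rate), 0.8)
})
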