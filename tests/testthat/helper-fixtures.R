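# Shared fixtures and independent oracles for the test suite.

toy_counts <- function() {
  m <- matrix(c(0L, 5L, 10L, 0L), nrow = 2, byrow = TRUE,
              dimnames = list(c("g1", "g2"), c("s1", "s2")))
  meta <- data.frame(sample_id = c("s1", "s2"), genotype = c("WT", "KO"),
                     treatment = "vehicle", timepoint_days = 0L,
                     replicate = 1L, stringsAsFactors = FALSE)
  expression_matrix(m, meta)
}

# metadata for an ad-hoc matrix: one WT/KO pair per column pair
make_meta <- function(ids, genotype = NULL) {
  n <- length(ids)
  if (is.null(genotype)) genotype <- rep(c("WT", "KO"), length.out = n)
  data.frame(sample_id = ids, genotype = genotype, treatment = "vehicle",
             timepoint_days = 0L,
             replicate = stats::ave(seq_len(n), genotype, FUN = seq_along),
             stringsAsFactors = FALSE)
}

# independent NB pmf from the gamma-function definition (not dnbinom)
nb_pmf_oracle <- function(y, mu, size) {
  exp(lgamma(y + size) - lgamma(size) - lfactorial(y) +
        size * log(size / (size + mu)) + y * log(mu / (size + mu)))
}

# brute-force two-sided conditional exact p: enumerate all splits of the
# total between the group sums and add up those no more likely than observed
exact_p_oracle <- function(ya, yb, na, nb, phi) {
  t <- ya + yb
  if (t == 0) return(1)
  a <- 0:t
  if (phi < 1e-8) {
    pr <- choose(t, a) * (na / (na + nb))^a * (nb / (na + nb))^(t - a)
  } else {
    m <- t / (na + nb)
    pr <- nb_pmf_oracle(a, na * m, na / phi) *
      nb_pmf_oracle(t - a, nb * m, nb / phi)
  }
  pr <- pr / sum(pr)
  sum(pr[pr <= pr[ya + 1] * (1 + 1e-10)])
}

# brute-force hypergeometric upper tail by pmf summation with choose()
hyper_p_oracle <- function(k, K, N, n) {
  i <- k:min(K, n)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# reference Benjamini-Hochberg step-up, written out directly
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  pmin(1, cummin(n / (n:1) * p[o]))[ro]
}

# brute-force TMM factor for one sample vs a reference (trim rule spelled out)
tmm_oracle <- function(y, yref, logratio_trim = 0.3, abundance_trim = 0.05) {
  n1 <- sum(y); n2 <- sum(yref)
  keep <- y > 0 & yref > 0
  M <- log2((y[keep] / n1) / (yref[keep] / n2))
  A <- 0.5 * log2((y[keep] / n1) * (yref[keep] / n2))
  v <- (n1 - y[keep]) / (n1 * y[keep]) + (n2 - yref[keep]) / (n2 * yref[keep])
  n <- length(M)
  loM <- floor(n * logratio_trim) + 1; hiM <- n + 1 - loM
  loA <- floor(n * abundance_trim) + 1; hiA <- n + 1 - loA
  sel <- rank(M) >= loM & rank(M) <= hiM & rank(A) >= loA & rank(A) <= hiA
  2^(sum(M[sel] / v[sel]) / sum(1 / v[sel]))
}

# dispersion estimated on the full matrix with the full group structure,
# as the pipeline does before per-timepoint contrasts
full_dispersions <- function(sim) {
  keep <- filter_expressed(sim$expr)
  cts <- sim$expr$counts[keep, , drop = FALSE]
  s <- sim$expr$samples
  grp <- paste(s$genotype, s$treatment, s$timepoint_days)
  list(counts = cts, samples = s,
       dispersions = estimate_dispersion(cts, grp,
                                         norm_factors = tmm_factors(cts)))
}

# run the imm-lncRNA screen on a simulated experiment; returns edges plus
# recovery metrics against the planted links
run_screen <- function(sim) {
  keep <- filter_expressed(sim$expr)
  cts <- sim$expr$counts[keep, , drop = FALSE]
  l2 <- cpm(cts, log = TRUE, lib_sizes = colSums(cts) * tmm_factors(cts))
  em <- structure(list(counts = cts, samples = sim$expr$samples),
                  class = "expression_matrix")
  sp <- split_by_biotype(em, sim$annotation)
  sc <- infiltration_scores(l2, sim$signatures)
  ce <- lnc_cell_edges(l2[rownames(sp$lnc$counts), , drop = FALSE], sc)
  truth <- paste(sim$truth$imm_lnc_links$lnc_id,
                 sim$truth$imm_lnc_links$celltype)
  found <- paste(ce$source, ce$target)
  planted_edges <- ce[ce$source %in% sim$truth$imm_lnc_links$lnc_id, ]
  planted_found <- paste(planted_edges$source, planted_edges$target)
  list(edges = ce, scores = sc, log2cpm = l2, split = sp,
       recall = mean(truth %in% found),
       precision_all = if (length(found)) mean(found %in% truth) else NA_real_,
       precision_planted = if (length(planted_found))
         mean(planted_found %in% truth) else NA_real_)
}
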