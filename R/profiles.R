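#' Enumerate model profiles for short time series
#'
#' All templates `(0, s1, s1+s2, ...)` with unit steps `s_i` in
#' `-max_unit_change..max_unit_change`, excluding the all-zero profile, in
#' lexicographic step order. Timepoints are treated as ordinal (equal
#' spacing).
#'
#' @param n_timepoints number of timepoints (>= 2), including baseline.
#' @param max_unit_change maximum per-step unit change.
#' @return matrix of templates (profiles x timepoints); rownames are profile
#'   ids ("P1", ...), attribute `steps` holds the step matrix.
#' @export
enumerate_profiles <- function(n_timepoints = 3, max_unit_change = 2) {
  stopifnot(n_timepoints >= 2, max_unit_change >= 1)
  k <- n_timepoints - 1
  grid <- expand.grid(rep(list(seq(-max_unit_change, max_unit_change)), k))
  # lexicographic by steps: first step major
  grid <- grid[do.call(order, as.list(grid)), , drop = FALSE]
  steps <- as.matrix(grid)
  keep <- rowSums(steps != 0) > 0
  steps <- steps[keep, , drop = FALSE]
  templates <- if (k == 1) cbind(0, steps)
  else cbind(0, t(apply(steps, 1, cumsum)))
  rownames(templates) <- paste0("P", seq_len(nrow(templates)))
  rownames(steps) <- rownames(templates)
  colnames(templates) <- paste0("t", seq_len(n_timepoints) - 1)
  attr(templates, "steps") <- steps
  templates
}

#' Per-timepoint mean trajectories relative to baseline
#'
#' Averages log2-CPM per timepoint within the selected samples and subtracts
#' the first timepoint, giving gene trajectories that start at 0.
#'
#' @param log2cpm genes x samples matrix (e.g. `cpm(mat, log = TRUE)`).
#' @param timepoints timepoint value per sample column.
#' @return genes x timepoints matrix of baseline-relative deltas; columns
#'   ordered by timepoint.
#' @export
gene_trajectories <- function(log2cpm, timepoints) {
  stopifnot(ncol(log2cpm) == length(timepoints))
  tps <- sort(unique(timepoints))
  means <- vapply(tps, function(tp)
    rowMeans(log2cpm[, timepoints == tp, drop = FALSE]),
    numeric(nrow(log2cpm)))
  if (nrow(log2cpm) == 1) means <- matrix(means, nrow = 1)
  colnames(means) <- paste0("t", tps)
  means - means[, 1]
}

# row-standardize for Pearson correlation via crossproduct; zero-variance
# rows flagged NA
std_rows <- function(m) {
  mu <- rowMeans(m)
  ctr <- m - mu
  ss <- sqrt(rowSums(ctr^2))
  z <- ctr / ss
  z[ss == 0, ] <- NA_real_
  z
}

#' Assign gene trajectories to model profiles
#'
#' Each gene goes to the profile maximizing the Pearson correlation between
#' its trajectory and the template; ties break toward the lowest profile id.
#' Zero-variance (flat) trajectories get `profile_id = NA` and are excluded
#' from significance testing.
#'
#' @param trajectories genes x timepoints matrix of baseline-relative deltas
#'   (first column 0), e.g. from [gene_trajectories()].
#' @param profiles template matrix from [enumerate_profiles()].
#' @return data.frame with `gene_id`, `profile_id`, `correlation`.
#' @export
assign_genes <- function(trajectories, profiles) {
  if (ncol(trajectories) != ncol(profiles))
    stop("trajectory length (", ncol(trajectories),
         ") does not match template length (", ncol(profiles), ")")
  zg <- std_rows(trajectories)
  zp <- std_rows(profiles)
  C <- zg %*% t(zp)
  C <- round(C, 12)  # collinear templates tie exactly despite fp noise
  flat <- !is.finite(C[, 1])
  best <- rep(NA_integer_, nrow(trajectories))
  best[!flat] <- max.col(C[!flat, , drop = FALSE], ties.method = "first")
  data.frame(gene_id = rownames(trajectories),
             profile_id = rownames(profiles)[best],
             correlation = C[cbind(seq_len(nrow(C)), best)],
             stringsAsFactors = FALSE)
}

# observed per-profile assignment counts (named by profile id, zeros kept)
profile_counts <- function(assignment, profiles) {
  tab <- table(factor(assignment$profile_id, levels = rownames(profiles)))
  as.vector(tab)
}

#' Permutation significance of profile occupancy
#'
#' Null: each gene's non-baseline timepoint values are permuted independently
#' and genes re-assigned; a profile's p-value is
#' `(1 + #{permuted count >= observed}) / (1 + n_permutations)`, Bonferroni
#' corrected across profiles.
#'
#' @param assignment data.frame from [assign_genes()].
#' @param trajectories the matrix the assignment was computed from.
#' @param profiles template matrix from [enumerate_profiles()].
#' @param n_permutations number of permutations (warning below 100).
#' @param seed RNG seed for reproducible permutations.
#' @return data.frame per profile: `profile_id`, template columns, `n_genes`,
#'   `expected_count` (mean permuted count), `p_value`, `p_corrected`,
#'   `significant`.
#' @export
profile_significance <- function(assignment, trajectories, profiles,
                                 n_permutations = 1000, seed = 1) {
  if (ncol(trajectories) < 3)
    stop("need at least 2 timepoints beyond baseline")
  if (n_permutations < 100)
    warning("fewer than 100 permutations; p-values will be coarse")
  obs <- profile_counts(assignment, profiles)
  keep <- !is.na(assignment$profile_id)
  traj <- trajectories[keep, , drop = FALSE]
  G <- nrow(traj)
  k <- ncol(traj) - 1
  zp <- std_rows(profiles)
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(seed)
  exceed <- numeric(nrow(profiles))
  cum <- numeric(nrow(profiles))
  for (b in seq_len(n_permutations)) {
    perm <- traj
    if (G > 0) {
      if (k == 2) {
        sw <- sample(c(TRUE, FALSE), G, replace = TRUE)
        perm[sw, 2:3] <- traj[sw, c(3, 2)]
      } else {
        for (g in seq_len(G)) perm[g, -1] <- traj[g, 1 + sample.int(k)]
      }
      zg <- std_rows(perm)
      C <- round(zg %*% t(zp), 12)
      flat <- !is.finite(C[, 1])
      best <- max.col(C[!flat, , drop = FALSE], ties.method = "first")
      cnt <- tabulate(best, nbins = nrow(profiles))
    } else cnt <- numeric(nrow(profiles))
    exceed <- exceed + (cnt >= obs)
    cum <- cum + cnt
  }
  p <- (1 + exceed) / (1 + n_permutations)
  p_corr <- pmin(1, p * nrow(profiles))
  out <- data.frame(profile_id = rownames(profiles), unclass(profiles)[, ],
                    n_genes = obs, expected_count = cum / n_permutations,
                    p_value = p, p_corrected = p_corr,
                    significant = p_corr < 0.05,
                    row.names = NULL, stringsAsFactors = FALSE)
  out
}

#' Per-profile mean trajectories and sorted member tables
#'
#' @param assignment data.frame from [assign_genes()].
#' @param trajectories the trajectory matrix.
#' @return list: `summary` (profile x timepoint mean-trajectory matrix over
#'   non-empty profiles) and `members` (data.frame sorted within profile by
#'   correlation to template, descending).
#' @export
cluster_summary <- function(assignment, trajectories) {
  asg <- assignment[!is.na(assignment$profile_id), ]
  if (nrow(asg) == 0) stop("no assigned genes")
  prof_ids <- unique(asg$profile_id)
  summ <- t(vapply(prof_ids, function(p) {
    colMeans(trajectories[asg$gene_id[asg$profile_id == p], , drop = FALSE])
  }, numeric(ncol(trajectories))))
  rownames(summ) <- prof_ids
  members <- asg[order(asg$profile_id, -asg$correlation, asg$gene_id), ]
  rownames(members) <- NULL
  list(summary = summ, members = members)
}
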