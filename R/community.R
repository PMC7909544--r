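# Community statistics implemented from first principles: rarefaction, alpha
# diversity, Bray-Curtis dissimilarity, and the Mantel / ANOSIM / PERMANOVA
# permutation tests. All permutation p-values use the (b + 1) / (n_perm + 1)
# estimator and so are never exactly 0.

#' Rarefy a count table to even depth
#'
#' Subsamples every sample column without replacement to exactly `depth`
#' reads; reproducible under `seed`.
#'
#' @param counts count_table (features x samples)
#' @param depth target depth; default is the minimum sample sum
#' @param seed integer seed
#' @return rarefied count_table with identical dimensions
#' @export
rarefy <- function(counts, depth = NULL, seed = 1L) {
  counts <- count_table(counts)
  totals <- colSums(counts)
  depth <- depth %||% min(totals)
  short <- totals < depth
  if (any(short)) {
    mf_stop("depth_error", "depth ", depth, " exceeds total of sample(s): ",
            paste(colnames(counts)[short], collapse = ", "))
  }
  out <- matrix(0L, nrow(counts), ncol(counts), dimnames = dimnames(counts))
  set.seed(seed)
  for (j in seq_len(ncol(counts))) {
    pool <- rep.int(seq_len(nrow(counts)), counts[, j])
    drawn <- sample(pool, depth, replace = FALSE)
    tab <- tabulate(drawn, nbins = nrow(counts))
    out[, j] <- as.integer(tab)
  }
  count_table(out)
}

#' Alpha diversity of one sample
#'
#' Observed species is the number of features with positive count; Shannon
#' entropy is -sum p_i log_base(p_i) over p_i > 0 (default base 2); Simpson
#' is the Gini-Simpson index 1 - sum p_i^2.
#'
#' @param x non-negative counts of one sample (positive sum)
#' @param shannon_base logarithm base for the Shannon index (default 2)
#' @return data.frame(observed_species, shannon, simpson, shannon_base)
#' @export
alpha_diversity <- function(x, shannon_base = 2) {
  if (any(x < 0) || sum(x) <= 0) {
    mf_stop("degenerate_sample_error",
            "sample must be non-negative with positive sum")
  }
  p <- x[x > 0] / sum(x)
  data.frame(
    observed_species = sum(x > 0),
    shannon = -sum(p * log(p, base = shannon_base)),
    simpson = 1 - sum(p^2),
    shannon_base = shannon_base
  )
}

#' Alpha diversity for every sample of a count table
#' @param counts count_table
#' @param shannon_base Shannon log base
#' @return data.frame with one row per sample
#' @export
alpha_diversity_table <- function(counts, shannon_base = 2) {
  rows <- lapply(seq_len(ncol(counts)), function(j) {
    cbind(data.frame(sample_id = colnames(counts)[j],
                     stringsAsFactors = FALSE),
          alpha_diversity(counts[, j], shannon_base = shannon_base))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Bray-Curtis dissimilarity matrix
#'
#' d(x, y) = 1 - 2 sum min(x_i, y_i) / (sum x_i + sum y_i): 0 for identical
#' samples, 1 for disjoint supports.
#'
#' @param counts non-negative matrix, rows = features, columns = samples,
#'   every sample with positive sum
#' @return symmetric dissimilarity matrix (samples x samples), zero diagonal
#' @export
bray_curtis <- function(counts) {
  m <- unclass(as.matrix(counts))
  if (any(m < 0)) mf_stop("domain_error", "negative abundance")
  cs <- colSums(m)
  if (any(cs <= 0)) {
    mf_stop("degenerate_sample_error", "zero-sum sample(s): ",
            paste(colnames(m)[cs <= 0], collapse = ", "))
  }
  n <- ncol(m)
  d <- matrix(0, n, n, dimnames = list(colnames(m), colnames(m)))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      shared <- sum(pmin(m[, i], m[, j]))
      d[i, j] <- d[j, i] <- 1 - 2 * shared / (cs[i] + cs[j])
    }
  }
  d
}

# validate a square symmetric distance matrix; returns it with dimnames
check_distance_matrix <- function(d) {
  d <- as.matrix(d)
  if (nrow(d) != ncol(d)) mf_stop("dimension_error", "distance matrix not square")
  if (max(abs(d - t(d))) > 1e-12) {
    mf_stop("domain_error", "distance matrix not symmetric")
  }
  if (any(abs(diag(d)) > 1e-12)) {
    mf_stop("domain_error", "distance matrix diagonal not zero")
  }
  d
}

#' Mantel test between two distance matrices
#'
#' Statistic: the Pearson correlation of the upper-triangle entries.
#' Significance: rows and columns of `d2` are permuted jointly; one-sided
#' p-value for permuted r >= observed, computed as (b + 1) / (n_perm + 1).
#'
#' @param d1,d2 distance matrices over the same samples (>= 4)
#' @param n_perm number of permutations (default 999)
#' @param seed integer seed
#' @return data.frame(statistic_name, statistic, n_permutations, p_value, seed)
#' @export
mantel <- function(d1, d2, n_perm = 999L, seed = 1L) {
  d1 <- check_distance_matrix(d1)
  d2 <- check_distance_matrix(d2)
  n <- nrow(d1)
  if (n < 4L) mf_stop("design_error", "Mantel test needs >= 4 samples")
  if (nrow(d2) != n) mf_stop("dimension_error", "matrix sizes differ")
  if (!is.null(rownames(d1)) && !is.null(rownames(d2))) {
    if (!setequal(rownames(d1), rownames(d2))) {
      mf_stop("design_error", "sample sets differ")
    }
    d2 <- d2[rownames(d1), rownames(d1)]
  }
  ut <- upper.tri(d1)
  v1 <- d1[ut]
  if (stats::sd(v1) == 0 || stats::sd(d2[ut]) == 0) {
    mf_stop("degenerate_matrix_error", "zero variance in a distance triangle")
  }
  r_obs <- stats::cor(v1, d2[ut])
  set.seed(seed)
  b <- 0L
  for (k in seq_len(n_perm)) {
    p <- sample.int(n)
    r_p <- stats::cor(v1, d2[p, p][ut])
    if (r_p >= r_obs) b <- b + 1L
  }
  data.frame(statistic_name = "mantel_r", statistic = r_obs,
             n_permutations = n_perm, p_value = (b + 1) / (n_perm + 1),
             seed = seed, stringsAsFactors = FALSE)
}

# mean within/between ranks from precomputed pair ranks and group labels
anosim_r_stat <- function(rank_d, same_group) {
  rw <- mean(rank_d[same_group])
  rb <- mean(rank_d[!same_group])
  n_pairs <- length(rank_d)
  # M/2 with M = n(n-1)/2 total pairs
  (rb - rw) / (n_pairs / 2)
}

#' Analysis of similarities (ANOSIM)
#'
#' Ranks all pairwise distances; R = (mean between-group rank - mean
#' within-group rank) / (M/2), M = n(n-1)/2. R near 1 means groups are well
#' separated, near 0 means no structure. One-sided permutation p (>=).
#'
#' @param d distance matrix
#' @param groups group label per sample (>= 2 groups, each >= 2 samples)
#' @param n_perm permutations (default 999)
#' @param seed integer seed
#' @return data.frame(statistic_name, statistic, n_permutations, p_value, seed)
#' @export
anosim <- function(d, groups, n_perm = 999L, seed = 1L) {
  d <- check_distance_matrix(d)
  groups <- as.character(groups)
  n <- nrow(d)
  if (length(groups) != n) mf_stop("dimension_error", "one label per sample")
  tab <- table(groups)
  if (length(tab) < 2L || any(tab < 2L)) {
    mf_stop("design_error", ">= 2 groups with >= 2 samples each required")
  }
  ut <- which(upper.tri(d), arr.ind = TRUE)
  rank_d <- rank(d[upper.tri(d)])
  same <- groups[ut[, 1L]] == groups[ut[, 2L]]
  r_obs <- anosim_r_stat(rank_d, same)
  set.seed(seed)
  b <- 0L
  for (k in seq_len(n_perm)) {
    g <- groups[sample.int(n)]
    if (anosim_r_stat(rank_d, g[ut[, 1L]] == g[ut[, 2L]]) >= r_obs) b <- b + 1L
  }
  data.frame(statistic_name = "anosim_R", statistic = r_obs,
             n_permutations = n_perm, p_value = (b + 1) / (n_perm + 1),
             seed = seed, stringsAsFactors = FALSE)
}

# pseudo-F from squared distances and labels
permanova_f_stat <- function(d2mat, groups) {
  n <- nrow(d2mat)
  g_levels <- unique(groups)
  g <- length(g_levels)
  ss_total <- sum(d2mat[upper.tri(d2mat)]) / n
  ss_within <- 0
  for (lev in g_levels) {
    idx <- which(groups == lev)
    sub <- d2mat[idx, idx, drop = FALSE]
    ss_within <- ss_within + sum(sub[upper.tri(sub)]) / length(idx)
  }
  ((ss_total - ss_within) / (g - 1)) / (ss_within / (n - g))
}

#' One-way PERMANOVA
#'
#' Pseudo-F = (SS_between / (g-1)) / (SS_within / (n-g)) with sums of squares
#' computed from squared pairwise distances: SS_total = sum_{i<j} d_ij^2 / n
#' and SS_within the analogous per-group sums. One-sided permutation p over
#' label shuffles.
#'
#' @param d distance matrix
#' @param groups group label per sample
#' @param n_perm permutations (default 999)
#' @param seed integer seed
#' @return data.frame(statistic_name, statistic, n_permutations, p_value, seed)
#' @export
permanova <- function(d, groups, n_perm = 999L, seed = 1L) {
  d <- check_distance_matrix(d)
  groups <- as.character(groups)
  n <- nrow(d)
  if (length(groups) != n) mf_stop("dimension_error", "one label per sample")
  tab <- table(groups)
  if (length(tab) < 2L || any(tab < 2L)) {
    mf_stop("design_error", ">= 2 groups with >= 2 samples each required")
  }
  if (n - length(tab) <= 0L) mf_stop("design_error", "no residual df")
  d2mat <- d^2
  f_obs <- permanova_f_stat(d2mat, groups)
  set.seed(seed)
  b <- 0L
  for (k in seq_len(n_perm)) {
    if (permanova_f_stat(d2mat, groups[sample.int(n)]) >= f_obs) b <- b + 1L
  }
  data.frame(statistic_name = "permanova_pseudoF", statistic = f_obs,
             n_permutations = n_perm, p_value = (b + 1) / (n_perm + 1),
             seed = seed, stringsAsFactors = FALSE)
}
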