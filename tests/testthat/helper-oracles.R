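# Independent brute-force oracles used to cross-check the package's
# first-principles implementations on small fixtures. Each oracle is written
# from the defining formula, independently of the code path it checks.

oracle_bray <- function(counts) {
  m <- unclass(as.matrix(counts))
  n <- ncol(m)
  d <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      num <- sum(abs(m[, i] - m[, j]))
      den <- sum(m[, i] + m[, j])
      d[i, j] <- num / den
    }
  }
  dimnames(d) <- list(colnames(m), colnames(m))
  d
}

oracle_mantel_r <- function(d1, d2) {
  v1 <- d1[upper.tri(d1)]
  v2 <- d2[upper.tri(d2)]
  sum((v1 - mean(v1)) * (v2 - mean(v2))) /
    sqrt(sum((v1 - mean(v1))^2) * sum((v2 - mean(v2))^2))
}

oracle_anosim_r <- function(d, groups) {
  n <- nrow(d)
  pairs <- which(upper.tri(d), arr.ind = TRUE)
  rk <- rank(d[upper.tri(d)])
  within <- groups[pairs[, 1]] == groups[pairs[, 2]]
  m_pairs <- n * (n - 1) / 2
  (mean(rk[!within]) - mean(rk[within])) / (m_pairs / 2)
}

# PERMANOVA pseudo-F via the Gower-centered matrix formulation
oracle_permanova_f <- function(d, groups) {
  n <- nrow(d)
  a <- -0.5 * d^2
  h <- diag(n) - matrix(1 / n, n, n)
  g <- h %*% a %*% h
  groups <- as.factor(groups)
  x <- stats::model.matrix(~ groups)
  hat <- x %*% solve(crossprod(x)) %*% t(x)
  ss_b <- sum(diag(hat %*% g %*% hat))
  ss_t <- sum(diag(g))
  n_g <- nlevels(groups)
  (ss_b / (n_g - 1)) / ((ss_t - ss_b) / (n - n_g))
}

oracle_vif <- function(x) {
  vapply(seq_len(ncol(x)), function(j) {
    r2 <- summary(stats::lm(x[, j] ~ x[, -j, drop = FALSE]))$r.squared
    1 / (1 - r2)
  }, numeric(1))
}

# CCA eigenvalues by explicit dense algebra: chi-square standardize, project
# onto the weighted constraint space with solve(), eigen-decompose the cross
# product of the fitted matrix
oracle_cca_eig <- function(y, x) {
  yt <- t(unclass(as.matrix(y)))
  p <- yt / sum(yt)
  r <- rowSums(p)
  cc <- colSums(p)
  qbar <- (p - outer(r, cc)) / sqrt(outer(r, cc))
  xc <- sweep(as.matrix(x), 2, colSums(r * as.matrix(x)), `-`)
  xw <- sqrt(r) * xc
  fitted <- xw %*% solve(crossprod(xw)) %*% crossprod(xw, qbar)
  ev <- eigen(fitted %*% t(fitted), symmetric = TRUE)$values
  sort(ev[ev > 1e-10], decreasing = TRUE)
}

# Kruskal stress-1 of a configuration against a dissimilarity matrix,
# recomputed from the definition (isotonic disparities in delta order)
oracle_stress1 <- function(coords, d) {
  dv_mat <- as.matrix(stats::dist(coords))
  dv <- dv_mat[upper.tri(dv_mat)]
  delta <- d[upper.tri(d)]
  o <- order(delta, dv)
  disp <- numeric(length(dv))
  disp[o] <- stats::isoreg(dv[o])$yf
  sqrt(sum((dv - disp)^2) / sum(dv^2))
}

# small random count table fixture
random_counts <- function(n_feat = 20, n_samp = 6, lambda = 10, seed = 1) {
  set.seed(seed)
  m <- matrix(rpois(n_feat * n_samp, lambda), n_feat, n_samp,
              dimnames = list(paste0("f", seq_len(n_feat)),
                              paste0("s", seq_len(n_samp))))
  m[, colSums(m) > 0, drop = FALSE]
}

tsv_tmp <- function(lines) {
  path <- tempfile(fileext = ".tsv")
  writeLines(lines, path)
  path
}
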