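# Canonical correspondence analysis (chi-square standardized response,
# weighted projection onto constraints, SVD), permutation significance,
# variance-inflation screening, permutation forward selection, and two-group
# variation partitioning.

#' Build a constraint (environment/vegetation covariate) table
#'
#' @param x data.frame or matrix, rows = samples (named), columns = variables
#' @param standardize center and scale each variable to mean 0, SD 1
#'   (default TRUE; units such as g/kg vs % otherwise dominate projections)
#' @return numeric matrix of class `constraint_table` with attribute
#'   `standardized`
#' @export
constraint_table <- function(x, standardize = TRUE) {
  m <- as.matrix(x)
  storage.mode(m) <- "double"
  if (is.null(rownames(m))) mf_stop("format_error", "sample names required")
  if (any(!is.finite(m))) mf_stop("domain_error", "non-finite covariate value")
  sds <- apply(m, 2L, stats::sd)
  if (any(sds == 0)) {
    mf_stop("domain_error", "constant variable(s): ",
            paste(colnames(m)[sds == 0], collapse = ", "))
  }
  if (standardize) m <- scale(m)
  attr(m, "scaled:center") <- NULL
  attr(m, "scaled:scale") <- NULL
  structure(m, standardized = standardize,
            class = c("constraint_table", "matrix", "array"))
}

# chi-square standardized response matrix (sites x features) and site masses
# from a non-negative abundance matrix in package orientation
# (features x samples)
chisq_standardize <- function(y) {
  y <- unclass(as.matrix(y))
  if (any(y < 0)) mf_stop("domain_error", "response must be non-negative")
  yt <- t(y)  # sites x features
  tot <- sum(yt)
  if (tot <= 0) mf_stop("degenerate_matrix_error", "response sums to zero")
  p <- yt / tot
  r <- rowSums(p)
  cc <- colSums(p)
  if (any(r <= 0) || any(cc <= 0)) {
    mf_stop("degenerate_matrix_error",
            "zero-sum sample or feature in response")
  }
  qbar <- (p - outer(r, cc)) / sqrt(outer(r, cc))
  if (sum(qbar^2) <= 1e-14) {
    mf_stop("degenerate_matrix_error",
            "response has no row/column heterogeneity: total inertia is 0")
  }
  list(qbar = qbar, r = r, c = cc)
}

# weighted, centered, row-weighted constraint matrix for the projection
weight_constraints <- function(x, r) {
  xc <- sweep(x, 2L, colSums(r * x), `-`)   # weighted column centering
  sqrt(r) * xc
}

# projection of qbar onto the column space of xw via pseudo-inverse
project_constrained <- function(qbar, xw) {
  sv <- svd(xw)
  pos <- sv$d > max(dim(xw)) * max(sv$d, 0) * .Machine$double.eps
  if (!any(pos)) return(list(fitted = qbar * 0, rank = 0L))
  u <- sv$u[, pos, drop = FALSE]
  list(fitted = u %*% (t(u) %*% qbar), rank = sum(pos))
}

#' Canonical correspondence analysis
#'
#' The response matrix is chi-square standardized (entries
#' (p_ij - r_i c_j) / sqrt(r_i c_j) from the relative-abundance table with
#' row/column masses r, c); total inertia is the sum of squared standardized
#' entries. The standardized matrix is projected by weighted least squares
#' onto the constraint space, and the singular value decomposition of the
#' projection yields the canonical eigenvalues, site scores and variable
#' biplot scores. Collinear constraints trigger a rank-deficiency warning and
#' the pseudo-inverse is used.
#'
#' @param y non-negative response matrix (features x samples): a count table
#'   or a log-scale family abundance matrix (non-negative by the ln(x+1)
#'   construction)
#' @param x constraint_table (samples x variables) over the same samples
#' @return list of class `cca_result`: total_inertia, constrained_inertia,
#'   proportion_explained, eigenvalues, site_scores, biplot_scores, rank
#' @export
cca <- function(y, x) {
  x <- as.matrix(x)
  if (ncol(as.matrix(y)) != nrow(x)) {
    mf_stop("design_error", "samples of response and constraints differ")
  }
  if (!is.null(colnames(y)) && !is.null(rownames(x))) {
    if (!setequal(colnames(y), rownames(x))) {
      mf_stop("design_error", "sample names of response and constraints differ")
    }
    x <- x[colnames(y), , drop = FALSE]
  }
  if (ncol(x) >= nrow(x) - 1L) {
    warning("number of constraints not smaller than n - 1; ",
            "solution is saturated or near-saturated")
  }
  std <- chisq_standardize(y)
  xw <- weight_constraints(x, std$r)
  pr <- project_constrained(std$qbar, xw)
  if (pr$rank < ncol(x)) {
    warning("constraints are rank-deficient (rank ", pr$rank, " < ",
            ncol(x), "); pseudo-inverse used")
  }
  total <- sum(std$qbar^2)
  constrained <- sum(pr$fitted^2)
  sv <- svd(pr$fitted)
  keep <- which(sv$d^2 > 1e-12 * max(sv$d^2, 1e-300))
  eig <- sv$d[keep]^2
  site <- (sv$u[, keep, drop = FALSE] / sqrt(std$r)) *
    rep(sv$d[keep], each = nrow(sv$u))
  rownames(site) <- rownames(xw)
  colnames(site) <- paste0("CCA", seq_along(keep))
  # biplot scores: weighted correlation of constraints with the axis scores
  axes_w <- sv$u[, keep, drop = FALSE]
  bip <- crossprod(xw, axes_w)
  bip <- bip / sqrt(colSums(xw^2))
  colnames(bip) <- colnames(site)
  structure(
    list(total_inertia = total, constrained_inertia = constrained,
         proportion_explained = constrained / total,
         eigenvalues = eig, site_scores = site, biplot_scores = bip,
         rank = pr$rank),
    class = "cca_result"
  )
}

#' Permutation test of a canonical correspondence analysis
#'
#' Statistic: the proportion of inertia explained (equivalently the
#' constrained inertia, since total inertia is permutation invariant). Rows
#' of the constraint matrix are permuted; p = (b + 1) / (n_perm + 1).
#'
#' @param y response matrix (features x samples)
#' @param x constraint_table
#' @param n_perm permutations (default 999)
#' @param seed integer seed
#' @return data.frame(statistic_name, statistic, n_permutations, p_value, seed)
#' @export
cca_permutation_test <- function(y, x, n_perm = 999L, seed = 1L) {
  x <- as.matrix(x)
  if (!is.null(colnames(y)) && !is.null(rownames(x))) {
    x <- x[colnames(y), , drop = FALSE]
  }
  std <- chisq_standardize(y)
  total <- sum(std$qbar^2)
  stat_for <- function(xm) {
    sum(project_constrained(std$qbar, weight_constraints(xm, std$r))$fitted^2) /
      total
  }
  obs <- stat_for(x)
  set.seed(seed)
  b <- 0L
  n <- nrow(x)
  for (k in seq_len(n_perm)) {
    if (stat_for(x[sample.int(n), , drop = FALSE]) >= obs) b <- b + 1L
  }
  data.frame(statistic_name = "cca_proportion_explained", statistic = obs,
             n_permutations = n_perm, p_value = (b + 1) / (n_perm + 1),
             seed = seed, stringsAsFactors = FALSE)
}

#' Variance inflation factors of a constraint table
#'
#' VIF_j = 1 / (1 - R^2_j) from the least-squares regression of variable j on
#' all the others; infinite under perfect collinearity.
#'
#' @param x constraint matrix (samples x variables, >= 2 variables)
#' @return named numeric vector of VIFs
#' @export
vif <- function(x) {
  x <- as.matrix(x)
  if (ncol(x) < 2L) mf_stop("design_error", "VIF needs >= 2 variables")
  vapply(seq_len(ncol(x)), function(j) {
    fit <- stats::lm.fit(cbind(1, x[, -j, drop = FALSE]), x[, j])
    rss <- sum(fit$residuals^2)
    tss <- sum((x[, j] - mean(x[, j]))^2)
    if (tss == 0) return(Inf)
    r2 <- 1 - rss / tss
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1L), USE.NAMES = FALSE) |> stats::setNames(colnames(x))
}

#' Iterative variance-inflation screening
#'
#' Repeatedly removes the variable with the largest VIF while any VIF is at
#' or above `vif_max` (default 20, the conventional collinearity cut for
#' constrained ordination).
#'
#' @param x constraint_table
#' @param vif_max removal threshold (default 20)
#' @return list(x = screened constraint matrix, removed = character vector,
#'   vifs = final VIFs)
#' @export
vif_screen <- function(x, vif_max = 20.0) {
  x <- as.matrix(x)
  removed <- character(0L)
  while (ncol(x) >= 2L) {
    v <- vif(x)
    if (all(v < vif_max)) break
    worst <- which.max(v)
    removed <- c(removed, colnames(x)[worst])
    x <- x[, -worst, drop = FALSE]
  }
  if (ncol(x) == 0L) {
    mf_stop("empty_constraints_error", "all variables removed by VIF screen")
  }
  final_v <- if (ncol(x) >= 2L) vif(x) else
    stats::setNames(1, colnames(x))
  list(x = x, removed = removed, vifs = final_v)
}

#' Monte-Carlo permutation forward selection of constraints
#'
#' Greedy: at each step the candidate adding the most constrained inertia is
#' tested by a conditional permutation test (its rows permuted, the already
#' selected variables held fixed); it is kept only if p < `alpha` and the
#' resulting set's maximum VIF stays below `vif_max`. Stops when no candidate
#' qualifies. An empty selection is allowed (with a warning).
#'
#' @param y response matrix (features x samples)
#' @param x screened constraint_table
#' @param alpha inclusion level (default 0.05)
#' @param n_perm permutations per candidate test (default 999)
#' @param vif_max collinearity bound on the growing set (default 20)
#' @param seed integer seed
#' @return list(x = selected constraint matrix or NULL, selected = character,
#'   trace = data.frame of the inclusion path)
#' @export
forward_select <- function(y, x, alpha = 0.05, n_perm = 999L, vif_max = 20.0,
                           seed = 1L) {
  x <- as.matrix(x)
  if (!is.null(colnames(y)) && !is.null(rownames(x))) {
    x <- x[colnames(y), , drop = FALSE]
  }
  std <- chisq_standardize(y)
  total <- sum(std$qbar^2)
  inertia_of <- function(xm) {
    if (is.null(xm) || ncol(xm) == 0L) return(0)
    sum(project_constrained(std$qbar, weight_constraints(xm, std$r))$fitted^2)
  }
  selected <- character(0L)
  candidates <- colnames(x)
  trace <- list()
  set.seed(seed)
  n <- nrow(x)
  current <- 0
  repeat {
    if (length(candidates) == 0L) break
    gains <- vapply(candidates, function(v) {
      inertia_of(x[, c(selected, v), drop = FALSE]) - current
    }, numeric(1L))
    best <- candidates[which.max(gains)]
    gain_obs <- max(gains)
    # conditional permutation: permute the candidate's rows only
    b <- 0L
    for (k in seq_len(n_perm)) {
      xp <- x[, c(selected, best), drop = FALSE]
      xp[, best] <- xp[sample.int(n), best]
      if (inertia_of(xp) - current >= gain_obs) b <- b + 1L
    }
    p <- (b + 1) / (n_perm + 1)
    cand_set <- x[, c(selected, best), drop = FALSE]
    max_vif <- if (ncol(cand_set) >= 2L) max(vif(cand_set)) else 1
    accept <- p < alpha && max_vif < vif_max
    trace[[length(trace) + 1L]] <- data.frame(
      variable = best, added_inertia = gain_obs, p_value = p,
      max_vif = max_vif, accepted = accept, stringsAsFactors = FALSE
    )
    if (!accept) break
    selected <- c(selected, best)
    candidates <- setdiff(candidates, best)
    current <- inertia_of(x[, selected, drop = FALSE])
  }
  if (length(selected) == 0L) {
    warning("forward selection retained no variable")
    return(list(x = NULL, selected = character(0L),
                trace = do.call(rbind, trace)))
  }
  list(x = x[, selected, drop = FALSE], selected = selected,
       trace = do.call(rbind, trace))
}

#' Two-group variation partitioning
#'
#' With a = proportion explained by group 1 alone, b = by group 2 alone and
#' t = by their union: unique1 = t - b, unique2 = t - a, shared = a + b - t,
#' unexplained = 1 - t. Fractions are raw (non-adjusted) proportions of
#' inertia and always sum to 1; the shared fraction may be negative (a known
#' property of the partition) and is reported as computed.
#'
#' @param y response matrix (features x samples)
#' @param x_group1,x_group2 constraint matrices for the two variable groups
#'   (no variable in common)
#' @return one-row data.frame: fraction_a (unique 1), fraction_b (unique 2),
#'   fraction_shared, fraction_unexplained, plus the marginal proportions
#'   prop_group1, prop_group2, prop_combined
#' @export
variation_partition <- function(y, x_group1, x_group2) {
  x1 <- as.matrix(x_group1)
  x2 <- as.matrix(x_group2)
  overlap <- intersect(colnames(x1), colnames(x2))
  if (length(overlap) > 0L) {
    mf_stop("design_error", "variable(s) in both groups: ",
            paste(overlap, collapse = ", "))
  }
  a <- cca(y, x1)$proportion_explained
  b <- cca(y, x2)$proportion_explained
  t_all <- suppressWarnings(cca(y, cbind(x1, x2))$proportion_explained)
  data.frame(
    fraction_a = t_all - b, fraction_b = t_all - a,
    fraction_shared = a + b - t_all, fraction_unexplained = 1 - t_all,
    prop_group1 = a, prop_group2 = b, prop_combined = t_all
  )
}
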