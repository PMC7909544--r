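# Non-metric multidimensional scaling minimizing Kruskal stress-1: monotone
# (isotonic) disparities fitted by pool-adjacent-violators, configuration
# updates by the Guttman transform (SMACOF majorization), best of several
# starts with classical scaling as one deterministic start.

# pairwise Euclidean distances of a configuration, as the upper-tri vector
config_dist_vec <- function(x, pair_i, pair_j) {
  diff <- x[pair_i, , drop = FALSE] - x[pair_j, , drop = FALSE]
  sqrt(rowSums(diff^2))
}

# Kruskal stress-1 given config distances and monotone disparities
stress1 <- function(dv, disp) {
  denom <- sum(dv^2)
  if (denom == 0) return(Inf)
  sqrt(sum((dv - disp)^2) / denom)
}

# monotone disparities: config distances PAVA-fitted in the order of the
# observed dissimilarities (primary tie treatment: ties in delta are ordered
# by the current config distance, letting them untie freely)
fit_disparities <- function(dv, ord_key) {
  o <- order(ord_key, dv)
  fit <- stats::isoreg(dv[o])$yf
  disp <- numeric(length(dv))
  disp[o] <- fit
  disp
}

# one Guttman-transform update of the configuration toward disparities
guttman_update <- function(x, disp, pair_i, pair_j) {
  n <- nrow(x)
  dv <- config_dist_vec(x, pair_i, pair_j)
  ratio <- ifelse(dv > 0, disp / dv, 0)
  b <- matrix(0, n, n)
  b[cbind(pair_i, pair_j)] <- -ratio
  b[cbind(pair_j, pair_i)] <- -ratio
  diag(b) <- -rowSums(b)
  (b %*% x) / n
}

#' Non-metric multidimensional scaling (Kruskal stress-1)
#'
#' Finds a k-dimensional configuration whose inter-point distances match, in
#' rank order, the observed dissimilarities. Misfit is Kruskal's stress-1,
#' sqrt(sum((d_hat - disp)^2) / sum(d_hat^2)), where d_hat are configuration
#' distances and disp the monotone (isotonic, pool-adjacent-violators)
#' regression of d_hat on the dissimilarity order. The configuration is
#' updated by Guttman-transform majorization; the best of `n_starts` starts
#' is returned (classical metric scaling as one deterministic start, the rest
#' random). Deterministic under `seed`.
#'
#' @param d distance matrix with >= k + 1 samples
#' @param k embedding dimension (default 2)
#' @param n_starts number of starts (default 20)
#' @param max_iter iterations per start (default 300)
#' @param tol stop when the stress improvement falls below this (default 1e-6)
#' @param seed integer seed
#' @return list of class `nmds_result`: coordinates (samples x k, columns
#'   centered), stress, n_starts, converged, seed
#' @export
nmds <- function(d, k = 2L, n_starts = 20L, max_iter = 300L, tol = 1e-6,
                 seed = 1L) {
  d <- check_distance_matrix(d)
  n <- nrow(d)
  if (n < k + 1L) mf_stop("design_error", "need >= k + 1 samples")
  pairs <- which(upper.tri(d), arr.ind = TRUE)
  pair_i <- pairs[, 1L]
  pair_j <- pairs[, 2L]
  delta <- d[upper.tri(d)]

  run_start <- function(x0) {
    x <- x0
    dv <- config_dist_vec(x, pair_i, pair_j)
    disp <- fit_disparities(dv, delta)
    s <- stress1(dv, disp)
    best_x <- x
    best_s <- s
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      x <- guttman_update(x, disp, pair_i, pair_j)
      dv <- config_dist_vec(x, pair_i, pair_j)
      disp <- fit_disparities(dv, delta)
      s_new <- stress1(dv, disp)
      if (s_new < best_s) {
        best_s <- s_new
        best_x <- x
      }
      if (abs(s - s_new) < tol) {
        converged <- TRUE
        break
      }
      s <- s_new
    }
    list(x = best_x, stress = best_s, converged = converged)
  }

  # deterministic classical-scaling start
  cm <- suppressWarnings(stats::cmdscale(stats::as.dist(d), k = k))
  if (ncol(cm) < k) {
    cm <- cbind(cm, matrix(0, n, k - ncol(cm)))
  }
  starts <- list(cm)
  set.seed(seed)
  for (s in seq_len(max(0L, n_starts - 1L))) {
    starts[[s + 1L]] <- matrix(stats::rnorm(n * k), n, k) * mean(delta)
  }
  fits <- lapply(starts, run_start)
  stresses <- vapply(fits, `[[`, numeric(1L), "stress")
  best <- fits[[which.min(stresses)]]
  coords <- scale(best$x, center = TRUE, scale = FALSE)
  attr(coords, "scaled:center") <- NULL
  dimnames(coords) <- list(rownames(d), paste0("NMDS", seq_len(k)))
  if (!any(vapply(fits, `[[`, logical(1L), "converged"))) {
    warning("NMDS did not converge in any start; best configuration returned")
  }
  structure(
    list(coordinates = coords, stress = best$stress,
         n_starts = length(starts),
         converged = best$converged, seed = seed),
    class = "nmds_result"
  )
}
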