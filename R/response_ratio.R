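# Response-ratio effect sizes for treatment/control contrasts of gene-family
# abundances, inverse-variance weighted meta-analysis, and functional-category
# shift summaries.

#' Response ratio of a treatment/control contrast
#'
#' The response ratio is the log proportional change between group means,
#' RR = ln(Xt / Xc), with sampling variance
#' v = st^2 / (nt Xt^2) + sc^2 / (nc Xc^2).
#' The (1 - alpha) confidence interval is RR +/- z * sqrt(v); the effect is
#' called significant when the interval excludes 0.
#'
#' @param xt_mean,xc_mean positive group means (here, means of normalized
#'   log-scale abundances)
#' @param st,sc group standard deviations (>= 0, not both 0)
#' @param nt,nc group sizes (>= 2)
#' @param z normal quantile for the CI (default 1.96, the 95% interval)
#' @return one-row data.frame: rr, variance, se, ci_low, ci_high,
#'   significant, plus the inputs
#' @export
response_ratio <- function(xt_mean, xc_mean, st, sc, nt, nc, z = 1.96) {
  if (any(xt_mean <= 0) || any(xc_mean <= 0)) {
    mf_stop("domain_error", "group means must be positive for a log ratio")
  }
  if (any(nt < 2) || any(nc < 2)) {
    mf_stop("domain_error", "group sizes must be >= 2")
  }
  if (any(st < 0) || any(sc < 0)) {
    mf_stop("domain_error", "standard deviations must be >= 0")
  }
  if (any(st == 0 & sc == 0)) {
    mf_stop("degenerate_variance_error",
            "both group standard deviations are zero")
  }
  rr <- log(xt_mean / xc_mean)
  v <- st^2 / (nt * xt_mean^2) + sc^2 / (nc * xc_mean^2)
  se <- sqrt(v)
  ci_low <- rr - z * se
  ci_high <- rr + z * se
  data.frame(
    xt_mean = xt_mean, xc_mean = xc_mean, st = st, sc = sc,
    nt = nt, nc = nc, rr = rr, variance = v, se = se,
    ci_low = ci_low, ci_high = ci_high,
    significant = ci_low > 0 | ci_high < 0
  )
}

#' Inverse-variance weighted response ratio (RR++)
#'
#' Combines individual response ratios with weights w = 1/v:
#' RR++ = sum(w * RR) / sum(w), with standard error
#' S_RR++ = sqrt(1 / sum(w)) and CI RR++ +/- z * S_RR++.
#'
#' @param rr numeric vector of individual response ratios
#' @param variance numeric vector of their sampling variances (> 0)
#' @param z normal quantile for the CI
#' @return one-row data.frame: n, rr_weighted, se_weighted, ci_low, ci_high,
#'   significant
#' @export
weighted_rr <- function(rr, variance, z = 1.96) {
  if (length(rr) == 0L) mf_stop("empty_input_error", "no response ratios")
  if (length(rr) != length(variance)) {
    mf_stop("dimension_error", "rr and variance lengths differ")
  }
  if (any(variance <= 0)) {
    mf_stop("domain_error", "variances must be positive")
  }
  w <- 1 / variance
  rw <- sum(w * rr) / sum(w)
  sew <- sqrt(1 / sum(w))
  data.frame(
    n = length(rr), rr_weighted = rw, se_weighted = sew,
    ci_low = rw - z * sew, ci_high = rw + z * sew,
    significant = (rw - z * sew) > 0 | (rw + z * sew) < 0
  )
}

#' Unpaired two-sided t-test for one gene family
#'
#' Welch (unequal variance) by default; a pooled-variance test is available.
#' When both groups have zero variance and equal means the p-value is 1 by
#' convention.
#'
#' @param values_a,values_b numeric vectors, each >= 2 values
#' @param pooled use the pooled-variance (classic) test instead of Welch
#' @return data.frame(statistic, df, p)
#' @export
gene_t_test <- function(values_a, values_b, pooled = FALSE) {
  if (length(values_a) < 2L || length(values_b) < 2L) {
    mf_stop("domain_error", "each group needs >= 2 values")
  }
  if (stats::sd(values_a) == 0 && stats::sd(values_b) == 0) {
    if (mean(values_a) == mean(values_b)) {
      return(data.frame(statistic = 0, df = NA_real_, p = 1))
    }
    return(data.frame(statistic = sign(mean(values_a) - mean(values_b)) * Inf,
                      df = NA_real_, p = 0))
  }
  tt <- stats::t.test(values_a, values_b, var.equal = pooled)
  data.frame(statistic = unname(tt$statistic), df = unname(tt$parameter),
             p = tt$p.value)
}

#' Response ratios and t-tests for every gene family under a contrast
#'
#' Group means and standard deviations are computed per family on the
#' normalized log-scale abundance matrix; families with a non-positive mean
#' in either group are excluded and listed (a log ratio is undefined there).
#'
#' @param fam family_abundance_matrix (families x samples)
#' @param design contrast_design
#' @param z normal quantile for the CI
#' @param bh also report Benjamini-Hochberg adjusted t-test p-values
#' @return data.frame, one row per evaluated family, with the response-ratio
#'   statistics, t-test record and category label; attribute
#'   `excluded_families` lists families skipped for non-positive means
#' @export
contrast_all_families <- function(fam, design, z = 1.96, bh = FALSE) {
  stopifnot(inherits(design, "contrast_design"))
  t_s <- intersect(design$treatment_samples, colnames(fam))
  c_s <- intersect(design$control_samples, colnames(fam))
  if (length(t_s) < 2L || length(c_s) < 2L) {
    mf_stop("design_error", "each group needs >= 2 samples in the matrix")
  }
  mt <- fam[, t_s, drop = FALSE]
  mc <- fam[, c_s, drop = FALSE]
  xt <- rowMeans(mt)
  xc <- rowMeans(mc)
  st <- apply(mt, 1L, stats::sd)
  sc <- apply(mc, 1L, stats::sd)
  # a family constant across all samples carries no evidence either way:
  # emitted as rr = 0, not significant (zero-variance, unequal-mean families
  # are excluded instead, as no finite CI exists for them)
  constant <- st == 0 & sc == 0 & xt == xc & xt > 0
  ok <- xt > 0 & xc > 0 & !(st == 0 & sc == 0)
  excluded <- rownames(fam)[!ok & !constant]
  if (!any(ok | constant)) {
    mf_stop("empty_matrix_error", "no family is evaluable")
  }
  rrres <- data.frame(
    rr = NA_real_, variance = NA_real_, se = NA_real_, ci_low = NA_real_,
    ci_high = NA_real_, significant = NA
  )[rep(1L, length(xt)), ]
  if (any(ok)) {
    rrres[ok, ] <- response_ratio(xt[ok], xc[ok], st[ok], sc[ok],
                                  length(t_s), length(c_s),
                                  z = z)[, names(rrres)]
  }
  rrres[constant, ] <- data.frame(rr = 0, variance = 0, se = 0, ci_low = 0,
                                  ci_high = 0, significant = FALSE)
  ok <- ok | constant
  tres <- do.call(rbind, lapply(which(ok), function(i) {
    gene_t_test(mt[i, ], mc[i, ])
  }))
  cat_v <- attr(fam, "category")
  out <- data.frame(
    family_id = rownames(fam)[ok],
    category = if (is.null(cat_v)) NA_character_ else
      unname(cat_v[rownames(fam)[ok]]),
    rrres[ok, c("rr", "variance", "se", "ci_low", "ci_high", "significant")],
    t_statistic = tres$statistic, t_df = tres$df, t_p = tres$p,
    stringsAsFactors = FALSE
  )
  if (bh) out$t_p_bh <- stats::p.adjust(out$t_p, method = "BH")
  rownames(out) <- NULL
  attr(out, "excluded_families") <- excluded
  out
}

#' Category-level shift summary
#'
#' Counts the families in one functional category whose response ratio is
#' significantly increased (CI entirely above 0) or decreased (CI entirely
#' below 0), and the corresponding fractions over families evaluated in that
#' category.
#'
#' @param results output of [contrast_all_families()]
#' @param category category label to summarize
#' @return one-row data.frame: category, n_families, n_sig_increased,
#'   n_sig_decreased, fraction_increased, fraction_decreased
#' @export
category_shift_summary <- function(results, category) {
  sub <- results[!is.na(results$category) & results$category == category, ]
  if (nrow(sub) == 0L) {
    mf_stop("empty_category_error", "no evaluated family in category '",
            category, "'")
  }
  inc <- sum(sub$significant & sub$rr > 0)
  dec <- sum(sub$significant & sub$rr < 0)
  data.frame(
    category = category, n_families = nrow(sub),
    n_sig_increased = inc, n_sig_decreased = dec,
    fraction_increased = inc / nrow(sub),
    fraction_decreased = dec / nrow(sub),
    stringsAsFactors = FALSE
  )
}

#' Shift summaries for every category present in a result table
#' @param results output of [contrast_all_families()]
#' @return data.frame, one row per category
#' @export
category_shift_all <- function(results) {
  cats <- sort(unique(results$category[!is.na(results$category)]))
  do.call(rbind, lapply(cats, function(k) category_shift_summary(results, k)))
}
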