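# GeoChip-style preprocessing: SNR spot filtering, relative-abundance
# normalization with natural-log transform, and gene-family aggregation.

#' Signal-to-noise ratio of an array spot
#'
#' SNR = (signal mean - background mean) / background standard deviation.
#' May be negative when the spot is dimmer than its local background.
#'
#' @param signal_mean spot foreground mean (arbitrary fluorescence units)
#' @param background_mean local background mean (same units)
#' @param background_sd local background standard deviation (> 0)
#' @return numeric SNR, vectorized over inputs
#' @export
compute_snr <- function(signal_mean, background_mean, background_sd) {
  if (any(background_sd <= 0)) {
    mf_stop("domain_error", "background_sd must be > 0")
  }
  (signal_mean - background_mean) / background_sd
}

#' Filter spots by signal-to-noise ratio
#'
#' Keeps exactly the spots with SNR >= `snr_min` (the conventional quality
#' cut removes spots with SNR below 2.0). Filtering is per spot, i.e. per
#' (probe, sample) cell: a probe that fails in one sample may survive in
#' another; cells with no surviving spot are absent and treated as 0
#' downstream. Probes with no surviving spot in any sample are dropped.
#'
#' @param spots spot_table
#' @param snr_min minimum SNR retained (default 2.0)
#' @return numeric matrix (probes x samples) of signal means with class
#'   `signal_matrix`; attribute `filter_report` holds n_total, n_kept,
#'   n_removed, n_probes_dropped
#' @export
filter_spots <- function(spots, snr_min = 2.0) {
  spots <- spot_table(as.data.frame(spots))
  snr <- compute_snr(spots$signal_mean, spots$background_mean,
                     spots$background_sd)
  keep <- snr >= snr_min
  kept <- spots[keep, , drop = FALSE]
  if (nrow(kept) == 0L) {
    mf_stop("empty_matrix_error",
            "no spots pass SNR >= ", snr_min, " (", nrow(spots),
            " spots examined, max SNR = ", signif(max(snr), 4), ")")
  }
  probes <- sort(unique(kept$probe_id))
  samples <- sort(unique(spots$sample_id))  # keep all samples, even if empty
  m <- matrix(0, length(probes), length(samples),
              dimnames = list(probes, samples))
  m[cbind(match(kept$probe_id, probes), match(kept$sample_id, samples))] <-
    kept$signal_mean
  report <- list(
    n_total = nrow(spots), n_kept = nrow(kept),
    n_removed = nrow(spots) - nrow(kept),
    n_probes_dropped = length(setdiff(unique(spots$probe_id), probes))
  )
  structure(m, filter_report = report, log_scale = FALSE,
            class = c("signal_matrix", class(m)))
}

#' Normalize a signal matrix by relative abundance, then ln(x + 1)
#'
#' Stage 1 rescales every sample column so that all column sums equal the
#' mean of the original column sums; this preserves the grand total while
#' making samples comparable. Stage 2 applies the natural-log transform
#' ln(x + 1), which is defined at zero (absent spots).
#'
#' @param m signal_matrix (probes x samples), raw scale
#' @return signal_matrix on the log scale (attribute `log_scale = TRUE`)
#' @export
normalize_signals <- function(m) {
  if (isTRUE(attr(m, "log_scale"))) {
    mf_stop("domain_error", "matrix is already log-scale")
  }
  cs <- colSums(m)
  if (any(cs <= 0)) {
    mf_stop("degenerate_sample_error", "zero-sum sample column(s): ",
            paste(colnames(m)[cs <= 0], collapse = ", "))
  }
  target <- mean(cs)
  scaled <- sweep(m, 2L, target / cs, `*`)
  out <- log1p(scaled)
  structure(out, filter_report = attr(m, "filter_report"), log_scale = TRUE,
            class = c("signal_matrix", "matrix", "array"))
}

#' Aggregate probe-level signals into gene families
#'
#' The family value per sample is the sum (or mean) of that family's probe
#' values in that sample; functional category labels are attached per family.
#' Unannotated probes are dropped with a count in the `dropped_probes`
#' attribute.
#'
#' @param m signal_matrix (probes x samples)
#' @param ann probe_annotation
#' @param agg "sum" (default) or "mean"
#' @return numeric matrix (families x samples) of class
#'   `family_abundance_matrix`, with attributes `category` and `subprocess`
#'   (named character vectors per family) and `log_scale` carried over
#' @export
aggregate_families <- function(m, ann, agg = c("sum", "mean")) {
  agg <- match.arg(agg)
  ann <- probe_annotation(as.data.frame(ann))
  idx <- match(rownames(m), ann$probe_id)
  annotated <- !is.na(idx)
  if (!any(annotated)) {
    mf_stop("empty_matrix_error", "no probes of the matrix are annotated")
  }
  n_dropped <- sum(!annotated)
  sub <- m[annotated, , drop = FALSE]
  fam <- ann$gene_family[idx[annotated]]
  f <- factor(fam, levels = sort(unique(fam)))
  agg_fun <- if (agg == "sum") colSums else colMeans
  out <- do.call(rbind, lapply(levels(f), function(g) {
    agg_fun(sub[f == g, , drop = FALSE])
  }))
  dimnames(out) <- list(levels(f), colnames(m))
  fam_map <- unique(as.data.frame(ann)[c("gene_family", "subprocess",
                                         "category")])
  cat_v <- stats::setNames(fam_map$category, fam_map$gene_family)[levels(f)]
  sub_v <- stats::setNames(fam_map$subprocess, fam_map$gene_family)[levels(f)]
  structure(out, category = cat_v, subprocess = sub_v,
            dropped_probes = n_dropped,
            log_scale = isTRUE(attr(m, "log_scale")),
            class = c("family_abundance_matrix", "matrix", "array"))
}

#' Write a family abundance matrix with category labels to TSV
#' @param x family_abundance_matrix
#' @param path output path
#' @export
write_family_matrix <- function(x, path) {
  df <- data.frame(
    family_id = rownames(x),
    category = attr(x, "category")[rownames(x)],
    subprocess = attr(x, "subprocess")[rownames(x)],
    as.data.frame(unclass(x)), check.names = FALSE,
    stringsAsFactors = FALSE
  )
  write_tsv_dialect(df, path)
}

#' Read a family abundance matrix written by [write_family_matrix()]
#' @param path TSV with family_id, category, subprocess and sample columns
#' @param log_scale whether the stored values are ln(x + 1) transformed
#'   (default TRUE, as written by the preprocessing chain)
#' @return family_abundance_matrix
#' @export
read_family_matrix <- function(path, log_scale = TRUE) {
  df <- read_tsv_dialect(path)
  required <- c("family_id", "category", "subprocess")
  if (!all(required %in% names(df))) {
    mf_stop("format_error", "family matrix needs columns: ",
            paste(required, collapse = ", "))
  }
  m <- as.matrix(df[, setdiff(names(df), required), drop = FALSE])
  rownames(m) <- df$family_id
  storage.mode(m) <- "double"
  structure(m,
            category = stats::setNames(df$category, df$family_id),
            subprocess = stats::setNames(df$subprocess, df$family_id),
            log_scale = log_scale,
            class = c("family_abundance_matrix", "matrix", "array"))
}

#' Run the full preprocessing chain: filter, normalize, aggregate
#'
#' @param spots spot_table
#' @param ann probe_annotation
#' @param snr_min SNR threshold (default 2.0)
#' @param agg family aggregation, "sum" or "mean"
#' @return family_abundance_matrix on the log scale
#' @export
preprocess_geochip <- function(spots, ann, snr_min = 2.0, agg = "sum") {
  m <- filter_spots(spots, snr_min = snr_min)
  m <- normalize_signals(m)
  aggregate_families(m, ann, agg = agg)
}
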