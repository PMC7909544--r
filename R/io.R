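# Typed in-memory data model and TSV readers/writers for all pipeline inputs.
#
# Containers are plain base-R structures (data.frame / matrix) validated on
# construction; matrices are always oriented rows = features, columns =
# samples.

STATUS_VOCAB <- c("degraded_severe", "degraded_light", "restored", "natural")

#' Construct and validate a spot table
#'
#' A spot table holds probe-level array scan records: one row per
#' (probe, sample) with the signal mean, local background mean and background
#' standard deviation in the same arbitrary fluorescence units. These are the
#' quantities that enter the signal-to-noise ratio used for spot quality
#' control.
#'
#' @param df data.frame with columns probe_id, sample_id, signal_mean,
#'   background_mean, background_sd
#' @return validated data.frame of class `spot_table`
#' @export
spot_table <- function(df) {
  required <- c("probe_id", "sample_id", "signal_mean",
                "background_mean", "background_sd")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0L) {
    mf_stop("format_error", "spot table missing column(s): ",
            paste(missing_cols, collapse = ", "))
  }
  df <- df[required]
  df$probe_id <- as.character(df$probe_id)
  df$sample_id <- as.character(df$sample_id)
  for (col in c("signal_mean", "background_mean", "background_sd")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    if (anyNA(v) && !anyNA(df[[col]])) {
      mf_stop("format_error", "non-numeric value in column ", col)
    }
    if (any(v < 0, na.rm = TRUE)) {
      mf_stop("domain_error", "negative value in column ", col)
    }
    df[[col]] <- v
  }
  key <- paste(df$probe_id, df$sample_id, sep = "\r")
  if (anyDuplicated(key)) {
    mf_stop("duplicate_key_error", "duplicate (probe_id, sample_id) pair: ",
            sub("\r", " / ", key[duplicated(key)][1L]))
  }
  if (nrow(df) == 0L) mf_stop("format_error", "spot table has no rows")
  rownames(df) <- NULL
  class(df) <- c("spot_table", "data.frame")
  df
}

#' Read a probe-level spot table from TSV
#'
#' @param path TSV file with columns probe_id, sample_id, signal_mean,
#'   background_mean, background_sd
#' @return `spot_table` data.frame, row order preserved
#' @export
read_spot_table <- function(path) {
  spot_table(read_tsv_dialect(path))
}

#' Write a spot table to TSV
#' @param x spot_table
#' @param path output path
#' @export
write_spot_table <- function(x, path) {
  write_tsv_dialect(as.data.frame(x), path)
}

#' Construct and validate a probe annotation table
#'
#' Maps each array probe to its gene family (e.g. nifH, amoA, mcrA), the
#' biogeochemical subprocess (e.g. denitrification, methanogenesis) and the
#' top-level functional category (e.g. "Nitrogen cycling"). A gene family
#' must map to exactly one (subprocess, category) pair.
#'
#' @param df data.frame with columns probe_id, gene_family, subprocess,
#'   category
#' @return validated data.frame of class `probe_annotation`
#' @export
probe_annotation <- function(df) {
  required <- c("probe_id", "gene_family", "subprocess", "category")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0L) {
    mf_stop("format_error", "annotation missing column(s): ",
            paste(missing_cols, collapse = ", "))
  }
  df <- df[required]
  for (col in required) df[[col]] <- as.character(df[[col]])
  if (anyDuplicated(df$probe_id)) {
    mf_stop("duplicate_key_error", "duplicate probe_id: ",
            df$probe_id[duplicated(df$probe_id)][1L])
  }
  fam_map <- unique(df[c("gene_family", "subprocess", "category")])
  if (anyDuplicated(fam_map$gene_family)) {
    bad <- fam_map$gene_family[duplicated(fam_map$gene_family)][1L]
    mf_stop("consistency_error", "gene family '", bad,
            "' maps to more than one (subprocess, category)")
  }
  rownames(df) <- NULL
  class(df) <- c("probe_annotation", "data.frame")
  df
}

#' Read a probe annotation table from TSV
#' @param path TSV with columns probe_id, gene_family, subprocess, category
#' @return `probe_annotation` data.frame
#' @export
read_probe_annotation <- function(path) {
  probe_annotation(read_tsv_dialect(path))
}

#' Write a probe annotation table to TSV
#' @param x probe_annotation
#' @param path output path
#' @export
write_probe_annotation <- function(x, path) {
  write_tsv_dialect(as.data.frame(x), path)
}

#' Intersect a spot table with an annotation
#'
#' Joining never invents probes: the output probe set is the intersection of
#' the two inputs' probe sets.
#'
#' @param spots spot_table
#' @param ann probe_annotation
#' @return list with `spots` restricted to annotated probes, and counts
#'   `n_kept`, `n_dropped_spots`, `n_unannotated_probes`
#' @export
annotate_spots <- function(spots, ann) {
  keep <- spots$probe_id %in% ann$probe_id
  list(
    spots = spot_table(as.data.frame(spots)[keep, , drop = FALSE]),
    n_kept = sum(keep),
    n_dropped_spots = sum(!keep),
    n_unannotated_probes = length(setdiff(unique(spots$probe_id),
                                          ann$probe_id))
  )
}

#' Construct and validate a feature count table
#'
#' @param counts non-negative integer matrix, rows = features (e.g. OTUs),
#'   columns = samples, with dimnames
#' @return validated integer matrix of class `count_table`
#' @export
count_table <- function(counts) {
  if (!is.matrix(counts)) counts <- as.matrix(counts)
  if (nrow(counts) == 0L || ncol(counts) == 0L) {
    mf_stop("dimension_error", "count table must have >= 1 feature and sample")
  }
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    mf_stop("format_error", "count table needs feature and sample names")
  }
  if (anyDuplicated(rownames(counts))) {
    mf_stop("duplicate_key_error", "duplicate feature id: ",
            rownames(counts)[duplicated(rownames(counts))][1L])
  }
  if (anyDuplicated(colnames(counts))) {
    mf_stop("duplicate_key_error", "duplicate sample id")
  }
  storage <- suppressWarnings(as.numeric(counts))
  if (anyNA(storage)) mf_stop("format_error", "non-numeric cell in count table")
  if (any(storage < 0)) mf_stop("domain_error", "negative count")
  if (any(storage != round(storage))) {
    mf_stop("format_error", "non-integer cell in count table")
  }
  m <- matrix(as.integer(round(storage)), nrow(counts), ncol(counts),
              dimnames = dimnames(counts))
  class(m) <- c("count_table", class(m))
  m
}

#' Read a feature (OTU) count table from TSV
#'
#' First column holds feature ids, remaining columns one per sample. The
#' conventional commented "#OTU ID" header line is accepted.
#'
#' @param path TSV file path
#' @return integer `count_table` matrix (features x samples)
#' @export
read_count_table <- function(path) {
  df <- read_tsv_dialect(path)
  if (ncol(df) < 2L) mf_stop("format_error", "count table needs >= 2 columns")
  ids <- as.character(df[[1L]])
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- ids
  count_table(m)
}

#' Write a count table to TSV
#' @param x count_table
#' @param path output path
#' @param feature_col header for the feature-id column
#' @export
write_count_table <- function(x, path, feature_col = "feature_id") {
  df <- data.frame(rownames(x), as.data.frame(unclass(x)),
                   check.names = FALSE, stringsAsFactors = FALSE)
  names(df)[1L] <- feature_col
  write_tsv_dialect(df, path)
}

#' Construct and validate a sample metadata table
#'
#' One record per sample: site, marsh type (Phragmites or Carex), degradation
#' status from the closed vocabulary (degraded_severe, degraded_light,
#' restored, natural), plus numeric soil/vegetation covariates.
#'
#' @param df data.frame with at least sample_id, site, marsh, status
#' @return validated data.frame of class `sample_metadata`
#' @export
sample_metadata <- function(df) {
  required <- c("sample_id", "site", "marsh", "status")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0L) {
    mf_stop("format_error", "metadata missing column(s): ",
            paste(missing_cols, collapse = ", "))
  }
  for (col in required) df[[col]] <- as.character(df[[col]])
  if (anyDuplicated(df$sample_id)) {
    mf_stop("duplicate_key_error", "duplicate sample_id")
  }
  bad_status <- setdiff(unique(df$status), STATUS_VOCAB)
  if (length(bad_status) > 0L) {
    mf_stop("vocabulary_error", "unknown status value(s): ",
            paste(bad_status, collapse = ", "),
            " (allowed: ", paste(STATUS_VOCAB, collapse = ", "), ")")
  }
  cov_cols <- setdiff(names(df), required)
  for (col in cov_cols) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    if (any(!is.finite(v) & !is.na(df[[col]]))) {
      mf_stop("format_error", "non-finite covariate in column ", col)
    }
    df[[col]] <- v
  }
  rownames(df) <- NULL
  class(df) <- c("sample_metadata", "data.frame")
  df
}

#' Read sample metadata from TSV
#' @param path TSV with sample_id, site, marsh, status and covariate columns
#' @return `sample_metadata` data.frame
#' @export
read_metadata <- function(path) {
  sample_metadata(read_tsv_dialect(path))
}

#' Write sample metadata to TSV
#' @param x sample_metadata
#' @param path output path
#' @export
write_metadata <- function(x, path) {
  write_tsv_dialect(as.data.frame(x), path)
}

#' Reconcile sample ids between a data table and metadata
#'
#' Samples present in the data but absent from metadata are an error (the
#' contrasts depend on complete group assignment); metadata-only samples are
#' reported.
#'
#' @param data_samples character vector of sample ids in the data
#' @param meta sample_metadata
#' @return list(common, data_only, metadata_only); errors if data_only
#'   non-empty
#' @export
reconcile_samples <- function(data_samples, meta) {
  data_only <- setdiff(data_samples, meta$sample_id)
  meta_only <- setdiff(meta$sample_id, data_samples)
  if (length(data_only) > 0L) {
    mf_stop("reconciliation_error",
            "samples in data but missing from metadata: ",
            paste(data_only, collapse = ", "))
  }
  list(common = intersect(data_samples, meta$sample_id),
       data_only = data_only, metadata_only = meta_only)
}

#' Construct a two-group contrast design
#'
#' @param treatment_group label of the treatment group
#' @param control_group label of the control group
#' @param assignment named character vector: sample_id -> group label
#' @return list of class `contrast_design`
#' @export
contrast_design <- function(treatment_group, control_group, assignment) {
  stopifnot(is.character(assignment), !is.null(names(assignment)))
  if (treatment_group == control_group) {
    mf_stop("design_error", "treatment and control groups must differ")
  }
  t_samples <- names(assignment)[assignment == treatment_group]
  c_samples <- names(assignment)[assignment == control_group]
  if (length(t_samples) < 2L || length(c_samples) < 2L) {
    mf_stop("design_error", "each contrast group needs >= 2 samples")
  }
  structure(
    list(treatment_group = treatment_group, control_group = control_group,
         treatment_samples = t_samples, control_samples = c_samples,
         assignment = assignment),
    class = "contrast_design"
  )
}
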