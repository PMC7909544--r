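# Pipeline orchestration: one config drives simulate/read -> preprocess ->
# response ratios -> diversity -> ordination -> constrained analysis, with a
# run manifest and deterministic TSV outputs.

#' Default pipeline configuration over the synthetic study
#'
#' @param seed master seed; all stage seeds are derived from it with
#'   [stage_seed()]
#' @param out_dir output directory
#' @return named list understood by [run_full_pipeline()]
#' @export
default_pipeline_config <- function(seed = 1L, out_dir = tempfile("marshfun_")) {
  list(
    seed = seed, out_dir = out_dir,
    simulate = TRUE,
    # geochip simulation: severe degradation raises N-cycling and
    # C-degradation gene abundance in the contrast
    geochip = list(
      nt = 3L, nc = 3L, probes_per_family = 10L, noise_sd = 0.2,
      effect_spec = list(
        "Nitrogen cycling" = list(fraction_affected = 0.95, theta = 0.5),
        "Carbon degradation" = list(fraction_affected = 0.95, theta = 0.4)
      )
    ),
    community = list(replicates = 3L, species_pool = 600L, depth = 10000L),
    thresholds = list(snr_min = 2.0, z = 1.96, alpha = 0.05, vif_max = 20,
                      n_perm = 999L, shannon_base = 2, rarefy_depth = NULL),
    env_groups = list(
      soil = c("pH", "TN", "TC", "TP", "TS", "WC"),
      vegetation = c("coverage", "height", "density")
    )
  )
}

#' Run the full analysis pipeline from one configuration
#'
#' Stages: (1) simulate or read inputs; (2) GeoChip preprocessing (SNR
#' filter, normalization, family aggregation); (3) response ratios, t-tests
#' and category-shift summary for the treatment/control contrast; (4)
#' rarefaction and alpha diversity; (5) Bray-Curtis, NMDS, ANOSIM, PERMANOVA
#' and a community-vs-environment Mantel test; (6) VIF screening, CCA with a
#' permutation test, forward selection and two-group variation partitioning.
#' Inputs are never mutated; every randomized stage draws its own seed from
#' the master seed via [stage_seed()].
#'
#' @param config list as produced by [default_pipeline_config()]
#' @return invisible list of all stage results (also written as TSV by
#'   [write_report()] when `config$out_dir` is set)
#' @export
run_full_pipeline <- function(config) {
  seed <- config$seed %||% 1L
  th <- config$thresholds

  if (isTRUE(config$simulate)) {
    gc_sim <- do.call(simulate_geochip_experiment, c(
      config$geochip, list(seed = stage_seed(seed, "geochip"))
    ))
    spots <- gc_sim$spots
    ann <- gc_sim$annotation
    design <- gc_sim$truth$design
    cm_sim <- do.call(simulate_community_tables, c(
      config$community, list(seed = stage_seed(seed, "community"))
    ))
    counts <- cm_sim$counts
    meta <- cm_sim$metadata
    env_sim <- simulate_environment(cm_sim$truth$axis,
                                    seed = stage_seed(seed, "environment"))
    constraints <- env_sim$constraints
    truth <- list(geochip = gc_sim$truth, community = cm_sim$truth,
                  environment = env_sim$truth)
  } else {
    spots <- read_spot_table(config$paths$spots)
    ann <- read_probe_annotation(config$paths$annotation)
    counts <- read_count_table(config$paths$counts)
    meta <- read_metadata(config$paths$metadata)
    env_df <- read_tsv_dialect(config$paths$constraints)
    rn <- as.character(env_df[[1L]])
    constraints <- constraint_table(
      `rownames<-`(as.matrix(env_df[, -1L, drop = FALSE]), rn)
    )
    design <- do.call(contrast_design, config$contrast)
    truth <- NULL
  }
  reconcile_samples(colnames(counts), meta)

  # --- preprocessing + response ratios -------------------------------------
  fam <- preprocess_geochip(spots, ann, snr_min = th$snr_min)
  rr_table <- contrast_all_families(fam, design, z = th$z)
  shifts <- category_shift_all(rr_table)

  # --- diversity ------------------------------------------------------------
  rare <- rarefy(counts, depth = th$rarefy_depth,
                 seed = stage_seed(seed, "rarefaction"))
  diversity <- alpha_diversity_table(rare, shannon_base = th$shannon_base)

  # --- community ordination and tests --------------------------------------
  bc <- bray_curtis(rare)
  ord <- nmds(bc, k = 2L, n_starts = 10L,
              seed = stage_seed(seed, "nmds"))
  groups <- meta$status[match(colnames(rare), meta$sample_id)]
  ano <- anosim(bc, groups, n_perm = th$n_perm,
                seed = stage_seed(seed, "anosim"))
  pmv <- permanova(bc, groups, n_perm = th$n_perm,
                   seed = stage_seed(seed, "permanova"))
  env_d <- as.matrix(stats::dist(constraints[colnames(rare), , drop = FALSE]))
  mant <- mantel(bc, env_d, n_perm = th$n_perm,
                 seed = stage_seed(seed, "mantel"))

  # --- constrained ordination ----------------------------------------------
  # VIF screen, then forward-select, then fit/test the CCA on the selected
  # variables (the full screened set is the fallback if nothing is selected)
  screened <- vif_screen(constraints[colnames(counts), , drop = FALSE],
                         vif_max = th$vif_max)
  fsel <- suppressWarnings(
    forward_select(counts, screened$x, alpha = th$alpha, n_perm = th$n_perm,
                   vif_max = th$vif_max, seed = stage_seed(seed, "forward"))
  )
  x_model <- fsel$x %||% screened$x
  cca_fit <- cca(counts, x_model)
  cca_test <- cca_permutation_test(counts, x_model, n_perm = th$n_perm,
                                   seed = stage_seed(seed, "cca"))
  g1 <- intersect(config$env_groups[[1L]], colnames(screened$x))
  g2 <- intersect(config$env_groups[[2L]], colnames(screened$x))
  vpa <- if (length(g1) > 0L && length(g2) > 0L) {
    variation_partition(counts,
                        screened$x[, g1, drop = FALSE],
                        screened$x[, g2, drop = FALSE])
  } else NULL

  manifest <- data.frame(
    key = c("package_version", "master_seed", "snr_min", "z", "alpha",
            "vif_max", "n_perm", "shannon_base"),
    value = c(as.character(utils::packageVersion("marshfun")), seed,
              th$snr_min, th$z, th$alpha, th$vif_max, th$n_perm,
              th$shannon_base),
    stringsAsFactors = FALSE
  )

  results <- list(
    family_matrix = fam, rr_table = rr_table, category_shifts = shifts,
    diversity = diversity, nmds = ord,
    anosim = ano, permanova = pmv, mantel = mant,
    vif = screened, cca = cca_fit, cca_test = cca_test,
    forward_selection = fsel, vpa = vpa,
    metadata = meta, manifest = manifest, truth = truth
  )
  if (!is.null(config$out_dir)) {
    write_report(results, config$out_dir, force = isTRUE(config$force))
  }
  invisible(results)
}

#' Write the pipeline report bundle
#'
#' Emits one TSV per result surface with stable column order, plus a
#' plain-text summary; refuses to overwrite an existing non-empty directory
#' unless `force = TRUE`. Optional stages absent from `results` are marked
#' "not run" in the summary.
#'
#' @param results list from [run_full_pipeline()]
#' @param out_dir output directory
#' @param force overwrite an existing non-empty directory
#' @return invisible character vector of written paths
#' @export
write_report <- function(results, out_dir, force = FALSE) {
  if (dir.exists(out_dir) && length(dir(out_dir)) > 0L && !force) {
    mf_stop("io_error", "output directory exists and is non-empty: ",
            out_dir, " (use force = TRUE)")
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0L)
  put <- function(df, name) {
    p <- file.path(out_dir, name)
    write_tsv_dialect(df, p)
    paths <<- c(paths, p)
  }
  if (!is.null(results$family_matrix)) {
    p <- file.path(out_dir, "family_abundance.tsv")
    write_family_matrix(results$family_matrix, p)
    paths <- c(paths, p)
  }
  if (!is.null(results$rr_table)) put(results$rr_table, "response_ratios.tsv")
  if (!is.null(results$category_shifts)) {
    put(results$category_shifts, "category_shifts.tsv")
  }
  if (!is.null(results$diversity)) put(results$diversity, "alpha_diversity.tsv")
  if (!is.null(results$nmds)) {
    put(data.frame(sample_id = rownames(results$nmds$coordinates),
                   results$nmds$coordinates, stress = results$nmds$stress,
                   stringsAsFactors = FALSE),
        "nmds_coordinates.tsv")
  }
  perm_rows <- do.call(rbind, Filter(Negate(is.null), list(
    results$anosim, results$permanova, results$mantel, results$cca_test
  )))
  if (!is.null(perm_rows)) put(perm_rows, "permutation_tests.tsv")
  if (!is.null(results$cca)) {
    put(data.frame(axis = seq_along(results$cca$eigenvalues),
                   eigenvalue = results$cca$eigenvalues,
                   total_inertia = results$cca$total_inertia,
                   constrained_inertia = results$cca$constrained_inertia,
                   proportion_explained = results$cca$proportion_explained),
        "cca_eigenvalues.tsv")
    put(data.frame(sample_id = rownames(results$cca$site_scores),
                   results$cca$site_scores, stringsAsFactors = FALSE),
        "cca_site_scores.tsv")
  }
  if (!is.null(results$vpa)) put(results$vpa, "variation_partition.tsv")
  if (!is.null(results$forward_selection$trace)) {
    put(results$forward_selection$trace, "forward_selection.tsv")
  }
  if (!is.null(results$manifest)) put(results$manifest, "manifest.tsv")

  summary_lines <- c(
    "marshfun pipeline report",
    paste0("stages run: ",
           paste(names(Filter(Negate(is.null), results)), collapse = ", ")),
    paste0("stages not run: ",
           paste(names(Filter(is.null, results)), collapse = ", ") %||% "none")
  )
  writeLines(summary_lines, file.path(out_dir, "summary.txt"))
  invisible(c(paths, file.path(out_dir, "summary.txt")))
}
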