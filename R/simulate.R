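# Synthetic-data generators emulating a multi-site, two-marsh wetland
# degradation study: lognormal probe signals with additive background and
# family-level planted effects, OTU tables whose richness and evenness track
# degradation status, and environmental covariates coupled to the community
# gradient. Every generator is a pure function of its parameters and seed,
# and records its ground truth.

#' Default study sites
#'
#' Six sites across the two marsh types, each carrying one degradation
#' status, three replicate samples per site — the layout of a typical
#' paired-marsh degradation survey.
#'
#' @return data.frame(site, marsh, status)
#' @export
default_study_sites <- function() {
  data.frame(
    site = c("P-SD", "P-LD", "P-NA", "C-SD", "C-RE", "C-NA"),
    marsh = rep(c("Phragmites", "Carex"), each = 3L),
    status = c("degraded_severe", "degraded_light", "natural",
               "degraded_severe", "restored", "natural"),
    stringsAsFactors = FALSE
  )
}

# numeric severity of each status: the latent degradation axis
status_severity <- c(degraded_severe = 1.0, degraded_light = 0.5,
                     restored = 0.25, natural = 0.0)

#' Default gene-family annotation vocabulary
#'
#' Marker families for nitrogen cycling, methane metabolism, carbon
#' degradation and carbon fixation, with their subprocesses.
#'
#' @return data.frame(gene_family, subprocess, category)
#' @export
default_family_catalog <- function() {
  rbind(
    data.frame(gene_family = c("nifH"), subprocess = "N fixation",
               category = "Nitrogen cycling"),
    data.frame(gene_family = c("amoA", "hao"), subprocess = "nitrification",
               category = "Nitrogen cycling"),
    data.frame(gene_family = c("narG", "nirK", "nirS", "norB", "nosZ"),
               subprocess = "denitrification", category = "Nitrogen cycling"),
    data.frame(gene_family = c("hzo", "hzsA"), subprocess = "anammox",
               category = "Nitrogen cycling"),
    data.frame(gene_family = c("napA", "nrfA"), subprocess = "DNRA",
               category = "Nitrogen cycling"),
    data.frame(gene_family = c("nasA", "narB", "nirA", "nirB"),
               subprocess = "assimilatory N reduction",
               category = "Nitrogen cycling"),
    data.frame(gene_family = c("ureC"), subprocess = "ammonification",
               category = "Nitrogen cycling"),
    data.frame(gene_family = c("mcrA", "hdrB"), subprocess = "methanogenesis",
               category = "Methane metabolism"),
    data.frame(gene_family = c("pmoA", "mmoX"),
               subprocess = "methane oxidation",
               category = "Methane metabolism"),
    data.frame(gene_family = c("amyX"), subprocess = "starch degradation",
               category = "Carbon degradation"),
    data.frame(gene_family = c("rgh"), subprocess = "pectin degradation",
               category = "Carbon degradation"),
    data.frame(gene_family = c("mnp"), subprocess = "lignin degradation",
               category = "Carbon degradation"),
    data.frame(gene_family = c("PCC"), subprocess = "C fixation",
               category = "Carbon fixation")
  )
}

#' Simulate a GeoChip-style probe experiment with planted effects
#'
#' Probe foreground signals are lognormal around a family baseline plus a
#' probe offset, with a multiplicative treatment effect exp(theta) applied to
#' all probes of an affected family; the recorded signal mean is foreground
#' plus the spot's background draw, so the signal-to-noise ratio is
#' (foreground) / background_sd. A configurable fraction of spots is given a
#' weak foreground so that it fails the SNR < 2 quality cut.
#'
#' @param n_families_per_category named integer vector: category ->
#'   number of families (synthetic family names are generated beyond the
#'   marker vocabulary when a category needs more)
#' @param probes_per_family probes per family (default 10)
#' @param nt,nc treatment and control replicate counts (default 3, the study
#'   design's per-site replication)
#' @param effect_spec named list: category -> list(fraction_affected, theta);
#'   affected families all carry log response ratio theta, the rest 0
#' @param noise_sd lognormal sigma of probe signals (default 0.2)
#' @param baseline_log_signal mean log foreground signal (default log(2000))
#' @param background_mean,background_sd background level and SD (defaults
#'   60, 20 fluorescence units)
#' @param snr_fail_fraction fraction of spots forced below the SNR cut
#'   (default 0.05)
#' @param seed integer seed
#' @return list(spots = spot_table, annotation = probe_annotation,
#'   truth = list(theta by family, design, parameters))
#' @export
simulate_geochip_experiment <- function(
    n_families_per_category = c("Nitrogen cycling" = 20,
                                "Carbon degradation" = 20,
                                "Methane metabolism" = 10,
                                "Carbon fixation" = 10),
    probes_per_family = 10L, nt = 3L, nc = 3L,
    effect_spec = list(), noise_sd = 0.2,
    baseline_log_signal = log(2000), background_mean = 60,
    background_sd = 20, snr_fail_fraction = 0.05, seed = 1L) {
  stopifnot(all(n_families_per_category >= 1), probes_per_family >= 1,
            nt >= 2, nc >= 2)
  if (noise_sd <= 0) mf_stop("domain_error", "noise_sd must be > 0")
  for (spec in effect_spec) {
    if (spec$fraction_affected < 0 || spec$fraction_affected > 1) {
      mf_stop("domain_error", "fraction_affected must lie in [0, 1]")
    }
  }
  set.seed(seed)
  catalog <- default_family_catalog()
  fam_rows <- list()
  for (cat_name in names(n_families_per_category)) {
    n_f <- n_families_per_category[[cat_name]]
    known <- catalog[catalog$category == cat_name, ]
    fams <- known$gene_family
    subs <- known$subprocess
    if (length(fams) < n_f) {
      extra <- paste0(gsub("[^A-Za-z]", "", cat_name), "_fam",
                      seq_len(n_f - length(fams)))
      fams <- c(fams, extra)
      subs <- c(subs, rep("uncharacterized", n_f - length(known$gene_family)))
    }
    fam_rows[[cat_name]] <- data.frame(
      gene_family = fams[seq_len(n_f)], subprocess = subs[seq_len(n_f)],
      category = cat_name, stringsAsFactors = FALSE
    )
  }
  families <- do.call(rbind, fam_rows)
  rownames(families) <- NULL

  # planted effects: exactly round(fraction * n) families per category
  theta <- stats::setNames(numeric(nrow(families)), families$gene_family)
  for (cat_name in names(effect_spec)) {
    spec <- effect_spec[[cat_name]]
    idx <- which(families$category == cat_name)
    n_aff <- round(spec$fraction_affected * length(idx))
    if (n_aff > 0L) theta[idx[seq_len(n_aff)]] <- spec$theta
  }

  samples <- c(paste0("T", seq_len(nt)), paste0("C", seq_len(nc)))
  is_treat <- c(rep(TRUE, nt), rep(FALSE, nc))

  ann <- do.call(rbind, lapply(seq_len(nrow(families)), function(i) {
    data.frame(
      probe_id = paste0(families$gene_family[i], "_p",
                        seq_len(probes_per_family)),
      gene_family = families$gene_family[i],
      subprocess = families$subprocess[i],
      category = families$category[i], stringsAsFactors = FALSE
    )
  }))

  n_probes <- nrow(ann)
  mu_family <- stats::rnorm(nrow(families), baseline_log_signal, 0.3)
  names(mu_family) <- families$gene_family
  probe_offset <- stats::rnorm(n_probes, 0, 0.15)
  # weak hybridization is a probe property (target absent or rare in the
  # community), so dimness persists across samples rather than striking
  # spots at random
  dim_probe <- stats::runif(n_probes) < snr_fail_fraction

  rows <- vector("list", length(samples))
  for (s in seq_along(samples)) {
    mu <- mu_family[ann$gene_family] + probe_offset +
      if (is_treat[s]) theta[ann$gene_family] else 0
    fg <- exp(stats::rnorm(n_probes, mu, noise_sd))
    fg[dim_probe] <- stats::runif(sum(dim_probe), 0, 1.9 * background_sd)
    bg <- pmax(stats::rnorm(n_probes, background_mean, background_sd / 10), 1)
    rows[[s]] <- data.frame(
      probe_id = ann$probe_id, sample_id = samples[s],
      signal_mean = bg + fg, background_mean = bg,
      background_sd = background_sd, stringsAsFactors = FALSE
    )
  }
  spots <- spot_table(do.call(rbind, rows))
  truth <- list(
    theta = theta, families = families,
    design = contrast_design(
      "treatment", "control",
      stats::setNames(ifelse(is_treat, "treatment", "control"), samples)
    ),
    parameters = list(
      probes_per_family = probes_per_family, nt = nt, nc = nc,
      noise_sd = noise_sd, baseline_log_signal = baseline_log_signal,
      background_mean = background_mean, background_sd = background_sd,
      snr_fail_fraction = snr_fail_fraction, seed = seed
    )
  )
  list(spots = spots, annotation = probe_annotation(ann), truth = truth)
}

#' Simulate group samples and response-ratio inputs for calibration studies
#'
#' Draws lognormal abundances for `n_families` independent families with a
#' planted log response ratio `theta` (on the lognormal mean scale) and
#' returns the per-family group summaries that feed [response_ratio()].
#' Used for null calibration (theta = 0) and CI-coverage checks.
#'
#' @param n_families number of independent families
#' @param nt,nc group sizes
#' @param theta true log response ratio (scalar or per-family vector)
#' @param noise_sd lognormal sigma (default 0.2)
#' @param mu_log baseline log mean (default log(50))
#' @param seed integer seed
#' @return data.frame(xt_mean, xc_mean, st, sc, nt, nc, theta)
#' @export
simulate_rr_groups <- function(n_families, nt = 50L, nc = 50L, theta = 0,
                               noise_sd = 0.2, mu_log = log(50), seed = 1L) {
  set.seed(seed)
  theta <- rep_len(theta, n_families)
  xt <- matrix(exp(stats::rnorm(n_families * nt,
                                rep(mu_log + theta, nt), noise_sd)),
               n_families, nt)
  xc <- matrix(exp(stats::rnorm(n_families * nc, mu_log, noise_sd)),
               n_families, nc)
  data.frame(
    xt_mean = rowMeans(xt), xc_mean = rowMeans(xc),
    st = apply(xt, 1L, stats::sd), sc = apply(xc, 1L, stats::sd),
    nt = nt, nc = nc, theta = theta
  )
}

#' Simulate OTU count tables with status-dependent richness and evenness
#'
#' Each site carries a species subset of the pool (richness set by its
#' degradation status) with a lognormal species-abundance distribution whose
#' sigma sets evenness (larger sigma = less even, typical of degraded
#' soils); species' log-abundances also shift along the latent degradation
#' axis, so composition tracks the gradient. Each replicate sample is a
#' multinomial draw at its sequencing depth.
#'
#' @param sites data.frame(site, marsh, status); default
#'   [default_study_sites()]
#' @param replicates replicate samples per site (default 3)
#' @param species_pool total number of species (default 600)
#' @param richness_by_status named vector of per-site richness
#' @param evenness_by_status named vector of lognormal sigma per status
#'   (higher = less even)
#' @param gradient_sd SD of species' responses to the degradation axis
#'   (default 1)
#' @param depth mean sequencing depth per sample (default 10000)
#' @param seed integer seed
#' @return list(counts = count_table, metadata = sample_metadata,
#'   truth = list(axis by sample, parameters))
#' @export
simulate_community_tables <- function(
    sites = default_study_sites(), replicates = 3L, species_pool = 600L,
    richness_by_status = c(degraded_severe = 200, degraded_light = 300,
                           restored = 350, natural = 400),
    evenness_by_status = c(degraded_severe = 1.6, degraded_light = 1.3,
                           restored = 1.2, natural = 1.0),
    gradient_sd = 1.0, depth = 10000L, seed = 1L) {
  if (any(richness_by_status > species_pool)) {
    mf_stop("domain_error", "richness_by_status exceeds species pool")
  }
  set.seed(seed)
  species <- paste0("OTU", seq_len(species_pool))
  # per-species response to the degradation axis (shared across sites)
  slope <- stats::rnorm(species_pool, 0, gradient_sd)
  base <- stats::rnorm(species_pool, 0, 1)

  sample_ids <- character(0L)
  meta_rows <- list()
  cols <- list()
  axis_by_sample <- numeric(0L)
  for (i in seq_len(nrow(sites))) {
    st <- sites$status[i]
    rich <- richness_by_status[[st]]
    sigma <- evenness_by_status[[st]]
    axis_site <- status_severity[[st]]
    present <- sample.int(species_pool, rich)
    # site-level lognormal abundance profile, shifted along the axis
    log_ab <- base[present] * sigma + slope[present] * axis_site
    p_site <- exp(log_ab)
    p_site <- p_site / sum(p_site)
    for (r in seq_len(replicates)) {
      sid <- paste0(sites$site[i], "-", r)
      sample_ids <- c(sample_ids, sid)
      axis_by_sample[sid] <- axis_site
      n_reads <- max(1L, round(depth * stats::runif(1, 0.85, 1.15)))
      draw <- stats::rmultinom(1L, n_reads, p_site)[, 1L]
      col <- integer(species_pool)
      col[present] <- draw
      cols[[sid]] <- col
      meta_rows[[sid]] <- data.frame(
        sample_id = sid, site = sites$site[i], marsh = sites$marsh[i],
        status = st, stringsAsFactors = FALSE
      )
    }
  }
  counts <- do.call(cbind, cols)
  dimnames(counts) <- list(species, sample_ids)
  counts <- counts[rowSums(counts) > 0, , drop = FALSE]
  list(
    counts = count_table(counts),
    metadata = sample_metadata(do.call(rbind, meta_rows)),
    truth = list(
      axis = axis_by_sample,
      parameters = list(replicates = replicates,
                        species_pool = species_pool,
                        richness_by_status = richness_by_status,
                        evenness_by_status = evenness_by_status,
                        gradient_sd = gradient_sd, depth = depth, seed = seed)
    )
  )
}

#' Simulate environmental covariates coupled to the community gradient
#'
#' Each covariate is loading x (latent degradation axis of the sample) +
#' Gaussian noise; variables with loading 0 are pure noise. Default
#' variables follow the soil (pH, TN, TC, TP, TS, WC) and vegetation
#' (coverage, height, density) panels of a wetland survey.
#'
#' @param axis named numeric vector: sample_id -> latent axis value (the
#'   `truth$axis` of [simulate_community_tables()])
#' @param coupling named numeric vector: variable -> axis loading
#' @param noise_sd Gaussian noise SD (default 0.3)
#' @param seed integer seed
#' @return list(constraints = constraint_table (standardized),
#'   raw = unstandardized matrix, truth = list(coupling, noise_sd, seed))
#' @export
simulate_environment <- function(
    axis,
    coupling = c(pH = -0.8, TN = 1.0, TC = 0.9, TP = 0.7, TS = 0,
                 WC = 0.8, coverage = -0.9, height = -0.6, density = -0.7),
    noise_sd = 0.3, seed = 1L) {
  if (is.null(names(axis))) mf_stop("design_error", "axis must be named")
  if (any(!is.finite(coupling))) {
    mf_stop("domain_error", "coupling loadings must be finite")
  }
  set.seed(seed)
  n <- length(axis)
  m <- sapply(names(coupling), function(v) {
    coupling[[v]] * axis + stats::rnorm(n, 0, noise_sd)
  })
  rownames(m) <- names(axis)
  list(
    constraints = constraint_table(m, standardize = TRUE),
    raw = m,
    truth = list(coupling = coupling, noise_sd = noise_sd, seed = seed)
  )
}
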