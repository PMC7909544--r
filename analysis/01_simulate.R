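#!/usr/bin/env Rscript
# Stage 1 — generate the synthetic study.
#
# Emulates the field design: six sites across a Phragmites and a Carex marsh
# (severely degraded, lightly degraded / restored, natural), three replicate
# soil samples per site. Writes the probe-level array table, probe
# annotation, OTU count table, sample metadata and environmental covariates
# as TSV under results/synthetic/.

library(marshfun)

seed <- 20260920L
out <- "results/synthetic"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

# GeoChip contrast: severely degraded (treatment) vs natural (control)
# Phragmites soils, with most nitrogen-cycling and carbon-degradation
# families elevated in the degraded soils.
gc <- simulate_geochip_experiment(
  nt = 3, nc = 3, probes_per_family = 10,
  effect_spec = list(
    "Nitrogen cycling" = list(fraction_affected = 0.95, theta = 0.5),
    "Carbon degradation" = list(fraction_affected = 0.95, theta = 0.4)
  ),
  noise_sd = 0.2, seed = stage_seed(seed, "geochip")
)
write_spot_table(gc$spots, file.path(out, "spots.tsv"))
write_probe_annotation(gc$annotation, file.path(out, "annotation.tsv"))

cm <- simulate_community_tables(seed = stage_seed(seed, "community"))
write_count_table(cm$counts, file.path(out, "otu_counts.tsv"),
                  feature_col = "#OTU ID")
write_metadata(cm$metadata, file.path(out, "metadata.tsv"))

env <- simulate_environment(cm$truth$axis,
                            seed = stage_seed(seed, "environment"))
env_df <- data.frame(sample_id = rownames(env$raw), env$raw,
                     check.names = FALSE)
utils::write.table(env_df, file.path(out, "environment.tsv"), sep = "\t",
                   quote = FALSE, row.names = FALSE)

cat("samples:", ncol(cm$counts),
    "| OTUs:", nrow(cm$counts),
    "| probes:", length(unique(gc$spots$probe_id)),
    "| affected families:", sum(gc$truth$theta != 0), "\n")
cat("written to", out, "\n")
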