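#!/usr/bin/env Rscript
# Stage 2 — GeoChip preprocessing.
#
# Reads the probe-level spot table from stage 1, removes poor-quality spots
# (SNR < 2), normalizes samples to a common total with an ln(x + 1)
# transform, and aggregates probes into gene families. Writes the normalized
# family-by-sample abundance matrix.

library(marshfun)

ind <- "results/synthetic"
out <- "results/geochip"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

spots <- read_spot_table(file.path(ind, "spots.tsv"))
ann <- read_probe_annotation(file.path(ind, "annotation.tsv"))

filtered <- filter_spots(spots, snr_min = 2.0)
rep <- attr(filtered, "filter_report")
cat(sprintf("spots: %d total, %d kept, %d removed (SNR < 2), %d probes dropped\n",
            rep$n_total, rep$n_kept, rep$n_removed, rep$n_probes_dropped))

fam <- aggregate_families(normalize_signals(filtered), ann)
write_family_matrix(fam, file.path(out, "family_abundance.tsv"))
cat("families:", nrow(fam), "x samples:", ncol(fam), "->",
    file.path(out, "family_abundance.tsv"), "\n")
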