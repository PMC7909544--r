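#!/usr/bin/env Rscript
# Stage 4 — community diversity and ordination.
#
# Rarefies the OTU table to even depth, computes alpha diversity (observed
# species, Shannon base 2, Gini-Simpson), Bray-Curtis dissimilarities, an
# NMDS ordination, and tests the separation of degradation statuses with
# ANOSIM and PERMANOVA plus a community-environment Mantel test.

library(marshfun)

seed <- 20260920L
ind <- "results/synthetic"
out <- "results/community"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

counts <- read_count_table(file.path(ind, "otu_counts.tsv"))
meta <- read_metadata(file.path(ind, "metadata.tsv"))
chk <- reconcile_samples(colnames(counts), meta)

rare <- rarefy(counts, seed = stage_seed(seed, "rarefaction"))
cat("rarefied to depth", sum(rare[, 1]), "\n")

div <- alpha_diversity_table(rare, shannon_base = 2)
div$status <- meta$status[match(div$sample_id, meta$sample_id)]
write.table(div, file.path(out, "alpha_diversity.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("\nmean diversity by status:\n")
print(aggregate(cbind(observed_species, shannon, simpson) ~ status, div,
                mean))

bc <- bray_curtis(rare)
ord <- nmds(bc, k = 2, n_starts = 20, seed = stage_seed(seed, "nmds"))
cat("\nNMDS stress:", signif(ord$stress, 4), "\n")
write.table(
  data.frame(sample_id = rownames(ord$coordinates), ord$coordinates,
             stress = ord$stress),
  file.path(out, "nmds.tsv"), sep = "\t", quote = FALSE, row.names = FALSE
)

groups <- meta$status[match(colnames(rare), meta$sample_id)]
tests <- rbind(
  anosim(bc, groups, n_perm = 999, seed = stage_seed(seed, "anosim")),
  permanova(bc, groups, n_perm = 999, seed = stage_seed(seed, "permanova"))
)
env <- read.table(file.path(ind, "environment.tsv"), sep = "\t", header = TRUE,
                  check.names = FALSE)
envm <- constraint_table(`rownames<-`(as.matrix(env[, -1]), env$sample_id))
tests <- rbind(tests,
               mantel(bc, as.matrix(dist(envm[colnames(rare), ])),
                      n_perm = 999, seed = stage_seed(seed, "mantel")))
write.table(tests, file.path(out, "permutation_tests.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
print(tests, row.names = FALSE)
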