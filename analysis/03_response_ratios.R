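#!/usr/bin/env Rscript
# Stage 3 — response-ratio meta-analysis of the degraded vs natural contrast.
#
# Computes per-family response ratios RR = ln(Xt/Xc) with the
# inverse-variance CI significance rule and Welch t-tests, summarizes
# significant shifts per functional category, and pools each category's
# per-family ratios into a weighted RR++.

library(marshfun)

out <- "results/geochip"
fam <- read_family_matrix(file.path(out, "family_abundance.tsv"))

samples <- colnames(fam)
design <- contrast_design(
  "degraded", "natural",
  setNames(ifelse(grepl("^T", samples), "degraded", "natural"), samples)
)

rr <- contrast_all_families(fam, design, z = 1.96)
write.table(rr, file.path(out, "response_ratios.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

shifts <- category_shift_all(rr)
write.table(shifts, file.path(out, "category_shifts.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
print(shifts, row.names = FALSE)

# pooled weighted response ratio per category (RR++)
pooled <- do.call(rbind, lapply(split(rr, rr$category), function(g) {
  g <- g[g$variance > 0, ]
  cbind(category = g$category[1], weighted_rr(g$rr, g$variance))
}))
write.table(pooled, file.path(out, "weighted_rr.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("\npooled RR++ per category:\n")
print(pooled, row.names = FALSE)
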