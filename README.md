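# marshfun

Statistical pipeline for soil-microbiome surveys of degraded wetlands that
pair a functional gene microarray (GeoChip-style probes for nitrogen-,
carbon- and methane-cycling gene families) with amplicon OTU tables and
soil/vegetation covariates. The package is aimed at microbial ecologists
comparing degraded, restored and natural marsh sites who need the full
chain from raw array spots to publishable effect sizes and ordinations,
with every step testable against known ground truth.

## What it computes

**Array preprocessing.** Spots are filtered by signal-to-noise ratio,
SNR = (signal mean − background mean) / background SD, keeping SNR ≥ 2;
samples are rescaled to a common total and transformed by ln(x + 1); probes
are aggregated into gene families (nifH, amoA, nosZ, mcrA, pmoA, ...) with
functional-category labels.

**Response-ratio meta-analysis.** Per family, with treatment/control means
X̄t, X̄c, SDs st, sc and sizes nt, nc on the normalized log scale:

    RR = ln(X̄t / X̄c),   ν = st²/(nt·X̄t²) + sc²/(nc·X̄c²)

with 95% CI RR ± 1.96·√ν; a family is significantly shifted when the CI
excludes 0. Families pool by inverse-variance weights w = 1/ν into
RR++ = Σw·RR / Σw with SE √(1/Σw). Category summaries report the fraction
of families significantly increased/decreased — the "95% of N-cycling genes
increased" style of statement.

**Community statistics** (first-principles implementations, cross-checked
against vegan in the test suite): rarefaction, observed species / Shannon
(base 2) / Gini-Simpson, Bray-Curtis dissimilarity, NMDS minimizing
Kruskal stress-1 (isotonic disparities + Guttman updates, multi-start),
Mantel, ANOSIM and one-way PERMANOVA with permutation p-values
(b + 1)/(n_perm + 1).

**Constrained ordination.** CCA via chi-square standardization, weighted
projection and SVD; iterative VIF screening (VIF ≥ 20 removed); Monte-Carlo
permutation forward selection; two-group variation partitioning into
unique / shared / unexplained fractions.

**Synthetic study.** Generators with recorded ground truth emulate the
design: two marshes, six sites, three replicates, lognormal probe signals
with planted family-level effects, OTU tables whose richness/evenness track
degradation status, covariates coupled to the community gradient.

## Worked example

```r
library(marshfun)

sim <- simulate_geochip_experiment(
  nt = 3, nc = 3,
  effect_spec = list("Nitrogen cycling" =
                       list(fraction_affected = 0.95, theta = 0.5)),
  seed = 7
)
fam <- preprocess_geochip(sim$spots, sim$annotation)   # SNR >= 2, ln(x+1)
rr  <- contrast_all_families(fam, sim$truth$design)
category_shift_summary(rr, "Nitrogen cycling")
```

The stage-by-stage drivers under `analysis/` run the same computations on a
shared synthetic study and write TSVs under `results/`. A run of
`analysis/01...05` prints, among other things:

```
spots: 3600 total, 3426 kept, 174 removed (SNR < 2), 29 probes dropped
mean diversity by status:
           status observed_species  shannon   simpson
1  degraded_light         279.6667 6.488324 0.9607221
2 degraded_severe         180.5000 5.552362 0.9520844
3         natural         395.8333 7.935186 0.9927046
4        restored         341.6667 7.205040 0.9778488
    statistic_name  statistic n_permutations p_value
          anosim_R  0.8589744            999   0.001
 permanova_pseudoF 14.6656664            999   0.001
          mantel_r  0.6807325            999   0.001
forward selection kept: WC, TS, coverage
CCA: 47.75% of inertia explained, p = 0.001
VPA: soil 34.46%, vegetation 17.48%, shared 19.12%, unexplained 28.94%
```

Read: degraded sites lose richness and evenness (observed species 180 vs
396; Shannon 5.6 vs 7.9 bits), community composition separates cleanly by
status (ANOSIM R = 0.86 at the 0.001 permutation floor), the environment
covaries with community distances (Mantel r = 0.68), and the selected
covariates explain 47.8% of the community inertia, split between soil and
vegetation panels with a 19.1% shared fraction.

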