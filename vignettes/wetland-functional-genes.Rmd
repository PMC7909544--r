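---
title: "Functional-gene and community analysis of degraded wetland soils: methods"
author: "marshfun"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Functional-gene and community analysis of degraded wetland soils: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(marshfun)
```

## What this package computes

`marshfun` implements the statistical core of a wetland soil-microbiome
survey that combines a functional gene microarray (GeoChip-style probes for
nitrogen-, carbon- and methane-cycling gene families) with amplicon-based
OTU tables and soil/vegetation covariates, contrasting degraded, restored
and natural marsh sites. The pipeline has four analytic layers:

1. **Array preprocessing** — spot-level quality control, cross-sample
   normalization, gene-family aggregation.
2. **Effect sizes** — the response-ratio meta-analysis per gene family with
   confidence-interval significance calls and per-category shift summaries.
3. **Community statistics** — rarefaction, alpha diversity, Bray–Curtis
   dissimilarity, NMDS, and the Mantel/ANOSIM/PERMANOVA permutation tests.
4. **Constrained ordination** — CCA with VIF screening, permutation forward
   selection, and two-group variation partitioning.

All four layers are exercised end to end on a synthetic study with known
ground truth; the `analysis/` scripts in the source tree are the narrative
drivers.

## Array preprocessing

Each array spot carries a foreground signal mean, a local background mean
and a background standard deviation. Spot quality is the signal-to-noise
ratio

$$\mathrm{SNR} = \frac{\text{signal mean} - \text{background mean}}
{\text{background SD}},$$

and spots with SNR < 2 are discarded (`snr_min = 2`, the conventional cut
for these arrays). Filtering is per spot: a probe rejected in one sample may
be retained in another, and a missing (probe, sample) cell contributes 0
downstream. Probes failing everywhere are dropped.

Normalization is two-stage. Stage 1 rescales every sample column so all
column totals equal the mean of the original totals; this makes samples
comparable while conserving the grand total. Stage 2 applies
$\ln(x + 1)$, which is defined at the zeros produced by filtering (plain
$\ln x$ is not). The scale-then-log order is fixed; scaling on the raw
fluorescence scale is where a "relative abundance" operation is meaningful.
Probe values are then summed into gene families (a mean aggregator is
available via `agg = "mean"`), and each family carries its subprocess and
functional-category label.

A consequence worth knowing: column rescaling is a *relative* operation.
When a large share of the community's functional signal genuinely rises in
one group, rescaling redistributes part of that rise as an apparent decline
of the unaffected families. The synthetic study shows this clearly — with
many nitrogen-cycling and carbon-degradation families elevated, the
untouched methane and carbon-fixation categories come out significantly
*decreased* at the same magnitude as the rescaling factor. Any analysis on
relative array data (including the study design this package emulates)
measures composition shifts, not absolute copy numbers.

## Response-ratio meta-analysis

For a family with treatment mean $\bar X_t$ (over $n_t$ samples, SD $s_t$)
and control mean $\bar X_c$ (over $n_c$, SD $s_c$), both on the normalized
log scale:

$$RR = \ln(\bar X_t / \bar X_c), \qquad
\nu = \frac{s_t^2}{n_t \bar X_t^2} + \frac{s_c^2}{n_c \bar X_c^2},$$

with $se = \sqrt\nu$ and the 95% interval $RR \pm 1.96\,se$. A family is
*significantly shifted* when the interval excludes 0 — the CI rule is the
significance criterion; the Welch unpaired *t*-test is reported alongside
but does not gate significance, and no multiple-testing correction is
applied by default (a Benjamini–Hochberg flag exists). Families are pooled
with inverse-variance weights $w = 1/\nu$:

$$RR_{++} = \frac{\sum w\,RR}{\sum w}, \qquad
S_{RR_{++}} = \sqrt{\frac{1}{\sum w}},$$

the standard fixed-effect meta-analytic combination. The category shift
summary counts families whose CI lies entirely above (increased) or below
(decreased) zero, as fractions of the families evaluated in that category.

Edge conventions: a family constant across all samples is reported as
$RR = 0$, not significant; a family with zero variance but unequal means
has no finite CI and is excluded and listed; families with a non-positive
mean in either group (impossible after $\ln(x+1)$ aggregation, possible for
user-supplied matrices) are excluded and listed. $z = 1.96$ is the normal
95% quantile; the paper-style CI uses no small-sample *t* correction, and
`z` is configurable.

Calibration, verified by the test suite at $n_t = n_c = 50$ with lognormal
signals (CV ≈ 0.2): the CI rule flags ≈ 5% of null families, and the 95%
interval covers a planted log-ratio ≈ 95% of the time. The delta-method
variance is a large-sample approximation: at $n = 3$ (the field design's
replication) intervals are anti-conservative, which is why the planted-
effect tests at $n = 3$ check only sign recovery.

## Community statistics

* **Rarefaction** subsamples each sample without replacement to a common
  depth (default: the minimum sample total), with a per-run seed.
* **Alpha diversity**: observed species, Shannon entropy and the
  Gini–Simpson index. The Shannon default is **base 2**: with roughly
  3,500 observed OTUs the field's reported Shannon values near 9–10 exceed
  $\ln(3500) \approx 8.2$, so bits are the only consistent unit; the base
  is recorded in the output and configurable.
* **Bray–Curtis**: $d = 1 - 2\sum_i \min(x_i, y_i) / (\sum x_i + \sum y_i)$.
* **NMDS** minimizes Kruskal stress-1 with isotonic (pool-adjacent-
  violators) disparities and Guttman-transform updates; one deterministic
  classical-scaling start plus random starts (default 20); ties in the
  dissimilarities are handled by the primary approach (tied dissimilarities
  may untie freely in the fit). The run never returns a configuration worse
  than its classical-scaling start; non-convergence in all starts yields a
  warning and the best configuration found.
* **Mantel** (Pearson correlation of distance triangles), **ANOSIM**
  (rank-based $R$) and one-way **PERMANOVA** (pseudo-$F$ from squared
  distances) all use simple label/row permutations with the unbiased
  estimator $p = (b + 1)/(n_{perm} + 1)$ — permutation p-values are never
  exactly 0, and with 999 permutations the floor is 0.001. Sidedness is
  one-sided ("greater"), the conventional choice for these statistics.

## Constrained ordination

CCA chi-square-standardizes the response table
($q_{ij} = (p_{ij} - r_i c_j)/\sqrt{r_i c_j}$ with row/column masses $r$,
$c$), projects it onto the weighted, centered constraint space by least
squares, and eigen-decomposes the projection via SVD. Total inertia is
$\sum q_{ij}^2$; the eigenvalue sum equals the constrained inertia.
Constraints are standardized (mean 0, SD 1) first — soil units (g/kg) and
percentages otherwise dominate the projection. Collinear constraint sets
fall back to a pseudo-inverse with a rank-deficiency warning. Log-scale
family matrices are valid responses as-is: $\ln(x+1)$ output is
non-negative, which is all the chi-square standardization requires.

VIF screening iteratively removes the variable with the largest
$\mathrm{VIF}_j = 1/(1 - R_j^2)$ while any VIF ≥ 20. Forward selection is
greedy on added constrained inertia; a candidate is kept only if its
conditional permutation test (candidate rows permuted, selected variables
fixed) gives $p < 0.05$ and the growing set's max VIF stays below 20. The
final CCA and its permutation test are fitted on the selected set — the
screening/selection/test order follows standard constrained-ordination
practice, and testing a near-saturated model (many covariates on few
samples) is uninformative because permuted models explain almost as much.

Variation partitioning between two variable groups reports raw
(non-adjusted) fractions: unique$_1 = t - b$, unique$_2 = t - a$,
shared $= a + b - t$, unexplained $= 1 - t$, where $a$, $b$, $t$ are the
proportions explained by group 1, group 2 and their union. The four
fractions sum to 1 by construction; the shared fraction can be negative
(a known property of the partition) and is reported as computed, not
clamped. Adjusted-$R^2$ partitioning is deliberately out of scope for the
default output because the emulated study reports raw percentages.

## The synthetic study

The generators reproduce the study's *design*, not its data: six sites
across a *Phragmites* and a *Carex* marsh carrying severely degraded,
lightly degraded, restored and natural statuses, three replicate samples
per site.

* **Array signals** are lognormal around a family baseline
  ($e^{\mu} \approx 2000$ fluorescence units, probe offsets of SD 0.15,
  replicate noise SD 0.2) plus an additive Gaussian background
  (mean 60, SD 20). Treatment effects are injected at the family level —
  all 10 probes of an affected family shift by the same $\theta$ — matching
  how such arrays report family-level responses. About 5% of probes are
  *dim*: their foreground sits below the SNR cut. Dimness is a probe
  property (the probe's target is absent or rare in these soils), so a dim
  probe fails in every sample rather than at random — per-spot random
  dropout would inject a large artificial within-group variance that real
  arrays do not show.
* **OTU tables** draw each sample multinomially from a site profile with a
  lognormal species-abundance distribution; degraded statuses get lower
  richness (200 vs 400 of a 600-species pool) and lower evenness
  (lognormal σ 1.6 vs 1.0), and species' log-abundances shift along a
  latent degradation axis so that composition tracks the gradient.
* **Environmental covariates** are loading × (latent axis) + Gaussian noise
  with the survey's variable panel (pH, TN, TC, TP, TS, WC, vegetation
  coverage/height/density); TS is uncoupled by default and serves as the
  built-in negative control.

What passing tests do **not** show about real data: the generators have no
spatial autocorrelation, no array batch or dye effects, no sequencing-depth
biases beyond multinomial sampling, no phylogenetic structure, and
independent families — so the calibration results are statements about the
method under its own assumptions, not field-accuracy guarantees.

## Numerical choices and problem sizes

* Permutation defaults: 999 permutations (the floor $p$ is then 0.001);
  calibration tests in the suite use 199 permutations over 500 replicate
  null simulations, which bounds the discreteness of the p-value grid at
  0.005 while keeping the suite quick.
* Calibration studies use 10,000 independent families at
  $n_t = n_c = 50$; planted-effect recovery is checked both at $n = 50$
  (fraction recovered) and at the field replication $n = 3$ (sign only).
* NMDS: convergence tolerance $10^{-6}$ on stress change, 300 iterations
  per start; stage-1 normalization equality of column sums holds to
  $10^{-9}$ relative; CCA eigenvalue/inertia identities to $10^{-9}$.
* Every randomized stage takes an explicit seed. The pipeline derives
  stage seeds from one master seed by hashing the stage name
  (`stage_seed()`), so adding a stage never shifts the streams of existing
  ones, and two runs with one master seed write byte-identical reports.

## A worked run

```{r, eval = FALSE}
cfg <- default_pipeline_config(seed = 1, out_dir = "run1")
res <- run_full_pipeline(cfg)
res$category_shifts
res$anosim
res$vpa
```

The same computations, stage by stage and with intermediate TSVs, are in
`analysis/01_simulate.R` through `analysis/05_constrained_ordination.R`.

## Known limitations

* Fixed-effect pooling only; no between-comparison heterogeneity ($\tau^2$).
* One-way PERMANOVA; no stratified or multi-factor designs.
* No UniFrac or other phylogenetic distances.
* The CI significance rule is uncorrected for multiplicity by design
  (matching the emulated study's per-gene rule); use the `bh` flag when a
  corrected decision is wanted.
* Relative normalization makes all array conclusions compositional (see
  above).
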