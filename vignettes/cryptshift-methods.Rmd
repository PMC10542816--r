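---
title: "cryptshift: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{cryptshift: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`cryptshift` is a single-cell UMI analysis pipeline for intestinal aging
studies, organized around exact statistics for cell-type abundance shifts
and validated against a ground-truthed synthetic data generator. This
vignette is the package's own account of its models: what each stage
assumes, which tunable parameters matter, how the generator emulates real
data, and where the open design choices were settled.

## The synthetic generator

Every downstream claim the test suite makes is relative to data from
`simulate_counts()`, so its generative model is the right place to start.

**Cell identities.** Each condition contributes `n_cells_per_condition`
cells whose types are drawn independently from that condition's composition
vector. Planted abundance shifts are encoded directly in the two
composition columns: a shifted type's per-condition proportions are chosen
so that its cross-product odds ratio equals the target (3 for the
ILC2-like and 5 for the cytotoxic-T-like type in the `immune9` preset, at a
5% baseline for ILC2), and the displaced mass is absorbed by a designated
type (the naive-T-like type, which therefore carries a true depletion,
OR ≈ 0.19). All other types have *identical* proportions in both columns,
hence true OR exactly 1 — this matters because the false-positive checks
count flags among types whose null is exactly true. Since the composition
columns must each sum to one, "two enriched types, everything else OR 1"
is only satisfiable with such an absorber; the depleted naive-T-like type
is part of the design, not a nuisance.

**Counts.** Per cell, a total depth is drawn log-normal (per-condition
`meanlog`/`sdlog`), and counts are allocated multinomially over genes with
weights `mu_g * G_g`, where `mu_g` is the type- and condition-specific mean
(baseline, times `2^lfc` for the type's markers, times any gene-set or
latent-axis factor) and `G_g` is a mean-1 Gamma variable with variance
`alpha_g`. At fixed depth this produces per-gene negative-binomial counts
with the `var = mu + alpha * mu^2` parameterization the sseq-style marker
test assumes; `alpha = 0` degenerates to Poisson. The depth layer
reproduces the per-cell heterogeneity that the downsampling stage must
correct.

**Mitochondrial fraction.** A per-cell Beta-jittered fraction
(mean `mito_fraction`, concentration `mito_concentration`; defaults 0.04
and 50) of the depth is routed to the `mt-` genes. The jitter is what makes
the mitochondrial QC cutoff testable: with these defaults roughly 5–10% of
cells exceed the 8% immune-preset cutoff.

**Latent axis.** In the `crypt10` preset, the Lgr5-expressing types (stem,
transit-amplifying, secretory precursor) carry a latent coordinate
`z ~ N(0, 1)` (shifted by +1 SD in the old condition), and 60 axis genes
have their means multiplied by `2^(loading * z)` with fixed signed loadings
in ±[0.4, 1]. This makes the first principal component of the axis genes
track the coordinate (|r| ≈ 0.95 in the tests), emulating a secretory
differentiation gradient, and gives the density-shift test a planted 1-SD
signal.

**Gene-set shifts.** `geneset_shifts` multiplies a set's gene means by
`2^lfc` in one condition (the `crypt10` preset upshifts an
antigen-presentation-like 40-gene set by 0.75 log2 units in old cells).
The shift is specified on the log2-mean scale because a count generator
cannot target the post-hoc Z-scale exactly; the scaled-unit additive-shift
recovery claims are therefore exercised directly on Z-matrices in the
tests, where that unit is well defined.

**Hashtags.** True tags are uniform over `n_tags`; singlets put
`1 - background_fraction` of a log-normal read total on their tag, doublets
split the signal evenly over two tags, and low-signal cells receive fewer
than 10 total reads. A `background_fraction >= 0.5` is rejected as
unidentifiable. The hashtag read-count law is a convention, not an
estimate — real hashing depth varies by protocol — so the demultiplexing
accuracy results should be read as "at 200-read scale with 2% background",
not as universal rates.

**Preset sizes.** `immune9` defaults to 4,500 cells per condition (the
scale of the lamina-propria datasets this design emulates); `crypt10` to
1,500 and `organoid7` to 2,000 per condition, chosen once as realistic
study sizes that keep a full pipeline run in tens of seconds. The unequal
post-filter condition totals of a real experiment cannot be encoded in a
single per-condition count; sampling noise supplies the imbalance instead.

**What the generator does not emulate:** ambient RNA, batch effects
(integration/CCA correction is out of scope), read-level artifacts
(FASTQs, PCR duplicates), doublets in the *expression* matrix (doublets
exist only in the hashtag layer), or gene–gene correlation beyond the
type/axis structure. Passing tests therefore demonstrate correctness of
the statistics under the stated model, not robustness to those real-data
phenomena.

## Demultiplexing, depth, QC, normalization

`classify_hashtags()` discards cells with fewer than `min_reads = 10`
hashtag reads (`low_signal`), then counts tags whose read fraction is at
least `presence_fraction = 0.2`: one present tag is `single` (and only
singles proceed downstream), two `double`, three `triple`, four or more
`multiple`. The category names and the 10-read floor are field conventions
for hashed experiments; the fraction rule is this package's explicit,
configurable criterion for ratio-based tag classification —
0.2 cleanly separates a 2% background from a 50/50 doublet split.


`downsample_to_common_depth()` equalizes per-sample median cell depth by
thinning each cell's UMIs *without replacement* — a multivariate
hypergeometric draw of `round(total * target/median_s)` UMIs, implemented
by sampling UMI indices directly. Without-replacement semantics guarantee
counts never increase and give the exact hypergeometric marginal the tests
verify; binomial thinning would be close but violates both properties. The
default target is the minimum per-sample median, and a requested target
above it is an error rather than silently upsampling.

QC boundary conventions are recorded in `qc_thresholds` and pinned by
tests: the detected-gene window (default 200–1500) is *inclusive* on both
ends, while the UMI cutoff (< 5000) and the mitochondrial percentage
cutoff (< 8 for immune-type data, < 20 for organoid-type data) are
*strict*. The mitochondrial criterion is interpreted as a percentage of
per-cell counts — the only unit under which both 8 and 20 are plausible QC
values; the raw-count reading would discard essentially every cell.

`normalize_log()` supports the two normalization conventions the presets
use: `scale_to_median` (each cell scaled to the median per-cell total,
then log10 — the crypt convention) and `scale_to_target` (scale to a fixed
total, default 10,000, then natural log — the Seurat-style convention used
for immune and organoid presets). Pseudocount 1 keeps zeros at zero so the
sparse representation of the log matrix stays exact; a zero pseudocount
with zeros present is an error, not an NaN factory.

## Variable genes, reduction, clustering

`select_hvg_mvp()` computes dispersion = variance/mean per gene on the
*pre-log* depth-scaled values. Dispersion on that scale has the
depth-interpretable "excess over Poisson" meaning; computing it on log
values would conflate mean and variance again. The choice is recorded in
the selection's metadata so it is auditable. Genes are binned into 20
equal-frequency mean bins (sizes differing by at most one, by rank
partition), dispersion is Z-scaled within bins, and selection takes genes
with mean in [0.0125, 2] and Z > 0.9 — under an i.i.d. null this admits
about `P(Z > 0.9) ≈ 18%` of genes, which the tests confirm.

`select_hvg_vst()` fits a loess (span 0.3, degree 2) of log10 variance on
log10 mean, standardizes each gene by its observed mean and the fitted SD,
clips at `sqrt(n_cells)`, and ranks genes by the variance of the clipped
standardized values. The local fit is the conventional
form of a mean–variance trend model; span 0.3 follows standard practice. The
clip bound prevents a handful of outlier cells from dominating a gene's
ranking.

PCA is `stats::prcomp` with centering and unit scaling (zero-variance
genes dropped with a warning), keeping the top 20 components by default.
All assertions about component directions compare up to sign, since the
sign of an eigenvector is arbitrary.

K-means runs Lloyd's algorithm from `n_init = 10` random starts (centers
sampled from the cells) and keeps the lowest within-cluster sum of
squares; the explicit start loop makes the argmin-over-starts contract
directly testable. `subcluster()` re-partitions one cluster and appends
new labels after the existing ones, leaving every other cell's label
untouched — after a split, label ids are therefore not contiguous, which
the cluster container tolerates by design.

`snn_cluster()` builds a k-nearest-neighbor graph (Euclidean, k = 20
including the cell itself), weights edges by the Jaccard overlap of
neighbor sets, prunes below 1/15, and partitions by weighted Louvain
modularity optimization. These defaults (k, Jaccard, 1/15, Louvain) are
fixed package choices within the named algorithm family. A caveat worth
stating: modularity optimization on a large sparse blob can split it into
several communities even when it is one "true" cluster; exact community
counts are only guaranteed when neighborhoods span most of a cluster,
which is how the tests construct their two-blob cases.

Annotation scores each cluster against reference marker sets by the
cluster mean of gene-wise Z-scaled expression and takes the argmax,
breaking ties lexicographically and flagging them; the full score table is
emitted for the manual review that real annotation ultimately is.

`density_shift_1d()` compares a marker-positive cell population's position
along one embedding axis between conditions: Gaussian kernel densities
(Silverman bandwidth) on a shared grid for display, and a two-sample
Kolmogorov–Smirnov test for inference. KS was chosen because the scientific
claim is a *distributional* shift (loss of a low-PC1 subpopulation, gain of
a high-PC1 one), not merely a mean shift.

## Marker testing

`sseq_exact_test()` contrasts one cluster against all other cells, per
gene, under a negative binomial with pooled mean and a common dispersion:
size factors are per-cell totals over their median; dispersions are
method-of-moments estimates shrunk toward a high quantile (99.5%) of the
per-gene estimates, with a shrinkage weight formed from the spread of
those estimates around their mean relative to their spread around the
target. The exact two-sided p conditions on the total count of the two
groups and sums the probabilities of all splits no more likely than the
observed one. The shrinkage constants are implementation choices validated
through simulation: on a 1,000-gene NB null (200 vs 200 cells) the
p < 0.05 fraction lands in [0.03, 0.07], and planted 4-fold markers are
recovered with mean log2 fold-change within 2 ± 0.3 at 500 cells/group.
Fold-changes use size-factor-normalized group sums with pseudocount 1,
which keeps zero-expressing groups finite while leaving well-expressed
genes essentially unbiased; note that large planted spikes slightly
inflate size factors and hence bias fold-changes a few percent low — a
property shared by any total-count normalization.

Rank tests (`wilcoxon_rank_sum`, `wilcoxon_signed_rank`) wrap the stock
implementations with explicit mode control: exact enumeration for small
tie-free samples (n ≤ 16 combined / n ≤ 20), normal approximation with tie
and continuity corrections otherwise; the tests verify the exact modes
against independent brute-force enumeration of all assignments. Zero
paired differences are dropped and counted (the classical convention).
Multiplicity uses Benjamini–Hochberg, the field default for marker
screens; markers are selected by `lfc >= 2` and adjusted `p < 0.05`, read
literally (≥ and <).

## Gene-set scoring

`zscale()` centers and scales each gene across *all* units jointly —
scaling within groups would erase the very differences being tested, so
the scaling population is recorded and asserted. Two unit conventions
reconcile the paired and unpaired test variants: for bulk-style data the
unit is the *gene* (a gene's score in a group is its mean Z across that
group's samples; groups are compared by a signed-rank test paired by gene,
the only unit shared across groups), while for single-cell data the unit
is the *cell* (a cell's score is its mean Z over the set; groups of cells
are compared unpaired). Boxplot summaries use type-7 (linear
interpolation) quartiles with whiskers to the most extreme points within
1.5 IQR. `foldchange_correlation()` reports per-set R² between two
contrasts' per-gene effects (least squares of one on the other), skipping
sets with fewer than three shared genes, and compares category-level R²
distributions by rank-sum.

## Composition statistics

`abundance_shift_test()` is described in the README; numerically, tails
and point probabilities are computed in log space, the two-sided p is the
point-probability sum (capped at 1 against rounding), the sample OR takes
a Haldane 0.5 correction only when a zero cell exists (and flags it), and
the exact conditional CI inverts the noncentral hypergeometric CDF by
root-finding on the log-odds in [−50, 50]. Degenerate observations at the
support's edge give 0 or infinite CI limits rather than root-finding
failures. Exact conditional CIs are conservative; the suite checks
coverage ≥ 94% at nominal 95% over 2,000 null tables rather than asserting
exact nominal coverage. Both one-sided tails are reported alongside the
two-sided p, since composition shifts are sometimes quoted one-sided; no
multiplicity correction is applied across cell types by default
(`composition_report(adjust = TRUE)` opts in to BH).

The urn convention deserves one note: with `m` and `n` the condition
totals, `k` the type total and `q` the type's count in the first
condition, the test draws `m` cells from a population of `m + n`
containing `k` type-C cells. This is the only coherent
sampling-without-replacement reading of a 2×2 composition table, and it is
verified against literal subset enumeration for every urn with N ≤ 12.

## Problem sizes and determinism

Every stochastic function takes an explicit seed and restores the caller's
RNG state, so pipeline runs are bit-reproducible from their config alone
(`run_report.json` records every parameter and seed). The test suite and
the acceptance script size their simulations to be decisive yet quick:
100-seed recovery studies for composition shifts (9,000 cells each),
2,000-table CI coverage, 1,000-replicate calibration for the marker and
gene-set tests, 10,000-replicate thinning for the downsampling law, and a
single full crypt-preset pipeline run (~3,000 cells, ~2,500 after QC) for
cluster recovery; the whole suite finishes in about a minute on one CPU.

## Known limitations

- The generator's independence assumptions (genes conditionally
  independent given type, depth and axis) make clustering easier than on
  real data; the ARI ≈ 0.99 recovery should not be read as a field
  benchmark.
- Exact conditional CIs and two-sided exact p-values are conservative for
  small counts; for very rare types the reported intervals can be wide.
- Louvain community counts depend on graph density (see above); SNN
  clustering is provided for parity with graph-based practice, but the
  presets' pipelines default to k-means, whose objective-level contracts
  are exactly testable.
- Hashtag doublets are simulated in the hashtag layer only; expression
  profiles of doublets (and ambient RNA) are out of scope, so demux
  accuracy here bounds only the classifier's behavior, not droplet-level
  artifacts.
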