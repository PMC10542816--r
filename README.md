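# cryptshift

Single-cell RNA-seq analysis pipeline for studies of intestinal aging, built
around exact statistics for differential cell-type abundance and validated
end-to-end on ground-truthed synthetic data.

## The problem

Aging reshapes the cellular composition of the intestine: stem cells are
depleted, secretory lineages expand, and lamina-propria immune populations
such as ILC2s and cytotoxic T cells become enriched. Detecting these shifts
from pooled, cell-hashed 10x experiments requires a chain of steps — hashtag
demultiplexing, depth equalization, QC, normalization, variable-gene
selection, clustering and annotation, marker testing, gene-set scoring — and
finally a statistic for "did this cell type's relative abundance change?".
`cryptshift` implements that chain for analysts working with
crypt/immune/organoid-style UMI data, with every stage testable against
simulated truth.

## The core statistic

For a cell type *C*, with `m` cells sequenced in the treatment condition and
`n` in the control, `k` cells of type *C* in total of which `q` fall in the
treatment condition, the 2×2 table

|        | treatment | control     |
|--------|-----------|-------------|
| type C | q         | k − q       |
| rest   | m − q     | n − (k − q) |

is summarized by the cross-product odds ratio
`OR = q·(n − k + q) / ((k − q)·(m − q))`. Under the null of no composition
shift, `q` conditioned on the margins is hypergeometric (sampling without
replacement: `k` type-C cells among `m + n`, `m` drawn). The package
reports:

- the exact two-sided p-value (sum of hypergeometric point probabilities no
  larger than the observed one), plus both one-sided tails;
- an exact conditional confidence interval for the OR, by inversion of the
  noncentral hypergeometric distribution (conservative by construction).

Around it sit the rest of the pipeline's statistics: an sseq-style
negative-binomial exact test for cluster markers (method-of-moments
dispersions shrunk toward a high quantile, exact test on group sums
conditional on their total), binned-dispersion ("mvp") and
standardized-variance ("vst") variable-gene selection, gene-set mean-Z
scoring with paired/unpaired Wilcoxon tests, hypergeometric set-overlap
tests, and a Kolmogorov–Smirnov comparison of marker-positive cells along a
principal-component axis.

## Worked example

Simulate the lamina-propria immune preset (9 cell types, young/old, with a
planted odds ratio of 3 for the ILC2-like type and 5 for the
cytotoxic-T-like type), then test each type's abundance shift:

```r
library(cryptshift)

spec <- make_preset("immune9")
cells <- simulate_cell_types(spec, seed = 1)
tab <- tabulate_composition(cells$cell_type, cells$condition,
                            conditions = c("old", "young"))
res <- composition_report(tab)
res[res$cell_type %in% c("ILC2", "CytotoxicT", "BCell"),
    c("cell_type", "q", "k", "odds_ratio", "ci_low", "ci_high", "p_value")]
```

```
   cell_type   q    k odds_ratio   ci_low   ci_high      p_value
1      BCell 844 1797  0.8592203 0.773621 0.9542181 4.393374e-03
2 CytotoxicT 609  754  4.7008481 3.894058 5.7024686 4.456512e-74
4       ILC2 618  859  2.8133486 2.404303 3.2991444 1.047074e-42
```

The two planted shifts are recovered near their true values (OR 2.81 with CI
[2.40, 3.30] against a true 3; OR 4.70 with CI [3.89, 5.70] against a true
5) at vanishing p-values, while B cells — simulated with no shift — sit near
OR 1 (their mildly small p is ordinary seed-level sampling noise at
9,000 cells). The full expression-level pipeline is one call:

```r
cfg <- pipeline_config(preset = "crypt10", seed = 7, out_dir = "out")
res <- run_pipeline(cfg)   # demux -> downsample -> QC -> ... -> composition
```

which writes `demux.tsv`, `qc_report.json`, `embedding.tsv`,
`clusters.tsv`, `markers.tsv`, `enrichment.tsv`, `composition.tsv` and a
`run_report.json` recording every parameter and seed. A thin command-line
wrapper is installed at `inst/exec/cryptshift`
(`cryptshift run --preset immune9 --seed 1 --out DIR`).

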