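# orthograft

Human ortholog conversion and xenograft harmonization for
high-dimensional expression data — an offline, scriptable toolkit.

## What problem this solves

Preclinical single-cell, single-nuclei and spatial transcriptomics is
generated in mouse, rat and xenograft models, while the
pharmacotranscriptomic databases used for drug repurposing (and most
human pathway resources) are keyed to human gene symbols. Using them
requires converting a non-human count matrix into the human ortholog
namespace. Because ortholog relationships have cardinality — a source
gene can map to zero, one or several human genes (`unmapped`, `one2one`,
`one2many`), and several source genes can share one human target
(`many2many` and many-to-one collisions) — the conversion is a lossy
aggregation, not a renaming. orthograft performs it under explicit,
reproducible policies and quantifies what happened, for the researcher
who needs to trust the converted matrix downstream.

It is intended for bioinformaticians and computational biologists who
want the conversion step in a script or pipeline rather than a GUI:
every operation is an R function over tabular (tibble) inputs and sparse
count matrices, and a command-line interface wraps the common workflows.

## The core operations

Given a features × observations count matrix $X$ and an ortholog table,
`convert_matrix()` builds the converted matrix $Y$ whose entry for human
gene $h$ in observation $j$ aggregates $X_{sj}$ over the retained source
genes $s$ mapping to $h$ — summing collisions, expanding one-to-many
fan-outs, and dropping unmapped rows under the default policy (each
decision point is configurable, and the aggregation is exact sparse
incidence-matrix arithmetic). For dual-species PDX matrices,
`convert_pdx()` partitions features by species, converts only the
non-human block, and merges it with the native human counts into a
separate "humanized" matrix, never touching the original.

Conversion quality is reported as:

* gene mapping rate: % of features with ≥ 1 human target;
* pseudobulk count efficiency $= 100 \cdot \mathrm{total}(Y)/\mathrm{total}(X)$,
  and the same ratio per cell/spot/pixel;
* biotype retention (did the protein-coding genes survive?);
* clustering concordance: Rand index
  $RI = (a + b)/\binom{n}{2}$ and its chance-adjusted form (ARI)
  between shared-nearest-neighbor clusterings computed before and after
  conversion with identical parameters and seed.

Synthetic generators (negative-binomial grouped counts, ortholog tables
with designed cardinality mixes, PDX mixtures) provide known ground
truth so the whole pipeline is testable offline.

## Worked example

```r
library(orthograft)

# 200 simulated mouse-style genes x 100 cells, 3 groups; ortholog table
# with 120 one2one, 20 one2many, 10 many2many blocks, 40 unmapped genes
x   <- simulate_counts(simulation_design(n_genes = 200, n_cells = 100, seed = 42))
sim <- simulate_ortholog_table(
  table_design(n_one2one = 120, n_one2many = 20, max_fanout = 3,
               n_many2many_blocks = 10, block_size = 2, n_unmapped = 40,
               seed = 42),
  feature_ids(x))
sim$table
#> <ortholog_table> synthetic -> human
#>   many2many: 40, one2many: 51, one2one: 120, unmapped: 40

res <- convert_matrix(x, sim$table, conversion_policy())
res$report
#> <conversion_report>
#>   features: 200 source, 160 mapped (80.00%), 191 output
#>   pseudobulk count efficiency: 104.06%
#>   per-observation efficiency (median): 102.96%
#>   warning: pseudobulk efficiency 104.06% exceeds 100%: one_to_many=expand
#>   replicates counts into multiple targets

concordance_report(x, res, n_top_genes = 150, n_components = 10,
                   k_neighbors = 15, seed = 0)
#> <concordance_report> RI = 0.9228, ARI = 0.8248 (3 clusters pre, 3 post)
```

Reading the numbers: 160 of 200 genes (80%) had a human ortholog; the
converted matrix holds 104.06% of the original counts because the
default policy expands one-to-many genes into every paralog (the report
flags exactly this); and clustering the cells before and after
conversion agrees on 92% of cell pairs (ARI 0.82), i.e. the group
structure survives the loss of the 40 unmapped genes largely intact.
`tidy(res)` gives the per-gene fates, `tidy(res$report)` the metric
table, and `autoplot(res$report)` a per-cell efficiency histogram.

Real data comes in the same way via `read_10x_mtx()` /
`read_dense_csv()` plus `read_ortholog_table()` (BioMart-export TSV or a
generic `source`/`target` TSV). For a PDX matrix:

```r
res <- convert_pdx(x, table, human_prefix = "GRCh38_", nonhuman_prefix = "mm10_")
res$humanized   # merged human-namespace matrix; res$original untouched
```

## Command line

```sh
Rscript inst/cli/orthograft simulate    --output-dir sim --seed 1
Rscript inst/cli/orthograft convert     --input sim/matrix --table sim/ortholog_table.tsv \
    --dialect generic_two_column --output-dir out
Rscript inst/cli/orthograft qc          --pre sim/matrix --post out/converted --output-dir qc
```

Each run writes its reports plus a `run_manifest.yaml`; identical
configs and seeds produce byte-identical report files.

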