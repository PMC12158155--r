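---
title: "Ortholog conversion and its quality metrics: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ortholog conversion and its quality metrics: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(orthograft)
```

## The problem

Preclinical transcriptomics is done in mice, rats and xenograft models,
but the pharmacotranscriptomic resources used for drug repurposing
(LINCS-style signature databases, human pathway collections) live in the
human gene namespace. Applying them to a mouse single-cell, single-nuclei
or spatial count matrix requires *humanization*: re-expressing the matrix
over human ortholog gene symbols. That operation is not a simple renaming.
Ortholog relationships have cardinality — one mouse gene may map to zero,
one, or several human genes, and several mouse genes may share one human
target — so any conversion embeds decisions about aggregation, expansion
and loss. orthograft makes those decisions explicit, applies them to
sparse matrices exactly, and quantifies what the conversion did to the
data.

## Mapping model

An ortholog table is a set of (source gene, human gene) pairs. Each
mapped pair is classified from the table's own degrees: with
$o$ = number of distinct human targets of the source and $i$ = number of
distinct sources of the target, a pair is `one2one` iff $o = i = 1$,
`many2many` iff $o > 1$ and $i > 1$, and `one2many` otherwise. Sources
with no target are kept as `unmapped` rows rather than discarded, so
mapping rates have a well-defined denominator. Homology-type strings
present in a BioMart export are treated as advisory only and always
recomputed: a subsetted export silently invalidates file-level labels,
and the recomputed classification is the one that actually governs
conversion behavior. Classification is idempotent.

Identifier matching is case-sensitive by default. Mouse symbols are
Title-case and human symbols upper-case, so case-folding usually "just
works" — but it can also create false merges between unrelated symbols,
so it is an explicit opt-in (`case_insensitive`). Symbols and Ensembl IDs
are both accepted, but never translated into one another: a matrix must
use the same identifier space as its table.

## Conversion policies

`convert_matrix()` exposes all three decision points rather than
hard-coding one behavior, because no single choice is right for every
analysis:

* **many_to_one** — several sources share one target. `sum` (default)
  adds their rows, matching the semantics of gene-level aggregation of
  counts. `max_total` keeps only the row of the source with the largest
  total count, with ties broken by lexicographically smallest source id
  for reproducibility. `drop_group` removes the target entirely whenever
  two or more sources collide on it.
* **one_to_many** — a source has several targets. `expand` (default)
  replicates its counts into every target; this preserves signal for all
  paralogs at the cost of pseudobulk efficiency above 100%, which the
  report computes and flags rather than hides. `drop` discards such
  sources as ambiguous.
* **unmapped** — `drop` (default) or `retain_tagged`, which keeps the
  rows under an `unmapped:` prefix so no counts are silently lost.

The default policy (sum, expand, drop) is the one that loses no mapped
signal; its inflation is fully disclosed in the report.

Aggregation is implemented as multiplication by a sparse 0/1 incidence
matrix (targets × sources). For integer inputs this is exactly the dense
definition — each output entry is a sum of input entries, with no
intermediate rounding — and the test suite holds the sparse path to
bit-identical agreement with an independent dense reference across all
twelve policy combinations. Output features are sorted lexicographically
so results do not depend on table row order. Observation columns,
per-observation metadata and embeddings pass through untouched: the
dimensional architecture of the input is preserved by construction.

Real-valued (normalized) matrices are converted by the same rules; the
report marks the input as non-integer so that "count efficiency" is
interpreted accordingly. Which layer to convert (raw counts or a
normalized assay) is the user's choice — exactly one matrix per run.

## PDX harmonization

Xenograft data mixes human (graft) and host (e.g. mouse) transcripts in
one matrix. `convert_pdx()` splits features by species, converts only the
non-human block, and merges the result with the native human counts,
summing rows that collide on one human symbol. The harmonized matrix is
returned alongside the untouched original, never overwriting it.

Species assignment uses, in order of reliability: explicit genome
prefixes when both are configured (as in multi-genome CellRanger output;
literal prefixes only, with `_` and `-` separators both accepted — no
regular expressions); otherwise membership among the table's source
genes (non-human) or targets (human); and for features in both or
neither namespaces, a case heuristic (all-uppercase → human, Title-case
→ non-human, anything else ambiguous). Ambiguous features default to
"treat as human, warn" because in a PDX the human graft is the analyte;
`ambiguous = "drop"` is available. Every report records which strategy
decided the partition, since the heuristic is an artifact decision, not
biology.

Two exact invariants follow from the merge-by-summation design and are
enforced by tests under every policy: the harmonized total equals the
human total plus the converted non-human total, and human rows without a
colliding converted symbol are bit-identical between input and output.
A matrix with no non-human features is a fixed point.

## Quality metrics

* **Gene mapping rate**: percent of matrix features with at least one
  target in the table.
* **Pseudobulk count efficiency**: $100 \cdot \mathrm{total}(Y) /
  \mathrm{total}(X)$, the matrix treated as one bulk sample. Values
  above 100% occur only under one-to-many expansion and are asserted as
  such.
* **Per-observation efficiency**: the same ratio per cell/spot/pixel
  column. Zero-count observations are reported as missing, not as 0 or
  100, to avoid skewing summaries; the weighted mean of the defined
  entries (weights = input column totals) equals the pseudobulk value
  exactly, which the tests verify.
* **Biotype retention**: per source biotype, the fraction of features
  whose conversion fate is "kept". Its headline use is confirming that
  protein-coding genes — the ones pharmacotranscriptomic scoring relies
  on — survive at a high rate. Features without annotation pool into
  `"unknown"`.
* **Clustering concordance**: the Rand index and adjusted Rand index
  between cluster labelings of the matrix before and after conversion.
  Both are always reported — the raw index answers "what fraction of
  observation pairs agree", the adjusted index corrects that for chance
  — because the two answer different questions and computing both costs
  nothing. Both are computed from the contingency table, are symmetric,
  and are invariant to label renaming; the raw index is held to exact
  agreement with exhaustive pair enumeration in tests, and the adjusted
  index is cross-checked against an independent implementation and
  against its null calibration (mean ≈ 0 for independent labelings).

## The clustering pipeline

Concordance needs a clustering that is identical in every detail on both
sides. `cluster_observations()` reproduces the conventional single-cell
recipe: library-size normalization to 10,000 counts per observation,
`log1p`, selection of the `n_top_genes` = 2000 most dispersed genes
(variance/mean of normalized values), per-gene z-scoring capped at 10,
PCA to `n_components` = 20, a `k_neighbors` = 20 nearest-neighbor graph
in component space, shared-nearest-neighbor edge weights by Jaccard
similarity of neighbor sets (self included) pruned below 1/15, and
multilevel modularity optimization at `resolution` = 0.8 under a fixed
seed. These defaults mirror common single-cell practice and are all
exposed as parameters.

One numerical choice matters more than it looks: the selected genes
enter PCA ordered by *numeric* criteria only (decreasing dispersion,
then decreasing total count), never by name or input position. A
converted matrix that merely renames genes therefore presents
bit-identical numbers to every downstream step, and clustering
concordance after a bijective 1:1 conversion is exactly 1 — not 1 up to
floating-point luck. Neighbor ties are broken by observation index, and
community detection is seeded, so repeated runs are identical.

## Synthetic data

Because the generator defines the conditions under which every claim is
tested, its model is stated precisely. Counts are negative binomial with
variance $\mu + \mu^2/\theta$ (θ = `nb_dispersion`; this
parameterization is stated explicitly because "dispersion" is ambiguous
across ecosystems). Gene base means are log-normal (meanlog 1, sdlog 1);
a `de_fraction` of genes receives group-specific log2 fold changes drawn
from $N(0, \texttt{lfc\_scale}^2)$; per-cell size factors are uniform on
`depth_range`. Defaults — 400 genes, 150 cells, 3 groups,
`de_fraction` 0.2, `lfc_scale` 1.5, θ = 2, depths in [0.6, 1.6] — are
desk-scale values typical of a down-sampled droplet scRNA-seq
experiment; the clustering-recovery fixtures use a deliberately
well-separated variant (250 genes, 120 cells, `de_fraction` 0.4,
`lfc_scale` 4, θ = 20) so that ground-truth recovery is exact and
failures indicate real defects rather than noise. Table designs place
designed numbers of one2one, one2many (fan-out uniform in
[2, `max_fanout`]), complete-bipartite many2many blocks and unmapped
sources, so mapping rates and cardinality counts have known ground
truth. All generators are bit-reproducible from the seed carried in the
design.

What the generator does *not* emulate: spatial autocorrelation, batch
effects, doublets, ambient RNA, and the long-tailed library-size
distributions of real droplet data. Passing tests therefore demonstrate
algorithmic correctness — exact aggregation, exact metric formulas,
deterministic clustering — not robustness to every artifact of real
tissue data.

## Degenerate inputs and edge cases

A conversion in which no feature maps raises a classed error carrying
mapping rate 0; a policy that removes every feature (e.g. `drop_group`
on a fully colliding table) warns and returns an empty matrix instead,
since the distinction is informative. Duplicate feature ids in input
files are made unique by suffixing with a warning. Zero-count columns
yield missing efficiencies plus a warning naming the observations.
Empty mapping files and dialect violations fail with errors naming the
missing column. Filtering a table can only shrink its mapped pairs;
sources that lose all targets become unmapped rows so denominators are
stable.

## The command line

Each subcommand (`convert`, `pdx-convert`, `qc`, `simulate`,
`fetch-table`) validates its inputs (exit 2), runs the corresponding
package functions (runtime failures exit 1), writes outputs atomically
(temp file + rename, so interrupted runs leave nothing partial), and
drops a `run_manifest.yaml` recording inputs, policy, seeds, package
version and timestamp beside the outputs. Configuration may come from a
YAML file, with explicit flags taking precedence. No command touches the
network: `fetch-table` exists only to print the BioMart export recipe
and refuses to do anything without `--allow-network`. Report TSVs print
percentages to two decimals; all in-memory values are full precision.

## Known limitations

* No translation between symbol and Ensembl ID spaces; mismatched
  namespaces simply look unmapped (by design, but worth checking when a
  mapping rate is unexpectedly low).
* No expression-aware paralog disambiguation: `max_total` uses total
  counts, not correlation structure.
* No read-level xenograft deconvolution; species assignment is
  feature-level, and unprefixed symbols shared by both genomes rest on a
  heuristic that every report flags.
* Seurat `.RDS` containers are not parsed. Export the counts matrix,
  metadata and embeddings to the supported formats (a 10x-style MTX
  triplet or dense CSV plus TSV metadata) and convert those; the
  converted matrix can be re-attached as a new assay in the original
  container.
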