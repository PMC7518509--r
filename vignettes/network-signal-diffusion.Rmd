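---
title: "Tissue-aware signal diffusion on protein interaction networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tissue-aware signal diffusion on protein interaction networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netdiffuse)
```

## The problem and the model

Disease-associated genes identified by individual omics screens
(differential expression, GWAS, methylation, rare/de novo variation,
open chromatin) are noisy and incomplete, and none of the screens says
*where* in the body the association acts. netdiffuse integrates such
pre-thresholded gene lists by propagating their combined signal over a
protein–protein interaction (PPI) network, separately for every
(tissue, cell-type) combination, so that genes embedded in
high-evidence neighborhoods accumulate signal even when they carry no
direct evidence themselves.

The method is a discrete-time Markov smoothing:

1. **Affinity matrix.** For an n-protein network, `A` is symmetric with
   `a_ij = λ` (default 1.5) if proteins i and j interact *and* share a
   subcellular micro-domain, `a_ij = 1` if they interact without a
   shared domain, and `0` otherwise. The amplification encodes that
   co-compartmentalized interactors are more likely to interact
   physically in vivo.
2. **Markov operator.** `M = D⁻¹A` with `D_ii = Σ_j a_ij`. Rows of `M`
   sum to 1; `m_ij` is the one-step random-walk probability from i
   to j.
3. **Signal.** The binary evidence matrix `E` (genes × layers) is
   summed to `S_i = Σ_j e_ij`, so a gene that is both differentially
   expressed and differentially methylated scores 2. Qualitative
   protein-abundance calls per (tissue, cell) column are mapped to
   weights High = 1, Medium = 0.75, Low = 0.5, Not detected = 0.25, and
   `S*_ij = w_ij · S_i` gives the tissue-specific starting matrix.
4. **Diffusion.** `Sᵗ = Mᵗ S*` is iterated; at each step the smoothness
   rate `R = SSE/SST` compares `M^{t+1}S*` with `MᵗS*`
   (`SSE = Σ (difference)²`, `SST = Σ (sum)²`, jointly over all genes
   and columns). The run stops at the first t with `R ≤ 0.05` and
   returns `Sᵗ` — the state *before* the extra comparison step — so the
   signal is never knowingly over-smoothed. Unchecked, the iteration
   would converge to a per-column constant profile and destroy all
   discriminative information.

Post-diffusion, each gene is classified by where its own row maximum
falls: `brain_unique` (strictly inside the flagged target columns),
`brain_and_elsewhere` (tied across compartments), or `non_brain`.
Brain-unique genes with input evidence are the "known" set; those
without are the novel candidates.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `amplification` | 1.5 | edge weight for co-localized interactors; 1 disables the localization adjustment |
| `missing_weight` | 0.25 | abundance weight for unobserved (gene, column) pairs — the "Not detected" floor |
| `r_threshold` | 0.05 | smoothness-rate stopping level |
| `t_max` | 50 | safety cap; real runs stop after a handful of steps |
| `operator` | `"left"` | `M X` (neighbor averaging). `"transpose"` spreads mass instead |

## Design choices where the method statement is open

* **Co-localization predicate.** Proteins may carry several
  micro-domains; we amplify when the two domain sets intersect — any
  shared compartment enables physical contact. Unannotated proteins
  get plain weight 1: absence of evidence is not evidence of absence.
* **One global affinity matrix.** Subcellular localization catalogs are
  not tissue-resolved, so the localization adjustment is applied once;
  tissue specificity enters only through the abundance weights in S*.
* **Operator orientation.** `Sᵗ = Mᵗ S*` is taken literally: with the
  row-stochastic `M` on the left, a node's new signal is the weighted
  *average* of its neighbors' signals. Whether a mass-spreading
  (transpose) convention was intended cannot be settled from the
  method statement alone, so the transpose is available behind
  `operator = "transpose"` but is not the default.
* **Isolated nodes.** `D⁻¹` is undefined at degree 0. Degree-zero nodes
  are excluded from the operator and pass their input signal through
  unchanged; they are listed in the pipeline's `isolates` field.
* **Stopping bookkeeping.** Accepting at `R(t) ≤ 0.05` returns `Sᵗ`,
  not `S^{t+1}`; `R` at an all-zero signal is defined as 0 (an all-zero
  matrix is already maximally smooth) rather than NaN. SSE/SST are
  summed jointly over genes and columns; a per-column variant exists
  behind `per_column = TRUE` but is not the default.
* **Gene alignment.** The working universe is the PPI node set:
  network genes without evidence start at `S_i = 0`; evidence genes
  absent from the network are dropped and logged. This is what makes
  `Mᵗ S*` dimensionally coherent.
* **Ties.** A gene is brain-unique only if its maximum *strictly*
  exceeds every non-brain column, with equality judged after rounding
  to 12 significant digits to absorb float noise. Under the
  all-weights-equal ablation every column of `S*` is identical, every
  gene ties across all columns, and the brain-unique count drops to
  zero — the directional ablation result falls out of the tie rule.

## What the synthetic generator emulates — and what it does not

`synthetic_spec()` / `generate_inputs()` draw every input the loaders
consume: an Erdős–Rényi (exchangeable null) or Barabási–Albert
(hub-heavy) graph, Poisson-many micro-domain assignments per protein,
qualitative abundance levels per (gene, column) with realistic
frequencies (15% High, 30% Medium, 30% Low, 25% Not detected), and
per-layer Bernoulli evidence on a seed-gene set (each seed is forced to
carry at least one hit so that `S_i > 0`). The default world is a
200-node ER graph at p = 0.05 with 10 tissue/cell columns (2 brain),
5 layers, and 20 seed genes at hit probability 0.4.

A planted module concentrates the signal: its nodes are additionally
wired at `p_within`, share one micro-domain, and carry High abundance
in brain columns but only Low / Not detected elsewhere. This is the
ground truth that the leave-one-out recovery and ablation tests look
for. A `null_signatures` option draws the evidence genes disjoint from
the module to measure background rates.

The generator does **not** emulate realistic omics summary statistics
(p-values, effect sizes, LD structure), correlated evidence layers, or
the degree-localization correlations of curated interactomes. A green
planted-module test therefore establishes that the machinery recovers
a strong, well-localized signal — not that real consortium data carry
one.

## Numerical notes

Row sums of `M` are asserted to 1 within 1e−12 at construction and
within 1e−10 after up to 10 sparse multiplications; diffusion states
are checked against a dense explicit matrix power to 1e−10 in the test
suite. Matrices are stored sparse (`Matrix`), so the intended scale
(≈16,000 nodes, ≈250,000 edges, 131 columns) fits comfortably in
workstation memory; `Mᵗ` itself is never materialized. Bipartite
components can make the walk oscillate so that R never falls below the
threshold; the `t_max` cap (with a `capped` flag on the result) guards
against that.

## A worked run

```{r worked}
fx <- worked_example_fixture()
pl <- run_pipeline(fx, verbose = FALSE)
pl$signal                     # P1 carries DE + methylation evidence
pl$result$diagnostics         # R falls to the 0.05 threshold
subset(pl$ranked, select = -argmax_columns)
```

## Limitations

Identifiers are opaque strings — no Ensembl/UniProt mapping is
attempted. Evidence layers must be thresholded upstream; the package
computes no DE/GWAS statistics. The classification counts depend on
the strict-max tie rule; alternative readings of "highest signal in
the brain" (e.g. cross-gene ranks within a column) are available via
the `column_ranks` attribute but are not the shipped definition.
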