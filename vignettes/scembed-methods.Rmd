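---
title: "Methods: expression-weighted aggregation of text-derived gene embeddings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: expression-weighted aggregation of text-derived gene embeddings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scembed)
```

## The model

The package's core object is a per-cell embedding built from two inputs: a
normalized expression matrix $X \in \mathbb{R}^{n \times m}$ (cells × genes,
library-size scaled and `log1p`-transformed) and a gene embedding table
$e_f \in \mathbb{R}^{m \times t}$ mapping each gene name to a fixed-length
vector, typically a language-model embedding of a textual description of the
gene's function. Cell embeddings are

$$e_{cells} = \mathrm{AVG}(X)\, e_f \;(+\, e_c),$$

where $\mathrm{AVG}$ is one of two weighting schemes applied to $X$ before the
matrix product:

* **aa** — every entry divided by the gene count $m$. Cell embeddings then
  scale linearly with a cell's total signal, which preserves magnitude
  information and suits perturbation-style analyses.
* **wa** — each row divided by its row sum, so weights sum to one and the
  embedding is a convex combination of gene vectors. This removes per-cell
  depth effects entirely, which is why it is the default for clustering,
  integration and annotation.

The optional term $e_c$ adds, per cell, the embedding of a cell-level metadata
label. It is pure vector addition with no scaling factor, and is only applied
when labels are explicitly supplied: the package treats it as an
evaluation-time probe, not an inference-time feature, since true labels are
unknown exactly when one would want to predict them.

Two degenerate-input conventions matter downstream. Cells with zero total
expression keep an all-zero weight row under `wa` (with a warning) instead of
producing NaNs, and are kept rather than dropped so that gene deletion — which
can empty a cell — never changes the matrix shape. Alignment between $X$ and
$e_f$ is always by gene name, never by column position; genes missing from the
table are an error unless the caller opts into intersect-and-warn.

The assumption doing the real work is that the embedding table has functional
block structure: genes acting in the same program lie close in embedding
space. Aggregation then maps cells with similar active programs to nearby
points even when their exact gene-level profiles differ — which is also what
makes projection-based batch integration possible with no trained alignment.

## Embedding providers

Where the gene vectors come from is deliberately outside the model. A provider
is anything implementing `describe` (name → text, via a prompt template with
one `{}` placeholder) and `embed` (text → $t$ reals). The shipped
`hash_provider()` derives a unit-norm pseudo-random vector from a stable FNV-1a
string hash: deterministic across platforms and sessions, near-orthogonal
across distinct names, and entirely offline. It carries no biological
information — it exists so the mechanics of the whole pipeline are testable —
whereas the synthetic generator below produces tables *with* planted biology.
Hosted-API adapters can implement the same contract; nothing in the package or
its tests requires them.

## Zero-shot tasks

All neighbourhood-based steps share one exact (non-approximate) kNN graph with
deterministic lower-index tie-breaking. Clustering is Leiden community
detection (modularity objective) on the undirected union of kNN edges, seeded
and with labels renumbered from 0. Two defaults deserve explanation:

* **Clustering graph density, k = 30.** With the more common k of 10–20, the
  modularity objective at resolution 1 fragments communities of a hundred or
  so cells (the resolution limit: a sparse kNN subgraph of a large community
  looks like several). At the problem sizes this package targets (hundreds to
  a few thousand cells), a 30-neighbour graph yields stable communities that
  match planted structure; the resolution parameter stays at 1.0 and both are
  caller-adjustable. The scIB-style "optimal clustering" resolution scan
  (0.1–2.0 in steps of 0.1, best NMI/ARI reported) is available in
  `integration_report(scan_resolution = TRUE)` and off by default.
* **Distance metric.** Euclidean by default, cosine by flag. On `wa`
  embeddings of cells with similar totals the two orderings rarely differ;
  Euclidean keeps the silhouette-based metrics and the graph on the same
  geometry.

Annotation is a majority vote over the k = 10 nearest labelled cells, with
ties resolved by the nearest neighbour among the tied labels — deterministic
and independent of label order. Batch integration simply aggregates each batch
over the intersected gene set and concatenates: any mixing observed is
attributable to the embedding space itself.

## Integration metrics

Every score is oriented so higher = better and clipped to $[0, 1]$:

* **NMI** uses arithmetic-mean normalization and returns 0 for a constant
  labeling (zero entropy) rather than NaN.
* **ARI** uses the pair-counting closed form and may be negative; it is
  clipped to 0 only when averaged into $S_{bio}$.
* **ASW**: mean silhouette width $\bar{s}$ mapped by $(\bar{s}+1)/2$ for type
  labels and $1-(\bar{s}+1)/2$ for batch labels; Euclidean distance;
  singleton clusters contribute width 0. Batch ASW is computed globally, not
  per cell type (a known difference from scIB's per-type variant, listed under
  limitations).
* **LISI (simplified)**: per cell, walk the distance-sorted neighbour list and
  count neighbours extracted before any label would appear a second time;
  average, then normalize by $(B-1)$ batches (iLISI) or invert against
  $(C-1)$ types (cLISI). This is the neighbour-walk simplification, not the
  inverse-Simpson original — scores from the two are not interchangeable.
* **Graph connectivity**: per type, the largest-connected-component fraction
  of the kNN subgraph induced on that type; averaged.
* **PCR**: per principal component, the $R^2$ of the PC score on batch
  indicators (computed directly as one minus the within-batch sum of squares
  over the total), accumulated as a variance-fraction-weighted sum. The raw
  quantity measures batch-explained variance, so the reported score is
  $1 - \text{batch variance}$, making "higher is better" literally true and
  $S_{batch}$ coherent; the raw value is available via `raw = TRUE`.
* **kBET**: per neighbourhood, a chi-squared goodness-of-fit test of batch
  composition against global proportions; the score is the fraction of cells
  accepted, where acceptance means $p > \alpha$ (strict, so $\alpha = 1$
  rejects everything by construction). Defaults: $\alpha = 0.05$, evaluated on
  the shared graph.

`integration_report()` computes everything on one shared graph (k = 50,
clipped to $n-1$) and composes $S_{batch}$ and $S_{bio}$ as exact arithmetic
means. A larger 90-neighbour graph is the usual LISI convention; the
standalone `lisi()` accepts any graph when that convention is wanted, while
the report favours a single substrate so its components are comparable.

## The fine-tuning adaptor

The adaptor is a small ReLU feed-forward encoder (hidden sizes [256, 64] by
default; the last hidden layer is the latent used downstream) with a linear
classifier head, trained by mini-batch Adam (lr $10^{-3}$, batch 128,
100 epochs) on

$$L_{total} = L_{classifier} + \lambda\, L_{contrastive}, \qquad \lambda = 100.$$

$L_{classifier}$ is softmax cross-entropy. $L_{contrastive}$ is a supervised
contrastive loss on the L2-normalized latent: for anchor $i$ with same-class
positives $P(i)$ within the mini-batch,

$$L_i = -\frac{1}{|P(i)|} \sum_{p \in P(i)}
  \log \frac{\exp(u_i \cdot u_p / \tau)}{\sum_{a \neq i} \exp(u_i \cdot u_a / \tau)},$$

averaged over anchors with at least one positive, temperature $\tau = 0.1$.
An InfoNCE-with-augmentation variant is deliberately not implemented —
expression profiles have no natural augmentation that would not distort the
aggregation semantics. With $\lambda = 100$ the contrastive term dominates the
gradient, which is the intent: the latent organizes by label first, and the
kNN annotator run in that latent benefits accordingly.

Training is plain base-R matrix arithmetic with manual backpropagation
(gradients are checked against finite differences in the test suite), runs in
seconds at desk scale, and is bit-for-bit reproducible: initialization, batch
order and the validation split all derive from the config seed. A stratified
90/10 validation split selects the best epoch by validation classifier loss;
setting `validation_split = 0` keeps the final epoch. Classes with a single
cell are rejected up front since they can never have a contrastive positive.

## The treatment screen

Candidates default to the top 10 differentially expressed genes between the
diseased and control cells (two-sample Wilcoxon rank-sum per gene,
Benjamini–Hochberg adjustment, ranked by adjusted p then absolute mean
difference — the test choice is this package's, as is conventional). Each
candidate is deleted by zeroing its column; under `wa` the remaining genes'
weights renormalize over the reduced row sums, recomputed from the zeroed
matrix, never cached. The score is the change in cosine similarity between
the per-condition mean embeddings, and a gene is a candidate iff
`score > 1e-4`, strictly.

The screen's default embedding space is the raw aggregation (the score
formula is generic in the embedding function); passing a trained adaptor
re-embeds through its latent instead, with the same trained weights before and
after deletion — no retraining. The default keeps the screen deterministic
given the data and embedding table, and directly checkable against a
straight-line oracle, which the test suite does to $10^{-10}$ both with and
without a model. Multi-state diseases are handled by running the screen once
per diseased state against the shared control.

## Synthetic data: what it emulates and what it does not

The generators exist so that every pipeline stage has data with known ground
truth. One `SynthSpec` couples both modalities through shared gene-function
groups: in the embedding table, a gene's vector is
$\text{normalize}(c \cdot \text{anchor}_g + (1-c) \cdot \text{noise})$ with
group coherence $c$ (default 0.8); in the expression model, each cell type
elevates its assigned groups by `type_separation` (default 2, log scale) over
a baseline drawn once per gene. Counts are negative-binomial with a log link
(`size = 2`, i.e. clearly overdispersed relative to Poisson) and then
library-size log-normalized. Batches beyond the first add per-gene Gaussian
log-scale offsets with standard deviation `batch_shift`, and types are
interleaved across batches so mixing is measurable.

The disease fixture draws control and diseased cells from the same programs,
elevating the driver genes by `driver_effect` (default 3) and a downstream
module — 20% of the first regular gene group — by $0.15 \times$ that, chosen
a priori from cosine-shift estimates so that deleting the driver moves the
diseased mean clearly past the 1e−4 threshold while deleting any single
module gene does not. Driver genes get private singleton embedding groups: a
unique embedding direction is what makes their deletion visible, while a
module gene's weight redistributes onto its coherent group neighbours.

Default problem sizes are the study conditions used throughout the tests and
the acceptance script: 400 cells and 100 genes per condition for the disease
screen, 600 cells × 200 genes × 4 types for zero-shot recovery, 300 cells ×
100 genes × 2–3 types × 2 batches (shift 1.5) for integration and adaptor
comparisons, and 500 genes in 10 groups at coherence 0.8 for the gene-function
probe. These sizes give stable, seed-robust outcomes while keeping any full
run in seconds.

What the generator does *not* emulate: dropout-rate structure beyond NB
sampling, doublets, ambient RNA, gene–gene correlation within a program
beyond the shared mean shift, nonlinear batch effects, or any specific
published dataset. Passing tests on this data therefore demonstrate that the
algorithms recover the structure they are designed to recover — not that any
particular biological claim transfers to a real atlas, where embedding tables
are noisier and type programs overlap.

## Numerical choices and degenerate inputs

* MTX files are written at `%.17g` so round trips are bit-exact; reading goes
  through `Matrix::readMM`. Embedding TSVs likewise carry full precision.
* kNN ties break toward the lower cell index; `order()`'s stable sort makes
  graphs reproducible across runs.
* `knn_annotate` clips k to the training size with a warning; `knn_graph`
  clips k to $n-1$.
* Zero-variance genes are skipped (with a warning) in per-gene correlation;
  constant truth vectors are an error for $R^2$; silhouette requires two
  classes; LISI normalization requires two labels of its kind.
* Latent normalization in the contrastive loss guards $\|h\| = 0$ (possible
  under ReLU) with an $\varepsilon$ floor; a NaN/Inf gradient aborts training
  with a diagnostic rather than continuing silently.
* All internal randomness runs under a saved-and-restored RNG state, so
  library calls never perturb the caller's stream.

## Known limitations

* The LISI variant is the simplified neighbour walk, bounded above by the
  number of distinct labels encountered; values are not comparable to
  inverse-Simpson LISI implementations.
* Batch ASW is global, not per cell type.
* Brute-force kNN is $O(n^2)$ memory and time — appropriate for the desk-scale
  datasets targeted here, not for atlases.
* The adaptor trains on CPU in base R; it is sized for thousands of cells and
  two-layer encoders, not for deep architectures.
* h5ad support covers dense and CSR/CSC `X`, index names, and the obs columns
  `cell_type`/`batch`/`condition` — a pragmatic subset of AnnData.
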