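---
title: "Predicting dense cortical neuropeptide networks from single-cell RNA-seq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting dense cortical neuropeptide networks from single-cell RNA-seq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Cortical neurons secrete neuropeptides — cleavage products of neuropeptide
precursor proteins (NPPs) — that act over sub-millimeter distances on
neuropeptide-selective G-protein-coupled receptors (NP-GPCRs). Because a
precursor gene expressed in one cell and a cognate receptor gene expressed
in another imply a possible directed paracrine connection, single-cell
RNA-seq of a cortical census makes peptidergic network structure
*predictable* from transcript abundance alone. `pepnet` implements that
prediction pipeline: single-cell expression statistics for NP genes,
selection of the focused NPP/NP-GPCR gene sets, a gene-subset cell-type
classification benchmark, and type-by-type coupling-matrix prediction with
transduction-family aggregation. The cell-type taxonomy (class → subclass →
type, about a hundred leaf types over two cortical areas) is an *input*;
the package does not re-derive it.

## Peak expression and related statistics

NP genes are highly differential: high in a minority of cells, zero in
most. A population mean is therefore uninformative, so peak expression is
summarized by the value at the **ascending 99.9th percentile** of the
single-cell distribution (nearest-rank convention: the sorted element at
1-based index `ceiling(0.999 * n)`, clamped to `n`). Applied to FPKM this
is the pFPKM metric; it is robust to sporadic outliers yet tracks the true
peak in even small expressing subsets. `peak_rank_table()` ranks these
peaks across a reference universe (rank 1 = highest; the percentile of a
gene with rank `r` over `N` genes is `100 (N - r + 1) / N`); ties are
broken lexicographically by gene symbol so ranks are reproducible.

Detection is a strict inequality, `value > threshold`, with a default of
1 CPM. Descending expression curves place each cell on a percentile axis
`100 (rank - 0.5) / n`; the `max_over_set` curve — the per-cell maximum
over a gene set — reads off what fraction of the population expresses at
least one gene of the set at any level. Co-expression multiplicities,
cognate-pair co-expression (bounded above by each member's detection
fraction), and Pearson/Spearman cross-area conservation correlations
complete the single-cell tier. Conservation coefficients in the
literature are often reported without naming the correlation method;
both are implemented and Pearson is the default.

Type-level profiles use the **5% trimmed mean** (both tails, count rounded
down) of CPM within each type, falling back to the plain mean when
trimming would exhaust the cells; the median is available as an
alternative. The trimmed mean resists both drop-out zeros and rare extreme
cells. Within-subclass versus global coefficients of variation
(sample standard deviation over mean, across type-level values) quantify
how much marker structure survives inside subclasses; subclasses with a
single type have no defined CV and are excluded automatically.

## Gene selection

Candidate NPP genes are first screened by per-type median CPM > 10 in at
least one type. The focused sets then require (1) the NPP's peak
percentile over the gene universe to be at least 80 (top quintile) and
(2) at least one cognate receptor to be locally expressed. Receptor
transcripts never reach precursor-like abundance (the published receptor
set spans roughly the 40th–95th peak percentile), so "locally expressed"
is operationalized permissively: detection in at least 0.5% of cells at
the 1 CPM threshold, or peak percentile at least 50. The 0.5% floor is
the envelope of the published receptor set — its least-detected member is
expressed in 0.5% of cells — and both cutoffs are exposed as parameters.
Selection is mutually closed under the cognate relation, and
`build_cognate_pairs()` enumerates the retained bipartite edges in
deterministic order (NPPs by peak rank, receptors by symbol). For the
shipped annotations this yields 18 precursors, 29 receptors and 37 pairs.
The per-pair `fraction_of_type_pairs()` is the product of the two
expressing-type fractions at thresholds of 1 CPM on trimmed-mean
profiles; the procedure behind the published fractions is unstated, so
the thresholds are parameters and that column is informational only.

## The synthetic census

`generate_dataset()` emulates the statistical structure the analysis
relies on, so every stage is testable without downloads:

* a balanced class → subclass → type hierarchy with unit merge heights
  (12 subclasses split 7:5 between GABAergic and glutamatergic, as in
  cortex; types dealt evenly, sizes differing by at most one);
* background genes with log-normal baselines and low type-to-type
  variability (log-scale sd 0.2), emulating housekeeping structure;
* NP-like genes expressed in a random minority of types (per-gene
  expressor fraction uniform on [0.05, 0.6]) at levels log-uniform over
  four decades, and *exactly zero* elsewhere — the high-to-zero transition
  characteristic of NP genes; every type is guaranteed at least one
  NP-like expressor;
* two areas whose type-level profiles differ by an independent log-normal
  perturbation (sd 0.05 by default, chosen to mirror the strong observed
  cross-area conservation);
* gamma–Poisson (negative-binomial) counts, dispersion 0.5, with
  log-normal library sizes (median 20,000 counts, log-sd 0.3), then CPM by
  row normalization. Overdispersion, not plain Poisson noise, is what
  produces realistic zero-inflation of low-mean NP-like genes;
* cells sampled 47% GABAergic / 53% glutamatergic, reflecting the
  interneuron-enriched census the analysis assumes.

Defaults are 100 types, 12 subclasses and 2,500 cells per area. The
generator does **not** simulate read-level noise, batch effects, doublets,
gene–gene correlation beyond type structure, or FPKM length effects —
so passing tests demonstrate algorithmic correctness and qualitative
behaviour, not quantitative performance on real tissue.

## The gene-subset classification benchmark

The question "do 47 NP genes suffice to identify cell types?" is answered
by representation linking. A **reference autoencoder** (four ReLU hidden
layers of width 100 per side, linear latent layer of dimension `d`
followed by batch normalization, input dropout 0.8, Adam, minibatch 956)
is trained to reconstruct the highly expressed gene set; its latent
embedding `z1` defines the benchmark geometry. A **linked autoencoder**
(width 50, no dropout) is then trained on a small gene set with loss
`L = R + lambda C`, `lambda = 100`, where `R` is the mean squared
reconstruction error and `C = MSE(z2, z1) + (sigma_min(z2) - 1)^2`. The
second term of `C` holds the standard deviation of the latent batch along
its least-variant principal direction at 1, preventing the latent space
from collapsing onto `z1`-matching directions only; it is implemented as
an additive penalty with an exact eigen-derivative. With `lambda = 0` the
loss reduces to plain reconstruction.

Implementation notes. The networks are plain matrix code: He
initialization, inverted dropout, batch normalization without affine
parameters (the latent layer is linear, so a learned affine would be
redundant with the adjacent dense layers), running statistics in
inference mode, and a linear output layer (inputs are standardized
`log10(CPM + 1)`, which is signed; raw CPM would let a handful of
abundant genes dominate the squared error — the transform is a config
switch). Training is deterministic given the seed carried by the
`autoencoder_spec()`.

Classification quality is scored by the **resolution index**. Node
heights of the taxonomy are normalized so `RI = 1 - height/height(root)`
is 0 at the root and 1 at every leaf. Under 13-fold cross-validation a
ridge-regularized Gaussian QDA (per-class covariance plus
`1e-4 x mean latent variance` on the diagonal — 5-dimensional latents
with small types otherwise yield singular covariances) is trained on leaf
labels; correctly classified cells score RI = 1, and misclassified cells
are re-scored by classifiers retrained on successively coarser label
sets, collapsing internal nodes one at a time in ascending height (finest
splits first, ties by label — a deterministic schedule chosen by the
package, since any merge order respecting the dendrogram would do), until the
prediction matches; the cell then inherits the RI of its current label's
node, flooring at 0 at the root. `compare_gene_sets()` runs the full
link → QDA → RI pipeline per gene set and reports bootstrap p-values for
differences in mean RI.

Latent dimension defaults to `d = 5` for quantitative runs (2 for
visualization); reference gene sets `HE(n)` (top per-cell maxima),
`DE(n)` (Kruskal–Wallis across leaf types on `log10(CPM+1)` — a stand-in
for an externally defined differential list), `DE47` (most variable
type-means within the DE pool), `Rand47` and expression-matched `Rand47`
(decile-binned maxima) are provided. Tests and the shipped benchmark run
scaled-down problem sizes — 20 types, ~5,000 cells, reference training
150 epochs on a 200-gene HE set, linked training 60 epochs at width 25
(the architecture behaves equivalently at width 25), 100 random subsets —
which comfortably separate an informative marker panel from random
subsets on synthetic data.

## Coupling matrices and transduction channels

For a cognate pair, the type-level coupling matrix over an area is the
outer product of the NPP gene's type-expression vector (rows, sources)
and the receptor gene's vector (columns, targets), in CPM·CPM units — a
rank-1 directed adjacency prediction. Zeros are common, and the logarithm
of zero is undefined, so the log10 display copy floors values at
`eps_log = 1e-2` CPM·CPM (a parameter). Subclass pooling is the
unweighted mean over subclass blocks; because the matrices are rank-1,
pooling commutes exactly with the outer product, which the tests verify
to 1e-12.

G-alpha aggregation merges pairs by their receptor's primary transduction
family — Gi/o inhibits cAMP, Gs stimulates cAMP, Gq/11 amplifies calcium
— into three channels. Two natural aggregation orders exist; the default
normalizes first: per pair, shift the log matrix to minimum 0 and scale
to maximum 1, sum within family, rescale the channel to [0, 1]. The
alternative (sum linear, then log and normalize) is available via the
`order` argument — normalizing per pair first prevents the strongest
pair from drowning out the rest of its family. Adjacency matrices export one CSV per pair and area with
deterministic names, and channels export per family.

## Numerical choices and degenerate inputs

Zero-total cells make CPM undefined and are rejected by name in
`counts_to_cpm()` (the generator drops them with a warning; at default
library sizes they do not occur). Taxonomies require a single root of
positive height, leaf heights 0 and monotone heights; trees without
branch lengths get unit-merge heights (maximum edge count down to a
leaf). Correlations refuse zero-variance input rather than returning
`NA`. Random draws everywhere go through explicit seeds
(`withr::with_seed`), so identical configurations produce byte-identical
artifacts; the pipeline manifest records parameters, seed and file
checksums.

## Known limitations

Transcript abundance is a proxy: translation, processing, secretion,
diffusion and receptor function are all assumed, and coupling matrices
are predictions to be tested physiologically, not measurements. The DE
gene stand-in is not the externally defined differential list, so
absolute RI values for DE sets are not comparable to published ones. The
synthetic census supports algorithm validation only; quantitative claims
about cortical tissue require the real census data. FPKM/CPM conversion
is out of scope (it needs exon lengths), so unit tags travel with the
data and comparisons across units are refused.
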