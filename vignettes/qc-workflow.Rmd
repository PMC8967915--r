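---
title: "Models and methods behind the scqckit quality-control workflow"
author: "scqckit authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind the scqckit quality-control workflow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope and data model

`scqckit` standardizes the quality-control stage of droplet-based
single-cell RNA-seq analysis: import of gene-by-barcode count matrices from
preprocessing tools, empty-droplet detection, per-cell metrics, doublet
scoring, ambient-RNA decontamination, HTML reporting and export. Data live
in a `SingleCellExperiment` whose metadata carries two things the class
does not: the **matrix level** and a **provenance log**.

Levels encode filtering progress, not count processing. A *Droplet* matrix
still contains empty droplets (CellRanger's "raw"); a *Cell* matrix keeps
only barcodes called as real cells ("filtered"); a *FilteredCell* matrix
additionally removes poor-quality cells. A Cell matrix can be derived only
from a Droplet matrix by column subsetting, and FilteredCell only from
Cell; the container enforces these transitions so a matrix can never
silently skip a filtering stage.

Every operation appends one provenance entry (operation name, the
parameters as actually used, the seed, a timestamp and the package
version). A single pipeline-level seed fans out to per-operation seeds by
hashing the operation name (CRC32), so inserting or removing one stage does
not perturb the random streams of the others; this is what makes the
end-to-end determinism test (two runs, identical summary tables) hold even
as the algorithm roster changes. Each QC algorithm is applied to the cells
of each sample separately; results on a multi-sample experiment equal
per-sample results concatenated.

# Empty-droplet detection

## Ambient pool and the Monte-Carlo multinomial test

Barcodes whose total UMI count is at most `lower` (default 100, exposed as
a parameter; the conventional pool bound, since droplets that small almost
never contain a cell) define the **ambient pool**. Pooled counts plus a
pseudo-count of 0.5 per gene, normalized, give the ambient profile
$\hat p$. A barcode $b$ with counts $x_b$ and total $t_b > \texttt{lower}$
is scored by its conditional multinomial log-likelihood

$$\log L_b = \log \binom{t_b}{x_{b1},\dots,x_{bG}} + \sum_g x_{bg} \log \hat p_g .$$

The Monte-Carlo p-value compares $\log L_b$ with `niters` simulated draws
from $\text{Multinomial}(t_b, \hat p)$ using the add-one estimator
$p_b = (1 + \#\{\log L^{sim} \le \log L_b\}) / (1 + \texttt{niters})$,
which can never be exactly zero; the `limited` flag records a zero tail
count, i.e. cases where more iterations could lower the p-value further.
Simulated likelihoods are compared with a $10^{-8}$ slack so exact ties in
the discrete outcome space count toward the tail, matching the exhaustive
enumeration oracle used in the tests. Simulation is *stratified by total*:
one simulated likelihood distribution per distinct total, shared by all
barcodes with that total, and extended incrementally from one total to the
next (an $O(\texttt{niters} \times \max t)$ C++ inner loop rather than
$O(\texttt{niters} \times \#\text{totals} \times \max t)$). The tests
verify this stratified scheme against brute-force enumeration on a 3-gene
model and verify super-uniformity of the p-values under the null.

q-values are Benjamini-Hochberg adjusted over *tested* barcodes only
(barcodes in the pool never enter the multiplicity correction). The cell
call is `q <= fdr` (default FDR 0.01, logged) **or** `total >= retain`,
where `retain` defaults to the per-sample barcode-rank knee so very large
cells cannot be lost to an unusual profile; calibration tests disable the
retain rule (`retain = Inf`).

## Knee and inflection of the barcode-rank curve

The log-log curve of rank versus total counts is summarized by a cubic
smoothing spline (default 10 degrees of freedom, logged) over the unique
(log10 average rank, log10 total) points above `lower`. We define the
**transition region** as the points where the fitted slope is at least
three quarters of the steepest fitted slope. The **knee** is the log-space
midpoint of the region's fitted endpoints and the **inflection** its foot.
On gradual real curves these land where droplet tools conventionally put
them (knee above inflection, both between the cell plateau and the ambient
plateau); on sharply two-plateau synthetic curves a curvature-corner
definition would ride up to the top of the cliff (about
$(\text{plateau ratio})^{0.79}$ above the plateaus' geometric mean), which
is why the midpoint-of-transition definition was chosen. Degenerate curves
(fewer than five unique totals, e.g. all barcodes equal) return that count
for both points.

# Per-cell metrics and outlier flagging

Per-cell totals, detected genes, top-N occupancy percentages
(N in {50, 100, 200, 500}, the conventional grid, configurable) and
gene-set percentages are computed per sample via the scater package — the
standard implementation of exactly these metrics. Two 0/0 conventions are
fixed and tested: an all-zero cell has gene-set percentage 0 and top-N
percentage 100 (0 detected genes is at most any N). Shipped mitochondrial
sets (human/mouse in symbol, Ensembl and Entrez form) carry the 13
mitochondrially encoded protein-coding genes; Ensembl version suffixes are
stripped on both sides before matching, and unmatched identifiers are
counted in provenance rather than silently dropped.

Outlier flagging uses the median absolute deviation with the 1.4826
normal-consistency factor and a default of 3 MADs, computed on
log2(x + 1) by default — per-cell totals are approximately log-normal, so
the log scale keeps the MAD meaningful; the raw scale remains available.
Zero MAD (degenerate spread) flags nothing, with a warning. The
implementation is cross-checked against `scater::isOutlier` in the tests.

# Doublet detection

Four scorers share the convention *higher = more doublet-like* and the
invariant `call == (score >= threshold)`.

**Simulation + kNN.** `round(sim_ratio * n)` artificial doublets are
formed by summing the raw counts of uniformly sampled cell pairs (no
library-size matching — real doublets are sums of real libraries).
Observed and simulated profiles are normalized jointly (counts-per-10k,
log1p), reduced to 30 PCs over the top 2,000 variable genes, and each
observed cell is scored by the fraction $q$ of simulated doublets among
its $k \approx \sqrt n$ nearest neighbours, mapped through the odds
correction $q(1-r)/(q(1-r) + (1-q)r)$ with $r$ the simulated fraction of
the joint set, so the score estimates a doublet probability.

**Binarized co-expression.** Each gene is binarized at its per-gene count
quantile (median by default; genes with a zero threshold binarize at
count > 0). Among the 500 most variably binarized genes, each pair is
weighted by $-\log P[\text{Binom}(n, p_i p_j) \le o_{ij}]$ — large when
the pair co-occurs far less than independence predicts, i.e. mutually
exclusive markers. A cell's score sums the weights of the top 500 pairs it
co-expresses. Fully deterministic; a hand-enumerated 4-gene toy matrix in
the tests pins the arithmetic.

**Gradient-boosted classifier.** Observed cells (label 0) and simulated
doublets (label 1) train an xgboost classifier (single-threaded for
reproducibility) on the same normalized feature space with 5-fold
cross-validation; observed cells are scored by their out-of-fold predicted
probability, so no cell is scored by a model that saw it.

**Hybrid and consensus.** The hybrid score is the sum of the two min-max
normalized component scores (range 0-2) with a re-derived threshold. The
consensus call requires at least `min_votes` (default 2) algorithms to
agree — the recommended way to flag doublets when no single algorithm is
preferred.

**Thresholds.** A two-component Gaussian mixture (mclust, model "V") is
fitted to each score distribution and the threshold placed at the smallest
score with upper-component posterior at least 0.5. The fit counts as
degenerate — and falls back to the (1 - expected_rate) quantile, default
rate 0.05 — when it fails, the components are indistinct, or the implied
call fraction is outside (0, 50%].

On the standard fixture (2,000 cells, 3 types, 10% heterotypic doublets)
the tests require AUROC at least 0.90 (kNN), 0.85 (classifier) and 0.80
(co-expression), call rates within 3-25%, and chance-level discrimination
against shuffled labels. A homotypic-only fixture shows the family's known
limitation: with no second cell type there is no expression mixing to
detect, and discrimination drops far below the heterotypic case. (It does
not drop all the way to chance in simulation: with only 500 genes, summed
libraries have depth and shot-noise signatures that a kNN in PCA space can
partially exploit. Real data, with ~20-30k genes and biological
overdispersion, hides this residual signal even better.)

# Ambient-RNA decontamination

Cell $c$ in cluster $k(c)$ is modelled as
$x_c \sim \text{Multinomial}\!\big(t_c,\; \theta_c \eta + (1-\theta_c)\phi_{k(c)}\big)$,
with $\eta$ the shared ambient profile, $\phi_k$ the cluster's native
profile and $\theta_c$ the cell's contamination fraction. Estimation is
EM on the penalized likelihood with Dirichlet smoothing
($\alpha = 10^{-2}$ pseudo-counts on $\eta$ and $\phi$, entering the
objective as $\alpha \sum \log \eta_g + \alpha \sum_k \sum_g \log \phi_{kg}$,
so the M-step is exactly the smoothed normalization and the penalized
objective is provably non-decreasing — asserted per iteration in the
tests). $\theta$ is initialized at 0.1 for every cell and $\eta$ at the
mean expression over all cells; identifiability comes from sharing $\eta$
across clusters, which is why a single cluster is an error rather than an
arbitrary answer.

Convergence is declared when the mean absolute change in $\theta$ falls
below `tol`. The default is $10^{-4}$: at $10^{-3}$ the geometric decay of
$\theta$ from its 0.1 initialization is cut off early, leaving a residual
of about 0.02 on contamination-free data, while $10^{-4}$ reaches the
fixed point in well under a hundred iterations at negligible cost. The
E-step responsibilities split every observed count exactly into native and
ambient parts, so per cell the native sum equals $t_c(1-\theta_c)$ by
construction; decontaminated counts are stored real-valued (rounding is
left to the consumer and documented at export).

When no labels are supplied, clusters are derived by CP10k/log1p
normalization, 30 PCs, and k-means with k chosen by mean silhouette width
over k = 2..10, seeded. User labels always override. The 2-D embedding for
reports is UMAP (single-threaded, seeded) on the same PCA space.

# Synthetic study conditions

The generator draws cell-type profiles from a Dirichlet (concentration 0.5
over the genes — distinctly separated types), sets the ambient profile to
their equal-weight mixture, and samples: empty droplets as pure ambient
multinomials at log-normal ~10-count depth; singlets from
$(1-\theta)\,\phi_{type} + \theta\,\eta$ at log-normal ~5,000-count depth
with $\theta \sim \text{Beta}(2, 18)$ (mean 0.10, a typical droplet-run
contamination level); and heterotypic doublets as sums of two independent
singlet draws from distinct types. Defaults are 500 genes, 3 types, 300
cells per type, 20,000 empties, 8% doublets. The doublet and
decontamination tests use 600 cells per type and a 10% doublet fraction
(2,000 cell barcodes); these sizes keep the whole suite within a few
minutes on one CPU while leaving the statistical criteria far from their
noise floors.

Because contamination is generated at the per-molecule level by the same
mixture the decontamination module fits, parameter recovery there is a
well-posed test of the estimator, not of model misspecification. What the
generator deliberately does **not** emulate: gene-length/GC bias,
overdispersion beyond multinomial sampling, ambient profiles that differ
from the cell-type mixture, intermediate cell states, or realistic gene
counts. Passing tests therefore demonstrate correctness of the algorithms
under their stated models and calibrated behaviour of the Monte-Carlo
test; they do not by themselves guarantee field performance on tissues
with continuous differentiation or strong batch structure.

# Interfaces and formats

Importers treat STARsolo, BUStools and dropEst as MEX dialects that differ
only in file naming, encoded in a single manifest table also used by the
fixture writer, so every supported layout is round-tripped in the tests.
Orientation on disk is decided by matching matrix dimensions against the
sidecar files, never by which dimension is larger. Counts are preserved
bit-exactly; duplicate gene identifiers abort the import (silent
uniquification would corrupt gene-set matching). CellRanger v3 feature
types other than "Gene Expression" are dropped, v2 `genes.tsv` and v3
`features.tsv.gz` conventions are honoured.

h5ad input and output are implemented natively on HDF5 following the
AnnData on-disk encoding (X as CSR cells-by-genes, obs/var dataframe
groups with explicit encoding attributes, obsm arrays, provenance as YAML
text under `uns`); interoperability with the Python AnnData reader and
writer is exercised in the test-suite in both directions. The gzip and
no-compression modes are supported; the lzf filter is specific to the
h5py stack and is rejected with a parameter error. Flat-file export
writes each assay as MatrixMarket plus shared sidecars, annotations and
embeddings as TSV, provenance as YAML, and a JSON manifest with MD5
checksums; metadata is serialized as YAML rather than any binary format
so a run is auditable with a text editor.

HTML reports are assembled by string templating with base64-embedded PNG
figures — fully self-contained files whose bytes are stable across
re-renders except for the timestamp line, which the tests exploit.

# Known limitations

Homotypic doublets are intrinsically out of reach of expression-mixing
detectors. The Monte-Carlo test's memory and time scale with
`niters x max(total)`; extremely deep barcodes dominate the incremental
simulation. The decontamination EM assumes the ambient profile is
expressible as a mixture resembling the observed cells; strongly
cell-free-enriched ambient RNA (e.g. from fragile cell types absent from
the final matrix) will be partially absorbed into cluster profiles. The
k-means cluster derivation targets compact, well-separated populations;
for continuous trajectories, user-supplied labels are preferable.
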