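---
title: "Models and methods in omicsweave"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in omicsweave}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette documents the statistical machinery of `omicsweave`: the models
and algorithms, the tunable parameters and their defaults, the numerical
choices, what the synthetic-data generator does and does not emulate, and the
design decisions we made where the design was genuinely open. It states no
empirical result that the package's tests or `scripts/acceptance.R` do not
themselves compute.

## 1. Data model

An `omics_dataset` is one measurement matrix (features × samples, missing
cells allowed) plus a features-metadata and a samples-metadata table aligned
to its axes. A `multiomics_set` is an ordered, named collection of such
datasets sharing a sample-ID namespace: the same sample ID always denotes the
same biological sample. Two rules resolve the common mismatches:

* metadata rows whose ID is absent from the matrix are dropped with a
  warning; matrix IDs absent from the metadata get an empty row. Hard
  failure would make iterative data assembly painful, silent dropping would
  hide errors; warn-and-continue is the middle ground.
* samples-metadata for a shared sample must not conflict across datasets on
  shared columns (`NA` never conflicts). There is no principled precedence
  order among omics files, so conflict is an error rather than a guess.

Matrices are stored features × samples internally regardless of the on-disk
orientation, which is declared at load time. Missing-value tokens on import
are the empty string, `NA` and `NaN` (case-insensitive); anything else
non-numeric is a parse error naming the cell. GFF3/GTF coordinates are kept
as in the file (1-based, inclusive); parsing is delegated to
`rtracklayer::import`, which handles both attribute dialects.

## 2. NIPALS PCA and imputation

`nipals_pca()` extracts components sequentially: for component *h*, the
score vector *t* and unit-norm loading vector *p* are alternately updated by
per-feature and per-sample least squares over *observed cells only*, the
fitted rank-one term is subtracted, and the next component starts on the
deflated matrix. On complete data this is ordinary power iteration and
agrees with the SVD up to column sign; the sign convention (largest
absolute loading entry made positive) fixes the arbitrary sign so runs are
reproducible across platforms.

**Convergence.** Iteration stops when the relative L2 change of the score
vector falls below `tol`. This successive-change criterion underestimates
the true component error by a factor of roughly `1/(1 - lambda2/lambda1)`,
so when consecutive eigenvalues are close a loose tolerance leaves visible
error in the components. The defaults are therefore strict —
`tol = 1e-12`, `max_iter = 5000` — which keeps agreement with a full
eigendecomposition far below `1e-6` even for near-degenerate spectra, at a
cost of a few hundred extra cheap iterations. Non-converged components are
flagged in `converged`, never an error.

**Scaling.** Centring uses observed-cell means; optional unit-variance
scaling uses observed-cell standard deviations and refuses zero-variance
features (there is no sensible scale for a constant feature). Explained
variance per component is the observed-cell sum of squares of the rank-one
fit over the total centred observed sum of squares.

**Imputation.** `impute_missing()` fits a NIPALS PCA per dataset and fills
each missing cell with its reconstruction (scores · loadingsᵀ, un-scaled,
un-centred), then refines iteratively: refit on the completed matrix,
re-fill, repeat until the imputed values change by less than `tol_impute`
(default `1e-4` relative) or `max_iter_impute` (50) rounds. A single pass
estimates loadings only from the incomplete-data fit, whose per-component
regressions accumulate bias under deflation; the iterative scheme (the
standard iterative-PCA / EM approach) converges to a self-consistent
low-rank completion and on rank-3 simulations reaches a masked-cell RMSE
near the noise floor. Observed cells are never altered — this is checked
bit-exactly in the tests. The imputation PCA is centred and unscaled by
default, with both flags exposed, and the component count is per-dataset.

## 3. Transformations and prefiltering

Three built-in transforms cover the common cases: `log2_halfmin` (zeros
replaced by half the smallest non-zero value in the *whole dataset*, then
log2 — the usual treatment of exact zeros in abundance data), `log2_plus1`,
and per-feature `zscore` (error on zero-variance features, by name). A
`custom` hook accepts any matrix-to-matrix function — variance-stabilising
transforms from other packages plug in here. Every application appends a
record (dataset, transform, parameters) to the dataset's transformation log
for reporting.

Unsupervised prefiltering scores features by MAD (plain
`median(|x - median|)`, no consistency constant — only the ranking matters)
or by COV (`sd/|mean|`; the absolute value gives negative-mean features
positive scores, and an exactly zero mean is an error rather than an
infinite score). The top `keep` features are retained; `keep` in (0, 1] as
a double is a fraction, above 1 (or integer-typed) a count. Ties at the
cutoff break by lexicographic feature ID so results are machine-independent.
Supervised prefiltering runs sPLS-DA and keeps the union of features
selected across components, with per-component keep counts of
`ceiling(keep/ncomp)` — the retained count is approximately, and never more
than slightly above, the target.

## 4. Integration methods

### Two-block sparse PLS

For blocks X (n × p) and Y (n × q), centred and by default unit-scaled, each
component finds the dominant singular pair of the cross-covariance
`M = XᵀY` by alternating iteration, initialised from the column of M with
the largest norm. Sparsity is imposed by soft-thresholding: to keep *k*
entries of a loading vector, the threshold is the magnitude of the
(k+1)-largest absolute entry, entries below it are zeroed, survivors shrink
toward zero by the threshold, and the vector is renormalised. This
guarantees exactly *k* non-zeros (ties at the cutoff, a measure-zero event
for continuous data, fall back to hard truncation) and preserves the
relative magnitudes of the survivors — the reason soft-thresholding is
preferred over plain truncation. Deflation follows the classical scheme:
`regression` mode deflates both blocks on the X-scores, `canonical` mode
deflates each block on its own scores. Convergence uses `tol = 1e-9`,
`max_iter = 500` on the X-loading change; the dominant-pair gap is
typically wide and the dense limit agrees with the cross-covariance SVD to
better than 1e-6 (asserted in the tests, and cross-checked against the
mixOmics implementation on dense and sparse instances).

### sPLS-DA

Exactly sPLS in regression mode with Y the centred one-hot indicator matrix
of the sample groups and no sparsity on the outcome side. Selected features
are the union of non-zero X-loadings across components. One caveat the test
suite documents explicitly: the *training-data* silhouette of a supervised
fit is optimistically biased — under permuted labels the selection step
still finds features that separate the random groups in-sample (mean
silhouette ≈ 0.3 at n = 60, p = 200, keepX = 10, against ≈ 0.8 for the true
labels). Comparing against a permutation null, as the tests do, is the
honest way to read such scores.

### Consensus multi-block PCA

A native multi-block method so that multi-block comparison paths work
without external tools. Per component, a global score vector *t* is found
by multi-block NIPALS: block loadings are the regressions of each block on
*t* (normalised), block scores follow, and *t* is updated as the normalised
weighted combination of block scores (consensus-PCA super-score with
norm preserved). All blocks are deflated on *t*, making global scores
orthogonal across components; with one block the procedure reduces exactly
to PCA. Per-component diagnostics record the summed squared covariances
between the global score and each block score.

### Adapters

`register_adapter(name, prepare, collect)` makes an external method
pipeline-callable: `prepare` maps a `multiomics_set` to the method's input,
`collect` maps its output to the package's `integration_result`, which is
validated on collection (unit-norm loading columns per dataset, coherent
selection masks, matching component counts). Violations fail at collect
time, not downstream.

## 5. Standard output, importance, consensus

Every integration result converts to two long tables: feature weights
(feature, dataset, dimension, weight — unselected features carry weight 0
rather than being omitted, so cross-method correlations are computable over
a common feature universe) and sample scores (sample, dimension, score).
For two-block methods that produce per-block sample scores, the standard
score is the average of the block scores (the standard format has one score
per sample per dimension; per-block scores remain in the raw result); for
sPLS-DA the X-block scores are used (the outcome block is an indicator
matrix, not data); for consensus multi-block PCA the global scores.

Importance is `m_ij = |w_ij| / max_i' |w_i'j|` with the maximum over
features of the same dataset and dimension — invariant to rescaling all of
a dimension's weights and to sign flips, both asserted as properties. An
all-zero (dataset, dimension) yields importance 0 everywhere and is flagged.

Consensus importance aggregates one chosen dimension per method:
average, geometric mean, harmonic mean, L2 norm, or product. Geometric and
harmonic means (and the product) are defined as 0 whenever any method gives
0 — the limit behaviour, deliberately not epsilon-padded, so a feature
invisible to one method is maximally penalised by the stringent
aggregators. The L2 norm is `sqrt(sum m²)`: the name says "norm", so the
square root is taken even though that makes it exceed 1 when several
methods agree. Only features present in *every* method's result (per
dataset) are scored, because importance is undefined for features a method
never saw (e.g. after different prefiltering); the intersection size is
reported so users can detect poor overlap. The aggregator inequalities
`harmonic ≤ geometric ≤ average ≤ max ≤ L2 ≤ sqrt(J)·max` hold for
positive inputs and are property-tested.

## 6. Evaluation

Silhouette scores use Euclidean distance on the selected score columns,
unweighted — the conventional choice, exposed per-dimension so users can
evaluate any subspace. Samples in singleton groups score 0 by convention.
The implementation is backed by `cluster::silhouette`; the tests hold it to
a from-scratch brute-force oracle at 1e-10 on random instances.

Feature-set enrichment tests whether a set's importance scores are shifted
against the rest of the dataset's features. Sets are first matched to the
background (the features actually present in the result) and sets smaller
than `min_size` (default 5) after matching are excluded and reported. The
test is a Welch two-sample *t* of member vs non-member importances: a
generally-applicable gene-set enrichment reduces to exactly this when the
per-feature statistic is a single score vector, and the unequal-variance
form is robust to the very different group sizes. P-values are
Benjamini–Hochberg adjusted across tested sets. The calibration test draws
1000 random sets under a permuted null and requires the empirical type-I
rate at 0.05 to land in [0.03, 0.07].

## 7. Comparison

`correlate_results` computes Pearson (optionally Spearman) correlations
between all pairs of latent dimensions of two results — sample scores over
the shared samples, feature weights over the shared (feature, dataset)
pairs — with at least 3 shared items required and zero-variance cells
reported `NA`. Pearson is the default because latent-dimension similarity
is conventionally judged linearly; Spearman is one argument away.
`cluster_correlations` assembles all pairwise matrices into one symmetric
block matrix (labels namespaced `method/dimension`), clusters on the
distance `1 − |r|` with average linkage, and returns the leaf order —
`NA` cells are treated as distance 1 for clustering but kept `NA` in the
values. `match_dimensions` pairs dimensions greedily by descending absolute
score correlation, each dimension used once, below-threshold pairs dropped.

## 8. Pipeline engine

Steps reference registered operations (`fn(inputs, params)` plus a version
string) and form a DAG through their input lists; cycles are an error
naming the offending steps. A step re-executes iff its definition hash —
operation name and version, canonically serialised parameters, input step
names, input-file digests — or any parent's output digest changed, or its
cache is absent. Code introspection is deliberately excluded from the hash:
deparsed closures are not portable across R versions or machines, so
operations declare a version string instead, and bumping it is the way to
force re-execution after a code change. Hashes are MD5 over canonical
serialisations (`tools::md5sum`); outputs are cached one RDS file per step;
run records (step, hash, seed, status, runtime) go to a tibble and to
`run_metadata.jsonl`. Failures mark all descendants failed and the record
is still persisted. `get_output` refuses stale caches (a step whose own or
ancestral definition changed since the cached run) rather than silently
returning outdated results.

Per-step seeds are a deterministic 32-bit FNV-1a-style mix of the global
seed and the UTF-8 bytes of the step name, reduced below 2^31 for
`set.seed`. A 64-bit mix would be marginally better distributed, but base R
has no exact 64-bit integer arithmetic and the 32-bit mix is exactly
portable, order-independent and sibling-independent, which is what the
reproducibility contract needs. Execution is sequential; the step contract
(pure function of inputs and seed) is what a parallel backend would need,
but none is shipped.

## 9. The synthetic-data generator

`generate_multiomics` simulates the structure latent-factor integration
methods assume: each block is `X = F Lᵀ + ε` (stored features × samples)
with standard-normal factors, a configurable number of shared and
block-specific factors, and i.i.d. Gaussian noise. A balanced two-group
sample split shifts the first shared factor by `group_effect`
factor-standard-deviations (group signal enters through factor 1 only,
mirroring the common situation where the leading latent dimension carries
the phenotype contrast). Loadings are sparse: a fraction `sparsity` of each
block's features is active per factor, active magnitudes are drawn
Unif(0.5, 1.5) with random sign, inactive loadings are exactly 0. Bounding
magnitudes away from zero is a deliberate departure from a Gaussian slab:
it makes "active" a well-defined ground truth that selection methods can
be scored against (a Gaussian slab puts many active loadings
indistinguishably close to zero, making recall an accident of the draw).
MCAR missingness and partial per-block sample inclusion are applied last;
everything is driven by one seed and is bit-reproducible.

Defaults — 100 samples; rna/protein/metabolite blocks of 200/150/100
features; noise SD 0.3; no missingness; one shared factor; sparsity 0.1;
group effect 2; full sample overlap — are the reference conditions used
throughout the tests and the acceptance script. Test problem sizes
elsewhere (50 × 20 PCA oracle, 100 × 50 imputation, n = 60 / p = 200
selection) were chosen as the smallest instances where the statistical
contracts are comfortably identifiable.

What the generator does *not* emulate: count distributions (a Poisson
block is a natural extension but the transforms that would motivate it are
out of scope), batch effects, feature-feature correlation beyond the factor
structure, non-random missingness, and the marginal distributions of any
real platform (SNP dosages, NMR abundances). Passing tests on this
generator show the machinery is correct under its assumed model, not that
any real dataset satisfies that model.

## 10. Known limitations

* Integration methods require complete data — impute first; this is
  enforced with an explicit error.
* No cross-validation tuning of `ncomp`/`keepX`: keep counts are
  user-specified. Tuning machinery is a different (and much more expensive)
  layer, and the external packages that provide it can be wrapped through
  the adapter interface.
* The external-method adapters ship with no bundled third-party methods;
  sPLS, sPLS-DA and consensus multi-block PCA are the native set.
* Sample scores for dataset-specific dimensions of two-block-plus methods
  assume a shared sample set at integration time.
* The pipeline engine runs sequentially and its cache format is
  RDS-per-step; distributed execution and remote storage are out of scope.
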