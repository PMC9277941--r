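---
title: "Methods: multiple-kernel fuzzy topic modeling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multiple-kernel fuzzy topic modeling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mkftm)
```

# The model

`mkftm` decomposes a corpus into `K` topics by clustering documents with
fuzzy memberships and converting the memberships into probability tables,
rather than by fitting a generative model with sampling or variational
inference. The pipeline is deterministic given a seed, and each stage is
an exported function so intermediate objects can be inspected.

## Term weighting

The bag-of-words count `tf_ij` of term `i` in document `j` is multiplied
by a global per-term weight, the fusion probabilistic IDF

$$\mathrm{FPIDF}(t) = \log\frac{M\,N\,(N - n_t)}{n_t^2},$$

with `N` documents, document frequency `n_t`, and `M` the maximum document
frequency over the vocabulary. By the product rule of logarithms this is
exactly the sum of a hybrid IDF `log(M N / n_t)` and the probabilistic IDF
`log((N − n_t)/n_t)`; the identity is verified to 1e-10 in the test suite
and is the package's core algebraic invariant. The weight decreases
strictly in `n_t`: rare terms discriminate, ubiquitous terms do not.

Two boundary situations need care:

* `n_t = N` makes the argument of the logarithm zero. We substitute
  `ε = 1/(2N)` for the zero factor inside the logarithm so the weight
  stays finite (and strongly negative).
* Terms in more than half of the corpus have a negative probabilistic
  component and can make the fused weight negative. Because every
  downstream probability table requires a nonnegative matrix, global
  weights are floored at zero *before* multiplication: such terms simply
  contribute nothing. This is deliberate — a term present nearly
  everywhere carries no topical signal.

`M` is taken at corpus level by default, so FP-IDF is one number per term
and the weighted matrix keeps the sparsity pattern of the counts. A
per-document variant (`global_max_scope = "document"`), where `M` is the
maximum document frequency among the terms each document contains, is
available for users who prefer a local calibration; it makes the weight a
per-term-per-document quantity.

The logarithm base is natural by default and configurable; changing it
rescales all weights by a constant and does not affect clustering.

## PCA

Documents (columns of the weighted matrix) are transposed to rows,
mean-centered per term, and projected onto the leading right singular
vectors. Centering only — no variance scaling — because the FP-IDF weights
*are* the signal and standardizing terms would undo them. The default
retains the components explaining 95% of variance, capped at
`min(n − 1, 200)`; an integer component count is also accepted. Component
signs are fixed by requiring the largest-magnitude loading of each
component to be positive, which makes repeated runs bit-identical.

PCA feeds only the clustering geometry. All probability tables are
computed from the pre-PCA weighted matrix, which is nonnegative; PCA
scores are signed and cannot be normalized into probabilities.

## Multiple-kernel fuzzy c-means

Given points `y_1..y_B`, kernels `G_1..G_S` and fuzzifier `s > 1`, each
iteration:

1. normalizes membership powers per cluster,
   `v̂_if = v_if^s / Σ_i v_if^s`;
2. computes the squared feature-space distance of every point to every
   fuzzy centroid under every kernel,
   `α_ifg = G_g(y_i,y_i) − 2 Σ_j v̂_jf G_g(y_i,y_j) + Σ_{j,j'} v̂_jf v̂_j'f G_g(y_j,y_j')`;
3. scores each kernel by its total fuzzy within-cluster scatter
   `β_g = Σ_{i,f} v_if^s α_ifg` and re-weights `z_g ∝ 1/β_g` on the
   simplex;
4. combines distances, `T²_if = Σ_g α_ifg z_g²`, and updates
   `v_if = 1/Σ_{f'} (T²_if / T²_if')^{1/(s−1)}`;
5. stops when the Frobenius norm of the membership change falls below the
   tolerance (default 1e-5, max 100 iterations).

`α` is a squared distance and is clipped at zero when floating-point
cancellation produces values in `(−1e-9, 0)`. A point at zero distance
from one or more centroids receives uniform membership over exactly those
clusters. A kernel with `β_g = 0` fits perfectly; its inverse is guarded
at 1e-12 so arithmetic stays finite, and the all-zero case falls back to
uniform kernel weights with a notice.

### Kernel bank

Three Gaussian kernels with bandwidths 0.5, 1 and 2 times the median
pairwise distance of the input points. The median heuristic makes the bank
self-scaling across corpora; Gaussian Gram matrices have unit diagonal by
construction, and the linear/polynomial options are diagonal-normalized
(`G(i,j)/√(G(i,i)G(j,j))`) so mixed banks stay commensurable.

### Initialization (a deliberate design choice)

Drawing the initial membership rows from a flat Dirichlet looks natural
but fails structurally for this algorithm: with hundreds of points, every
cluster's fuzzy centroid — a membership-weighted average of *all* points —
sits essentially at the global mean, all distances coincide, and the
update converges to the uniform-membership fixed point. We measured
exactly this on 200-document corpora (mean maximum membership 0.200, i.e.
`1/K`). The package therefore seeds each restart with `F` data points
chosen by distance-squared (k-means++-style) weighting and initializes
memberships from squared Euclidean distances to those seeds. Five restarts
are run by default and the solution with the smallest final fuzzy
objective `Σ_{i,f} v_if^s T²_if` is kept; restart seeds derive
deterministically from the master seed.

### Fuzzifier (a deliberate design choice)

The textbook default `s = 2` is calibrated to low-dimensional geometry. In
the ~100-dimensional PCA spaces typical of even small corpora, the ratios
`T²_if / T²_if'` concentrate near 1 and `s = 2` collapses memberships
toward uniform — a documented failure mode of fuzzy c-means in high
dimensions. The pipeline default is `s = 1.1`, close to the hard-cluster
limit but still producing graded memberships for genuinely mixed
documents. On planted-topic corpora this choice recovers cluster structure
at the same quality as k-means on the identical representation (ARI within
0.01 of the k-means ceiling), while `s = 2` yields chance-level
assignments. `s` remains configurable; `mkfcm_config()` used directly
still defaults to `s = 2` for users clustering low-dimensional data.

## From memberships to probabilities

The converged membership `v_jk` is identified with `P(T_k | D_j)`: it is
the only row-stochastic document-by-topic quantity the pipeline produces.
The remaining tables follow by the chain rule and normalization:
`P(D_j)` is document `j`'s share of total weighted mass;
`P(D_j, T_k) = P(T_k|D_j) P(D_j)`; `P(D_j|T_k)` normalizes the joint per
topic; `P(W_i|D_j)` column-normalizes the weighted matrix; and
`P(W_i|T_k) = Σ_j P(W_i|D_j) P(D_j|T_k)`. Topic columns of `P(W|T)` are
automatically normalized because they are convex combinations of
normalized document distributions. A topic with zero joint mass is kept
(preserving `K`) with a uniform column and a warning rather than being
dropped.

Documents left empty by preprocessing are dropped (with a message) rather
than kept as zero vectors, because the per-document normalizations above
divide by document sums.

# Evaluation utilities

**Calinski–Harabasz.** The variance-ratio criterion
`[(N−K)/(K−1)] · between / within` with squared Euclidean distances, the
form that reproduces the classic index; a flag offers the literal
unsquared reading. Hard clusters for the index come from seeded k-means on
the rows of `P(T|D)` (argmax memberships are the alternative). Zero within
scatter returns `Inf`; zero between scatter returns 0.

**Corpus log-likelihood.** Defined as the training-corpus likelihood of
the counts under the mixture `P(w|d) = Σ_k P(w|T_k) P(T_k|d)`, with a
1e-12 floor inside the logarithm so tokens outside the model's support
keep the sum finite. This is a *training* likelihood and is labeled as
such; no held-out fold-in is implemented.

**Classification.** A linear (shared-covariance) Gaussian discriminant on
the rows of `P(T|D)`, ridge-regularized with `λ = 1e-6 · trace(Σ)/d`,
priors from class frequencies. Prediction minimizes expected cost
`Σ_k p̂(k|x) C(y|k)`; with the default 0–1 cost this is the
maximum-posterior class, ties to the lowest class index. Cross-validation
is stratified: each class is shuffled once under the seed and dealt
round-robin into folds, so splits are deterministic.

# The synthetic generator

`generate_corpus()` draws `K_true` topic-word distributions from a
Dirichlet with concentration `topic_sharpness` (default 0.05: sharp,
realistic for specialty vocabularies), per-document topic mixtures from a
symmetric Dirichlet (`doc_topic_concentration`, default 0.1), Poisson
document lengths (mean 60), and tokens by the usual
topic-then-word sampling. Redundancy is emulated by duplicating a fraction
of documents with independent token dropout (default rate 0.1 within
duplicates), mirroring the near-duplicate passages that occur in curated
biomedical collections. Tokens are synthetic (`w001`, ...) and the corpus
is emitted pre-tokenized so clustering tests are decoupled from stemming;
writing it to disk and reloading exercises the full text path.

What it does **not** emulate: Zipfian marginal word frequencies, burstiness
(a word reappearing within a document more than multinomial sampling
predicts), document-length/topic correlation, stopword structure, or any
real biomedical vocabulary. Passing recovery tests on this generator shows
the pipeline recovers Dirichlet-multinomial planted structure; it does not
by itself certify performance on real abstracts.

## The recovery regime used in tests

The recovery experiments (test suite and `scripts/acceptance.R`) run at 5
topics, 500 terms, 200 documents, `topic_sharpness = 0.05`, and
`doc_topic_concentration = 0.02`. The last value defines the
*well-separated regime*: with concentration 0.02 almost every document is
dominated by a single planted topic, so the planted argmax label — the
reference for the adjusted Rand index — is well defined. At the generator's
general-purpose default of 0.1, a noticeable minority of documents are
near 50/50 topic mixtures; their argmax label is close to arbitrary, and
any clustering method (we verified k-means on the same representation
behaves identically) pays the same ARI penalty for them. Recovery under
redundancy adds 30% near-duplicates to the same regime. Topic-word
recovery is scored by greedy cosine matching of recovered to planted
distributions; document recovery by ARI between argmax assignments and
planted labels.

These problem sizes keep the full test suite and the acceptance script in
the tens of seconds on a single CPU while leaving the corpus large enough
(≈12,000 tokens) for stable recovery statistics.

# Numerical and degenerate-input conventions

* Ties in hard assignment (`hard_assignments()`, `top_words()`,
  `classify()`) break to the lowest index / vocabulary order.
* Cosine normalization, term probabilities, and all probability tables are
  exact normalizations; tests assert sums to 1 within 1e-12 (inputs) and
  1e-8 (fitted tables).
* Coincident points make the median pairwise distance zero; the Gaussian
  bandwidth heuristic falls back to 1.
* `n_components` as a fraction selects the smallest count reaching that
  cumulative variance; as an integer it must not exceed `min(n − 1, m)`.
* Empty corpora, zero rows/columns, vocabulary mismatches and unknown
  configuration keys raise typed conditions (`mkftm_*_error`) rather than
  propagating `NaN`s.

# Known limitations

* Topic quality inherits the limitations of hard-geometry clustering:
  topics are convex regions in PCA space, and extremely unbalanced topic
  sizes can be split or merged before restarts compensate.
* No out-of-sample inference: a fitted model describes its training
  corpus; classifying new documents requires refitting or using the
  exported topic features externally.
* The log-likelihood is comparable across models fitted to the *same*
  corpus and `K`, not across corpora.
* Stemming is English-only (Porter); non-English corpora should disable
  it.
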