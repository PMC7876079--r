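---
title: "A kernel framework for compositional and spatio-temporal microbiome analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A kernel framework for compositional and spatio-temporal microbiome analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kernbiome)
```

## The model

Sequencing-based abundance tables are compositional: each sample's counts
are constrained by an arbitrary library size, so only ratios between taxa
carry information. `kernbiome` treats every analysis — prediction,
ordination, importance retrieval — as an operation on a single N × N kernel
matrix of pairwise sample similarities, and provides kernels whose geometry
respects that compositionality.

The centered log-ratio transform clr(x) = log(x/G(x)), with G(x) the
geometric mean of the sample, maps the simplex onto the zero-sum hyperplane
of R^D and is invariant to rescaling of the sample total. The
**compositional linear kernel** is the inner product of clr coordinates and
the **Aitchison RBF kernel** is the Gaussian kernel under the Aitchison
(Euclidean-in-clr) distance. Both are therefore immune to library-size
differences, which we verify as an invariance property in the test suite
rather than assume. Two further kernels operate on (normalized) abundances
directly: one minus the Jensen–Shannon divergence, which is bounded in
[1 − ln 2, 1], and the quantitative Jaccard (Ružička) similarity
Σmin/Σmax, which tolerates zeros with no preprocessing at all.

A symmetric function is only a kernel if every evaluation matrix is
positive semi-definite; `check_psd()` makes that property testable (relative
eigenvalue criterion), and every kernel constructor in the package is
property-tested against it on random tables.

From one kernel matrix we run both branches of a typical study:

* **Supervised**: a support vector machine on the precomputed kernel
  (classification or ε-regression, via `kernlab`). We disable kernlab's
  shrinking heuristic: on rank-deficient precomputed kernels (a clr-based
  linear kernel has rank at most D − 1) it can terminate far from the
  optimum; without shrinking the fit agrees with an explicit-feature linear
  SVM to machine precision, which the test suite checks.
* **Unsupervised**: kernel PCA — double-center the kernel, eigendecompose,
  and scale eigenvectors by the square roots of their eigenvalues. For the
  compositional linear kernel this reproduces ordinary PCA of the clr
  matrix, which serves as the module's correctness oracle. Component signs
  are fixed by making each component's largest-magnitude entry positive.

## Zeros and normalization

Log-ratios are undefined at zero. Following the detection-limit view of
zeros, `replace_zeros()` adds a pseudocount to *all* entries (not only the
zeros), default 0.5 — half of one read for count tables. Because the clr is
scale-invariant the common offset is the only arbitrariness introduced.
For the non-compositional kernels, cumulative sum scaling
(`css_normalize()`) divides each sample by the sum of its counts up to a
quantile (default 0.5) of its nonzero counts, then rescales by the median of
those per-sample sums; this is robust to a few dominant taxa in a way that
total-sum scaling is not. The Jensen–Shannon kernel requires relative
frequencies and will close count rows to proportions itself, with a warning,
using the convention 0·ln(0/a) = 0.

## Longitudinal kernels

For individuals sampled at T common time points, the discrete functional
kernels compare trajectories directly: fLin(f, g) = Δt Σ f(t_i) g(t_i) and
fRBF(f, g) = exp(−γ Σ (f(t_i) − g(t_i))²). Multivariate versions sum
(fLin') or multiply (fRBF') over taxa, which is exactly a linear (times Δt)
or RBF kernel on the individuals-by-(taxa × time) flattened matrix — the
implementation computes them that way and the tests verify the identity
against an explicit per-taxon loop. A single γ is shared across taxa.
Discrete mode is the default: with few time points, fitting trajectories is
less reliable than using the points as they are, and the discrete
expressions require a complete regular grid (irregular grids are refused
rather than silently averaged).

The continuous kernels integrate ∫f·g dt or ∫(f−g)² dt over an interval,
reconstructing each trajectory by piecewise-linear interpolation; they
accept irregular and missing time points. Because the product (or squared
difference) of two piecewise-linear functions is piecewise quadratic,
per-segment Simpson quadrature on the union grid is *exact* — no refinement
parameter is needed, and the analytic examples in the tests hold to 1e-12.
No extrapolation is performed: intervals must lie inside both observed
supports. Interpolation is the package's choice where a scheme had to be
fixed; splines would be smoother but make the quadrature inexact and add a
smoothing parameter.

Compositional preprocessing of longitudinal counts is per sample:
pseudocount, then clr at each (individual, time) slice (`clr_timeseries()`),
then the functional kernel.

## Spatial integration

Given kernel matrices K_1, …, K_M from M sites over the same individuals,
the consensus kernel is K* = Σ β_z K_z with β_z ≥ 0 — a non-negative
combination, hence PSD. We normalize β to sum to 1: the overall scale of K*
is redundant with the SVM cost, and removing it makes weights comparable
across runs. Matrices are cosine-normalized (unit self-similarity) before
combination so that β is not distorted by kernels living on different
scales.

* **Supervised** (`mkl_optimize_supervised()`): β is found by exhaustive
  search on a simplex grid (step 0.1 for M ≤ 3, 0.25 above), scored jointly
  with the SVM cost by repeated k-fold cross-validation. The grid contains
  the one-hot corners, so the training-CV score of the consensus can never
  fall below the best single kernel. Ties are broken toward the most uniform
  β, then toward the smaller cost. A transparent grid search was preferred
  over gradient MKL: it is reproducible, trivially parallel over candidates,
  and adequate for the small M of body-site designs. One consequence worth
  knowing: when the task is so easy that many β reach a perfect CV score,
  the uniform tie-break wins — weight *ordering* is only revealed by
  benchmarks that run below the performance ceiling, and our integration
  benchmark therefore plants a moderate effect (clr shift 1) rather than a
  saturating one.
* **Unsupervised** (`consensus_unsupervised()`): β is proportional to the
  leading eigenvector of the M × M Frobenius-cosine similarity matrix of the
  centered, cosine-normalized kernels — the weights that maximize the
  average similarity of K* with the individual matrices. On a non-negative
  similarity matrix the leading eigenvector is non-negative
  (Perron–Frobenius); should negative entries occur they are clipped at zero
  with a warning.

Spatio-temporal data composes the two mechanisms: one functional kernel per
site, then MKL over sites (`spatiotemporal_kernel()`). Hierarchical designs
(first within an organ, then across organs) are expressed by nesting calls.

## Evaluation harness

`replicate_evaluation()` mirrors a replicated hold-out protocol: 80/20
train/test splits repeated n times (default 40) to obtain an error
distribution; on each training set, hyperparameters (SVM cost, and γ by
recomputing the kernel per candidate) are tuned by k-fold cross-validation
repeated r times (default 5 × 5, read as 5-fold CV repeated 5 times); the
final model is refit on the whole training set and scored once on the test
set. Metrics are accuracy and, for regression, the normalized mean squared
error — MSE divided by the *population* variance of the test targets, a
convention chosen so the trivial mean predictor scores ≈ 1. With group
identifiers (e.g. litters of full sibs) whole groups are assigned to one
side of every split; the suite asserts this over all replicates. A
one-random-time-point test protocol supports comparing longitudinal models
against per-time-point models at equal test size. Tuning only ever touches
the training block of the kernel matrix; a test poisons the test block with
NA and checks the result is unchanged.

All randomness derives deterministically from a single seed; identical
configurations give bit-identical reports.

Default grids: cost ∈ {0.01, 0.1, 1, 10, 100}; for RBF-type kernels the
median heuristic 1/median(pairwise squared distance) is the default γ and a
sensible center for a log-spaced grid. The small-cost end matters more than
it may appear: with more taxa than samples an ε-SVR interpolates at any
sufficiently large cost, so generalization is controlled almost entirely
below cost ≈ 0.1.

## Synthetic data

The generators exist so every claim above is testable end to end with known
ground truth. Samples are drawn from a logistic-normal model: a latent
Gaussian vector per sample (per-taxon baseline means plus unit noise) is
softmax-mapped to a composition, and counts are multinomial at a log-normal
library size (meanlog log 10⁴, sdlog 1 — an order-of-magnitude spread).
Since clr(softmax(z)) = z − mean(z), a shift planted on the latent scale is
exactly a clr-scale effect, so signature recovery has a well-posed truth.
Class signal is a ±effect/2 shift on a chosen set of informative taxa
(default 10 of 200, effect 2); regression targets are a linear combination
of the informative latent coordinates plus Gaussian noise. Multi-site data
shares a per-individual latent field across sites (correlation 0.5 by
default) with signal restricted to chosen sites; longitudinal data gives
each individual a stable baseline plus per-time fluctuation, with the class
divergence applied only at chosen time points — non-informative time points
are exchangeable between classes.

What the generators do *not* emulate: taxon–taxon correlation structure
beyond the simplex closure, phylogenetic relatedness, overdispersion beyond
multinomial sampling, batch effects, and structured (non-random)
missingness. Passing tests therefore demonstrate that the machinery recovers
planted compositional signal under realistic sparsity and depth variation —
not that any particular real dataset is predictable.

Problem sizes used by the test suite and the acceptance script are chosen to
exercise the asymptotic regimes cheaply: N up to 150 samples, D up to 1,000
taxa for the O(N²D) sample kernels and D·T up to 1,500 for the O(N²TD)
functional kernels, with 10–40 evaluation replicates per benchmark.

## Known limitations

* Signatures are defined only for linear kernels (cLin, fLin); importances
  for non-linear kernels would require permutation-style approaches that are
  out of scope here. Signature importances live on the clr scale — they
  quantify log-ratio relevance, not raw-abundance relevance.
* Kernel matrices are dense; N in the tens of thousands would need a
  different backend.
* The pseudocount magnitude is a modeling choice (default 0.5); results on
  heavily zero-inflated tables can be sensitive to it.
* Phylogeny-aware kernels (UniFrac-like, or log-ratio transforms along a
  tree) are not provided; the clr term in both compositional kernels is the
  natural place where such a transform could be substituted.
* β search is a fixed grid; with many sources (M > 6 or so) the grid grows
  combinatorially and a coarser step (0.25) is used, trading resolution for
  runtime.
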