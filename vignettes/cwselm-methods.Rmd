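---
title: "Similarity-activated extreme learning machines for virtual screening: models and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Similarity-activated extreme learning machines for virtual screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cwselm)
```

## The screening problem

Ligand-based virtual screening ranks a database of molecules so that the
compounds most likely to be active against a target appear first, letting
chemists assay a small top fraction instead of the whole library. The
molecules are represented as fixed-length binary fingerprints (bit vectors
encoding substructural features, e.g. 1024-bit hashed circular
fingerprints), and the benchmark regime this package is designed around is
extreme: on the order of 30 known actives against 15,000 confirmed
inactives per activity class, with the actives deliberately chosen to be
structurally heterogeneous (mean pairwise Tanimoto similarity around
0.15–0.28).

Two families of methods are implemented end to end:

* **Similarity searching** — score each database molecule by its mean
  similarity to the known actives (`similarity_search_baseline()`).
* **WS-ELM / CWS-ELM** — a single-hidden-layer network whose hidden
  activations are fingerprint similarity coefficients and whose output
  layer is solved in closed form (`wselm()`).

## Similarity coefficients

All sixteen coefficients operate on the contingency counts of a pair of
bit vectors of length $m$: $a$ bits set in both, $b$ set only in the
first, $c$ set only in the second, $d$ set in neither, $a+b+c+d=m$. The
registry (`coef_registry()`) records each coefficient's family
(association / correlation / distance) and theoretical range. The one
distance in the set, Mean Manhattan $(b+c)/m$, is exposed to every
downstream consumer in similarity orientation $1-(b+c)/m$, so "higher =
more similar" holds throughout.

Two numerical conventions matter:

* **Zero denominators.** The formulas are undefined on degenerate input
  (e.g. Tanimoto on two all-zero fingerprints, Yule when $ad+bc=0$). The
  package returns 0 in every such case rather than `NaN` or an error.
  Degenerate all-zero fingerprints carry no structural signal, and a
  total, deterministic ranking is required by every metric downstream.
  This convention is ours; sources for these coefficient families are
  typically silent on it.
* **Exact counts.** Contingency counts of binary inputs are computed by
  integer-exact matrix products before any formula is evaluated, so
  coefficient values are bit-exact functions of the inputs.

A useful identity, verified exhaustively in the tests over all
contingency compositions with $m \le 8$: Sokal/Sneath(1) is the
double-weight transform of Tanimoto, $s_{SS1} = s_{JT}/(2-s_{JT})$, hence
the two produce identical rankings and differ only through the non-linear
hidden layer of the network models.

## WS-ELM: the model

Given training fingerprints $X = [x_1,\dots,x_n]^\top$ with labels
$y_i \in \{+1,-1\}$ and $l$ hidden-node fingerprints $w_1,\dots,w_l$
drawn from the training set, the hidden layer is

$$H_{ij} = s(x_i, w_j),$$

the chosen similarity coefficient — there is no inner-product-plus-bias
activation, and consequently no bias term anywhere in the model. The
output layer solves the class-weighted ridge problem

$$\min_\beta \; \lVert \hat H \beta - \gamma\,y \rVert_2^2 +
  \tfrac{1}{C}\lVert\beta\rVert_2^2, \qquad \hat H = \gamma \cdot H,$$

with per-sample imbalance weights
$\gamma_i = \max(n_I,n_A)/n_A$ for actives and $\max(n_I,n_A)/n_I$ for
inactives (`class_weights()`), implemented as the linear system
$(I/C + \hat H^\top\hat H)\beta = \hat H^\top(\gamma y)$ solved by a
Cholesky factorisation (never an explicit inverse). Screening scores are
$\hat y = H(X_{\text{new}})\,\beta$.

Because the weights scale the rows of $H$, samples enter the normal
equations with effective weight $\gamma_i^2$. A variant in which the
weights enter linearly ($H^\top\Gamma H$, `weighting = "linear"`) is also
provided: the two correspond to two formulations that appear side by side
in the literature on weighted ELMs and differ whenever $\gamma \ne 1$.
The row-scaled (squared) form is the default because it is the one
written as an explicit algorithm in the source material for this model
family; the package treats the other as a documented alternative rather
than adjudicating.

Any factor-of-two difference in how the ridge penalty is written
($\lVert\beta\rVert^2/C$ vs $\lVert\beta\rVert^2/2C$) is absorbed by the
$C$ grid and does not change the model family.

## Hidden-node selection: random, k-means, SVC

The conventional choice (`method = "random"`) samples $l$ distinct
training rows uniformly without replacement — a *subset* of the training
set, so no duplicate hidden nodes whose redundant directions only the
ridge would suppress. Prediction quality then varies run to run, which
motivates the two deterministic selectors.

**k-means medoids** (`method = "kmeans"`, `kmeans_representatives()`).
Lloyd iteration under the coefficient's geometry: distance is
$1 - s_{\text{norm}}$ with the coefficient affinely rescaled to $[0,1]$
(so correlation-type coefficients on $[-1,1]$ are handled uniformly),
centroids are real-valued coordinate means, and a binary sample is
compared to a real centroid by evaluating the same formulas on fractional
"soft" counts ($a = \sum_k x_k c_k$, etc.). Initialisation is greedy
farthest-point seeding with the seeded generator choosing only the first
centre, so runs are reproducible. Coordinate means are not the exact
minimisers of the soft-count similarity objective, so an update step can
occasionally worsen it; the iteration therefore terminates — keeping the
previous assignment — as soon as the objective fails to decrease, which
makes the reported objective trace non-increasing by construction. An
empty cluster is re-seeded at the sample farthest from its current
centroid. Finally, each cluster is represented by its member most similar
to the cluster mean, so the hidden nodes are always genuine training
fingerprints and the node count equals $k$ exactly.

**Support vector clustering** (`method = "svc"`, `svdd_fit()`). The
smallest enclosing sphere of the data in kernel feature space, with the
similarity coefficient as the kernel:

$$\max_\beta \sum_i \beta_i K_{ii} - \beta^\top K \beta,
  \quad 0 \le \beta_i \le C_s,\ \textstyle\sum_i\beta_i = 1.$$

Samples with $0 < \beta_i < C_s$ lie on the sphere (boundary support
vectors) and become the hidden nodes; samples at the bound $C_s$ are
outliers. Outliers are excluded from the node set by default — they lie
outside every cluster contour, so they do not "bound" a cluster — with
`include_bounded = TRUE` as the documented alternative. The node count is
controlled only indirectly, through $C_s$.

Three numerical choices here:

* *Indefinite kernels.* Similarity coefficients are not guaranteed
  positive semidefinite. The Gram matrix's smallest eigenvalue is
  checked; if it is below $-10^{-8}\,\mathrm{tr}(K)$, a diagonal jitter of
  its magnitude is added (and reported in the fit) to keep the dual
  concave.
* *Solver.* The dual is solved by sequential minimal pairwise updates
  that preserve $\sum\beta = 1$: the pair with the largest KKT violation
  is updated analytically and clipped to the box, to tolerance $10^{-6}$
  with a cap of $10^5$ updates. The tests verify the optimum against a
  general-purpose interior-point QP solver.
* *Cluster labelling geometry.* Classical SVC connects two samples when
  the segment between them stays inside the sphere contour. With
  stationary kernels the self-term $K(z,z)$ is constant along the
  segment; with match-based similarity kernels it is not — a fractional
  convex-combination midpoint of two disjoint bit patterns has soft
  self-similarity well below the coefficient maximum (exactly $1/3$ under
  Tanimoto for disjoint dense patterns), which *lowers* its apparent
  distance to the sphere centre and falsely merges well-separated
  clusters. `svc_labels()` therefore interpolates along the *Hamming
  path* by default: the bits on which the endpoints differ are flipped
  progressively, every tested point is a valid binary fingerprint, and
  its kernel self-similarity stays at the maximum. Between-cluster
  chimeras are then correctly found far outside the sphere. Convex
  interpolation with soft-count evaluation remains available
  (`interpolation = "linear"`) for comparison.

Clustering always runs unsupervised on the full training set, actives and
inactives together: node selection sees only $X$, never $y$.

## Screening metrics

All early-recognition metrics consume a `rank_screen()` object, which
orders by descending score with ties broken by ascending input index —
a total, deterministic order, so any cut-off produces bit-for-bit
reproducible metrics.

* **Hit rate** at fraction $f$: the top window holds
  $n_{\text{top}} = \max(1, \mathrm{round}(f\,n))$ molecules (the
  rounding rule is stated because "top 1%" alone does not define one),
  and the default denominator is $\min(n_A, n_{\text{top}})$ — the
  maximum number of actives the window could possibly contain — so a
  perfect screen scores 100%. Plain recall is available via
  `denominator = "n_actives"`.
* **Enrichment factor**: active concentration in the window over active
  concentration overall; expectation 1 under random ranking (verified by
  Monte Carlo in the tests).
* **AUROC**: rank-based Mann–Whitney with midrank ties.
* **BEDROC** with $\alpha = 160.9$ (weight concentrated on the top 1%),
  via the robust-initial-enhancement normalisation and the standard
  bounded transformation to $[0,1]$.
* **TPR/FPR ratio** at a cut, with an infinite sentinel when the window
  contains no inactives.

## Kendall's coefficient of concordance

Agreement of $k$ judges (activity classes) ranking $N$ objects (methods
or coefficients) is measured by the tie-corrected coefficient

$$W = \frac{12\sum_i (R_i - \bar R)^2}{k^2(N^3-N) - k\sum_j T_j},
  \qquad T_j = \sum (t^3 - t),$$

with $\chi^2 = k(N-1)W$ on $N-1$ degrees of freedom. Formulations of the
tie correction differ across textbooks in whether average ranks and the
correction enter consistently; the form above is the standard rank-sum
(Siegel–Castellan) one, equals the classic uncorrected formula whenever
no ties exist, and is validated in the tests against the definitional
deviation form. `ranks_from_table()` produces the rank matrix from a raw
performance table with average ranks by default; a sequential
(first-occurrence) tie-break is provided as an option because published
concordance analyses sometimes rank tables that way — the bundled
six-classifier benchmark table is reproduced exactly only under
sequential ranking, and its published rank matrix visibly breaks its one
tied pair ordinally.

## The synthetic generator

`generate_synthetic()` emulates the structure of the benchmark regime:
$n_A$ actives derived from a small number of scaffold bit patterns
(Bernoulli seed patterns copied with independent per-bit flips) drowned
in Bernoulli decoys. Defaults are fixed at the study conditions — 30
actives, 15,000 decoys, $m = 1024$, 4 scaffolds, seed density 0.10, flip
probability 0.04, decoy density 0.10 — chosen once from the closed-form
expectation of the within-active Tanimoto similarity so that the
active-class mean pairwise similarity lands near 0.18, inside the
0.15–0.28 band of the benchmark's activity classes. Everything is a
deterministic function of the seed, and the generator restores the
caller's RNG state.

What the generator does *not* emulate: real substructure hashing (bits
here are independent given the scaffold, while fingerprint bits co-vary
through shared substructures), bit-position collision structure,
scaffold-hopping relationships between classes, and assay noise in the
labels. Passing the recovery tests therefore demonstrates that the
estimators and selectors work as specified on data with planted
structure, not that any particular hit rate will be achieved on real
screening collections.

The self-contained recovery benchmark used by the test suite runs at
2,000 molecules × 256 bits with the protocol split (10 actives + 160
decoys trained, the remaining 1,830 molecules screened), a size chosen so
the full suite completes in seconds on one core while still exhibiting
the qualitative behaviour of interest: clustering-selected nodes reach
AUROC ≥ 0.99 and show significantly smaller across-seed variance than
random selection at small node counts (one-sided variance test at the
0.05 level over 20 resampled training sets).

## The benchmarking protocol

`make_split()` reproduces the published split design: 170 training
molecules per run — 10 actives of the target class plus 160 sampled from
the non-target pool — with everything else as test set. Other classes'
actives are treated as inactives for the class under consideration by
default; `other_actives = "exclude"` covers the alternative reading of
the pooled-split design. `cv_grid_search()` tunes $l$/$k$/$C_s$ and $C$
by five-fold *stratified* cross-validation on AUROC. Stratification is
not optional: with 10 positives among 170, unstratified folds can easily
contain no positive, leaving AUROC undefined. Ties in mean validation
AUROC resolve to the simpler model (smaller node count, then smaller
$C$). `run_benchmark()` repeats split–tune–fit–score over seeded runs and
records hit rate, EF, AUROC, BEDROC and the hidden-node percentage per
run; `aggregate_benchmark()` reduces to the method × coefficient means.
The canonical hyper-parameter grids are
$C \in \{10^{-6},\dots,10^{6}\}$, node counts over $1..n_{Tr}$ (thinned
by default for tractability) and $C_s \in \{0.1,\dots,1.0\}$.

## Bundled benchmark tables

The package ships, as plain CSV under `inst/extdata/`, the summary tables
of the published MUV benchmark of these methods (per-class hit rates of
similarity searching and WS-ELM for all sixteen coefficients, the
corresponding rank matrices, and the six-way WS-ELM/CWS-ELM comparison
with hidden-node percentages), accessible through `muv_table()`. The
concordance statistics, column/grand means and the hit-rate/node-count
correlation recomputed from them by the test suite and by
`scripts/acceptance.R` are the package's reproducibility anchors. One
caveat found while validating the transcription: the published
concordance value for the WS-ELM coefficient ranking is not recoverable
from its own printed rank matrix under any standard tie treatment (the
tie-corrected value computed from the table is 0.505); the package
reports the faithful computation.

## Known limitations

* ECFP/FCFP fingerprint *generation* is out of scope; the SMILES adapter
  delegates to an external toolkit (OpenBabel path-based fingerprints)
  and makes no claim of bit-level parity with other vendors' circular
  fingerprints.
* Similarity-coefficient kernels may be indefinite; the diagonal-jitter
  stabilisation changes the SVDD problem slightly in those cases (the
  jitter magnitude is reported on the fit).
* The SMO solver targets the small-$n$ regime of the training protocol
  (hundreds of molecules); it is not tuned for SVDD on tens of thousands
  of points.
* `hit_rate`'s window rounding and tie policy are conventions; results at
  aggressive cut-offs (windows of a handful of molecules) are sensitive
  to them, which is precisely why they are fixed and documented.
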