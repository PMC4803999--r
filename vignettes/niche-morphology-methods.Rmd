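---
title: "Linking niche divergence to morphological divergence: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linking niche divergence to morphological divergence: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Overview

`nichemorph` implements a quantitative chain that connects the ecological
niches of a clade's species to their morphology:

1. **Suitability modelling.** For each species, a presence/background
   maximum-entropy model is fitted from locality records against gridded
   climate layers and projected to a suitability surface.
2. **Niche overlap and the background test.** Pairs of standardized
   suitability surfaces are compared with Warren's *I* (and Schoener's
   *D*, Hellinger's *H*), and a background randomization test classifies
   each *directed* species pair as divergent, conserved, or
   non-significant.
3. **Climate–morphology covariation.** Species-level climate means and a
   species × trait table are analysed by two-block partial least squares
   (2B-PLS) with the Rv coefficient and row-permutation significance.
4. **Phylogenetic signal.** Continuous-trait evolutionary models (white
   noise, Brownian motion, Pagel's lambda, Ornstein–Uhlenbeck, early
   burst, delta, kappa) are fitted by maximum likelihood and ranked by
   AICc — the gate for deciding whether comparative corrections are
   needed at all.
5. **Niche–morphology correlation.** A Mantel permutation test relates
   the Hellinger niche-distance matrix to Euclidean morphological
   distances.

Every stage can be run on synthetic inputs with known ground truth; the
generators are first-class, tested code, not fixtures.

# Suitability models

The model is an exponential (Gibbs) distribution over background cells.
With features $f(x)$ — the linear and squared terms of each climate
variable standardized by its background mean and standard deviation —
the raw output at cell $i$ is

$$q_i = \frac{\exp(\beta^\top f(x_i))}{\sum_j \exp(\beta^\top f(x_j))},$$

and $\beta$ minimizes $\log Z(\beta) - \bar f_{\text{presence}}^\top
\beta + \lambda \lVert \beta \rVert_1$, i.e. a maximum-entropy fit whose
feature expectations are pulled toward the presence feature means, with
an L1 penalty.  This is the same family as the widely used Maxent
approach restricted to linear + quadratic features; hinge, product and
threshold features are deliberately omitted so that the model is convex,
fully documented and deterministic.  The optimizer is FISTA with
backtracking; convergence is a relative objective change below `1e-8`
within 500 iterations, and non-convergence is an error (carrying the
gradient norm), never a silent result.

Parameters that matter:

* `reg` — the L1 weight; default $1/\sqrt{n_{\text{presence}}}$, so
  sparse samples are shrunk harder (the same instinct as sample-size
  dependent regularization in common Maxent defaults).
* `tau` — logistic prevalence, default 0.5; the logistic output is
  $\tau s_i / (\tau s_i + 1 - \tau)$ of the relative suitability
  $s_i = q_i \cdot K$ over $K$ background cells, so a zero-coefficient
  model maps to a constant 0.5.
* background definition — either the union of occupied regions of a
  label raster (ecoregion style) or a great-circle buffer (default
  100 km) around localities.  A zero-radius buffer degenerates to the
  occupied cells themselves.

Because the downstream overlap statistics re-standardize each surface to
sum to one, they are only mildly sensitive to the link choice; the
pipeline default is logistic-then-standardize, and both links are
exposed.

# Overlap statistics and the background test

Surfaces standardized to sum to one are probability distributions over
cells, compared by

* Hellinger distance $H = \sqrt{\sum_c (\sqrt{p_c} - \sqrt{q_c})^2}
  \in [0, \sqrt 2]$,
* Warren's $I = 1 - H^2/2 \in [0, 1]$,
* Schoener's $D = 1 - \tfrac12 \sum_c |p_c - q_c| \in [0, 1]$.

The identity $I = 1 - H^2/2$ is verified to `1e-12` in the test suite on
a thousand random surface pairs.

The background test asks, for a directed pair (focal, background
species): is the observed $I$ between the two fitted surfaces lower or
higher than expected when the background species' model is refitted from
*random* points of its own background?  Null replicate $r$ draws as many
uniform cells (with replacement) from the background species' mask as it
has occurrences, refits, projects, standardizes, and records $I$ against
the focal surface; replicate $r$ is seeded `seed + r` so streams are
reproducible and parallel-safe.  With add-one empirical p-values

$$p_{\text{low}} = \frac{1 + \#\{I_{\text{null}} \le I_{\text{obs}}\}}{n_{\text{reps}} + 1},
\qquad
p_{\text{high}} = \frac{1 + \#\{I_{\text{null}} \ge I_{\text{obs}}\}}{n_{\text{reps}} + 1},$$

the call is **divergent** if $p_{\text{low}} \le \alpha/2$,
**conserved** if $p_{\text{high}} \le \alpha/2$, else
**non-significant** (two-tailed at $\alpha = 0.05$ by default, 100
replicates per direction).  P-values can never be zero, and when
`nreps` is too small for $1/(n_{\text{reps}}+1)$ to reach $\alpha/2$
the test is explicitly powerless rather than silently anti-conservative.

Design choices worth stating:

* **Comparison extent.** Both surfaces are projected onto the *union* of
  the two species' backgrounds (linear-predictor extrapolation, no
  clamping) and standardized there.  The union is the only symmetric
  choice consistent with comparing niches "given the available
  environment of both species".
* **Null draws resample cells**, not occurrence points: the null is
  "this species' model could have arisen from anywhere in its available
  environment", which is the background test's design.
* **Calibration.** The exchangeable null for this test is a background
  species whose occurrences *are* uniform draws from its own mask; under
  that null the test suite verifies a rejection rate statistically
  indistinguishable from the nominal 5% across 200 seeded replicates.
  (A pair with literally identical occurrence sets is *not* a null case:
  its observed $I$ is exactly 1, above every null replicate, and is
  correctly called conserved — also covered by a test.)
* **Nested niches.** When one species' suitable set sits strictly inside
  the other's, the two directions of the test disagree by design
  (divergent from the broad species' viewpoint, conserved from the
  narrow one's); the acceptance suite plants exactly this geometry and
  checks the asymmetry.

# Two-block PLS and the Rv coefficient

Blocks are column-standardized (correlation mode, the default) or merely
centered (covariance mode).  The cross-block matrix
$R = X_s^\top Y_s/(n-1)$ is decomposed $R = U S V^\top$; latent scores
are $X_s U$ and $Y_s V$, the proportion of covariation carried by
dimension $d$ is $s_d^2 / \sum_j s_j^2$, and $r_d$ is the Pearson
correlation of the paired dimension-$d$ scores.  The Rv coefficient is

$$Rv = \frac{\operatorname{tr}(S_{12} S_{21})}
{\sqrt{\operatorname{tr}(S_{11}^2)\,\operatorname{tr}(S_{22}^2)}} \in [0, 1].$$

Significance permutes the rows of the second block (seeded, `nperm`
default 1000 — enough to resolve p-values near 0.01) and reports
one-tailed upper p-values for Rv, every $s_d$ and every $r_d$.
Proportions inherit their singular value's p-value (a proportion is a
monotone function of its $s_d$ with the others fixed); this is a
documented convention, not an exact identity.

Sign convention: SVD columns are sign-ambiguous, so for each dimension
the largest-magnitude entry of the *concatenated* loading vector
$[u_d; v_d]$ is made positive (ties to the lowest index), flipping
$u_d$ and $v_d$ together — flipping only one block would break
$R = USV^\top$.  This makes results bit-reproducible.

A useful consistency identity for published tables that print only some
dimensions: $\text{prop}_d = \text{prop}_{\text{ref}} \cdot
(s_d/s_{\text{ref}})^2$ (`pls_scaled_proportion()`).

# Continuous-trait models

All models are multivariate normal with mean $z_0 \mathbf 1$ and
covariance $\sigma^2 C(\theta)$, where $C$ is the shared root-to-MRCA
path-length matrix.  $z_0$ (GLS mean) and $\sigma^2$ (ML) are profiled
in closed form; the remaining scalar $\theta$ is optimized by bounded
search (tolerance `1e-8`, endpoints checked):
$\lambda, \kappa \in [0,1]$, $\delta \in (0, 3]$,
$\alpha \in (0, 50/T]$, EB rate $a \in [-10/T, 0)$ with $T$ the tree
depth.  The white model is the iid special case ($C = I$); on an
ultrametric tree $\lambda = 0$ reproduces it exactly and $\lambda = 1$
reproduces Brownian motion — both identities are tested.  Likelihoods go
through a Cholesky factorization and *fail* on non-positive-definite
covariances instead of ridge-repairing them: surfacing pathology beats
masking it.

The fitted model set has seven members.  Trend and drift models are
excluded deliberately: their extra parameters are unidentifiable on
ultrametric trees, which is the only tree shape this pipeline consumes
(inputs are expected ultrametric; `rescale_depth()` handles the common
depth-100 normalization, while penalized-likelihood dating is out of
scope).  Selection uses AICc — with eleven-ish species the small-sample
correction is material — and `model_select()` refuses to rank fits whose
AICc is undefined ($n \le k + 1$); the pipeline skips such models and
records the restriction.

Recovery properties verified at desk scale (200 runs, 128-tip pure-birth
trees): under Brownian simulation the median $\hat\lambda$ exceeds 0.9
and the median rate is within 20% of truth; under iid simulation
$\hat\lambda < 0.1$ in at least 95% of runs and the white model wins the
AICc ranking in the majority — the qualitative signature that licenses
non-phylogenetic analysis of a clade whose traits carry no tree signal.

# Distances and the Mantel test

Niche distances are pairwise Hellinger distances between standardized
surfaces on a common extent; morphological distances are Euclidean in
(optionally column-standardized) trait space.  The Mantel statistic is
the Pearson correlation of strict lower triangles; permutations relabel
the second matrix's rows and columns jointly (999 by default, seeded),
one-tailed upper.  The niche matrix is log-transformed by default —
Hellinger distances compress near their upper bound, and the log
restores resolution among strongly divergent pairs — with the raw scale
available.  For small label sets an exhaustive mode enumerates all
$n!$ relabelings and returns the exact tail fraction (identity
included, so $p \ge 1/n!$).

# Synthetic data: what it emulates and what it does not

* `gen_raster_stack()` — equicorrelated, box-kernel-smoothed Gaussian
  fields standardized per layer.  Smoothing uses truncated moving
  averages (no spectral methods) for portability and exact seeding.
  Negative equicorrelation is rejected for more than two layers
  (infeasible).
* `gen_virtual_species()` — Gaussian response niches:
  suitability $\exp(-\tfrac12 (e-\mu)^\top B^{-1} (e-\mu))$, occurrences
  sampled proportionally and placed at cell centers.  The Gaussian
  design gives differentiable control of niche offsets, hence
  controllable divergence strength for planted-effect tests.
* `sim_traits()` — exact multivariate-normal draws under the stated
  evolutionary model.
* `gen_covarying_blocks()` — a planted latent factor with chosen
  loadings and noise, the ground truth for PLS recovery and calibration.
* `gen_tree()` — unit-rate pure-birth trees, ultrametric by
  construction.

Default study sizes are desk-scale by choice: 48–64 cell grids, 4–10
layers, 20–60 occurrences per species (bracketing the 3–57 range typical
of rare-conifer datasets), 6 species in the default pipeline and up to
128 tips in recovery simulations.  What passing tests on these inputs
shows: the statistics are computed correctly, the randomization tests
hold their nominal levels, planted effects of realistic geometry are
detected with the right directionality.  What they do not show: that any
particular real landscape's spatial autocorrelation, sampling bias, or
trait measurement error is handled — synthetic fields are stationary and
isotropic, occurrences are sampled without observer bias, and traits are
noise-free linear responses.

# Numerical conventions and degenerate inputs

* Grids are cell-centered with corner origins; row 1 is the
  northernmost row; points exactly on cell edges belong to the
  north-west cell, so extraction is deterministic.
* Grid equality is tested to `1e-9` degrees; stacks reject any mismatch.
* Collinear variables are clustered by connected components of the
  "pairwise $r^2$ above threshold" graph (default 0.75) and one
  representative per cluster is kept by an explicit priority ranking
  (default: input order).  Components, unlike greedy pairwise drops,
  make the rule order-invariant; the priority input mirrors the
  expert-knowledge choice the rule cannot algorithmize.  Whether to
  correlate over occurrence-extracted values or whole layers is the
  caller's choice of input table; the pipeline uses the pooled
  occurrence table and documents it.
* Zero-variance columns, all-nodata layers, empty masks, label
  mismatches, missing trait cells and sub-minimum replicate counts are
  all named errors at the earliest stage that can detect them; missing
  trait values can be mean-imputed only by explicit request.
* One master seed drives everything; per-stage seeds are derived by
  hashing stage names (adding a stage never shifts another stage's
  stream), and replicate-level seeds are `seed + r`.

# Known limitations

* GeoTIFF input is recognised but not parsed; layers arrive as ESRI
  ASCII grids (single-band, corner-registered).  No projection or
  resampling: inputs must be co-registered.
* The suitability model is a clean maximum-entropy stand-in, not a
  re-implementation of any particular distribution-modelling program;
  feature classes beyond linear + quadratic are out of scope.
* No identity/equivalency niche test, no phylogenetically corrected
  PLS, no partial Mantel — each omission follows the analysis design
  this package supports rather than gaps to be filled.
* Phylogenetic uncertainty is handled by looping fits over a
  user-supplied tree sample, not by estimating trees.
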