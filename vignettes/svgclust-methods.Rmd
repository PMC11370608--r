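---
title: "Methods: kernel score tests, SVG pattern clustering and spatial domains"
author: "svgclust"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: kernel score tests, SVG pattern clustering and spatial domains}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The model

For one gene, let $y = (y_1,\dots,y_N)$ be its normalized expression over
$N$ spots with coordinates $s_1,\dots,s_N$. svgclust models

$$ y \sim \mathrm{MVN}\!\left(X\beta,\ \sigma_s^2 K + \delta I\right), $$

where $K_{ij} = k(\lVert s_i - s_j \rVert)$ is a spatial kernel, $\delta I$
the non-spatial noise covariance, and $X$ a covariate design — by default
the intercept alone, since cell-type or domain annotations are usually
unavailable or untrusted at spot level. A gene is *spatially variable*
(an SVG) when $\sigma_s^2 > 0$, so detection is the test of
$H_0: \sigma_s^2 = 0$.

## The variance-component score test

We use the canonical score test for a variance component: with null-model
residuals $r = y - X\hat\beta$ and residual variance
$\hat\delta = r^\top r / (N - k)$ (the unbiased divisor, so the
identity-kernel case is exact),

$$ T = \frac{r^\top K r}{\hat\delta}, \qquad
   T \overset{H_0}{\sim} \sum_i \lambda_i \chi^2_{1,i}, $$

where $\lambda_i$ are the eigenvalues of $P_0 K P_0$ and $P_0$ projects off
the column space of $X$. The weighted chi-square tail is evaluated by
numerical inversion of the characteristic function (Imhof's method), with
a Liu-type four-moment approximation as fallback where the inversion fails
or runs out of resolution (below roughly $10^{-8}$; reported p-values are
clamped to $[10^{-300}, 1]$). `davies_tail()` exposes this primitive and
is validated against Monte-Carlo simulation of the quadratic form.

Numerical notes, in decreasing order of visibility:

* **Shared spectra.** For a common design the spectrum is computed once
  per kernel and reused across genes. `kernel_context()` caches a
  truncated eigenbasis of each kernel (components holding all but
  `rank_tol = 1e-8` of the $|\lambda|$ mass); the statistic and its null
  spectrum are both formed in that basis, so the test is exact for the
  truncated kernel, which matches the full kernel to the stated tolerance.
  On smooth 2-D geometries the retained rank is far below $N$ (tens to a
  couple of hundred at $N = 2000$), which is what makes the per-gene
  covariate-adjusted retests affordable.
* **Design-specific spectra without new eigendecompositions.** For a
  design with orthonormal basis $Q$, the nonzero eigenvalues of
  $P_0 K P_0$ equal those of $G^{1/2} \Lambda G^{1/2}$ with
  $G = I - W W^\top$, $W = U^\top Q$ in the cached basis
  $K \approx U \Lambda U^\top$ — an $r \times r$ problem. Tests verify
  agreement with the direct $N \times N$ computation to $10^{-8}$.
* **Batched inversion.** Within one kernel, all genes share the weight
  vector, so the Imhof integrand's transcendental parts are evaluated once
  on a composite-Simpson grid sized to the oscillation count of the
  statistics in a magnitude bucket; each gene then costs one weighted sine
  sum. The batch agrees with the adaptive single-statistic route to about
  $10^{-6}$, and any out-of-range or Liu-discordant value falls back to
  the adaptive route.
* **Moment screens.** Probabilities beyond the inversion's resolution
  (four-moment value below $10^{-9}$) are taken from the moment match
  directly; in the covariate-adjusted retests the same shortcut is applied
  above $0.15$, where the moment match is accurate to a few parts in a
  thousand and no significance decision can change. All
  decision-relevant detection probabilities go through the exact
  inversion.

## The kernel bank

Ten kernels are used per the multi-kernel testing approach common in this
field: five Gaussian, $k(d) = \exp(-d^2/2l^2)$, and five Cosine,
$k(d) = \cos(2\pi d/\varphi)$. The scale parameters are not fixed
constants but the $\{0.1, 0.3, 0.5, 0.7, 0.9\}$ quantiles of the nonzero
pairwise spot distances, shared by both families — reproducible from the
data alone and spanning fine to smooth patterns. Cosine kernels are not
positive semidefinite; the score test does not require that (the null
spectrum simply contains negative weights).

## Combining kernels and selecting SVGs

Per-kernel p-values are combined with the equal-weight Cauchy combination
$T_c = \tfrac1{10}\sum_i \tan((0.5 - p_i)\pi)$,
$p_c = 0.5 - \arctan(T_c)/\pi$, which is valid under arbitrary dependence.
Inputs are clipped to $[10^{-15},\ 1 - 10^{-4}]$: the lower clip bounds
the evidence a single kernel can contribute; the asymmetric upper clip is
deliberate, because the tangent diverges at $p \to 1$ and a single
uninformative kernel at exactly $p = 1$ would otherwise cancel genuine
signal from the remaining kernels. Under the null the clip is active with
probability $10^{-3}$ per gene and leaves calibration intact (the null
suite checks the $p \le 0.05$ rate and Kolmogorov–Smirnov uniformity).

Benjamini–Hochberg is applied to the combined p-values across genes at
FDR level $\alpha = 0.05$ by default; `m1` genes are declared SVGs.

# Pattern clustering of the detected SVGs

If two SVGs follow the same spatial pattern they are correlated, and
adjusting one gene's test for the other should remove its spatial
significance. For every SVG $j$:

1. **Correlated set.** $S_j$ = all other detected SVGs with
   $|\mathrm{cor}| \ge 0.5$ (Pearson by default; Spearman available). The
   threshold is chosen so that correlated modules at the simulator's
   default $\rho = 0.6$ are recovered; it is configurable.
2. **Covariates.** With $|S_j| \le 3$ the member genes themselves
   (centered); otherwise the top $k_j$ principal components of the $S_j$
   submatrix, $k_j$ the smallest number reaching 80% cumulative variance.
   For very large dependency sets only the 30 most-correlated members
   enter the PCA (`max_correlated`): the top-correlated genes dominate the
   leading components, and the cap keeps the per-gene decomposition
   affordable when a module spans hundreds of genes.
3. **Adjusted retest.** The null model is refit with
   $[\,1 \mid \text{covariates}\,]$, kernel spectra are recomputed for
   that design, and the ten score tests are rerun and Cauchy-combined.
   A gene whose residual variance vanishes is *fully explained* and gets
   adjusted $p = 1$.
4. **Unique-pattern flag.** A gene is a unique-pattern singleton when it
   is significant after adjustment (BH over the $m_1$ adjusted p-values at
   the same $\alpha$) *and* its correlated set is empty.
5. **Graph and communities.** Nodes are the SVGs; edges join non-unique
   pairs with $|\mathrm{cor}| \ge$ threshold, weighted by the absolute
   correlation; Leiden community detection (modularity objective,
   resolution 1, fixed seed, parameters untuned) labels the clusters, and
   isolated nodes become singletons.

The design choice in step 4 deserves its own paragraph. Covariates
estimated from correlated peer genes cannot span the shared spatial
pattern exactly: every estimated component carries a noise admixture, so
a few percent of the pattern variance survives the regression. On
thousands of spots the score test reliably detects that leakage, which
means "still significant after adjustment" cannot by itself evidence a
distinct pattern — under that rule the strongest members of a coherent
module are flagged unique and the module fragments. Requiring an empty
correlated set is conservative in the right direction: a genuinely unique
gene that is uncorrelated with every other SVG keeps its flag, while a
gene that was not flagged but has no qualifying edges still ends up a
singleton through the graph. The residual cost — a unique-pattern gene
strongly correlated with a different-pattern module would be absorbed
into that module — is documented as a limitation; the adjusted p-values
remain in the dependency table for inspection.

# Spatial domain detection

Within each gene cluster the expression block is spatially smoothed (each
gene vector replaced by a row-stochastic Gaussian-kernel average over
spots) and reduced by PCA over spots; the per-cluster score blocks are
concatenated and a shared-nearest-neighbor graph over spots (Euclidean
kNN, $k = 10$, Jaccard overlap weights) is clustered — Leiden or Louvain
at resolution 1 when the number of domains is unknown, Walktrap cut at
$k_d$ when it is known. The smoothed-PCA embedding stands behind a
pluggable interface so that any spatially aware dimension-reduction method
can be substituted.

Defaults that matter, with the reasoning:

* **Smoothing bandwidth** defaults to the median distance to the 10th
  nearest neighboring spot — a local spot-spacing scale. A global scale
  such as the median pairwise distance (about half the tissue diameter)
  blurs structures only a few spot spacings wide and empirically destroys
  the downstream spot clustering on layered tissue.
* **Dimensions per cluster: 5.** Genes in one cluster share one spatial
  pattern by construction, so the leading few components carry the
  cluster's structure and later components are noise; aggregating 20 dims
  per cluster measurably diluted the embedding on the layered design. The
  pooled-top-SVG baseline (`pooled_baseline()`), which must summarize
  *all* patterns in a single PCA, keeps the conventional 20 dimensions.
* **Per-block standardization.** Each block is divided by the standard
  deviation of its leading component before concatenation, so a
  1000-gene cluster and a 40-gene cluster enter the spot graph on the
  same footing — unequal representation of minority patterns is the
  failure mode the clustering step exists to fix. Within-block variance
  ordering is preserved.
* **Singleton exclusion** (`min_cluster_size = 2`). A singleton's
  embedding column is one smoothed gene; in noisy data most singletons
  are false discoveries or weakly supported unique patterns, and their
  columns perturb spot neighborhoods. When nothing but singletons exists
  they are used anyway.

# Evaluation metrics

* **ARI** — the permutation-model adjusted Rand index (via `mclust`),
  used both for gene-cluster labels against true pattern groups and for
  domain labels against true layers.
* **PAS** — the fraction of spots whose label differs from at least 6 of
  their 10 Euclidean nearest neighboring spots (ties at the boundary
  distance broken by spot index; data sets of at most 10 spots use all
  other spots with a proportional threshold $\lceil 0.6(N-1)\rceil$).
  Lower is smoother.
* **Empirical power** — per gene, the fraction of replicates in which it
  is declared an SVG.
* **Empirical clustering FDR** — non-spatial genes appearing anywhere in
  the final clustering output (singletons count as output) divided by the
  total genes in that output; 0 when the output is empty.

# The simulation designs

**Pattern-group design** (`simulate_scenario_one()`): 53 genes x 2000
spots uniform on the unit square. Genes g1–g10 are independent noise,
g11–g20 correlated noise (compound symmetry $\rho_{ij} = \rho$ or AR(1)
$\rho_{ij} = \rho^{|i-j|}$; default $\rho = 0.6$), g21–g30/g31–g40/g41–g50
three correlated pattern groups whose spatial means are
$s_g f_p(\text{coords})$ with the effect strength rising linearly from
0.25 to 1.5 noise-sd units across each group, and g51–g53 three single
genes with unique patterns. The six pattern surfaces — a corner hotspot, a
linear gradient, a diagonal streak, an annulus, two opposing hotspots, and
periodic stripes — are fixed analytic functions standardized over the
spots, pairwise distinguishable (absolute correlation below 0.5), and span
the localized/smooth/periodic regimes the kernel bank targets. Each gene
is standardized; coordinates can be shared across replicates so kernel
spectra are computed once, with replicate randomness entering only
through the expression noise.

**Layered design** (`simulate_layered()`): grid spots partitioned into 5
parallel sinusoidally curved strata (4 cortex-like layers over a
white-matter-like band, widths 0.25/0.15/0.15/0.15/0.30 of the tissue
height). By default 2000 of 4865 genes become SVGs in three
domain-specific clusters (800 elevated in layer 1, 150 across layers 2–4
with a random primary layer carrying the full effect, 1050 in the
white-matter band); per-gene baseline means and noise variances are drawn
from log-normal distributions to emulate the spread of filtered cortex
data, effects are 2–3.5 noise-sd units, and each cluster shares a
non-spatial latent factor so within-cluster correlations resemble
co-regulated marker genes rather than being induced by the spatial mean
alone. The test suite runs this design reduced to 1500 spots and 1200
genes with proportionally scaled cluster sizes (197/37/259).

**Null design** (`simulate_null()`): i.i.d. standard normal expression,
for type-I-error calibration.

What the generators deliberately do *not* emulate: count noise
(Poisson/negative-binomial sampling, zero inflation), library-size
artifacts, hexagonal capture geometry, segmentation errors, or spatial
correlation in the non-signal noise. Passing tests therefore demonstrate
correctness of the statistics and the claimed orderings under Gaussian
noise with known structure, not end-to-end performance on raw counts —
raw counts should be filtered and log-normalized first
(`normalize_and_filter()`).

# Problem sizes used by the test suite

The packaged tests run 50 pattern-group replicates (53 x 2000, shared
coordinates) for the power/FDR/ARI study, 10 layered replicates at
1500 spots x 1200 genes for the domain-detection comparison, a 500 x 400
null calibration, and a 20-case x 1e6-draw Monte-Carlo check of the
quadratic-form tail; these sizes keep the full suite in the tens of
minutes on one CPU while leaving the Monte-Carlo error well below the
tolerances being asserted.

# Known limitations

* The score test treats $\hat\delta$ as fixed; at the spot counts used
  here the effect on calibration is within the tolerances verified by the
  null suite.
* A unique-pattern gene strongly correlated with a different-pattern
  module is absorbed into that module (see the unique-flag discussion).
* The smoothed-PCA embedding is a deliberate approximation of spatially
  aware dimension reduction, exposed behind an interface where a full
  probabilistic spatial factor model could be substituted.
* Covariates beyond the intercept are supported structurally in
  `detect_svgs()` but not exercised by the shipped simulations.
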