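---
title: "Particle measures, kernel norms, and diffeomorphic mapping in varimap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Particle measures, kernel norms, and diffeomorphic mapping in varimap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(varimap)
```

## The data model

Spatial-omics technologies report detections — mRNA transcripts, typed
cells — as points in tissue with one categorical feature per point.  A
tissue atlas reports the complementary object: a dense labeling of space by
region.  `varimap` represents both as *particle measures*

$$\mu = \sum_i w_i\,\delta_{x_i} \otimes p_i,$$

a weighted sum of point masses at positions $x_i \in \mathbb{R}^3$
(micrometers), each paired with a probability distribution $p_i$ over a
finite feature space $\mathcal F$ (genes, cell types, or atlas regions).
Mass lives in the weights: a detection table becomes a measure with
$w_i = 1$ per detection and one-hot $p_i$
(`empirical_measure_from_points()`), an atlas volume becomes one with
$w_i$ the foreground volume per cell and $p_i$ the per-cell label fractions
(`volume_to_particles()`).  2D sections are embedded in 3D with the section
plane as the third coordinate.  Per-detection mass defaults to 1; scaling
by section thickness is an explicit option (`section_weight`), since
whether slice spacing should scale mass depends on the acquisition design.

Closeness of two measures is the squared norm induced by the inner product

$$\langle\mu,\nu\rangle = \sum_{i,j} w_i w_j\,
  K_\sigma(x_i,x_j) \sum_{f,g} K_F(f,g)\, p_i(f)\, p_j(g),$$

a product of a spatial kernel (Gaussian or sum of Gaussians, unit peak per
component times an amplitude) and a feature kernel.  The feature kernel
defaults to the identity $K_F(f,g) = 1\{f = g\}$ for categorical features;
a Euclidean product on numeric feature values is available but off by
default.  Kernel amplitudes are *unit-peak* (not unit-integral): the
kernel at zero separation equals the sum of component amplitudes.  All
kernel sums run in double precision and squared distances are clamped at
zero on return to absorb cancellation between the three $O(N^2)$ sums.
No mass normalization between $\mu$ and $\nu$ is applied by default — the
censoring and latent-law machinery is what handles mass mismatch — though
`scale_mass()` exists for diagnostics.

## Diffeomorphic action and geodesic shooting

A smooth invertible map $\varphi$ transports a measure by moving positions
and scaling masses by the local Jacobian determinant,
$\varphi\cdot\mu = \sum_i |D\varphi|(x_i)\, w_i\, \delta_{\varphi(x_i)}
\otimes p_i$ (`apply_diffeo()`).  Flows of such maps are generated by
time-dependent velocity fields in a reproducing-kernel space $V$; the
registration objective is

$$\tfrac12\int_0^1\|v_t\|_V^2\,dt + \lambda\,
  \|\varphi_1\cdot\mu - \mu'\|^2_M.$$

In geodesic shooting the whole flow is parameterized by initial momenta —
a 3-vector $\rho^x_i$ and a scalar mass momentum $\rho^w_i$ per atlas
particle — and the states evolve by the Hamiltonian system whose velocity
field is

$$v(x) = \sum_i k_\sigma(x, x_i)\rho^x_i +
  \frac{x - x_i}{\sigma^2}\, w_i \rho^w_i\, k_\sigma(x, x_i),$$

with $\dot x_i = v(x_i)$, $\dot w_i = (\nabla\!\cdot\! v)(x_i)\, w_i$, and
$\dot\rho = -\nabla_q H$.  For sum-of-Gaussian kernels each component
contributes with its own $\sigma$ in every term.  Implementation choices:

* **Closed-form dynamics.**  The divergence and both momentum equations
  are derived analytically from the Hamiltonian
  $H = \tfrac12\sum_i [\rho^x_i\!\cdot\! v(x_i) + \rho^w_i w_i
  (\nabla\!\cdot\! v)(x_i)]$; the test suite validates every channel
  against central finite differences of $H$ and the divergence against a
  finite-difference divergence of the field.
* **Integrator.**  Fixed-step RK4 with `n_steps = 10` by default; forward
  Euler is kept purely as a cross-check.  Hamiltonian conservation along
  the path is the running accuracy diagnostic: observed drift is
  fourth-order in the step size (about $6\times10^{-7}$ relative at 20
  steps on 5-particle systems).
* **Outer optimization.**  Momenta (and optional similitude) are estimated
  with L-BFGS-B using finite-difference gradients.  No automatic
  differentiation is used anywhere in the package; consequently the
  intended operating envelope for the *fitting* functions is desk-scale
  (atlas particle counts in the tens to low hundreds), while the norm,
  resampling and scoring machinery handles thousands of particles
  comfortably.  A diverging trial step during line search receives a large
  finite penalty so the optimizer backs off instead of aborting.
* **Kinetic/data trade-off.**  The balance between deformation cost and
  matching term is implicit in the velocity-kernel amplitude (a larger
  amplitude makes deformation cheaper) plus an explicit `data_weight`
  multiplier defaulting to 1.  The synthetic recovery experiments in the
  tests use $\sigma_V = 20\,\mu m$, amplitude 400 and `data_weight = 10`,
  chosen by scale analysis so that the optimum is residual-dominated: with
  order-1 particle masses and order-$10\,\mu m$ displacements the kinetic
  term would otherwise bias endpoints measurably toward the atlas.
* **Similitude.**  A global rotation + translation + isotropic scale
  (rotation via a Rodrigues vector, scale via its logarithm) can be
  estimated in a first stage with momenta frozen, then held fixed — the
  coarse-then-fine convention.  Joint estimation is deliberately not the
  default; per-axis scaling is out of scope.

## Cross-modality mapping with latent feature laws

An atlas knows regions $\ell \in \mathcal L$, a target knows genes or cell
types $f \in \mathcal F$.  They are bridged by latent non-normalized laws
$p_\ell(f)$, assumed stationary over each region: atlas particle $i$ with
memberships $\pi_i(\ell)$ induces the measure
$\mu_A^p = \sum_i w_i \delta_{x_i} \otimes \sum_\ell \pi_i(\ell) p_\ell$.
Because the laws are non-normalized, the law mass multiplies the particle
weight and the conditional distribution is renormalized
(`induced_measure()`).  The joint objective adds to the kinetic and
matching terms a KL prior per region,

$$J_{KL}(p_\ell) = \frac{M^A_\ell}{\sum_f M^T_f} \sum_f p_\ell(f)
  \log\frac{\bar p_\ell(f)}{1/|\mathcal F|},$$

with $M^A_\ell$ the region's deformed (and censored) atlas mass —
recomputed at every objective evaluation — and $M^T_f$ the target's
feature masses.  The mass ratio is used verbatim as the prior weight; no
extra global multiplier is introduced.  Positivity $p_\ell > 0$ is
maintained by an elementwise softplus parameterization of free variables.
Laws initialize uniform with total mass matched to the target, so the fit
starts mass-balanced rather than from an arbitrary scale.  Zero-mass
regions contribute zero to the prior by convention.

Gross pose ambiguity is resolved by `rotation_sweep_objective()`: rotate
the atlas about its centroid by each candidate angle, re-fit the laws under
a frozen identity flow, and take the argmin objective.  On the bundled toy
fixture (`make_fig2_toy()`: a square atlas of three rectangular regions
against a two-feature black/white target laid out to correspond only under
a half-turn) the sweep selects 180 degrees by two to three orders of
magnitude in the objective.  The exact rectangle proportions of the fixture
are a frozen package convention; any layout with homogeneous-region
correspondence under the half-turn and none under the other quarter-turns
would serve.

## Censoring: partial-volume targets

Experiments measure subvolumes; atlases cover wholes.  A censor field
$\alpha_\lambda:\mathbb{R}^3\to[0,1]$, defined in *target* coordinates,
punctures the deforming atlas:
$\sum_i \alpha_\lambda(\varphi(x_i))|D\varphi|(x_i) w_i
\delta_{\varphi(x_i)}\otimes p_i$ (`censored_action()`).  Two forms:

* **Planar** (`planar_censor()`): the mean of two tanh fronts anchored on
  the first and last section planes with interior-pointing normals — for
  stacks truncated along the sectioning axis.  A single bandwidth
  $\lambda$ is shared by both fronts (separate bandwidths would double the
  parameter for no observed benefit on slab-shaped supports).
* **Dense classifier** (`fit_mlp_support()`): for irregular boundaries
  (hemi-sections), a small fully connected network on coordinates — layers
  $3\times15$ and $15\times5$ with exponential-linear activations, then
  $5\times1$ with a tanh output shifted and rescaled to $[0,1]$ via
  $(\tanh(z/\lambda)+1)/2$.  It is trained to separate measured particles
  (label 1) from user-supplied boundary particles and synthetic
  rostral/caudal cap sections (label 0), with the minority class
  up-weighted 1000:1, full-batch Adam, 500 epochs by default, and a seeded
  deterministic initialization.  Boundary points come from a CSV; there is
  no automatic medial-edge detection.  This is a coordinate-space
  classifier, not an image-space segmenter; convolutional architectures
  are out of scope.

The bandwidth joins the mapping optimization with the penalty
$J_s(\lambda) = u\ln u + 1 - u$, $u = \lambda^2/0.1$, zero at
$\lambda^2 = 0.1$.  The reference constant is dimensionless, so a unit
convention is required: the penalty treats $\lambda$ in millimeters
(minimum at a $\approx 316\,\mu m$ transition zone, a plausible
smoothness for brain-scale stacks), configurable via `unit = "um"`.

## Rigid pre-alignment of section stacks

Within a stack, each interior section gets an in-plane rotation and
translation minimizing the summed pairwise varifold distance between
adjacent sections; the first and last sections are pinned (otherwise a
global motion is free), and sections are centered at their mass centroids
first.  Optimization starts from zero motion — with an optional multi-start
over quarter-turns for gross flips — and uses central finite differences
(the parameter count is just 3 per interior section).  Convergence is
L-BFGS's relative-improvement criterion with a 500-iteration cap.  For
symmetric sections the deterministic optimizer path from the zero start
defines the answer; stacks whose *endpoint* sections are corrupted are the
caller's responsibility.  The in-plane distance deliberately ignores the
stacking coordinate, which would only contribute a constant attenuation
between adjacent planes.

## Scale-space resampling

The closest fixed-complexity measure to a high-resolution measure in the
varifold norm, at scale $\sigma$ (`optimize_approximation()`):

1. **Initialize** on a lattice of cubes with edge $\sigma$ (half-open
   intervals anchored at the bounding-box minimum): one particle per
   occupied cube at a seeded-random member particle's position, cube mass
   as weight, uniform feature distribution.
2. **Stage 1**: optimize weights and distributions with positions fixed
   (200 L-BFGS iterations by default).
3. **Stage 2**: optimize positions, weights and distributions jointly
   (another 200).

The approximation metric's spatial bandwidth is tied to $\sigma$ — one
scale per approximation level — and the same kernel is used in both stages
and for reported distances.  Gradients here are fully analytic (the
objective is quadratic in the weighted features), chained through a
softplus for weights and a row-softmax for the simplex rows.  Kernel terms
beyond $4\sigma$ are zeroed; the truncated sums agree with exact ones to
better than $10^{-6}$ relative.  Inputs too large for one quadratic
objective can be halved or quartered at weighted medians along the
longest axes and approximated independently (`split` in
`approx_config()`).  Each scale is fit independently; a simultaneous
multi-scale cascade is future work, not implemented.

Two baselines exist for comparison, not production use: Lloyd k-means on
positions (`kmeans_baseline()`, via `stats::kmeans`) and kernel
redistribution onto cube centers (`grid_baseline()`).  Both ignore the
feature axis when placing particles, and on feature-striped toys the
optimized approximation achieves severalfold smaller varifold distance at
matched particle count.

## Mutual-information feature selection

A feature is spatially informative if, within a local neighborhood, which
half of the neighborhood a subregion falls in predicts the feature's local
abundance.  Per section and feature: counts on a $\sigma\times\sigma$
grid ($\sigma = 50\,\mu m$ default, half-open square membership), quantile
binning by $t_k = \inf\{t \ge 0: F(t)\ge k/q\}$, then the conditional
mutual information $I(X; M \mid C)$ over uniformly drawn (megasquare,
square, split direction) triples, where megasquares are $2K\times 2K$
blocks split into vertical or horizontal halves.  Defaults $q = 10$,
$K = 4$ ($400\,\mu m$ neighborhoods at the default $\sigma$) are package
conventions, reported in output metadata.  All blocks at stride 1 are
enumerated; stride is configurable for speed.  Squares with zero total
count across all features are out-of-support, and megasquares need at
least half their squares in support.  Binning and scoring are per-section
(scores are defined sectionwise) and aggregate across a stack by
summation.  Scores are reported both in nats and scaled by the draw count
$|\Omega|$, since large-data uses of such scores are often reported on the
count scale.  Decoy features (default label pattern `^BLANK`) are scored
like any other and flagged.  Selection is greedy and independent per
feature; joint selection over pairs or triples is out of scope.

## Synthetic data: what it emulates, what it does not

`make_fig2_toy()` freezes the cross-modality toy; `make_warped_pair()`
produces atlas/target pairs under analytic warps (identity, translation,
radial expansion $x \mapsto c + (x-c)(1+\epsilon r)$ with Jacobian
determinant $(1+2\epsilon r)(1+\epsilon r)^2$, default
$\epsilon = 0.002\,\mu m^{-1}$ — about a 20% peak volume change over a
$40\,\mu m$ cloud); `make_censored_stack()` builds serial stacks with known
jitter, rostral/caudal truncation and hemi cuts, sharing one point
constellation across sections by default so injected motions are exactly
recoverable.  These fixtures exercise geometry, mass transport, censoring
and feature logic, but they are noiseless beyond sampling: no detection
noise model beyond Poisson-like thinning, no segmentation error, no
cell-typing error, no section-dependent feature drift.  Passing tests
demonstrate correctness of the machinery, not performance on real MERFISH
or BARseq data.

## Problem sizes and numerical conventions

Test and example problem sizes — 5-particle Hamiltonian checks, 12-particle
recovery fits, 300-particle resampling toys, $8\times 8$ MI grids — are
chosen so the whole suite runs in minutes on one CPU while every check
remains non-trivial (each has a brute-force or closed-form oracle at the
same size).  Other conventions: empty measures are legal with norm 0;
duplicate detection coordinates are allowed; ties in feature ranking break
lexicographically; kernel distance clamping at zero; all stochastic entry
points (`seed` arguments) are deterministic under a fixed seed, and none
introduces randomness by default.

## Known limitations

* Finite-difference outer gradients cap practical momenta counts; a few
  hundred atlas particles per fit is the comfortable envelope.
* The censor classifier's decision surface is only as good as the supplied
  boundary points; 15–20 per section is the intended density.
* Quantile binning with heavily tied counts (sparse genes) collapses bins,
  deflating MI scores for very sparse features — by construction, not
  accident.
* Serialization uses plain-text containers; they are exact for the data
  sizes intended but not compact for millions of particles.
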