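---
title: "Methods: likelihood-free posterior estimation for multi-fiber diffusion MRI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: likelihood-free posterior estimation for multi-fiber diffusion MRI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dmripost)
```

# The inverse problem

Each white-matter voxel may contain up to three crossing fiber
populations. The measured diffusion-weighted signal mixes their
contributions nonlinearly, and at realistic noise levels the inverse
problem is ill-posed: distinct parameter configurations explain the
data almost equally well. `dmripost` implements a simulation-based
(likelihood-free) treatment of this problem:

1. a **forward model** simulates signals from known parameters;
2. a **convolutional classifier** estimates the number of fibers per
   voxel from a 2-D image of the orientation distribution function
   (ODF);
3. a **mixture-density network (MDN)** per fiber count maps the same
   image to a full posterior distribution over all model parameters;
4. the **unscented transform** propagates that posterior into derived
   microstructure measures, yielding uncertainties instead of bare
   point estimates.

# Forward model

For a voxel with $n$ fibers, unit gradient direction $u$ and b-value
$b$, the normalized signal is the biexponential multi-tensor

$$
S(b, u) = \frac{1}{n} \sum_{i=1}^{n}
  \left[ w_i \, e^{-b\, u^\top D_i u}
  + (1 - w_i)\, e^{-b\, u^\top \bar D_i u} \right],
$$

with a fast tensor $D_i$ and a slow tensor $\bar D_i$ per fiber,
both cylindrically symmetric about the fiber axis
$m(\theta_i, \varphi_i)$:
$D_i = \lambda_{1i}\, m m^\top + \lambda_{2i} (I - m m^\top)$ and
analogously $\bar D_i$ with $(\lambda_{3i}, \lambda_{4i})$. The
$1/n$ prefactor normalizes $S(0) = 1$ regardless of the fiber count.
The fast fraction is fixed at $w = 0.7$. Each fiber contributes six
free parameters $x_i = [\theta_i, \varphi_i, \lambda_{1i}, \lambda_{2i},
\lambda_{3i}, \lambda_{4i}]$ and the voxel parameter vector
$\alpha = [x_1, \dots, x_n]$ has dimension $6n$.

Units: b-values in s/mm² multiplied by eigenvalues in μm²/ms are made
dimensionless by a factor of $10^{-3}$ inside the kernel, so at
$b = 1000$ and $\lambda_1 = 2$ the fast attenuation along the fiber is
exactly $e^{-2}$.

```{r forward}
vp <- voxel_params(list(fiber_params(0, 0, 2, 0.5, 0.5, 0.2)))
sch <- acquisition_scheme(rbind(c(0, 0, 1)), 1000)
simulate_signal(vp, sch)$values
0.7 * exp(-2) + 0.3 * exp(-0.5)
```

Both angles are restricted to $[0, \pi]$: diffusion is antipodally
symmetric, so fiber orientations are axes, and this half-range gives
each axis a unique representative.

**Exchange symmetry.** The signal is invariant under any permutation
of the fibers (implemented so the invariance is bit-exact), so the
true posterior has at least $n!$ symmetric modes.
`count_equivalent_permutations()` verifies the count 1/2/6 by direct
simulation; it motivates the MDN component floors below.

## Priors and the synthetic acquisition

Training and evaluation data are drawn from uniform priors with
rejection: fast eigenvalues in $[1, 3]$ μm²/ms, slow in
$[0.1, 0.6]$ μm²/ms, fast-tensor FA above 0.2 for every fiber when
$n \ge 2$, and minimum pairwise crossing angles of 10° ($n = 2$) and
45° ($n = 3$). The synthetic protocol emulates an HCP-style
acquisition — 90 directions at each of $b = 1000, 2000, 3000$ s/mm² —
with zero-mean Gaussian noise $\sigma = 0.04$ (average SNR ≈ 3;
Gaussian is an adequate approximation of Rician magnitude noise at
this level).

# ODF maps

Per shell, the signal is fit with the even real symmetric spherical
harmonic (SH) basis up to degree $L = 8$ (45 coefficients) by
regularized least squares with a Laplace–Beltrami penalty
($\lambda = 6\times10^{-3}$, weights $(l(l+1))^2$). The q-ball ODF is
obtained analytically through the Funk–Radon transform, which is
diagonal in the SH basis with eigenvalues $2\pi P_l(0)$. The ODF of
each shell is evaluated on a $32 \times 32$ grid (rows: $\theta \in
[0, \pi]$; columns: $\varphi \in [0, 2\pi)$) and min–max normalized
per channel, producing the $32 \times 32 \times 3$ image that both
networks consume. A constant (isotropic) channel is mapped to zeros.
`find_peaks()` extracts local ODF maxima with antipodal folding and a
merge radius, for inspection and classical peak-based analyses.

# Fiber-count classifier

The classifier is a small CNN: two stages of (5×5 convolution,
6 feature maps, zero-padding 4, ReLU, 2×2 max pooling of stride 2) —
flattening to $11 \times 11 \times 6 = 726$ — followed by fully
connected layers of widths 1000, 500, 84 and a head 64–32–16–3, with
a softmax cross-entropy loss. The reference recipe trains with SGD
(momentum 0.95, learning rate $10^{-4}$); `classifier_config()` also
offers Adam, which reaches useful accuracy within minutes on one CPU
and is used by the desk-scale configurations. A 10% validation split
is scored each epoch and the best-validation weights are restored.

Because no deep-learning framework is available in the target R
environment, the package carries its own minimal engine (im2col
convolution, pooling, dense layers, SGD/Adam) with compiled kernels;
every analytic gradient is checked against finite differences in the
test suite.

# Posterior networks

One MDN per fiber count maps the ODF image to a Gaussian mixture over
$\alpha$:

$$ q_\psi(\alpha) = \sum_{i=1}^{m} w_i \,
   \mathcal N(\alpha;\ \mu_i, \Sigma_i), $$

with $m = 5$ components for $n \in \{1, 2\}$ and $m = 10$ for $n = 3$
(at least $n!$ is required by the exchange symmetry). The network
emits, per component, a weight logit, a mean, and a packed
lower-triangular Cholesky factor whose diagonal passes through a
softplus (plus a small floor), which guarantees a valid positive
definite covariance for any output. Parameters are standardized to
$[-1, 1]$ using the prior bounds; means and covariances are mapped
back to natural units on the way out.

Training is single-round neural posterior estimation with the prior
as proposal: parameters are drawn from the prior, signals simulated
and rendered, and the loss is the negative mean log mixture density
of the true parameters (`snpe_loss()` documents the equivalence).
Gradients of the loss with respect to all head outputs are computed
analytically in compiled code.

Two presets are exposed:

* **full** — the reference recipe: classifier-style trunk
  (padding 4), seven fully connected layers of width 1000, Adam at
  $5\times10^{-5}$, batch 100, early stopping with patience 30 on a
  10% validation split, $2\times10^6$ simulated samples. This is a
  GPU-days workload and is supported by configuration, not run by the
  tests.
* **desk** — same architecture family at laptop scale: compact trunk
  (padding 0, flatten $5 \times 5 \times 6 = 150$), hidden width 128,
  Adam at $10^{-3}$, patience 8, tens of thousands of samples.
  Desk-scale runs demonstrate the method end-to-end in minutes on one
  CPU; they are not expected to reach the full-scale accuracy bounds
  recorded in `full_scale_bounds()`.

## Point estimates and the dominant component

The point estimate is the mean of the *dominant* mixture component,
selected by $\delta_i = w_i \cdot \mathrm{trace}(\Sigma_i^{1/2})$
(principal matrix square root), i.e. the component carrying the most
probability mass spread; per-parameter uncertainties are the square
roots of its covariance diagonal. Whether the trace factor should
reward or penalize spread is an open modelling question, so the
alternative $w_i / \mathrm{trace}(\Sigma_i^{1/2})$ is available as
`select_dominant_component(rule = "inverse")`; both reduce to
$\arg\max w_i$ when the component covariances are equal.

# Derived measures and uncertainty propagation

Closed forms in the eigenvalues (fast fraction $w$, $n$ fibers):

* fast-tensor FA:
  $\sqrt{(\lambda_1-\lambda_2)^2 / (\lambda_1^2 + 2\lambda_2^2)}$;
* fast-tensor MD: $(\lambda_1 + 2\lambda_2)/3$;
* MSD: $\frac{\pi^2}{n} \sum_i [\, w (\lambda_{1i} + 2\lambda_{2i})
  + (1-w)(\lambda_{3i} + 2\lambda_{4i})\,]$;
* RTOP: $\frac{2\pi^{3/2}}{n} \sum_i [\, w / (\lambda_{2i}
  \sqrt{\lambda_{1i}}) + (1-w)/(\lambda_{4i}\sqrt{\lambda_{3i}})\,]$,
  the compartment-weighted inverse square-root determinant of the
  cylindrical tensors ($\det D = \lambda_1 \lambda_2^2$).

GFA is a signal-domain measure, std(S)/rms(S) on the $b = 1000$
shell; the package uses the population (divide-by-N) standard
deviation so that $\mathrm{GFA}^2 = 1 - \overline S^2 /
\overline{S^2}$ holds exactly and GFA ≤ 1 (`type = "sample"` is
available).

`posterior_measure()` propagates the dominant component through a
measure with the symmetric unscented transform: $2d + 1$ sigma
points, spread $\kappa = 3 - d$, weights $\kappa/(d+\kappa)$ and
$1/(2(d+\kappa))$; sigma points falling below a lower bound are
reflected into the feasible region and counted. The transform is
exact for affine maps, which the test suite asserts, and it is
compared against Monte-Carlo propagation for every measure. Maps from
multiple estimates can be pooled with the inverse-variance weighted
mean (`variance_weighted_mean()`).

# Baselines and evaluation

`baseline_fit()` provides classical nonlinear least squares on the
same forward model via Levenberg–Marquardt with random prior-drawn
restarts: `"LM"` is unbounded, `"TRF"` is the bound-constrained
variant on the prior box (the environment has no trust-region
reflective solver; bounded LM fills that role). Every restart's
endpoint is kept, which directly exposes the multi-modality of the
inverse problem — restarts from different basins return different
solutions of nearly equal residual.

Evaluation utilities: fiber-matched angular error (best permutation
over $n!$ assignments of $\arccos|\langle \hat m, m\rangle|$),
eigenvalue error after the same matching, signal NMSE, binned error
sweeps over FA / GFA / crossing angle / $\lambda_1$
(`run_sweep()`), and the fast/slow weight-mismatch robustness
experiment (`weight_mismatch_experiment()`), which trains or
configures an estimator at $w = 0.7$ and tests it at
$w \in \{0.5, \dots, 0.9\}$.

# Limitations

* Desk-scale networks demonstrate the pipeline; quantitative accuracy
  at the level of `full_scale_bounds()` requires the full recipe.
* The forward model assumes cylindrically symmetric compartments and
  a fixed fast fraction; gray-matter water exchange is out of scope.
* Gaussian noise is assumed throughout; at SNR well below 3 the
  Rician floor is no longer negligible.
* The well-separated sanity protocol caps the attainable fast-tensor
  FA at $\approx 0.603$ because the fast eigenvalue prior is bounded
  by $[1, 3]$; its FA floor is set accordingly.
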