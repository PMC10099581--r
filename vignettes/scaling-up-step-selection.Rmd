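---
title: "From step-selection kernels to space-use patterns: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From step-selection kernels to space-use patterns: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stepscale)
```

## The model

Step selection analysis parametrises a one-step movement kernel: the
probability density that an animal at location $x$ (having arrived on
bearing $\alpha$) is at $z$ one step of duration $\tau$ later is

$$
p_\tau(z \mid x, \alpha, t) \;=\;
\frac{\psi_\tau(|z - x|, \alpha)\,
      \exp\{\beta \cdot Z(x, z, t)\}}
     {\int_\Omega \psi_\tau(|z' - x|, \alpha)\,
      \exp\{\beta \cdot Z(x, z', t)\}\, dz'},
$$

where $\psi_\tau$ is a *selection-free* kernel describing intrinsic
movement ability (step lengths, and optionally turn angles), $Z$ is a
vector of movement covariates, $\beta$ their selection strengths, and
$\Omega$ a bounded study area. The kernel is truncated at the boundary of
$\Omega$ — a "no go" condition: no probability mass ever leaves the study
area. This package consumes $\beta$; estimating it from telemetry data is
the job of conditional-logistic step-selection fitting tools and is out of
scope here.

Everything else in the package is machinery for *scaling up* this
single-step model to long-run space-use patterns:

* **Master equation.** On a raster discretisation $S$ of $\Omega$,
  propagation is a column-stochastic matrix product
  $U(s, t + \tau) = \sum_{s'} P_\tau(s \mid s')\, U(s', t)$, where column
  $s'$ of $P$ is the kernel evaluated from the centre of cell $s'$
  (`build_transition_matrix()`, `propagate()`).
* **Steady states.** The fixed point $U^* = P U^*$ is found by power
  iteration (`steady_state_fixed_point()`) or as the eigenvalue-1
  eigenvector (`steady_state_eigen()`).
* **Closed forms.** For kernels whose covariates depend only on the step
  end point ($Z_i(x,z,t) = \tilde Z_i(z)$) and whose $\psi_\tau$ is
  radially symmetric, the steady state has the closed form
  $u^*(x) \propto e^{\beta \cdot \tilde Z(x)}
  \int_\Omega e^{\beta \cdot \tilde Z(z)} \psi_\tau(|x - z|)\, dz$
  (`steady_state_barnett_moorcroft()`), with two limits: a uniform
  $\psi_\tau$ gives the classical resource-selection form
  $u^* \propto e^{\beta \cdot \tilde Z}$ (`steady_state_rsf()`), and an
  arbitrarily narrow $\psi_\tau$ gives
  $u^* \propto e^{2\beta \cdot \tilde Z}$ (`steady_state_doubled()`) —
  the effect of selection on space use doubles as the selection scale
  shrinks. The same factor of two appears in the drift term of the
  small-step advection–diffusion approximation, whose diffusion constant
  `diffusion_constant()` computes.
* **Individual-based simulation.** `simulate_movement()` draws stochastic
  realisations of one or many kernels, including animals coupled through
  each other's occurrence distributions and correlated movement
  ($\kappa > 0$), neither of which the linear steady-state theory can
  handle.
* **Metrics.** `bhattacharyya_affinity()`, `locational_variance()`,
  `ud_size_ratio()` and `segregation_index()` quantify overlap and size
  agreement between distributions, for goodness-of-fit comparisons of
  data against model output.

### A worked discrete identity

On the discretised grid the closed form is not merely approximate: with
end-point-only covariates the chain
$P(s \mid s') \propto \psi(|s - s'|) e^{\beta \tilde Z(s)}$ satisfies
detailed-balance-like cancellation, and
$U^*(s) \propto e^{\beta \tilde Z(s)} \sum_z e^{\beta \tilde Z(z)}
\psi(|s - z|)$ is its *exact* stationary distribution. The package's
tests exploit this: the closed form and power iteration agree to solver
tolerance (around $10^{-10}$ in L1 on a $20 \times 20$ grid), far inside
the $10^{-3}$ one would accept from discretisation arguments alone.

## Parameters that matter

| parameter | meaning | units | default |
|---|---|---|---|
| `rate` ($\lambda$) | exponential step-length decay | 1/length | — |
| `sd` | Gaussian step-length scale | length | — |
| `kappa` ($\kappa$) | turn-angle concentration | — | 0 |
| `tau` ($\tau$) | step duration | time | 1 |
| `beta` ($\beta$) | selection strength per covariate | per covariate unit | — |
| `od_bandwidth` | OD smoothing bandwidth | length | 2 cell units |
| `od_window` | steps contributing to an OD | steps | 500 |
| `stepping_stones_per_step` | path interpolation density | points/step | 10 |
| `od_update_interval` | steps between OD refreshes | steps | 1 |
| `tol` | steady-state L1 residual | — | $10^{-10}$ |
| `max_iter` | power-iteration cap | — | $10^6$ |

Coordinates are continuous in cell-size units with the origin at the
lower-left corner; cell $(i, j)$ covers a half-open unit square, and a
point maps to the cell containing it. Trajectory times are step indices
times $\tau$; bearings are radians clockwise from north. Distances are
Euclidean between cell centres; the integral in the kernel's normalising
constant uses the midpoint rule (cell centres times cell area), which
keeps transition matrices exactly column-stochastic after normalisation.

A note on $\beta$ for occurrence-distribution covariates: ODs here are
cell *masses* summing to 1, so their numerical range shrinks with grid
size (peak values around $10^{-2}$ on a $20 \times 20$ grid). An
interaction coefficient must be read against that scale — "strong
avoidance" means $\beta_{j,j'} \times \mathrm{range}(O_{j'})$ of order
one or more on the log-weight scale, which on such grids puts useful
coefficients in the tens to hundreds.

## The synthetic landscape generator

`generate_resource_layer()` draws Gaussian white noise, low-pass filters
it with a periodic Gaussian kernel of standard deviation `smoothness`
cells (via the FFT), and rescales to $[0, 1]$. This emulates the one
property the downstream mathematics cares about — a smooth, bounded,
spatially autocorrelated habitat-quality field — and nothing else. It
does not emulate: anisotropy, linear features (rivers, roads), habitat
classes with sharp boundaries, temporal change, or any observation noise.
Tests passing on these fields therefore demonstrate the correctness of
the scaling-up machinery, not robustness of any inference to real-world
landscape structure. Because the range is fixed to $[0, 1]$, smoothness
manifests as reduced *normalised roughness* (neighbour differences
relative to the field's spread) rather than reduced variance.

## Numerical choices

* **Overflow safety.** Kernel weights are computed as
  $\psi \cdot e^{\beta Z - \max(\beta Z)}$; the shift cancels on
  normalisation and is added back analytically in
  `normalising_constant()`.
* **The delta (stay-in-place) family** is implemented by cell
  containment, not by a length threshold: after within-cell jitter, the
  distance to one's own cell centre can exceed the distance to a
  neighbour's, so a radius test would be wrong.
* **Closed-form inner integral.** $\psi$ is truncated where it falls
  below $10^{-12}$ of $\psi(0)$; inside that radius the full dense
  distance matrix is used when it fits, otherwise a per-cell loop.
* **Turn angles.** A von Mises-style factor
  $e^{\kappa \cos(\theta - \alpha)}$ multiplies $\psi$; the factor is 1
  for the zero-length step, where no direction is defined. The
  master-equation engine rejects $\kappa > 0$ (its state space has no
  bearing component); the simulator handles it.
* **Steady-state solvers.** Power iteration reports its iteration count
  and final L1 residual and flags non-convergence instead of erroring —
  oscillatory long-time behaviour is a legitimate scientific outcome.
  The eigen route warns when eigenvalue 1 is degenerate (disconnected
  chain), clips eigenvector noise below $10^{-12}$, and renormalises.
* **Boundary effects.** With a finite-width $\psi$, the no-go truncation
  makes the steady state dip at the study-area edge even with $\beta = 0$
  (edge cells lose reachable neighbours). This is a real property of the
  model, not an artefact; it vanishes as $\psi$ flattens. Keep the UD
  small at the boundary when comparing against data.
* **Simulation sampling** is exact categorical over cells followed by a
  uniform within-cell jitter — no MCMC, no rejection. For static,
  uncoupled, $\kappa = 0$ kernels the per-cell step distributions are
  cached after first use (and kernels are then evaluated from cell
  centres, exactly the master equation's discretisation), which makes
  $10^4$-replicate runs cheap without changing the sampled law.

## Design choices where the design was open

* **Central-place distance enters at the end point.** The worked
  resource + central-place kernel uses $-\beta_C |z - x_C|$: a distance
  penalty depending only on the start point is constant across candidate
  steps, cancels in the kernel's normalisation, and produces no
  localising tendency at all. Start-point distance covariates remain
  available (`kind = "dist_start"`) for start-dependent hypotheses.
* **Occurrence distributions** are built by straight-line stepping-stone
  interpolation (10 points per step by default, endpoints counted once)
  over the most recent `od_window` steps, smoothed with a fixed-bandwidth
  Gaussian kernel evaluated at cell centres. Continuous-time
  movement-model OD fitting is deliberately not used; fixed-bandwidth KDE
  is transparent, fast, and sufficient for a covariate that animals
  plausibly perceive in smoothed form.
* **Causality of "recent space use".** The OD entering the step at time
  $t$ uses only fixes strictly before $t$. Before the first step the OD
  is the smoothed release point.
* **Update order** of interacting animals is re-randomised every step;
  a fixed order would introduce a systematic asymmetry the model does
  not intend.
* **Diffusion constant.** The second-moment integral is taken over
  $\psi$ normalised to a planar probability density. The raw
  (unnormalised) reading produces a quantity whose dimensions depend on
  the arbitrary scale of $\psi$; normalising makes $D_\tau$ the mean
  squared displacement per $4\tau$ of the selection-free step, e.g.
  $D = 3/(2\lambda^2)$ for the exponential family and $\sigma^2/2$ for
  the Gaussian.
* **Cumulative UD.** `cumulative_ud()` implements the time-average that
  trajectory-pooling UD estimators measure; it coincides with the
  instantaneous UD only at steady state, and the package keeps the two
  notions separate on purpose.

## Problem sizes and statistical power in the test suite

The tests run the full pipeline at deliberately modest sizes: kernels and
steady states on $10 \times 10$ to $50 \times 50$ grids, a
$100 \times 100$ grid for kernel-normalisation checks, propagation runs
of a few hundred steps, and paired two-animal simulations of 150 steps
across ten seeds. These sizes are stated here as the package's reference
configurations; all scale up linearly in cells and steps.

One check deserves a power note. The empirical endpoint distribution of
$n$ replicate simulations, compared with the propagated UD, has a Monte
Carlo floor
$\mathbb{E}[\mathrm{TV}] \approx \tfrac12 \sqrt{2/(\pi n)} \sum_s
\sqrt{u_s}$
even for a perfect simulator. At $n = 10^4$ a total-variation target of
0.02 therefore requires $\sum_s \sqrt{u_s} \lesssim 5$, i.e. a UD
concentrated on roughly 25 effective cells. The consistency check uses a
localised kernel ($\lambda = 1$, $\beta_C = 2$, $\beta_R = 1.5$ on a
$10 \times 10$ grid, $\sum\sqrt{u} \approx 3.9$) chosen from that
closed-form computation; the simulator's unbiasedness is separately
visible in the $1/\sqrt{n}$ scaling of the distance.

## Known limitations

* No bearing-augmented master equation: correlated movement
  ($\kappa > 0$) is simulation-only, and its long-run distributions must
  be estimated empirically (`endpoint_ud()`, `occurrence_distribution()`).
* No map projections or CRS handling; rasters are plain grids in
  cell-size units (ESRI ASCII grid I/O only).
* No estimation of $\beta$ from data.
* Steady-state solvers require a time-invariant kernel; time-varying
  providers are propagation-only.
* Dense transition matrices scale as (cells)$^2$; the sparse path
  (automatic above $10^4$ cells) assumes the kernel is effectively
  local, and drops tail mass below $10^{-12}$ per column before
  renormalising.
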