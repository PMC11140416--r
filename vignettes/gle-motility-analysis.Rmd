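---
title: "Memory-kernel analysis and classification of cell trajectories"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Memory-kernel analysis and classification of cell trajectories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gletraj)
```

## The model

`gletraj` models the planar motion of a cell center $x(t), y(t)$ with the
generalized Langevin equation (GLE)

$$\ddot{x}(t) = -\int_0^{t} \Gamma(t-t')\,\dot{x}(t')\,dt' + F_R(t),$$

with an identical, independent equation for $y(t)$. The memory (friction)
kernel $\Gamma(t)$ encodes how past velocities feed back on the present
acceleration; the random force $F_R$ is a zero-mean Gaussian process with
$\langle F_R(0)F_R(t)\rangle = B\,\Gamma(t)$, where
$B=\langle v^2\rangle$ is the mean-squared velocity. For motile cells this
is an *effective* (surrogate) description: equilibrium relations between
friction and noise are not assumed to hold microscopically, but a single
effective kernel reproducing the observed velocity autocorrelation function
(VACF) always exists and, for a Gaussian process, characterizes the dynamics
completely. Consequently only the effective kernel is identifiable from
trajectories, and that is what the package extracts.

For strongly confined swimming algae the extracted kernels are well
described by a sharp peak plus a damped oscillation,

$$\Gamma(t) = 2a\,\delta(t) + b\,e^{-t/\tau}\cos(\Omega t),$$

with friction rate $a$ (1/s), oscillation amplitude $b$ (1/s$^2$), decay
time $\tau$ (s) and frequency $\Omega$ (1/s); $\Omega$ reflects the
flagellar beating cycle. Together with $B$ this gives five parameters per
cell, which are the features used for classification.

## Pipeline and estimators

For each cell the pipeline is: positions $\to$ (optional running-mean
smoothing) $\to$ half-step velocities $v_{i+1/2}=(x_{i+1}-x_i)/\Delta$
$\to$ VACF and MSD $\to$ Volterra extraction of the kernel $\to$ parametric
fit $\to$ clustering.

**VACF/MSD.** Both are time-averaged over all overlapping pairs, estimated
per spatial component and then averaged over the two components with equal
weight (the model decouples $x$ and $y$, so averaging the per-component
estimates is the unbiased combination). $C_{vv}(0)$ is the estimator of
$B$.

**Volterra inversion.** Integrating the GLE against $\dot x(0)$ gives
$$C_{vv}(t) - C_{vv}(0) = -\int_0^t C_{vv}(s)\, G(t-s)\, ds, \qquad
G(t)=\int_0^t \Gamma(s)\,ds .$$
Because $C_{vv}$ is even and $G$ odd, $G$ is discretized on half steps and
$C_{vv}$ on full steps; the resulting triangular system is solved by exact
forward recursion (`extract_G()`), and $\Gamma$ follows by the staggered
central difference with $\Gamma_0 = 2G_{1/2}/\Delta$ (`gamma_from_G()`).
The recursion is the exact inverse of its own discretization (a test
asserts the identity to machine precision); against the *continuum* kernel
it carries an $O(\Delta^2)$ quadrature error with constant
$\sim(\Omega\Delta)^2/12$, i.e. about $10^{-2}$ relative at
$\Delta = 2\,$ms and $\Omega \approx 120\,$/s, falling fourfold per halving
of $\Delta$. No smoothing or regularization is applied to the recursion;
noise is handled upstream (position smoothing) and downstream (fitting a
restricted window).

**Forward model.** The model VACF solves
$C'_{vv}(t) = -a\,C_{vv}(t) - \int_0^t b\,e^{-(t-s)/\tau}\cos(\Omega(t-s))\,C_{vv}(s)\,ds$
with $C_{vv}(0)=B$. Introducing the two convolution states turns this into
a 3-variable constant-coefficient linear ODE, propagated *exactly* on the
grid by its matrix exponential; an independent closed form from the roots
of the characteristic cubic (partial fractions of the Laplace transform) is
implemented as a cross-check, and the two routes agree to $10^{-14}$
relative in tests. The MSD is obtained from the same system augmented with
its double integral; the supplementary closed-form MSD expression is not
transcribed — the numerically exact solver, validated by the dual route and
by the $b=0$ closed form $C_{vv}=Be^{-at}$, defines the forward model.

**Finite sampling step and localization noise.** Positions are observed at
a finite step $\Delta$ and with i.i.d. Gaussian localization error
$\sigma_{\rm loc}$. The noisy MSD gains $2\sigma_{\rm loc}^2$ at every
nonzero lag, and the discrete VACF follows from the second-difference
stencil of the noisy MSD (with the even extension
$\mathrm{MSD}(-\Delta)=\mathrm{MSD}(\Delta)$ at lag 0, justified by
stationarity). Pure noise leaves the exact signature
$(2\sigma^2/\Delta^2, -\sigma^2/\Delta^2, 0, \dots)$.

## The two fitting routes

**Direct kernel fit** (`fit_kernel()`, the default route and the source of
the clustering features): bounded least squares of the parametric kernel
against the extracted $\Gamma(i\Delta)$ over the first 0.2 s. Beyond that
window the extraction amplifies estimator noise, so the window is both the
extraction horizon default and the fit range. Constraints: the two
contributions to $\Gamma_0 = 2a/\Delta + b$ (namely $2a/\Delta$ and $b$)
each within $[0.1\%, 99.9\%]$ of the measured $\Gamma_0$,
$\tau \in [0.05, 3]$ s, $\Omega \in [20, 250]$ /s. (Constraining $a$
itself against $\Gamma_0$ would compare quantities of different units and
excludes realistic values; the contribution form is the dimensionally
consistent reading.) $B$ is attached as the measured $C_{vv}(0)$, not
fitted. Because the model is multi-modal in $\Omega$, the optimizer
restarts from Latin-hypercube draws inside the box (8 by default, fixed
internal seed, user RNG untouched) and keeps the best solution; parameter
standard deviations come from the covariance at the optimum.

**Discretized noisy-VACF fit** (`fit_noisy_vacf()`): unweighted least
squares of the discretized noisy model against the measured VACF up to
0.2 s, over $(a, b, \tau, \Omega, B, \sigma_{\rm loc})$, with the same
kernel bounds, $B$ within a factor 10 of the measured $C_{vv}(0)$ and
$\sigma_{\rm loc}\in[0,1]\,\mu$m (well above pixel scale but preventing a
noise/signal swap). Since $\sigma_{\rm loc}$ affects only lags 0 and 1,
the fit is initialized in stages: the five-parameter noise-free model is
fitted to lags $\ge 2$ from a neutral grid of $\Omega$ and $\tau$ starts,
$\sigma_{\rm loc}$ is read off the lag-0 residual, and the joint fit is
polished from there (plus Latin-hypercube joint starts as a safety net).
Very short windows flag the fit as under-determined instead of reporting a
silent success.

**A deliberate asymmetry.** Finite-difference velocities average the true
velocity over one step; this smears the kernel's $\delta$ peak over lags
$\{0, 1\}$ with weights $\{2/3, 1/6\}$. The direct route therefore
*underestimates $a$ systematically* (by roughly one third at
$\Delta = 2\,$ms for beating-scale kernels), while $b$, $\Omega$ and $B$
are recovered to a few percent and the plateau of $G$ still recovers $a$
accurately in the Markovian limit. The discretized-VACF route models the
finite step exactly and recovers $a$ without this bias. We keep the direct
fit as the feature source (its biases are identical across cells and do
not perturb classification, and it is the more robust estimator on short
noisy records) and regard the noisy-VACF fit as the validation tool for
discretization and noise effects; both are exposed and both are exercised
by the test suite and the acceptance script.

## The simulator as ground truth

A kernel of the family above (with an additional
$\sin(\Omega t)/(\tau\Omega)$ correction, negligible when
$\tau\Omega \gg 1$) arises exactly from a Markovian embedding: the observed
coordinate, harmonically coupled with strength $K$ to one hidden damped
coordinate, obeys the GLE after the hidden mode is integrated out. The map
is $a=\gamma_x/m$, $b=K/m$, $\tau = 2m_y/\gamma_y$,
$\Omega = \sqrt{K/m_y - 1/\tau^2}$ (the hidden mode must be underdamped),
inverted with the gauge $m=1$ since only ratios are identifiable.

`simulate_embedding()` integrates the resulting 4-variable linear SDE per
component with the *exact* discrete-time Gaussian transition: the
propagator is the matrix exponential of the drift and the innovation
covariance is the exactly integrated noise covariance (Van Loan's method).
There is no integrator bias at any step size, so no internal substepping is
needed; a resolution error is raised only when the sampling step cannot
resolve the fastest rate of the model. Trajectories start from the
stationary distribution (velocities and the relative coordinate drawn from
the solution of the Lyapunov equation), so correlation estimates carry no
transient. Equipartition ($\langle v^2\rangle = k_BT/m$) holds exactly for
the stationary law and is verified on simulation output within Monte-Carlo
error.

`generate_population()` draws per-cell parameters log-normally around a
population center and simulates each cell. The shipped demo conditions
(`demo_population_specs()`) emulate the two flagellar-beating phenotypes of
confined *Chlamydomonas reinhardtii* — a faster, lower-friction
"wobbler"-like population ($a=4$/s, $b=1200$/s$^2$, $\tau=0.6$ s,
$\Omega=150$/s, $B=1500\,\mu$m$^2$/s$^2$) and a slower, higher-friction
"synchro"-like one ($a=10$/s, $b=4000$/s$^2$, $\tau=0.5$ s, $\Omega=90$/s,
$B=400\,\mu$m$^2$/s$^2$) — at the experimental sampling step
$\Delta=2\,$ms, with 15% relative cell-to-cell spread and pixel-scale
localization noise $\sigma_{\rm loc}=0.02\,\mu$m. Speeds are tens of
$\mu$m/s, matching the confined-algae regime. What the generator does *not*
emulate: non-Gaussian behavior, switching between beating modes within a
record, drift or interactions with other cells; passing tests therefore
validate the estimators and protocol under the model's own assumptions,
not those aspects of real data.

## Clustering protocol

Cells are classified by X-means on the median-rescaled five-parameter
vectors, cluster numbers allowed from 2 to 20, Euclidean metric. X-means
runs k-means at the current $k$ and tests a 2-way split of every cluster
(child k-means seeded at the two members farthest apart), accepting a split
only if a model-selection score improves. The split criterion is an open
design point (the original protocol's "noiseless description length" is
specified only by citation); the package implements a two-part
description-length score — Gaussian residual code length, plus
$\tfrac12\log(nd)$ nats per scalar model parameter, plus an equal
*selection* cost for the data-optimized split boundary, plus the empirical
entropy of the assignments — with the spherical-Gaussian BIC as a
configurable alternative. The selection term is essential: without it the
apparent gain of an optimized split of a single Gaussian cluster
(measured at up to ~16 nats for 20 points in 5 dimensions) overlaps the
parameter cost alone, producing occasional spurious splits, whereas
legitimate splits of merged populations at $\ge 4\times$
separation-to-spread gain well over 100 nats. Splits are attempted only
for clusters of at least 5 points and never accepted when a child would be
a (near-)singleton.

Because k-means is initialization-dependent, the protocol runs X-means once
for every unordered pair of cells as the two initial centers
($n(n-1)/2$ runs, e.g. 1711 for 59 cells) and keeps the partition occurring
most often (compared in canonical, permutation-invariant form). Ties are
broken by the lexicographically smallest canonical labeling and flagged.
The whole procedure is deterministic given the feature table. Accuracy
against ground truth is the best agreement over label permutations.

## Numerical choices and degenerate inputs

* Internal units are fixed (seconds, micrometers); readers convert.
* Gaps and non-uniform sampling are hard errors — the estimators assume a
  uniform grid, and interpolation would bias the kernel.
* Default smoothing window 2 (the smallest nontrivial running mean),
  recorded in provenance metadata. For noisy-VACF fits the package uses
  unsmoothed positions, because smoothing correlates the localization
  noise that the model treats as independent.
* `extract_G` refuses ill-conditioned input
  ($C_{vv,1}+C_{vv,0}\approx 0$); `conditional_velocity` refuses
  covariance values with $|C_{vv}(t)| > C_{vv}(0)$ (estimator noise at
  long lags) instead of returning a negative variance.
* k-means re-seeds an emptied cluster at the point farthest from its
  assigned center; assignment ties go to the lowest cluster index.
* Multi-start draws use a fixed internal seed under a preserved RNG state,
  so fits are reproducible and do not disturb the caller's stream.

## Problem sizes used in tests

Unit tests run on records of $10^3$–$10^5$ steps; the end-to-end property
checks use the study-scale sizes the estimators are designed for:
$10^6$-step records for simulator-equivalence and conditional-Gaussian
checks, 40-cell cohorts of $5\times10^5$-step records for parameter
recovery, and 40–59-cell feature tables (780–1711 consensus runs) for the
clustering protocol. These sizes make Monte-Carlo error bars small enough
for the stated tolerances while keeping the full suite runnable on a
single CPU in minutes.

## Known limitations

* Only the effective (surrogate) kernel is identifiable; the package makes
  no attempt to separate friction memory from noise memory.
* The direct kernel route's $\delta$-amplitude $a$ carries the
  finite-sampling bias discussed above; use the noisy-VACF route when an
  unbiased $a$ or $\sigma_{\rm loc}$ matters.
* The Volterra extraction degrades at horizons much longer than 0.2 s on
  noisy data (error accumulation is the reason for the restricted fit
  window).
* Trajectories are 2-D; confining potentials, run-and-tumble statistics
  and image-level processing are out of scope.
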