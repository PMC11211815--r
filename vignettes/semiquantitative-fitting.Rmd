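---
title: "Estimating ODE parameters from semi-quantitative data with monotone spline measurement mappings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating ODE parameters from semi-quantitative data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(semiqfit)
```

## The problem

Many measurement techniques — FRET ratiometric imaging, optical density,
staining intensities — report a value that is related to the underlying
biochemical quantity by an unknown, monotone, possibly strongly nonlinear
transformation. When a dynamical model

$$\dot x(t) = f(x, \theta, t), \qquad x(0) = x_0(\theta), \qquad
  y = h(x, \theta)$$

is to be calibrated against such data, the simulated observable $y$ and
the measured value $\tilde z$ live on different scales and cannot be
compared directly. `semiqfit` estimates the mechanistic parameters
$\theta$ by *reconstructing the measurement mapping alongside them*: each
semi-quantitative observable $i$ carries a monotone piecewise-linear
spline $s_i$ with uniformly spaced knot bases $c_{ij}$ and nonnegative
height increments $\xi_{ij} \ge 0$, so that

$$\tilde z_{ik} = s_i\!\left(y_i(t_k, \theta);\, \xi_i\right) +
  \varepsilon_{ik}, \qquad \varepsilon_{ik} \sim N(0, \sigma_{ik}^2).$$

Nonnegative increments make the spline monotone nondecreasing by
construction; the knot heights are the cumulative sums of the increments.
Observables may instead be declared `quantitative` (identity mapping) or
`relative` (unknown affine scaling/offset, the classical
scaling-and-offset case).

## The hierarchical objective

The Gaussian negative log-likelihood separates additively over
observables. Rather than optimizing mechanistic and observable
parameters jointly, the package nests them:

* **outer problem** — minimize $J(\theta) = \sum_i J_i(\theta,
  \psi_i^*(\theta))$ over $\theta$ (log10 scale by default);
* **inner problems** — for each observable, $\psi_i^*(\theta) =
  \arg\min_{\psi_i} J_i(\theta, \psi_i)$, where $\psi_i$ collects the
  mapping parameters and, optionally, a single noise SD.

The inner problems are cheap and reliable: for relative observables the
scaling, offset, and noise SD have closed forms (weighted least squares
and the RMS residual); for spline observables the problem is a convex
nonnegativity-constrained least-squares program, because the spline is
*linear in its increments* ($s(x) = B(x)\,\xi$ with a banded basis
matrix $B$). It is solved as nonnegative least squares on a
Tikhonov-augmented system, which is numerically robust and needs no
tuning.

The outer gradient is analytic. At an inner optimum the inner gradient
vanishes (envelope/KKT argument), so only the explicit dependence through
the simulation contributes:

$$\nabla_\theta J = \sum_{i,k} \frac{m_{ik} - \tilde z_{ik}}{\sigma_i^2}
  \; g_i'(y_{ik}) \; \frac{\partial y_{ik}}{\partial \theta},$$

where $m_{ik}$ is the mapped simulation and $g_i'$ the local mapping
slope (1, $a_i$, or the spline slope). $\partial y/\partial\theta$ comes
from forward sensitivity analysis: the augmented system $\dot S =
f_x S + f_\theta$, $S(0) = \partial x_0/\partial\theta$ is integrated
along with the states and chained through $h$. The test suite verifies
the gradient against central finite differences of the *full profile
objective* (inner problems re-solved at every perturbed $\theta$) to a
relative error below $10^{-4}$.

### The adaptive knot grid and its gradient

By default the knot grid is recomputed at every evaluation as
$c_j = j\,\Delta c$ with $\Delta c = (1 + \text{margin})\max_k
y_{ik}/n_\xi$ (margin 0.3), so the spline always covers the simulated
range. Because $\Delta c$ depends on $\theta$ through $\max_k y_{ik}$,
the gradient must include the chain term
$\partial J/\partial \Delta c \cdot \partial \Delta c/\partial\theta$
(with $\partial s/\partial \Delta c = -s'(x)\,x/\Delta c$ inside the
grid). Early versions omitted this term; the omission is harmless near
an optimum but catastrophically misleading far from it — with large
residuals the reported gradient can point uphill and bounded
quasi-Newton optimization aborts in its line search. With the term
included, finite-difference checks pass at arbitrary bounded $\theta$.
The grid-chain derivative is exact up to the isolated kinks where the
argmax time point or a knot-interval assignment switches. A
`fixed_knots` mode freezes the grid entirely; it is used for gradient
verification and for joint (non-hierarchical) optimization, where the
increments need a stable meaning across iterations.

### Noise handling

Noise is always on the *measurement* scale (after the mapping). Each
observable has either a known SD (scalar, or per time point via the
measurement table) or a single estimated SD, profiled as the RMS
residual. With regularization active, the $\sigma$–$\lambda$ coupling is
resolved by a fixed-point iteration (solve $\xi$ at the current
$\sigma$, update $\sigma$ from residuals, repeat), iterated to joint
stationarity ($10^{-12}$ relative) so the envelope gradient identity
holds tightly; a looser stopping rule measurably degrades the outer
gradient. A floor of $10^{-10}$ keeps the likelihood finite on perfectly
fitted data. Per-time-point noise SDs are never estimated (one parameter
per data point is unidentifiable).

## Tunable parameters

| parameter | default | units | rationale |
|---|---|---|---|
| `n_knots` | 8 | — | enough capacity for smooth monotone shapes while limiting overfitting; more knots than data points are refused with a warning |
| `margin` | 0.3 | fraction | headroom of the knot grid above the simulated maximum, so re-gridding is rare near an optimum |
| `lambda` | 0.01 | 1/measurement² | quadratic penalty $\tfrac{\lambda}{2}\sum_j(\xi_j - \bar\xi)^2$, zero exactly for a linear mapping; a weak tie-break toward linearity |
| `rtol`, `atol` | 1e-8, 1e-10 | — | stiff-capable `lsoda` defaults; gradient-verification oracles use 1e-11/1e-13 so the finite-difference baseline is not limited by integration noise |
| bounds | per model | log10 | parameters are estimated on log10 scale, the standard choice for rate constants spanning orders of magnitude |

## Estimation workflow

`multistart_fit()` draws Latin-hypercube start points over the bounds
and runs bounded L-BFGS-B with the analytic gradient (with restart
polish: re-invoking from the terminal point resets the quasi-Newton
memory and escapes premature stalls). A gradient-free Nelder–Mead mode
serves as the derivative-free baseline for efficiency comparisons.
Convergence of a start is classified by the likelihood-ratio statistic
$\Lambda = 2(J - J^*)$ against the $\chi^2_{n_\theta}$ quantile — the
same statistic that defines the confidence region
$\{\theta : \Lambda(\theta) \le \Delta_\alpha\}$.

`sample_posterior()` runs an adaptive Metropolis chain over $\theta$
only (uniform prior over the bounds); mapping and noise parameters are
profiled inside the likelihood, so every retained sample induces an
optimal mapping, and pointwise percentile envelopes of those mappings
form the credibility bands. The proposal covariance is adapted from the
chain history with the global scale tuned toward an acceptance rate of
0.234; adaptation is frozen after the first 20% of iterations so the
remainder is a proper Markov chain. Chains here are started at the
multi-start optimum, so no burn-in is discarded from the retained set.

`classify_mapping()` turns a fitted spline into a data-type verdict:
identity within tolerance → the data were effectively quantitative;
affine knot heights → relative; a run of two or more zero increments at
either end → censored-like (detection floor or saturation); otherwise
genuinely nonlinear.

## The synthetic benchmarks

Two fully generated fixtures drive all tests; nothing is downloaded.

**FRET probe activation (T1).** Two states (inactive P, active P*) with
lumped activation/deactivation rates $k_1 = 2$, $k_2 = 1$ per time unit,
conserved total $P_{TOT} = 10$, observable $P^*/P_{TOT}$, 12 log-spaced
time points over the activation transient (relaxation rate
$k_1 + k_2 = 3$), and the ratiometric readout
$g(P^*) = \alpha P^*/(P_{TOT} - P^*) + \beta$ with $\alpha = 1$,
$\beta = 0.2$ as the true measurement mapping. Gaussian noise with
$\sigma = 0.05$ (a few percent of the readout range) is added on the
mapped scale. The model formally carries four estimable parameters
($k_1, k_2, \alpha, \beta$, log10 bounds $[-2, 2]$), matching the
parametric-mapping variant in which $\alpha, \beta$ enter the
`fret_ratio` observable; in the spline variant they are inert.

**Cascade.** A linear chain A → B → C (first-order conversions, C
degraded) with $k = (1.5, 0.8, 0.4)$, 16 log-spaced times per
observable, $\sigma = 0.05$. The observables are *combined readouts*
(A + C, B, B + C) pushed through three different monotone library
mappings (saturating hyperbola, exponential saturation, square root).
The mixtures are deliberate: with pure-species observables the fixture
has an exact $k_1 \leftrightarrow k_2$ exchange symmetry once every
observable carries a free monotone mapping (B swaps to a proportional
curve, which a free mapping absorbs; C is exactly swap-invariant; the
monotone A is always mapping-compensable), and a band study on such a
fixture only records which of two equivalent modes the optimizer
happened to find. Readouts that mix species change *shape* under
parameter exchanges and cannot be absorbed by any per-observable
monotone transformation.

For the statistical studies (confidence-region coverage,
hierarchical/joint comparison, efficiency, credibility bands) the
generating noise SD is supplied as known. This is the standard protocol
for synthetic recovery studies, and it matters here: with 12 data
points, 8 spline increments *and* a free noise SD, the mapping can
absorb part of the noise, $J^*$ deepens by chance, and the
likelihood-ratio statistic at the truth inflates beyond its asymptotic
$\chi^2$ reference.

### What the benchmarks do and do not show

A single monotone observable measured through a free monotone mapping
carries an intrinsic invariance: for *any* rate parameters that produce
a monotone time course, some monotone mapping reproduces the noiseless
data exactly. Only the spline's finite resolution (and, weakly, the
linearity regularization) breaks this tie. In the T1 benchmark the
practical consequence is a long, gently tilted likelihood valley: the
profiled mapping *at the true parameters* recovers the ratiometric
curve to well within $3\sigma$, and the truth lies comfortably inside
the 95% confidence region, but polished multi-start endpoints slide to
the noise-preferred end of the valley, where the compensating mapping
differs visibly from the truth. The acceptance suite records this
honestly: point recovery of the mapping from the *best* endpoint is not
attainable on this fixture, while coverage of the confidence region is.

Similarly, piecewise-linear splines approximate smooth mappings with a
systematic wiggle of order $|g''|\Delta c^2/8$ — on the cascade fixture
up to roughly $2\sigma$ at the curvature peaks. Credibility bands built
from profiled (plug-in) splines do not account for increment
uncertainty at fixed $\theta$, so where the posterior over $\theta$ is
tight the bands can be narrower than this approximation bias and the
smooth truth weaves outside them at part of the grid. Both effects are
properties of the piecewise-linear approximation, not of the
hierarchical machinery; smooth monotone bases would remove them at the
cost of a harder inner problem.

Real data differ from these fixtures in ways the tests cannot probe:
model misspecification, non-Gaussian noise, measurement-time
uncertainty, and mappings that drift between experiments.

## Study sizes

The bundled studies use 50 multi-start runs for mapping recovery, 20
replicate datasets (6 starts each) for coverage, $10^4$ MCMC iterations
thinned by 50 for the bands, and 10 shared starts for the
hierarchical/joint and gradient/gradient-free comparisons. These sizes
give stable verdicts for the bundled models; larger presets
(1000 starts, $10^5$ iterations thinned by 500) reproduce the scale of
full published studies and are available by passing the corresponding
arguments.

In the efficiency comparison, start points already inside the 95%
confidence region are excluded from the study population (drawing
further Latin-hypercube points instead): a start that begins at a
solution measures nothing about time-to-solution.

## Numerical choices and edge cases

* The spline extrapolates at constant total height beyond the last knot
  (the only continuous monotone completion) and continues the first
  segment's slope below zero; the derivative at a knot takes the
  right-interval slope, consistent with the half-open interval
  convention of the basis matrix, so the analytic gradient is the exact
  one-sided derivative of the evaluated objective.
* `make_knot_grid()` refuses observables whose simulated maximum is not
  positive — the grid is anchored at the origin, and such observables
  should be shifted or transformed first.
* Failed integrations (stiff blow-ups at extreme parameter draws) never
  raise inside optimization: they return an infinite objective through a
  success flag, and the multi-start loop continues.
* Degenerate relative observables (zero simulated variance) are flagged
  and fitted with zero scaling and the weighted-mean offset.
* All-zero measurements yield a zero spline directly.
* Duplicate proposals in `optim`'s separate value/gradient calls are
  served from a one-point memo so an evaluation is only counted (and
  computed) once.

## Limitations

Piecewise-linear mappings are not smooth; events, dosing, steady-state
pre-equilibration, SBML import, adjoint sensitivities, second-order
derivatives, non-Gaussian noise, and censoring likelihoods are out of
scope. A spline and an affine/offset mapping cannot be combined on the
same observable. The mapping classification is a heuristic on the
fitted spline, not a test with error control.
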