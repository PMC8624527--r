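---
title: "Piecewise-affine soft sensing: models, identification, and design choices"
author: "pwasoft"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Piecewise-affine soft sensing: models, identification, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pwasoft)
```

## The problem

Key quality variables of a batch fermentation — cell concentration $X$ and
product (e.g. protease) concentration $P$ — are assayed offline on a slow
grid (hourly), while easy process variables (broth temperature $T$,
dissolved oxygen $DO$, $pH$, air flow $q$, stirring speed $v$, tank pressure
$p$) are logged every few minutes. A *soft sensor* estimates the slow,
expensive outputs from the fast, cheap inputs. A single global model
struggles because a batch run traverses physiologically distinct phases
(adjustment/lag, exponential growth, stationary), each with its own local
dynamics. `pwasoft` therefore identifies a *piecewise-affine ARX* (PWARX)
multi-model: regressor space is partitioned into polyhedral regions, each
carrying its own affine ARX law.

## The model

For a chosen scalar target $y$ and $r$ inputs, the regression vector at time
$k$ stacks past outputs and (delayed) past inputs,

$$X(k) = [\,y(k-1), \dots, y(k-n_y),\;
          u_1(k-p-1), \dots, u_r(k-p-1), \dots,
          u_1(k-p-n_u), \dots, u_r(k-p-n_u)\,]^\top \in \mathbb{R}^n,$$

with $n = n_y + n_u r$, and the model is

$$y(k) = [X(k)^\top, 1]\,\theta_i + \varepsilon(k)
  \quad \text{when } X(k) \in \Omega_i, \qquad i = 1, \dots, S,$$

where the $\Omega_i$ are closed polyhedra that tile regressor space and each
$\theta_i \in \mathbb{R}^{n+1}$ includes an affine term. Identification must
deliver the orders $(n_y, n_u)$, the number of local models $S$, the
parameters $\theta_i$, and the dividing surfaces between regions — four
coupled sub-problems that the package solves in sequence.

Clustering operates in *modeling space*: the augmented vectors
$z(k) = [X(k)^\top, y(k)]^\top$. Because the system is locally affine,
samples governed by the same law form coherent clouds in $z$-space.

## Order selection: false nearest neighbors and Cao statistics

Regression vectors of growing dimension are built along the nested schedule
$(n_y, n_u) = (1,1), (2,1), (2,2), (3,2), \dots$ (output lag first), so each
step's coordinate set contains the previous one. For each dimension the
nearest neighbor of every point is found under the $L_\infty$ norm; when the
dimension is increased, the distance of that pair can only grow, and the
growth is the diagnostic:

* **False-neighbor fraction.** A neighbor is false when the relative growth
  $(d^{(n+1)} - d^{(n)})/d^{(n)}$ reaches a threshold $R_T$ (default 10, the
  low end of the conventional $[10, 50]$ range). The minimum embedding
  dimension is the smallest one where this fraction drops to (near) zero —
  the method's primary termination rule. The variant that divides by
  $d^{(n+1)}$ is retained behind `criterion = "printed"`, but under
  $L_\infty$ nesting that ratio is below 1, so it cannot flag anything at
  conventional thresholds.
* **Cao statistics.** $E(n)$ is the mean growth factor
  $\alpha(p,n) = d^{(n+1)}(p)/d^{(n)}(p) \ge 1$ and $E_0(n) = E(n+1)/E(n)$.
  On input/output embeddings $E_0$ oscillates with the *type* of appended
  coordinate (an appended input lag is exogenous and never becomes
  predictable, an appended output lag may), so $|E_0 - 1| < tol$ is kept
  only as a secondary trigger; with `tol = Inf` it degenerates to returning
  the smallest dimension, which is occasionally useful as a baseline.
* **Noise detection.** The appended-coordinate statistic $E_2$ (each
  appended coordinate's neighbor difference, scaled by that coordinate's own
  dispersion, ratioed between consecutive dimensions) stays near 1 at
  *every* dimension for a structureless series: no coordinate ever becomes
  predictable. `cao_statistics()` flags such series as degenerate; direct
  computation shows that the $E_0$ band itself does *not* stay near 1 for
  white noise at low dimensions (neighbor distances concentrate and $E(n)$
  falls steeply), which is why the detector uses $E_2$.

Several splits $(n_y, n_u)$ can share the selected total dimension; they are
ranked by one-step least-squares ARX residual on a chronological hold-out
tail (default 25%), which disambiguates, e.g., $(2,1)$ from $(1,2)$ on a
single-input system.

Zero-distance neighbor pairs (duplicated points) are excluded from all
ratio statistics and counted, never divided by.

## Joint identification of S and the local parameters

For fixed orders, the number of local models and their parameters are
optimized together by a particle swarm whose particles encode the whole
multi-model: $[\theta_1, Z_1, \dots, \theta_S, Z_S]$, where $Z_i$ is the
$i$-th cluster center in $z$-space. A particle's fitness is

$$J_1 = \sum_k \big(y(k) - [X(k)^\top, 1]\,\theta_{\ell(k)}\big)^2,$$

with $\ell(k)$ the index of the nearest center to $z(k)$ (ties to the lowest
index). Each empty cluster multiplies $J_1$ by an additional factor of 10
and, between iterations, has its center teleported to the worst-fitted
sample — both measures keep the search from inflating $S$ with unused
centers.

The bi-objective "fit well with few models" is resolved lexicographically:
an outer loop tries $S = 1, 2, \dots$ and stops at the first $S$ whose best
$J_1$ meets the search threshold $Y_{ts}$. When the threshold is never met,
the best $S$ found is returned and flagged. $Y_{ts}$ defaults to 1% of the
total output sum of squares around its mean — the point where a model
explains 99% of output variance; the threshold is a tunable with real
leverage, since a looser value merges phases and a tighter one splits them.

### The swarm and its compression factor

The velocity update is
$v \leftarrow \mu\,(w v + c_1 r_1 (p^b - p) + c_2 r_2 (p_g^b - p))$ with
inertia $w = 0.729$ and $c_1 = c_2 = 1.49$ (standard constricted-PSO
practice). The multiplier $\mu$ is the *iteration-dependent compression
factor*

$$\mu(G) = \delta\,\sigma^{G/(N+G-1)}, \qquad \delta = 24,\ \sigma = 0.01,\
N = 300,$$

a strictly decreasing schedule whose decrements shrink with $G$: fast decay
early (escape local optima), smooth decay late (fine local search). As
printed, the schedule starts near $23.6$, while its stated intent is to run
from 1 towards 0; the default mode `icf_normalized` therefore divides by
$\mu(1)$, preserving the decay shape while matching the intended range. The
raw schedule (`icf_printed`), the constant Clerc constriction factor
(`clerc`, $\phi = 2/|2-\rho-\sqrt{\rho^2-4\rho}|$, $\rho = c_1+c_2 > 4$) and
plain PSO (`none`) are selectable for comparison, and
`plot_compression_schedules()` draws $\mu(G)$ across $(\delta, \sigma)$
regimes.

### Initialization and local refinement

The swarm's behavior on this problem is dominated by the cluster-center
coordinates, and a particle dimension of $S(2n+2)$ (48 for the three-phase
fixture) is too large for naive random starts within the iteration budget.
Two design choices address this:

* **Initialization.** Centers are seeded by greedy farthest-point sampling
  of the $z$-vectors (keeping them in the data cloud) followed by three
  Lloyd iterations (farthest points sit at cloud extremes; the Lloyd steps
  pull them into cluster interiors). Half the particles take their
  $\theta$ blocks from per-cluster least squares on the induced labels; the
  other half draw $\theta$ uniformly in the search box, preserving
  diversity.
* **Elitist local search.** After every swarm iteration the incumbent best
  is offered two refinements — per-cluster least squares of $\theta$ at its
  current labels, and the same after one Lloyd step on its centers — and is
  replaced when a refinement improves $J_1$. This is the classical
  clusterwise-regression alternation embedded inside the global search: the
  swarm explores center space, the refinement solves the easy conditional
  subproblem exactly.

Search bounds are $[-10, 10]$ per $\theta$ coordinate (generous for data
normalized to $[-1,1]$) and the data bounding box per center coordinate.
Positions leaving the box are clipped with the violated velocity component
zeroed. An optional final `polish` step refits each $\theta_i$ by
per-cluster least squares; it is off by default so the returned parameters
are the swarm's own, and on in recovery benchmarks where the attainable
optimum is the least-squares solution itself.

## Dividing surfaces

After identification, the regions are made explicit. Clusters adjacent under
the nearest-center rule (every cluster is adjacent to the cluster of its
nearest other center; distance ties make all tied clusters adjacent) get a
separating hyperplane trained by a least squares support vector machine on
the two clusters' regressor vectors: solve

$$\begin{bmatrix} 0 & y^\top \\ y & \Omega + I/\gamma \end{bmatrix}
\begin{bmatrix} b \\ \alpha \end{bmatrix} =
\begin{bmatrix} 0 \\ \mathbf{1} \end{bmatrix},
\qquad \Omega_{kl} = y_k y_l K(x_k, x_l),$$

then read the primal parameters $w = \sum_k \alpha_k y_k x_k$ and
$v = \operatorname{mean}_k (y_k - w^\top x_k)$. The offset is averaged over
all training points rather than taken from a single support vector — the
numerically stable equivalent in the separable case. Hyperplane extraction
is only meaningful for the linear kernel; the RBF kernel
($K = \exp(-\|x_i - x_j\|^2/\sigma^2)$, width default 0.2) remains available
for the sign classifier but refuses to emit $(w, v)$. The penalty weight
$\gamma$ defaults to 10. Because surfaces exist only for adjacent pairs, a
three-region model typically carries two surfaces, not three.

At prediction time a point belongs to the region whose surface constraints
it satisfies (boundary values count as satisfying: closed polyhedra; among
several satisfied regions the lowest index wins). Pairwise-trained surfaces
can leave a sliver of regressor space claimed by no region; such points fall
back to the nearest center in regressor space, and the event is logged. The
region map is therefore total and deterministic.

## Evaluation

One-step-ahead (series-parallel) prediction is the default: measured lags
in, $\hat y(k) = [X(k)^\top, 1]\,\theta_{\text{region}(X(k))}$ out.
`error_metrics()` reports MAPE as a fraction of the relative-error series
$e(k) = (y - \hat y)/y$ — samples with $|y|$ below $10^{-8}$ (normalized
scale) are excluded and counted — and RMSE over all samples. Metrics are
computed on the normalized scale, with physical-unit metrics alongside
whenever the model carries its scaling transform; which scale a published
MAPE refers to is often ambiguous, so both are always available.
`evaluate_model()` adds an RMSE-versus-cumulative-test-size table in
20-sample increments, the standard stability diagnostic for a soft sensor.
The natural baseline is a single global affine ARX law fit by least squares
(`fit_global_arx()`); a multi-model is only worth its complexity if it beats
that. A free-run simulation mode exists for inspecting long-horizon behavior
but plays no part in the standard evaluation.

## Synthetic data: what it emulates, and what it does not

No public fermentation batches accompany the method, so the package ships
generators that make every stage testable:

* `gen_pwarx_dataset()` draws from an exact PWARX system with a known
  partition (nearest-center or coordinate-threshold), known $\theta_i$, and
  Gaussian output noise, returning ground-truth labels for recovery scoring.
  A divergence guard aborts on unstable parameterizations.
* `make_two_regime_benchmark()` is the parameter-recovery standard: one
  input alternating between two levels (square wave with AR(1) jitter), two
  well-separated regimes under a nearest-center partition, no noise — the
  true labeling is exactly representable by the clustering rule, so exact
  recovery is attainable.
* `make_three_phase_fixture()` emulates the three-phase batch structure
  with $r = 6$ inputs and orders $(1, 1)$, so each $\theta_i$ has 8 entries.
  The regime follows a dissolved-oxygen ramp through two thresholds
  (adjustment at high DO, growth at mid, stationary at low), giving
  contiguous phases of roughly a third of each batch. The three laws were
  chosen once so that the phases are genuinely distinct: output-lag
  coefficients of different sign and magnitude across regimes and
  sign-flipped input responses, which keeps any two-regime merge far above
  the 1%-of-variance threshold while each true regime fits to noise level.
  Defaults produce 10 batches of 96 samples with sequential
  train/validation/test labels of 576/204/180 samples.
* `gen_fermentation_batches()` is a mechanistic surrogate of the sampling
  campaign: logistic biomass growth ($\mu_{\max} = 0.12\,h^{-1}$, carrying
  capacity 40 g/L) modulated multiplicatively by bell-shaped deviations of
  $T$, $pH$ and $DO$ from their setpoints (28 °C, 7.3, 40%), Luedeking–Piret
  product formation $dP/dt = a\,dX/dt + b X$ ($a = 0.08$, $b = 0.002$),
  inputs wandering around setpoints as AR(1) perturbations (coefficient 0.9,
  2% of setpoint), 5-minute Euler integration over 80 h, hourly output
  observations, linear interpolation to the fast grid, min–max normalization
  to $[-1, 1]$, uniform thinning to 96 retained samples per batch, and
  sequential 576/204/180 split labels. (80 h at 5 minutes is 960 samples per
  batch; a 960-sample *total* over 10 batches is only consistent with
  thinning, hence the 96-per-batch default, configurable.)

What passing tests on these generators shows: the pipeline recovers the
number of regimes, their parameters, and their boundaries when regimes are
affine, separated in modeling space, and persistently excited, and it beats
a global affine law when the data truly switch regimes. What it does not
show: performance on real fermentations, where regimes drift continuously,
noise is non-Gaussian, sensors fail, and the surrogate's smooth kinetics are
a caricature — notably, the surrogate itself is so smooth on the thinned
grid that a *single* affine law often already explains 99% of one-step
output variance, and the identification then honestly returns $S = 1$.

## Numerical choices

* Ties: nearest-neighbor and cluster ties break to the lowest index;
  boundary points belong to the lower-indexed region.
* Zero distances in embedding statistics are skipped and counted.
* Rank-deficient least squares falls back to the minimum-norm solution with
  a warning (single-point clusters).
* The LS-SVM system is solved densely; a singular system raises an error
  with a conditioning report rather than returning garbage.
* All randomness flows from explicit integer seeds through derived
  per-component seeds; repeated runs are bit-identical, and the CLI writes
  no timestamps so whole artifacts are byte-identical under a fixed seed.
* Model JSON is written with 17 significant digits (exact IEEE round-trip).
* Test-time values outside the training range are transformed by the stored
  affine map without clipping; constant channels map to 0 and are flagged.
* Pure delay $p$ defaults to 0 and is configurable; lag windows never cross
  batch boundaries (mixing batches would fabricate dynamics across runs).

## Known limitations

* The regressor convention uses strictly past values; formulations that
  include the current or future output in the regressor are not supported.
* Pairwise surfaces do not guarantee a consistent global partition; the
  nearest-center fallback makes assignment total but can disagree with the
  training labels near multi-region junctions.
* The incremental-$S$ loop inherits the threshold's bias: $Y_{ts}$ set too
  loose under-segments, too tight over-segments. On smooth data with a
  dominant output lag, $S = 1$ at the default threshold is the expected,
  honest answer.
* MAPE is undefined near zero crossings of the target; the floor rule
  excludes such samples and reports how many.
* The swarm is a heuristic: recovery guarantees are empirical (seeded
  benchmark suites), not analytic.

## Problem sizes used in the test suite

The shipped tests run the full pipeline at deliberately modest sizes — 10
batches × 96 samples for the three-phase fixture, 300 samples for the
two-regime benchmark, 30 particles × ≤300 iterations for swarm runs, and
white-noise series of 1,200–1,500 points for the degeneracy diagnostics —
sizes at which every property under test is already stable across seeds.
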