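---
title: "Monotone smoothing splines and the continuous germination index"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Monotone smoothing splines and the continuous germination index}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(germspline)
```

## The statistical problem

A germination assay plants `N*` seeds and scores daily how many have
completed germination, yielding a discrete, nondecreasing cumulative count
per accession. Although the counts are integers, they are naturally read as
a discretisation of a continuous germination process: with growing `N*` the
cumulative proportion curve approaches a smooth, nonnegative, nondecreasing
function that need not reach 1 (dormant or nonviable seeds never germinate).
`germspline` estimates that function — the absolute germination distribution
function (AGDF) — per accession, derives the continuous germination index
(CGI) as its area, and compares scalar germination indices by how well each
predicts the estimated curves in a function-on-scalar regression.

## The AGDF model

Given data `(t_j, y_j)` with weights `w_j` on a domain `[a, b]`, `agdf()`
minimises

$$J_l(f) = (1-\alpha)\int_a^b \left(f^{(l)}(t)\right)^2 dt
  + \alpha \sum_j w_j\, (y_j - f(t_j))^2, \qquad \alpha \in (0,1),$$

over splines satisfying $s(t) \ge 0$ and $s'(t) \ge 0$ for **all**
$t \in [a,b]$, not merely at grid points. The solution space is a clamped
B-spline basis of degree $k$ on a fixed break sequence; clamping (boundary
knots repeated $k+1$ times) makes the basis a nonnegative partition of unity
and pins the endpoint values to the first and last coefficients, so a basis
with $m$ breaks has dimension $m - 1 + k$ (nine functions for the default
five breaks with quintic splines).

### Enforcing the shape constraints

The derivative of a degree-$k$ spline is a degree-$(k-1)$ spline whose
B-spline coefficients are positive multiples of the consecutive differences
of the original coefficients. Requiring those differences to be nonnegative
is therefore *sufficient* for monotonicity everywhere, and together with a
nonnegative first coefficient it gives global nonnegativity. (It is not
necessary: a monotone spline can have a locally decreasing control polygon.
The sufficient cone is the standard choice because it is convex, linear in
the coefficients, and exact at the data resolutions used here.)

Substituting $b = Tg$, where $T$ is the lower-triangular cumulative-sum map
and $g \ge 0$ collects the first coefficient and the increments, turns the
constrained problem into one canonical nonnegative least-squares system:
stack $\sqrt{\alpha}\, W^{1/2} C\, T$ (collocation rows) over
$\sqrt{1-\alpha}\, R\, T$ (penalty rows, $R$ a symmetric-eigendecomposition
square root of the penalty Gram matrix with small negative eigenvalues
clipped at zero) and solve $\min \lVert A g - z\rVert^2,\ g \ge 0$ with the
Lawson–Hanson algorithm (`pracma::lsqnonneg`). The solver's active-set exit
condition is the KKT system of the cone-constrained problem; the fit object
records the scaled maximum violation (`fit$kkt`, checked at `1e-6` in the
tests, with feasibility re-verified on dense grids at `1e-8`).

### Parameters and defaults

* **`degree` (k = 5).** Quintic splines are the conventional choice for
  germination curves: smooth second derivatives for downstream functional
  analysis while remaining low-dimensional on 10–28 day windows.
* **`penalty_order` (l = 1).** The first-derivative penalty shrinks toward a
  *constant* (its null space), which is shape-neutral: it never pushes the
  fit against the monotonicity cone. Orders up to `k` are accepted.
* **`breaks`.** Fixed a priori, not data-driven: `c(0, 7, 14, 21, 28)` for
  28-day assays, `c(0, 2, 5, 8, 10)` for 10-day assays (slightly denser early,
  where germination events concentrate), otherwise five equally spaced
  breaks. Knot selection is out of scope by design.
* **`alpha` (0.5).** Equal weight on smoothness and fidelity — a good general
  compromise for daily scoring; `alpha -> 1` interpolates the data (verified
  as a limit property in the tests).
* **`weights` (all 1).** Available for unequal scoring effort; zero weights
  drop points, but at least two weighted points are required.

Records are anchored at `(t = 0, y = 0)` when day 0 is absent, since scoring
starts the day after planting. Duplicate days are rejected rather than
averaged — data cleaning is deliberately the caller's job. An all-zero
(fully dormant) record yields the zero spline; indices that divide by the
germinated total are reported as `NA`, never silently as 0, and cohort
functions can either keep or drop such accessions.

## The continuous germination index

$\mathrm{CGI} = \int_a^b s(t)\,dt$ is computed with the exact B-spline
antiderivative identity
$\int_a^b \sum_\nu b_\nu B_\nu = \sum_\nu b_\nu (\tau_{\nu+k+1}-\tau_\nu)/(k+1)$
on the clamped knot sequence $\tau$; the composed trapezoidal rule is kept as
an independent cross-check (`method = "trapezoid"`, agreement at `1e-6` in
the tests, with the expected $O(h^2)$ convergence). Since $s$ is a
nondecreasing proportion curve, $0 \le \mathrm{CGI} \le b - a$; it increases
with both the final proportion and the speed of germination, which is what
makes it a continuous counterpart of the weighted germination index GI.

## Scoring indices by functional regression

For curves $y_i(t)$ and a scalar index $x_i$, `fosr()` fits
$y_i(t) = \beta_0(t) + x_i\beta_1(t) + \varepsilon_i(t)$ by minimising the
integrated criterion $\int \lVert y(t) - X\beta(t)\rVert^2 dt$. With
responses and coefficient functions expanded in one shared basis this is
*exactly* ordinary least squares on the coefficient matrix (verified in the
tests against direct minimisation of the integral criterion). The global
$R^2_{glob} = \sum_i \lVert\hat y_i - \bar y\rVert_2^2 / \sum_i \lVert y_i -
\bar y\rVert_2^2$ uses exact $L^2$ norms via the basis Gram matrix, not grid
sums; the pointwise $R^2(t)$ uses the explained/total form, which coincides
with $1 - SSE/SST$ because every pointwise fit contains an intercept.
Pointwise values are clipped to $[0,1]$ for reporting and flagged undefined
where the curves nearly coincide ($SST(t) < 10^{-12}$); negative unclipped
values can only arise from numerical noise at such points. A covariate with
variance below $10^{-12}$, or a design with condition number above $10^{12}$,
marks the model singular and all $R^2$ output `NA` — this is a real outcome
(e.g. regressing curves with identical LT50 on LT50), not an error.

## What the synthetic generator does and does not emulate

`simulate_cohort()` draws cumulative counts from a Hill-type sigmoid
$p(t) = c\, t^a / (b^a + t^a)$ with binomial noise: increments are drawn
from the not-yet-germinated seeds with the conditional hazard
$(p(t_j)-p(t_{j-1}))/(1-p(t_{j-1}))$, so the day-$t$ count is exactly
$\mathrm{Binomial}(N^*, p(t))$ while monotonicity holds by construction.
Defaults (25 seeds, shape 4–6, plateaus 0.2–0.95, half-times 2–15 days)
mirror typical assay scales. The generator captures sampling noise and the
percentage/speed trade-off; it does **not** emulate seed-to-seed correlation
within dishes, censoring by assay termination, secondary dormancy, or
multi-phase germination, so passing simulation tests demonstrates correct
recovery under idealised sigmoid kinetics, not robustness to those
real-data features.

## Numerical choices

* Penalty and Gram matrices use Gauss–Legendre quadrature per knot interval
  with $k - l + 1$ nodes — exact for the piecewise-polynomial integrands —
  rather than sparse approximations.
* The penalty square root clips eigenvalues below zero (they only arise from
  roundoff; the first-derivative penalty has a one-dimensional null space).
* Degenerate inputs: all-zero data short-circuit to the zero spline;
  decreasing data collapse to the weighted-mean constant (all increments
  active at zero); ties in days are errors.
* Fixed `%.6g` formatting in CSV writers keeps repeated runs byte-identical.
* Problem sizes in the test-suite: dense-grid shape checks use 2,001 points,
  quadrature oracles 10,001–200,001 points, and the Monte-Carlo speed
  comparison 200 replicate accessions per cohort at 50 seeds each — small
  enough for interactive runs while leaving the checks sharp.

## Design decisions on open points

* **LT50** is the first *observation day* reaching half the final
  germination level, without interpolation (an interpolating variant is
  available via `interpolate = TRUE`). This convention reproduces the
  self-consistent published benchmark entries; half of *final* — not half of
  planted — is the operative definition.
* **GI weights** are $T - t + 1$ with $T$ the experiment's last scoring day
  (10 for the hypothetical scenarios, 28 for a four-week assay), so the
  first day gets weight $T$ and the last weight 1. GI is defined on the
  stated count units and is the only index that is not invariant to the
  planted-seed scale.
* **TG** is reported as a proportion, **CVG** on the percent-per-day scale.
* **Proportions, not percentages**, enter the smoother: CGI magnitudes on a
  10-day domain then live in $[0, 10]$, which matches the published values;
  the fit itself is scale-equivariant so the choice is cosmetic for the
  spline (exactly equivariant in the tests at `1e-8`).
* The benchmark table ships to its printed precision — sets built from
  thirds of 95 total 94.8, and no renormalisation is applied.

## Limitations

* The smoothing parameters are fixed a priori; no cross-validation, and no
  uncertainty quantification for the spline or the regression coefficients.
* The sufficient-cone constraint can, in principle, be slightly conservative
  relative to the exact set of monotone splines; on all benchmark and
  simulated fits checked, the constrained optimum also satisfies the exact
  conditions with inactive margin.
* The functional regression assumes a single scalar covariate with linear
  effect; functional ANOVA and multi-covariate models are out of scope.
* With very few curves ($N = 4$ scenarios) $R^2_{glob}$ is descriptive, not
  inferential.
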