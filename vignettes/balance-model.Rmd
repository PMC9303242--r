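---
title: "The balance model: methods and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The balance model: methods and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(signalbalance)
```

## The model

An individual controls a budget $R \ge 0$ of some limiting resource — or,
more abstractly, a level of quality — and allocates it among $n \ge 2$
fitness components, $u_1 + \dots + u_n = R$, $u_i \ge 0$. Each component
$x_i(u_i)$ is a positive trait that increases with its investment; fitness
is either the sum (additive trade-off, components in a common currency) or
the product (multiplicative trade-off, e.g. mating success $\times$
viability) of the components. By convention the first component is the
signal/mating-success component: its investment $u_1$ drives an (implicit,
monotone) signal trait, so the relationship of $u_1^*$ to $R$ is the
criterion for signal honesty. We do not model the signal trait map itself;
monotonicity makes it informationally equivalent to $u_1$.

At an interior optimum, marginal fitness returns are equal across funded
components. Under the additive rule this is equality of the derivatives
$x_i'(u_i^*)$; under the multiplicative rule, equality of the elasticities
$S_i(u_i) = x_i'(u_i)/x_i(u_i)$. A component left at zero must satisfy
$S_i(u_i^*) \ge S_j(0)$ against every funded $i$ (derivatives in place of
elasticities when additive). `verify_marginal_conditions()` checks both.

Honesty hinges on how $S_2$ responds to investment. Since
$S_2' = (x_2''x_2 - x_2'^2)/x_2^2$, the sign of the margin
$m(u) = x_2''x_2 - x_2'^2$ (`condition8_margin()`) decides: $m \le 0$
everywhere (linear or decelerating viability — and exponentials, which sit
exactly at $m = 0$) makes $S_2$ non-increasing, and a *strictly* decreasing
$S_2$ guarantees $u_1^*$ non-decreasing in $R$. A positive-$m$ interval is
necessary, but not sufficient, for honesty to break down. The package
treats the sufficiency claim as an empirically tested property (the test
suite exercises it on randomly generated scenarios), not as proved
machinery.

## Components and scenarios

Catalog forms (`make_component()`) carry hand-derived analytic first and
second derivatives; the test suite verifies every form against central
finite differences at random points (relative tolerance $10^{-5}$).
User-supplied functions (`tabulated_component()`) fall back to central
differences with step $h = 10^{-6}\max(1, |u|)$ (one-sided at the domain
edge; a larger $h = 10^{-4}\max(1,|u|)$ for second differences, where the
$O(h^{-2})$ roundoff amplification dominates otherwise).

The built-in scenarios pair:

* `fig1_additive` / `fig1_multiplicative`: $x_1 = 1.5u_1 - 0.7u_1^2$,
  $x_2 = u_2$. The additive version has a single slope-matching point at
  $u_1 = 5/14 \approx 0.357$ ($x_1 = 25/56 \approx 0.446$), so the optimal
  signal is budget-independent: uninformative, though not dishonest. The
  multiplicative version is honest.
* `fig2`: $x_1 = 0.2 + u_1 - 0.5u_1^2$, $x_2 = u_2 + u_2^{20}$. The
  viability term accelerates violently once $u_2$ approaches 1; the margin
  $m$ turns positive near $u_2 \approx 0.74$ and honesty breaks: the
  optimal path drops $u_1$ over a budget interval. ($m$ turns negative
  again near $u_2 \approx 1.44$, where $S_2 \approx 20/u_2$ resumes
  decreasing — acceleration alone is not enough; it must beat the
  $1/x_2$ dilution.) The scenario records a recommended budget range of
  $[0, 3]$; far larger budgets overflow $u_2^{20}$ in double precision,
  and the solver reports (never clips) non-finite evaluations.
* `fig3`: $x_1 = \exp[0.1u_1 + \mathrm{erf}(3(u_1 - 3))]$,
  $x_2 = \exp[1 - e^{-u_2}]$. Here $S_2(u) = e^{-u}$ is strictly
  decreasing, so the path is honest, yet rich: a no-signal corner prefix
  ($u_1^* = 0$, baseline $x_1(0) = e^{\mathrm{erf}(-9)} \approx 0.368$) up
  to $R \approx 2.3$, a stretch with $u_2^*$ pinned at $\ln 10$ (where
  $S_2 = 0.1$ matches the pre-sigmoid slope of the signal), a
  discontinuous jump at $R \approx 2.90$ where the allocation tunnels to
  the far side of the sigmoid, a stretch with $u_2^* = 0$ ending at
  $R \approx 3.38$, and finally joint increase. The corner prefix does not
  count against honesty: absent signals simply mark the lower quality
  range.
* `symmetric_linear`: $x_1 = u_1$, $x_2 = u_2$, multiplicative; the
  optimum is the equal split, a convenient exact fixture.

`erf` is computed from the normal CDF ($\mathrm{erf}(z) = 2\Phi(z\sqrt2)-1$),
exact to double precision.

## The optimizer

For $n = 2$ the problem is one-dimensional in $u_1 \in [0, R]$. The
objective can be multimodal (the sigmoidal scenario has two coexisting
local optima near the jump), so single-start local optimisation is
incorrect. The solver (i) evaluates a dense scan (default 4096 points,
uniform in $u_1$; any non-finite value aborts with the offending point),
(ii) brackets every interior local maximum between its scan neighbours and
refines each by golden-section search, (iii) polishes each refined point by
root-finding on the analytic first-order condition
$x_1'x_2 - x_1x_2'$ (multiplicative) or $x_1' - x_2'$ (additive) when the
bracket shows a sign change, accepting the stationary point unless it is
worse beyond numerical noise, and (iv) always evaluates both corners. Ties
within $10^{-9}$ (relative) in fitness return the smaller $u_1$ and set
`multiplicity = TRUE`; the budget at which two optima tie is exactly a
discontinuity of the path. This yields interior first-order residuals
around $10^{-9}$, comfortably inside the $10^{-6}$ diagnostic tolerance.

For $n > 2$ the budget is split recursively: optimise $u_1$ against the
optimal allocation of the remainder, with coarser inner scans. This is
deterministic by construction — we chose a dense nested scan over seeded
multistart because the scan already brackets multimodality and removes
seed dependence from results — and is documented as best-effort;
`brute_force_allocation()` (exhaustive simplex gridding, $n \le 3$) is the
independent cross-check, and the property tests hold the $n = 2$ solver to
it on 50 random scenarios.

`allocation_path()` solves each budget on a strictly increasing grid,
flags jumps in $u_1^*$ exceeding
$\max(0.05,\ 10 \times \mathrm{median}\ |\Delta u_1|)$ between adjacent
grid points, and narrows each jump bracket by bisection on $R$ (assigning
each midpoint to the branch whose $u_1$ it is nearer) to width
$\le 10^{-4}$. Budget intervals where a component sits at zero are
reported as corner segments.

## Honesty classification

`honesty_report()` ignores decreases of $u_1^*$ smaller than an absolute
tolerance (default $10^{-6}$) so that refinement noise cannot create
spurious dishonesty, reports maximal violation intervals otherwise, and
separately flags the constant-$x_1$ case (information-free, as in the
additive example) and the no-signal corner prefix. The two theoretical
diagnostics are evaluated over the viability investments the path actually
visits: sign regimes of $m(u)$ (`classify_regimes()`, probing plus root
bisection at sign changes; margins below $10^{-9}$ of the local $x^2$
scale count as zero, which is where exponential components sit) and strict
decrease of $S_2$ (`s2_monotonicity()`, 512 probe points by default, a
necessary-condition check rather than a proof; a failure returns a witness
pair). If $S_2$ is strictly decreasing and the path still shows a
violation, the report warns: that combination indicates a solver failure,
not dishonesty.

## Random scenarios and what the tests show

`random_scenario()` builds multiplicative two-component scenarios for the
property tests: $x_1$ is an increasing concave quadratic with positive
intercept (positivity and monotonicity on the working range $[0, 10]$ hold
by construction, not clipping), and $x_2$ comes from a requested curvature
class — concave quadratic (decelerating), positive-slope linear, or a
power-sum $c + u + (u/u_{1/2})^{p}$-style accelerating form with
$p \in [6, 20]$ and the half-way scale $u_{1/2}$ placed inside the working
range so the acceleration is actually visited. Parameter ranges
(slopes and intercepts of order one) were fixed once as representative of
trade-offs whose components change by factors of a few across the budget
range. Generation is seed-deterministic and restores the caller's RNG
state.

The property tests run the sufficiency claim (strictly decreasing $S_2$
$\Rightarrow$ honest) on 30 such scenarios over 200-point budget grids,
the necessity claim (dishonesty $\Rightarrow$ positive-margin interval
within the visited range) on accelerating scenarios, and oracle
equivalence of the solver on 50 scenarios. Problem sizes (grids of
150–601 budgets, scans of 1024–4096 points, brute-force grids of $10^4$)
were chosen so the full suite runs in well under a minute at desk scale
while leaving grid spacing far finer than any tolerance asserted. These
scenarios emulate smooth, deterministic allocation problems; they do not
emulate measurement noise, discrete strategies, receiver coevolution, or
within-lifetime reallocation, so passing tests speak to the allocation
theory, not to inference from empirical data.

## Known limitations

* $n > 2$ optimisation is best-effort (nested scans); certify solutions
  with `verify_marginal_conditions()` or the brute-force oracle.
* Discontinuity detection is grid-relative: jumps smaller than the
  threshold, or multiple jumps between adjacent grid points, need a finer
  grid.
* Honesty is assessed on the analysed grid only; it is a numerical
  classification at the stated tolerances, not a proof.
* Direct viability costs of signaling (predation on the ornament itself)
  are not modelled; the trade-off is purely through the shared budget.
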