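---
title: "Methods: ensemble optimal control of adaptive therapy schedules"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ensemble optimal control of adaptive therapy schedules}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oncoctrl)
```

## The model

`oncoctrl` studies long-term drug scheduling for a tumor made of a
drug-sensitive subpopulation $s$ and a drug-resistant subpopulation $r$,
competing for shared resources under logistic (Lotka–Volterra) dynamics.
After normalizing populations by the carrying capacity and time by the
sensitive proliferation rate $r_S$, the state evolves as

$$
\dot s(\tau) = \big(1 - s - r\big)\big(1 - \hat d_D\, u(\tau)\big)\, s - \hat d_T\, s,
\qquad
\dot r(\tau) = \hat r_R \big(1 - s - r\big)\, r - \hat d_T\, r,
$$

with total burden $n = s + r$ and a normalized dose $u(\tau) \in [0,1]$ as
the control. The system is control-affine: the drug only multiplies the
sensitive growth term, so a strong enough dose ($\hat d_D > 1$) turns
sensitive growth into decay while leaving resistant cells untouched.
Parameters:

| parameter | meaning | default / range |
|---|---|---|
| $\hat d_D$ | rescaled drug sensitivity ($2 d_D$) | 1.5 |
| $\hat d_T$ | rescaled turnover rate ($d_T / r_S$) | 0 (most adverse) |
| $\hat r_R$ | resistant proliferation relative to sensitive | $[0.5, 1]$ |
| $\hat f_0$ | initial resistant fraction | $[0.002, 0.1]$ |
| $n_0$ | initial normalized burden | 0.25, 0.50, 0.75 |

The initial state is $s(0) = (1 - \hat f_0)\, n_0$, $r(0) = \hat f_0\, n_0$.
The package also implements the $n$-species generalization with transition
matrices (`general_model_spec()`); unit tests verify that the two-species
specialization matches the non-dimensional system to $10^{-12}$. Resistance
here is purely primary: no sensitive-to-resistant transitions occur during
the dynamics, so the model is about *managing* a pre-existing resistant
clone, not preventing its emergence.

## Parameter uncertainty as an ensemble

Patient-specific values of $\hat r_R$ and $\hat f_0$ are unknown, so a
schedule is evaluated against a whole *ensemble* of tumors: a probability
measure over parameter tuples $\theta = (\hat d_D, \hat d_T, \hat r_R, \hat
f_0)$. The reference ensemble (`theta_grid()`) is a uniform product grid of

* 25 nodes $\hat r_R = 0.5, 0.52, \ldots, 0.98$, and
* 49 nodes $\hat f_0 = 0.002, 0.004, \ldots, 0.098$,

i.e. $N = 1225$ tumors with weight $1/1225$ each. Both axes are half-open
equispaced grids: the stated node counts and spacings fix the largest node
one step below the nominal upper interval ends ($1$ and $0.1$). This is the
package's reproduction of the benchmark grid; with upper-inclusive
endpoints the worst-case progression times come out 4–5 days shorter and
the benchmark tables no longer match.

## Numerical scheme

All trajectories use the explicit Euler method with stepsize
$h = r_S/8 = 3.375\times 10^{-3}$ in normalized time — exactly 8 steps per
simulation day — matching the benchmark tables bit-for-bit. Euler is a
deliberate choice over adaptive solvers: the reported quantities are tied
to this discretization, and the optimizer differentiates *the discrete
scheme itself* (below), which requires a fixed grid. Adaptive solvers
(deSolve) appear only as independent oracles in the test suite. The state
stays in the simplex $\{s, r \ge 0,\ s + r \le 1\}$ up to $O(h)$
excursions for any admissible control; the integrator guards against
runaway states ($n > 1.5$) instead of implementing a smooth vector-field
cutoff — the invariance property guarantees the guard never fires for
admissible inputs, so the cutoff would only matter for analytical
arguments, not computation.

## Time to progression

A tumor "progresses" when its burden reaches 120% of the initial value.
On the Euler grid the package reads both progression metrics as suprema of
sub-threshold times:

* `ttp_days` — the last grid time before the burden has ever reached
  $1.2\,n_0$ (one step before the first crossing);
* `ttp_prime_days` — the last grid time with burden $\le 1.2\,n_0$,
  which credits schedules whose trajectories exceed the threshold early
  but re-descend (the Off-On protocol and hyperbolic-cost schedules do
  this by design).

Both are censored at the horizon. Reading both metrics as suprema keeps
`ttp_days <= ttp_prime_days` exact for every member — the discrete analogue
of the continuity argument that orders the two in continuous time — and
for monotone crossings the two coincide, as observed for MTD and On-Off
runs. Reporting convention: per-member days are floored to whole days;
ensemble means are the floor of the mean of grid-resolution day values.
This convention reproduces every entry of the benchmark tables exactly;
the first-crossing alternative shifts several entries by one day.
Horizons are paired with the initial burden: 750 days for $n_0 = 0.25$,
1000 for $0.50$, 1500 for $0.75$ ($T = 20.25, 27, 40.5$).

## Therapy protocols

* **MTD** — continuous maximal dose, $u \equiv 1$.
* **On-Off adaptive therapy** — treat until the burden halves
  ($n \le n_0/2$), pause until it recovers ($n \ge n_0$), repeat.
* **Off-On adaptive therapy** — surveil until the burden nears progression
  ($n \ge 1.2\,n_0$), then treat until it halves, repeat.

Rules observe only the total burden $n$ (subpopulations are not separately
measurable in practice) and are re-evaluated at every Euler step; switches
trigger exactly at threshold equality. A `decision interval` coarser than
the step is deliberately not the default: the protocols are defined in
continuous time and the step is already 1/8 day.

## Costs and ensemble functionals

Open-loop schedules are scored by integral burden penalties
$\ell^1(n) = n - n_0$ (linear, symmetric) and
$\ell^2(n) = \sqrt{1 + (n - n_0)^2} - 1 + (n - n_0)$ (hyperbolic,
asymmetric: growth costs more than shrinkage earns, encoding
stabilization rather than eradication as the goal). The ensemble
functional is either the weighted average of per-member integrals or their
maximum (worst case / minimax).

Quadrature is the left-endpoint Riemann sum over the Euler nodes, the
final state carrying no weight. The rule is chosen to pair exactly with
the discretize-then-differentiate adjoint: the adjoint's terminal
condition $g(T) = 0$ and the left rule make the assembled gradient the
*exact* derivative of the discrete functional, so the finite-difference
oracle in the tests is an equality check (to $10^{-5}$ relative,
limited by the differencing itself), not an approximation comparison.
Swapping the quadrature endpoint changes functional values by $O(h)$ and
none of the reported day values beyond their tolerance.

## Gradients and projected descent

For each member, the backward recursion

$$
g_K = 0, \qquad
g_k = g_{k+1}\big(I + h\, \partial_x f(x_k, u_k)\big) + h\, \ell'(n_k)\,(1,1)
$$

yields the discrete adjoint, and the L2 (Riesz) gradient field is
$\nabla J_k = \sum_\theta w_\theta\, g^\theta_{k+1} F_1^\theta(x^\theta_k)$
with $F_1 = (-\hat d_D (1 - n)\, s,\ 0)^\top$; the raw directional
derivative is $h \sum_k \nabla J_k\, \delta_k$. The optimizer iterates

$$
u \leftarrow \Pi_{[0,1]}\big[u - \eta\, \nabla J\big],
\qquad \eta = 0.125,\ u^{(0)} \equiv 0.5,\ 500 \text{ iterations},
$$

with the step applied to the L2-scaled gradient. The scaling is a genuine
design decision: applied instead to the raw per-step derivative
($h\nabla J$), the effective step would be $\sim\!4\times10^{-4}$ and 500
iterations would leave the flat initial guess essentially unchanged,
contradicting the bang-bang profiles the benchmark schedules exhibit.
The projected step equals projection along the tangent-cone direction at
every iterate (verified on boundary-touching runs), so no separate cone
projection is needed. One control value per Euler step is optimized; runs
are deterministic and bit-reproducible.

The minimax variant is a plain projected subgradient iteration with the
same constant step: each iteration locates the member with the largest
individual cost (lowest index on ties) and descends along that member's
gradient. More elaborate subgradient schemes (diminishing steps, iterate
averaging) exist in the literature; the plain variant is implemented and
documented as such, and worst-case results should be read with that in
mind.

## What reproduces, and a known divergence

With these conventions the package reproduces, on the full 1225-member
grid: all 18 MTD / On-Off table entries and all 9 Off-On entries within
±2 days (most exactly), the single-tumor runs at 370 / 424 / 459 days
exactly, the linear-cost optimized schedules (indistinguishable from MTD,
as expected from a symmetric penalty), and the hyperbolic-cost averaged
schedule for $n_0 = 0.5$ (mean TTP′ 334 vs 336 reference).

The hyperbolic averaged problem for $n_0 = 0.75$ converges to a different
local optimum than the reference run: mean TTP′ 764 days versus the
reported 660. The functional is nonconvex in $u$, and two independent
implementations of the identical update (the package's C++ path and a
NumPy prototype) agree with each other to all reported digits, so the
discrepancy is a basin-of-attraction difference, not an implementation
error — plausibly seeded by arithmetic differences (e.g. single-precision
autodifferentiation) in the original experiments. Notably the package's
optimum scores *better* on the progression metric (longer mean TTP′ with
the same functional form). The per-day control parameterization was also
examined and moves the result further away (mean 909), so the per-step
parameterization stands. Similarly, the worst-case (minimax) hyperbolic
schedules depend on the exact subgradient scheme; the linear minimax runs
land within a day of MTD while hyperbolic minimax runs can settle in
basins tens of days away from it.

## Problem sizes in the test suite

Unit and property tests run on small ensembles (2–6 members) and short
horizons (tens of days, 40–200 control steps), where finite-difference
oracles and plain-R re-implementations are exact companions. The
reproduction tests run the full 1225-member grid at the reference
horizons and all five 500-iteration optimizations; a full suite completes
in minutes on one core because the Euler and adjoint sweeps are compiled.

## Limitations

* No acquired resistance, no pharmacokinetics (dose is identified with
  effect-site concentration), no stochastic or spatial effects: the
  ensemble expresses parametric uncertainty over a deliberately simple
  deterministic model.
* Progression metrics are grid-resolution quantities; no sub-step event
  location is attempted.
* The synthetic-ensemble generator samples the same parameter boxes as
  the reference grid; it emulates parametric spread, not measurement
  noise or model misspecification, so passing tests say nothing about
  fit to clinical data.
* Optimized schedules are open-loop: they fix a dose profile in advance
  rather than reacting to observations, and their worst-case versions
  inherit the subgradient caveats above.
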