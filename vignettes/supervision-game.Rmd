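---
title: "The tripartite healthcare-fraud supervision game: model and methods"
author: "fraudgame"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The tripartite healthcare-fraud supervision game: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fraudgame)
```

## The model

Healthcare fraud supervision is modelled as an evolutionary game between
three boundedly rational populations: hospitals choosing between *compliant*
and *illegal* operation (frequency of compliance $x$), third-party
investigators choosing between *true* and *false* investigation (frequency of
true investigation $y$), and local governments choosing between *strict
supervision* and *non-supervision* (frequency of strict supervision $z$).
Players do not best-respond instantly; strategy frequencies drift toward
whatever currently earns more than the population average — the replicator
dynamics.

Sixteen non-negative parameters (arbitrary common currency unit) describe
the stage game: operating costs $C_{h1} > C_{h2}$ and incomes
$I_{h2} > I_{h1}$ of the hospital (illegal operation is cheaper and more
lucrative), investigation costs $C_{t1} > C_{t2}$ and incomes
$I_{t2} > I_{t1}$ of the third party (the excess income under a false
investigation is a bribe from an illegal hospital), the government's
supervision cost $C_g$ and social benefits $I_{g1} > I_{g2}$, and a
reward–punishment mechanism: a reward $A_h < C_{h1}$ to compliant hospitals
under strict supervision, fines $P_h$ (hospital) and $P_t$ (third party), a
superior-government reward $A_g < C_g$ for supervising and a fine $P_g$ for
unsupervised fraud.  `validate_params()` enforces these orderings; the
*strict* tier additionally requires $P_h, P_t, P_g > 0$ because the
threshold formulas divide by them.

The payoff table over the eight pure-strategy profiles
(`payoff_matrix()`) is the single source of truth.  An illegal hospital is
fined $P_h$ unless **both** supervisors look away; the third party is fined
$P_t$ for a false investigation only under strict supervision; the
government pays $C_g$ and earns $A_g$ when it supervises, collects the
fines, and is itself fined $P_g$ when fraud passes both filters.

## Replicator dynamics and the two modes

Writing each player's expected-payoff advantage of its first strategy as a
*factor function*,

$$G(y,z) = C_{h2}-C_{h1}+I_{h1}-I_{h2}+zA_h+P_h(y+z-yz),$$
$$J(x,z) = C_{t2}-C_{t1}+(1-x)(I_{t1}-I_{t2})+zP_t \quad (\text{matrix form}),$$
$$H(x,y) = C_g-A_g-P_g-P_h-P_t+xA_h+(x+y-xy)(P_g+P_h)+yP_t,$$

the dynamics are
$$\dot x = x(1-x)\,G, \qquad \dot y = y(1-y)\,J, \qquad \dot z = z(z-1)\,H,$$
so $H$ is the *disadvantage* of strict supervision: $z$ grows where $H<0$.

The package implements two `mode`s of the third-party equation.  The
`"reference"` mode is the equation system in the form conventionally stated
for this game, whose $J$ carries an extra bilinear term
$xz(I_{t1}-I_{t2})$; the `"matrix"` mode is derived exactly from the payoff
table.  `equation_audit()` certifies, by exact polynomial-identity testing
on a grid (all expressions are degree-3 polynomials, so generic agreement is
a proof), that the $x$- and $z$-equations coincide in both modes, that the
$y$-equations differ by exactly $y(1-y)\,xz\,(I_{t1}-I_{t2})$, and that the
three-term truncated variant of the supervision payoff $E_{31}$ omits
exactly the profile term $(1-x)(1-y)(I_{g2}-C_g+P_h+P_t+A_g)$.

The divergence is not cosmetic.  Under the scenario-3 parameter set the
corner $(1,0,1)$ has eigenvalue $C_{t2}-C_{t1}+I_{t1}-I_{t2}+P_t = -0.3$
under the reference dynamics but $C_{t2}-C_{t1}+P_t = +0.2$ under the
matrix dynamics, so the policy-target equilibrium is an ESS only under the
reference mode.  The reference mode is therefore the default — it is the
form under which the tabulated eigenvalues and scenario endpoints of this
model are reproducible — and the matrix mode is provided for transparency.
A second consequence: $\partial J/\partial z = P_t + x(I_{t1}-I_{t2})$ in
reference mode can be negative when $x(I_{t2}-I_{t1}) > P_t$, so the
"more supervision, more honest investigation" coupling is guaranteed only
in the matrix mode (where $\partial J/\partial z = P_t$).

## Equilibria and stability

All eight cube corners are rest points for any parameter set
(`pure_equilibria()`).  `candidate_equilibria()` enumerates the full census
of 15 candidates: 8 corners, one candidate per face (the two surviving
factor equations are affine there and solved exactly), and one interior
candidate obtained by eliminating $x$ and $y$ through the indifference
thresholds and searching $H(x^*(t), y^*(t)) = 0$ in the remaining variable
over a wide window.  Candidates outside $[0,1]^3$ are flagged, not dropped;
degenerate faces (on $z=1$ both $G$ and $J$ lose their dependence on the
free variable) are reported `undefined` with a reason.

Stability is assessed by the first Lyapunov method.  At a corner the
Jacobian is diagonal, with entries $(1-2x)G$, $(1-2y)J$, $(2z-1)H$;
`eigenvalues_at_pure()` reports them in the conventional per-corner order of
this model's tabulation.  `classify_equilibrium()` calls ESS / unstable /
saddle by strict signs with tolerance `tol = 1e-9`; any eigenvalue within
`tol` of zero yields `"indeterminate"` because linearization is inconclusive
there (the scenario-1 set itself puts $A_h+P_h$ exactly equal to
$C_{h1}-C_{h2}+I_{h2}-I_{h1}$, a tie at corner E7).  Mixed candidates are
enumerated but never classified — asymptotically stable states of a
replicator system must be strict pure Nash equilibria, so face and interior
candidates are out of classification scope.

Five corners can never be ESS for valid parameters (E2, E3, E5, E7, E8 each
have an eigenvalue forced positive by the cost/income orderings).  The
condition flags bear a precise relation to the remaining three:
condition A ($C_g > A_g+P_g+P_h+P_t$) is *exactly equivalent* to E1 being
the ESS, whereas B and C are *necessary but not sufficient* for E4 and E6:
E4 additionally needs $C_g < A_g+P_g+P_h+P_t$, and E6 needs
$P_t < C_{t1}-C_{t2}+I_{t2}-I_{t1}$ and $A_h+P_h > C_{h1}-C_{h2}+I_{h2}-I_{h1}$
(the tabulated "definitely negative" eigenvalue signs make these extra
inequalities tacit).  The test suite asserts the exact characterisations on
a thousand random parameter sets rather than the loose equivalences.

## Thresholds and region measures

On each player's own face the factor's zero set is an indifference curve:
$y^*(z)$ for the hospital, $x^*(z)$ for the third party, $y^{**}(x)$ for the
government.  Their axis intercepts define segment lengths
($A_1B_1 = \frac{C_{h1}-C_{h2}-I_{h1}+I_{h2}}{A_h+P_h}$ and so on) whose
right triangle halves approximate the basin measures $V_{h2}$ (illegal
operation), $V_{t2}$ (false investigation) and $V_{g1}$ (strict
supervision).  The curves are hyperbolic, not straight, and the intercepts
routinely exceed 1 (scenario 1 gives $A_1C_1 = 2$), so
`threshold_geometry()` reports the triangle construction *clipped* to
$[0,1]$ with explicit flags, alongside an `"integral"` method that measures
the exact sign regions $\{G<0\}$, $\{J<0\}$, $\{H<0\}$ by a midpoint rule
on a $512\times512$ grid (the default resolution leaves quadrature error
well below the $10^{-3}$ comparison tolerances used in tests; because
parameter bumps shift the factors pointwise-monotonically, the grid measure
is exactly monotone at any resolution).  When the government's intercepts
are non-positive the strict-supervision region is empty and $V_{g1}=0$.

`sensitivity_signs()` differentiates the six segment lengths in closed form,
cross-checks against central finite differences, and propagates the signs to
the region measures along the segments the standard proofs use ($A_1B_1$,
$A_2B_2$, $A_3B_3$).  One caveat it reports honestly: $\partial
A_3B_3/\partial P_g = \partial A_3B_3/\partial P_h =
(A_h+C_g-A_g-P_t)/(A_h+P_g+P_h)^2$, whose sign flips exactly under ESS
condition C, so the textbook "fines always enlarge the supervision basin"
sign claim holds for the segment only outside that regime.  The
region-measure version of the claim *is* unconditional ($\partial
H/\partial P_g = -(1-x)(1-y) \le 0$ pointwise) and is what the test suite
asserts on random sets via the integral method.

## Numerical integration

The replicator field is polynomial and non-stiff; `integrate_game()` uses
adaptive Runge–Kutta 4(5) (`deSolve`, method `"ode45"`) with `rtol = 1e-8`,
`atol = 1e-10`, reporting on 201 evenly spaced times by default.

Interior coordinates are integrated on the *logit* scale, where the
dynamics collapse to $\dot u = G$, $\dot v = J$, $\dot w = -H$ with
$(x,y,z) = \mathrm{logistic}(u,v,w)$.  This choice is deliberate: direct
Cartesian integration (with clamping to $[0,1]$) absorbs trajectories onto
boundary faces once a coordinate is within machine epsilon of the boundary,
and a saddle corner that is attracting *within* a face then permanently
captures about 1% of trajectories — an artifact, since the exact flow
never reaches the boundary in finite time and eventually escapes saddles.
In logit coordinates the interior flow is represented exactly, boundary
containment is automatic, and escape happens as in the exact dynamics.
Components whose initial value is exactly 0 or 1 are held fixed (boundary
faces are invariant), so corner starts yield constant trajectories.

`converged_state()` declares convergence when, over the final 10% of the
trajectory, the state moves less than `tol` (default $10^{-3}$) and the
frequency-scale rates stay below `2 tol` — plus a drift guard: for any
initially interior component that ends within 0.01 of a boundary, the
per-capita growth rate (the factor value) must point *into* that boundary.
Without the guard, a trajectory lingering exponentially close to a saddle
corner looks stationary at frequency scale ($\dot x = x(1-x)G$ vanishes as
$x$ saturates even when $G>0$) although it will leave; such states are
reported "not converged".  Default horizon $T=50$ comfortably settles all
three scenario presets (which are typically plotted on $T\in[0,10]$ or
$[0,20]$); endpoint assertions use a 0.01 comparison tolerance, and halving
the integrator tolerances moves preset endpoints by less than $10^{-6}$.

## Scenario presets and the parameter sampler

The three built-in presets are the standard study conditions of this model,
started from $(x,y,z) = (0.8, 0.5, 0.2)$:

1. **Costly supervision** (condition A): everything decays —
   $(0,0,0)$, full defection.
2. **Affordable supervision, weak deterrence** (condition B, with
   $C_g < A_g+P_g+P_h+P_t$): $(0,0,1)$, the government supervises but
   fines are too small to deter.
3. **Subsidised supervision, strong hospital fine** (condition C):
   $(1,0,1)$, compliant operation under strict supervision — the policy
   target.  The third party still drifts to false investigation in every
   scenario: with no reward for true investigations, $J<0$ throughout.

`sample_valid_params()` is the test-suite generator: costs and incomes
uniform on $(0,10]$, rewards and fines on $(0,5]$, rejection-sampled until
the strict constraints (and, optionally, one of conditions A/B/C) hold,
fully determined by its seed.  The ranges bracket the scenario presets
(whose values lie in $[0.5, 10]$) and put every ordering constraint in a
non-degenerate regime; roughly one draw in sixty is a valid game, so a
sample costs microseconds.  What the generator emulates is the *parameter
uncertainty* of the model — it makes no claim that real supervision regimes
are uniformly distributed, and passing property tests certify the
mathematics (classification algebra, containment, convergence targeting)
rather than any empirical fact about healthcare systems.

## Problem sizes used by the test suite

Property tests run on 1000 sampled parameter sets for the classification
algebra, 200 sets × 5 interior starts (1000 trajectories, horizon $T=150$)
for containment and ESS-consistency, 200 sets for eigenvalue-table
fidelity, and 40 sets for region-measure monotonicity at grid resolution
128 (exact monotonicity is resolution-independent; 128 keeps the loop
fast).  These sizes were chosen so the whole suite certifies each property
broadly while finishing in a few minutes on a single core.

## Known limitations

* Mixed (face/interior) equilibria are enumerated but not classified; no
  center-manifold analysis backs the `"indeterminate"` calls.
* The triangle region measures are the model's own approximation; the
  integral method is the reference when the two disagree.
* No finite-population or stochastic dynamics; no time-varying parameters;
  no reward mechanism for the third party (under every preset the third
  party ends at false investigation, which is the model's point, not a
  bug); patients are not modelled as a fourth player.
* Convergence detection is heuristic at any finite horizon: the drift guard
  removes the saddle-lingering false positives we observed, but a state
  hovering near a boundary with a drift smaller than the tolerance is still
  called converged.
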