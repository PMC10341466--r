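# fraudgame

Evolutionary-game analysis of healthcare-fraud supervision.

Hospitals can bill for services never rendered; governments hire third-party
investigators to catch them; investigators can be bribed into filing false
reports; and a superior government rewards or fines the local government for
how well it supervises the whole arrangement.  `fraudgame` implements this
three-player game — hospital (compliant vs illegal operation), third-party
investigator (true vs false investigation), local government (strict
supervision vs non-supervision) — as a tested replicator-dynamics simulator
and stability analyzer, for policy modellers who want to know *which
reward–punishment mechanisms make compliance evolutionarily stable*.

## The model

Strategy frequencies `(x, y, z)` — compliance, true investigation, strict
supervision — evolve on the unit cube by replicator dynamics

    dx/dt = x(1-x) G(y,z)
    dy/dt = y(1-y) J(x,z)
    dz/dt = z(z-1) H(x,y)

where `G`, `J`, `H` are each player's expected payoff advantage, affine–
bilinear functions of the 16 game parameters: costs (`Ch1 > Ch2`,
`Ct1 > Ct2`, `Cg`), incomes (`Ih2 > Ih1`, `It2 > It1`, `Ig1 > Ig2`) and the
mechanism (reward `Ah < Ch1`, fines `Ph`, `Pt`, superior-government reward
`Ag < Cg` and fine `Pg`).  The package provides:

* the full 8-profile payoff matrix and expected payoffs (`payoff_matrix()`,
  `expected_payoffs()`), the single source of truth for the dynamics;
* the replicator field in two documented variants (`mode = "reference"`,
  the conventionally stated equations, vs `mode = "matrix"`, derived
  exactly from the payoff table; `equation_audit()` certifies their
  precise algebraic difference);
* equilibrium analysis: the 15-candidate census (`candidate_equilibria()`),
  corner eigenvalues and first-Lyapunov classification
  (`eigenvalues_at_pure()`, `classify_equilibrium()`, `stability_report()`),
  and the ESS conditions A/B/C (`condition_flags()`);
* indifference thresholds, intercept geometry, basin measures and
  sensitivity signs (`y_star()`, `threshold_geometry()`,
  `sensitivity_signs()`);
* deterministic simulation, scenario presets, convergence and
  crossing-time diagnostics, and parameter sweeps (`integrate_game()`,
  `run_scenario()`, `parameter_sweep()`), wrapped in a classed model object
  (`fraud_game()`) with `print`, `summary`, `coef`, `simulate` and `plot`
  methods;
* a command-line front end in `inst/scripts/fraudgame`
  (`simulate | stability | thresholds | sweep | check`).

## Worked example

Scenario preset 3 is the policy success case: a strong hospital fine and a
subsidised supervision cost.

```r
library(fraudgame)
g <- fraud_game(scenario_params(3))
g
#> Tripartite healthcare-fraud supervision game (mode: reference )
#> Healthcare-fraud supervision game parameters
#>  Ch1 Ch2 Ct1 Ct2 Cg Ih1 Ih2 It1 It2 Ig1 Ig2  Ah  Ph  Pt  Ag Pg
#>    6 4.5   2   1  5 6.5   7 2.5   3 5.5   4 0.6 4.5 1.2 4.9  3
#> ESS conditions: A = FALSE  B = FALSE  C = TRUE
#> ESS corner(s): E6
```

Condition C (`Ah + Cg < Ag + Pt`) holds, so the corner `E6 = (1, 0, 1)` —
compliant hospitals under strict supervision — is the unique evolutionarily
stable strategy.  The eigenvalue table confirms it (all three negative only
at E6):

```r
stability_report(scenario_params(3))
#>   point lambda1 lambda2 lambda3    class condA condB condC
#> 1    E1    -2.0    -1.5     8.6   saddle FALSE FALSE  TRUE
#> ...
#> 6    E6    -0.5    -0.3    -3.1      ESS FALSE FALSE  TRUE
#> ...
```

Simulation from the standard initial state `(0.8, 0.5, 0.2)` lands there:

```r
tr <- simulate(g)          # replicator ODE, T = 50
tail(as.data.frame(tr), 1)
#>     time x            y z
#> 201   50 1 4.680725e-08 1
```

Note `y -> 0`: with no reward for true investigations, the third party
always drifts to false investigation — the model's central caveat about
outsourced supervision.  The basin geometry quantifies how mechanism levers
move these outcomes; for scenario 2, strict supervision starts from a basin
of measure ~0.08 on the `(x, y)` face:

```r
threshold_geometry(scenario_params(2))
#> region measures:
#>    Vh1    Vh2    Vt1    Vt2    Vg1    Vg2
#> 0.0000 1.0000 0.0000 1.0000 0.0798 0.9202
```

Sweeps reproduce the comparative statics: e.g. a larger hospital fine `Ph`
speeds the drift to compliance (`parameter_sweep(scenario_params(3), "Ph",
c(4.5, 5, 5.5), metric = list(component = "x", level = 0.9, direction =
"above"))` gives strictly decreasing crossing times).

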