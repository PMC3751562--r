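# pancfate

Multicellular modelling of pancreatic acinar–islet cell fate control by
contact-mediated (lateral) signaling.

## The problem

Pancreatic acinar cells can transdifferentiate into hormone-producing islet
cells — a candidate route to β-cell replacement in diabetes — and they do so
*in vitro* after nothing more than enzymatic dissociation of the tissue,
without genetic manipulation. Two contact-mediated signals are implicated:
a **lateral stabilization** signal between adjacent acinar cells that
maintains the exocrine identity, and Delta–Notch-type **lateral
inhibition** that hampers endocrine commitment. `pancfate` implements a
dynamical model of this system for researchers studying cell-fate stability
and microenvironment-induced reprogramming: it couples a four-factor gene
regulatory circuit per cell to its neighbours on a tissue and asks which
fate patterns are stable, and how they are lost.

## The model

Each cell carries four dimensionless expression levels: *A* (an upstream
inducer, Hnf6-like), *X* (pro-endocrine, Ngn3-like), *Y* (exocrine
determinant, Ptf1a-like) and *Z* (terminal islet marker, Isl1-like). With
X̄, Ȳ the average expression of *X*, *Y* over the directly adjacent cells
and Hill coefficient *n*:

    dA/dt = 1 / (1 + r Yⁿ + r Zⁿ) − A
    dX/dt = q Aⁿ / (q + a X̄ⁿ) − X + ξ_x(t)
    dY/dt = (q Aⁿ + b (Y Ȳ)ⁿ) / (q + b (Y Ȳ)ⁿ + c Xⁿ + c Zⁿ) − Y + ξ_y(t)
    dZ/dt = (Xⁿ + s Zⁿ) / (1 + s Zⁿ) − Z

The `a` term is lateral inhibition (neighbour *X* represses own *X*
production); the multiplicative `b (Y Ȳ)ⁿ` term is lateral stabilization —
it requires *Y* activity in both the cell *and* its neighbours. ξ are
additive Gaussian white-noise terms of amplitude η. Cells classify as
**acinar** (*Y* ≈ 1), **islet** (*Z* ≈ 1) or multipotent **progenitor**
(both low, *A* high).

The package provides:

* `grn_rhs()`, `model_params()` — the per-cell kinetics and the reference
  parameter set (`a = 1000`, `b = 2000`, `c = 500`, `q = 1e-4`, `r = 100`,
  `s = 50`, `n = 3`, `η = 1e-3`);
* `hex_lattice()`, `triangle3()`, `graph_tissue()` — tissues with occupancy
  (density), periodic or void boundaries, and the minimal three-cell
  tissue used for bifurcation analysis;
* `simulate_tissue()` — a seeded 2nd-order Heun–Maruyama integrator
  (`dt = 0.02`, compiled core) with scheduled parameter switches ("lateral
  stabilization lost at t = 0");
* `find_fixed_point()`, `continue_branch()`, `find_fold()`,
  `directional_stability()` — Newton steady-state solving with analytic
  Jacobians, branch continuation and saddle-node (fold) location;
* `run_development()`, `run_conversion()`, `run_recovery()`,
  `run_density_sweep()`, `run_shape_sweep()` — canned protocols for
  development, transdifferentiation and conversion-efficiency sweeps;
* a command-line tool (`exec/pancfate`) with `simulate`, `bifurcate`,
  `sweep` and `report` subcommands driven by YAML configs.

## Worked example

```r
library(pancfate)

tri <- triangle3()
p <- model_params()          # reference parameterization

# the three coexisting tissue states
for (branch in c("acinar", "mixed", "islet")) {
  fp <- find_fixed_point(steady_state_guess(tri, branch), tri, p)
  cat(sprintf("%-6s sum(Y) = %.3f  stable: %s\n",
              branch, sum(fp$states[, "Y"]), fp$stable))
}

# critical stabilization strength: fold of the mixed branch
fp_mixed <- find_fixed_point(steady_state_guess(tri, "mixed"), tri, p)
b_c <- find_fold(fp_mixed, tri, p, "b", c(1e-4, 1), tol = 1e-4)$value
cat(sprintf("b_c = %.4g\n", b_c))

# acinar-to-islet conversion after loss of lateral stabilization
res <- run_conversion("stab", width = 30, height = 30, seed = 1)
print(res)
```

prints

```
acinar sum(Y) = 3.000  stable: TRUE
mixed  sum(Y) = 2.000  stable: TRUE
islet  sum(Y) = 0.000  stable: TRUE
b_c = 0.01193
Scenario 'conversion_stab' (seed 1): 900 cells
  final fates: acinar 0, islet 900, progenitor 0
  conversion fraction 1.000, time to half 19
```

Reading: on the minimal three-cell tissue the model is multistable — all
three cells acinar (summed *Y* = 3), all islet (summed *Y* = 0) or a mixed
pattern (summed *Y* = 2) are simultaneously stable at the reference
parameters. The last acinar-containing attractor vanishes in a fold when
lateral stabilization drops below `b_c ≈ 0.012`. On a 30×30 lattice
initialized as adult acinar tissue, setting `b = 0` at `t = 0` converts
every cell to the islet fate; the population is half-converted 19 time
units after the switch.

## Documentation

The methods vignette (`vignettes/lateral-signaling-fate-control.Rmd`)
describes the model assumptions, the numerical choices (integrator,
Newton/continuation settings, neighbour-signal normalization at partial
occupancy) and the known limitations. All exported functions carry roxygen
documentation.
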