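---
title: "Lateral signaling and pancreatic cell-fate control: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Lateral signaling and pancreatic cell-fate control: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pancfate)
```

## The model

`pancfate` models a patch of pancreatic tissue as cells on a lattice, each
carrying four dimensionless transcription-factor levels: an upstream
inducer $A$ (Hnf6-like), a pro-endocrine factor $X$ (Ngn3-like), the
exocrine determinant $Y$ (Ptf1a-like) and a terminal islet marker $Z$
(Isl1-like). All regulation is Hill-type with a shared exponent $n$;
variables are scaled so steady-state expression lies between 0 and 1.
Within a cell, $A$ induces both lineage factors, $X$ trans-activates $Z$,
$Z$ auto-activates, $X$ and $Z$ both suppress $Y$, and the mature markers
$Y$ and $Z$ feed back negatively on $A$. Two couplings link a cell to the
average expression $\bar X$, $\bar Y$ of its direct neighbours:

* **lateral inhibition** — neighbour $X$ suppresses own $X$ production
  through the term $a \bar X^n$ in the denominator of the $X$ equation,
  independent of the cell's own $X$. This is the Delta–Notch motif that
  produces alternating ("salt-and-pepper") fate patterns;
* **lateral stabilization** — the multiplicative term $b (Y \bar Y)^n$
  up-regulates $Y$ only when $Y$ is expressed in the cell *and* in its
  neighbours, a contact-dependent positive feedback that maintains a
  shared exocrine identity across a tissue. The molecular carrier
  (cadherin/β-catenin signaling versus gap-junctional communication) is
  deliberately left abstract: only the conditional, multiplicative form
  matters here.

Additive Gaussian white noise of amplitude $\eta_x$, $\eta_y$ acts on the
two fate-determining factors $X$ and $Y$ only; $A$ and $Z$ are treated as
deterministic read-outs of their regulators.

Cells are classified from their state: **islet** if $Z$ exceeds its
threshold, **acinar** if $Y$ exceeds its threshold and $Z$ does not, and
**progenitor** (multipotent) otherwise. Steady states cluster near 0 and
1, so any mid-range threshold separates them; the default is the symmetric
choice 0.5 for both markers, configurable in `classify_fates()`. The rare
transient case of both markers high is resolved in favour of islet; under
the reference parameters mature fates are mutually exclusive, so this
affects no steady state.

## Tissues and the neighbour average at partial occupancy

Two tissue geometries matter. The **three-cell tissue** (`triangle3()`,
three mutually adjacent cells, coordination 2) is the smallest system in
which homogeneous acinar, homogeneous islet *and* mixed configurations can
all occur, and is where all bifurcation analysis is done. The **hexagonal
lattice** (`hex_lattice()`) uses "odd-r" offset indexing with a
row-parity-dependent six-site stencil, fixed so snapshots are
bit-reproducible. Boundaries are periodic by default (bulk behaviour, no
edge artifacts; this requires an even number of rows so the stencil closes
under wrap-around) and can be set to `"fixed"` (void outside), which the
aggregate-shape protocol uses for finite cell clusters. Arbitrary
neighbour graphs are available via `graph_tissue()`.

Sites can be vacant. The neighbour signal of cell $i$ divides the sum of
neighbour expression by the topology's **nominal coordination number**
(6 on the lattice, 2 on the three-cell tissue), with vacant sites
contributing zero:
$$\bar X_i = \tfrac{1}{m}\sum_{j \in N(i),\ \text{occupied}} X_j, \qquad
  m = \text{coordination}.$$
This choice makes the received stabilization scale with local cell
density: an acinar cell with a single acinar neighbour receives
$\bar Y = Y/6$, not $Y$, and is therefore much easier to destabilize than
a bulk cell. Averaging over occupied neighbours only would make an
isolated cell pair exactly as stable as confluent tissue and would erase
the density dependence of conversion efficiency that the model exists to
study. On a fully occupied lattice with identical cells the two
conventions coincide ($\bar X = X$, $\bar Y = Y$), which is what lets the
three-cell homogeneous analysis transfer to the lattice.

## Stochastic integration

The coupled SDE system is integrated with the second-order
**Heun–Maruyama** predictor–corrector at time step $dt = 0.02$ (model time
is dimensionless). Per step, with drift $f$ and the additive noise
increment $g\,\Delta W$ where $g = (0, \eta_x, \eta_y, 0)$ per cell and
$\Delta W = \sqrt{dt}\, N(0,1)$:
$$s^* = s + f(s)\,dt + g\,\Delta W, \qquad
  s' = s + \tfrac{1}{2}\big(f(s) + f(s^*)\big)\,dt + g\,\Delta W,$$
with the *same* Wiener increment in both stages (fresh draws would break
the convergence order) and neighbour signals recomputed from the predictor
state for the corrector drift. For additive noise the Itô and Stratonovich
interpretations coincide, so the corrector is unambiguous.

**Clamping.** All components are clamped at 0 after each stage. With $n$
odd, Hill terms of (even slightly) negative arguments would corrupt
denominators, and expression levels are physically non-negative. Two
facts document that clamping is a guard, not a driver: it never activates
in noise-free runs (the deterministic flow is forward-invariant on the
unit box — every production term lies in $[0,1]$), and every clamp event
has magnitude of order $\eta\sqrt{dt} \approx 1.4\times 10^{-4}$, the size
of one noise increment. Clamp *frequency*, however, is not small in every
scenario: whenever a tissue rests in a state with $X$ at its tiny
steady-state value (adult acinar or islet tissue), roughly half of the
$X$-noise increments point below zero and are rectified. This produces a
slight positive bias in $X$ of noise-increment size and no visible effect
on any fate statistic. There is no clamp above 1: the deterministic flow
cannot leave the unit box upward, and noise excursions above 1 are
transient and self-correcting (drift at $Y > 1$ is negative).

**Reproducibility.** One seeded generator drives a run; draws are taken in
a fixed order (per step: one standard-normal vector for all cells' $X$,
then one for $Y$), so a seed fixes the trajectory bitwise. The production
path is a compiled kernel; a pure-R reference stepper with the identical
scheme and draw order backs it in the test suite, together with an
adaptive-ODE comparison (noise off) and an Ornstein–Uhlenbeck
stationary-variance check of the discretization (the scheme's stationary
variance for $dV = -V\,dt + \eta\,dW$ at $dt = 0.02$ differs from
$\eta^2/2$ by 0.03%, far below Monte-Carlo resolution).

**Protocols as schedules.** Parameter changes ("stabilization lost at
$t=0$", "recovered at $t = t_\mathrm{rec}$") are a schedule of
`(time, parameter, value)` rows; runs may start at $t = -t_\mathrm{pre}$
(default burn-in 20 time units in the conversion protocols) so the switch
marks $t = 0$. Events are recorded with old and new values.

## Steady states, stability, folds

`find_fixed_point()` applies Newton iteration to the stacked
$4\,n_\mathrm{cells}$-dimensional drift with an **analytic Jacobian**,
including the coupling blocks through $\bar X$, $\bar Y$ (residual
tolerance $10^{-10}$, 100-iteration cap; non-convergence is a reported
outcome, not an error, because fold bisection probes parameter values
where no nearby solution exists). Stability is read from the Jacobian
spectrum; because the symmetric tissues force eigenvalue multiplicities,
stability calls compare real parts against a $10^{-8}$ tolerance and never
rely on eigenvalue ordering.

**Directional stability.** Statements like "stable against perturbations
in $Y$ but unstable against perturbations in $X$" are operationalized by
assigning each growing eigenvalue to the variable with the largest
absolute **left**-eigenvector loading (summed over cells). The left/right
distinction is essential in this circuit: at the multipotent progenitor
state the growing mode is excited almost exclusively by $X$ perturbations
(left loading ratio $X : Y \approx 120 : 1$) — it is the
lateral-inhibition competition mode — yet its *right* eigenvector is
dominated by $Y$, because $Y$ responds strongly to $X$ through the $c X^n$
repression. Assigning by right-eigenvector loading would mislabel the mode
as a $Y$ instability. An independent probe (`probe_stability()`) perturbs
a single cell by $\delta = 10^{-3}$ in one variable and tests growth over
a short horizon (10 time units by default); the horizon is deliberately
short because near an unstable point *any* asymmetric perturbation
eventually leaks into the growing mode through the regulatory couplings.

**Continuation and folds.** `continue_branch()` performs
natural-parameter continuation with multiplicative steps (coupling
strengths span seven decades) and adaptive step-halving on Newton failure;
a point is accepted only if Newton converges to a branch-continuous
solution (within 0.25 in max-norm of the previous point, a bound that
cleanly separates on-branch motion from jumps to other attractors, whose
distance is order 1). `find_fold()` walks a branch into the bracket and
then bisects on the question "does Newton, seeded from the nearest
accepted branch point, converge to a branch-continuous solution?",
refining the bracket to a requested width (defaults: $10^{-4}$). This
existence-bisection reproduces the two printed critical values without
pseudo-arclength machinery, which would only be needed to trace the
unstable partner branch through the fold.

**Which fold is the critical stabilization strength?** On the three-cell
tissue, the *homogeneous* all-acinar branch persists (and stays linearly
stable) down to $b \approx 0.0015$. The *mixed* branch — two acinar cells
plus one islet cell, the configuration every acinar cell in a
heterogeneous tissue locally resembles — loses existence in a fold at
$b \approx 0.0119$, an eightfold larger value, because each acinar cell in
it is stabilized by only one acinar neighbour ($\bar Y = Y/2$, and the
stabilization term carries $(1/2)^n = 1/8$). The package therefore
identifies the critical stabilization strength $b_c$ of the bifurcation
diagram with the mixed-branch fold: it is the last attractor containing
acinar cells to vanish in that region of $b$, and below it any acinar
sub-population embedded in converting tissue is unsustainable. Both folds
are computable with `find_fold()`; the acceptance script reports the
mixed-branch fold as $b_c$ and, with stabilization lost ($b = 0$), the
saddle-node of the multipotent progenitor branch in the inhibition
strength as $a_c \approx 0.0017$. Both are reported to two significant
figures, matching their "$\approx$" precision.

## Scenario protocols and their defaults

All protocol clocks are dimensionless model time; the defaults below were
chosen once, from the relaxation times of the circuit (single-cell
relaxation $\sim 1$; full lattice conversion half-time $\sim 20$), so that
every run reaches steady classification, and are configurable:

* `run_development()` — full-density lattice, embryonic initial condition
  ($A = 1$, rest 0), noise on, $t_\mathrm{end} = 100$. Noise breaks the
  symmetry of the early promiscuous co-expression phase; lateral
  inhibition then scatters islet cells through acinar fields, and acinar
  commitment spreads as waves (homeogenetic induction).
* `run_conversion()` — adult initial condition ($Y = 1$, rest 0), burn-in
  20, then `stab` ($b \to 0$), `both` ($a = b \to 0$) or
  `inhibition_only` ($a \to 0$); $t_\mathrm{end} = 200$.
* `run_recovery()` — $b \to 0$ at $t = 0$, restored at $t_\mathrm{rec}$.
  The outcome classification is package-defined (the distinction is
  qualitative in the underlying biology): *completed* if the final islet
  fraction exceeds 0.95; otherwise *mixed re-decision* if the islet
  fraction grew by more than 0.05 after recovery (cells still multipotent
  at recovery re-ran the developmental decision); otherwise *arrested*
  (the islet fraction froze at its recovery-time value).
* `run_density_sweep()` — occupancy sampled per site at each density,
  adult start, $b$ *held* at a low value throughout (conversion is driven
  by missing neighbours, not by a schedule), $t_\mathrm{end} = 300$,
  default 30×30 lattice and 20 replicate seeds per grid cell with means
  and standard errors reported. Replicate seeds are derived
  deterministically from the base seed.
* `run_shape_sweep()` — explicit occupancy masks on a fixed-boundary
  lattice, summarized by mean occupied neighbours per cell (compactness)
  versus conversion fraction.

The conversion fraction always uses the cells present at $t = 0$ as its
denominator (all start acinar under the adult preset).

## What the simulations do and do not emulate

The generator reproduces the study conditions of the underlying model:
fixed cells on a lattice, binary presence/absence of the two couplings,
additive expression noise, and dimensionless time. It does **not** model
cell movement, division, death or re-aggregation; enzymatic dissociation
enters only as reduced occupancy or as $b$ set low, and Notch-inhibitor
dosing only as $a \to 0$. Passing tests therefore validate the dynamical
claims of the model — multistability, the critical coupling strengths,
sequential versus direct conversion, density- and shape-dependent yield —
not quantitative agreement with any particular in-vitro preparation.

## Numerical choices, degenerate inputs, limitations

* Newton on corner states: guesses may contain exact zeros; with
  $n \ge 2$ all analytic partial derivatives are finite there
  ($0^{\,n-1} = 0$), and iterates may transiently carry tiny negative
  components without harm since odd powers of $O(10^{-12})$ values are
  negligible against $q$.
* Degenerate eigenvalues at symmetric fixed points (the three-cell
  permutation symmetry forces multiplicity-2 modes) are handled by
  tolerance-based real-part comparisons; the eigenbasis condition number
  is checked and flagged before left-eigenvector assignment.
* The empty tissue simulates to an empty trajectory (a no-op, not an
  error); population averages over zero cells are an error.
* Trajectory and sweep CSVs are written with 17 significant digits so
  read-backs reproduce the doubles exactly; every CLI run directory
  contains the fully-resolved YAML config and seed, from which the run is
  bit-reproducible.
* Test-suite problem sizes: lattice statistics use the default 30×30
  tissue (pattern statistics need a few hundred cells); sweeps in the
  test suite use 20 replicates at three densities and three
  stabilization strengths; bifurcation work is exact on the three-cell
  system. Larger lattices change no qualitative result, only smooth the
  statistics.
* Known limitations: no upper state clamp (see above); fold location by
  existence-bisection reports only the fold position, not the unstable
  partner branch beyond it; continuation is restricted to small systems
  (the Jacobian is dense, $4 n_\mathrm{cells}$ square); and the
  directional-stability assignment, while double-checked by the probe, is
  a heuristic wherever growing modes mix variables with comparable left
  loadings.
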