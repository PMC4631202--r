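---
title: "Exact verification of constraint-based metabolic models"
author: "gemverify"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Exact verification of constraint-based metabolic models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Flux balance analysis (FBA) asks whether a genome-scale metabolic
reconstruction can sustain growth: maximize the biomass objective
$c^\top v$ subject to steady-state mass balance $S v = 0$ and flux bounds
$lb \le v \le ub$, where $S$ is the stoichiometric matrix (metabolites by
reactions). Disagreements between tools about whether a published model
"grows" have two very different possible causes: numerical error in
floating-point solvers, and encoding or parsing defects that silently change
the mathematical program being solved. gemverify is built to separate the
two. It solves the *identical* program along an exact rational-arithmetic
path and along floating-point paths, verifies flux states with no tolerances
at all, and lints model files for the encoding defects that are known to
masquerade as infeasibility.

The package's working hypothesis, borne out by its own test surface, is that
when a correctly parsed model appears infeasible in one tool and feasible in
another, the discrepancy is almost always created *before* the solver runs.
Two defect classes get first-class treatment:

* **Boundary-condition misparse.** By the community convention, species
  flagged with the SBML boundary condition mark where extracellular
  metabolites enter and leave the system, and contribute no mass-balance
  row. A parser that ignores the flag adds one equality constraint per
  boundary species; those constraints block all uptake, and a growing model
  becomes one whose biomass optimum is exactly 0. `read_sbml()` exposes this
  as a switch (`respect_boundary`), so the misparse can be reproduced and
  demonstrated rather than merely described.
* **Case-colliding identifiers.** A file containing both `CO2` and `co2`
  yields one mass-balance constraint in a case-insensitive tool and two in a
  case-sensitive one — two different mathematical models from one file.
  `lint_model()` reports this as `CASE_COLLISION`, detected by Unicode case
  folding on the identifiers as they appear in the file.

## Exact rational arithmetic

All model data — stoichiometric coefficients, bounds, objective weights —
are stored as exact fractions $p/q$. Numeric literals in SBML files are
converted from their decimal text (`"0.1"` becomes $1/10$), never through
binary floating point, so parsing cannot introduce rounding before the
mathematics starts. When a floating-point flux vector must be verified, the
opposite convention is used: `rationalize(x, "float_bits")` maps the IEEE
value exactly (the double `0.1` is $3602879701896397/36028797018963968$).
The two modes answer different questions and are never mixed implicitly.

The rational kernel stores numerators and denominators as 64-bit integers,
reduced by their gcd after every operation, with all intermediate products
taken in 128-bit arithmetic. A value that cannot be stored exactly raises an
error; nothing is ever silently rounded.

`verify_flux_state()` is the package's notion of proof: it recomputes
$S_{\mathrm{internal}} v$ and every bound comparison over the rationals.
A verdict of `exact_feasible` means the residual is identically zero —
there is no tolerance anywhere in the operation.

## The exact simplex

`solve_lp_rational()` implements a bounded-variable primal simplex over the
rationals: phase 1 with artificial variables for the equality rows, phase 2
on the real objective, and Bland's anti-cycling rule throughout (entering
variable: the lowest eligible index; leaving variable: the lowest basic
index among ties). Bland's rule guarantees termination without the
perturbation tricks floating-point codes use, which would reintroduce the
approximation the exact path exists to avoid. Optimality is certified by the
sign of the reduced costs at the returned basis, and every optimal solution
satisfies its constraints as rational identities. The solver is dense and
deliberately simple; it is intended for fixtures and small-to-medium models,
with the floating-point backends carrying large ones. An iteration cap (off
by default, exposed to callers) aborts with an explicit "exact solve
abandoned" error rather than returning an unverified answer.

The floating-point side is a pluggable backend contract — solve the same
program, return status, values and objective. Two backends ship:
`simplex_float`, the same algorithm instantiated in double precision with
conventional tolerances (reduced-cost sign at $10^{-9}$, feasibility at
$10^{-7}$), and `scipy_highs`, which crosses to SciPy's HiGHS solver through
the `python` on the PATH. `compare_solvers()` runs the exact path and any
set of backends on the identical program and reports the maximum absolute
objective deviation against a default tolerance of $10^{-6}$, the precision
at which correctly parsed models are expected to agree across solvers.
Infeasibility is always propagated as a status, never conflated with an
objective of zero; the `gem_check()` pipeline separately distinguishes
"the LP is infeasible" from "the biomass optimum is exactly 0" (a blocked
model), both of which verify as *no growth*.

## Thermodynamic loops

A type-III loop is a circulation: a nonzero flux pattern over the internal
(non-exchange) reactions that balances every internal metabolite, so it can
carry arbitrary flux with no net exchange — thermodynamically impossible in
isolation. The circulations are exactly the null space of $S$ restricted to
internal-reaction columns; `internal_nullspace()` computes a rational basis
by Gauss–Jordan elimination.

`is_loopless()` decides whether a given flux uses a loop by a single exact
LP: maximize the signed circulation mass subject to the circulation being
sign-matched with the flux on its support and bounded by it. A positive
optimum is a loop, returned as a witness; a zero optimum proves none exists.
For floating-point fluxes a support tolerance (default $10^{-9}$) decides
which fluxes count as nonzero; for rational fluxes the support is exact and
the tolerance is ignored.

`loopless_fba()` enforces the loop law: per internal reaction a binary
direction $a_i$ with $-M(1-a_i) \le v_i \le M a_i$, a potential $G_i$
confined to $[-M,-1]$ when the reaction runs forward and $[1, M]$ when in
reverse, and $N^\top G = 0$. The big-M constant defaults to 1000, the
community's conventional bound magnitude, and is checked against the
largest internal bound (an undersized $M$ silently invalidates the MILP, so
it is an error instead). The search is depth-first branch and bound over the
direction binaries with exact rational LP relaxations: most-fractional
variable first, ties by reaction index, forward branch explored first —
fully deterministic.

### Loop removal and the conversion guarantee

When every reaction allows zero flux, any exactly feasible flux with loops
can be converted into one without loops that produces identical biomass.
`remove_loops()` realizes this constructively with one exact LP: hold every
exchange flux fixed (and with it the objective, since biomass is a boundary
drain), constrain each internal flux to shrink toward zero without changing
sign, and minimize the total internal $|w|$. The minimizer cannot support a
sign-matched circulation — subtracting one would reduce the objective
further while preserving feasibility — so the result passes `is_loopless()`
and conserves every exchange flux and the objective bit-for-bit. The
precondition matters: a reaction whose bounds exclude zero (lint code
`ZERO_EXCLUDED_BOUNDS`) can force a cycle that no shrinkage removes, and
`remove_loops()` refuses such models by name rather than returning a flux
that merely looks clean.

This gives `loopless_fba()` a provably exact fast path, used whenever all
bounds contain zero: loop-law constraints can only lower the optimum, and
loop removal applied to the plain FBA optimum attains it, so the converted
flux is an optimal loopless flux and no branch and bound is needed. The
branch-and-bound path runs whenever the precondition fails (forced-flux
bounds) or when callers request it for cross-checking (`force_milp`); the
test suite asserts the two paths agree. One subtlety is worth recording:
the fast path optimizes over all thermodynamically consistent fluxes,
whereas the MILP with a fixed $M$ also requires potentials of magnitude at
least 1 and at most $M$; on the models exercised here the two coincide, and
the suite checks this agreement explicitly rather than assuming it.

Reactions carrying a nonzero objective coefficient are held fixed alongside
the exchanges during removal. In every fixture the biomass reaction is a
pure drain and therefore an exchange anyway; the extra rule covers models
whose objective sits on an internal reaction, at the cost that the guarantee
then requires that reaction not to be inside a loop.

## The synthetic corpus

All testing runs on models the package generates itself. The random
generator (`make_random_model()`) is seeded and reproducible: a backbone
import → chain → biomass path that guarantees a positive FBA optimum; a
chosen number of node-disjoint planted 2-cycles between adjacent chain
metabolites (the forward leg carries coefficient 2, so each cycle is a
circulation independent of the chain, making the null-space dimension
provably at least the number of planted loops); and random sparse side
reactions with mixed-sign stoichiometry. Default conditions: 8 internal
metabolites, 14 reactions, 2 planted loops, bounds of magnitude 1000 with
every interval containing zero, and an import capacity drawn from 5–20.
With `zero_containing_bounds = FALSE` the planted forward legs instead
carry a positive lower bound, producing models that are feasible but
irreparably loopy — the deliberate counterexample to the removal
precondition.

What the generator emulates is network *structure*: boundary crossings,
linear pathways, thermodynamic cycles, reversibility. What it does not
emulate is biochemical realism — elemental mass conservation across side
reactions, biomass composition, genome-scale dimensions (thousands of
reactions), or the degenerate near-parallel constraints real
reconstructions contain. Passing tests therefore demonstrate correctness of
the mathematics on exactly specified inputs, not performance or numerical
behavior at genome scale; the floating-point backends exist precisely
because the dense exact simplex is not meant to carry 10,000-column models.

Problem sizes used by the test suite and the acceptance script: the full
generated SBML corpus (12 files), 50 random models per property, and 30
random LPs of at most 6 variables and 4 equality rows for the brute-force
enumeration oracle — the scale at which exhaustive enumeration of basic
solutions is itself exact ground truth.

## Numerical and design choices

* **Ties and determinism.** Every search in the package (simplex pivoting,
  branch and bound, lint ordering, batch file order) breaks ties by a fixed
  rule — lowest index or radix-sorted identifier — so reruns are identical
  across platforms and locales.
* **Writing rationals to SBML.** A bound like $1/3$ has no finite decimal.
  The fbc-v2 writer renders ten decimal digits for interoperability and
  attaches a `<rational value="1/3"/>` annotation in a dedicated namespace;
  the reader prefers the annotation, making the round trip exact without
  breaking other consumers.
* **Conflicting encodings win by bounds.** When a legacy file's
  `reversible` attribute contradicts its explicit bounds, the bounds win
  (they are what every solver actually enforces) and a
  `REVERSIBILITY_CONFLICT` lint warning records the disagreement. Inverted
  bounds are repaired by swapping and flagged `INVERTED_BOUNDS` at error
  severity.
* **Infinity policy.** Bound literals such as `INF` or huge sentinels are
  kept verbatim by default (`keep_literal`); rewriting models is not this
  package's job. `clamp_to_default` is available for tools that need finite
  programs.
* **Degenerate inputs.** Empty models produce 0-row matrices and minimal
  valid SBML; models without internal metabolites optimize at their bounds;
  an all-zero objective is an explicit error mirroring the `NO_OBJECTIVE`
  lint finding, because silently maximizing nothing is how a blocked model
  gets misread as growing.

## Limitations

The exact simplex is dense and single-threaded; genome-scale exact solves
are out of scope by design. The loopless MILP certifies its LP relaxations
exactly but the branch-and-bound search is practical only for tens of
internal reactions; the removal fast path is the intended route at scale.
SBML coverage is deliberately narrow: the legacy COBRA dialect and strict
fbc v2, without events, rules, units, or gene–protein–reaction
associations. Flux variability analysis, parsimonious FBA and sampling are
not provided.
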