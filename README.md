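# gemverify

Exact verification of constraint-based (genome-scale) metabolic models.

When two tools disagree about whether a published metabolic reconstruction
can produce biomass, the cause is usually not floating-point error in the
solver but a defect introduced *before* the solver runs: an SBML parser that
ignores the boundary-condition convention and thereby blocks all uptake, or
a file that encodes both `CO2` and `co2` and becomes two different
mathematical models in two different tools. gemverify is a toolkit for
settling such disputes with proofs instead of tolerances. It is written for
the constraint-based modeling community: model curators auditing
reconstructions, method developers cross-checking solvers, and anyone who
needs a feasibility claim that survives scrutiny.

## What it does

Flux balance analysis (FBA) is the linear program

> maximize c·v   subject to   S·v = 0,  lb ≤ v ≤ ub

with S the stoichiometric matrix (metabolites × reactions), v the flux
vector, and c the biomass objective. gemverify:

* **parses SBML** in the legacy COBRA dialect (kinetic-law `LOWER_BOUND` /
  `UPPER_BOUND` / `OBJECTIVE_COEFFICIENT` parameters) and in SBML Level 3 +
  fbc version 2, converting every numeric literal to an exact rational from
  its decimal text ("0.1" is 1/10, not the nearest double), with the
  boundary-condition semantics explicit and switchable;
* **solves FBA exactly** with a rational-arithmetic bounded-variable simplex
  (Bland's rule, no tolerances anywhere), alongside pluggable
  floating-point backends (a built-in double-precision simplex and SciPy's
  HiGHS via `python`), and cross-checks that all paths agree to within
  10⁻⁶ on the identical program;
* **verifies flux states** by recomputing S·v and every bound check over
  exact fractions — a verdict of `exact_feasible` is a zero-residual
  rational identity, i.e. a proof the flux carries no numerical error;
* **handles thermodynamic (type-III) loops**: computes the exact circulation
  space, detects loops in a flux state by one LP, solves loopless FBA
  (loop-law MILP by branch and bound over exact LP relaxations), and
  converts loopy optima into loopless ones by a single sign-constrained
  L1-minimization that preserves every exchange flux and the biomass
  objective bit-for-bit whenever all bounds allow zero flux;
* **lints models** for the encoding defects that masquerade as
  infeasibility: `CASE_COLLISION`, `BOUNDARY_IN_INTERNAL_REACTION`,
  `NO_EXCHANGES`, `INVERTED_BOUNDS`, `DUPLICATE_STOICH_ROW`, `NO_OBJECTIVE`,
  `ZERO_EXCLUDED_BOUNDS`, `REVERSIBILITY_CONFLICT`;
* **generates its whole test corpus** (toy loop model, boundary and
  case-collision fixtures, seeded random models with planted cycles) — no
  downloads required.

## Worked example

The canonical toy model: import A (capacity 10), convert A → B, a
reversible B/C pair forming a thermodynamic loop, and a biomass drain on B.

```r
library(gemverify)
m <- make_toy_loop_model()
stoichiometric_matrix(m)
#> <ratmat 3 x 5>
#>   EX_A R1 R2 R3 BIO
#> A 1    -1 0  0  0
#> B 0    1  -1 1  -1
#> C 0    0  1  -1 0

f <- solve_fba(m, "exact")
f
#> <flux state> status=optimal, mode=exact, solver=rational_simplex, objective=10
rat_format(f$values)
#>    EX_A      R1      R2      R3     BIO
#>    "10"    "10" "-1000" "-1000"    "10"
```

The optimum is exactly 10, but the simplex happened to park 1000 units of
flux on the B/C cycle — a type-III loop, flagged with a witness:

```r
is_loopless(m, f)$witness$description
#> [1] "R2- R3-"

w <- remove_loops(m, f)     # one exact LP; exchanges and biomass held fixed
rat_format(w$values)
#> EX_A   R1   R2   R3  BIO
#> "10" "10"  "0"  "0" "10"
verify_flux_state(m, w)
#> <verification> exact_feasible, objective=10
```

The loop is gone, the biomass is still exactly 10, and the verification is
a rational identity, not a tolerance check.

The boundary-condition misparse, reproduced on demand: parsing the same
file while ignoring the boundary flag adds a mass-balance row for the
boundary species, nothing can enter the system, and the "optimum" collapses
to exactly 0:

```r
p <- tempfile(fileext = ".xml"); make_boundary_fixture(p)
bad <- read_sbml(p, parse_options(respect_boundary = FALSE))$model
solve_fba(bad, "exact")
#> <flux state> status=optimal, mode=exact, solver=rational_simplex, objective=0
```

## Command line

A thin Rscript CLI wraps the same functions
(`inst/cli/gemverify.R`, installed under `system.file("cli", package = "gemverify")`):

```sh
Rscript gemverify.R check MODEL.xml [--misparse-boundary] [--tol 1e-6]
Rscript gemverify.R batch DIR
Rscript gemverify.R fba MODEL.xml --mode both
Rscript gemverify.R loopless MODEL.xml [--remove-loops FLUX.tsv]
Rscript gemverify.R fixtures --out DIR
Rscript gemverify.R convert LEGACY.xml FBC2.xml
```

Reports are JSON with rationals as `"p/q"` strings; exit codes distinguish
all-verified (0), any infeasible (2), any parse error (3), any solver
disagreement (4).

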