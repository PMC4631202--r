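# Synthetic model corpus: every model, defect fixture and SBML file the test
# surface needs is generated here, deterministically, with no downloads.

#' The canonical toy loop model
#'
#' Three internal metabolites A, B, C and one boundary species `A_b`.
#' `EX_A` imports A (bounds 0..10), `R1` converts A to B, `R2`/`R3` form a
#' reversible B/C interconversion pair — the minimal type-III loop, a
#' circulation that can carry any amount of flux with no net exchange — and
#' `BIO` drains B as the biomass objective. Plain FBA reaches objective 10;
#' the internal null space has dimension 1 (the R2+R3 cycle).
#'
#' @return A `gem_model`.
#' @export
make_toy_loop_model <- function() {
  mets <- list(gem_metabolite("A"), gem_metabolite("B"), gem_metabolite("C"),
               gem_metabolite("A_b", boundary = TRUE))
  rxns <- list(
    gem_reaction("EX_A", c(A_b = -1, A = 1), 0, 10),
    gem_reaction("R1", c(A = -1, B = 1), 0, 1000),
    gem_reaction("R2", c(B = -1, C = 1), -1000, 1000),
    gem_reaction("R3", c(C = -1, B = 1), -1000, 1000),
    gem_reaction("BIO", c(B = -1), 0, 1000, objective = 1))
  gem_model("toy_loop", mets, rxns)
}

#' A loop-free linear chain model
#'
#' Import, a chain A to B to C, and a biomass drain; the internal null space
#' is empty, so the loop-law constraints are vacuous and loopless FBA must
#' agree with plain FBA exactly.
#'
#' @return A `gem_model`.
#' @export
make_loop_free_chain <- function() {
  mets <- list(gem_metabolite("A"), gem_metabolite("B"), gem_metabolite("C"),
               gem_metabolite("A_b", boundary = TRUE))
  rxns <- list(
    gem_reaction("EX_A", c(A_b = -1, A = 1), 0, 10),
    gem_reaction("R1", c(A = -1, B = 1), 0, 1000),
    gem_reaction("R2", c(B = -1, C = 1), 0, 1000),
    gem_reaction("BIO", c(C = -1), 0, 1000, objective = 1))
  gem_model("loop_free_chain", mets, rxns)
}

#' A model whose only biomass route forces a thermodynamic cycle
#'
#' The cycle reaction `R2` (B to C) carries a positive lower bound, so every
#' feasible flux drives the B/C cycle: plain FBA is feasible, but no loopless
#' flux exists and loopless FBA must report infeasibility. Because a bound
#' excludes zero, the loop-removal guarantee deliberately does not apply
#' (lint flags `ZERO_EXCLUDED_BOUNDS`).
#'
#' @return A `gem_model`.
#' @export
make_forced_cycle_model <- function() {
  mets <- list(gem_metabolite("A"), gem_metabolite("B"), gem_metabolite("C"),
               gem_metabolite("A_b", boundary = TRUE))
  rxns <- list(
    gem_reaction("EX_A", c(A_b = -1, A = 1), 0, 10),
    gem_reaction("R1", c(A = -1, B = 1), 0, 1000),
    gem_reaction("R2", c(B = -1, C = 1), 1, 1000),
    gem_reaction("R3", c(C = -1, B = 1), -1000, 1000),
    gem_reaction("BIO", c(B = -1), 0, 1000, objective = 1))
  gem_model("forced_cycle", mets, rxns)
}

#' Write the boundary-semantics fixture
#'
#' The toy loop model as a legacy-dialect SBML file in which `A_b` carries
#' `boundaryCondition="true"`. Parsed with the boundary flag respected, the
#' FBA optimum is 10; parsed with the flag ignored, `A_b` gains a mass-balance
#' row, nothing can enter the system, and the optimum collapses to 0 — the
#' file is the vehicle for demonstrating that "infeasibility" of this kind is
#' a parsing artifact.
#'
#' @param path output file path.
#' @return Invisibly, `path`.
#' @export
make_boundary_fixture <- function(path) {
  write_sbml_legacy(make_toy_loop_model(), path)
}

#' Write the case-collision fixture
#'
#' A small solvable legacy-dialect model containing both `CO2` and `co2` as
#' species ids, participating in distinct reactions. Case-insensitive tools
#' merge them into one constraint; case-sensitive tools create two — the same
#' file yields different mathematical models, which is exactly what the
#' `CASE_COLLISION` lint finding reports (exactly one finding for this file).
#'
#' @param path output file path.
#' @return Invisibly, `path`.
#' @export
make_case_collision_sbml <- function(path) {
  mets <- list(gem_metabolite("X"), gem_metabolite("CO2"), gem_metabolite("co2"),
               gem_metabolite("X_b", boundary = TRUE))
  rxns <- list(
    gem_reaction("EX_X", c(X_b = -1, X = 1), 0, 10),
    gem_reaction("R_upper", c(X = -1, CO2 = 1), 0, 1000),
    gem_reaction("R_lower", c(X = -1, co2 = 1), 0, 1000),
    gem_reaction("EX_CO2", c(CO2 = -1), 0, 1000),
    gem_reaction("EX_co2", c(co2 = -1), 0, 1000),
    gem_reaction("BIO", c(X = -1), 0, 1000, objective = 1))
  write_sbml_legacy(gem_model("case_collision", mets, rxns), path)
}

#' Specification for a random model
#'
#' @param n_metabolites number of internal chain metabolites (>= 2).
#' @param n_reactions total reaction count (at least the backbone plus the
#'   planted loops).
#' @param n_planted_loops number of node-disjoint planted 2-cycles; each adds
#'   one independent circulation, so the internal null-space dimension is at
#'   least this number. Requires `n_planted_loops <= (n_metabolites - 1)/2`.
#' @param bound_magnitude magnitude used for wide bounds (default 1000).
#' @param zero_containing_bounds if `TRUE` (default) every bound interval
#'   contains zero, the precondition of the loop-removal guarantee.
#' @param seed integer seed; the same spec always generates the same model.
#' @return A `random_model_spec` list.
#' @export
random_model_spec <- function(n_metabolites = 8, n_reactions = 14,
                              n_planted_loops = 2, bound_magnitude = 1000,
                              zero_containing_bounds = TRUE, seed = 1) {
  if (n_metabolites < 2) stop("need at least 2 metabolites")
  if (n_planted_loops > (n_metabolites - 1) / 2)
    stop("infeasible spec: n_planted_loops may not exceed (n_metabolites - 1)/2")
  backbone <- 2 + (n_metabolites - 1)          # exchange + chain + biomass
  if (n_reactions < backbone + 2 * n_planted_loops)
    stop("infeasible spec: n_reactions too small for backbone plus planted loops")
  structure(list(n_metabolites = n_metabolites, n_reactions = n_reactions,
                 n_planted_loops = n_planted_loops,
                 bound_magnitude = as_vrat(bound_magnitude),
                 zero_containing_bounds = isTRUE(zero_containing_bounds),
                 seed = as.integer(seed)),
            class = "random_model_spec")
}

#' Generate a random constraint-based model
#'
#' Seeded and reproducible. The skeleton guarantees a biomass route: one
#' boundary import, a chain `M1 -> M2 -> ... -> Mk`, and a biomass drain of
#' `Mk` with objective 1, so FBA is always feasible with positive optimum.
#' Planted loops are node-disjoint 2-cycles between adjacent chain metabolites
#' (with a coefficient-2 forward leg, so each is an independent circulation
#' not collinear with the chain); remaining reaction slots are filled with
#' random sparse side reactions over internal metabolites.
#'
#' @param spec a [random_model_spec()].
#' @return A `gem_model`.
#' @export
make_random_model <- function(spec) {
  stopifnot(inherits(spec, "random_model_spec"))
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(spec$seed)

  k <- spec$n_metabolites
  B <- spec$bound_magnitude
  met_names <- paste0("M", seq_len(k))
  mets <- c(lapply(met_names, gem_metabolite),
            list(gem_metabolite("S_b", boundary = TRUE)))

  uptake <- as_vrat(sample(5:20, 1))
  rxns <- list(gem_reaction("EX_S", c(S_b = -1, M1 = 1), 0, uptake))
  for (i in seq_len(k - 1)) {
    st <- c(-1, 1); names(st) <- c(met_names[i], met_names[i + 1])
    rxns[[length(rxns) + 1]] <-
      gem_reaction(paste0("C", i), st, if (runif(1) < 0.3) -B else as_vrat(0), B)
  }
  rxns[[length(rxns) + 1]] <-
    gem_reaction("BIO", stats::setNames(-1, met_names[k]), 0, B, objective = 1)

  # planted node-disjoint 2-cycles on chain positions 1, 3, 5, ...
  # With zero_containing_bounds = FALSE the forward leg is forced to carry
  # flux (positive lower bound), planting an unavoidable thermodynamic cycle
  # while keeping the model feasible: the reverse leg absorbs it.
  pos <- seq(1, by = 2, length.out = spec$n_planted_loops)
  for (j in seq_along(pos)) {
    p <- pos[j]
    st1 <- c(-2, 2); names(st1) <- c(met_names[p], met_names[p + 1])
    st2 <- c(-1, 1); names(st2) <- c(met_names[p + 1], met_names[p])
    lb1 <- if (spec$zero_containing_bounds) -B else as_vrat(sample(1:3, 1))
    rxns[[length(rxns) + 1]] <- gem_reaction(paste0("L", j, "f"), st1, lb1, B)
    rxns[[length(rxns) + 1]] <- gem_reaction(paste0("L", j, "r"), st2, -B, B)
  }

  n_side <- spec$n_reactions - length(rxns)
  for (j in seq_len(n_side)) {
    nm <- sample(met_names, sample(2:3, 1))
    co <- sample(c(-2, -1, 1, 2), length(nm), replace = TRUE)
    # force mixed signs so side reactions are conversions, not spurious exchanges
    if (all(co > 0)) co[1] <- -co[1]
    if (all(co < 0)) co[1] <- -co[1]
    names(co) <- nm
    lb <- if (runif(1) < 0.5) -B else as_vrat(0)
    rxns[[length(rxns) + 1]] <- gem_reaction(paste0("X", j), co, lb, B)
  }
  gem_model(paste0("random_", spec$seed), mets, rxns)
}

#' Write the full fixture corpus
#'
#' Emits every SBML fixture the verification pipeline is exercised on —
#' the toy loop model (fbc v2), the boundary and case-collision fixtures
#' (legacy dialect), the loop-free chain and forced-cycle models, and a set
#' of seeded random models — plus `expected.json` recording, for each file,
#' quantities computed at generation time (exact FBA objective as a rational
#' string, lint finding counts) that batch runs can be compared against.
#'
#' @param dir output directory (created if needed).
#' @param n_random number of random models to include (default 7).
#' @return Invisibly, the file paths written.
#' @export
write_fixture_corpus <- function(dir, n_random = 7) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  emit <- function(name, writer) {
    p <- file.path(dir, name)
    writer(p)
    paths <<- c(paths, p)
    p
  }
  emit("toy_loop.xml", function(p) write_sbml_fbc2(make_toy_loop_model(), p))
  emit("boundary_fixture.xml", make_boundary_fixture)
  emit("case_collision.xml", make_case_collision_sbml)
  emit("loop_free_chain.xml", function(p) write_sbml_fbc2(make_loop_free_chain(), p))
  emit("forced_cycle.xml", function(p) write_sbml_fbc2(make_forced_cycle_model(), p))
  for (s in seq_len(n_random))
    emit(sprintf("random_%02d.xml", s),
         function(p) write_sbml_fbc2(make_random_model(random_model_spec(seed = s)), p))

  expected <- list()
  for (p in paths) {
    parsed <- read_sbml(p)
    fba <- solve_fba(parsed$model, "exact")
    expected[[basename(p)]] <- list(
      status = fba$status,
      objective = if (fba$status == "optimal") rat_format(fba$objective_value) else NULL,
      lint_codes = as.list(table(parsed$lint$code)))
  }
  jsonlite::write_json(expected, file.path(dir, "expected.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(paths, file.path(dir, "expected.json")))
}
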