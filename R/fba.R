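# Flux balance analysis: build the LP from a model, solve it on the exact
# rational path and on pluggable floating-point backends, and cross-check the
# two. Infeasibility is always reported as a status, never coerced to an
# objective of zero: conflating "the model cannot grow" with "the optimum is
# zero" is precisely the misreading this toolkit exists to correct.

#' Build the FBA linear program
#'
#' Standard FBA: maximize `c . v` subject to `S_internal . v = 0` and
#' `lb <= v <= ub`. One equality row per internal metabolite — boundary
#' species contribute no row — and columns in model reaction order.
#'
#' @param model a `gem_model` with at least one nonzero objective coefficient.
#' @return A [rational_lp()].
#' @export
build_fba_lp <- function(model) {
  obj <- objective_vector(model)
  if (length(obj) == 0 || all(obj$num == 0))
    stop("no objective: every objective coefficient is zero (lint code NO_OBJECTIVE)")
  S <- stoichiometric_matrix(model, include_boundary = FALSE)
  b <- bounds_vectors(model)
  rational_lp(objective = obj, eq_matrix = S,
              eq_rhs = rat_zero(nrow(S$num)),
              lower = b$lb, upper = b$ub, ids = rxn_ids(model))
}

new_flux_state <- function(values, objective, status, mode, provenance) {
  structure(list(values = values, objective_value = objective, status = status,
                 mode = mode, provenance = provenance), class = "gem_flux")
}

#' @export
print.gem_flux <- function(x, ...) {
  cat("<flux state> status=", x$status, ", mode=", x$mode,
      ", solver=", x$provenance, sep = "")
  if (x$status == "optimal") {
    o <- if (is_vrat(x$objective_value)) rat_format(x$objective_value)
         else format(x$objective_value)
    cat(", objective=", o, sep = "")
  }
  cat("\n")
  invisible(x)
}

#' Solve FBA
#'
#' Exact mode runs the rational simplex and returns a flux state whose
#' feasibility and optimality are exact rational statements (it re-verifies
#' under [verify_flux_state()] with a zero residual). Float mode delegates to
#' a registered floating-point backend solving the identical program.
#'
#' @param model a `gem_model`.
#' @param mode `"exact"` or `"float"`.
#' @param backend float-backend label (see [list_backends()]); ignored in
#'   exact mode.
#' @return A `gem_flux` with `values`, `objective_value`, `status`, `mode`,
#'   and solver `provenance`. On a non-optimal status the values are absent.
#' @export
solve_fba <- function(model, mode = c("exact", "float"), backend = "simplex_float") {
  mode <- match.arg(mode)
  lp <- build_fba_lp(model)
  if (mode == "exact") {
    sol <- solve_lp_rational(lp)
    vals <- if (sol$status == "optimal") sol$values else NULL
    return(new_flux_state(vals, if (sol$status == "optimal") sol$objective_value else NULL,
                          sol$status, "exact", "rational_simplex"))
  }
  fn <- get_backend(backend)
  res <- fn(lp)
  vals <- if (res$status == "optimal") res$values else NULL
  new_flux_state(vals, if (res$status == "optimal") res$objective_value else NULL,
                 res$status, "float", backend)
}

# ---- float backend registry -------------------------------------------------

backend_env <- new.env(parent = emptyenv())

#' Register a floating-point LP backend
#'
#' A backend is any function taking a [rational_lp()] and returning
#' `list(status, values, objective_value)` for the same program — the narrow
#' contract that makes solvers interchangeable.
#'
#' @param name backend label.
#' @param fn backend function.
#' @export
register_fba_backend <- function(name, fn) {
  stopifnot(is.character(name), is.function(fn))
  assign(name, fn, envir = backend_env)
  invisible(name)
}

#' List registered float backends
#' @return Character vector of backend labels.
#' @export
list_backends <- function() sort(ls(backend_env))

get_backend <- function(name) {
  if (!exists(name, envir = backend_env, inherits = FALSE))
    stop("float backend unavailable: '", name, "' (registered: ",
         paste(list_backends(), collapse = ", "), ")")
  get(name, envir = backend_env, inherits = FALSE)
}

scipy_available <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    ok <- nzchar(Sys.which("python")) &&
      identical(suppressWarnings(system2("python", c("-c", shQuote("import scipy.optimize")),
                                         stdout = FALSE, stderr = FALSE)), 0L)
    cache <<- ok
    ok
  }
})

# SciPy linprog (HiGHS) via the python on PATH; the LP crosses as JSON.
scipy_backend <- function(lp) {
  script <- system.file("python", "solve_lp.py", package = "gemverify")
  if (!nzchar(script)) stop("float backend unavailable: scipy_highs helper script not found")
  if (!scipy_available()) stop("float backend unavailable: scipy_highs (no python/scipy)")
  A <- as.matrix(lp$eq_matrix); dimnames(A) <- NULL
  as_bound <- function(x) lapply(unname(as.numeric(x)), function(v) if (is.finite(v)) v else NULL)
  payload <- list(A = unname(apply(A, 1, as.numeric, simplify = FALSE)),
                  ncol = ncol(A),
                  b = as.numeric(lp$eq_rhs), c = as.numeric(lp$objective),
                  lb = as_bound(lp$lower), ub = as_bound(lp$upper))
  fin <- tempfile(fileext = ".json"); fout <- tempfile(fileext = ".json")
  on.exit(unlink(c(fin, fout)), add = TRUE)
  jsonlite::write_json(payload, fin, auto_unbox = TRUE, digits = NA, null = "null")
  rc <- system2("python", c(script, fin, fout), stdout = FALSE, stderr = FALSE)
  if (rc != 0L || !file.exists(fout)) stop("scipy_highs backend failed (exit ", rc, ")")
  res <- jsonlite::read_json(fout, simplifyVector = TRUE)
  values <- as.numeric(res$x)
  names(values) <- lp$ids
  list(status = res$status, values = values,
       objective_value = as.numeric(res$objective))
}

.onLoad <- function(libname, pkgname) {
  register_fba_backend("simplex_float", function(lp) solve_lp_float(lp))
  register_fba_backend("scipy_highs", scipy_backend)
}

#' Cross-check exact and floating-point FBA
#'
#' Runs the exact rational solve and every requested float backend on the
#' identical program and reports each backend's objective together with the
#' maximum absolute deviation from the exact objective. Statuses must all
#' match; a status mismatch sets `agrees = FALSE` with a note, regardless of
#' objective values.
#'
#' @param model a `gem_model`.
#' @param backends float-backend labels (default the built-in float simplex).
#' @param tolerance agreement tolerance on the objective (default `1e-6`).
#' @return A `gem_agreement`: `exact_objective` (`vrat`), `exact_status`,
#'   `float_objectives` and `float_statuses` per backend,
#'   `max_abs_difference`, `tolerance`, `agrees`, and an optional `note`.
#' @export
compare_solvers <- function(model, backends = "simplex_float", tolerance = 1e-6) {
  if (length(backends) < 1) stop("at least one float backend is required")
  exact <- solve_fba(model, "exact")
  fobj <- numeric(0); fstat <- character(0)
  for (b in backends) {
    fs <- solve_fba(model, "float", backend = b)
    fobj[b] <- if (fs$status == "optimal") fs$objective_value else NA_real_
    fstat[b] <- fs$status
  }
  note <- NULL
  if (!all(fstat == exact$status)) {
    agrees <- FALSE
    maxdiff <- NA_real_
    note <- paste0("status mismatch: exact=", exact$status, ", ",
                   paste0(names(fstat), "=", fstat, collapse = ", "))
  } else if (exact$status != "optimal") {
    agrees <- TRUE   # consistently infeasible/unbounded
    maxdiff <- 0
  } else {
    maxdiff <- max(abs(fobj - as.numeric(exact$objective_value)))
    agrees <- maxdiff <= tolerance
  }
  structure(list(exact_objective = exact$objective_value,
                 exact_status = exact$status,
                 float_objectives = fobj, float_statuses = fstat,
                 max_abs_difference = maxdiff, tolerance = tolerance,
                 agrees = agrees, note = note),
            class = "gem_agreement")
}

#' @export
print.gem_agreement <- function(x, ...) {
  cat("<solver agreement> exact status=", x$exact_status, sep = "")
  if (x$exact_status == "optimal")
    cat(", exact objective=", rat_format(x$exact_objective), sep = "")
  cat("\n  backends: ",
      paste0(names(x$float_statuses), "=", x$float_statuses,
             ifelse(is.na(x$float_objectives), "",
                    paste0(" (", format(x$float_objectives, digits = 12), ")")),
             collapse = ", "), "\n", sep = "")
  cat("  max |float - exact| = ", format(x$max_abs_difference),
      " (tolerance ", format(x$tolerance), "): ",
      if (isTRUE(x$agrees)) "agree" else "DISAGREE", "\n", sep = "")
  if (!is.null(x$note)) cat("  note: ", x$note, "\n", sep = "")
  invisible(x)
}
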