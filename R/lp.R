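# Exact rational linear programming and exact verification of flux states.
#
# The solver is a bounded-variable primal simplex over exact rationals with
# Bland's anti-cycling rule (entering column: first eligible index; leaving
# row: smallest basic index among ties), phase-1 artificials for the equality
# rows, and no perturbation or tolerance anywhere. An optimal status therefore
# certifies exact feasibility (A.x = b and l <= x <= u as rational identities)
# and exact optimality (nonnegative reduced costs at the returned basis).

#' Construct an equality-constrained, bounded rational LP
#'
#' The program is: maximize `objective . x` subject to `eq_matrix . x = eq_rhs`
#' and `lower <= x <= upper`, all data exact rationals. Infinite bounds are
#' encoded as rationals with denominator 0 (`vrat(1, 0)` / `vrat(-1, 0)`).
#'
#' @param objective `vrat` of length n (maximized).
#' @param eq_matrix `ratmat` with n columns (may have 0 rows).
#' @param eq_rhs `vrat` of length `nrow(eq_matrix)`.
#' @param lower,upper `vrat` bounds of length n; `lower <= upper` required.
#' @param ids optional column (variable) ids.
#' @return A `rational_lp`.
#' @export
rational_lp <- function(objective, eq_matrix, eq_rhs, lower, upper, ids = NULL) {
  objective <- as_vrat(objective); eq_rhs <- as_vrat(eq_rhs)
  lower <- as_vrat(lower); upper <- as_vrat(upper)
  stopifnot(inherits(eq_matrix, "ratmat"))
  n <- ncol(eq_matrix$num); m <- nrow(eq_matrix$num)
  if (length(objective) != n || length(lower) != n || length(upper) != n)
    stop("rational_lp: objective/bounds length must equal ncol(eq_matrix)")
  if (length(eq_rhs) != m)
    stop("rational_lp: eq_rhs length must equal nrow(eq_matrix)")
  if (any(cpp_rat_compare(lower$num, lower$den, upper$num, upper$den) > 0))
    stop("rational_lp: lower > upper for some variable")
  if (is.null(ids)) ids <- eq_matrix$dimnames[[2]] %||% paste0("x", seq_len(n))
  structure(list(objective = objective, eq_matrix = eq_matrix, eq_rhs = eq_rhs,
                 lower = lower, upper = upper, ids = ids),
            class = "rational_lp")
}

#' @export
print.rational_lp <- function(x, ...) {
  cat("<rational_lp> ", length(x$ids), " variables, ",
      nrow(x$eq_matrix$num), " equality rows\n", sep = "")
  invisible(x)
}

#' Solve a rational LP exactly
#'
#' @param lp a [rational_lp()].
#' @param max_iterations simplex pivot cap; exceeding it raises an error
#'   (\dQuote{exact solve abandoned}) rather than returning an unverified answer.
#' @return An `lp_solution`: `status` (`"optimal"`, `"infeasible"`,
#'   `"unbounded"`), exact `values` (named `vrat`), exact `objective_value`,
#'   `basis` (per-variable activity: basic / at lower / at upper / free) and
#'   the pivot count.
#' @export
solve_lp_rational <- function(lp, max_iterations = 200000) {
  stopifnot(inherits(lp, "rational_lp"))
  res <- cpp_simplex_rat(lp$eq_matrix$num, lp$eq_matrix$den,
                         lp$eq_rhs$num, lp$eq_rhs$den,
                         lp$objective$num, lp$objective$den,
                         lp$lower$num, lp$lower$den,
                         lp$upper$num, lp$upper$den,
                         as.numeric(max_iterations))
  if (res$status == "iteration_limit")
    stop("exact solve abandoned: simplex iteration cap (", max_iterations, ") reached")
  values <- new_vrat(res$xnum, res$xden, lp$ids)
  basis <- c("at_lower", "at_upper", "free", "basic")[res$vstat + 1L]
  names(basis) <- lp$ids
  structure(list(status = res$status, values = values,
                 objective_value = new_vrat(res$objnum, res$objden),
                 basis = basis, iterations = res$iterations),
            class = "lp_solution")
}

#' @export
print.lp_solution <- function(x, ...) {
  cat("<lp_solution> status=", x$status, sep = "")
  if (x$status == "optimal")
    cat(", objective=", rat_format(x$objective_value), sep = "")
  cat(" (", x$iterations, " pivots)\n", sep = "")
  invisible(x)
}

#' Solve a rational LP with the floating-point simplex
#'
#' Same program, double-precision arithmetic and tolerances; used as the
#' built-in float backend against which the exact path is cross-checked.
#'
#' @param lp a [rational_lp()].
#' @param max_iterations pivot cap.
#' @return List with `status`, numeric `values` (named), numeric `objective_value`.
#' @export
solve_lp_float <- function(lp, max_iterations = 200000) {
  stopifnot(inherits(lp, "rational_lp"))
  A <- as.matrix(lp$eq_matrix)
  if (length(A) == 0) A <- matrix(0, nrow(lp$eq_matrix$num), ncol(lp$eq_matrix$num))
  dimnames(A) <- NULL
  res <- cpp_simplex_dbl(A, as.numeric(lp$eq_rhs), as.numeric(lp$objective),
                         as.numeric(lp$lower), as.numeric(lp$upper),
                         as.numeric(max_iterations))
  if (res$status == "iteration_limit")
    stop("float solve abandoned: simplex iteration cap reached")
  values <- res$x
  names(values) <- lp$ids
  list(status = res$status, values = values, objective_value = res$objective)
}

#' Verify a flux state exactly
#'
#' Recomputes the mass-balance residual `S_internal . v` and every bound check
#' in exact rational arithmetic — there are no tolerances anywhere in this
#' operation, so a verdict of `exact_feasible` is a proof that the flux state
#' carries no numerical error.
#'
#' @param model a `gem_model`.
#' @param flux named flux assignment covering every reaction: a `vrat`,
#'   a character vector of rational literals, or a numeric vector (converted
#'   exactly from its IEEE bits).
#' @return A `gem_verification`: exact `residual` per internal metabolite,
#'   `bound_violations` (reaction id and exact amount), exact
#'   `objective_value`, and `verdict` in `exact_feasible`,
#'   `infeasible_mass_balance`, `infeasible_bounds`.
#' @export
verify_flux_state <- function(model, flux) {
  v <- flux_as_vrat(flux)
  missing <- setdiff(rxn_ids(model), names(v))
  if (length(missing))
    stop("flux is missing reaction(s): ", paste(missing, collapse = ", "))
  v <- v[rxn_ids(model)]

  S <- stoichiometric_matrix(model, include_boundary = FALSE)
  residual <- rat_matvec(S, v)

  b <- bounds_vectors(model)
  low_bad <- which(v < b$lb)
  up_bad <- which(v > b$ub)
  viol_id <- c(rxn_ids(model)[low_bad], rxn_ids(model)[up_bad])
  amounts <- c(if (length(low_bad)) rat_format(v[low_bad] - b$lb[low_bad]),
               if (length(up_bad)) rat_format(v[up_bad] - b$ub[up_bad]))
  ord <- order(viol_id)
  bound_violations <- data.frame(reaction = viol_id[ord],
                                 amount = amounts[ord],
                                 stringsAsFactors = FALSE)

  obj <- rat_sum(objective_vector(model) * v)
  balanced <- all(residual$num == 0)
  verdict <- if (!balanced) "infeasible_mass_balance"
             else if (nrow(bound_violations) > 0) "infeasible_bounds"
             else "exact_feasible"
  structure(list(residual = residual, bound_violations = bound_violations,
                 objective_value = obj, verdict = verdict),
            class = "gem_verification")
}

#' @export
print.gem_verification <- function(x, ...) {
  cat("<verification> ", x$verdict,
      ", objective=", rat_format(x$objective_value), "\n", sep = "")
  if (x$verdict == "infeasible_mass_balance") {
    nz <- which(x$residual$num != 0)
    cat("  nonzero residuals: ",
        paste0(names(x$residual)[nz], "=", rat_format(x$residual[nz]), collapse = ", "),
        "\n", sep = "")
  }
  if (nrow(x$bound_violations) > 0) {
    cat("  bound violations:\n")
    print.data.frame(x$bound_violations)
  }
  invisible(x)
}

# Accept vrat, character literals, numeric (exact via IEEE bits), or a
# FluxState; always returns a named vrat.
flux_as_vrat <- function(flux) {
  if (inherits(flux, "gem_flux")) flux <- flux$values
  if (is_vrat(flux)) {
    if (is.null(names(flux))) stop("flux vector must be named by reaction id")
    return(flux)
  }
  if (is.character(flux)) {
    v <- rat_parse(flux); names(v) <- names(flux); return(v)
  }
  if (is.numeric(flux)) {
    v <- rationalize(flux, "float_bits"); names(v) <- names(flux); return(v)
  }
  if (is.list(flux)) {
    v <- do.call(c, lapply(flux, as_vrat)); names(v) <- names(flux); return(v)
  }
  stop("cannot interpret flux of class ", class(flux)[1])
}

#' Read a flux vector from two-column delimited text
#'
#' Column 1 is the reaction id, column 2 an exact rational (`"p/q"`) or
#' decimal literal, converted digit-exactly.
#'
#' @param path file path (tab- or whitespace-delimited; `#` comments allowed).
#' @return Named `vrat`.
#' @export
read_flux_tsv <- function(path) {
  tab <- utils::read.table(path, header = FALSE, comment.char = "#",
                           colClasses = "character",
                           col.names = c("reaction", "flux"))
  v <- rat_parse(tab$flux)
  names(v) <- tab$reaction
  v
}

#' Write a flux vector as two-column delimited text
#' @param flux named `vrat` (or coercible flux assignment).
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_flux_tsv <- function(flux, path) {
  v <- flux_as_vrat(flux)
  writeLines(paste(names(v), rat_format(v), sep = "\t"), path)
  invisible(path)
}
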