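# In-memory representation of a constraint-based metabolic model.
#
# A model is the data of the FBA program max c.v s.t. S.v = 0, lb <= v <= ub:
# metabolites are the rows of S, reactions its columns, and every coefficient,
# bound and objective weight is an exact rational. Metabolites flagged as
# boundary species (the SBML boundaryCondition convention) mark where material
# crosses the system boundary and contribute no mass-balance row.

#' Construct a metabolite
#'
#' @param id non-empty identifier, unique within a model (case-sensitive).
#' @param name free-text name.
#' @param compartment compartment identifier.
#' @param boundary logical; `TRUE` marks an SBML boundary-condition species,
#'   which is excluded from mass balance.
#' @return A `gem_metabolite`.
#' @export
gem_metabolite <- function(id, name = id, compartment = "c", boundary = FALSE) {
  if (!is.character(id) || length(id) != 1 || !nzchar(id))
    stop("metabolite id must be a non-empty string")
  structure(list(id = id, name = name, compartment = compartment,
                 boundary = isTRUE(boundary)), class = "gem_metabolite")
}

#' Construct a reaction
#'
#' Stoichiometric coefficients are exact rationals; negative coefficients are
#' consumed species, positive ones produced. Zero coefficients are dropped at
#' construction so that matrix equality is well defined.
#'
#' @param id non-empty identifier, unique within a model.
#' @param stoich named coefficient vector (names are metabolite ids); numeric
#'   (integer-valued), character rational literals, or a `vrat`.
#' @param lower,upper flux bounds (rational scalars; `lower <= upper` required).
#' @param objective objective coefficient (rational scalar, default 0).
#' @param reversible logical; defaults to `lower < 0`.
#' @return A `gem_reaction`.
#' @export
gem_reaction <- function(id, stoich, lower, upper, objective = 0,
                         reversible = NULL) {
  if (!is.character(id) || length(id) != 1 || !nzchar(id))
    stop("reaction id must be a non-empty string")
  nm <- names(stoich)
  coef <- as_vrat(stoich)
  if (length(coef) > 0 && (is.null(nm) || any(!nzchar(nm))))
    stop("stoichiometry must be a fully named vector (reaction ", id, ")")
  keep <- coef$num != 0
  coef <- coef[keep]; nm <- nm[keep]
  if (anyDuplicated(nm)) stop("duplicate metabolite in stoichiometry of ", id)
  lower <- as_vrat(if (is.numeric(lower) && is.infinite(lower)) vrat(sign(lower), 0) else lower)
  upper <- as_vrat(if (is.numeric(upper) && is.infinite(upper)) vrat(sign(upper), 0) else upper)
  objective <- as_vrat(objective)
  stopifnot(length(lower) == 1, length(upper) == 1, length(objective) == 1)
  if (isTRUE(lower > upper))
    stop("reaction ", id, ": lower bound exceeds upper bound")
  if (is.null(reversible)) reversible <- isTRUE(lower < as_vrat(0))
  structure(list(id = id, met_ids = unname(nm), coef = coef,
                 lb = lower, ub = upper, obj = objective,
                 reversible = isTRUE(reversible)), class = "gem_reaction")
}

#' Construct a model
#'
#' Validates identifier uniqueness (case-sensitive; case-insensitive collisions
#' are lint findings, not errors) and that every stoichiometric entry resolves
#' to a metabolite of the model.
#'
#' @param id model identifier.
#' @param metabolites list of [gem_metabolite()] objects.
#' @param reactions list of [gem_reaction()] objects.
#' @param provenance optional list of parse-time facts used by [lint_model()]
#'   (raw species ids from the file, bound repairs, reversibility conflicts).
#' @return A `gem_model`.
#' @export
gem_model <- function(id, metabolites, reactions, provenance = list()) {
  met_ids <- vapply(metabolites, function(m) m$id, character(1))
  rxn_ids <- vapply(reactions, function(r) r$id, character(1))
  if (anyDuplicated(met_ids))
    stop("duplicate metabolite id(s): ",
         paste(unique(met_ids[duplicated(met_ids)]), collapse = ", "))
  if (anyDuplicated(rxn_ids))
    stop("duplicate reaction id(s): ",
         paste(unique(rxn_ids[duplicated(rxn_ids)]), collapse = ", "))
  for (r in reactions) {
    bad <- setdiff(r$met_ids, met_ids)
    if (length(bad))
      stop("reaction ", r$id, " references unknown metabolite(s): ",
           paste(bad, collapse = ", "))
  }
  names(metabolites) <- met_ids
  names(reactions) <- rxn_ids
  structure(list(id = id, metabolites = metabolites, reactions = reactions,
                 provenance = provenance), class = "gem_model")
}

#' @export
print.gem_model <- function(x, ...) {
  nb <- sum(vapply(x$metabolites, function(m) m$boundary, logical(1)))
  cat("<gem_model '", x$id, "'> ", length(x$metabolites), " metabolites (",
      nb, " boundary), ", length(x$reactions), " reactions\n", sep = "")
  invisible(x)
}

met_ids <- function(model) names(model$metabolites)

rxn_ids <- function(model) names(model$reactions)

boundary_ids <- function(model) {
  ids <- met_ids(model)
  ids[vapply(model$metabolites, function(m) m$boundary, logical(1))]
}

internal_met_ids <- function(model) setdiff(met_ids(model), boundary_ids(model))

objective_vector <- function(model) {
  vecs <- lapply(model$reactions, function(r) r$obj)
  out <- do.call(c, c(vecs, list(as_vrat(numeric(0)))))
  names(out) <- rxn_ids(model)
  out
}

bounds_vectors <- function(model) {
  lb <- do.call(c, c(lapply(model$reactions, function(r) r$lb), list(as_vrat(numeric(0)))))
  ub <- do.call(c, c(lapply(model$reactions, function(r) r$ub), list(as_vrat(numeric(0)))))
  names(lb) <- names(ub) <- rxn_ids(model)
  list(lb = lb, ub = ub)
}

#' Exact stoichiometric matrix
#'
#' Entry (i, j) is reaction j's coefficient for metabolite i as an exact
#' rational. With `include_boundary = FALSE` (the mass-balance view used by
#' FBA) rows for boundary-condition species are omitted.
#'
#' @param model a `gem_model`.
#' @param include_boundary logical; keep rows for boundary species?
#' @return A [ratmat] with metabolite rows and reaction columns.
#' @export
stoichiometric_matrix <- function(model, include_boundary = FALSE) {
  rows <- if (include_boundary) met_ids(model) else internal_met_ids(model)
  nr <- length(rows); nc <- length(model$reactions)
  num <- matrix(0, nr, nc); den <- matrix(1, nr, nc)
  ridx <- structure(seq_len(nr), names = rows)
  for (j in seq_len(nc)) {
    r <- model$reactions[[j]]
    keep <- r$met_ids %in% rows
    if (!any(keep)) next
    i <- ridx[r$met_ids[keep]]
    num[i, j] <- r$coef$num[keep]
    den[i, j] <- r$coef$den[keep]
  }
  ratmat(num, den, dimnames = list(rows, rxn_ids(model)))
}

#' Identify exchange reactions
#'
#' A reaction crosses the system boundary if it (a) involves a boundary
#' metabolite — the convention of record — or (b) has one-signed stoichiometry
#' over internal metabolites (a pure source or sink, covering models that
#' encode exchanges without boundary species). Deterministic: returns ids in
#' model order.
#'
#' @param model a `gem_model`.
#' @return Character vector of reaction ids.
#' @export
identify_exchanges <- function(model) {
  bids <- boundary_ids(model)
  out <- character(0)
  for (r in model$reactions) {
    if (any(r$met_ids %in% bids)) { out <- c(out, r$id); next }
    s <- rat_sign(r$coef)
    if (all(s >= 0) || all(s <= 0)) out <- c(out, r$id)
  }
  out
}

internal_reaction_ids <- function(model) setdiff(rxn_ids(model), identify_exchanges(model))

#' Lint finding codes
#'
#' The fixed enumeration of model-encoding defects reported by [lint_model()]:
#' \describe{
#'   \item{CASE_COLLISION}{species ids equal under case folding but distinct as
#'     strings (one tool's single constraint is another tool's two).}
#'   \item{BOUNDARY_IN_INTERNAL_REACTION}{a boundary species takes part in a
#'     reaction that interconverts internal metabolites.}
#'   \item{NO_EXCHANGES}{no reaction crosses the system boundary; nothing can
#'     enter, so no growth is possible.}
#'   \item{INVERTED_BOUNDS}{a lower bound exceeded its upper bound in the file
#'     (repaired by swapping at parse time).}
#'   \item{DUPLICATE_STOICH_ROW}{two internal metabolites with identical rows
#'     of S (a redundant constraint).}
#'   \item{NO_OBJECTIVE}{every objective coefficient is zero.}
#'   \item{ZERO_EXCLUDED_BOUNDS}{a reaction whose bounds exclude zero flux;
#'     the loop-removal guarantee requires all reactions to allow zero flux.}
#'   \item{REVERSIBILITY_CONFLICT}{explicit bounds contradict the reversible
#'     flag; the bounds win.}
#' }
#' @name lint-codes
NULL

lint_code_levels <- c("BOUNDARY_IN_INTERNAL_REACTION", "CASE_COLLISION",
                      "DUPLICATE_STOICH_ROW", "INVERTED_BOUNDS", "NO_EXCHANGES",
                      "NO_OBJECTIVE", "REVERSIBILITY_CONFLICT",
                      "ZERO_EXCLUDED_BOUNDS")

new_lint_report <- function(code = character(), severity = character(),
                            subject = character(), message = character()) {
  stopifnot(all(code %in% lint_code_levels))
  df <- data.frame(code = code, severity = severity, subject = subject,
                   message = message, stringsAsFactors = FALSE)
  df <- df[order(df$code, df$subject, method = "radix"), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("gem_lint", "data.frame")
  df
}

#' @export
print.gem_lint <- function(x, ...) {
  if (nrow(x) == 0) cat("<lint> clean\n")
  else {
    cat("<lint> ", nrow(x), " finding(s)\n", sep = "")
    print.data.frame(x)
  }
  invisible(x)
}

lint_bind <- function(...) {
  parts <- Filter(function(p) !is.null(p) && nrow(p) > 0, list(...))
  if (length(parts) == 0) return(new_lint_report())
  df <- do.call(rbind, lapply(parts, as.data.frame))
  new_lint_report(df$code, df$severity, df$subject, df$message)
}

#' Lint a model for encoding defects
#'
#' Pure and deterministic: findings are ordered by code then subject id, and
#' two calls on the same model yield identical reports. Case-collision
#' detection uses Unicode case folding on the raw file ids when available,
#' because the defect lives in the file, before any id handling.
#'
#' @param model a `gem_model`.
#' @param raw_species_ids optional character vector of species ids as they
#'   appeared in the source file (pre-normalization); defaults to ids recorded
#'   by the reader, then to the model's metabolite ids.
#' @return A `gem_lint` report (data frame of code/severity/subject/message).
#' @export
lint_model <- function(model, raw_species_ids = NULL) {
  code <- character(); severity <- character(); subject <- character(); msg <- character()
  add <- function(co, se, su, me) {
    code <<- c(code, co); severity <<- c(severity, se)
    subject <<- c(subject, su); msg <<- c(msg, me)
  }

  ids <- raw_species_ids
  if (is.null(ids)) ids <- model$provenance$raw_species_ids
  if (is.null(ids)) ids <- met_ids(model)
  folded <- casefold(ids, upper = FALSE)
  for (key in unique(folded[duplicated(folded)])) {
    grp <- sort(unique(ids[folded == key]), method = "radix")
    if (length(grp) > 1)
      add("CASE_COLLISION", "warning", paste(grp, collapse = "|"),
          paste0("species ids ", paste(sQuote(grp), collapse = " and "),
                 " collide under case folding; case-insensitive tools will merge them"))
  }

  for (rid in model$provenance$inverted_bounds %||% character(0))
    add("INVERTED_BOUNDS", "error", rid,
        "lower bound exceeded upper bound in the source file (repaired by swapping)")

  for (rid in model$provenance$reversibility_conflicts %||% character(0))
    add("REVERSIBILITY_CONFLICT", "warning", rid,
        "explicit bounds contradict the reversible flag; bounds take precedence")

  exch <- identify_exchanges(model)
  if (length(model$reactions) > 0 && length(exch) == 0)
    add("NO_EXCHANGES", "warning", model$id,
        "no exchange reactions: no mass can enter or leave the system")

  obj <- objective_vector(model)
  if (length(model$reactions) > 0 && all(obj$num == 0))
    add("NO_OBJECTIVE", "warning", model$id, "all objective coefficients are zero")

  zero <- as_vrat(0)
  bids <- boundary_ids(model)
  for (r in model$reactions) {
    if (isTRUE(r$lb > zero) || isTRUE(r$ub < zero))
      add("ZERO_EXCLUDED_BOUNDS", "warning", r$id,
          paste0("bounds [", rat_format(r$lb), ", ", rat_format(r$ub),
                 "] exclude zero flux; loop-removal guarantee does not apply"))
    onb <- r$met_ids %in% bids
    if (any(onb)) {
      s <- rat_sign(r$coef)[!onb]
      if (any(s > 0) && any(s < 0))
        add("BOUNDARY_IN_INTERNAL_REACTION", "warning", r$id,
            "boundary species participates in a reaction interconverting internal metabolites")
    }
  }

  S <- stoichiometric_matrix(model, include_boundary = FALSE)
  if (nrow(S$num) > 1) {
    key <- apply(cbind(S$num, S$den), 1, paste, collapse = ",")
    for (k in unique(key[duplicated(key)])) {
      grp <- sort(internal_met_ids(model)[key == k], method = "radix")
      add("DUPLICATE_STOICH_ROW", "info", paste(grp, collapse = "|"),
          paste0("metabolites ", paste(sQuote(grp), collapse = " and "),
                 " have identical stoichiometric rows"))
    }
  }

  new_lint_report(code, severity, subject, msg)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
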