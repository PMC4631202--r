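# End-to-end verification pipeline: parse -> lint -> FBA (exact and float) ->
# solver agreement -> loop analysis -> verdict. Every stage failure downgrades
# the verdict; nothing passes silently. A verdict of verified_feasible always
# carries the exact rational flux vector as its certificate.

#' Verify one SBML model file
#'
#' Runs the full pipeline on one file and returns a machine-readable report.
#' The verdict is one of:
#' \describe{
#'   \item{verified_feasible}{exact FBA found an optimum, the flux re-verified
#'     with zero rational residual, float and exact solvers agree, and the
#'     reported flux is loopless (directly, or after loop removal).}
#'   \item{verified_infeasible}{no growth is possible under the parsed
#'     constraints, with an exact certificate: the LP is infeasible, the exact
#'     biomass optimum is 0 (blocked), or biomass requires a
#'     thermodynamically infeasible cycle.}
#'   \item{parse_error}{the file could not be parsed into a model.}
#'   \item{solver_disagreement}{float and exact objectives (or statuses)
#'     disagree beyond tolerance.}
#' }
#'
#' @param path SBML file path.
#' @param options a [parse_options()]; use `misparse_boundary = TRUE` to
#'   override `respect_boundary` for demonstration.
#' @param backends float backends for the agreement check.
#' @param tolerance objective agreement tolerance (default `1e-6`).
#' @param big_M loop-law constant.
#' @param misparse_boundary deliberately ignore the boundary-condition flag,
#'   reproducing the diagnosed parsing error; clearly non-default.
#' @return A `gem_check_report`.
#' @export
gem_check <- function(path, options = parse_options(), backends = "simplex_float",
                      tolerance = 1e-6, big_M = 1000, misparse_boundary = FALSE) {
  if (misparse_boundary) options$respect_boundary <- FALSE
  report <- list(path = path, model_id = NA_character_, verdict = NULL,
                 lint = NULL, fba = NULL, agreement = NULL,
                 loopless = NULL, loop_removal_applied = FALSE,
                 exact_flux = NULL, notes = character(0))
  parsed <- tryCatch(read_sbml(path, options), error = function(e) e)
  if (inherits(parsed, "error")) {
    report$verdict <- "parse_error"
    report$notes <- conditionMessage(parsed)
    class(report) <- "gem_check_report"
    return(report)
  }
  model <- parsed$model
  report$model_id <- model$id
  report$lint <- parsed$lint

  fba_exact <- tryCatch(solve_fba(model, "exact"), error = function(e) e)
  if (inherits(fba_exact, "error")) {
    report$verdict <- "parse_error"
    report$notes <- paste("cannot pose FBA:", conditionMessage(fba_exact))
    class(report) <- "gem_check_report"
    return(report)
  }
  report$fba <- list(status = fba_exact$status,
                     objective_exact = if (fba_exact$status == "optimal")
                       rat_format(fba_exact$objective_value) else NULL)

  agree <- compare_solvers(model, backends = backends, tolerance = tolerance)
  report$agreement <- agree
  report$fba$objective_float <- unname(agree$float_objectives[1])

  if (!isTRUE(agree$agrees)) {
    report$verdict <- "solver_disagreement"
    class(report) <- "gem_check_report"
    return(report)
  }
  if (fba_exact$status != "optimal") {
    report$verdict <- "verified_infeasible"
    report$notes <- c(report$notes, "FBA program is infeasible (exact certificate)")
    class(report) <- "gem_check_report"
    return(report)
  }
  if (fba_exact$objective_value == as_vrat(0)) {
    # feasible but blocked: the biomass function cannot carry nonzero flux
    report$verdict <- "verified_infeasible"
    report$notes <- c(report$notes, "biomass blocked: exact optimum is 0")
    class(report) <- "gem_check_report"
    return(report)
  }

  ver <- verify_flux_state(model, fba_exact)
  if (ver$verdict != "exact_feasible") {
    # cannot happen for a rational-simplex optimum; never pass silently
    report$verdict <- "solver_disagreement"
    report$notes <- paste("exact optimum failed re-verification:", ver$verdict)
    class(report) <- "gem_check_report"
    return(report)
  }

  flux <- fba_exact
  ll <- is_loopless(model, flux)
  if (!ll$loopless) {
    rem <- tryCatch(remove_loops(model, flux), error = function(e) e)
    if (inherits(rem, "error")) {
      llf <- loopless_fba(model, big_M = big_M)
      report$loopless <- list(feasible = llf$status == "optimal",
                              objective = if (llf$status == "optimal")
                                rat_format(llf$objective_value) else NULL)
      if (llf$status != "optimal") {
        report$verdict <- "verified_infeasible"
        report$notes <- c(report$notes,
                          "biomass requires a thermodynamically infeasible cycle")
        class(report) <- "gem_check_report"
        return(report)
      }
      flux <- llf
    } else {
      flux <- rem
      report$loop_removal_applied <- TRUE
      report$loopless <- list(feasible = TRUE,
                              objective = rat_format(flux$objective_value))
    }
  } else {
    report$loopless <- list(feasible = TRUE,
                            objective = rat_format(flux$objective_value))
  }

  report$exact_flux <- as.list(rat_format(flux$values))
  report$verdict <- "verified_feasible"
  class(report) <- "gem_check_report"
  report
}

#' @export
print.gem_check_report <- function(x, ...) {
  cat("<check> ", x$path, ": ", x$verdict, sep = "")
  if (!is.null(x$fba$objective_exact))
    cat(", exact objective ", x$fba$objective_exact, sep = "")
  if (isTRUE(x$loop_removal_applied)) cat(" (loop removal applied)")
  cat("\n")
  if (!is.null(x$lint) && nrow(x$lint) > 0)
    cat("  lint: ", paste(unique(x$lint$code), collapse = ", "), "\n", sep = "")
  if (length(x$notes)) cat("  note: ", paste(x$notes, collapse = "; "), "\n", sep = "")
  invisible(x)
}

#' Convert a check report to JSON-ready structure
#' @param report a `gem_check_report`.
#' @return A plain list; rationals appear as `"p/q"` strings so exact
#'   certificates round-trip losslessly.
#' @export
check_report_as_list <- function(report) {
  ag <- report$agreement
  list(path = report$path, model_id = report$model_id, verdict = report$verdict,
       lint = if (is.null(report$lint)) NULL else as.data.frame(report$lint),
       fba = report$fba,
       agreement = if (is.null(ag)) NULL else list(
         exact_status = ag$exact_status,
         exact_objective = if (ag$exact_status == "optimal") rat_format(ag$exact_objective) else NULL,
         float_objectives = as.list(ag$float_objectives),
         max_abs_difference = ag$max_abs_difference,
         tolerance = ag$tolerance, agrees = ag$agrees, note = ag$note),
       loopless = report$loopless,
       loop_removal_applied = report$loop_removal_applied,
       exact_flux = report$exact_flux,
       notes = report$notes)
}

#' Verify every SBML file in a directory
#'
#' Applies [gem_check()] to all `.xml`/`.sbml` files (sorted, so reruns are
#' byte-identical) and aggregates verdict counts. A file that fails to parse
#' is counted under `parse_error` and does not affect the others.
#'
#' @param dir directory of SBML files.
#' @param ... passed to [gem_check()].
#' @return A `gem_batch_summary`: `counts` (named verdict counts) and
#'   `reports` (per-file `gem_check_report`s, in file order).
#' @export
gem_batch <- function(dir, ...) {
  files <- sort(list.files(dir, pattern = "\\.(xml|sbml)$", full.names = TRUE),
                method = "radix")
  reports <- lapply(files, function(f)
    tryCatch(gem_check(f, ...), error = function(e) {
      structure(list(path = f, model_id = NA_character_, verdict = "parse_error",
                     lint = NULL, fba = NULL, agreement = NULL, loopless = NULL,
                     loop_removal_applied = FALSE, exact_flux = NULL,
                     notes = conditionMessage(e)),
                class = "gem_check_report")
    }))
  verdicts <- vapply(reports, function(r) r$verdict, character(1))
  lv <- c("verified_feasible", "verified_infeasible", "parse_error",
          "solver_disagreement")
  counts <- vapply(lv, function(v) sum(verdicts == v), integer(1))
  structure(list(counts = counts, reports = reports, files = files),
            class = "gem_batch_summary")
}

#' @export
print.gem_batch_summary <- function(x, ...) {
  cat("<batch> ", length(x$reports), " model file(s)\n", sep = "")
  for (v in names(x$counts)) if (x$counts[[v]] > 0)
    cat("  ", v, ": ", x$counts[[v]], "\n", sep = "")
  invisible(x)
}
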