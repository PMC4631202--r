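# SBML input/output for constraint-based models, covering the two encodings
# the community actually uses: the legacy COBRA dialect (SBML Level 2 with
# LOWER_BOUND / UPPER_BOUND / OBJECTIVE_COEFFICIENT kinetic-law parameters)
# and SBML Level 3 with the Flux Balance Constraints package version 2, the
# unambiguous target format.
#
# Two deliberate design points:
#   * Numeric literals are converted to exact rationals from their decimal
#     text ("0.1" -> 1/10), never through binary floating point, so parsing
#     cannot manufacture numerical error.
#   * The boundary-condition convention is explicit and switchable: species
#     flagged boundaryCondition="true" mark the system boundary and are
#     excluded from mass balance. Setting respect_boundary = FALSE treats
#     them as internal, which adds one mass-balance constraint per boundary
#     species and blocks all uptake -- the classic misparse that turns a
#     growing model into an "infeasible" one.

FBC2_NS <- "http://www.sbml.org/sbml/level3/version1/fbc/version2"
SBML_L2_NS <- "http://www.sbml.org/sbml/level2"
SBML_L3_NS <- "http://www.sbml.org/sbml/level3/version1/core"
RATIONAL_NS <- "https://gemverify.invalid/rational"
MATHML_NS <- "http://www.w3.org/1998/Math/MathML"

#' Parse options for SBML reading
#'
#' @param dialect `"auto"` (detect), `"legacy_cobra"`, or `"fbc2"`.
#' @param respect_boundary honor the SBML boundary-condition flag (default
#'   `TRUE`). `FALSE` reproduces the misparse in which boundary species gain
#'   mass-balance rows and block all uptake.
#' @param default_bound_magnitude bound used when a reaction carries no
#'   explicit bounds: `(-default, +default)` if reversible, `(0, +default)`
#'   otherwise. Must be positive. Default 1000.
#' @param infinity_policy `"keep_literal"` keeps infinite/huge bound literals
#'   verbatim; `"clamp_to_default"` replaces infinities with the default
#'   magnitude.
#' @return A `parse_options` list.
#' @export
parse_options <- function(dialect = c("auto", "legacy_cobra", "fbc2"),
                          respect_boundary = TRUE,
                          default_bound_magnitude = 1000,
                          infinity_policy = c("keep_literal", "clamp_to_default")) {
  dbm <- as_vrat(default_bound_magnitude)
  if (!isTRUE(dbm > as_vrat(0))) stop("default_bound_magnitude must be positive")
  structure(list(dialect = match.arg(dialect),
                 respect_boundary = isTRUE(respect_boundary),
                 default_bound_magnitude = dbm,
                 infinity_policy = match.arg(infinity_policy)),
            class = "parse_options")
}

ln_find_all <- function(node, name, scope = ".//") {
  xml2::xml_find_all(node, paste0(scope, "*[local-name()='", name, "']"))
}

ln_find_first <- function(node, name, scope = ".//") {
  xml2::xml_find_first(node, paste0(scope, "*[local-name()='", name, "']"))
}

attr_local <- function(node, name, default = NA_character_) {
  a <- xml2::xml_attrs(node)
  hit <- which(names(a) == name | endsWith(names(a), paste0(":", name)))
  if (length(hit) == 0) default else unname(a[hit[1]])
}

# Exact value of an SBML attribute: a sibling <rational value="p/q"/>
# annotation (written by write_sbml_fbc2 for non-decimal rationals) wins over
# the decimal text.
node_value_rat <- function(node, attr = "value") {
  ann <- xml2::xml_find_first(
    node, paste0("./*[local-name()='annotation']//*[local-name()='rational']"))
  if (!inherits(ann, "xml_missing")) {
    v <- xml2::xml_attr(ann, "value")
    if (!is.na(v)) return(rat_parse(v))
  }
  txt <- attr_local(node, attr)
  if (is.na(txt)) return(NULL)
  rat_parse(txt)
}

#' Detect the SBML dialect of a file
#'
#' `fbc2` iff the fbc version-2 namespace is declared and used; otherwise
#' `legacy_cobra` for any SBML document containing reactions. A file in which
#' neither pattern holds raises a "dialect undetermined" error — never a
#' silent guess.
#'
#' @param path SBML file path.
#' @return `"fbc2"` or `"legacy_cobra"`.
#' @export
detect_dialect <- function(path) {
  doc <- xml2::read_xml(path)
  ns <- xml2::xml_ns(doc)
  fbc_declared <- any(vapply(ns, identical, logical(1), FBC2_NS))
  if (fbc_declared) {
    uses <- length(ln_find_all(doc, "listOfObjectives")) > 0 ||
      any(vapply(ln_find_all(doc, "reaction"),
                 function(r) !is.na(attr_local(r, "lowerFluxBound")), logical(1)))
    if (uses) return("fbc2")
  }
  if (length(ln_find_all(doc, "reaction")) > 0) return("legacy_cobra")
  stop("dialect undetermined: no fbc v2 markers and no reactions in ", path)
}

#' Read an SBML model
#'
#' Parses either dialect into a `gem_model` with exact rational coefficients
#' and bounds, and lints it. See [parse_options()] for the boundary-condition
#' and bound-defaulting semantics.
#'
#' @param path SBML file path.
#' @param options a [parse_options()] list.
#' @return List with `model` (a `gem_model`) and `lint` (a `gem_lint`).
#' @export
read_sbml <- function(path, options = parse_options()) {
  if (!file.exists(path)) stop("file not found: ", path)
  doc <- xml2::read_xml(path)
  dialect <- options$dialect
  if (dialect == "auto") dialect <- detect_dialect(path)

  mnode <- ln_find_first(doc, "model")
  if (inherits(mnode, "xml_missing")) stop("no <model> element in ", path)
  model_id <- attr_local(mnode, "id", tools::file_path_sans_ext(basename(path)))

  # --- species -----------------------------------------------------------
  snodes <- ln_find_all(mnode, "species")
  raw_ids <- vapply(snodes, function(s) attr_local(s, "id"), character(1))
  if (anyNA(raw_ids) || any(!nzchar(raw_ids))) stop("species without id in ", path)
  if (anyDuplicated(raw_ids))
    stop("duplicate species id(s) in file: ",
         paste(unique(raw_ids[duplicated(raw_ids)]), collapse = ", "))
  flagged <- vapply(snodes, function(s)
    identical(attr_local(s, "boundaryCondition", "false"), "true"), logical(1))
  mets <- lapply(seq_along(snodes), function(i) {
    s <- snodes[[i]]
    gem_metabolite(raw_ids[i],
                   name = attr_local(s, "name", raw_ids[i]),
                   compartment = attr_local(s, "compartment", "c"),
                   boundary = options$respect_boundary && flagged[i])
  })

  # --- reactions ---------------------------------------------------------
  dflt <- options$default_bound_magnitude
  pinf <- vrat(1, 0); ninf <- vrat(-1, 0)
  clamp <- function(x) {
    if (options$infinity_policy == "clamp_to_default" && !all(rat_is_finite(x)))
      (if (x$num > 0) dflt else -dflt) else x
  }
  inverted <- character(0); conflicts <- character(0)

  fbc_params <- list()
  if (dialect == "fbc2") {
    for (p in ln_find_all(mnode, "parameter", scope = "./*[local-name()='listOfParameters']/")) {
      pid <- attr_local(p, "id")
      val <- node_value_rat(p)
      if (!is.na(pid) && !is.null(val)) fbc_params[[pid]] <- val
    }
  }

  rnodes <- ln_find_all(mnode, "reaction")
  if (length(rnodes) == 0) stop("model has no reactions: ", path)
  rxns <- vector("list", length(rnodes))
  for (i in seq_along(rnodes)) {
    r <- rnodes[[i]]
    rid <- attr_local(r, "id")
    if (is.na(rid) || !nzchar(rid)) stop("reaction without id in ", path)
    rev_attr <- identical(attr_local(r, "reversible", "true"), "true")

    stoich_ids <- character(0)
    stoich_val <- as_vrat(numeric(0))
    collect <- function(listname, sgn) {
      lst <- ln_find_first(r, listname, scope = "./")
      if (inherits(lst, "xml_missing")) return()
      for (sr in ln_find_all(lst, "speciesReference", scope = "./")) {
        sp <- attr_local(sr, "species")
        co <- node_value_rat(sr, "stoichiometry")
        if (is.null(co)) co <- as_vrat(1)
        co <- if (sgn < 0) -co else co
        j <- match(sp, stoich_ids)
        if (is.na(j)) {
          stoich_ids <<- c(stoich_ids, sp)
          stoich_val <<- c(stoich_val, co)
        } else {
          stoich_val[j] <<- stoich_val[j] + co
        }
      }
    }
    collect("listOfReactants", -1L)
    collect("listOfProducts", +1L)
    stoich <- stoich_val
    names(stoich) <- stoich_ids

    lb <- ub <- obj <- NULL
    if (dialect == "legacy_cobra") {
      kl <- ln_find_first(r, "kineticLaw", scope = "./")
      if (!inherits(kl, "xml_missing")) {
        for (p in ln_find_all(kl, "parameter")) {
          pid <- attr_local(p, "id")
          if (is.na(pid)) pid <- attr_local(p, "name")
          val <- node_value_rat(p)
          if (is.null(val)) next
          if (identical(pid, "LOWER_BOUND")) lb <- val
          else if (identical(pid, "UPPER_BOUND")) ub <- val
          else if (identical(pid, "OBJECTIVE_COEFFICIENT")) obj <- val
        }
      }
    } else {
      lref <- attr_local(r, "lowerFluxBound")
      uref <- attr_local(r, "upperFluxBound")
      if (!is.na(lref)) lb <- fbc_params[[lref]]
      if (!is.na(uref)) ub <- fbc_params[[uref]]
    }
    if (is.null(lb)) lb <- if (rev_attr) -dflt else as_vrat(0)
    if (is.null(ub)) ub <- dflt
    if (is.null(obj)) obj <- as_vrat(0)
    lb <- clamp(lb); ub <- clamp(ub)
    if (isTRUE(lb > ub)) {
      tmp <- lb; lb <- ub; ub <- tmp
      inverted <- c(inverted, rid)
    }
    if (!rev_attr && isTRUE(lb < as_vrat(0))) conflicts <- c(conflicts, rid)
    rxns[[i]] <- gem_reaction(rid, stoich, lb, ub, objective = obj,
                              reversible = isTRUE(lb < as_vrat(0)))
  }

  if (dialect == "fbc2") {
    ids_rx <- vapply(rxns, function(r) r$id, character(1))
    objlist <- ln_find_first(mnode, "listOfObjectives")
    if (!inherits(objlist, "xml_missing")) {
      active <- attr_local(objlist, "activeObjective")
      onodes <- ln_find_all(objlist, "objective", scope = "./")
      onode <- NULL
      for (o in onodes)
        if (is.na(active) || identical(attr_local(o, "id"), active)) { onode <- o; break }
      if (!is.null(onode)) {
        if (!identical(attr_local(onode, "type", "maximize"), "maximize"))
          stop("only maximization objectives are supported")
        for (fo in ln_find_all(onode, "fluxObjective")) {
          rid <- attr_local(fo, "reaction")
          co <- node_value_rat(fo, "coefficient")
          if (is.null(co)) co <- as_vrat(1)
          j <- match(rid, ids_rx)
          if (is.na(j)) stop("fluxObjective references unknown reaction ", rid)
          rxns[[j]]$obj <- co
        }
      }
    }
  }

  model <- gem_model(model_id, mets, rxns,
                     provenance = list(raw_species_ids = raw_ids,
                                       boundary_flagged = raw_ids[flagged],
                                       inverted_bounds = inverted,
                                       reversibility_conflicts = conflicts,
                                       dialect = dialect,
                                       source = path))
  list(model = model, lint = lint_model(model))
}

# ---- writing ----------------------------------------------------------------

# Render a rational for an SBML numeric attribute. Exact when the denominator
# is of the form 2^a * 5^b (a finite decimal); otherwise a 10-digit decimal
# plus needs_annotation = TRUE so the writer attaches the exact p/q.
render_sbml_value <- function(x) {
  stopifnot(length(x) == 1)
  if (!all(rat_is_finite(x)))
    return(list(text = if (x$num > 0) "INF" else "-INF", needs_annotation = FALSE))
  num <- x$num; den <- x$den
  if (den == 1) return(list(text = sprintf("%.0f", num), needs_annotation = FALSE))
  d <- den; a <- 0; b <- 0
  while (d %% 2 == 0) { d <- d / 2; a <- a + 1 }
  while (d %% 5 == 0) { d <- d / 5; b <- b + 1 }
  if (d == 1) {
    k <- max(a, b)
    scaled <- abs(num) * (10^k / den)
    if (scaled <= 2^53) {
      ip <- floor(scaled / 10^k)
      fp <- scaled - ip * 10^k
      txt <- paste0(if (num < 0) "-" else "", sprintf("%.0f", ip), ".",
                    formatC(fp, width = k, flag = "0", format = "d"))
      return(list(text = txt, needs_annotation = FALSE))
    }
  }
  list(text = sprintf("%.10f", num / den), needs_annotation = TRUE)
}

xml_add_rational_annotation <- function(node, x) {
  ann <- xml2::xml_add_child(node, "annotation")
  xml2::xml_add_child(ann, "rational", xmlns = RATIONAL_NS,
                      value = rat_format(x))
}

set_value_attr <- function(node, attr, x) {
  r <- render_sbml_value(x)
  xml2::xml_set_attr(node, attr, r$text)
  if (r$needs_annotation) xml_add_rational_annotation(node, x)
}

model_compartments <- function(model) {
  comps <- unique(vapply(model$metabolites, function(m) m$compartment, character(1)))
  if (length(comps) == 0) "c" else comps
}

write_species_refs <- function(rnode, reaction, side) {
  sel <- if (side > 0) rat_sign(reaction$coef) > 0 else rat_sign(reaction$coef) < 0
  if (!any(sel)) return(invisible())
  lst <- xml2::xml_add_child(rnode,
                             if (side > 0) "listOfProducts" else "listOfReactants")
  idx <- which(sel)
  for (i in idx) {
    co <- abs(reaction$coef[i])
    sr <- xml2::xml_add_child(lst, "speciesReference",
                              species = reaction$met_ids[i], constant = "true")
    set_value_attr(sr, "stoichiometry", co)
  }
  invisible()
}

#' Write a model as SBML Level 3 + fbc version 2
#'
#' Emits the strict fbc-v2 encoding: every reaction references explicit bound
#' parameters, one active maximization objective lists all nonzero objective
#' coefficients, and boundary metabolites are written with
#' `boundaryCondition="true"`. Values whose exact rational is not a finite
#' decimal (e.g. 1/3) are rendered to 10 decimal digits and additionally carry
#' a `<rational value="p/q"/>` annotation that [read_sbml()] uses to restore
#' the exact value, so the round trip is exact.
#'
#' @param model a `gem_model`.
#' @param path output file path.
#' @return Invisibly, `path`.
#' @export
write_sbml_fbc2 <- function(model, path) {
  doc <- xml2::xml_new_root("sbml", xmlns = SBML_L3_NS,
                            "xmlns:fbc" = FBC2_NS,
                            level = "3", version = "1", "fbc:required" = "false")
  mn <- xml2::xml_add_child(doc, "model", id = model$id, "fbc:strict" = "true")

  lc <- xml2::xml_add_child(mn, "listOfCompartments")
  for (comp in model_compartments(model))
    xml2::xml_add_child(lc, "compartment", id = comp, constant = "true")

  if (length(model$metabolites) > 0) {
    ls <- xml2::xml_add_child(mn, "listOfSpecies")
    for (m in model$metabolites)
      xml2::xml_add_child(ls, "species", id = m$id, name = m$name,
                          compartment = m$compartment,
                          hasOnlySubstanceUnits = "false",
                          boundaryCondition = if (m$boundary) "true" else "false",
                          constant = "false")
  }

  if (length(model$reactions) > 0) {
    lp <- xml2::xml_add_child(mn, "listOfParameters")
    for (r in model$reactions) {
      for (side in c("lb", "ub")) {
        pn <- xml2::xml_add_child(lp, "parameter",
                                  id = paste0(r$id, "_", side),
                                  constant = "true")
        set_value_attr(pn, "value", r[[side]])
      }
    }
    lr <- xml2::xml_add_child(mn, "listOfReactions")
    for (r in model$reactions) {
      rn <- xml2::xml_add_child(lr, "reaction", id = r$id,
                                reversible = if (r$reversible) "true" else "false",
                                fast = "false",
                                "fbc:lowerFluxBound" = paste0(r$id, "_lb"),
                                "fbc:upperFluxBound" = paste0(r$id, "_ub"))
      write_species_refs(rn, r, -1)
      write_species_refs(rn, r, +1)
    }
    lo <- xml2::xml_add_child(mn, "fbc:listOfObjectives",
                              "fbc:activeObjective" = "obj")
    on <- xml2::xml_add_child(lo, "fbc:objective", "fbc:id" = "obj",
                              "fbc:type" = "maximize")
    lfo <- xml2::xml_add_child(on, "fbc:listOfFluxObjectives")
    for (r in model$reactions) {
      if (r$obj$num == 0) next
      fo <- xml2::xml_add_child(lfo, "fbc:fluxObjective", "fbc:reaction" = r$id)
      set_value_attr(fo, "fbc:coefficient", r$obj)
    }
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Write a model in the legacy COBRA SBML dialect
#'
#' SBML Level 2 with per-reaction kinetic-law parameters `LOWER_BOUND`,
#' `UPPER_BOUND` and `OBJECTIVE_COEFFICIENT`, and boundary species flagged
#' `boundaryCondition="true"` — the historical encoding this toolkit must be
#' able to both read and reproduce for regression fixtures.
#'
#' @param model a `gem_model`.
#' @param path output file path.
#' @return Invisibly, `path`.
#' @export
write_sbml_legacy <- function(model, path) {
  doc <- xml2::xml_new_root("sbml", xmlns = SBML_L2_NS, level = "2", version = "1")
  mn <- xml2::xml_add_child(doc, "model", id = model$id)

  lc <- xml2::xml_add_child(mn, "listOfCompartments")
  for (comp in model_compartments(model))
    xml2::xml_add_child(lc, "compartment", id = comp)

  if (length(model$metabolites) > 0) {
    ls <- xml2::xml_add_child(mn, "listOfSpecies")
    for (m in model$metabolites)
      xml2::xml_add_child(ls, "species", id = m$id, name = m$name,
                          compartment = m$compartment,
                          boundaryCondition = if (m$boundary) "true" else "false")
  }

  if (length(model$reactions) > 0) {
    lr <- xml2::xml_add_child(mn, "listOfReactions")
    for (r in model$reactions) {
      rn <- xml2::xml_add_child(lr, "reaction", id = r$id,
                                reversible = if (r$reversible) "true" else "false")
      write_species_refs(rn, r, -1)
      write_species_refs(rn, r, +1)
      kl <- xml2::xml_add_child(rn, "kineticLaw")
      math <- xml2::xml_add_child(kl, "math", xmlns = MATHML_NS)
      xml2::xml_add_child(math, "cn", "0")
      lpars <- xml2::xml_add_child(kl, "listOfParameters")
      for (spec in list(c("LOWER_BOUND", "lb"), c("UPPER_BOUND", "ub"),
                        c("OBJECTIVE_COEFFICIENT", "obj"))) {
        pn <- xml2::xml_add_child(lpars, "parameter", id = spec[1])
        set_value_attr(pn, "value", r[[spec[2]]])
      }
    }
  }
  xml2::write_xml(doc, path)
  invisible(path)
}
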