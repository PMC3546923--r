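#' Export the LOS model as SBML Level 3
#'
#' Serializes the model — five dynamic species, the fixed environment
#' quantities as boundary species, all kinetic constants as parameters, and
#' every reaction with its full rate law as MathML — to an SBML Level 3
#' Version 1 document. The MathML is generated from the same R expressions
#' the native right-hand side evaluates, so a parser can reconstruct and
#' cross-check the rate laws (see [sbml_rhs()]).
#'
#' @param p `los_parameters`.
#' @param e `los_environment`.
#' @param path optional file path; when given the document is written there.
#' @return `xml_document` (invisibly when `path` is given).
#' @examples
#' doc <- export_sbml(los_parameters(), los_environment())
#' @export
export_sbml <- function(p, e, path = NULL) {
  rep <- los_validate(p, e)
  if (!attr(rep, "ok")) {
    stop("refusing to export an invalid model:\n",
      paste(" -", unclass(rep), collapse = "\n"), call. = FALSE)
  }
  doc <- xml2::xml_new_root("sbml",
    xmlns = "http://www.sbml.org/sbml/level3/version1/core",
    level = "3", version = "1")
  model <- xml2::xml_add_child(doc, "model", id = "los_model",
    name = "Leukotriene A4 and 5-oxoETE synthesis model",
    substanceUnits = "substance", timeUnits = "time",
    extentUnits = "substance")
  comps <- xml2::xml_add_child(model, "listOfCompartments")
  xml2::xml_add_child(comps, "compartment", id = "cell", size = "1",
    constant = "true")
  species <- xml2::xml_add_child(model, "listOfSpecies")
  for (nm in names(los_state())) {
    xml2::xml_add_child(species, "species", id = nm, compartment = "cell",
      initialConcentration = "0", hasOnlySubstanceUnits = "false",
      boundaryCondition = "false", constant = "false")
  }
  boundary <- setdiff(names(e), "cpla2_scale")
  for (nm in boundary) {
    xml2::xml_add_child(species, "species", id = nm, compartment = "cell",
      initialConcentration = as.character(e[[nm]]),
      hasOnlySubstanceUnits = "false", boundaryCondition = "true",
      constant = "true")
  }
  pars <- xml2::xml_add_child(model, "listOfParameters")
  for (nm in names(p)) {
    xml2::xml_add_child(pars, "parameter", id = nm,
      value = as.character(p[[nm]]), constant = "true")
  }
  xml2::xml_add_child(pars, "parameter", id = "cpla2_scale",
    value = as.character(e[["cpla2_scale"]]), constant = "true")
  reactions <- xml2::xml_add_child(model, "listOfReactions")
  for (rx in .los_reaction_table()) {
    rnode <- xml2::xml_add_child(reactions, "reaction", id = rx$id,
      reversible = tolower(as.character(rx$reversible)))
    if (length(rx$reactants)) {
      lst <- xml2::xml_add_child(rnode, "listOfReactants")
      for (sp in rx$reactants) {
        xml2::xml_add_child(lst, "speciesReference", species = sp,
          stoichiometry = "1", constant = "true")
      }
    }
    if (length(rx$products)) {
      lst <- xml2::xml_add_child(rnode, "listOfProducts")
      for (sp in rx$products) {
        xml2::xml_add_child(lst, "speciesReference", species = sp,
          stoichiometry = "1", constant = "true")
      }
    }
    kl <- xml2::xml_add_child(rnode, "kineticLaw")
    math <- xml2::xml_add_child(kl, "math",
      xmlns = "http://www.w3.org/1998/Math/MathML")
    .expr_to_mathml(rx$rate, math)
  }
  if (!is.null(path)) {
    xml2::write_xml(doc, path)
    return(invisible(doc))
  }
  doc
}

# Reaction network with symbolic rate laws. The expressions reference
# species ids, environment ids and parameter ids; helper terms are expanded
# inline so each kinetic law is self-contained.
.los_reaction_table <- function() {
  DZ   <- quote(1 + Z / K_dz)
  D2   <- quote(1 + Ca / K_2Ca)
  DzCa <- substitute((dz) * (1 + Ca / K_3Ca), list(dz = DZ))
  r1   <- quote(k_ox + k_ox2 * Ca / K_2Ca)
  r2   <- quote(k_r + k_r2 * Ca / K_2Ca)
  r7   <- quote(k_ing * (1 + Ca / K_2Ca))
  dHP  <- quote(1 + AA / K_AA_i)
  dL   <- substitute(1 + (AA / K_AA_i) / (dz) +
    (dhp) * (AA / K_AA + HT / K_HT + PF / K_PF) / (dz),
    list(dz = DZ, dhp = dHP))
  DHP  <- substitute((dhp) * (k_lo * AA / K_AA + k_3 * K_d3 * HP * (dhp)) /
    ((dz) * (k_LTAsyn + k_3 * (dhp))), list(dhp = dHP, dz = DZ))
  Dred <- substitute(((d2) / (dzca)) *
    ((rr2) + ((rr1) / K_ox) * (LOH + HT) + (rr7) * Z / K_dz) /
    ((rr2) * K_r + (rr1) * (LOOH + HP)),
    list(d2 = D2, dzca = DzCa, rr1 = r1, rr2 = r2, rr7 = r7))
  Dtot <- substitute((dl) + (dhpc) + (dred),
    list(dl = dL, dhpc = DHP, dred = Dred))
  sc <- substitute(Fa / (dtot), list(dtot = Dtot))
  list(
    list(id = "cPLA2", reversible = FALSE, reactants = character(0),
      products = "AA",
      rate = quote(cpla2_scale * Vmax_PLA2 * (Ca / (K_Ca_PLA2 + Ca)) *
        PL / (Km_PLA2_APC + PL))),
    list(id = "oxygenase", reversible = FALSE, reactants = "AA",
      products = character(0),
      rate = substitute(k_lo * (AA / K_AA) / (dz) * (s),
        list(dz = DZ, s = sc))),
    list(id = "LTA4_synthase", reversible = FALSE, reactants = character(0),
      products = "LTA4",
      rate = substitute(k_LTAsyn * (dhpc) / (dhp) * (s),
        list(dhpc = DHP, dhp = dHP, s = sc))),
    list(id = "HP_release", reversible = TRUE, reactants = character(0),
      products = "HP",
      rate = substitute(k_3 * (s) * ((dhpc) - K_d3 * HP * (dhp) / (dz)),
        list(s = sc, dhpc = DHP, dhp = dHP, dz = DZ))),
    list(id = "pseudoperoxidase_HP", reversible = TRUE, reactants = "HP",
      products = "HT",
      rate = substitute((rr1) * (s) * (HP * (dred) - HT / K_ox),
        list(rr1 = r1, s = sc, dred = Dred))),
    list(id = "pseudoperoxidase_LOOH", reversible = TRUE,
      reactants = character(0), products = character(0),
      rate = substitute((rr1) * (s) * (LOOH * (dred) - LOH / K_ox),
        list(rr1 = r1, s = sc, dred = Dred))),
    list(id = "GPx", reversible = FALSE, reactants = "HP", products = "HT",
      rate = quote(GPx_full * (kcat_GPx * (HP / Km_HP_GPx) *
        (GSH / Km_GSH_GPx) * (GSH / Km_GSH_GPx)) /
        ((HP / Km_HP_GPx) * (1 + HT / K_HT_GPx) +
         (GSH / Km_GSH_GPx) * (GSH / Km_GSH_GPx) * (1 + GSSG / K_GSSG_GPx) +
         (GSH / Km_GSH_GPx) * (GSH / Km_GSH_GPx) * (HP / Km_HP_GPx)))),
    list(id = "HEDH", reversible = TRUE, reactants = "HT",
      products = "oxoETE",
      rate = quote(HEDH_full *
        (k1_hedh * k2_hedh * (HT / K_HT_hedh) * (NADP / K_NADP_hedh) -
         km1_hedh * km2_hedh * (oxoETE / K_oxoETE_hedh) *
           (NADPH / K_NADPH_hedh)) /
        ((1 + NADP / K_NADP_hedh + oxoETE / K_oxoETE_hedh) * k1_hedh *
           (HT / K_HT_hedh) + km2_hedh * (NADPH / K_NADPH_hedh) +
         (1 + HT / K_HT_hedh + NADPH / K_NADPH_hedh) * km1_hedh *
           (oxoETE / K_oxoETE_hedh) + k2_hedh * (NADP / K_NADP_hedh)))),
    list(id = "HT_degradation", reversible = FALSE, reactants = "HT",
      products = character(0), rate = quote(k_HTd * HT)),
    list(id = "LTA4_degradation", reversible = FALSE, reactants = "LTA4",
      products = character(0), rate = quote(k_LTAd * LTA4)),
    list(id = "oxoETE_degradation", reversible = FALSE,
      reactants = "oxoETE", products = character(0),
      rate = quote(k_oxoETEd * oxoETE))
  )
}

# R expression -> content MathML, appended under `parent`.
.expr_to_mathml <- function(expr, parent) {
  if (is.numeric(expr)) {
    xml2::xml_add_child(parent, "cn", format(expr, digits = 17))
    return(invisible())
  }
  if (is.name(expr)) {
    xml2::xml_add_child(parent, "ci", as.character(expr))
    return(invisible())
  }
  if (is.call(expr)) {
    op <- as.character(expr[[1]])
    if (op == "(") return(.expr_to_mathml(expr[[2]], parent))
    tag <- switch(op, "+" = "plus", "-" = "minus", "*" = "times",
      "/" = "divide", "^" = "power",
      stop("cannot serialize operator '", op, "'", call. = FALSE))
    apply_node <- xml2::xml_add_child(parent, "apply")
    xml2::xml_add_child(apply_node, tag)
    for (i in seq_along(expr)[-1]) .expr_to_mathml(expr[[i]], apply_node)
    return(invisible())
  }
  stop("cannot serialize expression of class ", class(expr)[1],
    call. = FALSE)
}

# content MathML node -> R expression (for the round-trip cross-check).
.mathml_to_expr <- function(node) {
  nm <- xml2::xml_name(node)
  if (nm == "cn") return(as.numeric(xml2::xml_text(node)))
  if (nm == "ci") return(as.name(trimws(xml2::xml_text(node))))
  if (nm == "math") {
    kids <- xml2::xml_children(node)
    stopifnot(length(kids) == 1)
    return(.mathml_to_expr(kids[[1]]))
  }
  if (nm == "apply") {
    kids <- xml2::xml_children(node)
    op <- switch(xml2::xml_name(kids[[1]]), plus = "+", minus = "-",
      times = "*", divide = "/", power = "^",
      stop("unsupported MathML operator ", xml2::xml_name(kids[[1]]),
        call. = FALSE))
    args <- lapply(kids[-1], .mathml_to_expr)
    Reduce(function(a, b) call(op, a, b), args)
  } else {
    stop("unsupported MathML node ", nm, call. = FALSE)
  }
}

#' Evaluate the right-hand side of an exported SBML document
#'
#' Parses the kinetic laws back out of the MathML, evaluates them at a given
#' state, and assembles species derivatives from the reaction stoichiometry.
#' This closes the round trip entirely through the serialized artifact, so
#' agreement with [los_rhs()] verifies the export.
#'
#' @param doc `xml_document` from [export_sbml()] (or read from file).
#' @param s state vector, [los_state()].
#' @return named derivative vector over the five dynamic species, uM/min.
#' @export
sbml_rhs <- function(doc, s) {
  root <- xml2::xml_root(doc)
  xml2::xml_ns_strip(root)
  env <- new.env(parent = baseenv())
  for (node in xml2::xml_find_all(root, ".//parameter")) {
    assign(xml2::xml_attr(node, "id"),
      as.numeric(xml2::xml_attr(node, "value")), envir = env)
  }
  for (node in xml2::xml_find_all(root,
    ".//species[@boundaryCondition='true']")) {
    assign(xml2::xml_attr(node, "id"),
      as.numeric(xml2::xml_attr(node, "initialConcentration")), envir = env)
  }
  for (nm in names(s)) assign(nm, s[[nm]], envir = env)
  deriv <- stats::setNames(numeric(length(s)), names(s))
  for (rnode in xml2::xml_find_all(root, ".//reaction")) {
    math <- xml2::xml_find_first(rnode, ".//kineticLaw/math")
    v <- eval(.mathml_to_expr(math), envir = env)
    for (sp in xml2::xml_attr(
      xml2::xml_find_all(rnode, ".//listOfReactants/speciesReference"),
      "species")) {
      if (sp %in% names(deriv)) deriv[sp] <- deriv[sp] - v
    }
    for (sp in xml2::xml_attr(
      xml2::xml_find_all(rnode, ".//listOfProducts/speciesReference"),
      "species")) {
      if (sp %in% names(deriv)) deriv[sp] <- deriv[sp] + v
    }
  }
  deriv
}

#' Structural validation of an exported SBML document
#'
#' Checks well-formedness, the SBML level-3 namespace, the presence and
#' uniqueness of the five dynamic species, boundary species for every
#' environment quantity, and that every reaction carries a kinetic law.
#'
#' @param doc `xml_document`.
#' @return character vector of problems (length 0 when valid).
#' @export
validate_sbml <- function(doc) {
  problems <- character(0)
  root <- xml2::xml_root(doc)
  if (!grepl("sbml/level3", xml2::xml_attr(root, "xmlns") %||%
    xml2::xml_ns(root)[[1]])) {
    problems <- c(problems, "missing SBML level-3 namespace")
  }
  copy <- xml2::read_xml(as.character(doc))
  xml2::xml_ns_strip(copy)
  dyn <- xml2::xml_attr(xml2::xml_find_all(copy,
    ".//species[@boundaryCondition='false']"), "id")
  if (!setequal(dyn, names(los_state()))) {
    problems <- c(problems, paste("dynamic species mismatch:",
      paste(dyn, collapse = ",")))
  }
  if (anyDuplicated(dyn)) problems <- c(problems, "duplicate species ids")
  rx <- xml2::xml_find_all(copy, ".//reaction")
  no_kl <- vapply(rx, function(r) {
    length(xml2::xml_find_all(r, ".//kineticLaw")) == 0
  }, logical(1))
  if (any(no_kl)) {
    problems <- c(problems, paste("reactions without kinetic law:",
      paste(xml2::xml_attr(rx[no_kl], "id"), collapse = ",")))
  }
  problems
}

`%||%` <- function(a, b) if (is.null(a) || is.na(a)) b else a
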