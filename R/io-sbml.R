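# SBML Level 3 Version 1 + FBC v2 serialization.
#
# Covers the subset of SBML-FBC that constraint-based analysis needs:
# species with compartment/formula/charge, reactions with stoichiometry,
# per-reaction flux-bound parameters, gene-product associations (and/or
# trees), an active objective, and subsystem labels (carried in reaction
# notes as "SUBSYSTEM: <label>"). Identifiers are encoded to SBML SIds by
# prefixing (M_/R_/G_) and replacing every non-alphanumeric character with
# "__<utf8 code>__", the reversible convention used by COBRA-style tools.

SBML_NS <- "http://www.sbml.org/sbml/level3/version1/core"
FBC_NS <- "http://www.sbml.org/sbml/level3/version1/fbc/version2"
XHTML_NS <- "http://www.w3.org/1999/xhtml"

encode_sid <- function(id, prefix) {
  chars <- strsplit(id, "", fixed = TRUE)[[1]]
  enc <- vapply(chars, function(ch) {
    if (grepl("^[A-Za-z0-9_]$", ch)) ch else sprintf("__%d__", utf8ToInt(ch))
  }, character(1))
  paste0(prefix, paste(enc, collapse = ""))
}

decode_sid <- function(sid, prefix) {
  s <- sub(paste0("^", prefix), "", sid)
  m <- gregexpr("__([0-9]+)__", s)
  regmatches(s, m) <- lapply(regmatches(s, m), function(hits) {
    vapply(hits, function(h) intToUtf8(as.integer(gsub("__", "", h))), character(1))
  })
  s
}

#' Write a metabolic model as SBML Level 3 + FBC v2
#'
#' @param model A `metabolic_model`.
#' @param path Output path (`.xml`).
#' @return `path`, invisibly.
#' @export
write_sbml <- function(model, path) {
  validate_model(model)
  num <- function(x) format(x, scientific = FALSE, trim = TRUE, digits = 15)
  doc <- xml2::xml_new_root("sbml", xmlns = SBML_NS, "xmlns:fbc" = FBC_NS,
                            level = "3", version = "1", "fbc:required" = "false")
  mdl <- xml2::xml_add_child(doc, "model", id = encode_sid(model$id, ""),
                             "fbc:strict" = "true")
  if (!is.null(model$eps_reaction_id)) {
    notes <- xml2::xml_add_child(mdl, "notes")
    body <- xml2::xml_add_child(notes, "body", xmlns = XHTML_NS)
    xml2::xml_add_child(body, "p", paste0("EPS_REACTION: ", model$eps_reaction_id))
  }
  comps <- unique(model$metabolites$compartment)
  loc <- xml2::xml_add_child(mdl, "listOfCompartments")
  for (cp in comps)
    xml2::xml_add_child(loc, "compartment", id = encode_sid(cp, "C_"),
                        constant = "true")
  los <- xml2::xml_add_child(mdl, "listOfSpecies")
  for (i in seq_len(nrow(model$metabolites))) {
    mt <- model$metabolites[i, ]
    sp <- xml2::xml_add_child(los, "species", id = encode_sid(mt$id, "M_"),
                              name = mt$name,
                              compartment = encode_sid(mt$compartment, "C_"),
                              hasOnlySubstanceUnits = "false",
                              boundaryCondition = "false", constant = "false")
    if (!is.na(mt$formula)) xml2::xml_set_attr(sp, "fbc:chemicalFormula", mt$formula)
    if (!is.na(mt$charge)) xml2::xml_set_attr(sp, "fbc:charge", as.character(mt$charge))
  }
  lop <- xml2::xml_add_child(mdl, "listOfParameters")
  for (j in seq_len(nrow(model$reactions))) {
    rid <- model$reactions$id[j]
    xml2::xml_add_child(lop, "parameter", id = paste0("lb_", encode_sid(rid, "R_")),
                        value = num(model$reactions$lower_bound[j]),
                        constant = "true", "sboTerm" = "SBO:0000625")
    xml2::xml_add_child(lop, "parameter", id = paste0("ub_", encode_sid(rid, "R_")),
                        value = num(model$reactions$upper_bound[j]),
                        constant = "true", "sboTerm" = "SBO:0000625")
  }
  lor <- xml2::xml_add_child(mdl, "listOfReactions")
  for (j in seq_len(nrow(model$reactions))) {
    rid <- model$reactions$id[j]
    sid <- encode_sid(rid, "R_")
    rx <- xml2::xml_add_child(lor, "reaction", id = sid,
                              name = model$reactions$name[j],
                              reversible = if (model$reactions$lower_bound[j] < 0) "true" else "false",
                              fast = "false",
                              "fbc:lowerFluxBound" = paste0("lb_", sid),
                              "fbc:upperFluxBound" = paste0("ub_", sid))
    notes <- xml2::xml_add_child(rx, "notes")
    body <- xml2::xml_add_child(notes, "body", xmlns = XHTML_NS)
    xml2::xml_add_child(body, "p", paste0("SUBSYSTEM: ", model$reactions$subsystem[j]))
    st <- model$stoichiometry[[rid]]
    subs <- st[st < 0]; prods <- st[st > 0]
    if (length(subs)) {
      lre <- xml2::xml_add_child(rx, "listOfReactants")
      for (m in names(subs))
        xml2::xml_add_child(lre, "speciesReference", species = encode_sid(m, "M_"),
                            stoichiometry = num(-subs[[m]]), constant = "true")
    }
    if (length(prods)) {
      lpr <- xml2::xml_add_child(rx, "listOfProducts")
      for (m in names(prods))
        xml2::xml_add_child(lpr, "speciesReference", species = encode_sid(m, "M_"),
                            stoichiometry = num(prods[[m]]), constant = "true")
    }
    rule <- parse_gpr(model$reactions$gpr[j])
    if (!is.null(rule$tree)) {
      gpa <- xml2::xml_add_child(rx, "fbc:geneProductAssociation")
      write_gpa_node(gpa, rule$tree)
    }
  }
  if (length(model$genes)) {
    logp <- xml2::xml_add_child(mdl, "fbc:listOfGeneProducts")
    for (g in model$genes)
      xml2::xml_add_child(logp, "fbc:geneProduct", "fbc:id" = encode_sid(g, "G_"),
                          "fbc:label" = g)
  }
  loo <- xml2::xml_add_child(mdl, "fbc:listOfObjectives", "fbc:activeObjective" = "obj")
  ob <- xml2::xml_add_child(loo, "fbc:objective", "fbc:id" = "obj", "fbc:type" = "maximize")
  lfo <- xml2::xml_add_child(ob, "fbc:listOfFluxObjectives")
  xml2::xml_add_child(lfo, "fbc:fluxObjective",
                      "fbc:reaction" = encode_sid(model$biomass_reaction_id, "R_"),
                      "fbc:coefficient" = "1")
  xml2::write_xml(doc, path)
  invisible(path)
}

write_gpa_node <- function(parent, node) {
  if (is.character(node)) {
    xml2::xml_add_child(parent, "fbc:geneProductRef",
                        "fbc:geneProduct" = encode_sid(node, "G_"))
    return(invisible(NULL))
  }
  el <- xml2::xml_add_child(parent, if (node$op == "and") "fbc:and" else "fbc:or")
  for (a in node$args) write_gpa_node(el, a)
  invisible(NULL)
}

#' Read a metabolic model from SBML Level 3 + FBC v2
#'
#' Inverse of [write_sbml()]: the write -> read round trip preserves ids,
#' stoichiometries, bounds, GPR semantics and subsystem labels. Files
#' produced by other FBC-compliant tools are readable as long as they use
#' flux-bound parameters and gene-product associations.
#'
#' @param path Path to the SBML file.
#' @param biomass_reaction_id Override for the biomass reaction; defaults
#'   to the active FBC objective.
#' @return A `metabolic_model`.
#' @export
read_sbml <- function(path) {
  doc <- tryCatch(xml2::read_xml(path), error = function(e)
    stop(sprintf("cannot parse SBML file %s: %s", path, conditionMessage(e)),
         call. = FALSE))
  ns <- c(s = SBML_NS, fbc = FBC_NS)
  mdl <- xml2::xml_find_first(doc, "./s:model", ns)
  if (inherits(mdl, "xml_missing"))
    stop(sprintf("%s: no <model> element in the SBML namespace", path), call. = FALSE)
  params <- xml2::xml_find_all(mdl, "./s:listOfParameters/s:parameter", ns)
  pvals <- stats::setNames(as.numeric(xml2::xml_attr(params, "value")),
                           xml2::xml_attr(params, "id"))
  sp <- xml2::xml_find_all(mdl, "./s:listOfSpecies/s:species", ns)
  mets <- data.frame(
    id = decode_sid(xml2::xml_attr(sp, "id"), "M_"),
    name = xml2::xml_attr(sp, "name"),
    compartment = decode_sid(xml2::xml_attr(sp, "compartment"), "C_"),
    formula = xml2::xml_attr(sp, "fbc:chemicalFormula", ns),
    charge = as.integer(xml2::xml_attr(sp, "fbc:charge", ns)),
    stringsAsFactors = FALSE)
  mets$name <- ifelse(is.na(mets$name), mets$id, mets$name)
  rx_nodes <- xml2::xml_find_all(mdl, "./s:listOfReactions/s:reaction", ns)
  rxns <- lapply(rx_nodes, function(rx) {
    sid <- xml2::xml_attr(rx, "id")
    rid <- decode_sid(sid, "R_")
    get_side <- function(xp, sign) {
      refs <- xml2::xml_find_all(rx, xp, ns)
      stats::setNames(sign * as.numeric(xml2::xml_attr(refs, "stoichiometry")),
                      decode_sid(xml2::xml_attr(refs, "species"), "M_"))
    }
    st_l <- get_side("./s:listOfReactants/s:speciesReference", -1)
    st_r <- get_side("./s:listOfProducts/s:speciesReference", 1)
    st <- numeric(0)
    for (m in names(st_l)) st[m] <- (if (m %in% names(st)) st[[m]] else 0) + st_l[[m]]
    for (m in names(st_r)) st[m] <- (if (m %in% names(st)) st[[m]] else 0) + st_r[[m]]
    lb_ref <- xml2::xml_attr(rx, "fbc:lowerFluxBound", ns)
    ub_ref <- xml2::xml_attr(rx, "fbc:upperFluxBound", ns)
    lb <- if (!is.na(lb_ref) && lb_ref %in% names(pvals)) pvals[[lb_ref]] else
      if (identical(xml2::xml_attr(rx, "reversible"), "true")) -1000 else 0
    ub <- if (!is.na(ub_ref) && ub_ref %in% names(pvals)) pvals[[ub_ref]] else 1000
    note <- xml2::xml_text(xml2::xml_find_first(
      rx, ".//*[starts-with(text(), 'SUBSYSTEM')]"))
    subsystem <- if (is.na(note)) "other" else trimws(sub("^SUBSYSTEM:\\s*", "", note))
    gpa <- xml2::xml_find_first(rx, "./fbc:geneProductAssociation", ns)
    gpr <- if (inherits(gpa, "xml_missing")) "" else read_gpa_node(xml2::xml_child(gpa), ns)
    rname <- xml2::xml_attr(rx, "name")
    reaction(rid, st, name = if (is.na(rname)) rid else rname,
             lower_bound = lb, upper_bound = ub, gpr = gpr, subsystem = subsystem)
  })
  obj_rxn <- xml2::xml_find_first(
    mdl, "./fbc:listOfObjectives/fbc:objective/fbc:listOfFluxObjectives/fbc:fluxObjective", ns)
  if (inherits(obj_rxn, "xml_missing"))
    stop(sprintf("%s: no active FBC objective; cannot identify the biomass reaction", path),
         call. = FALSE)
  biomass_id <- decode_sid(xml2::xml_attr(obj_rxn, "fbc:reaction", ns), "R_")
  eps_note <- xml2::xml_text(xml2::xml_find_first(
    mdl, "./s:notes//*[starts-with(text(), 'EPS_REACTION')]", ns))
  eps_id <- if (is.na(eps_note)) NULL else trimws(sub("^EPS_REACTION:\\s*", "", eps_note))
  gp <- xml2::xml_find_all(mdl, "./fbc:listOfGeneProducts/fbc:geneProduct", ns)
  genes <- if (length(gp)) decode_sid(xml2::xml_attr(gp, "fbc:id", ns), "G_") else NULL
  metabolic_model(mets, rxns, biomass_reaction_id = biomass_id,
                  eps_reaction_id = eps_id, genes = genes,
                  id = { mid <- xml2::xml_attr(mdl, "id"); if (is.na(mid)) "model" else decode_sid(mid, "") })
}

read_gpa_node <- function(node, ns) {
  nm <- xml2::xml_name(node)
  if (nm == "geneProductRef") {
    return(decode_sid(xml2::xml_attr(node, "fbc:geneProduct", ns), "G_"))
  }
  parts <- vapply(xml2::xml_children(node), function(ch) {
    s <- read_gpa_node(ch, ns)
    if (xml2::xml_name(ch) %in% c("and", "or")) paste0("(", s, ")") else s
  }, character(1))
  paste(parts, collapse = if (nm == "and") " and " else " or ")
}
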