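# SBML export/import for instantiated flux networks. Level 3 Version 1 core
# with flux bounds carried as SBML parameters referenced by reaction
# annotations in the flux-balance style (one species per compartmentalized
# metabolite; exchange reactions marked as boundary reactions).

sanitize_sbml_id <- function(ids) {
  vapply(ids, function(id) {
    chars <- strsplit(id, "")[[1]]
    ok <- grepl("[A-Za-z0-9_]", chars)
    out <- paste(ifelse(ok, chars,
                        sprintf("_x%02X_", vapply(chars, utf8ToInt, integer(1)))),
                 collapse = "")
    if (grepl("^[0-9]", out)) out <- paste0("_", out)
    out
  }, character(1), USE.NAMES = FALSE)
}

unsanitize_sbml_id <- function(ids) {
  vapply(ids, function(id) {
    id <- sub("^_(?=[0-9])", "", id, perl = TRUE)
    while (grepl("_x[0-9A-F]{2}_", id)) {
      m <- regmatches(id, regexpr("_x[0-9A-F]{2}_", id))
      ch <- intToUtf8(strtoi(substr(m, 3, 4), 16L))
      id <- sub(m, ch, id, fixed = TRUE)
    }
    id
  }, character(1), USE.NAMES = FALSE)
}

#' Export a flux network to SBML
#'
#' Writes one species per compartmentalized metabolite and one reaction per
#' network reaction, with flux bounds as global parameters referenced from
#' each reaction; exchange reactions are written as boundary reactions
#' (their exchanged species flagged `boundaryCondition` on the opposite
#' side). Ids containing characters outside the SBML identifier alphabet
#' are deterministically escaped (`_xHH_`), and the escaping is reversible,
#' so a re-import recovers the original stoichiometric system.
#'
#' @param network A `flux_network`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
export_sbml <- function(network, path) {
  stopifnot(inherits(network, "flux_network"))
  doc <- xml2::xml_new_root(
    "sbml", xmlns = "http://www.sbml.org/sbml/level3/version1/core",
    level = "3", version = "1")
  model <- xml2::xml_add_child(doc, "model", id = "flux_network")
  cmp <- xml2::xml_add_child(model, "listOfCompartments")
  for (cc in unique(network$metabolites$compartment)) {
    xml2::xml_add_child(cmp, "compartment", id = cc, constant = "true")
  }
  sp <- xml2::xml_add_child(model, "listOfSpecies")
  for (i in seq_len(nrow(network$metabolites))) {
    m <- network$metabolites[i, ]
    xml2::xml_add_child(sp, "species", id = sanitize_sbml_id(m$id),
                        name = m$id, compartment = m$compartment,
                        hasOnlySubstanceUnits = "false",
                        boundaryCondition = "false", constant = "false")
  }
  par <- xml2::xml_add_child(model, "listOfParameters")
  rl <- xml2::xml_add_child(model, "listOfReactions")
  for (i in seq_len(nrow(network$reactions))) {
    r <- network$reactions[i, ]
    rid <- sanitize_sbml_id(r$id)
    lb <- if (is.finite(r$lb)) r$lb else -network$default_bound
    ub <- if (is.finite(r$ub)) r$ub else network$default_bound
    xml2::xml_add_child(par, "parameter", id = paste0(rid, "_lb"),
                        value = format(lb, digits = 12), constant = "true")
    xml2::xml_add_child(par, "parameter", id = paste0(rid, "_ub"),
                        value = format(ub, digits = 12), constant = "true")
    rx <- xml2::xml_add_child(rl, "reaction", id = rid, name = r$id,
                              reversible = if (r$lb < 0) "true" else "false",
                              fast = "false")
    xml2::xml_set_attr(rx, "sboTerm",
                       if (r$kind == "internal") "SBO:0000176" else "SBO:0000627")
    st <- network$stoich[network$stoich$reaction_id == r$id, ]
    reac <- st[st$coef < 0, ]; prod <- st[st$coef > 0, ]
    if (nrow(reac)) {
      lr <- xml2::xml_add_child(rx, "listOfReactants")
      for (j in seq_len(nrow(reac))) {
        xml2::xml_add_child(lr, "speciesReference",
                            species = sanitize_sbml_id(reac$metabolite_id[j]),
                            stoichiometry = format(-reac$coef[j], digits = 12),
                            constant = "true")
      }
    }
    if (nrow(prod)) {
      lp <- xml2::xml_add_child(rx, "listOfProducts")
      for (j in seq_len(nrow(prod))) {
        xml2::xml_add_child(lp, "speciesReference",
                            species = sanitize_sbml_id(prod$metabolite_id[j]),
                            stoichiometry = format(prod$coef[j], digits = 12),
                            constant = "true")
      }
    }
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Import a stoichiometric system from SBML
#'
#' Generic reader recovering what [export_sbml()] wrote (and any plain SBML
#' L3 core document): species, reactions, signed stoichiometry, and flux
#' bounds when present as `<id>_lb` / `<id>_ub` parameters.
#'
#' @param path SBML file.
#' @return List with `metabolites`, `reactions` (with `lb`, `ub`), and
#'   `stoich` tibbles, ids unescaped.
#' @export
read_sbml_network <- function(path) {
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  species <- xml2::xml_find_all(doc, ".//listOfSpecies/species")
  mets <- tibble::tibble(
    id = unsanitize_sbml_id(xml2::xml_attr(species, "id")),
    compartment = xml2::xml_attr(species, "compartment"))
  pars <- xml2::xml_find_all(doc, ".//listOfParameters/parameter")
  pv <- stats::setNames(as.numeric(xml2::xml_attr(pars, "value")),
                        xml2::xml_attr(pars, "id"))
  rx_nodes <- xml2::xml_find_all(doc, ".//listOfReactions/reaction")
  rows <- list(); rxs <- list()
  for (rx in rx_nodes) {
    rid_s <- xml2::xml_attr(rx, "id")
    rid <- unsanitize_sbml_id(rid_s)
    lb <- unname(pv[paste0(rid_s, "_lb")])
    ub <- unname(pv[paste0(rid_s, "_ub")])
    rxs[[length(rxs) + 1L]] <- tibble::tibble(
      id = rid, lb = if (is.na(lb)) -Inf else lb,
      ub = if (is.na(ub)) Inf else ub)
    for (node in xml2::xml_find_all(rx, "./listOfReactants/speciesReference")) {
      rows[[length(rows) + 1L]] <- tibble::tibble(
        reaction_id = rid,
        metabolite_id = unsanitize_sbml_id(xml2::xml_attr(node, "species")),
        coef = -as.numeric(xml2::xml_attr(node, "stoichiometry")))
    }
    for (node in xml2::xml_find_all(rx, "./listOfProducts/speciesReference")) {
      rows[[length(rows) + 1L]] <- tibble::tibble(
        reaction_id = rid,
        metabolite_id = unsanitize_sbml_id(xml2::xml_attr(node, "species")),
        coef = as.numeric(xml2::xml_attr(node, "stoichiometry")))
    }
  }
  list(metabolites = mets, reactions = dplyr::bind_rows(rxs),
       stoich = dplyr::bind_rows(rows))
}
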