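# Toy models built in code for the unit tests.

met_row <- function(id, formula, charge = 0L, is_class = FALSE,
                    instances = character()) {
  tibble::tibble(id = id, name = sub("\\[.\\]$", "", id), formula = formula,
                 charge = as.integer(charge),
                 compartment = ifelse(grepl("\\[p\\]$", id), "p", "c"),
                 is_class = is_class, instances = list(instances))
}

# A -> B -> C chain with an ATP-hydrolysis-style reaction for balance tests.
toy_chain_model <- function() {
  mets <- dplyr::bind_rows(
    met_row("A[c]", "CH4"), met_row("B[c]", "CH2"), met_row("C[c]", "CH2"),
    met_row("nofor[c]", NA_character_, charge = NA))
  rxn <- tibble::tibble(
    id = c("R_AB", "R_BC", "R_UNK"),
    direction = c("forward", "forward", "forward"))
  st <- tibble::tibble(
    reaction_id = c("R_AB", "R_AB", "R_BC", "R_BC", "R_UNK", "R_UNK"),
    metabolite_id = c("A[c]", "B[c]", "B[c]", "C[c]", "B[c]", "nofor[c]"),
    coef = c(-1, 1, -1, 1, -1, 1))
  flux_model(mets, rxn, st)
}

# Gene-association patterns: a two-subunit complex whose reaction is lost on
# either subunit knockout (the aspartate-transcarbamylase regulatory-subunit
# situation), a redundant complex-plus-single-activities association where
# knocking out the complex-only member is ineffective, and a substrate
# supplied by a carrier protein with and without an alternative supplier.
toy_gpr_model <- function() {
  mets <- dplyr::bind_rows(met_row("S[c]", "C2"), met_row("P[c]", "C2"),
                           met_row("Q[c]", "C2"), met_row("T[c]", "C2"))
  rxn <- tibble::tibble(
    id = c("R_COMPLEX", "R_REDUNDANT", "R_CARRIER", "R_CARRIER2"),
    direction = "forward")
  st <- tibble::tibble(
    reaction_id = rep(rxn$id, each = 2),
    metabolite_id = rep(c("S[c]", "P[c]"), 4),
    coef = rep(c(-1, 1), 4))
  gpr <- dplyr::bind_rows(
    tibble::tibble(reaction_id = "R_COMPLEX", unit = 1L,
                   gene = c("pyrB", "pyrI")),
    tibble::tibble(reaction_id = "R_REDUNDANT", unit = 1L,
                   gene = c("entD", "entE", "entF", "entG")),
    tibble::tibble(reaction_id = "R_REDUNDANT", unit = 2L, gene = "entE"),
    tibble::tibble(reaction_id = "R_REDUNDANT", unit = 3L, gene = "entF"),
    tibble::tibble(reaction_id = "R_REDUNDANT", unit = 4L, gene = "entG"),
    tibble::tibble(reaction_id = "R_CARRIER", unit = 1L, gene = "enz1"),
    tibble::tibble(reaction_id = "R_CARRIER2", unit = 1L, gene = "enz2"))
  suppliers <- tibble::tibble(
    reaction_id = c("R_CARRIER", "R_CARRIER2", "R_CARRIER2"),
    substrate = c("S[c]", "S[c]", "S[c]"),
    gene = c("acpP", "acpP", "acpQ"))
  flux_model(mets, rxn, st, gpr = gpr, suppliers = suppliers)
}

# Class-instantiation toy: a generic alcohol oxidized to a generic aldehyde;
# only the carbon-number-matched bindings are mass-balanced.
toy_class_model <- function() {
  mets <- dplyr::bind_rows(
    met_row("etoh[c]", "C2H6O"), met_row("prop_ol[c]", "C3H8O"),
    met_row("acald[c]", "C2H4O"), met_row("propanal[c]", "C3H6O"),
    met_row("nad[c]", "C21H26N7O14P2", -1L),
    met_row("nadh[c]", "C21H27N7O14P2", -2L),
    met_row("h[c]", "H", 1L),
    met_row("ALCOHOL[c]", NA_character_, charge = NA, is_class = TRUE,
            instances = c("etoh[c]", "prop_ol[c]")),
    met_row("ALDEHYDE[c]", NA_character_, charge = NA, is_class = TRUE,
            instances = c("acald[c]", "propanal[c]")))
  rxn <- tibble::tibble(id = "R_OXID", direction = "forward")
  st <- tibble::tibble(
    reaction_id = "R_OXID",
    metabolite_id = c("ALCOHOL[c]", "nad[c]", "ALDEHYDE[c]", "nadh[c]", "h[c]"),
    coef = c(-1, -1, 1, 1, 1))
  flux_model(mets, rxn, st)
}

# Independent element counter used as the enumeration oracle for
# instantiation tests (kept separate from the package's parser on purpose).
oracle_count_elements <- function(formula) {
  if (is.na(formula)) return(NULL)
  out <- integer()
  for (tok in regmatches(formula,
                         gregexpr("[A-Z][a-z]?[0-9]*", formula))[[1]]) {
    el <- gsub("[0-9]", "", tok)
    n <- suppressWarnings(as.integer(gsub("[^0-9]", "", tok)))
    if (is.na(n)) n <- 1L
    out[el] <- (if (el %in% names(out)) out[[el]] else 0L) + n
  }
  out
}

# Fermentation fixture augmented with synthetic stand-ins for protoheme and
# pyridoxal 5'-phosphate (isomer formulas of existing intermediates, so the
# one-step synthesis reactions stay balanced); used by the anaerobic
# modification tests.
growth_network_with_anaerobic_members <- function() {
  m <- fixture_fermentation()
  m$metabolites <- dplyr::bind_rows(
    m$metabolites,
    tibble::tibble(id = c("pheme[c]", "pydx5p[c]"),
                   name = c("protoheme (synthetic stand-in)",
                            "pyridoxal 5'-phosphate (synthetic stand-in)"),
                   formula = c("C5H4O5", "C3H4O7P"),
                   charge = c(-2L, -3L), compartment = "c",
                   is_class = FALSE, instances = list(character(), character())))
  m$reactions <- dplyr::bind_rows(
    m$reactions,
    tibble::tibble(id = c("PHEME-SYNTH", "PYDX5P-SYNTH"),
                   direction = "forward", relevant = TRUE, spontaneous = FALSE,
                   flags = list(character(), character())))
  m$stoich <- dplyr::bind_rows(
    m$stoich,
    tibble::tibble(reaction_id = c("PHEME-SYNTH", "PHEME-SYNTH",
                                   "PYDX5P-SYNTH", "PYDX5P-SYNTH"),
                   metabolite_id = c("akg[c]", "pheme[c]", "3pg[c]", "pydx5p[c]"),
                   coef = c(-1, 1, -1, 1)))
  net <- build_network(m, nutrients = growth_nutrients(),
                       secretions = fermentation_secretions())
  net <- set_bounds(net, "FHL-RXN", ub = 0)
  bm <- fixture_biomass()
  bm$members <- dplyr::bind_rows(
    bm$members,
    tibble::tibble(metabolite_id = c("pheme[c]", "pydx5p[c]"),
                   coef = c(0.01, 0.005)))
  set_biomass(net, bm)
}
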