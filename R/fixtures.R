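# Deterministic fixture networks: desk-scale, fully mass- and charge-balanced
# models of E. coli aerobic core energy metabolism and mixed-acid
# fermentation, plus two toy networks used to pin down solver behavior.

fixture_formulas <- function() {
  tibble::tribble(
    ~id,          ~formula,             ~charge,
    "glc__D[p]",  "C6H12O6",             0L,
    "g6p[c]",     "C6H11O9P",           -2L,
    "f6p[c]",     "C6H11O9P",           -2L,
    "dha[c]",     "C3H6O3",              0L,
    "dhap[c]",    "C3H5O6P",            -2L,
    "g3p[c]",     "C3H5O6P",            -2L,
    "13dpg[c]",   "C3H4O10P2",          -4L,
    "3pg[c]",     "C3H4O7P",            -3L,
    "2pg[c]",     "C3H4O7P",            -3L,
    "pep[c]",     "C3H2O6P",            -3L,
    "pyr[c]",     "C3H3O3",             -1L,
    "accoa[c]",   "C23H34N7O17P3S",     -4L,
    "coa[c]",     "C21H32N7O16P3S",     -4L,
    "cit[c]",     "C6H5O7",             -3L,
    "icit[c]",    "C6H5O7",             -3L,
    "akg[c]",     "C5H4O5",             -2L,
    "succoa[c]",  "C25H35N7O19P3S",     -5L,
    "succ[c]",    "C4H4O4",             -2L,
    "fum[c]",     "C4H2O4",             -2L,
    "mal__L[c]",  "C4H4O5",             -2L,
    "oaa[c]",     "C4H2O5",             -2L,
    "nad[c]",     "C21H26N7O14P2",      -1L,
    "nadh[c]",    "C21H27N7O14P2",      -2L,
    "nadp[c]",    "C21H25N7O17P3",      -3L,
    "nadph[c]",   "C21H26N7O17P3",      -4L,
    "q8[c]",      "C49H74O4",            0L,
    "q8h2[c]",    "C49H76O4",            0L,
    "atp[c]",     "C10H12N5O13P3",      -4L,
    "adp[c]",     "C10H12N5O10P2",      -3L,
    "pi[c]",      "HO4P",               -2L,
    "h2o[c]",     "H2O",                 0L,
    "h[c]",       "H",                   1L,
    "h[p]",       "H",                   1L,
    "co2[c]",     "CO2",                 0L,
    "o2[c]",      "O2",                  0L,
    "for[c]",     "CHO2",               -1L,
    "actp[c]",    "C2H3O5P",            -2L,
    "ac[c]",      "C2H3O2",             -1L,
    "acald[c]",   "C2H4O",               0L,
    "etoh[c]",    "C2H6O",               0L,
    "lac__D[c]",  "C3H5O3",             -1L,
    "h2[c]",      "H2",                  0L,
    "pyr[p]",     "C3H3O3",             -1L,
    "succ[p]",    "C4H4O4",             -2L,
    "fdp[c]",     "C6H10O12P2",         -4L
  )
}

fixture_met_table <- function(ids) {
  f <- fixture_formulas()
  f <- f[match(ids, f$id), ]
  tibble::tibble(id = f$id, name = sub("\\[.\\]$", "", f$id),
                 formula = f$formula, charge = f$charge,
                 compartment = met_compartment(f$id))
}

# equation strings in the model grammar; gpr as "a and b or c" unit syntax
core_energy_reactions <- function(convention) {
  p <- proton_conventions(convention)
  ndh_cin <- p$nadh_h + 1                 # charge moved + 1 chemical proton
  tribble_rxn <- tibble::tribble(
    ~id, ~equation, ~gpr,
    "GLUCOSE-PTS",
    "glc__D[p] + pep[c] -> g6p[c] + pyr[c]", "ptsI and ptsH and crr",
    "PGLUCISOM-RXN", "g6p[c] <-> f6p[c]", "pgi",
    "RXN0-313", "f6p[c] -> dha[c] + g3p[c]", "fsaA or fsaB",
    "2.7.1.121-RXN", "dha[c] + pep[c] -> dhap[c] + pyr[c]", "dhaK and dhaL and dhaM",
    "TRIOSEPISOMERIZATION-RXN", "dhap[c] <-> g3p[c]", "tpiA",
    "GAPOXNPHOSPHN-RXN",
    "g3p[c] + nad[c] + pi[c] <-> 13dpg[c] + nadh[c] + h[c]", "gapA",
    "PHOSGLYPHOS-RXN", "13dpg[c] + adp[c] -> 3pg[c] + atp[c]", "pgk",
    "3PGAREARR-RXN", "3pg[c] <-> 2pg[c]", "gpmA or gpmM",
    "2PGADEHYDRAT-RXN", "2pg[c] <-> pep[c] + h2o[c]", "eno",
    "PYRUVDEH-RXN",
    "pyr[c] + coa[c] + nad[c] -> accoa[c] + co2[c] + nadh[c]",
    "aceE and aceF and lpd",
    "CITSYN-RXN",
    "accoa[c] + oaa[c] + h2o[c] -> cit[c] + coa[c] + h[c]", "gltA",
    "ACONITATEDEHYDR-RXN", "cit[c] <-> icit[c]", "acnA or acnB",
    "ISOCITDEH-RXN",
    "icit[c] + nadp[c] -> akg[c] + co2[c] + nadph[c]", "icd",
    "2OXOGLUTARATEDEH-RXN",
    "akg[c] + coa[c] + nad[c] -> succoa[c] + co2[c] + nadh[c]",
    "sucA and sucB and lpd",
    "SUCCOASYN-RXN",
    "succoa[c] + adp[c] + pi[c] -> succ[c] + atp[c] + coa[c]", "sucC and sucD",
    "SUCCINATE-DEHYDROGENASE",
    "succ[c] + q8[c] -> fum[c] + q8h2[c]", "sdhA and sdhB and sdhC and sdhD",
    "FUMHYDR-RXN", "fum[c] + h2o[c] <-> mal__L[c]", "fumA or fumB or fumC",
    "MALATE-DEH-RXN",
    "mal__L[c] + nad[c] <-> oaa[c] + nadh[c] + h[c]", "mdh",
    "PYRNUTRANSHYDROGEN-RXN",
    "nadph[c] + nad[c] -> nadp[c] + nadh[c]", "sthA",
    "NADH-DEHYDROG-A-RXN",
    sprintf("nadh[c] + q8[c] + %d h[c] -> nad[c] + q8h2[c] + %d h[p]",
            ndh_cin, p$nadh_h), "nuoA and nuoB",
    "CYTOCHROME-BO-OXIDASE",
    if (p$o2_convention == "whole") {
      sprintf("2 q8h2[c] + o2[c] + %d h[c] -> 2 q8[c] + 2 h2o[c] + %d h[p]",
              p$ox_h, p$ox_h)
    } else {
      sprintf("q8h2[c] + 0.5 o2[c] + %d h[c] -> q8[c] + h2o[c] + %d h[p]",
              p$ox_h, p$ox_h)
    }, "cyoA and cyoB",
    "ATP-SYNTHASE",
    sprintf("adp[c] + pi[c] + %d h[p] -> atp[c] + h2o[c] + %d h[c]",
            p$syn_h, p$syn_h - 1), "atpA and atpD",
    "ATPM", "atp[c] + h2o[c] -> adp[c] + pi[c] + h[c]", NA_character_
  )
  tribble_rxn
}

proton_conventions <- function(convention = c("ecocyc", "ijo")) {
  convention <- match.arg(convention)
  # frozen output of derive_proton_coefficients() for each convention
  if (convention == "ecocyc") {
    list(nadh_h = 4L, o2_convention = "whole", ox_h = 8L, syn_h = 5L)
  } else {
    list(nadh_h = 3L, o2_convention = "half", ox_h = 4L, syn_h = 4L)
  }
}

#' Derive electron-transport proton coefficients from a reference flux vector
#'
#' The NADH-dehydrogenase translocation stoichiometry and the oxidase O2
#' convention are fixed by the convention in use, but the oxidase proton
#' pumping and ATP-synthase H+/ATP coefficients are not printed anywhere.
#' Total proton conservation across both membranes at the reference
#' ATP-maximization optimum reduces to one linear Diophantine relation
#' `synthase_flux * h_syn - oxidase_flux * h_ox = nadh_h * nadh_flux`,
#' whose smallest positive-integer solution is the unique physically sensible
#' choice. This function enumerates it.
#'
#' @param nadh_h Protons released to the periplasm per NADH oxidized (4 under
#'   the 4 H+/2e- convention, 3 under 3 H+/2e-).
#' @param oxidase_flux,synthase_flux,nadh_flux Reference fluxes of the
#'   oxidase, ATP synthase, and NADH dehydrogenase at the ATP-maximization
#'   optimum (mmol/gCDW/hr).
#' @param max_h Search bound for the coefficients (default 20).
#' @return Named integer vector `c(oxidase = ..., synthase = ...)`: protons
#'   pumped per unit oxidase flux and consumed per ATP synthesized.
#' @examples
#' derive_proton_coefficients(4, 60, 176, 100)    # whole-O2 convention
#' derive_proton_coefficients(3, 120, 195, 100)   # half-O2 convention
#' @export
derive_proton_coefficients <- function(nadh_h, oxidase_flux, synthase_flux,
                                       nadh_flux = 100, max_h = 20) {
  need <- nadh_h * nadh_flux
  for (h_syn in seq_len(max_h)) {
    for (h_ox in seq_len(max_h)) {
      if (synthase_flux * h_syn - oxidase_flux * h_ox == need) {
        return(c(oxidase = h_ox, synthase = h_syn))
      }
    }
  }
  stop("no integral proton stoichiometry solves the steady-state balance",
       call. = FALSE)
}

fermentation_reactions <- function() {
  tibble::tribble(
    ~id, ~equation, ~gpr,
    # classical lower glycolysis: the aldol-cleavage branch of the core
    # network consumes its second PEP in the dihydroxyacetone PTS, so a
    # growth network needs phosphofructokinase, aldolase and pyruvate
    # kinase to spare PEP for biomass precursors
    "6PFRUCTPHOS-RXN",
    "f6p[c] + atp[c] -> fdp[c] + adp[c] + h[c]", "pfkA or pfkB",
    "F16ALDOLASE-RXN", "fdp[c] <-> dhap[c] + g3p[c]", "fbaA",
    "PEPDEPHOS-RXN", "pep[c] + adp[c] + h[c] -> pyr[c] + atp[c]",
    "pykF or pykA",
    "PYRUVFORMLY-RXN",
    "pyr[c] + coa[c] -> accoa[c] + for[c]", "pflB",
    "PHOSACETYLTRANS-RXN",
    "accoa[c] + pi[c] <-> actp[c] + coa[c]", "pta",
    "ACETATEKIN-RXN", "actp[c] + adp[c] <-> ac[c] + atp[c]", "ackA",
    "ACETALD-DEHYDROG-RXN",
    "accoa[c] + nadh[c] + h[c] <-> acald[c] + coa[c] + nad[c]", "adhE",
    "ALCOHOL-DEHYDROG-RXN",
    "acald[c] + nadh[c] + h[c] -> etoh[c] + nad[c]", "adhE",
    "D-LACTATE-DEHYDROGENASE-RXN",
    "pyr[c] + nadh[c] + h[c] -> lac__D[c] + nad[c]", "ldhA",
    "PEPCARBOX-RXN",
    "pep[c] + co2[c] + h2o[c] -> oaa[c] + pi[c] + h[c]", "ppc",
    "FUMARATE-REDUCTASE-RXN",
    "fum[c] + q8h2[c] -> succ[c] + q8[c]", "frdA and frdB",
    "FHL-RXN", "for[c] + h[c] -> co2[c] + h2[c]", "fdhF and hycE",
    "PYR-TRANSPORT", "pyr[p] + h[p] -> pyr[c] + h[c]", "btsT",
    "SUCC-TRANSPORT", "succ[p] + 2 h[p] -> succ[c] + 2 h[c]", "dctA"
  )
}

fixture_from_tables <- function(rxn_tbl) {
  parsed <- lapply(rxn_tbl$equation, parse_reaction_equation)
  st <- dplyr::bind_rows(lapply(seq_along(parsed), function(i) {
    tibble::tibble(reaction_id = rxn_tbl$id[i],
                   metabolite_id = parsed[[i]]$stoich$metabolite_id,
                   coef = parsed[[i]]$stoich$coef)
  }))
  reactions <- tibble::tibble(
    id = rxn_tbl$id,
    direction = vapply(parsed, `[[`, character(1), "direction"),
    relevant = TRUE,
    spontaneous = is.na(rxn_tbl$gpr),
    flags = rep(list(character()), nrow(rxn_tbl))
  )
  gpr <- parse_gpr_strings(rxn_tbl$id, rxn_tbl$gpr)
  mets <- fixture_met_table(sort(unique(st$metabolite_id)))
  flux_model(mets, reactions, st, gpr = gpr)
}

#' Aerobic core energy network fixture
#'
#' A fully balanced desk-scale model of glucose catabolism to CO2: PTS
#' uptake, glycolysis through the fructose-6-phosphate aldolase /
#' dihydroxyacetone-PTS branch, pyruvate dehydrogenase, the full TCA cycle,
#' transhydrogenase, and an electron transport chain (NADH dehydrogenase and
#' succinate dehydrogenase feeding a cytochrome bo oxidase) coupled to ATP
#' synthase, with ATP hydrolysis (`ATPM`) as the standing objective reaction.
#' Under `"ecocyc"` conventions the NADH dehydrogenase translocates
#' 4 H+/2e- and the oxidase is written per whole O2; under `"ijo"` it
#' translocates 3 H+/2e- and the oxidase is written per half O2. Oxidase and
#' synthase proton coefficients are the frozen output of
#' [derive_proton_coefficients()].
#'
#' @param convention `"ecocyc"` or `"ijo"`.
#' @return A `flux_model`.
#' @export
fixture_core_energy <- function(convention = c("ecocyc", "ijo")) {
  convention <- match.arg(convention)
  fixture_from_tables(core_energy_reactions(convention))
}

#' Mixed-acid fermentation network fixture
#'
#' The core energy network extended with pyruvate-formate lyase,
#' phosphotransacetylase / acetate kinase, acetaldehyde and alcohol
#' dehydrogenases, D-lactate dehydrogenase, PEP carboxylase with fumarate
#' reductase (the reductive succinate branch), formate-hydrogen lyase
#' (present in the model; disabled by default at network level), and
#' periplasmic pyruvate and succinate transporters.
#'
#' @inheritParams fixture_core_energy
#' @return A `flux_model`.
#' @export
fixture_fermentation <- function(convention = "ecocyc") {
  fixture_from_tables(dplyr::bind_rows(core_energy_reactions(convention),
                                       fermentation_reactions()))
}

#' Standard nutrient and secretion sets for the energy fixtures
#'
#' Glucose is supplied in the periplasm at the stated bound; O2 directly in
#' the cytosol (unconstrained by default); fermentation products, CO2, water
#' and periplasmic protons are freely secreted.
#'
#' @param glucose Glucose uptake bound, mmol/gCDW/hr (default 10).
#' @param o2 O2 uptake bound (`NA` = unconstrained).
#' @return A `metabolite_set`.
#' @export
core_energy_nutrients <- function(glucose = 10, o2 = NA_real_) {
  metabolite_set(c("glc__D[p]", "o2[c]", "h2o[c]"),
                 coef = c(glucose, o2, NA_real_),
                 role = c("C", NA, NA))
}

#' @rdname core_energy_nutrients
#' @export
growth_nutrients <- function(glucose = 10, o2 = NA_real_) {
  # biomass members carry phosphorus out of the system, so growth media
  # must supply phosphate (cytosol-supplied in this desk-scale network,
  # which carries no phosphate transporter)
  metabolite_set(c("glc__D[p]", "o2[c]", "h2o[c]", "pi[c]"),
                 coef = c(glucose, o2, NA_real_, NA_real_),
                 role = c("C", NA, NA, "P"))
}

#' @rdname core_energy_nutrients
#' @export
core_energy_secretions <- function() {
  metabolite_set(c("co2[c]", "h2o[c]", "h[c]", "h[p]"))
}

#' @rdname core_energy_nutrients
#' @export
fermentation_secretions <- function() {
  metabolite_set(c("co2[c]", "h2o[c]", "h[c]", "h[p]", "ac[c]", "for[c]",
                   "etoh[c]", "lac__D[c]", "succ[c]", "h2[c]"))
}

#' Ready-to-solve fixture networks
#'
#' Convenience wrappers: build the fixture model, attach the standard
#' exchanges, and set the ATP-hydrolysis objective (and, for the
#' fermentation network, disable formate-hydrogen lyase unless requested).
#'
#' @inheritParams fixture_core_energy
#' @inheritParams core_energy_nutrients
#' @param fhl Enable formate-hydrogen lyase (default `FALSE`).
#' @return A `flux_network` with objective `ATPM`.
#' @export
fixture_core_energy_network <- function(convention = "ecocyc", glucose = 10,
                                        o2 = NA_real_) {
  net <- build_network(fixture_core_energy(convention),
                       nutrients = core_energy_nutrients(glucose, o2),
                       secretions = core_energy_secretions())
  set_objective(net, "ATPM")
}

#' @rdname fixture_core_energy_network
#' @export
fixture_fermentation_network <- function(convention = "ecocyc", glucose = 10,
                                         o2 = 0, fhl = FALSE) {
  net <- build_network(fixture_fermentation(convention),
                       nutrients = core_energy_nutrients(glucose, o2),
                       secretions = fermentation_secretions())
  if (!fhl) net <- set_bounds(net, "FHL-RXN", ub = 0)
  set_objective(net, "ATPM")
}

#' Miniature core biomass set for the fixture networks
#'
#' Eight glycolytic and TCA-cycle precursors drained at coefficients of
#' realistic magnitude (mmol/gCDW). Deliberately small: it creates a rich
#' essentiality structure on the fermentation fixture (unique routes,
#' isozyme pairs, complexes) without requiring the full biosynthetic
#' machinery of a genome-scale biomass set.
#'
#' @param gam,ngam Maintenance parameters passed to [biomass_objective()].
#' @param variant Biomass variant label.
#' @return A `biomass_objective`.
#' @export
fixture_biomass <- function(gam = 53.95, ngam = 3.15, variant = "core") {
  members <- metabolite_set(
    c("g6p[c]", "f6p[c]", "g3p[c]", "3pg[c]", "pep[c]", "pyr[c]",
      "oaa[c]", "akg[c]"),
    coef = c(0.205, 0.071, 0.129, 1.496, 0.704, 2.831, 1.787, 1.078))
  biomass_objective(members, gam = gam, ngam = ngam, variant = variant)
}

#' Growth-configured fermentation fixture network
#'
#' Fermentation network with the miniature biomass attached (objective
#' `BIOMASS`), aerobic by default.
#'
#' @inheritParams fixture_fermentation_network
#' @inheritParams fixture_biomass
#' @return A `flux_network` with a biomass objective.
#' @export
fixture_growth_network <- function(glucose = 10, o2 = NA_real_, fhl = FALSE,
                                   gam = 53.95, ngam = 3.15) {
  net <- build_network(fixture_fermentation(),
                       nutrients = growth_nutrients(glucose, o2),
                       secretions = fermentation_secretions())
  if (!fhl) net <- set_bounds(net, "FHL-RXN", ub = 0)
  set_biomass(net, fixture_biomass(gam = gam, ngam = ngam))
}

#' Toy diamond network with two alternate routes
#'
#' One source metabolite, one sink, and two internal routes of equal yield
#' but different length (two reactions versus three). Used to pin down the
#' taxicab stage: both routes achieve the same stage-1 optimum, and flux
#' minimization must select the shorter one.
#'
#' @return A `flux_network` with objective `SECRETION[D[c]]`, uptake bound 1.
#' @export
fixture_diamond <- function() {
  mets <- tibble::tibble(
    id = c("A[c]", "B[c]", "D[c]", "E[c]", "F[c]"),
    name = c("A", "B", "D", "E", "F"),
    formula = "C", charge = 0L, compartment = "c")
  rxn <- tibble::tibble(
    id = c("R_AB", "R_BD", "R_AE", "R_EF", "R_FD"),
    direction = "forward")
  st <- tibble::tibble(
    reaction_id = c("R_AB", "R_AB", "R_BD", "R_BD", "R_AE", "R_AE",
                    "R_EF", "R_EF", "R_FD", "R_FD"),
    metabolite_id = c("A[c]", "B[c]", "B[c]", "D[c]", "A[c]", "E[c]",
                      "E[c]", "F[c]", "F[c]", "D[c]"),
    coef = rep(c(-1, 1), 5))
  m <- flux_model(mets, rxn, st)
  net <- build_network(m, nutrients = metabolite_set("A[c]", coef = 1),
                       secretions = metabolite_set("D[c]"))
  set_objective(net, "SECRETION[D[c]]")
}

#' Toy model with a biomass member blocked by an unbalanced reaction
#'
#' Nutrient A converts to B by a balanced reaction; the only route from B to
#' C is deliberately mass-unbalanced, so network construction filters it out
#' and C becomes unproducible. Restoring the balance makes C producible
#' again.
#'
#' @param fixed Repair the unbalanced reaction (default `FALSE`).
#' @return A `flux_model`.
#' @export
fixture_blocked_biomass <- function(fixed = FALSE) {
  mets <- tibble::tibble(
    id = c("A[c]", "B[c]", "C[c]"),
    name = c("A", "B", "C"),
    formula = c("C2", "C2", if (fixed) "C2" else "C3"),
    charge = 0L, compartment = "c")
  rxn <- tibble::tibble(id = c("R_AB", "R_BC"), direction = "forward")
  st <- tibble::tibble(
    reaction_id = c("R_AB", "R_AB", "R_BC", "R_BC"),
    metabolite_id = c("A[c]", "B[c]", "B[c]", "C[c]"),
    coef = c(-1, 1, -1, 1))
  flux_model(mets, rxn, st)
}
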