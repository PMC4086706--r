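pathology_model <- function() {
  mets <- dplyr::bind_rows(
    met_row("A[c]", "C2"), met_row("B[c]", "C2"), met_row("C[c]", "C2"),
    met_row("D[c]", "C2"), met_row("E[c]", "C3"),
    met_row("iso1[c]", "C5"), met_row("iso2[c]", "C5"))
  rxn <- tibble::tibble(
    id = c("R_OK1", "R_OK2", "R_BAD", "R_IRR", "R_POLY", "R_ONE",
           "R_VAR", "R_ORPHAN"),
    direction = "forward",
    relevant = c(TRUE, TRUE, TRUE, FALSE, TRUE, TRUE, TRUE, TRUE),
    spontaneous = FALSE,
    flags = list(character(), character(), character(), character(),
                 "polymerization", character(), "variable-stoichiometry",
                 character()))
  st <- dplyr::bind_rows(
    tibble::tibble(reaction_id = "R_OK1", metabolite_id = c("A[c]", "B[c]"),
                   coef = c(-1, 1)),
    tibble::tibble(reaction_id = "R_OK2", metabolite_id = c("B[c]", "C[c]"),
                   coef = c(-1, 1)),
    tibble::tibble(reaction_id = "R_BAD", metabolite_id = c("C[c]", "E[c]"),
                   coef = c(-1, 1)),                       # C2 -> C3
    tibble::tibble(reaction_id = "R_IRR", metabolite_id = c("A[c]", "C[c]"),
                   coef = c(-1, 1)),
    tibble::tibble(reaction_id = "R_POLY", metabolite_id = c("A[c]", "D[c]"),
                   coef = c(-1, 1)),
    tibble::tibble(reaction_id = "R_ONE", metabolite_id = c("A[c]", "B[c]"),
                   coef = c(-1, -1)),                      # substrates only
    tibble::tibble(reaction_id = "R_VAR", metabolite_id = c("A[c]", "B[c]"),
                   coef = c(-1, 1)),
    tibble::tibble(reaction_id = "R_ORPHAN",
                   metabolite_id = c("iso1[c]", "iso2[c]"), coef = c(-1, 1)))
  flux_model(mets, rxn, st)
}

test_that("the filter cascade removes each pathology under its category", {
  f <- apply_filters(pathology_model())
  log <- f$report$log
  cat_of <- function(id) log$filter[log$reaction_id == id]
  expect_equal(cat_of("R_BAD"), "unbalanced")
  expect_equal(cat_of("R_IRR"), "irrelevant")
  expect_equal(cat_of("R_POLY"), "polymerization")
  expect_equal(cat_of("R_ONE"), "one-sided")
  expect_equal(cat_of("R_VAR"), "variable-stoichiometry")
  expect_equal(cat_of("R_ORPHAN"), "disconnected")
  expect_setequal(f$reactions$id, c("R_OK1", "R_OK2"))
})

test_that("disconnected filtering matches a brute-force connectivity oracle", {
  f <- apply_filters(pathology_model())
  # oracle: bipartite sharing over the retained candidate set
  # {R_OK1, R_OK2, R_ORPHAN}; the orphan shares no metabolite
  shared <- function(a, b) length(intersect(a, b)) > 0
  mets_of <- list(R_OK1 = c("A[c]", "B[c]"), R_OK2 = c("B[c]", "C[c]"),
                  R_ORPHAN = c("iso1[c]", "iso2[c]"))
  oracle_connected <- vapply(names(mets_of), function(r) {
    any(vapply(setdiff(names(mets_of), r),
               function(o) shared(mets_of[[r]], mets_of[[o]]), logical(1)))
  }, logical(1))
  expect_equal(sort(f$reactions$id),
               sort(names(oracle_connected)[oracle_connected]))
})

test_that("exclusion log partitions the source reactions", {
  m <- pathology_model()
  f <- apply_filters(m)
  accounted <- c(unique(f$reactions$source_id), f$report$log$reaction_id)
  expect_setequal(accounted, m$reactions$id)
  expect_equal(anyDuplicated(accounted), 0L)
})

test_that("the filter cascade is idempotent", {
  m <- fixture_fermentation()
  f1 <- apply_filters(m)
  # rebuild a model from the surviving reactions and re-filter: nothing
  # further is excluded once exchange context is carried along
  keep <- m$reactions$id %in% f1$reactions$source_id
  m2 <- m
  m2$reactions <- m$reactions[keep, ]
  m2$stoich <- m$stoich[m$stoich$reaction_id %in% m2$reactions$id, ]
  f2 <- apply_filters(m2, exchange_metabolites = c(
    growth_nutrients()$metabolite_id, fermentation_secretions()$metabolite_id))
  expect_equal(nrow(f2$report$log), 0L)
})

test_that("class reactions instantiate to the mass-balanced bindings only", {
  m <- toy_class_model()
  out <- instantiate_classes(m, "R_OXID")
  expect_null(out$rejected)
  # oracle: enumerate the 2 x 2 grid with an independent element counter
  alcohols <- c("etoh[c]", "prop_ol[c]"); aldehydes <- c("acald[c]", "propanal[c]")
  fm <- stats::setNames(m$metabolites$formula, m$metabolites$id)
  nadd <- mapply(function(a, b) {
    la <- oracle_count_elements(fm[[a]]); lb <- oracle_count_elements(fm[[b]])
    # alcohol + NAD -> aldehyde + NADH + H: alcohol must have exactly 2 more H
    identical(la[["C"]], lb[["C"]]) && la[["H"]] - lb[["H"]] == 2 &&
      la[["O"]] == lb[["O"]]
  }, rep(alcohols, each = 2), rep(aldehydes, 2))
  expect_equal(nrow(out$reactions), sum(nadd))
  bound <- vapply(out$reactions$binding, function(b) unname(b[["ALCOHOL[c]"]]),
                  character(1))
  expect_setequal(bound, c("etoh[c]", "prop_ol[c]"))
})

test_that("instantiation edge cases: identity, cap, empty instance list", {
  m <- toy_class_model()
  # a classless reaction passes through as itself
  m2 <- fixture_core_energy()
  out <- instantiate_classes(m2, "ATPM")
  expect_equal(out$reactions$id, "ATPM")
  # permutation cap
  capped <- instantiate_classes(m, "R_OXID", cap = 3)
  expect_equal(capped$rejected, "permutation-cap")
  # class with no instances is ambiguous, not an exception
  m3 <- m
  m3$metabolites$instances[[match("ALDEHYDE[c]", m3$metabolites$id)]] <- character()
  m3$metabolites$instances[[match("ALCOHOL[c]", m3$metabolites$id)]] <- "etoh[c]"
  expect_equal(instantiate_classes(m3, "R_OXID")$rejected,
               "ambiguous-instantiation")
})

test_that("a class slot keeps only the binding that balances its partner", {
  mets <- dplyr::bind_rows(
    met_row("x1[c]", "C2H4O"), met_row("x2[c]", "C3H6O"),
    met_row("x1p[c]", "C2H4O"),
    met_row("CLS[c]", NA_character_, charge = NA, is_class = TRUE,
            instances = c("x1[c]", "x2[c]")))
  rxn <- tibble::tibble(id = "R", direction = "forward")
  st <- tibble::tibble(reaction_id = c("R", "R"),
                       metabolite_id = c("CLS[c]", "x1p[c]"),
                       coef = c(-1, 1))
  m <- flux_model(mets, rxn, st)
  out <- instantiate_classes(m, "R")
  # only the isomer binding CLS -> x1 balances against product x1p
  expect_equal(nrow(out$reactions), 1L)
  expect_equal(unname(out$reactions$binding[[1]][["CLS[c]"]]), "x1[c]")
})

test_that("all instantiation outputs re-check as balanced", {
  m <- toy_class_model()
  out <- instantiate_classes(m, "R_OXID")
  probe <- m
  probe$stoich <- out$stoich
  probe$reactions <- tibble::tibble(id = out$reactions$id,
                                    direction = "forward", relevant = TRUE,
                                    spontaneous = FALSE,
                                    flags = rep(list(character()),
                                                nrow(out$reactions)))
  expect_true(all(check_mass_balance(probe, out$reactions$id)$status ==
                    "balanced"))
})

test_that("exchange attachment honors bounds, compartments and empty sets", {
  net <- build_network(fixture_core_energy())
  net <- attach_exchanges(net, nutrients = core_energy_nutrients(glucose = 10))
  rx <- net$reactions
  expect_equal(rx$ub[rx$id == "UPTAKE[glc__D[p]]"], 10)
  expect_equal(rx$ub[rx$id == "UPTAKE[o2[c]]"], net$default_bound)
  st <- net$stoich[net$stoich$reaction_id == "UPTAKE[o2[c]]", ]
  expect_equal(net$metabolites$compartment[
    net$metabolites$id == st$metabolite_id], "c")
  # empty secretion set adds nothing
  n0 <- nrow(net$reactions)
  net2 <- attach_exchanges(net, secretions = metabolite_set(character()))
  expect_equal(nrow(net2$reactions), n0)
  # unknown nutrient warns and is skipped
  expect_warning(
    net3 <- attach_exchanges(net, nutrients = metabolite_set("ghost[p]")),
    "ghost")
  expect_false("UPTAKE[ghost[p]]" %in% net3$reactions$id)
})

test_that("fixture networks pass the filter cascade with zero exclusions", {
  for (m in list(fixture_core_energy("ecocyc"), fixture_core_energy("ijo"),
                 fixture_fermentation())) {
    f <- apply_filters(m)
    expect_equal(nrow(f$report$log), 0L)
    expect_equal(nrow(f$reactions), nrow(m$reactions))
  }
})
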