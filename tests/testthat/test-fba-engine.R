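test_that("biomass assembly wires GAM into the reaction and NGAM as a floor", {
  net <- fixture_fermentation_network()
  net <- set_biomass(net, fixture_biomass(gam = 53.95, ngam = 3.15))
  st <- net$stoich[net$stoich$reaction_id == "BIOMASS", ]
  expect_equal(st$coef[st$metabolite_id == "atp[c]"], -53.95)
  expect_equal(st$coef[st$metabolite_id == "adp[c]"], 53.95)
  expect_equal(st$coef[st$metabolite_id == "pyr[c]"], -2.831)
  expect_equal(net$reactions$lb[net$reactions$id == "ATPM"], 3.15)
  # zero-maintenance biomass contains only the member drains
  net0 <- set_biomass(fixture_fermentation_network(),
                      fixture_biomass(gam = 0, ngam = 0))
  st0 <- net0$stoich[net0$stoich$reaction_id == "BIOMASS", ]
  expect_setequal(st0$metabolite_id, fixture_biomass()$members$metabolite_id)
})

test_that("absent biomass members are a hard error listing the ids", {
  net <- fixture_fermentation_network()
  bm <- biomass_objective(metabolite_set("ghost[c]", coef = 1), gam = 0,
                          ngam = 0)
  expect_error(set_biomass(net, bm), "ghost")
})

test_that("biomass drains scale linearly with the biomass flux", {
  # two-member toy with coefficients {X: 2, Y: 4}: at flux 0.5 the uptakes
  # must be 1.0 and 2.0 (linearity oracle: coefficient times flux)
  mets <- dplyr::bind_rows(met_row("X[c]", "C"), met_row("Y[c]", "C"),
                           met_row("Z[c]", "C"))
  m <- flux_model(
    mets,
    tibble::tibble(id = c("R_XZ", "R_YZ"), direction = "forward"),
    tibble::tibble(reaction_id = c("R_XZ", "R_XZ", "R_YZ", "R_YZ"),
                   metabolite_id = c("X[c]", "Z[c]", "Y[c]", "Z[c]"),
                   coef = c(-1, 1, -1, 1)))
  net <- build_network(m, nutrients = metabolite_set(c("X[c]", "Y[c]")),
                       secretions = metabolite_set("Z[c]"))
  net <- set_biomass(net, biomass_objective(
    metabolite_set(c("X[c]", "Y[c]"), coef = c(2, 4)), gam = 0, ngam = 0))
  sol <- solve_fba(net, fixed = c(BIOMASS = 0.5))
  expect_equal(flux_of(sol, "UPTAKE[X[c]]"), 1.0, tolerance = 1e-9)
  expect_equal(flux_of(sol, "UPTAKE[Y[c]]"), 2.0, tolerance = 1e-9)
})

test_that("closing every uptake yields a zero, no-growth optimum", {
  net <- fixture_core_energy_network(glucose = 0)
  net <- set_bounds(net, "UPTAKE[o2[c]]", ub = 0)
  net <- set_bounds(net, "UPTAKE[h2o[c]]", ub = 0)
  sol <- solve_fba(net)
  expect_equal(sol$status, "optimal")
  expect_equal(sol$objective_value, 0, tolerance = 1e-9)
  expect_false(sol$growth)
})

test_that("the taxicab stage selects the shorter of two equal-yield routes", {
  net <- fixture_diamond()
  sol <- solve_fba(net, minimize_fluxes = TRUE)
  expect_equal(sol$objective_value, 1, tolerance = 1e-9)
  # vertex enumeration oracle: route A-B-D has Sum|v| = 4 (uptake, two
  # internal steps, secretion), route A-E-F-D has 5
  expect_equal(sol$sum_abs_flux, 4, tolerance = 1e-9)
  expect_equal(flux_of(sol, "R_AB"), 1, tolerance = 1e-9)
  expect_equal(flux_of(sol, "R_AE"), 0)
})

test_that("taxicab minimization preserves the objective and reduces Sum|v|", {
  net <- fixture_fermentation_network(o2 = 0)
  s1 <- solve_fba(net, minimize_fluxes = FALSE)
  s2 <- solve_fba(net, minimize_fluxes = TRUE)
  expect_equal(s2$objective_value, s1$objective_value, tolerance = 1e-8)
  expect_lte(s2$sum_abs_flux, s1$sum_abs_flux + 1e-9)
})

test_that("solver statuses propagate instead of masquerading as no-growth", {
  # a driven cycle touching the objective is unbounded
  mets <- dplyr::bind_rows(met_row("A[c]", "C"), met_row("B[c]", "C"))
  m <- flux_model(mets,
                  tibble::tibble(id = c("R1", "R2"),
                                 direction = c("forward", "forward")),
                  tibble::tibble(reaction_id = c("R1", "R1", "R2", "R2"),
                                 metabolite_id = c("A[c]", "B[c]", "B[c]", "A[c]"),
                                 coef = c(-1, 1, -1, 1)))
  net <- build_network(m, nutrients = metabolite_set("A[c]", coef = 1))
  net <- set_objective(net, "R1")
  expect_equal(solve_fba(net)$status, "unbounded")
  # an unsatisfiable maintenance floor is infeasible
  net2 <- fixture_core_energy_network(glucose = 0)
  net2 <- set_bounds(net2, "ATPM", lb = 5)
  expect_equal(solve_fba(net2)$status, "infeasible")
})

test_that("rescaling a reaction moves stage-2 fluxes but not the optimum", {
  net <- fixture_core_energy_network()
  sol <- solve_fba(net, minimize_fluxes = TRUE)
  net2 <- net
  i <- net2$stoich$reaction_id == "PGLUCISOM-RXN"
  net2$stoich$coef[i] <- net2$stoich$coef[i] * 2
  sol2 <- solve_fba(net2, minimize_fluxes = TRUE)
  expect_equal(sol2$objective_value, sol$objective_value, tolerance = 1e-8)
  expect_equal(flux_of(sol2, "PGLUCISOM-RXN"),
               flux_of(sol, "PGLUCISOM-RXN") / 2, tolerance = 1e-6)
})

test_that("half- and whole-O2 oxidase conventions give identical exchanges", {
  half <- fixture_core_energy_network("ijo")
  whole_model <- normalize_stoichiometry(fixture_core_energy("ijo"),
                                         "CYTOCHROME-BO-OXIDASE")
  whole <- build_network(whole_model, nutrients = core_energy_nutrients(10),
                         secretions = core_energy_secretions())
  whole <- set_objective(whole, "ATPM")
  s_half <- solve_fba(half, minimize_fluxes = TRUE)
  s_whole <- solve_fba(whole, minimize_fluxes = TRUE)
  expect_equal(s_whole$objective_value, s_half$objective_value,
               tolerance = 1e-8)
  for (ex in c("UPTAKE[o2[c]]", "SECRETION[co2[c]]", "SECRETION[h2o[c]]")) {
    expect_equal(flux_of(s_whole, ex), flux_of(s_half, ex), tolerance = 1e-6)
  }
  expect_equal(flux_of(s_half, "CYTOCHROME-BO-OXIDASE"),
               2 * flux_of(s_whole, "CYTOCHROME-BO-OXIDASE"),
               tolerance = 1e-6)
})

test_that("chemostat runs pin the substrate and scale homogeneously", {
  net <- fixture_growth_network(ngam = 0)
  c0 <- chemostat_run(net, "glc__D[p]", 0)
  expect_equal(c0$objective_value, 0, tolerance = 1e-9)
  c1 <- chemostat_run(net, "glc__D[p]", 3.008)
  c2 <- chemostat_run(net, "glc__D[p]", 6.016)
  expect_equal(flux_of(c1, "UPTAKE[glc__D[p]]"), 3.008, tolerance = 1e-8)
  expect_equal(c2$objective_value, 2 * c1$objective_value, tolerance = 1e-6)
  expect_true(all(c("metabolite_id", "flux") %in% names(c1$exchange_fluxes)))
  # uptake reported negative, production positive
  glc <- c1$exchange_fluxes$flux[c1$exchange_fluxes$metabolite_id == "glc__D[p]"]
  expect_equal(glc, -3.008, tolerance = 1e-8)
})

test_that("maintenance ATP makes growth affine, not linear, in uptake", {
  net <- fixture_growth_network(ngam = 3.15)
  c1 <- chemostat_run(net, "glc__D[p]", 3.008)
  c2 <- chemostat_run(net, "glc__D[p]", 6.016)
  expect_gt(c2$objective_value, 2 * c1$objective_value)
})

test_that("a single-point sweep equals a plain solve", {
  net <- fixture_fermentation_network(o2 = 0)
  sw <- flux_sweep(net, "UPTAKE[o2[c]]", 0)
  sol <- solve_fba(set_bounds(net, "UPTAKE[o2[c]]", ub = 0))
  expect_equal(unique(sw$objective), sol$objective_value, tolerance = 1e-9)
  f <- stats::setNames(sw$flux, sw$reaction_id)
  expect_equal(unname(f["ATPM"]), flux_of(sol, "ATPM"), tolerance = 1e-9)
})

test_that("sweeping an exchange unused by the optimum leaves it flat", {
  # anaerobically, periplasmic succinate cannot reach the ATP objective
  # (its oxidation needs the quinone pool the fumarate reductase refills),
  # so sweeping its uptake must not move the optimum
  net <- fixture_fermentation_network(o2 = 0)
  net <- attach_exchanges(net, nutrients = metabolite_set("succ[p]", coef = 0))
  sw <- flux_sweep(net, "UPTAKE[succ[p]]", seq(0, 10, by = 5))
  obj <- unique(round(sw$objective, 6))
  expect_length(obj, 1L)
})

test_that("reachability flags blocked members and repair flips them", {
  broken <- fixture_blocked_biomass(fixed = FALSE)
  fixed <- fixture_blocked_biomass(fixed = TRUE)
  bm <- metabolite_set(c("B[c]", "C[c]"), coef = 1)
  scan_of <- function(m) {
    # in the broken model C[c] drops out of the network entirely, so its
    # secretion exchange is skipped with a warning by design
    net <- suppressWarnings(
      build_network(m, nutrients = metabolite_set("A[c]", coef = 10),
                    secretions = metabolite_set("C[c]")))
    reachability_scan(net, bm)
  }
  r1 <- scan_of(broken)
  expect_true(r1$producible[r1$metabolite_id == "B[c]"])
  expect_false(r1$producible[r1$metabolite_id == "C[c]"])
  r2 <- scan_of(fixed)
  expect_true(all(r2$producible))
})

test_that("every optimum satisfies steady state to 1e-6", {
  nets <- list(
    fixture_core_energy_network("ecocyc"),
    fixture_core_energy_network("ijo"),
    fixture_fermentation_network(o2 = 0),
    fixture_growth_network())
  for (net in nets) {
    for (minimize in c(FALSE, TRUE)) {
      sol <- solve_fba(net, minimize_fluxes = minimize)
      expect_equal(sol$status, "optimal")
      expect_lt(steady_state_residual(net, sol), 1e-6)
    }
  }
})

test_that("tidy, glance and autoplot work on solutions", {
  sol <- solve_fba(fixture_core_energy_network())
  td <- tidy(sol, nonzero = TRUE)
  expect_true(all(td$flux != 0))
  gl <- glance(sol)
  expect_equal(gl$objective, 216, tolerance = 1e-6)
  expect_s3_class(autoplot(sol), "ggplot")
})
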