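#' Solve a flux network by two-stage flux balance analysis
#'
#' Stage 1 maximizes the flux of the network's objective reaction subject to
#' steady state (`S v = 0` for every metabolite) and the per-reaction bounds.
#' When `minimize_fluxes` is on, stage 2 pins the objective at its stage-1
#' optimum and minimizes the taxicab norm `Sum|v|`, which selects a
#' parsimonious flux vector among the alternate optima. The reported
#' objective value is always the stage-1 optimum; the growth call is
#' `objective > eps`. Infeasible and unbounded solver outcomes are reported
#' as such, never silently coerced to no-growth (an unbounded status points
#' to a thermodynamically broken cycle touching the objective).
#'
#' @param network A `flux_network` with an objective set (see
#'   [set_objective()] or [set_biomass()]).
#' @param minimize_fluxes Run the taxicab minimization stage (default `TRUE`).
#' @param eps Growth threshold on the objective flux (default `1e-6`); must
#'   exceed solver tolerance.
#' @param fixed Optional named numeric vector pinning reactions to exact flux
#'   values (equality constraints), as in the chemostat protocol.
#' @return An `fba_solution`: `status`, `objective_value`, `fluxes`
#'   (tibble `reaction_id`, `flux` in mmol/gCDW/hr), `growth`, `mu` (equals
#'   the biomass flux when the objective is the biomass reaction), and
#'   `sum_abs_flux`.
#' @examples
#' net <- fixture_core_energy_network(glucose = 10)
#' sol <- solve_fba(net)
#' glance(sol)
#' @export
solve_fba <- function(network, minimize_fluxes = TRUE, eps = 1e-6, fixed = NULL) {
  stopifnot(inherits(network, "flux_network"))
  if (is.na(network$objective)) stop("network has no objective reaction", call. = FALSE)
  res <- lp_two_stage(network, network$objective,
                      minimize_fluxes = minimize_fluxes, fixed = fixed)
  fluxes <- if (is.null(res$v)) {
    tibble::tibble(reaction_id = network$reactions$id, flux = NA_real_)
  } else {
    tibble::tibble(reaction_id = names(res$v), flux = unname(res$v))
  }
  growth <- res$status == "optimal" && isTRUE(res$value > eps)
  structure(
    list(status = res$status,
         objective_value = res$value,
         objective_id = network$objective,
         fluxes = fluxes,
         growth = growth,
         mu = if (identical(network$objective, "BIOMASS")) res$value else NA_real_,
         sum_abs_flux = res$sum_abs,
         minimized = res$stage2,
         eps = eps),
    class = "fba_solution"
  )
}

#' @export
print.fba_solution <- function(x, ...) {
  cat("<fba_solution> status: ", x$status,
      ", objective(", x$objective_id, ") = ",
      formatC(x$objective_value, digits = 6, format = "g"),
      if (x$minimized) paste0(", Sum|v| = ", formatC(x$sum_abs_flux, digits = 6,
                                                     format = "g")),
      ", growth: ", x$growth, "\n", sep = "")
  invisible(x)
}

#' Extract one reaction's flux from a solution
#' @param solution An `fba_solution`.
#' @param reaction_id Reaction id.
#' @return Numeric flux (mmol/gCDW/hr).
#' @export
flux_of <- function(solution, reaction_id) {
  i <- match(reaction_id, solution$fluxes$reaction_id)
  if (is.na(i)) stop("no such reaction in solution: ", reaction_id, call. = FALSE)
  solution$fluxes$flux[i]
}

#' Steady-state residual of a solution on its network
#'
#' @param network The solved `flux_network`.
#' @param solution The `fba_solution`.
#' @return Maximum absolute component of `S v` over all metabolites.
#' @export
steady_state_residual <- function(network, solution) {
  st <- dplyr::left_join(network$stoich, solution$fluxes,
                         by = c("reaction_id" = "reaction_id"))
  resid <- tapply(st$coef * st$flux, st$metabolite_id, sum)
  max(abs(resid))
}

#' Chemostat-style growth simulation
#'
#' Implements the substrate-limited protocol: the measured substrate uptake is
#' the only fixed constraint (an equality on its uptake exchange); all other
#' exchange bounds stay at their defaults; biomass is maximized with taxicab
#' minimization. Returns the solution augmented with an extracellular flux
#' summary.
#'
#' @param network A `flux_network` with a biomass objective attached.
#' @param substrate_id Metabolite id of the limiting substrate (must be in
#'   the nutrient set, e.g. `"glc__D[p]"`).
#' @param uptake Measured uptake rate, mmol/gCDW/hr.
#' @return An `fba_solution` with an extra `exchange_fluxes` tibble
#'   (`metabolite_id`, `flux`; positive = production, negative = uptake).
#' @export
chemostat_run <- function(network, substrate_id, uptake) {
  stopifnot(inherits(network, "flux_network"))
  rid <- paste0("UPTAKE[", substrate_id, "]")
  if (!rid %in% network$reactions$id) {
    stop("substrate has no uptake exchange: ", substrate_id, call. = FALSE)
  }
  network <- set_bounds(network, rid, ub = max(uptake, network$default_bound))
  sol <- solve_fba(network, minimize_fluxes = TRUE,
                   fixed = stats::setNames(uptake, rid))
  ex <- network$reactions[network$reactions$kind %in% c("uptake", "efflux"), ]
  fl <- sol$fluxes$flux[match(ex$id, sol$fluxes$reaction_id)]
  mid <- sub("^(UPTAKE|SECRETION)\\[(.*)\\]$", "\\2", ex$id)
  sgn <- ifelse(ex$kind == "uptake", -1, 1)     # production positive
  sol$exchange_fluxes <- dplyr::arrange(
    tibble::tibble(metabolite_id = mid, flux = sgn * fl),
    .data$metabolite_id)
  sol
}

#' Sweep an exchange bound and re-solve at each point
#'
#' One solve per bound value with everything else held constant; per-point
#' solver failures are recorded, not raised, so a sweep never aborts midway.
#'
#' @param network A `flux_network` with an objective.
#' @param exchange_id Id of the exchange reaction whose upper bound is swept.
#' @param bounds Monotone numeric vector of bound values.
#' @param minimize_fluxes Passed to [solve_fba()].
#' @return A tidy tibble `(bound, reaction_id, flux, status, objective)` in
#'   long format, ready for plotting.
#' @examples
#' net <- fixture_fermentation_network(glucose = 10, o2 = 0)
#' sweep <- flux_sweep(net, "UPTAKE[o2[c]]", seq(0, 20, by = 2.5))
#' @export
flux_sweep <- function(network, exchange_id, bounds, minimize_fluxes = TRUE) {
  stopifnot(inherits(network, "flux_network"))
  if (is.unsorted(bounds) && is.unsorted(rev(bounds))) {
    stop("`bounds` must be monotone", call. = FALSE)
  }
  purrr::map_dfr(bounds, function(b) {
    net_b <- set_bounds(network, exchange_id, ub = b)
    sol <- tryCatch(solve_fba(net_b, minimize_fluxes = minimize_fluxes),
                    error = function(e) NULL)
    if (is.null(sol) || sol$status != "optimal") {
      return(tibble::tibble(bound = b, reaction_id = NA_character_,
                            flux = NA_real_,
                            status = if (is.null(sol)) "error" else sol$status,
                            objective = NA_real_))
    }
    tibble::tibble(bound = b, reaction_id = sol$fluxes$reaction_id,
                   flux = sol$fluxes$flux, status = sol$status,
                   objective = sol$objective_value)
  })
}

#' Producibility scan of biomass members
#'
#' For each biomass member the network is re-solved with a temporary drain of
#' that single metabolite as the objective; a member is producible when the
#' maximal drain exceeds `eps`, blocked otherwise. The input network is never
#' modified.
#'
#' @param network A `flux_network` with nutrients attached.
#' @param biomass A `biomass_objective` (or any tibble with `metabolite_id`).
#' @param eps Producibility threshold (default `1e-6`).
#' @return Tibble `(metabolite_id, producible, max_drain)`.
#' @export
reachability_scan <- function(network, biomass, eps = 1e-6) {
  stopifnot(inherits(network, "flux_network"))
  members <- if (inherits(biomass, "biomass_objective")) {
    biomass$members$metabolite_id
  } else tibble::as_tibble(biomass)$metabolite_id
  purrr::map_dfr(members, function(mid) {
    if (!mid %in% network$metabolites$id) {
      return(tibble::tibble(metabolite_id = mid, producible = FALSE,
                            max_drain = 0))
    }
    net <- network
    net$reactions <- dplyr::bind_rows(net$reactions, tibble::tibble(
      id = "DRAIN", source_id = "DRAIN", kind = "efflux",
      lb = 0, ub = net$default_bound))
    net$stoich <- dplyr::bind_rows(net$stoich, tibble::tibble(
      reaction_id = "DRAIN", metabolite_id = mid, coef = -1))
    net <- set_objective(net, "DRAIN")
    sol <- solve_fba(net, minimize_fluxes = FALSE)
    ok <- sol$status == "optimal" && sol$objective_value > eps
    tibble::tibble(metabolite_id = mid, producible = ok,
                   max_drain = if (sol$status == "optimal") sol$objective_value else 0)
  })
}
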