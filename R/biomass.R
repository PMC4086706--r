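#' Define a biomass objective
#'
#' A biomass objective drains each member metabolite at its measured
#' coefficient (mmol per gram cell dry weight), plus a growth-associated
#' maintenance (GAM) turnover of ATP hydrolysis inside the biomass reaction,
#' and a non-growth-associated maintenance (NGAM) floor imposed as a lower
#' bound on the standing ATP-hydrolysis reaction. A biomass flux of 1.0
#' represents a specific growth rate of 1.0 per hour.
#'
#' @param members A `metabolite_set` (or tibble with `metabolite_id`, `coef`)
#'   with strictly positive coefficients in mmol/gCDW.
#' @param gam Growth-associated maintenance, mmol ATP/gCDW (default 53.95).
#' @param ngam Non-growth-associated maintenance, mmol ATP/gCDW/hr
#'   (default 3.15).
#' @param variant `"core"` (minimal growth-required set) or `"expanded"`
#'   (measured wild-type composition).
#' @return An object of class `biomass_objective`.
#' @export
biomass_objective <- function(members, gam = 53.95, ngam = 3.15,
                              variant = c("core", "expanded")) {
  variant <- match.arg(variant)
  members <- tibble::as_tibble(members)[, c("metabolite_id", "coef")]
  stopifnot(all(members$coef > 0), gam >= 0, ngam >= 0)
  structure(list(members = members, gam = gam, ngam = ngam, variant = variant),
            class = "biomass_objective")
}

#' @export
print.biomass_objective <- function(x, ...) {
  cat("<biomass_objective> ", nrow(x$members), " members (", x$variant,
      "), GAM ", x$gam, " mmol ATP/gCDW, NGAM ", x$ngam,
      " mmol ATP/gCDW/hr\n", sep = "")
  invisible(x)
}

#' Attach a biomass objective to a network
#'
#' Adds a single `BIOMASS` reaction consuming every member at its coefficient
#' together with `gam` units of ATP + H2O, producing `gam` units of
#' ADP + Pi + H+, sets the NGAM lower bound on the ATP-hydrolysis reaction,
#' and makes `BIOMASS` the network objective. Members absent from the network
#' are a hard error (use [reachability_scan()] to diagnose blocked members).
#'
#' @param network A `flux_network`.
#' @param biomass A `biomass_objective`.
#' @param energy_ids Named character vector mapping the maintenance couple
#'   (`atp`, `h2o`, `adp`, `pi`, `h`) to network metabolite ids.
#' @param atpm_id Id of the standing ATP-hydrolysis reaction that carries the
#'   NGAM floor (default `"ATPM"`); only consulted when `ngam > 0`.
#' @return The modified network (with `$biomass` recorded).
#' @export
set_biomass <- function(network, biomass,
                        energy_ids = c(atp = "atp[c]", h2o = "h2o[c]",
                                       adp = "adp[c]", pi = "pi[c]", h = "h[c]"),
                        atpm_id = "ATPM") {
  stopifnot(inherits(network, "flux_network"), inherits(biomass, "biomass_objective"))
  missing <- setdiff(biomass$members$metabolite_id, network$metabolites$id)
  if (length(missing)) {
    stop("biomass member(s) absent from network: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  st <- tibble::tibble(reaction_id = "BIOMASS",
                       metabolite_id = biomass$members$metabolite_id,
                       coef = -biomass$members$coef)
  if (biomass$gam > 0) {
    gam_missing <- setdiff(unname(energy_ids), network$metabolites$id)
    if (length(gam_missing)) {
      stop("maintenance metabolite(s) absent from network: ",
           paste(gam_missing, collapse = ", "), call. = FALSE)
    }
    gam_st <- tibble::tibble(
      reaction_id = "BIOMASS",
      metabolite_id = unname(energy_ids[c("atp", "h2o", "adp", "pi", "h")]),
      coef = biomass$gam * c(-1, -1, 1, 1, 1))
    st <- dplyr::bind_rows(st, gam_st)
    # a biomass member may itself be part of the maintenance couple
    st <- dplyr::summarise(dplyr::group_by(st, .data$reaction_id, .data$metabolite_id),
                           coef = sum(.data$coef), .groups = "drop")
    st <- st[abs(st$coef) > 1e-12, ]
  }
  network$reactions <- network$reactions[network$reactions$id != "BIOMASS", ]
  network$stoich <- network$stoich[network$stoich$reaction_id != "BIOMASS", ]
  network$reactions <- dplyr::bind_rows(network$reactions, tibble::tibble(
    id = "BIOMASS", source_id = "BIOMASS", kind = "biomass", lb = 0, ub = Inf))
  network$stoich <- dplyr::bind_rows(network$stoich, st)
  if (biomass$ngam > 0) {
    if (!atpm_id %in% network$reactions$id) {
      stop("ATP-hydrolysis reaction not found for NGAM floor: ", atpm_id,
           call. = FALSE)
    }
    network <- set_bounds(network, atpm_id, lb = biomass$ngam)
  }
  network$biomass <- biomass
  set_objective(network, "BIOMASS")
}
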