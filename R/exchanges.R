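#' Define a metabolite set (nutrients, secretions, or biomass members)
#'
#' A metabolite set is a tibble of metabolite ids with optional coefficients.
#' For nutrient sets the coefficient is the uptake bound in mmol/gCDW/hr
#' (`NA` = unconstrained, i.e. the network's default large bound); for biomass
#' sets it is the drain in mmol/gCDW; secretion sets need no coefficient.
#'
#' @param metabolite_id Character vector of metabolite ids (ids carry their
#'   compartment suffix, e.g. `"glc__D[p]"`, `"nh4[c]"` for a cytosol-supplied
#'   nutrient).
#' @param coef Numeric coefficients recycled to length (default `NA`).
#' @param role Optional element role per member (`"C"`, `"N"`, `"P"`, `"S"`,
#'   or `NA`), used by phenotype-microarray media construction.
#' @return A tibble of class `metabolite_set`.
#' @export
metabolite_set <- function(metabolite_id, coef = NA_real_, role = NA_character_) {
  out <- tibble::tibble(
    metabolite_id = as.character(metabolite_id),
    coef = rep_len(as.numeric(coef), length(metabolite_id)),
    role = rep_len(as.character(role), length(metabolite_id))
  )
  class(out) <- c("metabolite_set", class(out))
  out
}

met_compartment <- function(ids) {
  cpt <- sub("^.*\\[([^]]+)\\]$", "\\1", ids)
  ifelse(cpt == ids, "c", cpt)
}

#' Attach nutrient and secretion exchanges to a network
#'
#' Creates one uptake exchange per nutrient, bounded above by the nutrient
#' coefficient (or the network's default large bound when unconstrained), and
#' one unbounded efflux exchange per secretion. The exchange acts in the
#' compartment encoded in the metabolite id, so cytosol-flagged nutrients
#' (e.g. ammonium supplied directly in the cytosol) exchange straight into
#' the cytosol while ordinary nutrients enter the periplasm. Set members that
#' reference metabolites absent from the network are skipped with a warning.
#'
#' @param network A `flux_network`.
#' @param nutrients,secretions `metabolite_set`s (either may be `NULL`).
#' @return The network with `UPTAKE[...]` and `SECRETION[...]` reactions
#'   added.
#' @export
attach_exchanges <- function(network, nutrients = NULL, secretions = NULL) {
  stopifnot(inherits(network, "flux_network"))
  add <- function(net, ids, coefs, kind) {
    for (i in seq_along(ids)) {
      mid <- ids[i]
      if (!mid %in% net$metabolites$id) {
        warning(kind, " exchange skipped, metabolite not in network: ", mid,
                call. = FALSE)
        next
      }
      rid <- paste0(if (kind == "uptake") "UPTAKE[" else "SECRETION[", mid, "]")
      if (rid %in% net$reactions$id) next
      ub <- if (kind == "uptake" && is.finite(coefs[i])) coefs[i] else net$default_bound
      net$reactions <- dplyr::bind_rows(net$reactions, tibble::tibble(
        id = rid, source_id = rid, kind = kind, lb = 0, ub = ub))
      net$stoich <- dplyr::bind_rows(net$stoich, tibble::tibble(
        reaction_id = rid, metabolite_id = mid,
        coef = if (kind == "uptake") 1 else -1))
    }
    net
  }
  if (!is.null(nutrients)) {
    network <- add(network, nutrients$metabolite_id, nutrients$coef, "uptake")
    network$nutrients <- nutrients
  }
  if (!is.null(secretions)) {
    network <- add(network, secretions$metabolite_id, secretions$coef, "efflux")
    network$secretions <- secretions
  }
  network
}

#' Set or change a reaction's flux bounds
#'
#' @param network A `flux_network`.
#' @param reaction_id Reaction id.
#' @param lb,ub New lower/upper bounds (either may be omitted).
#' @return The modified network.
#' @export
set_bounds <- function(network, reaction_id, lb = NULL, ub = NULL) {
  stopifnot(inherits(network, "flux_network"))
  i <- match(reaction_id, network$reactions$id)
  if (is.na(i)) stop("unknown reaction id: ", reaction_id, call. = FALSE)
  if (!is.null(lb)) network$reactions$lb[i] <- lb
  if (!is.null(ub)) network$reactions$ub[i] <- ub
  network
}

#' Declare the objective reaction of a network
#'
#' @param network A `flux_network`.
#' @param reaction_id Id of the reaction whose flux is maximized.
#' @return The modified network.
#' @export
set_objective <- function(network, reaction_id) {
  stopifnot(inherits(network, "flux_network"))
  if (!reaction_id %in% network$reactions$id) {
    stop("unknown reaction id: ", reaction_id, call. = FALSE)
  }
  network$objective <- reaction_id
  network
}
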