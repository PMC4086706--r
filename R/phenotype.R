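# Phenotype-microarray style nutrient-utilization screening: media
# construction, aerobic/anaerobic adjustment, cross-dataset consensus, and
# growth-prediction benchmarking.

#' Construct the nutrient set for a phenotype-microarray well
#'
#' Starts from a base minimal-media composition in which each member may be
#' tagged with the element role it supplies (`C`, `N`, `P`, `S`), removes
#' the base source of the varied role, and adds the well's variable nutrient
#' in the periplasm. Ferric iron in the base is replaced by ferrous iron
#' (enterobactin-mediated ferric uptake is not modeled), ammonium is
#' supplied in the cytosol, and MOPS buffer, when present, is flagged usable
#' as a sulfur source (role `S`). A variable nutrient equal to the base
#' source reproduces the base media.
#'
#' @param base A `metabolite_set` with a `role` column (see
#'   [pm_base_media()]).
#' @param variable_id Metabolite id of the varied nutrient; an id without a
#'   compartment suffix is placed in the periplasm.
#' @param role Element role of the well (`"C"`, `"N"`, `"P"`, `"S"`).
#' @param bound Uptake bound for the variable nutrient (default 10).
#' @return A `metabolite_set`.
#' @export
build_media_nutrients <- function(base, variable_id, role, bound = 10) {
  stopifnot(role %in% c("C", "N", "P", "S"))
  base <- tibble::as_tibble(base)
  if (!"role" %in% names(base)) base$role <- NA_character_
  # ferric -> ferrous replacement
  fe3 <- grepl("^fe3\\[", base$metabolite_id)
  base$metabolite_id[fe3] <- sub("^fe3\\[", "fe2[", base$metabolite_id[fe3])
  # MOPS is usable as a sulfur source when present
  base$role[grepl("^mops\\[", base$metabolite_id)] <- "S"
  # ammonium enters the cytosol directly
  nh4 <- grepl("^nh4\\[", base$metabolite_id)
  base$metabolite_id[nh4] <- sub("\\[[^]]+\\]$", "[c]", base$metabolite_id[nh4])
  if (!grepl("\\[[^]]+\\]$", variable_id)) {
    variable_id <- paste0(variable_id, "[p]")
  }
  keep <- is.na(base$role) | base$role != role
  out <- base[keep, c("metabolite_id", "coef", "role")]
  if (!variable_id %in% out$metabolite_id) {
    out <- dplyr::bind_rows(out, tibble::tibble(
      metabolite_id = variable_id, coef = bound, role = role))
  }
  class(out) <- c("metabolite_set", class(tibble::tibble()))
  out
}

#' Base minimal-media composition for the fixture networks
#'
#' Glucose as the carbon source plus unconstrained O2, with placeholder
#' nitrogen / phosphorus / sulfur sources so element-role replacement can be
#' exercised. Shipped as a plain-text fixture
#' (`inst/extdata/pm_base_media.tsv`) rather than hard-coded.
#'
#' @param glucose Carbon-source bound (default 10 mmol/gCDW/hr).
#' @return A `metabolite_set` with a `role` column.
#' @export
pm_base_media <- function(glucose = 10) {
  path <- system.file("extdata", "pm_base_media.tsv", package = "fluxbal",
                      mustWork = TRUE)
  tb <- tibble::as_tibble(utils::read.delim(path, sep = "\t",
                                            stringsAsFactors = FALSE))
  tb$coef[tb$metabolite_id == "glc__D[p]"] <- glucose
  out <- metabolite_set(tb$metabolite_id, coef = tb$coef, role = tb$role)
  out
}

#' Anaerobic model adjustment
#'
#' Applies the standard anaerobic modifications: the O2 uptake bound is set
#' to zero, the formate-hydrogen lyase reaction is enabled, and the
#' protoheme and pyridoxal 5'-phosphate requirements are removed from the
#' biomass objective. Members absent from the biomass are logged, not an
#' error, and the operation is idempotent.
#'
#' @param network A `flux_network` (with or without a biomass attached).
#' @param o2_exchange,fhl_id Ids of the O2 uptake exchange and the
#'   formate-hydrogen lyase reaction.
#' @param drop_members Biomass member ids removed anaerobically.
#' @return The adjusted network, with a character vector of log messages in
#'   `attr(, "anaerobic_log")`.
#' @export
apply_anaerobic_mods <- function(network, o2_exchange = "UPTAKE[o2[c]]",
                                 fhl_id = "FHL-RXN",
                                 drop_members = c("pheme[c]", "pydx5p[c]")) {
  stopifnot(inherits(network, "flux_network"))
  log <- character()
  if (o2_exchange %in% network$reactions$id) {
    network <- set_bounds(network, o2_exchange, ub = 0)
    log <- c(log, paste0("O2 uptake bound set to 0 (", o2_exchange, ")"))
  } else log <- c(log, "no O2 exchange present; nothing to close")
  if (fhl_id %in% network$reactions$id) {
    network <- set_bounds(network, fhl_id, lb = 0, ub = Inf)
    log <- c(log, "formate-hydrogen lyase enabled")
  } else log <- c(log, "no formate-hydrogen lyase reaction present")
  if (!is.null(network$biomass)) {
    bm <- network$biomass
    present <- intersect(drop_members, bm$members$metabolite_id)
    absent <- setdiff(drop_members, bm$members$metabolite_id)
    if (length(absent)) {
      log <- c(log, paste0("biomass member absent, no-op: ",
                           paste(absent, collapse = ", ")))
    }
    if (length(present)) {
      bm$members <- bm$members[!bm$members$metabolite_id %in% present, ]
      network <- set_biomass(network, bm)
      log <- c(log, paste0("removed from biomass: ",
                           paste(present, collapse = ", ")))
    }
  }
  attr(network, "anaerobic_log") <- log
  network
}

#' Consensus call across phenotype-microarray datasets
#'
#' Per dataset, `normal` and `low` respiration scores are combined into a
#' positive result and `none` is negative. The consensus is positive when
#' every dataset is positive, negative when every dataset is negative, and
#' `no-consensus` otherwise (such wells are excluded from accuracy
#' computation). A `"majority"` policy is available as an alternative
#' reading; unanimity is the default.
#'
#' @param scores Character vector of per-dataset scores (`"normal"`,
#'   `"low"`, `"none"`).
#' @param policy `"unanimity"` (default) or `"majority"` (ties =
#'   no-consensus).
#' @return `"positive"`, `"negative"`, or `"no-consensus"`.
#' @examples
#' pm_consensus(c("normal", "low", "low", "normal"))  # positive
#' pm_consensus(c("normal", "none", "low", "none"))   # no-consensus
#' @export
pm_consensus <- function(scores, policy = c("unanimity", "majority")) {
  policy <- match.arg(policy)
  stopifnot(length(scores) >= 1)
  bad <- setdiff(scores, c("normal", "low", "none"))
  if (length(bad)) stop("unknown score(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  pos <- scores %in% c("normal", "low")
  if (policy == "unanimity") {
    if (all(pos)) "positive" else if (all(!pos)) "negative" else "no-consensus"
  } else {
    if (sum(pos) > sum(!pos)) "positive"
    else if (sum(pos) < sum(!pos)) "negative"
    else "no-consensus"
  }
}

with_media <- function(network, nutrients) {
  drop <- network$reactions$kind == "uptake"
  ids <- network$reactions$id[drop]
  network$reactions <- network$reactions[!drop, ]
  network$stoich <- network$stoich[!network$stoich$reaction_id %in% ids, ]
  suppressWarnings(attach_exchanges(network, nutrients = nutrients))
}

#' Phenotype-microarray growth-prediction screen
#'
#' For every consensus-scored well the well medium is constructed from the
#' base composition, attached to the network, and solved; the growth call is
#' compared with the consensus respiration call (respiration is compared
#' directly with simulated growth via the checkpoint-linkage argument). The
#' result aggregates a confusion matrix in the growth-positive orientation;
#' no-consensus wells are listed separately and never scored.
#'
#' @param network A `flux_network` with a biomass objective attached.
#' @param wells Long tibble `(well, nutrient_id, role, dataset, score)`.
#' @param base Base media `metabolite_set` (default [pm_base_media()]).
#' @param aerobic Logical; `FALSE` applies [apply_anaerobic_mods()] per
#'   well.
#' @param policy Consensus policy, see [pm_consensus()].
#' @param eps Growth threshold.
#' @return A `screen_result` with `per_well`, `no_consensus`, and `stats`.
#' @export
pm_screen <- function(network, wells, base = pm_base_media(), aerobic = TRUE,
                      policy = "unanimity", eps = 1e-6) {
  stopifnot(inherits(network, "flux_network"))
  wl <- dplyr::summarise(
    dplyr::group_by(tibble::as_tibble(wells), .data$well, .data$nutrient_id,
                    .data$role),
    consensus = pm_consensus(.data$score, policy = policy), .groups = "drop")
  wl <- dplyr::arrange(wl, .data$well)
  no_cons <- wl$well[wl$consensus == "no-consensus"]
  scored <- wl[wl$consensus != "no-consensus", ]
  sim <- purrr::map_chr(seq_len(nrow(scored)), function(i) {
    med <- build_media_nutrients(base, scored$nutrient_id[i], scored$role[i])
    med <- med[med$metabolite_id %in% network$metabolites$id, ]
    net <- with_media(network, med)
    if (!aerobic) net <- apply_anaerobic_mods(net)
    sol <- tryCatch(solve_fba(net, minimize_fluxes = FALSE, eps = eps),
                    error = function(e) NULL)
    if (is.null(sol)) return("error")
    if (sol$status == "infeasible") return("no-growth")
    if (sol$status != "optimal") return("error")
    if (sol$growth) "growth" else "no-growth"
  })
  per <- scored
  per$sim_call <- sim
  errs <- per[per$sim_call == "error", ]
  per <- per[per$sim_call != "error", ]
  per$category <- dplyr::case_when(
    per$sim_call == "growth" & per$consensus == "positive" ~ "tp",
    per$sim_call == "growth" & per$consensus == "negative" ~ "fp",
    per$sim_call == "no-growth" & per$consensus == "positive" ~ "fn",
    TRUE ~ "tn")
  k <- table(factor(per$category, levels = c("tp", "fp", "fn", "tn")))
  structure(
    list(per_well = per, no_consensus = no_cons, failed = errs,
         stats = confusion_stats(k[["tp"]], k[["fp"]], k[["fn"]], k[["tn"]])),
    class = "screen_result")
}
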