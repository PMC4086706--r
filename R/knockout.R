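#' Simulate a gene knockout on a flux network
#'
#' All reactions gene-disabled by the knockout set (see
#' [gene_disabled_reactions()]) are removed from a copy of the network
#' (bounds pinned to zero) and the network is re-solved. Following the
#' screening convention, any growth at all (`objective > eps`) scores the
#' knockout nonessential; a blocked biomass scores it essential. The taxicab
#' stage is skipped by default during knockouts since the growth call depends
#' only on the stage-1 optimum.
#'
#' @param network A `flux_network` with a biomass (or other) objective.
#' @param model The `flux_model` the network was built from (carries the
#'   gene-product associations).
#' @param genes Character vector: one gene, or a set for a multi-gene
#'   knockout.
#' @param minimize_fluxes Run the taxicab stage (default `FALSE`).
#' @param eps Growth threshold.
#' @return An `fba_solution` with extra fields `knockout` (the gene set) and
#'   `disabled_reactions`.
#' @examples
#' net <- fixture_growth_network()
#' simulate_knockout(net, fixture_fermentation(), "gapA")$growth
#' @export
simulate_knockout <- function(network, model, genes, minimize_fluxes = FALSE,
                              eps = 1e-6) {
  stopifnot(inherits(network, "flux_network"))
  disabled <- gene_disabled_reactions(model, genes)
  hit <- network$reactions$source_id %in% disabled
  network$reactions$lb[hit] <- 0
  network$reactions$ub[hit] <- 0
  sol <- solve_fba(network, minimize_fluxes = minimize_fluxes, eps = eps)
  sol$knockout <- genes
  sol$disabled_reactions <- disabled
  sol
}

#' Experimental essentiality criteria
#'
#' Narrow criteria: a deletion strain is essential when OD600 is at or below
#' 0.005 after both 24 and 48 hours on minimal medium (no perceptible growth
#' over a long period). Broad criteria: essential when OD600 is at or below
#' 0.091 after 24 hours (impaired growth over a shorter period; captures the
#' severe-growth-defect population the narrow criteria miss). Boundary
#' equality classifies as essential.
#'
#' @param mode `"narrow"` or `"broad"`.
#' @return An `essentiality_criteria` object.
#' @export
essentiality_criteria <- function(mode = c("narrow", "broad")) {
  mode <- match.arg(mode)
  structure(list(mode = mode,
                 threshold = if (mode == "narrow") 0.005 else 0.091),
            class = "essentiality_criteria")
}

#' Classify experimental observations as essential or nonessential
#'
#' @param observations Tibble with columns `gene`, `od600_24h`, and (for the
#'   narrow criteria) `od600_48h`.
#' @param criteria An [essentiality_criteria()] object.
#' @return The input with an added `exp_call` column
#'   (`"essential"`/`"nonessential"`).
#' @examples
#' obs <- tibble::tibble(gene = c("cysN", "cysD"), od600_24h = c(0.088, 0.104))
#' classify_experimental(obs, essentiality_criteria("broad"))
#' @export
classify_experimental <- function(observations, criteria) {
  stopifnot(inherits(criteria, "essentiality_criteria"))
  obs <- tibble::as_tibble(observations)
  if (criteria$mode == "narrow") {
    if (!"od600_48h" %in% names(obs) || anyNA(obs$od600_48h)) {
      stop("narrow criteria require 48 hr OD600 for every observation",
           call. = FALSE)
    }
    ess <- obs$od600_24h <= criteria$threshold &
      obs$od600_48h <= criteria$threshold
  } else {
    ess <- obs$od600_24h <= criteria$threshold
  }
  obs$exp_call <- ifelse(ess, "essential", "nonessential")
  obs
}

#' Confusion matrix statistics in the growth-positive orientation
#'
#' Positive means growth: `tp` = simulated growth with experimental growth,
#' `fp` = simulated growth with experimental no-growth, `fn` = simulated
#' no-growth with experimental growth, `tn` = simulated no-growth with
#' experimental no-growth. Sensitivity is the percentage of gene deletions
#' (or media) resulting in growth that the simulation identifies;
#' specificity the percentage of no-growth outcomes identified. Percentages
#' are rounded half-up to one decimal.
#'
#' @param tp,fp,fn,tn Non-negative integer counts.
#' @return One-row tibble: counts, `total`, `correct`, `accuracy`,
#'   `sensitivity`, `specificity` (percent).
#' @examples
#' confusion_stats(1175, 58, 12, 200)   # 95.2 / 99.0 / 77.5
#' @export
confusion_stats <- function(tp, fp, fn, tn) {
  stopifnot(tp >= 0, fp >= 0, fn >= 0, tn >= 0)
  total <- tp + fp + fn + tn
  tibble::tibble(
    tp = tp, fp = fp, fn = fn, tn = tn, total = total, correct = tp + tn,
    accuracy = round_half_up(100 * (tp + tn) / total, 1),
    sensitivity = round_half_up(100 * tp / (tp + fn), 1),
    specificity = round_half_up(100 * tn / (tn + fp), 1))
}

round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

#' Single-gene knockout essentiality screen
#'
#' Simulates every gene knockout on the configured medium, classifies the
#' experimental table under the chosen criteria, and tabulates agreement in
#' the growth-positive confusion-matrix orientation. Iteration order is the
#' sorted gene list, so screens are deterministic. Genes without
#' experimental data are reported in `unscored` and excluded from the
#' matrix.
#'
#' @param network A `flux_network` with biomass and nutrients configured for
#'   the medium under test.
#' @param model The source `flux_model`.
#' @param experimental Tibble `(gene, od600_24h, od600_48h, ...)`.
#' @param criteria An [essentiality_criteria()].
#' @param genes Genes to screen (default: all model genes).
#' @param eps Growth threshold.
#' @return A `screen_result`: `per_gene` tibble (gene, sim_call, exp_call,
#'   category), `stats` (one-row [confusion_stats()] output), `unscored`.
#' @export
ko_screen <- function(network, model, experimental,
                      criteria = essentiality_criteria("broad"),
                      genes = NULL, eps = 1e-6) {
  genes <- sort(if (is.null(genes)) model_genes(model) else genes)
  exp_cls <- classify_experimental(experimental, criteria)
  sim <- purrr::map_chr(genes, function(g) {
    sol <- simulate_knockout(network, model, g, eps = eps)
    if (sol$status != "optimal") {
      if (sol$status == "infeasible") "essential" else
        stop("solver status ", sol$status, " for knockout ", g, call. = FALSE)
    } else if (sol$growth) "nonessential" else "essential"
  })
  per <- tibble::tibble(gene = genes, sim_call = sim)
  per <- dplyr::left_join(per, exp_cls[, c("gene", "exp_call")], by = "gene")
  unscored <- per$gene[is.na(per$exp_call)]
  scored <- per[!is.na(per$exp_call), ]
  scored$category <- dplyr::case_when(
    scored$sim_call == "nonessential" & scored$exp_call == "nonessential" ~ "tp",
    scored$sim_call == "nonessential" & scored$exp_call == "essential" ~ "fp",
    scored$sim_call == "essential" & scored$exp_call == "nonessential" ~ "fn",
    TRUE ~ "tn")
  k <- table(factor(scored$category, levels = c("tp", "fp", "fn", "tn")))
  structure(
    list(per_gene = scored, unscored = unscored,
         stats = confusion_stats(k[["tp"]], k[["fp"]], k[["fn"]], k[["tn"]]),
         criteria = criteria),
    class = "screen_result")
}

#' @export
print.screen_result <- function(x, ...) {
  s <- x$stats
  cat("<screen_result> n = ", s$total, " (", s$correct, " correct): accuracy ",
      format_percent(s$accuracy), ", sensitivity ", format_percent(s$sensitivity),
      ", specificity ", format_percent(s$specificity), "\n", sep = "")
  invisible(x)
}

format_percent <- function(x) sprintf("%.1f%%", x)
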