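#' Reactions disabled by a gene knockout set
#'
#' A reaction is gene-disabled by a knockout set when every one of its
#' catalyst units contains at least one knocked-out gene (a complex is lost
#' when any subunit is lost; isozyme units rescue each other), or when a
#' substrate-supplier gene with no alternative declared supplier for the same
#' substrate is knocked out. Reactions with no catalyst units are spontaneous
#' or orphan and are never disabled via catalysis.
#'
#' @param model A `flux_model`.
#' @param knockout Character vector of gene ids (one gene or a set).
#' @return Character vector of disabled reaction ids (possibly empty).
#' @examples
#' m <- fixture_fermentation()
#' gene_disabled_reactions(m, "gapA")
#' @export
gene_disabled_reactions <- function(model, knockout) {
  stopifnot(inherits(model, "flux_model"))
  knockout <- unique(as.character(knockout))
  known <- model_genes(model)
  missing <- setdiff(knockout, known)
  if (length(missing)) {
    warning("gene(s) not in any association: ", paste(missing, collapse = ", "),
            call. = FALSE)
  }
  disabled <- character()
  if (nrow(model$gpr)) {
    units <- dplyr::summarise(
      dplyr::group_by(model$gpr, .data$reaction_id, .data$unit),
      dead = any(.data$gene %in% knockout), .groups = "drop"
    )
    rxns <- dplyr::summarise(
      dplyr::group_by(units, .data$reaction_id),
      all_dead = all(.data$dead), .groups = "drop"
    )
    disabled <- rxns$reaction_id[rxns$all_dead]
  }
  if (nrow(model$suppliers)) {
    subs <- dplyr::summarise(
      dplyr::group_by(model$suppliers, .data$reaction_id, .data$substrate),
      lost = all(.data$gene %in% knockout), .groups = "drop"
    )
    disabled <- union(disabled, unique(subs$reaction_id[subs$lost]))
  }
  sort(disabled)
}
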