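#' Instantiate compound-class reactions
#'
#' Reactions written against compound classes (generic reactants such as "an
#' alcohol") are replaced by the set of concrete reactions obtained by binding
#' every class participant to one of its declared instances, keeping only
#' bindings whose instance reaction is mass-balanced. The same class appearing
#' on both sides of a reaction binds to a single instance (paired binding).
#' Reactions whose binding space exceeds `cap` permutations are rejected with
#' category `"permutation-cap"`; reactions with a class slot admitting no
#' mass-balanced binding (including classes with empty instance lists) are
#' rejected as `"ambiguous-instantiation"`.
#'
#' @param model A `flux_model`.
#' @param reaction_id Reaction id to instantiate.
#' @param cap Maximum number of candidate bindings to enumerate (default
#'   10000).
#' @param check_charge Passed to the balance check applied to each candidate.
#' @return A list with `reactions` (tibble of instance reactions: `id`,
#'   `source_id`, `binding` list-column) and `stoich` (their stoichiometry),
#'   or, on rejection, `reactions` empty and `rejected` giving the category.
#'   A reaction with no class participants is returned unchanged as its own
#'   single instance.
#' @export
instantiate_classes <- function(model, reaction_id, cap = 10000, check_charge = TRUE) {
  stopifnot(inherits(model, "flux_model"), cap >= 1)
  s <- model$stoich[model$stoich$reaction_id == reaction_id, ]
  if (!nrow(s)) stop("unknown reaction id: ", reaction_id, call. = FALSE)
  idx <- match(s$metabolite_id, model$metabolites$id)
  cls <- unique(s$metabolite_id[model$metabolites$is_class[idx]])
  if (!length(cls)) {
    return(list(
      reactions = tibble::tibble(id = reaction_id, source_id = reaction_id,
                                 binding = list(character())),
      stoich = s, rejected = NULL
    ))
  }
  inst_lists <- lapply(cls, function(cid) {
    model$metabolites$instances[[match(cid, model$metabolites$id)]]
  })
  names(inst_lists) <- cls
  if (any(lengths(inst_lists) == 0)) {
    return(list(reactions = tibble::tibble(), stoich = tibble::tibble(),
                rejected = "ambiguous-instantiation"))
  }
  n_perm <- prod(lengths(inst_lists))
  if (n_perm > cap) {
    return(list(reactions = tibble::tibble(), stoich = tibble::tibble(),
                rejected = "permutation-cap"))
  }
  grid <- expand.grid(inst_lists, stringsAsFactors = FALSE,
                      KEEP.OUT.ATTRS = FALSE)
  kept_r <- list(); kept_s <- list(); k <- 0L
  for (i in seq_len(nrow(grid))) {
    binding <- stats::setNames(as.character(grid[i, ]), cls)
    si <- s
    si$metabolite_id <- ifelse(si$metabolite_id %in% cls,
                               binding[si$metabolite_id], si$metabolite_id)
    # paired binding can merge a consumed and produced slot of the same class
    agg <- stats::aggregate(coef ~ metabolite_id, data = si, FUN = sum)
    agg <- agg[abs(agg$coef) > 1e-12, , drop = FALSE]
    if (!nrow(agg)) next
    tmp_id <- paste0(reaction_id, "//", k + 1L)
    probe <- model
    probe$stoich <- tibble::tibble(reaction_id = tmp_id,
                                   metabolite_id = agg$metabolite_id,
                                   coef = agg$coef)
    probe$reactions <- tibble::tibble(
      id = tmp_id, direction = model$reactions$direction[model$reactions$id == reaction_id],
      relevant = TRUE, spontaneous = FALSE, flags = list(character()))
    st <- check_mass_balance(probe, tmp_id, check_charge = check_charge)$status
    if (st != "balanced") next
    k <- k + 1L
    iid <- paste0(reaction_id, "//", paste(binding, collapse = "+"))
    kept_r[[k]] <- tibble::tibble(id = iid, source_id = reaction_id,
                                  binding = list(binding))
    kept_s[[k]] <- tibble::tibble(reaction_id = iid,
                                  metabolite_id = agg$metabolite_id,
                                  coef = agg$coef)
  }
  if (k == 0L) {
    return(list(reactions = tibble::tibble(), stoich = tibble::tibble(),
                rejected = "ambiguous-instantiation"))
  }
  list(reactions = dplyr::bind_rows(kept_r), stoich = dplyr::bind_rows(kept_s),
       rejected = NULL)
}
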