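#' Assemble a flux model definition from its component tables
#'
#' A `flux_model` is the database-like description of a metabolic system
#' before network construction: metabolites (with formula, charge and
#' compartment), reactions (direction, physiological-relevance and type
#' flags), signed stoichiometry, gene-product associations, and compartments.
#' All tables are tibbles; referential integrity across id columns is
#' enforced at construction.
#'
#' @param metabolites Tibble with columns `id` (unique), `name`, `formula`
#'   (Hill-notation string or `NA` for structure-unknown), `charge` (integer
#'   or `NA`), `compartment`, and optionally `is_class` (logical) and
#'   `instances` (list-column of metabolite ids, non-empty only for classes).
#' @param reactions Tibble with columns `id` (unique), `direction` (one of
#'   `"forward"`, `"reverse"`, `"reversible"`), and optionally `relevant`
#'   (logical, default `TRUE`), `spontaneous` (logical, default `FALSE`), and
#'   `flags` (list-column with subsets of `"polymerization"`,
#'   `"polymer-segment"`, `"protein-modification"`, `"variable-stoichiometry"`).
#' @param stoich Long tibble `(reaction_id, metabolite_id, coef)`; negative
#'   coefficients are consumed, positive produced; zero coefficients are
#'   rejected.
#' @param gpr Optional tibble `(reaction_id, unit, gene)`. Rows sharing a
#'   `(reaction_id, unit)` pair form one catalyst unit (a complex: all genes
#'   required); multiple units on a reaction are isozymes (any unit suffices).
#' @param suppliers Optional tibble `(reaction_id, substrate, gene)` of genes
#'   whose products supply a reaction substrate (e.g. carrier proteins);
#'   alternative suppliers are rows sharing `(reaction_id, substrate)`.
#' @param compartments Tibble with column `id`; defaults to cytosol `"c"`,
#'   periplasm `"p"`, extracellular `"e"`.
#' @return An object of class `flux_model`.
#' @export
flux_model <- function(metabolites, reactions, stoich, gpr = NULL,
                       suppliers = NULL, compartments = NULL) {
  metabolites <- tibble::as_tibble(metabolites)
  reactions <- tibble::as_tibble(reactions)
  stoich <- tibble::as_tibble(stoich)
  if (is.null(compartments)) {
    compartments <- tibble::tibble(
      id = c("c", "p", "e"),
      name = c("cytosol", "periplasm", "extracellular")
    )
  }
  compartments <- tibble::as_tibble(compartments)
  if (!"charge" %in% names(metabolites)) metabolites$charge <- NA_integer_
  if (!"name" %in% names(metabolites)) metabolites$name <- metabolites$id
  if (!"is_class" %in% names(metabolites)) metabolites$is_class <- FALSE
  if (!"instances" %in% names(metabolites)) {
    metabolites$instances <- rep(list(character()), nrow(metabolites))
  }
  metabolites$charge <- as.integer(metabolites$charge)
  if (!"relevant" %in% names(reactions)) reactions$relevant <- TRUE
  if (!"spontaneous" %in% names(reactions)) reactions$spontaneous <- FALSE
  if (!"flags" %in% names(reactions)) {
    reactions$flags <- rep(list(character()), nrow(reactions))
  }
  gpr <- if (is.null(gpr)) {
    tibble::tibble(reaction_id = character(), unit = integer(), gene = character())
  } else tibble::as_tibble(gpr)
  suppliers <- if (is.null(suppliers)) {
    tibble::tibble(reaction_id = character(), substrate = character(), gene = character())
  } else tibble::as_tibble(suppliers)

  if (anyDuplicated(metabolites$id)) {
    stop("duplicate metabolite ids: ",
         paste(unique(metabolites$id[duplicated(metabolites$id)]), collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(reactions$id)) {
    stop("duplicate reaction ids: ",
         paste(unique(reactions$id[duplicated(reactions$id)]), collapse = ", "),
         call. = FALSE)
  }
  bad_cpt <- setdiff(metabolites$compartment, compartments$id)
  if (length(bad_cpt)) {
    stop("undeclared compartment(s): ", paste(bad_cpt, collapse = ", "), call. = FALSE)
  }
  bad_met <- setdiff(stoich$metabolite_id, metabolites$id)
  if (length(bad_met)) {
    stop("stoichiometry references unknown metabolite(s): ",
         paste(bad_met, collapse = ", "), call. = FALSE)
  }
  bad_rxn <- setdiff(stoich$reaction_id, reactions$id)
  if (length(bad_rxn)) {
    stop("stoichiometry references unknown reaction(s): ",
         paste(bad_rxn, collapse = ", "), call. = FALSE)
  }
  if (any(stoich$coef == 0)) stop("zero stoichiometric coefficients are not allowed", call. = FALSE)
  empty <- setdiff(reactions$id, stoich$reaction_id)
  if (length(empty)) {
    stop("reaction(s) with empty stoichiometry: ", paste(empty, collapse = ", "), call. = FALSE)
  }
  bad_dir <- setdiff(reactions$direction, c("forward", "reverse", "reversible"))
  if (length(bad_dir)) stop("unknown direction value(s): ", paste(bad_dir, collapse = ", "), call. = FALSE)
  noclass <- !metabolites$is_class & lengths(metabolites$instances) > 0
  if (any(noclass)) {
    stop("non-class metabolite(s) with instances: ",
         paste(metabolites$id[noclass], collapse = ", "), call. = FALSE)
  }
  bad_inst <- setdiff(unlist(metabolites$instances), metabolites$id)
  if (length(bad_inst)) {
    stop("class instance(s) not declared as metabolites: ",
         paste(bad_inst, collapse = ", "), call. = FALSE)
  }
  bad_gpr <- setdiff(gpr$reaction_id, reactions$id)
  if (length(bad_gpr)) {
    stop("gene association references unknown reaction(s): ",
         paste(bad_gpr, collapse = ", "), call. = FALSE)
  }

  structure(
    list(metabolites = metabolites, reactions = reactions, stoich = stoich,
         gpr = gpr, suppliers = suppliers, compartments = compartments),
    class = "flux_model"
  )
}

#' @export
print.flux_model <- function(x, ...) {
  n_class <- sum(x$metabolites$is_class)
  cat("<flux_model> ", nrow(x$reactions), " reactions, ",
      nrow(x$metabolites), " metabolites (", n_class, " classes), ",
      length(unique(x$gpr$gene)), " genes, ",
      nrow(x$compartments), " compartments\n", sep = "")
  invisible(x)
}

#' All genes referenced by a model's gene-product associations
#'
#' @param model A `flux_model`.
#' @return Character vector of gene ids (catalysts and substrate suppliers).
#' @export
model_genes <- function(model) {
  stopifnot(inherits(model, "flux_model"))
  sort(unique(c(model$gpr$gene, model$suppliers$gene)))
}

# Look up element-count vectors (NULL = unknown) for a set of metabolite ids.
met_elements <- function(metabolites, ids) {
  idx <- match(ids, metabolites$id)
  lapply(metabolites$formula[idx], function(f) {
    if (is.na(f) || !nzchar(f)) NULL else parse_formula(f)
  })
}
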