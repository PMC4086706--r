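#' Parse a reaction equation string
#'
#' Grammar: `"2 A[c] + B[p] -> C[c]"`. Terms are `+`-separated, each an
#' optional positive (possibly fractional) coefficient followed by a
#' metabolite id carrying its compartment suffix (`[c]`, `[p]`, `[e]`; a
#' bare id means cytosol). Arrows: `->` irreversible forward, `<-`
#' irreversible reverse, `<->` reversible.
#'
#' @param equation A single equation string.
#' @return List with `stoich` (tibble `metabolite_id`, `coef`; negative =
#'   consumed) and `direction`.
#' @examples
#' parse_reaction_equation("2 A[c] + B[p] -> C[c]")
#' @export
parse_reaction_equation <- function(equation) {
  arrow <- regmatches(equation, regexpr("<->|->|<-", equation))
  if (!length(arrow)) stop("no reaction arrow in: ", equation, call. = FALSE)
  direction <- switch(arrow, "->" = "forward", "<-" = "reverse",
                      "<->" = "reversible")
  sides <- strsplit(equation, "<->|->|<-")[[1]]
  if (length(sides) != 2) stop("malformed equation: ", equation, call. = FALSE)
  parse_side <- function(side, sgn) {
    side <- trimws(side)
    if (!nzchar(side)) return(NULL)
    terms <- trimws(strsplit(side, " \\+ ")[[1]])
    out <- lapply(terms, function(tm) {
      m <- regmatches(tm, regexec("^([0-9]*\\.?[0-9]+[ ]+)?(.+)$", tm))[[1]]
      coef <- if (nzchar(trimws(m[2]))) as.numeric(trimws(m[2])) else 1
      id <- trimws(m[3])
      if (!grepl("\\[[^]]+\\]$", id)) id <- paste0(id, "[c]")
      tibble::tibble(metabolite_id = id, coef = sgn * coef)
    })
    dplyr::bind_rows(out)
  }
  st <- dplyr::bind_rows(parse_side(sides[1], -1), parse_side(sides[2], 1))
  if (!nrow(st)) stop("empty equation: ", equation, call. = FALSE)
  st <- dplyr::summarise(dplyr::group_by(st, .data$metabolite_id),
                         coef = sum(.data$coef), .groups = "drop")
  st <- st[st$coef != 0, ]
  list(stoich = st, direction = direction)
}

format_coef <- function(x) {
  ifelse(abs(x - round(x)) < 1e-12, format(round(x)), format(x))
}

#' Format one reaction's stoichiometry as an equation string
#'
#' @param stoich Tibble with `metabolite_id`, `coef` for a single reaction.
#' @param direction Reaction direction.
#' @return The equation string in the grammar of [parse_reaction_equation()].
#' @export
format_reaction_equation <- function(stoich, direction = "forward") {
  side <- function(rows) {
    if (!nrow(rows)) return("")
    co <- abs(rows$coef)
    paste(ifelse(abs(co - 1) < 1e-12, rows$metabolite_id,
                 paste(format_coef(co), rows$metabolite_id)),
          collapse = " + ")
  }
  arrow <- switch(direction, forward = "->", reverse = "<-",
                  reversible = "<->")
  paste(side(stoich[stoich$coef < 0, ]), arrow,
        side(stoich[stoich$coef > 0, ]))
}

# "a and b or c" -> catalyst units; " or " separates units, " and " joins
# genes within a unit.
parse_gpr_strings <- function(reaction_ids, gpr_strings) {
  rows <- list()
  for (i in seq_along(reaction_ids)) {
    g <- gpr_strings[i]
    if (is.na(g) || !nzchar(trimws(g))) next
    units <- trimws(strsplit(g, " or ")[[1]])
    for (u in seq_along(units)) {
      genes <- trimws(strsplit(units[u], " and ")[[1]])
      rows[[length(rows) + 1L]] <- tibble::tibble(
        reaction_id = reaction_ids[i], unit = u, gene = genes)
    }
  }
  if (!length(rows)) {
    return(tibble::tibble(reaction_id = character(), unit = integer(),
                          gene = character()))
  }
  dplyr::bind_rows(rows)
}

format_gpr_string <- function(gpr_rows) {
  if (!nrow(gpr_rows)) return(NA_character_)
  units <- split(gpr_rows$gene, gpr_rows$unit)
  paste(vapply(units, paste, character(1), collapse = " and "),
        collapse = " or ")
}

#' Read and write model definition tables
#'
#' The on-disk dialect is three tab-separated files in `dir`:
#' `metabolites.tsv` (id, name, formula, charge, compartment, class,
#' instances — instances comma-separated), `reactions.tsv` (id, equation,
#' direction, flags — flags comma-separated, plus relevant / spontaneous
#' logicals), and `gpr.tsv` (reaction_id, catalysts in
#' `"a and b or c"` syntax, suppliers as `"substrate:gene1|gene2;..."`).
#' Writing then reading reproduces an equal model.
#'
#' @param dir Directory containing (or to receive) the three files.
#' @return `read_model_tsv()` returns a `flux_model`; `write_model_tsv()`
#'   returns `dir` invisibly.
#' @export
read_model_tsv <- function(dir) {
  rd <- function(f) utils::read.delim(file.path(dir, f), sep = "\t",
                                      stringsAsFactors = FALSE,
                                      na.strings = "NA",
                                      check.names = FALSE)
  met <- tibble::as_tibble(rd("metabolites.tsv"))
  met$formula <- as.character(met$formula)
  met$is_class <- as.logical(met$class)
  met$instances <- lapply(met$instances, function(x) {
    if (is.na(x) || !nzchar(x)) character() else strsplit(x, ",")[[1]]
  })
  met$class <- NULL
  rxn <- tibble::as_tibble(rd("reactions.tsv"))
  parsed <- lapply(seq_len(nrow(rxn)), function(i) {
    tryCatch(parse_reaction_equation(rxn$equation[i]),
             error = function(e) stop("reactions.tsv line ", i + 1, ": ",
                                      conditionMessage(e), call. = FALSE))
  })
  st <- dplyr::bind_rows(lapply(seq_along(parsed), function(i) {
    tibble::tibble(reaction_id = rxn$id[i],
                   metabolite_id = parsed[[i]]$stoich$metabolite_id,
                   coef = parsed[[i]]$stoich$coef)
  }))
  reactions <- tibble::tibble(
    id = rxn$id,
    direction = if ("direction" %in% names(rxn)) rxn$direction else
      vapply(parsed, `[[`, character(1), "direction"),
    relevant = if ("relevant" %in% names(rxn)) as.logical(rxn$relevant) else TRUE,
    spontaneous = if ("spontaneous" %in% names(rxn))
      as.logical(rxn$spontaneous) else FALSE,
    flags = lapply(if ("flags" %in% names(rxn)) rxn$flags else
      rep(NA_character_, nrow(rxn)), function(x) {
        if (is.na(x) || !nzchar(x)) character() else strsplit(x, ",")[[1]]
      }))
  gpr <- NULL; suppliers <- NULL
  gf <- file.path(dir, "gpr.tsv")
  if (file.exists(gf)) {
    g <- tibble::as_tibble(rd("gpr.tsv"))
    gpr <- parse_gpr_strings(g$reaction_id, as.character(g$catalysts))
    sup_rows <- list()
    if ("suppliers" %in% names(g)) {
      for (i in seq_len(nrow(g))) {
        sv <- g$suppliers[i]
        if (is.na(sv) || !nzchar(sv)) next
        for (chunk in strsplit(sv, ";")[[1]]) {
          kv <- strsplit(chunk, ":")[[1]]
          sup_rows[[length(sup_rows) + 1L]] <- tibble::tibble(
            reaction_id = g$reaction_id[i], substrate = kv[1],
            gene = strsplit(kv[2], "\\|")[[1]])
        }
      }
    }
    suppliers <- if (length(sup_rows)) dplyr::bind_rows(sup_rows) else NULL
  }
  flux_model(met, reactions, st, gpr = gpr, suppliers = suppliers)
}

#' @rdname read_model_tsv
#' @param model A `flux_model` to serialize.
#' @export
write_model_tsv <- function(model, dir) {
  stopifnot(inherits(model, "flux_model"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  met <- model$metabolites
  met_out <- data.frame(
    id = met$id, name = met$name, formula = met$formula, charge = met$charge,
    compartment = met$compartment, class = met$is_class,
    instances = vapply(met$instances, paste, character(1), collapse = ","),
    stringsAsFactors = FALSE)
  utils::write.table(met_out, file.path(dir, "metabolites.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, na = "NA")
  eqs <- vapply(model$reactions$id, function(rid) {
    format_reaction_equation(
      model$stoich[model$stoich$reaction_id == rid, ],
      model$reactions$direction[model$reactions$id == rid])
  }, character(1))
  rxn_out <- data.frame(
    id = model$reactions$id, equation = unname(eqs),
    direction = model$reactions$direction,
    relevant = model$reactions$relevant,
    spontaneous = model$reactions$spontaneous,
    flags = vapply(model$reactions$flags, paste, character(1), collapse = ","),
    stringsAsFactors = FALSE)
  utils::write.table(rxn_out, file.path(dir, "reactions.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, na = "NA")
  gids <- unique(c(model$gpr$reaction_id, model$suppliers$reaction_id))
  gpr_out <- data.frame(
    reaction_id = gids,
    catalysts = vapply(gids, function(rid) {
      format_gpr_string(model$gpr[model$gpr$reaction_id == rid, ])
    }, character(1)),
    suppliers = vapply(gids, function(rid) {
      sp <- model$suppliers[model$suppliers$reaction_id == rid, ]
      if (!nrow(sp)) return(NA_character_)
      paste(vapply(split(sp, sp$substrate), function(d) {
        paste0(d$substrate[1], ":", paste(d$gene, collapse = "|"))
      }, character(1)), collapse = ";")
    }, character(1)),
    stringsAsFactors = FALSE)
  utils::write.table(gpr_out, file.path(dir, "gpr.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, na = "NA")
  invisible(dir)
}
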