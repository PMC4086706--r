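#' Read and write declarative run-configuration files
#'
#' The run file mirrors the layout of declarative FBA configuration files:
#' bracketed sections `[nutrients]` (metabolite id, optional uptake bound),
#' `[secretions]` (metabolite id), `[biomass]` (metabolite id, coefficient),
#' and `[options]` (key/value pairs: `minimize-fluxes` yes/no, `objective`,
#' `gam`, `ngam`, `eps`, `cap`, `default-bound`, `seed`). Lines starting
#' with `#` are comments. A run is reproducible from its configuration
#' alone.
#'
#' @param path File path.
#' @return `read_run_config()` returns a `run_config` list with elements
#'   `nutrients`, `secretions` (both `metabolite_set`), `biomass` (tibble),
#'   and `options` (named list).
#' @export
read_run_config <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  section <- NA_character_
  nutr <- list(); secr <- list(); biom <- list(); opts <- list()
  for (ln in lines) {
    if (grepl("^\\[.*\\]$", ln)) { section <- gsub("\\[|\\]", "", ln); next }
    parts <- strsplit(ln, "\t| +")[[1]]
    if (is.na(section)) stop("entry before any section: ", ln, call. = FALSE)
    switch(section,
      nutrients = {
        nutr[[length(nutr) + 1L]] <- tibble::tibble(
          metabolite_id = parts[1],
          coef = if (length(parts) > 1) as.numeric(parts[2]) else NA_real_)
      },
      secretions = {
        secr[[length(secr) + 1L]] <- tibble::tibble(metabolite_id = parts[1])
      },
      biomass = {
        biom[[length(biom) + 1L]] <- tibble::tibble(
          metabolite_id = parts[1], coef = as.numeric(parts[2]))
      },
      options = { opts[[parts[1]]] <- paste(parts[-1], collapse = " ") },
      stop("unknown section: ", section, call. = FALSE))
  }
  nut_tb <- dplyr::bind_rows(nutr)
  sec_tb <- dplyr::bind_rows(secr)
  structure(list(
    nutrients = if (nrow(nut_tb)) metabolite_set(nut_tb$metabolite_id,
                                                 nut_tb$coef) else NULL,
    secretions = if (nrow(sec_tb)) metabolite_set(sec_tb$metabolite_id) else NULL,
    biomass = if (length(biom)) dplyr::bind_rows(biom) else NULL,
    options = opts), class = "run_config")
}

#' @rdname read_run_config
#' @param config A `run_config` (or compatible list).
#' @export
write_run_config <- function(config, path) {
  out <- character()
  if (!is.null(config$nutrients)) {
    out <- c(out, "[nutrients]",
             paste0(config$nutrients$metabolite_id,
                    ifelse(is.na(config$nutrients$coef), "",
                           paste0("\t", config$nutrients$coef))))
  }
  if (!is.null(config$secretions)) {
    out <- c(out, "[secretions]", config$secretions$metabolite_id)
  }
  if (!is.null(config$biomass)) {
    out <- c(out, "[biomass]",
             paste0(config$biomass$metabolite_id, "\t", config$biomass$coef))
  }
  if (length(config$options)) {
    out <- c(out, "[options]",
             paste0(names(config$options), "\t", unlist(config$options)))
  }
  writeLines(out, path)
  invisible(path)
}

#' Write a plain-text solution report
#'
#' Lists solver status, the objective, all nonzero fluxes sorted by
#' decreasing magnitude, and an exchange-flux summary (production positive,
#' uptake negative).
#'
#' @param solution An `fba_solution`.
#' @param path Output file.
#' @param network The solved network (used to identify exchanges); optional.
#' @return `path`, invisibly.
#' @export
write_solution_report <- function(solution, path, network = NULL) {
  fl <- solution$fluxes[order(-abs(solution$fluxes$flux)), ]
  fl <- fl[!is.na(fl$flux) & fl$flux != 0, ]
  lines <- c(
    paste0("status\t", solution$status),
    paste0("objective\t", solution$objective_id, "\t",
           format(solution$objective_value, digits = 10)),
    paste0("growth\t", tolower(solution$growth)),
    if (!is.na(solution$mu)) paste0("mu\t", format(solution$mu, digits = 10)),
    if (!is.na(solution$sum_abs_flux))
      paste0("sum_abs_flux\t", format(solution$sum_abs_flux, digits = 10)),
    "", "# nonzero fluxes (mmol/gCDW/hr)",
    paste0(fl$reaction_id, "\t", format(fl$flux, digits = 10, trim = TRUE)))
  if (!is.null(network)) {
    ex <- network$reactions[network$reactions$kind %in% c("uptake", "efflux"), ]
    if (nrow(ex)) {
      f <- solution$fluxes$flux[match(ex$id, solution$fluxes$reaction_id)]
      sgn <- ifelse(ex$kind == "uptake", -1, 1)
      mid <- sub("^(UPTAKE|SECRETION)\\[(.*)\\]$", "\\2", ex$id)
      lines <- c(lines, "", "# exchange fluxes (production positive)",
                 paste0(mid, "\t", format(sgn * f, digits = 10, trim = TRUE)))
    }
  }
  writeLines(lines, path)
  invisible(path)
}
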