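#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy methods for solved and screened objects
#'
#' `tidy()` returns the per-unit table (fluxes for a solution, per-gene or
#' per-well calls for a screen); `glance()` a one-row summary.
#'
#' @param x An `fba_solution` or `screen_result`.
#' @param nonzero For solutions: keep only nonzero fluxes (default `FALSE`).
#' @param ... Unused.
#' @return A tibble.
#' @name tidiers
NULL

#' @rdname tidiers
#' @export
tidy.fba_solution <- function(x, nonzero = FALSE, ...) {
  fl <- x$fluxes
  if (nonzero) fl <- fl[!is.na(fl$flux) & fl$flux != 0, ]
  fl
}

#' @rdname tidiers
#' @export
glance.fba_solution <- function(x, ...) {
  tibble::tibble(status = x$status, objective = x$objective_value,
                 growth = x$growth, mu = x$mu,
                 sum_abs_flux = x$sum_abs_flux, minimized = x$minimized)
}

#' @rdname tidiers
#' @export
tidy.screen_result <- function(x, ...) {
  if (!is.null(x$per_gene)) x$per_gene else x$per_well
}

#' @rdname tidiers
#' @export
glance.screen_result <- function(x, ...) x$stats
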