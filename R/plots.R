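#' Plot methods
#'
#' `autoplot()` on an `fba_solution` draws the largest-magnitude fluxes as a
#' horizontal bar chart; on a `screen_result` it draws the confusion matrix
#' as a tile plot. [plot_flux_sweep()] draws selected reaction fluxes along
#' a swept exchange bound.
#'
#' @param object An `fba_solution` or `screen_result`.
#' @param n Number of reactions to show (solutions; default 20).
#' @param ... Unused.
#' @return A ggplot object.
#' @name plots
NULL

#' @rdname plots
#' @importFrom ggplot2 autoplot
#' @export
autoplot.fba_solution <- function(object, n = 20, ...) {
  fl <- object$fluxes[!is.na(object$fluxes$flux) & object$fluxes$flux != 0, ]
  fl <- fl[order(-abs(fl$flux)), ][seq_len(min(n, nrow(fl))), ]
  fl$reaction_id <- stats::reorder(fl$reaction_id, abs(fl$flux))
  ggplot2::ggplot(fl, ggplot2::aes(x = .data$flux, y = .data$reaction_id)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "flux (mmol/gCDW/hr)", y = NULL,
                  title = paste0("objective ", object$objective_id, " = ",
                                 signif(object$objective_value, 6)))
}

#' @rdname plots
#' @export
autoplot.screen_result <- function(object, ...) {
  s <- object$stats
  df <- tibble::tibble(
    sim = factor(c("growth", "growth", "no-growth", "no-growth"),
                 levels = c("growth", "no-growth")),
    exp = factor(c("growth", "no-growth", "growth", "no-growth"),
                 levels = c("no-growth", "growth")),
    n = c(s$tp, s$fp, s$fn, s$tn))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$sim, y = .data$exp)) +
    ggplot2::geom_tile(ggplot2::aes(fill = .data$n), color = "grey30") +
    ggplot2::geom_text(ggplot2::aes(label = .data$n)) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue") +
    ggplot2::labs(x = "simulated", y = "experimental",
                  title = sprintf("accuracy %.1f%%", s$accuracy))
}

#' @rdname plots
#' @param sweep A tibble from [flux_sweep()].
#' @param reactions Reaction ids to draw.
#' @export
plot_flux_sweep <- function(sweep, reactions) {
  df <- sweep[sweep$reaction_id %in% reactions, ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$bound, y = .data$flux,
                                   color = .data$reaction_id)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "swept exchange bound (mmol/gCDW/hr)",
                  y = "flux (mmol/gCDW/hr)", color = NULL)
}

#' @export
#' @importFrom ggplot2 autoplot
ggplot2::autoplot
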