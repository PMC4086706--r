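# Synthetic experimental datasets: deterministic generators (pure functions
# of configuration + seed) emulating the bimodal OD600 structure of
# high-throughput knockout growth data and multi-dataset phenotype-
# microarray respiration scores.

#' Generate a synthetic knockout OD600 table with ground truth
#'
#' Draws a two-mode OD600 distribution mimicking the bimodal histogram of
#' genome-wide deletion-library growth measurements: a non-growing mode
#' concentrated below the narrow threshold (0.005), an intermediate
#' severe-growth-defect tail between the narrow and broad thresholds (0.005
#' to 0.091) so that narrow and broad criteria disagree on a known subset,
#' and a growing mode around OD 0.4. With all noise scales zero the modes
#' collapse to their central values and classification recovers the ground
#' truth exactly.
#'
#' @param genes Character vector of gene names (ground truth is assigned
#'   deterministically in order), or an integer count.
#' @param frac_nongrowing Fraction of genes in the non-growing mode
#'   (narrow-essential), default 0.11.
#' @param frac_defect Fraction in the severe-defect tail (broad-essential
#'   only), default 0.07.
#' @param noise Relative noise scale for all modes (0 = deterministic
#'   central values), default 0.25.
#' @param seed Integer seed; same seed, same table.
#' @return Tibble `(gene, od600_24h, od600_48h, media, truth_narrow,
#'   truth_broad)` with truth columns in `essential`/`nonessential` terms.
#' @export
generate_essentiality_table <- function(genes, frac_nongrowing = 0.11,
                                        frac_defect = 0.07, noise = 0.25,
                                        seed = 1L, media = "glucose") {
  if (is.numeric(genes) && length(genes) == 1L) {
    genes <- sprintf("gene%04d", seq_len(genes))
  }
  n <- length(genes)
  set.seed(seed)
  n_ng <- round(frac_nongrowing * n)
  n_df <- round(frac_defect * n)
  mode <- rep("growing", n)
  if (n_ng > 0) mode[seq_len(n_ng)] <- "nongrowing"
  if (n_df > 0) mode[n_ng + seq_len(n_df)] <- "defect"
  draw24 <- vapply(mode, function(m) {
    switch(m,
      nongrowing = max(0, 0.002 * (1 + noise * stats::rnorm(1))),
      defect = min(0.089, max(0.006, 0.045 * (1 + noise * stats::rnorm(1)))),
      growing = max(0.15, 0.40 * exp(noise * stats::rnorm(1, sd = 0.5))))
  }, numeric(1))
  draw48 <- vapply(seq_len(n), function(i) {
    switch(mode[i],
      nongrowing = max(0, draw24[i] * (1 + noise * stats::rnorm(1, sd = 0.2))),
      defect = min(0.3, draw24[i] * (1.5 + noise * stats::rnorm(1, sd = 0.3))),
      growing = draw24[i] * (1.1 + noise * stats::rnorm(1, sd = 0.1)))
  }, numeric(1))
  tibble::tibble(
    gene = genes, od600_24h = unname(draw24), od600_48h = unname(draw48),
    media = media,
    truth_narrow = ifelse(mode == "nongrowing", "essential", "nonessential"),
    truth_broad = ifelse(mode %in% c("nongrowing", "defect"),
                         "essential", "nonessential"))
}

#' Generate a synthetic multi-dataset phenotype-microarray score table
#'
#' Per well and dataset, a respiration score is drawn from the well's ground
#' truth: positive wells score `normal` or `low`, negative wells `none`.
#' With probability `disagreement` one randomly chosen dataset flips,
#' producing a no-consensus well under the unanimity policy, so the expected
#' no-consensus fraction equals the configured rate.
#'
#' @param wells Tibble `(well, nutrient_id, role, truth)` with `truth` in
#'   `"positive"`/`"negative"`, or an integer count of synthetic wells.
#' @param n_datasets Number of experimental datasets (default 4).
#' @param disagreement Probability a well receives one flipped dataset
#'   (default `70/383`, the observed conflict rate).
#' @param seed Integer seed.
#' @return Long tibble `(well, nutrient_id, role, dataset, score, truth)`.
#' @export
generate_pm_dataset <- function(wells, n_datasets = 4,
                                disagreement = 70 / 383, seed = 1L) {
  if (is.numeric(wells) && length(wells) == 1L) {
    n <- wells
    wells <- tibble::tibble(
      well = sprintf("W%03d", seq_len(n)),
      nutrient_id = sprintf("nutrient%03d[p]", seq_len(n)),
      role = "C",
      truth = rep_len(c("positive", "negative"), n))
  }
  wells <- tibble::as_tibble(wells)
  set.seed(seed)
  rows <- purrr::map_dfr(seq_len(nrow(wells)), function(i) {
    truth_pos <- wells$truth[i] == "positive"
    sc <- if (truth_pos) {
      sample(c("normal", "low"), n_datasets, replace = TRUE, prob = c(0.7, 0.3))
    } else rep("none", n_datasets)
    if (stats::runif(1) < disagreement) {
      j <- sample.int(n_datasets, 1)
      sc[j] <- if (truth_pos) "none" else "low"
    }
    tibble::tibble(well = wells$well[i], nutrient_id = wells$nutrient_id[i],
                   role = wells$role[i], dataset = seq_len(n_datasets),
                   score = sc, truth = wells$truth[i])
  })
  rows
}
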