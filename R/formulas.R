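#' Parse a chemical formula into element counts
#'
#' Formulas use Hill-style notation (`"C6H12O6"`, `"HPO4"`, `"H"`); element
#' symbols are one capital letter optionally followed by a lowercase letter,
#' with an optional integer count. An empty or `NA` formula returns `NULL`,
#' marking the metabolite structure-unknown.
#'
#' @param formula A single formula string, or `NA`.
#' @return A named integer vector of element counts, or `NULL` for `NA`/empty.
#' @examples
#' parse_formula("C6H12O6")
#' @export
parse_formula <- function(formula) {
  if (length(formula) != 1L) stop("`formula` must be a single string", call. = FALSE)
  if (is.na(formula) || !nzchar(formula)) return(NULL)
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", formula)[[1]]
  toks <- regmatches(formula, gregexpr("([A-Z][a-z]?)([0-9]*)", formula))[[1]]
  if (sum(nchar(toks)) != nchar(formula)) {
    stop("malformed formula: ", formula, call. = FALSE)
  }
  el <- sub("[0-9]*$", "", toks)
  n <- as.integer(ifelse(grepl("[0-9]+$", toks), sub("^[A-Za-z]+", "", toks), "1"))
  out <- tapply(n, el, sum)
  storage.mode(out) <- "integer"
  out[order(names(out))]
}

# Sum a list of (count-vector, multiplier) pairs into one element tally.
# Returns NULL if any component is structure-unknown (NULL counts).
sum_elements <- function(counts, mult) {
  if (any(vapply(counts, is.null, logical(1)))) return(NULL)
  all_el <- sort(unique(unlist(lapply(counts, names))))
  tot <- stats::setNames(numeric(length(all_el)), all_el)
  for (i in seq_along(counts)) {
    v <- counts[[i]]
    tot[names(v)] <- tot[names(v)] + mult[i] * as.numeric(v)
  }
  tot
}
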