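#' Check mass and charge balance of reactions
#'
#' For each reaction the signed per-element sums over all participants are
#' computed (protons are counted like any other element). A reaction is
#' `balanced` when every element delta and the net charge delta are zero,
#' `unbalanced` otherwise, and `undetermined` when any participant is
#' structure-unknown (absent formula) or, when `check_charge` is on, has an
#' absent charge. Class metabolites have no structure of their own, so class
#' reactions are `undetermined` until instantiated.
#'
#' @param model A `flux_model`.
#' @param reaction_id Optional character vector of reaction ids to check
#'   (default: all reactions).
#' @param check_charge Should charge balance be required alongside element
#'   balance? A charge-only imbalance then yields `unbalanced`. Default `TRUE`.
#' @return A tibble with one row per reaction: `reaction_id`, `status`
#'   (`"balanced"`, `"unbalanced"`, `"undetermined"`), `delta` (list-column of
#'   named per-element net counts, `NULL` when undetermined), `charge_delta`.
#' @examples
#' m <- fixture_core_energy()
#' dplyr::count(check_mass_balance(m), status)
#' @export
check_mass_balance <- function(model, reaction_id = NULL, check_charge = TRUE) {
  stopifnot(inherits(model, "flux_model"))
  ids <- if (is.null(reaction_id)) model$reactions$id else reaction_id
  unknown <- setdiff(ids, model$reactions$id)
  if (length(unknown)) {
    stop("unknown reaction id(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  res <- lapply(ids, function(rid) {
    s <- model$stoich[model$stoich$reaction_id == rid, ]
    idx <- match(s$metabolite_id, model$metabolites$id)
    is_class <- model$metabolites$is_class[idx]
    counts <- met_elements(model$metabolites, s$metabolite_id)
    charges <- model$metabolites$charge[idx]
    undet <- any(is_class) || any(vapply(counts, is.null, logical(1))) ||
      (check_charge && anyNA(charges))
    if (undet) {
      return(list(status = "undetermined", delta = NULL, charge_delta = NA_real_))
    }
    delta <- sum_elements(counts, s$coef)
    delta <- delta[abs(delta) > 1e-9]
    qd <- if (check_charge) sum(s$coef * as.numeric(charges)) else NA_real_
    ok <- length(delta) == 0 && (!check_charge || abs(qd) < 1e-9)
    list(status = if (ok) "balanced" else "unbalanced",
         delta = delta, charge_delta = qd)
  })
  tibble::tibble(
    reaction_id = ids,
    status = vapply(res, `[[`, character(1), "status"),
    delta = lapply(res, `[[`, "delta"),
    charge_delta = vapply(res, `[[`, numeric(1), "charge_delta")
  )
}

# Continued-fraction rationalization of a numeric coefficient.
rationalize <- function(x, max_den = 1e6, tol = 1e-9) {
  stopifnot(is.finite(x), x != 0)
  sgn <- sign(x); x <- abs(x)
  # Stern-Brocot style best rational approximation
  p0 <- 0; q0 <- 1; p1 <- 1; q1 <- 0; r <- x
  repeat {
    a <- floor(r)
    p2 <- a * p1 + p0; q2 <- a * q1 + q0
    if (q2 > max_den) break
    p0 <- p1; q0 <- q1; p1 <- p2; q1 <- q2
    if (abs(p1 / q1 - x) < tol * max(1, x)) break
    if (abs(r - a) < 1e-12) break
    r <- 1 / (r - a)
  }
  c(num = sgn * p1, den = q1)
}

gcd2 <- function(a, b) if (b == 0) a else gcd2(b, a %% b)

#' Rescale reactions to minimum whole-integer stoichiometry
#'
#' Each reaction's coefficients are multiplied by the least common multiple of
#' their (rationalized) denominators and divided by the overall greatest
#' common divisor, yielding integer coefficients with GCD 1. Direction and
#' participant order are preserved; the input model is not modified. Scaling
#' never changes a reaction's balance status, but it can change taxicab-
#' minimized flux vectors, which is why a fixed canonical scaling matters.
#'
#' @param model A `flux_model` (or a reaction subset via `reaction_id`).
#' @param reaction_id Optional reaction ids to normalize (default all).
#' @return A new `flux_model` with rescaled stoichiometry.
#' @examples
#' m <- fixture_core_energy(convention = "ijo")   # half-O2 oxidase convention
#' normalize_stoichiometry(m)                     # whole-O2, others doubled
#' @export
normalize_stoichiometry <- function(model, reaction_id = NULL) {
  stopifnot(inherits(model, "flux_model"))
  ids <- if (is.null(reaction_id)) model$reactions$id else reaction_id
  st <- model$stoich
  for (rid in ids) {
    i <- which(st$reaction_id == rid)
    co <- st$coef[i]
    fr <- vapply(co, rationalize, numeric(2))
    dens <- fr["den", ]
    l <- Reduce(function(a, b) a / gcd2(a, b) * b, dens, accumulate = FALSE)
    ints <- round(co * l)
    g <- Reduce(gcd2, abs(ints))
    st$coef[i] <- ints / g
  }
  model$stoich <- st
  model
}
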