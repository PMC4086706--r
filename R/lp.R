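# Linear-programming layer: dense two-stage simplex over split fluxes.
#
# Every reaction flux v is represented by one or two non-negative variables
# (forward and, for reversible reactions, reverse magnitude), so the taxicab
# norm Sum|v| is the plain sum of variables and both stages are ordinary LPs:
#   stage 1  max  v_obj      s.t.  S v = 0, bounds
#   stage 2  min  Sum|v|     s.t.  S v = 0, bounds, v_obj = stage-1 optimum
# (if the pinned stage-2 system is numerically brittle the stage-1 vertex is
# kept, so taxicab minimization degrades gracefully instead of failing)

lp_split <- function(reactions) {
  fwd <- reactions$ub > 0
  rev <- reactions$lb < 0
  tibble::tibble(
    rxn = c(reactions$id[fwd], reactions$id[rev]),
    sign = c(rep(1, sum(fwd)), rep(-1, sum(rev))),
    cap = c(reactions$ub[fwd], -reactions$lb[rev])
  )
}

# One LP over the split-variable polytope, via the internal bounded-variable
# simplex. ge_rows: list of list(coef, rhs) inequality rows (coef . x >= rhs),
# converted to equalities with surplus columns; eq_rows: exact equalities.
lp_run <- function(S_eq, vars, a, maximize, ge_rows = NULL, eq_rows = NULL,
                   eps = 1e-9) {
  m0 <- nrow(S_eq); n0 <- ncol(S_eq)
  k <- length(ge_rows)
  A <- S_eq; b <- rep(0, m0)
  if (!is.null(eq_rows) && length(eq_rows)) {
    A <- rbind(A, do.call(rbind, lapply(eq_rows, `[[`, "coef")))
    b <- c(b, vapply(eq_rows, `[[`, numeric(1), "rhs"))
  }
  if (k) {
    G <- do.call(rbind, lapply(ge_rows, `[[`, "coef"))
    A <- rbind(A, G)
    b <- c(b, vapply(ge_rows, `[[`, numeric(1), "rhs"))
    A <- cbind(A, rbind(matrix(0, nrow(A) - k, k), -diag(k)))
  }
  upper <- c(vars$cap, rep(Inf, k))
  cost <- c(if (maximize) -a else a, rep(0, k))
  res <- bounded_simplex(A, b, cost, upper, tol = eps)
  if (res$status != "optimal") {
    return(list(status = res$status, value = NA_real_, x = NULL))
  }
  x <- res$x[seq_len(n0)]
  list(status = "optimal", value = sum(a * x), x = x)
}

recombine_fluxes <- function(vars, x, reaction_ids, zap = 1e-9) {
  v <- stats::setNames(rep(0, length(reaction_ids)), reaction_ids)
  contrib <- vars$sign * x
  for (i in seq_along(contrib)) v[vars$rxn[i]] <- v[vars$rxn[i]] + contrib[i]
  v[abs(v) < zap] <- 0
  v
}

rxn_row <- function(vars, rid, flip = FALSE) {
  coef <- rep(0, nrow(vars))
  k <- which(vars$rxn == rid)
  coef[k] <- vars$sign[k] * (if (flip) -1 else 1)
  coef
}

# Full two-stage solve over a flux_network. `fixed` is a named numeric vector
# of reactions pinned to exact flux values (chemostat protocol); values must
# lie within the reaction's bounds and be non-negative.
lp_two_stage <- function(network, objective_id, minimize_fluxes = TRUE,
                         fixed = NULL, eps_tol = 1e-9) {
  rx <- network$reactions
  if (!is.null(fixed)) {
    for (rid in names(fixed)) {
      i <- match(rid, rx$id)
      if (is.na(i)) stop("cannot fix absent reaction: ", rid, call. = FALSE)
      val <- unname(fixed[rid])
      if (val < 0) stop("fixed fluxes must be non-negative; reverse the ",
                        "exchange instead: ", rid, call. = FALSE)
      rx$ub[i] <- val               # cap at the fixed value ...
      rx$lb[i] <- 0
    }
  }
  mets <- sort(unique(network$stoich$metabolite_id))
  vars <- lp_split(rx[rx$ub > 0 | rx$lb < 0, ])
  n <- nrow(vars)
  S_vars <- matrix(0, length(mets), n, dimnames = list(mets, NULL))
  st <- network$stoich
  for (j in seq_len(n)) {
    rows <- st[st$reaction_id == vars$rxn[j], ]
    S_vars[rows$metabolite_id, j] <- rows$coef * vars$sign[j]
  }
  # conserved moieties (cofactor pools) make S rank-deficient; the simplex
  # tableau needs an independent equality block, and dropping dependent
  # zero-RHS rows is exact
  qrd <- qr(t(S_vars))
  S_eq <- S_vars[qrd$pivot[seq_len(qrd$rank)], , drop = FALSE]

  zero_sol <- function(status) {
    list(status = status, value = NA_real_, v = NULL, sum_abs = NA_real_,
         stage2 = FALSE)
  }
  if (!any(vars$rxn == objective_id)) {
    # objective pinned to zero on both sides (e.g. all uptakes closed)
    v <- stats::setNames(rep(0, nrow(rx)), rx$id)
    return(list(status = "optimal", value = 0, v = v, sum_abs = 0,
                stage2 = FALSE))
  }
  obj_coef <- rxn_row(vars, objective_id)

  ge_rows <- list()
  for (rid in names(fixed)) {                   # ... and floor it (equality)
    val <- unname(fixed[rid])
    if (val > 0) {
      ge_rows[[length(ge_rows) + 1L]] <- list(coef = rxn_row(vars, rid),
                                              rhs = val)
    }
  }
  pos_lb <- which(rx$lb > 0)
  for (i in pos_lb) {
    ge_rows[[length(ge_rows) + 1L]] <- list(coef = rxn_row(vars, rx$id[i]),
                                            rhs = rx$lb[i])
  }
  neg_ub <- which(rx$ub < 0)                    # reverse-only forced flux
  for (i in neg_ub) {
    ge_rows[[length(ge_rows) + 1L]] <- list(
      coef = rxn_row(vars, rx$id[i], flip = TRUE), rhs = -rx$ub[i])
  }

  s1 <- lp_run(S_eq, vars, obj_coef, maximize = TRUE, ge_rows = ge_rows,
               eps = eps_tol)
  if (s1$status != "optimal") return(zero_sol(s1$status))
  v1 <- recombine_fluxes(vars, s1$x, rx$id)
  if (!minimize_fluxes) {
    return(list(status = "optimal", value = s1$value, v = v1,
                sum_abs = sum(abs(v1)), stage2 = FALSE))
  }
  pin <- list(coef = obj_coef, rhs = s1$value)
  s2 <- lp_run(S_eq, vars, rep(1, n), maximize = FALSE,
               ge_rows = ge_rows, eq_rows = list(pin), eps = eps_tol)
  if (s2$status != "optimal") {
    # keep the stage-1 vertex if the pinned stage-2 problem is brittle
    return(list(status = "optimal", value = s1$value, v = v1,
                sum_abs = sum(abs(v1)), stage2 = FALSE))
  }
  v2 <- recombine_fluxes(vars, s2$x, rx$id)
  list(status = "optimal", value = s1$value, v = v2, sum_abs = sum(abs(v2)),
       stage2 = TRUE)
}
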