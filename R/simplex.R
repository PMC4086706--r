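# Dense two-phase bounded-variable simplex with Bland's anti-cycling rule.
#
# Solves   min  c'x   s.t.  A x = b,  0 <= x <= u   (u may be Inf)
# deterministically: entering variable = smallest eligible index, leaving
# variable = smallest basis index among the ratio-test ties, so repeated
# runs produce identical vertices. Phase 1 minimizes artificial variables
# from the all-slack basis; artificials are then pinned to zero and kept,
# which handles redundant or degenerate constraint sets without basis
# surgery.

bounded_simplex <- function(A, b, cost, upper, tol = 1e-9, max_iter = 50000L) {
  m <- nrow(A); n <- ncol(A)
  stopifnot(length(b) == m, length(cost) == n, length(upper) == n)
  neg <- b < 0
  if (any(neg)) { A[neg, ] <- -A[neg, , drop = FALSE]; b[neg] <- -b[neg] }
  Afull <- cbind(A, diag(m))
  up <- c(upper, rep(Inf, m))
  N <- n + m
  basis <- n + seq_len(m)
  at_upper <- rep(FALSE, N)

  run_phase <- function(cvec, basis, at_upper, iter_left) {
    repeat {
      if (iter_left <= 0L) {
        return(list(status = "iteration-limit", basis = basis,
                    at_upper = at_upper))
      }
      nb <- setdiff(seq_len(N), basis)
      B <- Afull[, basis, drop = FALSE]
      xn <- ifelse(at_upper[nb], up[nb], 0)
      xB <- tryCatch(
        drop(solve(B, b - Afull[, nb, drop = FALSE] %*% xn)),
        error = function(e) NULL)
      if (is.null(xB)) {
        return(list(status = "singular", basis = basis, at_upper = at_upper))
      }
      y <- drop(solve(t(B), cvec[basis]))
      rc <- cvec[nb] - drop(crossprod(Afull[, nb, drop = FALSE], y))
      elig <- (!at_upper[nb] & rc < -tol) | (at_upper[nb] & rc > tol)
      if (!any(elig)) {
        return(list(status = "optimal", basis = basis, at_upper = at_upper,
                    xB = xB, nb = nb, xn = xn))
      }
      j <- min(nb[elig])                             # Bland: smallest index
      sigma <- if (at_upper[j]) -1 else 1
      d <- sigma * drop(solve(B, Afull[, j]))
      # x_j moves by sigma * t >= 0, basic values by -d * t; blocking
      # candidates: basic falling to 0, basic rising to its cap, or x_j
      # reaching its own opposite bound
      cand_var <- integer(); cand_t <- numeric(); cand_row <- integer()
      dec <- which(d > tol)
      if (length(dec)) {
        cand_var <- c(cand_var, basis[dec])
        cand_t <- c(cand_t, pmax(xB[dec], 0) / d[dec])
        cand_row <- c(cand_row, dec)
      }
      inc <- which(d < -tol & is.finite(up[basis]))
      if (length(inc)) {
        cand_var <- c(cand_var, basis[inc])
        cand_t <- c(cand_t, pmax(up[basis][inc] - xB[inc], 0) / (-d[inc]))
        cand_row <- c(cand_row, inc)
      }
      if (is.finite(up[j])) {
        cand_var <- c(cand_var, j)
        cand_t <- c(cand_t, up[j])
        cand_row <- c(cand_row, NA_integer_)
      }
      if (!length(cand_t)) {
        return(list(status = "unbounded", basis = basis, at_upper = at_upper))
      }
      t_star <- min(cand_t)
      tied <- which(cand_t <= t_star + tol)
      pick <- tied[which.min(cand_var[tied])]        # Bland on ties
      if (is.na(cand_row[pick])) {
        at_upper[j] <- !at_upper[j]                  # bound flip, basis kept
      } else {
        leave <- cand_row[pick]
        at_upper[basis[leave]] <- d[leave] < 0       # left at its cap?
        basis[leave] <- j
        at_upper[j] <- FALSE
      }
      iter_left <- iter_left - 1L
    }
  }

  ph1 <- run_phase(c(rep(0, n), rep(1, m)), basis, at_upper, max_iter)
  if (ph1$status != "optimal") {
    return(list(status = if (ph1$status == "unbounded") "infeasible"
                else ph1$status, value = NA_real_, x = NULL))
  }
  x <- rep(0, N); x[ph1$nb] <- ph1$xn; x[ph1$basis] <- ph1$xB
  if (sum(x[n + seq_len(m)]) > 1e-7) {
    return(list(status = "infeasible", value = NA_real_, x = NULL))
  }
  up[n + seq_len(m)] <- 0                            # pin artificials
  ph2 <- run_phase(c(cost, rep(0, m)), ph1$basis, ph1$at_upper, max_iter)
  if (ph2$status != "optimal") {
    return(list(status = ph2$status, value = NA_real_, x = NULL))
  }
  x <- rep(0, N); x[ph2$nb] <- ph2$xn; x[ph2$basis] <- ph2$xB
  xs <- x[seq_len(n)]
  xs <- pmin(pmax(xs, 0), ifelse(is.finite(upper), upper, Inf))
  list(status = "optimal", value = sum(cost * xs), x = xs)
}
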