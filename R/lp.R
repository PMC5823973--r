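# Dense two-phase primal simplex for the small, fully bounded linear programs
# that flux balance and flux variability analysis generate. Bland's pivoting
# rule is used throughout, so the method terminates on degenerate bases (the
# stoichiometric LPs here are highly degenerate). Problem sizes are tiny by LP
# standards (tens of reactions), so a dense tableau is both simple and fast.

#' Solve a bounded linear program
#'
#' Maximizes (or minimizes) \code{obj \%*\% v} subject to \code{Aeq \%*\% v ==
#' beq} and \code{lb <= v <= ub}. This is the narrow solver interface behind
#' [fba()], [fva()] and [elastic_relax()]; it is exported because toy models
#' and tests use it directly.
#'
#' @param obj numeric objective coefficient vector (length n).
#' @param Aeq numeric equality-constraint matrix (m x n).
#' @param beq numeric equality right-hand side (length m).
#' @param lb,ub numeric lower/upper variable bounds (length n). `ub` may
#'   contain `Inf`; `lb` must be finite.
#' @param maximize logical; maximize (default) or minimize.
#' @param tol pivot tolerance.
#' @return list with elements `status` ("optimal", "infeasible" or
#'   "unbounded"), `v` (solution, `NA` unless optimal) and `objective`.
#' @examples
#' # A -> B -> ATP chain with uptake capped at 10
#' S <- rbind(c(1, -1, 0), c(0, 1, -1))
#' solve_lp(c(0, 0, 1), S, c(0, 0), lb = c(0, 0, 0), ub = c(10, 100, 100))
#' @export
solve_lp <- function(obj, Aeq, beq, lb, ub, maximize = TRUE, tol = 1e-9) {
  n <- length(obj)
  Aeq <- matrix(as.numeric(Aeq), nrow = length(beq), ncol = n)
  stopifnot(length(lb) == n, length(ub) == n, all(is.finite(lb)))
  if (any(lb > ub + 1e-12)) {
    return(list(status = "infeasible", v = rep(NA_real_, n), objective = NA_real_))
  }
  # shift x = v - lb >= 0
  u <- ub - lb
  bshift <- as.numeric(beq - Aeq %*% lb)
  sense <- if (maximize) 1 else -1
  cvec <- sense * obj  # maximize cvec'x internally

  has_ub <- is.finite(u)
  n_ub <- sum(has_ub)
  m_eq <- length(bshift)
  m <- m_eq + n_ub

  # columns: n structural, n_ub bound slacks, m_eq artificials
  ncol_t <- n + n_ub + m_eq
  Tb <- matrix(0, m, ncol_t)
  rhs <- numeric(m)
  basis <- integer(m)

  # equality rows first (sign-flipped so rhs >= 0), artificial basic
  for (i in seq_len(m_eq)) {
    row <- Aeq[i, ]
    bi <- bshift[i]
    if (bi < 0) { row <- -row; bi <- -bi }
    Tb[i, seq_len(n)] <- row
    Tb[i, n + n_ub + i] <- 1
    rhs[i] <- bi
    basis[i] <- n + n_ub + i
  }
  # upper-bound rows x_j + s_j = u_j, slack basic
  ub_idx <- which(has_ub)
  for (k in seq_along(ub_idx)) {
    i <- m_eq + k
    Tb[i, ub_idx[k]] <- 1
    Tb[i, n + k] <- 1
    rhs[i] <- u[ub_idx[k]]
    basis[i] <- n + k
  }

  cost <- numeric(ncol_t)
  cost_rhs <- 0

  run_simplex <- function(allowed) {
    # Bland's rule: entering = lowest-index column with negative reduced cost
    repeat {
      ent <- 0L
      for (j in allowed) {
        if (cost[j] < -tol) { ent <- j; break }
      }
      if (ent == 0L) return("optimal")
      col <- Tb[, ent]
      pos <- which(col > tol)
      if (!length(pos)) return("unbounded")
      ratios <- rhs[pos] / col[pos]
      rmin <- min(ratios)
      cand <- pos[ratios <= rmin + tol]
      # tie-break: lowest basis index leaves (Bland)
      prow <- cand[which.min(basis[cand])]
      piv <- Tb[prow, ent]
      Tb[prow, ] <<- Tb[prow, ] / piv
      rhs[prow] <<- rhs[prow] / piv
      other <- which(abs(Tb[, ent]) > 1e-13)
      other <- other[other != prow]
      if (length(other)) {
        fac <- Tb[other, ent]
        Tb[other, ] <<- Tb[other, , drop = FALSE] - outer(fac, Tb[prow, ])
        rhs[other] <<- rhs[other] - fac * rhs[prow]
        Tb[other, ent] <<- 0
      }
      cfac <- cost[ent]
      if (abs(cfac) > 0) {
        cost <<- cost - cfac * Tb[prow, ]
        cost_rhs <<- cost_rhs - cfac * rhs[prow]
        cost[ent] <<- 0
      }
      basis[prow] <<- ent
    }
  }

  # ---- phase 1: minimize sum of artificials ----
  art_cols <- n + n_ub + seq_len(m_eq)
  cost <- numeric(ncol_t)
  cost[art_cols] <- 1
  cost_rhs <- 0
  for (i in seq_len(m)) {        # reduce cost row against initial basis
    cb <- cost[basis[i]]
    if (cb != 0) {
      cost <- cost - cb * Tb[i, ]
      cost_rhs <- cost_rhs - cb * rhs[i]
      cost[basis[i]] <- 0
    }
  }
  st <- run_simplex(seq_len(n + n_ub))
  phase1_obj <- -cost_rhs
  if (phase1_obj > 1e-7) {
    return(list(status = "infeasible", v = rep(NA_real_, n), objective = NA_real_))
  }
  # drive remaining artificials out of the basis where possible
  for (i in seq_len(m)) {
    if (basis[i] %in% art_cols) {
      j <- which(abs(Tb[i, seq_len(n + n_ub)]) > tol)
      if (length(j)) {
        ent <- j[1]
        piv <- Tb[i, ent]
        Tb[i, ] <- Tb[i, ] / piv
        rhs[i] <- rhs[i] / piv
        other <- setdiff(which(abs(Tb[, ent]) > 0), i)
        if (length(other)) {
          fac <- Tb[other, ent]
          Tb[other, ] <- Tb[other, , drop = FALSE] - outer(fac, Tb[i, ])
          rhs[other] <- rhs[other] - fac * rhs[i]
          Tb[other, ent] <- 0
        }
        basis[i] <- ent
      }
      # else: row is redundant (zero on structural columns, rhs ~ 0)
    }
  }
  drop_rows <- which(basis %in% art_cols)
  if (length(drop_rows)) {
    Tb <- Tb[-drop_rows, , drop = FALSE]
    rhs <- rhs[-drop_rows]
    basis <- basis[-drop_rows]
    m <- length(basis)
  }

  # ---- phase 2: maximize cvec'x  (minimize -cvec'x); artificials are
  # never allowed to enter and none is basic after row cleanup ----
  cost <- numeric(ncol_t)
  cost[seq_len(n)] <- -cvec
  cost_rhs <- 0
  for (i in seq_len(m)) {
    cb <- cost[basis[i]]
    if (cb != 0) {
      cost <- cost - cb * Tb[i, ]
      cost_rhs <- cost_rhs - cb * rhs[i]
      cost[basis[i]] <- 0
    }
  }
  st <- run_simplex(seq_len(n + n_ub))
  if (st == "unbounded") {
    return(list(status = "unbounded", v = rep(NA_real_, n), objective = if (maximize) Inf else -Inf))
  }
  x <- numeric(ncol_t)
  x[basis] <- rhs
  v <- x[seq_len(n)] + lb
  # snap to bounds to remove simplex round-off
  v <- pmin(pmax(v, lb), ifelse(is.finite(ub), ub, v))
  list(status = "optimal", v = v, objective = sum(obj * v))
}
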