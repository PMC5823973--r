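# Independent brute-force oracle for bounded stoichiometric LPs: enumerate
# candidate vertices of {v : S v = 0, lb <= v <= ub} by fixing subsets of
# variables at their bounds and solving the remaining linear system.
# Exponential, so only for n <= 8.

enumerate_lp_max <- function(obj, S, lb, ub, tol = 1e-8) {
  n <- length(obj)
  S <- matrix(as.numeric(S), ncol = n)
  r <- qr(S)$rank
  k <- n - r                      # bound constraints active at a vertex
  best <- -Inf
  feasible <- FALSE
  check <- function(v) {
    if (any(v < lb - tol) || any(v > ub + tol)) return()
    if (max(abs(S %*% v)) > tol) return()
    feasible <<- TRUE
    val <- sum(obj * v)
    if (val > best) best <<- val
  }
  if (k == 0) {
    # vertex determined by S v = 0 alone (if unique solution exists)
    v <- tryCatch(qr.solve(S, rep(0, nrow(S))), error = function(e) NULL)
    if (!is.null(v)) check(v)
  } else {
    combos <- utils::combn(n, k)
    for (ci in seq_len(ncol(combos))) {
      fixed <- combos[, ci]
      free <- setdiff(seq_len(n), fixed)
      Sf <- S[, free, drop = FALSE]
      for (mask in 0:(2^k - 1)) {
        at_ub <- as.logical(bitwAnd(mask, 2^(seq_len(k) - 1)))
        vfix <- ifelse(at_ub, ub[fixed], lb[fixed])
        rhs <- -S[, fixed, drop = FALSE] %*% vfix
        sol <- tryCatch(qr.solve(Sf, rhs), error = function(e) NULL)
        if (is.null(sol)) next
        if (max(abs(Sf %*% sol - rhs)) > tol) next
        v <- numeric(n)
        v[fixed] <- vfix
        v[free] <- sol
        check(v)
      }
    }
  }
  if (!feasible) list(status = "infeasible", objective = NA_real_)
  else list(status = "optimal", objective = best)
}
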