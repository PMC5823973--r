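# Independent brute-force oracle for steady-state 13C labeling: full
# isotopomer (2^n states per metabolite) fixed-point iteration. Shares only
# the model/flux data structures with the package; the algorithm (state
# space, update rule, convergence) is entirely different from the EMU
# solver it checks.

brute_force_isotopomers <- function(model, fluxes, tracer, ftol = 1e-9,
                                    tol = 1e-13, max_iter = 20000) {
  nc <- stats::setNames(model$metabolites$n_carbons, model$metabolites$id)
  v <- fluxes

  # oriented reactions with parsed maps; source injections
  oriented <- list()
  producers <- list()
  for (rxn in model$reactions) {
    w <- v[[rxn$id]]
    if (is.na(w) || abs(w) <= ftol) next
    st <- rxn$stoichiometry
    produced <- names(st)[sign(st) * sign(w) > 0]
    produced_c <- produced[nc[produced] >= 1]
    if (is.null(rxn$atom_map)) {
      if (length(st) == 1 && length(produced_c) == 1) {
        producers[[produced_c]] <- c(producers[[produced_c]],
                                     list(list(type = "src", w = abs(w))))
      }
      next
    }
    lhs <- lapply(strsplit(rxn$atom_map$lhs, ":"), function(p)
      list(met = p[1], letters = strsplit(p[2], "")[[1]]))
    rhs <- lapply(strsplit(rxn$atom_map$rhs, ":"), function(p)
      list(met = p[1], letters = strsplit(p[2], "")[[1]]))
    if (w < 0) { tmp <- lhs; lhs <- rhs; rhs <- tmp }
    for (sp in rhs) {
      producers[[sp$met]] <- c(producers[[sp$met]], list(
        list(type = "rxn", w = abs(w), lhs = lhs, out = sp)))
    }
  }

  # substrate isotopomer distribution under the tracer (index = bit pattern
  # over positions, 1-based; bit i set = atom i heavy)
  tracer_dist <- function(met) {
    k <- nc[[met]]
    d <- numeric(2^k)
    d[1] <- 1
    if (met == tracer$substrate) {
      idx <- sum(2^(tracer$positions - 1)) + 1
      d[1] <- 1 - tracer$enrichment
      d[idx] <- d[idx] + tracer$enrichment
    }
    d
  }

  mets_tracked <- names(producers)[vapply(producers, function(ps)
    sum(vapply(ps, `[[`, 0, "w")), 0) > ftol]
  dist <- lapply(mets_tracked, function(m) { d <- numeric(2^nc[[m]]); d[1] <- 1; d })
  names(dist) <- mets_tracked

  get_dist <- function(met) {
    if (met %in% names(dist)) dist[[met]] else tracer_dist(met)
  }

  # product distribution for one oriented mapped reaction term
  product_dist <- function(term, sym_perm = NULL) {
    out <- term$out
    k <- length(out$letters)
    res <- numeric(2^k)
    # joint enumeration over reactant isotopomers (independence across
    # distinct reactant molecules)
    reac <- term$lhs
    dists <- lapply(reac, function(sp) get_dist(sp$met))
    idx <- lapply(dists, function(d) seq_along(d))
    grid <- expand.grid(idx, KEEP.OUT.ATTRS = FALSE)
    out_letters <- out$letters
    if (!is.null(sym_perm)) out_letters <- out$letters[sym_perm]
    for (g in seq_len(nrow(grid))) {
      pr <- 1
      heavy <- character(0)
      for (j in seq_along(reac)) {
        state <- grid[g, j] - 1
        pr <- pr * dists[[j]][state + 1]
        if (pr == 0) break
        kk <- length(reac[[j]]$letters)
        bits <- bitwAnd(state, 2^(seq_len(kk) - 1)) > 0
        heavy <- c(heavy, reac[[j]]$letters[bits])
      }
      if (pr == 0) next
      obits <- out_letters %in% heavy
      oidx <- sum(2^(which(obits) - 1)) + 1
      res[oidx] <- res[oidx] + pr
    }
    res
  }

  sym <- model$symmetric
  for (iter in seq_len(max_iter)) {
    delta <- 0
    for (m in mets_tracked) {
      ps <- producers[[m]]
      total <- sum(vapply(ps, `[[`, 0, "w"))
      acc <- numeric(2^nc[[m]])
      for (p in ps) {
        if (p$type == "src") {
          acc <- acc + p$w * tracer_dist(m)
        } else if (m %in% names(sym)) {
          acc <- acc + (p$w / 2) * (product_dist(p) +
                                      product_dist(p, sym_perm = sym[[m]]))
        } else {
          acc <- acc + p$w * product_dist(p)
        }
      }
      # each term is a probability distribution, so acc sums to `total` up
      # to roundoff; renormalize to stop drift amplifying through cycles
      newd <- acc / sum(acc)
      delta <- max(delta, max(abs(newd - dist[[m]])))
      dist[[m]] <- newd
    }
    if (delta < tol) break
  }

  # collapse isotopomers to mass-isotopologue distributions
  out <- lapply(mets_tracked, function(m) {
    k <- nc[[m]]
    mid <- numeric(k + 1)
    for (state in 0:(2^k - 1)) {
      nheavy <- sum(bitwAnd(state, 2^(seq_len(k) - 1)) > 0)
      mid[nheavy + 1] <- mid[nheavy + 1] + dist[[m]][state + 1]
    }
    stats::setNames(mid, paste0("m+", 0:k))
  })
  names(out) <- mets_tracked
  out
}
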