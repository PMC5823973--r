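# Toy and random network builders shared across the test files.

mk_rxn <- function(id, stoich, lb, ub, subsystem = NA_character_,
                   map = NULL, hydride = NULL) {
  list(id = id, stoichiometry = stoich, lb = lb, ub = ub,
       subsystem = subsystem, atom_map = map, hydride_map = hydride)
}

# linear chain: EX_A (uptake <= 10) -> A -> B -> ATP demand
toy_chain_model <- function(uptake = 10) {
  mets <- data.frame(id = c("a", "b", "atp"), name = c("A", "B", "ATP"),
                     compartment = "c", n_carbons = c(1, 1, 0),
                     stringsAsFactors = FALSE)
  metabolic_model(mets, list(
    mk_rxn("EX_A", c(a = 1), -uptake, uptake),
    mk_rxn("R_AB", c(a = -1, b = 1), 0, 100),
    mk_rxn("DM_ATP", c(b = -1, atp = 1), 0, 100),
    mk_rxn("ATPM", c(atp = -1), 0, 100)
  ), objective = "ATPM", id = "chain")
}

# two parallel paths from A to ATP with configurable yields
toy_parallel_model <- function(yield1 = 2, yield2 = 1, uptake = 10) {
  mets <- data.frame(id = c("a", "atp"), name = c("A", "ATP"),
                     compartment = "c", n_carbons = c(1, 0),
                     stringsAsFactors = FALSE)
  metabolic_model(mets, list(
    mk_rxn("EX_A", c(a = 1), 0, uptake),
    mk_rxn("PATH1", c(a = -1, atp = yield1), 0, 100),
    mk_rxn("PATH2", c(a = -1, atp = yield2), 0, 100),
    mk_rxn("ATPM", c(atp = -1), 0, 1000)
  ), objective = "ATPM", id = "parallel")
}

# random bounded stoichiometric LP instance (for the vertex-enumeration
# oracle); returns list(S, lb, ub, obj)
random_lp_instance <- function(seed) {
  set.seed(seed)
  n <- sample(3:8, 1)
  m <- sample(2:5, 1)
  S <- matrix(sample(-2:2, n * m, replace = TRUE), m, n)
  lb <- round(runif(n, -10, 0), 2)
  ub <- pmax(round(runif(n, -1, 10), 2), lb)
  obj <- round(runif(n, -1, 1), 2)
  list(S = S, lb = lb, ub = ub, obj = obj)
}

# Random atom-mapped network with a labeled substrate, built from
# isomerase / cleavage / condensation steps so carbon is conserved, plus a
# steady-state flux vector without futile circulation (throughput maximized,
# then total flux minimized). Metabolites have <= 5 carbons.
random_emu_network <- function(seed, with_symmetry = FALSE) {
  set.seed(seed)
  repeat {
    n_met <- sample(4:7, 1)
    ncs <- sample(1:5, n_met, replace = TRUE)
    ids <- sprintf("M%d", seq_len(n_met))
    rxns <- list()
    add <- function(r) rxns[[length(rxns) + 1]] <<- r
    # source into M1, sink out of a random met
    add(mk_rxn("SRC", stats::setNames(1, ids[1]), 0, 10))
    letters_for <- function(k, off = 0) paste(letters[off + seq_len(k)], collapse = "")
    n_internal <- sample(3:6, 1)
    for (i in seq_len(n_internal)) {
      type <- sample(c("iso", "split", "cond"), 1)
      if (type == "iso") {
        from <- sample(ids, 1)
        cand <- ids[ncs == ncs[match(from, ids)] & ids != from]
        if (!length(cand)) next
        to <- sample(cand, 1)
        k <- ncs[match(from, ids)]
        perm <- sample(k)
        add(mk_rxn(sprintf("R%d", i), stats::setNames(c(-1, 1), c(from, to)),
                   0, 10,
                   map = list(lhs = paste0(from, ":", letters_for(k)),
                              rhs = paste0(to, ":", paste(letters[perm], collapse = "")))))
      } else if (type == "split") {
        cand0 <- ids[ncs >= 2]
        if (!length(cand0)) next
        from <- sample(cand0, 1)
        k <- ncs[match(from, ids)]
        k1 <- sample(seq_len(k - 1), 1)
        cand1 <- ids[ncs == k1 & ids != from]
        cand2 <- ids[ncs == k - k1 & ids != from]
        if (!length(cand1) || !length(cand2)) next
        p1 <- sample(cand1, 1); p2 <- sample(cand2, 1)
        if (p1 == p2) next
        perm <- sample(k)
        add(mk_rxn(sprintf("R%d", i),
                   stats::setNames(c(-1, 1, 1), c(from, p1, p2)), 0, 10,
                   map = list(lhs = paste0(from, ":", letters_for(k)),
                              rhs = c(paste0(p1, ":", paste(letters[perm[seq_len(k1)]], collapse = "")),
                                      paste0(p2, ":", paste(letters[perm[(k1 + 1):k]], collapse = ""))))))
      } else {
        s1 <- sample(ids, 1); s2 <- sample(ids[ids != s1], 1)
        k1 <- ncs[match(s1, ids)]; k2 <- ncs[match(s2, ids)]
        cand <- ids[ncs == k1 + k2 & !(ids %in% c(s1, s2))]
        if (!length(cand)) next
        to <- sample(cand, 1)
        perm <- sample(k1 + k2)
        add(mk_rxn(sprintf("R%d", i),
                   stats::setNames(c(-1, -1, 1), c(s1, s2, to)), 0, 10,
                   map = list(lhs = c(paste0(s1, ":", letters_for(k1)),
                                      paste0(s2, ":", letters_for(k2, k1))),
                              rhs = paste0(to, ":", paste(letters[perm], collapse = "")))))
      }
    }
    sink_met <- sample(ids, 1)
    add(mk_rxn("SINK", stats::setNames(-1, sink_met), 0, 10))
    mets <- data.frame(id = ids, name = ids, compartment = "c",
                       n_carbons = ncs, stringsAsFactors = FALSE)
    sym <- list()
    if (with_symmetry) {
      cand <- ids[ncs >= 2]
      if (length(cand)) {
        sm <- sample(cand, 1)
        sym[[sm]] <- rev(seq_len(ncs[match(sm, ids)]))
      }
    }
    model <- tryCatch(
      metabolic_model(mets, rxns, objective = "SINK", symmetric = sym,
                      id = sprintf("emu_random_%d", seed)),
      error = function(e) NULL)
    if (is.null(model)) next
    if (nrow(validate_atom_maps(model)$violations)) next
    # steady-state fluxes: maximize sink, then minimize total flux
    S <- stoichiometric_matrix(model)
    bnd <- cbind(lb = vapply(model$reactions, `[[`, 0, "lb"),
                 ub = vapply(model$reactions, `[[`, 0, "ub"))
    rids <- names(model$reactions)
    obj1 <- as.numeric(rids == "SINK")
    s1 <- solve_lp(obj1, S, rep(0, nrow(S)), bnd[, 1], bnd[, 2])
    if (s1$status != "optimal" || s1$objective < 0.5) next
    lb2 <- bnd[, 1]; ub2 <- bnd[, 2]
    i <- match("SINK", rids)
    lb2[i] <- s1$objective; ub2[i] <- s1$objective
    s2 <- solve_lp(rep(1, length(rids)), S, rep(0, nrow(S)), lb2, ub2,
                   maximize = FALSE)
    if (s2$status != "optimal") next
    v <- stats::setNames(s2$v, rids)
    tracer <- tracer_spec("M1", "13C",
                          sample(seq_len(ncs[1]), sample(ncs[1], 1)),
                          enrichment = sample(c(1, 0.7), 1))
    return(list(model = model, fluxes = v, tracer = tracer))
  }
}
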