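# Steady-state 13C isotopologue prediction by EMU (elementary metabolite
# unit) decomposition. EMUs are generated backward from the metabolites of
# interest, grouped by size, and each size class is solved as one linear
# system; convolutions couple a size only to strictly smaller ones, so the
# cascade is closed. Reactions are taken at their net flux (oriented by
# sign); symmetric metabolites are produced as a 50/50 average over their
# equivalent orientations; CO2 is an unlabeled, infinite pool unless the
# tracer itself labels it.

emu_key <- function(met, atoms) paste0(met, "|", paste(atoms, collapse = ","))

# MID of a boundary (source) EMU under the tracer: molecules are either
# unlabeled or carry the tracer pattern, so the EMU sees a two-point mixture.
source_emu_mid <- function(met, atoms, tracer) {
  mid <- numeric(length(atoms) + 1)
  if (!is.null(tracer) && met == tracer$substrate) {
    k <- length(intersect(atoms, tracer$positions))
    mid[1] <- 1 - tracer$enrichment
    mid[k + 1] <- mid[k + 1] + tracer$enrichment
  } else {
    mid[1] <- 1
  }
  mid
}

convolve_mid <- function(a, b) {
  out <- numeric(length(a) + length(b) - 1)
  for (i in seq_along(a)) {
    out[i:(i + length(b) - 1)] <- out[i:(i + length(b) - 1)] + a[i] * b
  }
  out
}

is_co2 <- function(met) grepl("^co2", met)

#' Simulate steady-state 13C mass-isotopologue distributions
#'
#' Given a flux vector at steady state, the network's atom maps and a 13C
#' tracer, solves the metabolic-and-isotopic steady state by EMU
#' decomposition and returns the mass-isotopologue fraction vector of every
#' requested metabolite. Only net fluxes are used (no exchange-flux
#' bidirectionality); a reaction carrying flux into a traced metabolite must
#' have an atom map unless it is a single-species boundary exchange, which
#' injects substrate at the tracer's composition (or unlabeled).
#'
#' @param network an `atom_transition_network` (or `metabolic_model`).
#' @param fluxes an `fba_fit` or named flux vector (µmol/min/gDW).
#' @param tracer a `tracer_spec` with isotope `"13C"` (or shorthand string).
#' @param metabolites metabolites to report (default: every carbon-bearing,
#'   non-CO2 metabolite with nonzero production).
#' @param ftol fluxes with magnitude below this are treated as zero.
#' @param .atoms internal: restrict the (single) requested metabolite to a
#'   subset of its carbon slots, returning that EMU's distribution.
#' @return object of class `labeling_state`: named list of isotopologue
#'   fraction vectors (`m+0` ... `m+N`, N = carbon count).
#' @export
simulate_13c <- function(network, fluxes, tracer, metabolites = NULL,
                         ftol = 1e-9, .atoms = NULL) {
  if (inherits(network, "metabolic_model")) {
    network <- atom_transition_network(network)
  }
  model <- network$model
  if (is.character(tracer)) tracer <- parse_tracer(tracer, model)
  if (tracer$isotope != "13C") stop("simulate_13c requires a 13C tracer")
  v <- if (inherits(fluxes, "fba_fit")) fluxes$fluxes else fluxes
  sv <- max(abs(stoichiometric_matrix(model) %*% v[names(model$reactions)]))
  if (sv > 1e-6) stop("flux vector is not at steady state (max |S v| = ",
                      format(sv), ")")
  nc <- network$n_carbons

  # ---- orient reactions by net flux; index producers per metabolite ----
  producers <- list()   # met -> list of list(type, w, rid)
  oriented <- list()    # rid -> list(w, side_in, side_out)
  add_producer <- function(met, entry) {
    producers[[met]] <<- c(producers[[met]], list(entry))
  }
  for (rxn in model$reactions) {
    w <- v[[rxn$id]]
    if (is.na(w) || abs(w) <= ftol) next
    st <- rxn$stoichiometry
    produced <- names(st)[sign(st) * sign(w) > 0]
    produced_c <- produced[nc[produced] >= 1 & !is_co2(produced)]
    map <- network$maps[[rxn$id]]
    if (is.null(map)) {
      if (length(st) == 1 && length(produced_c) == 1) {
        add_producer(produced_c, list(type = "src", w = abs(w * st[[1]]),
                                      rid = rxn$id))
      } else if (length(produced_c)) {
        stop("reaction ", rxn$id, " carries flux into ",
             paste(produced_c, collapse = ", "), " but has no atom map")
      }
      next
    }
    side_in <- if (w > 0) map$lhs else map$rhs
    side_out <- if (w > 0) map$rhs else map$lhs
    missing <- setdiff(produced_c, names(side_out))
    if (length(missing)) {
      stop("reaction ", rxn$id, ": produced metabolite ",
           paste(missing, collapse = ", "), " missing from its atom map")
    }
    oriented[[rxn$id]] <- list(w = abs(w), side_in = side_in,
                               side_out = side_out)
    for (m in produced_c) add_producer(m, list(type = "rxn", w = abs(w),
                                               rid = rxn$id))
  }
  total_prod <- vapply(producers, function(ps) sum(vapply(ps, `[[`, 0, "w")), 0)

  if (is.null(metabolites)) {
    metabolites <- names(producers)[total_prod[names(producers)] > ftol]
    metabolites <- metabolites[!is_co2(metabolites)]
  } else {
    bad <- setdiff(metabolites, names(producers))
    if (length(bad)) {
      stop("metabolite(s) with label demand but no production: ",
           paste(bad, collapse = ", "))
    }
  }

  # a metabolite is a boundary source for the EMU system if CO2 or if it has
  # only source-type producers
  is_source_met <- function(met) {
    if (is_co2(met)) return(TRUE)
    ps <- producers[[met]]
    !is.null(ps) && all(vapply(ps, `[[`, "", "type") == "src")
  }

  # ---- backward EMU generation ----
  target_atoms <- function(m) {
    if (!is.null(.atoms)) .atoms else seq_len(nc[[m]])
  }
  if (!is.null(.atoms) && length(metabolites) != 1) {
    stop(".atoms requires exactly one metabolite")
  }
  emus <- list()    # key -> list(met, atoms, size, terms = list(w, parts))
  queue <- lapply(metabolites, function(m) list(met = m, atoms = target_atoms(m)))
  while (length(queue)) {
    u <- queue[[1]]; queue <- queue[-1]
    key <- emu_key(u$met, u$atoms)
    if (!is.null(emus[[key]]) || is_source_met(u$met)) next
    ps <- producers[[u$met]]
    if (is.null(ps) || sum(vapply(ps, `[[`, 0, "w")) <= ftol) {
      stop("metabolite ", u$met, " has label demand but no production")
    }
    terms <- list()
    for (p in ps) {
      if (p$type == "src") {
        terms <- c(terms, list(list(w = p$w, parts = list(
          list(met = u$met, atoms = u$atoms, source = TRUE, injected = TRUE)))))
        next
      }
      orx <- oriented[[p$rid]]
      sp_out <- orx$side_out[[u$met]]
      # letter -> (met, slot) lookup over the reactant side
      orientations <- list(u$atoms)
      if (u$met %in% names(network$symmetric)) {
        perm <- network$symmetric[[u$met]]
        orientations <- list(u$atoms, perm[u$atoms])
      }
      for (atoms_o in orientations) {
        letters_needed <- sp_out$letters[atoms_o]
        parts_by_met <- list()
        for (li in seq_along(letters_needed)) {
          lt <- letters_needed[li]
          hit <- NULL
          for (sp_in in orx$side_in) {
            slot <- match(lt, sp_in$letters)
            if (!is.na(slot)) { hit <- list(met = sp_in$met, slot = slot); break }
          }
          if (is.null(hit)) {
            stop("reaction ", p$rid, ": atom '", lt, "' of ", u$met,
                 " has no reactant origin")
          }
          parts_by_met[[hit$met]] <- c(parts_by_met[[hit$met]], hit$slot)
        }
        parts <- lapply(names(parts_by_met), function(m) {
          list(met = m, atoms = sort(parts_by_met[[m]]),
               source = is_source_met(m), injected = FALSE)
        })
        terms <- c(terms, list(list(w = p$w / length(orientations),
                                    parts = parts)))
        for (pt in parts) {
          if (!pt$source) {
            queue <- c(queue, list(list(met = pt$met, atoms = pt$atoms)))
          }
        }
      }
    }
    emus[[key]] <- list(met = u$met, atoms = u$atoms, size = length(u$atoms),
                        terms = terms)
  }

  # ---- solve size classes in ascending order ----
  solved <- list()  # key -> mid
  emu_mid <- function(pt) {
    if (pt$source) {
      source_emu_mid(pt$met, pt$atoms, tracer)
    } else {
      solved[[emu_key(pt$met, pt$atoms)]]
    }
  }
  sizes <- sort(unique(vapply(emus, `[[`, 0L, "size")))
  for (s in sizes) {
    keys <- names(emus)[vapply(emus, `[[`, 0L, "size") == s]
    n <- length(keys)
    A <- matrix(0, n, n, dimnames = list(keys, keys))
    B <- matrix(0, n, s + 1)
    for (i in seq_len(n)) {
      e <- emus[[keys[i]]]
      A[i, i] <- total_prod[[e$met]]
      for (tm in e$terms) {
        same_size_unknown <- length(tm$parts) == 1 && !tm$parts[[1]]$source &&
          length(tm$parts[[1]]$atoms) == s && !tm$parts[[1]]$injected
        if (same_size_unknown) {
          k2 <- emu_key(tm$parts[[1]]$met, tm$parts[[1]]$atoms)
          A[i, k2] <- A[i, k2] - tm$w
        } else {
          mid <- Reduce(convolve_mid, lapply(tm$parts, emu_mid))
          B[i, ] <- B[i, ] + tm$w * mid
        }
      }
    }
    X <- tryCatch(solve(A, B), error = function(e) {
      stop("singular labeling system at EMU size ", s,
           " (a traced metabolite has zero effective production)")
    })
    for (i in seq_len(n)) solved[[keys[i]]] <- pmax(X[i, ], 0)
  }

  out <- lapply(metabolites, function(m) {
    atoms <- target_atoms(m)
    mid <- if (is_source_met(m)) {
      source_emu_mid(m, atoms, tracer)
    } else {
      solved[[emu_key(m, atoms)]]
    }
    mid <- mid / sum(mid)
    stats::setNames(mid, paste0("m+", seq_along(mid) - 1))
  })
  names(out) <- metabolites
  structure(out, class = "labeling_state", isotope = "13C",
            tracer = tracer)
}

#' @export
print.labeling_state <- function(x, digits = 4, ...) {
  tr <- attr(x, "tracer")
  cat("Labeling state (", attr(x, "isotope"), " tracer on ", tr$substrate,
      "): ", length(x), " metabolites\n", sep = "")
  for (m in names(x)) {
    nz <- x[[m]][x[[m]] > 1e-4]
    cat("  ", format(m, width = 10), " ",
        paste(sprintf("%s=%.*f", names(nz), digits, nz), collapse = "  "),
        "\n", sep = "")
  }
  invisible(x)
}
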