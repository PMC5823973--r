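# Tracer specifications, the atom-transition view of a model, and
# deterministic single-route label propagation.

tracer_name_map <- c(glucose = "glc", glutamine = "gln", glutamate = "glu",
                     lactate = "lac", pyruvate = "pyr", aspartate = "asp",
                     malate = "mal", fumarate = "fum", alanine = "ala")

#' Specify an isotope tracer
#'
#' Either construct directly, or parse the field's shorthand with
#' `parse_tracer()`: `"U-13C-glutamine"` (uniformly labeled),
#' `"1-13C-glutamine"` (position 1), `"4-2H-glucose"` (deuterium at C4).
#' Common metabolite names resolve to the extracellular species of the
#' reference network (`glutamine` -> `gln_e`).
#'
#' @param substrate metabolite id of the labeled substrate (extracellular).
#' @param isotope `"13C"` or `"2H"`.
#' @param positions integer vector of labeled atom positions (1-based on the
#'   substrate's carbon skeleton).
#' @param enrichment fraction of substrate molecules carrying the label,
#'   in [0, 1]; default 1.
#' @return object of class `tracer_spec`.
#' @export
tracer_spec <- function(substrate, isotope = c("13C", "2H"), positions,
                        enrichment = 1.0) {
  isotope <- match.arg(isotope)
  positions <- sort(unique(as.integer(positions)))
  if (!length(positions) || any(positions < 1)) {
    stop("labeled positions must be positive integers")
  }
  if (enrichment < 0 || enrichment > 1) stop("enrichment must be in [0, 1]")
  structure(list(substrate = substrate, isotope = isotope,
                 positions = positions, enrichment = enrichment),
            class = "tracer_spec")
}

#' @rdname tracer_spec
#' @param x shorthand string, e.g. `"U-13C-glutamine"`.
#' @param model optional `metabolic_model` used to resolve `"U"` to the
#'   substrate's full carbon set and validate positions.
#' @export
parse_tracer <- function(x, model = NULL) {
  m <- regmatches(x, regexec("^(U|[0-9,]+)-(13C|2H)-(.+)$", x))[[1]]
  if (!length(m)) stop("unrecognized tracer shorthand: ", x)
  pos_str <- m[2]; isotope <- m[3]; met <- m[4]
  sub_id <- if (!is.null(model) && met %in% model$metabolites$id) met
    else if (met %in% names(tracer_name_map)) paste0(tracer_name_map[[met]], "_e")
    else met
  nc <- NULL
  if (!is.null(model)) {
    i <- match(sub_id, model$metabolites$id)
    if (is.na(i)) stop("tracer substrate not in model: ", sub_id)
    nc <- model$metabolites$n_carbons[i]
  }
  positions <- if (pos_str == "U") {
    if (is.null(nc)) stop("'U' tracer needs a model to resolve the carbon count")
    seq_len(nc)
  } else as.integer(strsplit(pos_str, ",")[[1]])
  if (!is.null(nc) && any(positions > nc)) {
    stop("labeled position beyond the ", nc, "-carbon skeleton of ", sub_id)
  }
  tracer_spec(sub_id, isotope, positions)
}

#' @export
print.tracer_spec <- function(x, ...) {
  cat(sprintf("Tracer: %s at %s position(s) %s, enrichment %.2f\n",
              x$isotope, x$substrate, paste(x$positions, collapse = ","),
              x$enrichment))
  invisible(x)
}

# ---- atom transition network ----

# Parsed view of a reaction's atom map: for each side, a named list
# met -> letters; plus slot-level source lookup for products.
parse_reaction_map <- function(rxn) {
  if (is.null(rxn$atom_map)) return(NULL)
  lhs <- parse_map_side(rxn$atom_map$lhs, rxn$id)
  rhs <- parse_map_side(rxn$atom_map$rhs, rxn$id)
  names(lhs) <- vapply(lhs, `[[`, "", "met")
  names(rhs) <- vapply(rhs, `[[`, "", "met")
  list(lhs = lhs, rhs = rhs)
}

#' Atom-transition view of a model
#'
#' Parses the atom maps, symmetric-metabolite permutations and hydride
#' annotations into the structure used by [simulate_13c()],
#' [simulate_2h_hydride()] and [route_masks()].
#'
#' @param model a `metabolic_model`.
#' @return object of class `atom_transition_network`.
#' @export
atom_transition_network <- function(model) {
  rep <- validate_atom_maps(model)
  if (nrow(rep$violations)) {
    stop("atom map violations; first: ", rep$violations$reaction[1], ": ",
         rep$violations$problem[1])
  }
  maps <- lapply(model$reactions, parse_reaction_map)
  hydride <- Filter(Negate(is.null),
                    lapply(model$reactions, `[[`, "hydride_map"))
  nc <- stats::setNames(model$metabolites$n_carbons, model$metabolites$id)
  structure(list(model = model, maps = maps, symmetric = model$symmetric,
                 hydride = hydride, n_carbons = nc),
            class = "atom_transition_network")
}

#' @export
print.atom_transition_network <- function(x, ...) {
  cat("Atom-transition network:", sum(!vapply(x$maps, is.null, TRUE)),
      "mapped reactions;", length(x$symmetric), "symmetric metabolites;",
      length(x$hydride), "hydride edges\n")
  invisible(x)
}

#' Single-route label propagation
#'
#' Propagates the tracer's labeled positions along an ordered reaction list
#' with no mixing — the formal version of a labeling schematic. Each
#' reaction is oriented automatically (the currently labeled metabolite must
#' appear on one side); co-substrates are unlabeled; the resulting integer
#' mass shift of every metabolite on the route is returned. Symmetric
#' intermediates permute positions but not counts, so mass shifts are
#' orientation-independent.
#'
#' @param network an `atom_transition_network` (or a `metabolic_model`).
#' @param route character vector of reaction ids, in pathway order.
#' @param tracer a `tracer_spec` (or shorthand string).
#' @return named integer vector: mass shift of the substrate and of each
#'   labeled product along the route.
#' @export
route_masks <- function(network, route, tracer) {
  if (inherits(network, "metabolic_model")) {
    network <- atom_transition_network(network)
  }
  if (is.character(tracer)) tracer <- parse_tracer(tracer, network$model)
  nc <- network$n_carbons
  if (any(tracer$positions > nc[[tracer$substrate]])) {
    stop("tracer positions exceed carbon count of ", tracer$substrate)
  }
  labeled <- stats::setNames(list(tracer$positions), tracer$substrate)
  current <- tracer$substrate        # metabolites reached so far
  shifts <- stats::setNames(length(tracer$positions), tracer$substrate)
  for (rid in route) {
    map <- network$maps[[rid]]
    if (is.null(map)) stop("reaction ", rid, " has no atom map")
    hit_l <- intersect(names(map$lhs), current)
    hit_r <- intersect(names(map$rhs), current)
    if (length(hit_l)) {
      side_in <- map$lhs; side_out <- map$rhs; used <- hit_l
    } else if (length(hit_r)) {
      side_in <- map$rhs; side_out <- map$lhs; used <- hit_r
    } else {
      stop("route disconnected at ", rid,
           ": no previously formed metabolite among its reactants")
    }
    # letters carried by labeled atoms of the consumed metabolites; a step
    # whose reactants lost the label continues with unlabeled products
    hot <- unlist(lapply(intersect(used, names(labeled)),
                         function(m) side_in[[m]]$letters[labeled[[m]]]))
    for (m in used) labeled[[m]] <- NULL
    current <- setdiff(current, used)
    for (sp in side_out) {
      current <- union(current, sp$met)
      hits <- which(sp$letters %in% hot)
      if (length(hits)) {
        labeled[[sp$met]] <- hits
        shifts[sp$met] <- length(hits)
      }
    }
  }
  shifts
}
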