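# Metabolic network container and its JSON serialization.
#
# A model is a list with: compartments (character), a metabolite table
# (id, name, compartment, n_carbons, formula), a list of reactions
# (id, stoichiometry as a named numeric vector, lb, ub, subsystem, optional
# atom_map / hydride_map), the id of the objective reaction, and an optional
# table of symmetric metabolites with their equivalent atom permutation
# (fumarate, succinate).

#' Construct a metabolic model
#'
#' @param metabolites data.frame with columns `id`, `name`, `compartment`,
#'   `n_carbons` and optionally `formula`.
#' @param reactions list of reactions; each a list with `id`,
#'   `stoichiometry` (named numeric, negative = consumed), `lb`, `ub`,
#'   optional `subsystem`, `atom_map` (list with `lhs`/`rhs` character
#'   vectors of `"metabolite:letters"` entries, one lowercase letter per
#'   carbon) and `hydride_map` (list with `pool` and either `donor` or
#'   `acceptor`, both `"metabolite:atom_index"`).
#' @param objective id of the objective reaction (flux maximized by [fba()]).
#' @param compartments character vector of compartment ids; defaults to the
#'   compartments used by `metabolites`.
#' @param symmetric named list mapping metabolite ids to an integer
#'   permutation of their carbon slots (molecular symmetry; label scrambling).
#' @param id model identifier.
#' @return object of class `metabolic_model`.
#' @export
metabolic_model <- function(metabolites, reactions, objective,
                            compartments = NULL, symmetric = list(),
                            id = "model") {
  metabolites <- as.data.frame(metabolites, stringsAsFactors = FALSE)
  if (is.null(metabolites$formula)) metabolites$formula <- NA_character_
  if (is.null(metabolites$name)) metabolites$name <- metabolites$id
  if (is.null(compartments)) compartments <- sort(unique(metabolites$compartment))
  names(reactions) <- vapply(reactions, `[[`, "", "id")
  model <- structure(list(
    id = id,
    compartments = compartments,
    metabolites = metabolites[, c("id", "name", "compartment", "n_carbons", "formula")],
    reactions = reactions,
    objective = objective,
    symmetric = symmetric
  ), class = "metabolic_model")
  validate_model(model)
  model
}

validate_model <- function(model) {
  mets <- model$metabolites
  if (anyDuplicated(mets$id)) {
    stop("duplicate metabolite ids: ",
         paste(unique(mets$id[duplicated(mets$id)]), collapse = ", "))
  }
  rids <- vapply(model$reactions, `[[`, "", "id")
  if (anyDuplicated(rids)) {
    stop("duplicate reaction ids: ", paste(rids[duplicated(rids)], collapse = ", "))
  }
  if (!all(mets$compartment %in% model$compartments)) {
    stop("metabolite compartment not declared: ",
         paste(setdiff(mets$compartment, model$compartments), collapse = ", "))
  }
  if (any(mets$n_carbons < 0)) stop("negative carbon count")
  for (rxn in model$reactions) {
    unknown <- setdiff(names(rxn$stoichiometry), mets$id)
    if (length(unknown)) {
      stop("reaction ", rxn$id, ": unknown metabolite ",
           paste(unknown, collapse = ", "))
    }
    if (rxn$lb > rxn$ub) {
      stop("reaction ", rxn$id, ": lower bound ", rxn$lb,
           " exceeds upper bound ", rxn$ub)
    }
  }
  if (!model$objective %in% rids) {
    stop("objective reaction not found: ", model$objective)
  }
  for (m in names(model$symmetric)) {
    nc <- mets$n_carbons[match(m, mets$id)]
    p <- model$symmetric[[m]]
    if (is.na(nc) || !setequal(p, seq_len(nc))) {
      stop("symmetric permutation for ", m, " is not a permutation of its carbons")
    }
  }
  invisible(model)
}

#' Stoichiometric matrix of a model
#'
#' Rows are metabolites (in `model$metabolites$id` order), columns reactions;
#' entry (i, j) is the signed coefficient of metabolite i in reaction j.
#'
#' @param model a `metabolic_model`.
#' @return numeric matrix with dimnames.
#' @export
stoichiometric_matrix <- function(model) {
  mids <- model$metabolites$id
  rids <- names(model$reactions)
  S <- matrix(0, length(mids), length(rids), dimnames = list(mids, rids))
  for (rxn in model$reactions) {
    S[names(rxn$stoichiometry), rxn$id] <- rxn$stoichiometry
  }
  S
}

reaction_bounds <- function(model) {
  cbind(lb = vapply(model$reactions, `[[`, 0, "lb"),
        ub = vapply(model$reactions, `[[`, 0, "ub"))
}

#' @export
print.metabolic_model <- function(x, ...) {
  cat("Metabolic model <", x$id, ">\n", sep = "")
  cat("  compartments: ", paste(x$compartments, collapse = ", "), "\n", sep = "")
  cat("  metabolites:  ", nrow(x$metabolites), "\n", sep = "")
  cat("  reactions:    ", length(x$reactions), "\n", sep = "")
  n_mapped <- sum(!vapply(x$reactions, function(r) is.null(r$atom_map), TRUE))
  cat("  atom-mapped:  ", n_mapped, "\n", sep = "")
  cat("  objective:    ", x$objective, "\n", sep = "")
  invisible(x)
}

# ---- atom map helpers ----

# parse "met:abcde" entries into list(met=, letters=character vector)
parse_map_side <- function(entries, rxn_id) {
  lapply(entries, function(e) {
    parts <- strsplit(e, ":", fixed = TRUE)[[1]]
    if (length(parts) != 2) stop("reaction ", rxn_id, ": malformed atom map entry '", e, "'")
    list(met = parts[1], letters = strsplit(parts[2], "")[[1]])
  })
}

#' Check carbon atom maps for conservation and bijectivity
#'
#' For every atom-mapped reaction, verifies that the mapped species exist in
#' the stoichiometry, that letter counts match the metabolites' carbon counts,
#' and that the map is a bijection between reactant and product carbon slots
#' (each letter used exactly once per side). Symmetric metabolites
#' (fumarate, succinate) are reported so downstream simulation applies
#' orientation scrambling. Violations are reported, not thrown.
#'
#' @param model a `metabolic_model`.
#' @return list with `violations` (data.frame: reaction, problem) and
#'   `symmetric` (character vector of symmetric metabolite ids).
#' @export
validate_atom_maps <- function(model) {
  nc <- stats::setNames(model$metabolites$n_carbons, model$metabolites$id)
  probs <- list()
  note <- function(rid, msg) probs[[length(probs) + 1]] <<- data.frame(
    reaction = rid, problem = msg, stringsAsFactors = FALSE)
  for (rxn in model$reactions) {
    am <- rxn$atom_map
    if (is.null(am)) next
    rid <- rxn$id
    lhs <- parse_map_side(am$lhs, rid)
    rhs <- parse_map_side(am$rhs, rid)
    for (side in list(lhs, rhs)) {
      for (sp in side) {
        if (!sp$met %in% names(rxn$stoichiometry)) {
          note(rid, paste0("mapped species ", sp$met, " not in stoichiometry"))
        } else if (length(sp$letters) != nc[[sp$met]]) {
          note(rid, paste0(sp$met, ": map has ", length(sp$letters),
                           " atoms but metabolite has ", nc[[sp$met]], " carbons"))
        }
      }
    }
    l_letters <- unlist(lapply(lhs, `[[`, "letters"))
    r_letters <- unlist(lapply(rhs, `[[`, "letters"))
    if (length(l_letters) != length(r_letters)) {
      note(rid, paste0("carbon count not conserved: ", length(l_letters),
                       " reactant vs ", length(r_letters), " product atoms"))
    }
    if (anyDuplicated(l_letters)) note(rid, "duplicate letters on reactant side")
    if (anyDuplicated(r_letters)) note(rid, "duplicate letters on product side")
    missing <- setdiff(l_letters, r_letters)
    extra <- setdiff(r_letters, l_letters)
    if (length(missing)) note(rid, paste0("atom(s) dropped: ", paste(missing, collapse = "")))
    if (length(extra)) note(rid, paste0("atom(s) invented: ", paste(extra, collapse = "")))
  }
  viol <- if (length(probs)) do.call(rbind, probs) else
    data.frame(reaction = character(), problem = character(), stringsAsFactors = FALSE)
  list(violations = viol, symmetric = names(model$symmetric))
}

# ---- JSON dialect ----

#' Read or write a model in the packaged JSON dialect
#'
#' The dialect mirrors the in-memory structure:
#' `{"id":..., "compartments":[...], "metabolites":[{id,name,compartment,
#' n_carbons,formula}], "reactions":[{id,stoichiometry:{met:coef},lb,ub,
#' subsystem,atom_map,hydride_map}], "objective":id, "symmetric":{met:[perm]}}`.
#'
#' @param path file path.
#' @return `read_model_json` returns a validated `metabolic_model`.
#' @export
read_model_json <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  mets <- do.call(rbind, lapply(raw$metabolites, function(m) data.frame(
    id = m$id, name = m$name %||% m$id, compartment = m$compartment,
    n_carbons = m$n_carbons, formula = m$formula %||% NA_character_,
    stringsAsFactors = FALSE)))
  rxns <- lapply(raw$reactions, function(r) {
    list(id = r$id,
         stoichiometry = unlist(r$stoichiometry),
         lb = as.numeric(r$lb), ub = as.numeric(r$ub),
         subsystem = r$subsystem %||% NA_character_,
         atom_map = if (!is.null(r$atom_map))
           list(lhs = unlist(r$atom_map$lhs), rhs = unlist(r$atom_map$rhs)),
         hydride_map = if (!is.null(r$hydride_map)) lapply(r$hydride_map, unlist))
  })
  metabolic_model(mets, rxns, objective = raw$objective,
                  compartments = unlist(raw$compartments),
                  symmetric = lapply(raw$symmetric, unlist),
                  id = raw$id %||% "model")
}

#' @rdname read_model_json
#' @param model a `metabolic_model`.
#' @export
write_model_json <- function(model, path) {
  out <- list(
    id = model$id,
    compartments = model$compartments,
    metabolites = lapply(seq_len(nrow(model$metabolites)), function(i) {
      m <- model$metabolites[i, ]
      x <- list(id = m$id, name = m$name, compartment = m$compartment,
                n_carbons = m$n_carbons)
      if (!is.na(m$formula)) x$formula <- m$formula
      x
    }),
    reactions = lapply(model$reactions, function(r) {
      x <- list(id = r$id, stoichiometry = as.list(r$stoichiometry),
                lb = r$lb, ub = r$ub)
      if (!is.null(r$subsystem) && !is.na(r$subsystem)) x$subsystem <- r$subsystem
      if (!is.null(r$atom_map)) x$atom_map <- list(lhs = as.list(r$atom_map$lhs),
                                                   rhs = as.list(r$atom_map$rhs))
      if (!is.null(r$hydride_map)) x$hydride_map <- r$hydride_map
      x
    }),
    objective = model$objective,
    symmetric = model$symmetric
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Load / save a model, dispatching on file extension
#'
#' `.json` uses the packaged dialect; `.xml`/`.sbml` uses SBML Level 3 with
#' the flux-balance (fbc) package (bounds and objective only; atom maps are
#' carried only by the JSON dialect).
#'
#' @param path file path ending in `.json`, `.xml` or `.sbml`.
#' @return a validated `metabolic_model`.
#' @export
load_model <- function(path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         json = read_model_json(path),
         xml = ,
         sbml = read_model_sbml(path),
         stop("unrecognized model format: .", ext))
}

#' @rdname load_model
#' @param model a `metabolic_model`.
#' @export
save_model <- function(model, path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         json = write_model_json(model, path),
         xml = ,
         sbml = write_model_sbml(model, path),
         stop("unrecognized model format: .", ext))
}

#' Packaged central-carbon reference reconstruction
#'
#' Loads the reconstruction shipped with the package: glycolysis, pyruvate
#' fate, TCA cycle, glutaminolysis, malate-aspartate shuttle, the
#' glycerol-3-phosphate shuttle, cytosolic reductive carboxylation
#' (IDH1 operating as a carboxylase, aconitase, ATP-citrate lyase, MDH1,
#' cytosolic fumarase, ME1), and the respiratory chain as proton-pumping
#' lumped complexes with an ATP-demand objective. Carbon atom maps cover all
#' carbon-carrying reactions; GAPDH, LDH, MDH1 and GPD1 additionally carry
#' hydride-transfer annotations for deuterium tracing.
#'
#' @return a `metabolic_model`.
#' @export
build_reference_network <- function() {
  read_model_json(system.file("extdata", "reference_model.json",
                              package = "mtflux", mustWork = TRUE))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
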