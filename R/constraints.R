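# Conversion of measured rates into model constraints, and recovery when a
# jointly infeasible measurement set needs relaxing.

#' Assemble a constraint set from measured rates
#'
#' `constraint_set()` is the low-level container: exchange-flux intervals and
#' respiratory-complex capacity caps keyed by reaction id.
#' `build_constraints()` derives one from measurement-level objects: CORE
#' exchange rates become `rate +/- k * SE` intervals on the matching exchange
#' reactions, and complex-resolved respirometry rates become upper bounds on
#' the lumped respiratory-chain reactions after unit conversion (see
#' [ocr_to_flux_bound()]).
#'
#' @param exchange_bounds data.frame with columns `reaction`, `lb`, `ub`.
#' @param complex_caps data.frame with columns `reaction`, `ub`.
#' @return object of class `constraint_set`.
#' @export
constraint_set <- function(exchange_bounds = NULL, complex_caps = NULL) {
  eb <- if (is.null(exchange_bounds)) {
    data.frame(reaction = character(), lb = numeric(), ub = numeric(),
               stringsAsFactors = FALSE)
  } else as.data.frame(exchange_bounds, stringsAsFactors = FALSE)
  rownames(eb) <- NULL
  cc <- if (is.null(complex_caps)) {
    data.frame(reaction = character(), ub = numeric(), stringsAsFactors = FALSE)
  } else as.data.frame(complex_caps, stringsAsFactors = FALSE)
  rownames(cc) <- NULL
  if (any(eb$lb > eb$ub)) {
    stop("constraint lb > ub for: ",
         paste(eb$reaction[eb$lb > eb$ub], collapse = ", "))
  }
  if (any(cc$ub < 0)) stop("negative complex capacity cap")
  structure(list(exchange_bounds = eb, complex_caps = cc),
            class = "constraint_set")
}

#' @export
print.constraint_set <- function(x, ...) {
  cat("Constraint set:", nrow(x$exchange_bounds), "exchange bounds,",
      nrow(x$complex_caps), "complex caps\n")
  invisible(x)
}

#' Convert a protein-normalized oxygen consumption rate to a flux bound
#'
#' Complex-resolved OCR is measured in pmol O2/min/µg protein; model fluxes
#' are µmol/min/gDW on an electron-pair basis (one NADH, succinate or QH2
#' oxidized per unit flux, i.e. 1/2 O2). The bridge is
#' `ocr * 1e-6 (pmol->µmol) * protein_ug_per_gdw * 2 (O2 -> electron pairs)`.
#' Neither factor is measured directly; `protein_ug_per_gdw` defaults to
#' 5e5 µg/gDW (protein ~ half of dry mass) and is exposed so users can log
#' and override it.
#'
#' @param ocr rate in pmol O2/min/µg protein.
#' @param protein_ug_per_gdw µg protein per g dry weight.
#' @return upper bound in µmol/min/gDW (electron-pair basis).
#' @export
ocr_to_flux_bound <- function(ocr, protein_ug_per_gdw = 5e5) {
  ocr * 1e-6 * protein_ug_per_gdw * 2
}

# complex id -> lumped RC reaction id in the reference network
complex_reaction_map <- c(CI = "CI", CII = "CII", CIII = "CIII", CIV = "CIV")

#' @rdname constraint_set
#' @param core_fluxes data.frame of exchange rates with columns
#'   `metabolite_id`, `rate`, `standard_error` (µmol/min/gDW; negative =
#'   uptake), as produced by [core_flux_from_plate()]. `metabolite_id` must
#'   match the base name of an exchange reaction (`EX_<metabolite_id>`).
#' @param complex_ocr data.frame with columns `complex_id` (CI..CIV) and
#'   `ocr` (pmol O2/min/µg protein), as produced by [extract_complex_ocr()].
#' @param k half-width of the exchange interval in standard errors.
#' @param protein_ug_per_gdw unit bridge passed to [ocr_to_flux_bound()].
#' @export
build_constraints <- function(core_fluxes = NULL, complex_ocr = NULL, k = 1,
                              protein_ug_per_gdw = 5e5) {
  eb <- NULL
  if (!is.null(core_fluxes) && nrow(core_fluxes)) {
    eb <- data.frame(
      reaction = paste0("EX_", core_fluxes$metabolite_id),
      lb = core_fluxes$rate - k * core_fluxes$standard_error,
      ub = core_fluxes$rate + k * core_fluxes$standard_error,
      stringsAsFactors = FALSE)
  }
  cc <- NULL
  if (!is.null(complex_ocr) && nrow(complex_ocr)) {
    rxn <- complex_reaction_map[complex_ocr$complex_id]
    if (anyNA(rxn)) {
      stop("unknown complex id: ",
           paste(complex_ocr$complex_id[is.na(rxn)], collapse = ", "))
    }
    cc <- data.frame(
      reaction = unname(rxn),
      ub = ocr_to_flux_bound(complex_ocr$ocr, protein_ug_per_gdw),
      stringsAsFactors = FALSE)
  }
  constraint_set(eb, cc)
}

#' Apply measured constraints to a model
#'
#' Returns a copy of the model with bounds tightened to the intersection of
#' the structural bounds and the measured intervals/caps; the input model is
#' untouched. A measurement that would widen a structural bound is clipped to
#' it with a warning (measurements cannot relax structure). An empty
#' intersection (e.g. measured uptake on a secretion-only reaction) is an
#' error naming the reaction. The measured intervals are recorded on the
#' returned model so [elastic_relax()] knows which bounds are data-derived.
#'
#' @param model a `metabolic_model`.
#' @param constraints a `constraint_set`.
#' @return a constrained `metabolic_model`.
#' @export
apply_constraints <- function(model, constraints) {
  stopifnot(inherits(constraints, "constraint_set"))
  out <- model
  meta <- list()
  tighten <- function(rid, new_lb, new_ub) {
    rxn <- out$reactions[[rid]]
    if (is.null(rxn)) stop("constraint references unknown reaction: ", rid)
    lb <- max(rxn$lb, new_lb)
    ub <- min(rxn$ub, new_ub)
    if (lb > ub + 1e-12) {
      stop("infeasible constraint on ", rid, ": measured [",
           format(new_lb), ", ", format(new_ub), "] does not intersect structural [",
           format(rxn$lb), ", ", format(rxn$ub), "]")
    }
    if (new_lb < rxn$lb - 1e-12 || new_ub > rxn$ub + 1e-12) {
      warning("measurement on ", rid,
              " extends beyond structural bounds; clipped", call. = FALSE)
    }
    meta[[rid]] <<- data.frame(
      reaction = rid, lb = lb, ub = ub,
      structural_lb = rxn$lb, structural_ub = rxn$ub, stringsAsFactors = FALSE)
    out$reactions[[rid]]$lb <<- lb
    out$reactions[[rid]]$ub <<- ub
  }
  eb <- constraints$exchange_bounds
  for (i in seq_len(nrow(eb))) tighten(eb$reaction[i], eb$lb[i], eb$ub[i])
  cc <- constraints$complex_caps
  for (i in seq_len(nrow(cc))) {
    rid <- cc$reaction[i]
    rxn <- out$reactions[[rid]]
    if (is.null(rxn)) stop("constraint references unknown reaction: ", rid)
    tighten(rid, rxn$lb, cc$ub[i])
  }
  out$measured <- if (length(meta)) do.call(rbind, meta) else NULL
  out
}

#' Read or write a constraint set as JSON
#'
#' Format: `{"exchange_bounds": {"EX_glc": [lb, ub], ...},
#' "complex_caps": {"CI": ub, ...}}`.
#'
#' @param path file path.
#' @export
read_constraints <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  eb <- if (length(raw$exchange_bounds)) data.frame(
    reaction = names(raw$exchange_bounds),
    lb = vapply(raw$exchange_bounds, function(x) as.numeric(x[[1]]), 0),
    ub = vapply(raw$exchange_bounds, function(x) as.numeric(x[[2]]), 0),
    stringsAsFactors = FALSE)
  cc <- if (length(raw$complex_caps)) data.frame(
    reaction = names(raw$complex_caps),
    ub = vapply(raw$complex_caps, as.numeric, 0),
    stringsAsFactors = FALSE)
  constraint_set(eb, cc)
}

#' @rdname read_constraints
#' @param constraints a `constraint_set`.
#' @export
write_constraints <- function(constraints, path) {
  eb <- constraints$exchange_bounds
  cc <- constraints$complex_caps
  out <- list(
    exchange_bounds = stats::setNames(
      lapply(seq_len(nrow(eb)), function(i) c(eb$lb[i], eb$ub[i])), eb$reaction),
    complex_caps = stats::setNames(as.list(cc$ub), cc$reaction))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Relax measurement-derived bounds to restore feasibility
#'
#' When jointly applied measurements make the model infeasible, finds the
#' minimum total (L1) relaxation of the measured intervals that admits a
#' steady-state flux vector; structural bounds are never relaxed. Feasible
#' models come back unchanged with zero slack.
#'
#' @param model a constrained `metabolic_model` (from [apply_constraints()]).
#' @return list with `model` (bounds widened by the fitted slacks), `slack`
#'   (data.frame: reaction, slack_lower, slack_upper) and `total_slack`.
#' @export
elastic_relax <- function(model) {
  meas <- model$measured
  if (is.null(meas) || !nrow(meas)) {
    fit <- fba(model)
    if (fit$status != "optimal") {
      stop("model has no measurement-derived bounds to relax and is ", fit$status)
    }
    return(list(model = model, slack = data.frame(
      reaction = character(), slack_lower = numeric(), slack_upper = numeric()),
      total_slack = 0))
  }
  S <- stoichiometric_matrix(model)
  rids <- names(model$reactions)
  n <- length(rids)
  k <- nrow(meas)
  im <- match(meas$reaction, rids)
  # variables: v (structural bounds), m (measured box), s_up, s_dn >= 0
  nv <- n + 3 * k
  Aeq <- matrix(0, nrow(S) + k, nv)
  Aeq[seq_len(nrow(S)), seq_len(n)] <- S
  for (j in seq_len(k)) {
    r <- nrow(S) + j
    Aeq[r, im[j]] <- 1          # v_i - m_j - s_up_j + s_dn_j = 0
    Aeq[r, n + j] <- -1
    Aeq[r, n + k + j] <- -1
    Aeq[r, n + 2 * k + j] <- 1
  }
  # v gets structural bounds (measured rows widened back to structure)
  bnd <- reaction_bounds(model)
  vlb <- bnd[, "lb"]; vub <- bnd[, "ub"]
  vlb[im] <- meas$structural_lb
  vub[im] <- meas$structural_ub
  span <- max(abs(c(vlb[is.finite(vlb)], vub[is.finite(vub)])), 1)
  lb <- c(vlb, meas$lb, rep(0, 2 * k))
  ub <- c(vub, meas$ub, rep(2 * span, 2 * k))
  obj <- c(rep(0, n + k), rep(1, 2 * k))
  sol <- solve_lp(obj, Aeq, rep(0, nrow(Aeq)), lb, ub, maximize = FALSE)
  if (sol$status != "optimal") {
    stop("structural infeasibility: model infeasible even with all ",
         "measured bounds relaxed")
  }
  s_up <- sol$v[n + k + seq_len(k)]
  s_dn <- sol$v[n + 2 * k + seq_len(k)]
  s_up[s_up < 1e-9] <- 0
  s_dn[s_dn < 1e-9] <- 0
  out <- model
  for (j in seq_len(k)) {
    rid <- meas$reaction[j]
    out$reactions[[rid]]$lb <- max(meas$structural_lb[j], meas$lb[j] - s_dn[j])
    out$reactions[[rid]]$ub <- min(meas$structural_ub[j], meas$ub[j] + s_up[j])
  }
  list(model = out,
       slack = data.frame(reaction = meas$reaction, slack_lower = s_dn,
                          slack_upper = s_up, stringsAsFactors = FALSE),
       total_slack = sum(s_up) + sum(s_dn))
}
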