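# Flux balance analysis and flux variability analysis on a metabolic_model.

#' Flux balance analysis
#'
#' Maximizes the flux of the model's objective reaction (an ATP-demand
#' reaction in the packaged reconstruction) subject to steady-state mass
#' balance `S v = 0` and the reaction bounds, and returns the optimal flux
#' vector. Solves are deterministic (single-threaded dense simplex with
#' Bland's rule), so repeated calls return the same vertex; alternate optima
#' are characterized with [fva()].
#'
#' @param model a `metabolic_model`.
#' @return an object of class `fba_fit`: list with `status` ("optimal",
#'   "infeasible" or "unbounded"), `objective_value`, `fluxes` (named vector,
#'   µmol/min/gDW), `objective_reaction` and `model`.
#' @seealso [fva()], [knockout()], [atp_contribution_scan()]
#' @export
fba <- function(model) {
  S <- stoichiometric_matrix(model)
  bnd <- reaction_bounds(model)
  obj <- as.numeric(names(model$reactions) == model$objective)
  sol <- solve_lp(obj, S, rep(0, nrow(S)), bnd[, "lb"], bnd[, "ub"])
  fluxes <- stats::setNames(sol$v, names(model$reactions))
  structure(list(
    status = sol$status,
    objective_value = if (sol$status == "optimal") sol$objective else NA_real_,
    fluxes = fluxes,
    objective_reaction = model$objective,
    model = model,
    tol = 1e-6
  ), class = "fba_fit")
}

#' @export
print.fba_fit <- function(x, ...) {
  cat("FBA fit (objective: ", x$objective_reaction, ")\n", sep = "")
  cat("  status:    ", x$status, "\n", sep = "")
  if (x$status == "optimal") {
    cat(sprintf("  objective: %.6g umol/min/gDW\n", x$objective_value))
    cat("  nonzero fluxes: ", sum(abs(x$fluxes) > x$tol), " of ",
        length(x$fluxes), "\n", sep = "")
  }
  invisible(x)
}

#' @export
coef.fba_fit <- function(object, ...) object$fluxes

#' @export
summary.fba_fit <- function(object, ...) {
  fl <- object$fluxes
  active <- fl[abs(fl) > object$tol]
  out <- list(status = object$status,
              objective_value = object$objective_value,
              n_reactions = length(fl),
              n_active = length(active),
              top = sort(abs(active), decreasing = TRUE)[seq_len(min(15, length(active)))])
  class(out) <- "summary.fba_fit"
  out
}

#' @export
print.summary.fba_fit <- function(x, ...) {
  cat("FBA summary: status ", x$status, ", objective ",
      format(x$objective_value, digits = 6), "\n", sep = "")
  cat(x$n_active, "of", x$n_reactions, "reactions carry flux; largest |flux|:\n")
  print(round(x$top, 4))
  invisible(x)
}

#' @export
plot.fba_fit <- function(x, n = 20, ...) {
  fl <- x$fluxes[abs(x$fluxes) > x$tol]
  fl <- fl[order(abs(fl), decreasing = TRUE)][seq_len(min(n, length(fl)))]
  graphics::dotchart(rev(fl), xlab = "flux (umol/min/gDW)",
                     main = "Largest predicted fluxes", ...)
  invisible(x)
}

#' Flux variability analysis
#'
#' For each reaction, minimizes and maximizes its flux subject to the model
#' constraints plus the requirement that the objective stays at or above
#' `gamma` times its optimum. Reactions whose range width is below `tol` are
#' flagged unique: their predicted flux admits no alternate optimum.
#'
#' @param model a `metabolic_model`.
#' @param gamma fraction of the optimal objective to enforce, in (0, 1];
#'   default 1 (certify uniqueness at the optimum).
#' @param reactions reaction ids to analyze (default all).
#' @param tol width below which a flux is flagged unique.
#' @return object of class `fva_result`: data.frame with columns `reaction`,
#'   `flux_min`, `flux_max`, `width`, `unique`, plus attributes
#'   `objective_value` and `gamma`.
#' @export
fva <- function(model, gamma = 1.0, reactions = NULL, tol = 1e-6) {
  stopifnot(gamma > 0, gamma <= 1)
  fit <- fba(model)
  if (fit$status != "optimal") {
    stop("FVA requires an optimal FBA solution; status was ", fit$status)
  }
  zstar <- fit$objective_value
  S <- stoichiometric_matrix(model)
  bnd <- reaction_bounds(model)
  rids <- names(model$reactions)
  iobj <- match(model$objective, rids)
  lb <- bnd[, "lb"]; ub <- bnd[, "ub"]
  lb[iobj] <- max(lb[iobj], gamma * zstar - 1e-9)
  zero <- rep(0, nrow(S))
  res <- lapply(if (is.null(reactions)) rids else reactions, function(rid) {
    i <- match(rid, rids)
    if (is.na(i)) stop("unknown reaction: ", rid)
    obj <- as.numeric(seq_along(rids) == i)
    lo <- solve_lp(obj, S, zero, lb, ub, maximize = FALSE)
    hi <- solve_lp(obj, S, zero, lb, ub, maximize = TRUE)
    if (lo$status != "optimal" || hi$status != "optimal") {
      stop("FVA subproblem for ", rid, " returned ", lo$status, "/", hi$status)
    }
    data.frame(reaction = rid, flux_min = lo$objective, flux_max = hi$objective,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$width <- out$flux_max - out$flux_min
  out$unique <- out$width < tol
  attr(out, "objective_value") <- zstar
  attr(out, "gamma") <- gamma
  class(out) <- c("fva_result", "data.frame")
  out
}

#' @export
print.fva_result <- function(x, ...) {
  cat("FVA at gamma = ", attr(x, "gamma"), " (objective ",
      format(attr(x, "objective_value"), digits = 6), "): ",
      sum(x$unique), " of ", nrow(x), " reaction fluxes unique\n", sep = "")
  NextMethod()
}
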