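# In-silico knockouts, ATP-contribution scans and between-condition flux
# differencing.

#' Block a reaction and re-solve
#'
#' Sets both bounds of the reaction to zero and reruns [fba()]; the input
#' model is untouched.
#'
#' @param model a `metabolic_model`.
#' @param reaction_id reaction to block.
#' @return an `fba_fit` for the blocked model.
#' @export
knockout <- function(model, reaction_id) {
  if (!reaction_id %in% names(model$reactions)) {
    stop("unknown reaction: ", reaction_id)
  }
  model$reactions[[reaction_id]]$lb <- 0
  model$reactions[[reaction_id]]$ub <- 0
  fba(model)
}

#' Per-reaction contribution to ATP production
#'
#' Blocks each reaction in turn (bounds set to zero, all other constraints
#' unchanged) and records the drop in optimal objective relative to the
#' complete model: `contribution = Z_full - Z_blocked` and
#' `percent_of_atp = 100 * contribution / Z_full`. A knockout that makes the
#' model infeasible loses all ATP production and is recorded as a
#' contribution of `Z_full` (100%). Contributions have no conservation
#' property across reactions (blocked flux reroutes), so only
#' non-negativity is meaningful; rows are returned in the model's reaction
#' order.
#'
#' @param model a `metabolic_model` whose full FBA is optimal.
#' @param reactions reaction ids to scan (default: all).
#' @return object of class `contribution_table`: data.frame with columns
#'   `reaction`, `objective_blocked`, `contribution`, `percent_of_atp`,
#'   `infeasible`; attribute `objective_full`.
#' @export
atp_contribution_scan <- function(model, reactions = NULL) {
  full <- fba(model)
  if (full$status != "optimal") {
    stop("full model does not solve to optimality: ", full$status)
  }
  zf <- full$objective_value
  rids <- if (is.null(reactions)) names(model$reactions) else reactions
  rows <- lapply(rids, function(rid) {
    kfit <- knockout(model, rid)
    zb <- if (kfit$status == "optimal") kfit$objective_value else 0
    infeas <- kfit$status != "optimal"
    contrib <- zf - zb
    data.frame(reaction = rid, objective_blocked = zb,
               contribution = contrib,
               percent_of_atp = if (zf > 0) 100 * contrib / zf else 0,
               infeasible = infeas, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  # clip tiny negative round-off
  out$contribution[out$contribution < 0 & out$contribution > -1e-6] <- 0
  out$percent_of_atp[out$percent_of_atp < 0 & out$percent_of_atp > -1e-4] <- 0
  attr(out, "objective_full") <- zf
  class(out) <- c("contribution_table", "data.frame")
  out
}

#' @export
print.contribution_table <- function(x, n = 10, ...) {
  cat("ATP-contribution scan (full objective ",
      format(attr(x, "objective_full"), digits = 6), "); top contributors:\n",
      sep = "")
  ord <- order(x$contribution, decreasing = TRUE)
  print.data.frame(utils::head(x[ord, ], n), row.names = FALSE)
  invisible(x)
}

#' Flux difference between two conditions
#'
#' Computes `delta = coef(result_b) - coef(result_a)` per reaction, ranks
#' reactions by `|delta|` (descending, ties broken by reaction id) and flags
#' the top decile (`ceiling(decile * n_ranked)` reactions). Exchange
#' reactions are included but labeled so they can be filtered.
#'
#' @param result_a,result_b optimal `fba_fit` objects over the same reaction
#'   set (condition A is the reference; positive `delta` = higher flux in B).
#' @param decile fraction of reactions to flag (default 0.10).
#' @return object of class `flux_difference_table`: data.frame with columns
#'   `reaction`, `flux_a`, `flux_b`, `delta`, `rank`, `top_decile`,
#'   `is_exchange`.
#' @export
flux_difference <- function(result_a, result_b, decile = 0.10) {
  stopifnot(inherits(result_a, "fba_fit"), inherits(result_b, "fba_fit"))
  if (result_a$status != "optimal" || result_b$status != "optimal") {
    stop("both fits must be optimal")
  }
  ra <- names(result_a$fluxes); rb <- names(result_b$fluxes)
  if (!identical(sort(ra), sort(rb))) {
    stop("reaction sets differ: ",
         paste(c(setdiff(ra, rb), setdiff(rb, ra)), collapse = ", "))
  }
  fa <- result_a$fluxes
  fb <- result_b$fluxes[names(fa)]
  delta <- fb - fa
  ord <- order(-abs(delta), names(fa))
  rank <- integer(length(delta))
  rank[ord] <- seq_along(delta)
  n_top <- ceiling(decile * length(delta))
  is_ex <- vapply(result_a$model$reactions[names(fa)], function(r) {
    length(r$stoichiometry) == 1
  }, TRUE)
  out <- data.frame(reaction = names(fa), flux_a = unname(fa),
                    flux_b = unname(fb), delta = unname(delta),
                    rank = rank, top_decile = rank <= n_top,
                    is_exchange = unname(is_ex), stringsAsFactors = FALSE)
  out <- out[order(out$rank), ]
  rownames(out) <- NULL
  class(out) <- c("flux_difference_table", "data.frame")
  out
}

#' @export
print.flux_difference_table <- function(x, n = 10, ...) {
  cat("Flux differences (B - A); ", sum(x$top_decile),
      " top-decile reactions:\n", sep = "")
  print.data.frame(utils::head(x, n), row.names = FALSE, digits = 4)
  invisible(x)
}

#' Network response to deleting one reaction
#'
#' Blocks `reaction_id`, re-solves, and returns the per-reaction flux
#' difference (deleted minus full) with top-decile ranking — which pathways
#' absorb the rerouted flux. If the deletion is infeasible the difference is
#' taken against an all-zero flux vector (total shutdown) and flagged.
#'
#' @inheritParams knockout
#' @param decile fraction of reactions to flag.
#' @return a `flux_difference_table` with attribute `deleted_feasible`.
#' @export
deletion_response <- function(model, reaction_id, decile = 0.10) {
  full <- fba(model)
  if (full$status != "optimal") {
    stop("model does not solve to optimality: ", full$status)
  }
  del <- knockout(model, reaction_id)
  feasible <- del$status == "optimal"
  if (!feasible) {
    del$fluxes[] <- 0
    del$status <- "optimal"   # zero vector stands in for total shutdown
    del$objective_value <- 0
  }
  out <- flux_difference(full, del, decile = decile)
  attr(out, "deleted_feasible") <- feasible
  attr(out, "deleted_reaction") <- reaction_id
  out
}
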