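# Deuterium tracing through the cytosolic NAD(H) pool. The model is the
# field's standard schematic: a deuterated substrate position rides its
# carbon to the dehydrogenase donor atom (positional propagation through the
# carbon atom maps), the abstracted hydride enters one well-mixed NAD(H)
# pool whose enrichment is the flux-weighted deuterated share of all
# hydride-producing fluxes, and every NADH-consuming reduction transfers
# label to its product at the pool enrichment. No kinetic isotope effects,
# no solvent exchange, no inter-compartment NADH deuteration.

#' Simulate deuterium transfer through the cytosolic NAD(H) pool
#'
#' For a 2H tracer (e.g. `"4-2H-glucose"`), computes the deuterium
#' enrichment at each annotated hydride-donor atom by positional propagation
#' through the carbon atom maps (the glucose C4 deuteron reaches the C1 of
#' glyceraldehyde 3-phosphate through the aldolase split), mixes the donor
#' fluxes into the NAD(H) pool, and labels each annotated acceptor's product
#' with m+1 at the pool enrichment.
#'
#' @inheritParams simulate_13c
#' @param tracer a `tracer_spec` with isotope `"2H"` (or shorthand).
#' @return object of class `hydride_state`: list with `pool_fraction`
#'   (deuterated fraction of the NAD(H) pool), `donors` and `acceptors`
#'   (data.frames with fluxes, enrichments and flux shares) and `labeling`
#'   (per acceptor-product metabolite, an m+0/m+1 fraction vector).
#' @export
simulate_2h_hydride <- function(network, fluxes, tracer, ftol = 1e-9) {
  if (inherits(network, "metabolic_model")) {
    network <- atom_transition_network(network)
  }
  model <- network$model
  if (is.character(tracer)) tracer <- parse_tracer(tracer, model)
  if (tracer$isotope != "2H") stop("simulate_2h_hydride requires a 2H tracer")
  if (!length(network$hydride)) {
    stop("model carries no hydride-transfer annotations")
  }
  v <- if (inherits(fluxes, "fba_fit")) fluxes$fluxes else fluxes

  parse_site <- function(x) {
    parts <- strsplit(x, ":", fixed = TRUE)[[1]]
    list(met = parts[1], atom = as.integer(parts[2]))
  }
  hyd <- lapply(names(network$hydride), function(rid) {
    h <- network$hydride[[rid]]
    list(rid = rid, pool = h$pool,
         donor = if (!is.null(h$donor)) parse_site(h$donor),
         acceptor = if (!is.null(h$acceptor)) parse_site(h$acceptor))
  })
  pools <- unique(vapply(hyd, `[[`, "", "pool"))
  if (length(pools) != 1) {
    stop("expected a single NAD(H) pool; found: ", paste(pools, collapse = ", "))
  }
  pool <- pools[1]

  # net production/consumption of the pool metabolite per reaction
  pool_flux <- vapply(model$reactions, function(r) {
    cf <- r$stoichiometry[pool]
    if (is.na(cf)) 0 else cf * v[[r$id]]
  }, 0)
  total_production <- sum(pool_flux[pool_flux > ftol])
  if (total_production <= ftol) {
    stop("zero turnover of ", pool, ": pool enrichment undefined")
  }

  # positional deuterium enrichment at each active donor atom, via the
  # carbon atom maps (a 13C pseudo-tracer at the same position gives the
  # positional propagation)
  pseudo <- tracer_spec(tracer$substrate, "13C", tracer$positions,
                        tracer$enrichment)
  donors <- Filter(function(h) !is.null(h$donor) &&
                     pool_flux[[h$rid]] > ftol, hyd)
  donor_df <- do.call(rbind, lapply(donors, function(h) {
    st <- simulate_13c(network, v, pseudo, metabolites = h$donor$met,
                       ftol = ftol, .atoms = h$donor$atom)
    p <- 1 - st[[h$donor$met]][["m+0"]]
    data.frame(reaction = h$rid, donor_metabolite = h$donor$met,
               donor_atom = h$donor$atom, flux = pool_flux[[h$rid]],
               enrichment = p, stringsAsFactors = FALSE)
  }))
  labeled_in <- if (is.null(donor_df)) 0 else
    sum(donor_df$flux * donor_df$enrichment)
  pool_fraction <- labeled_in / total_production

  consumers <- Filter(function(h) !is.null(h$acceptor) &&
                        pool_flux[[h$rid]] < -ftol, hyd)
  total_consumption <- -sum(pool_flux[pool_flux < -ftol])
  acceptor_df <- do.call(rbind, lapply(consumers, function(h) {
    data.frame(reaction = h$rid, product_metabolite = h$acceptor$met,
               product_atom = h$acceptor$atom, flux = -pool_flux[[h$rid]],
               flux_share = -pool_flux[[h$rid]] / total_consumption,
               stringsAsFactors = FALSE)
  }))
  labeling <- list()
  if (!is.null(acceptor_df)) {
    for (m in unique(acceptor_df$product_metabolite)) {
      labeling[[m]] <- stats::setNames(c(1 - pool_fraction, pool_fraction),
                                       c("m+0", "m+1"))
    }
  }
  structure(list(pool = pool, pool_fraction = pool_fraction,
                 donors = donor_df, acceptors = acceptor_df,
                 labeling = labeling, tracer = tracer),
            class = "hydride_state")
}

#' @export
print.hydride_state <- function(x, ...) {
  cat(sprintf("Deuterium hydride transfer via %s: pool fraction %.4f\n",
              x$pool, x$pool_fraction))
  if (!is.null(x$donors)) {
    cat("  donors:\n"); print.data.frame(x$donors, row.names = FALSE, digits = 4)
  }
  if (!is.null(x$acceptors)) {
    cat("  acceptors:\n"); print.data.frame(x$acceptors, row.names = FALSE, digits = 4)
  }
  invisible(x)
}
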