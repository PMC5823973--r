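# Heteroplasmy-graded synthetic measurement panels with known ground truth.
# A condition profile maps a heteroplasmy fraction h to respiratory-capacity
# and glycolytic scalings, derives a ground-truth flux vector by FBA on the
# reference network, and the generators emit CORE plates, complex-resolved
# respirometry plates and isotopologue tables that the measurements module
# can invert.

# Baseline condition parameters (µmol/min/gDW except where noted). The
# respiratory-chain base capacities and uptake capacities were chosen once so
# the unperturbed (h = 0) model respires near capacity with modest overflow
# lactate and the high-heteroplasmy model is forced into cytosolic NADH
# recycling; see the methods vignette.
synthetic_base <- list(
  glc_uptake = 0.55,     # pinned glucose uptake at h = 0 (transporter-limited)
  gln_uptake = 0.4,      # pinned glutamine uptake (biosynthetic programs)
  pyr_uptake_max = 0.1,  # medium pyruvate availability
  glu_uptake_max = 0.05,
  asp_uptake_max = 0,    # standard medium carries no aspartate
  rc_base = c(CI = 2.4, CII = 0.8, CIII = 2.6, CIV = 2.8),
  ocr_residual = 2,      # non-complex-driven OCR, pmol O2/min/ug protein
  protein_per_well = 10, # ug
  fresh_medium = c(glc = 25000, gln = 4000, pyr = 1000, lac = 0, glu = 0,
                   asp = 0, mal = 0, fum = 0, ala = 0),  # uM
  medium_volume = 1e-3,  # L
  cells = 5e5,           # cells per well (constant over the assay)
  gdw_per_cell = 3e-10,  # g dry weight per cell
  ion_scale = 1e6        # arbitrary total-ion intensity scale
)

#' Heteroplasmy-graded condition profile
#'
#' Maps a heteroplasmy fraction to the condition it induces: each
#' respiratory-complex capacity is scaled by `max(0, 1 - alpha * h)` and the
#' glycolytic (glucose uptake) capacity by `1 + beta * h`, mirroring the
#' dose-dependent fall in complex-driven respiration and the reciprocal rise
#' in glycolysis. The ground-truth flux vector is the FBA optimum of the
#' reference network under those capacities and is deterministic in
#' `(h, seed, parameters)`.
#'
#' @param h heteroplasmy fraction in [0, 1].
#' @param seed integer master seed for datasets generated from this profile.
#' @param alpha slope of the capacity loss per complex (default 0.9).
#' @param beta slope of the glycolytic up-regulation (default 1.5).
#' @param noise_cv coefficient of variation of measurement noise (default 0.05).
#' @param base named list of baseline parameters (see `mtflux:::synthetic_base`).
#' @return object of class `condition_profile` with the scalings, the
#'   constrained model and the ground-truth fluxes.
#' @export
make_profile <- function(h, seed = 1L, alpha = 0.9, beta = 1.5,
                         noise_cv = 0.05, base = synthetic_base) {
  if (h < 0 || h > 1) stop("heteroplasmy h must be in [0, 1]")
  rc_scale <- pmax(0, 1 - alpha * h)
  rc_scale <- stats::setNames(rep(rc_scale, length(base$rc_base)),
                              names(base$rc_base))
  glyc_scale <- 1 + beta * h
  model <- build_reference_network()
  glc <- base$glc_uptake * glyc_scale
  cs <- constraint_set(
    exchange_bounds = data.frame(
      reaction = c("EX_glc", "EX_gln", "EX_pyr", "EX_glu", "EX_asp"),
      lb = c(-glc, -base$gln_uptake, -base$pyr_uptake_max,
             -base$glu_uptake_max, -base$asp_uptake_max),
      ub = c(-glc, -base$gln_uptake, 50, 10, 50),
      stringsAsFactors = FALSE),
    complex_caps = data.frame(
      reaction = names(base$rc_base),
      ub = unname(base$rc_base * rc_scale[names(base$rc_base)]),
      stringsAsFactors = FALSE))
  constrained <- apply_constraints(model, cs)
  fit <- fba(constrained)
  if (fit$status != "optimal") {
    stop("ground-truth FBA not optimal at h = ", h, ": ", fit$status)
  }
  structure(list(
    label = sprintf("mT%d", round(100 * h)),
    h = h,
    rc_capacity_scale = rc_scale,
    glycolytic_scale = glyc_scale,
    ground_truth_fluxes = fit$fluxes,
    objective_value = fit$objective_value,
    model = constrained,
    noise_cv = noise_cv,
    seed = as.integer(seed),
    alpha = alpha, beta = beta,
    base = base
  ), class = "condition_profile")
}

#' @export
print.condition_profile <- function(x, ...) {
  cat(sprintf("Condition %s: h = %.2f, RC capacity x%.2f, glycolysis x%.2f\n",
              x$label, x$h, x$rc_capacity_scale[[1]], x$glycolytic_scale))
  cat(sprintf("  ground-truth ATP objective: %.4f umol/min/gDW (seed %d)\n",
              x$objective_value, x$seed))
  invisible(x)
}

#' Whole-cell isotopologue pools from a compartmentalized labeling state
#'
#' LC-MS measures total cellular pools, not compartment-resolved ones. This
#' helper averages the cytosolic and mitochondrial isotopologue
#' distributions of each metabolite, weighted by each compartment species'
#' total production rate under the flux vector (a steady-state proxy for
#' pool turnover), and returns one distribution per metabolite base name.
#' Extracellular species are excluded (they are measured in the medium).
#'
#' @param state a `labeling_state` from [simulate_13c()].
#' @param model the `metabolic_model` the state was computed on.
#' @param fluxes the flux vector used (named, or an `fba_fit`).
#' @return named list of pooled isotopologue fraction vectors.
#' @export
pool_isotopologues <- function(state, model, fluxes) {
  v <- if (inherits(fluxes, "fba_fit")) fluxes$fluxes else fluxes
  S <- stoichiometric_matrix(model)
  prod_rate <- rowSums(pmax(S %*% diag(v[colnames(S)]), 0))
  names(prod_rate) <- rownames(S)
  comp <- stats::setNames(model$metabolites$compartment, model$metabolites$id)
  intra <- names(state)[comp[names(state)] %in% c("c", "m")]
  base_names <- sub("_[cm]$", "", intra)
  out <- list()
  for (b in unique(base_names)) {
    species <- intra[base_names == b]
    w <- prod_rate[species]
    if (sum(w) <= 0) next
    mids <- lapply(state[species], unname)
    len <- max(lengths(mids))
    acc <- numeric(len)
    for (i in seq_along(species)) {
      mid <- c(mids[[i]], numeric(len - length(mids[[i]])))
      acc <- acc + w[[i]] * mid
    }
    out[[b]] <- stats::setNames(acc / sum(w), paste0("m+", seq_len(len) - 1))
  }
  out
}

# multiplicative gaussian noise, clamped at zero
noisy <- function(x, cv) {
  if (cv == 0) return(x)
  pmax(0, x * (1 + cv * stats::rnorm(length(x))))
}

#' Synthetic CORE (consumption-and-release) plate
#'
#' Spent-medium concentrations follow the profile's ground-truth exchange
#' fluxes (`spent = fresh + rate * cells * t * gdw / V`), perturbed by
#' multiplicative Gaussian noise with the profile's CV on both spent and
#' fresh (blank) rows; non-physical negative concentrations are clamped to
#' zero and flagged. With zero noise, [core_flux_from_plate()] inverts the
#' generator exactly.
#'
#' @param profile a `condition_profile`.
#' @param n_replicates spent-medium replicates (and fresh blanks).
#' @param duration_h assay duration in hours.
#' @param noise_cv overrides the profile's noise CV if given.
#' @return data.frame in the CORE plate layout (see [read_core_table()]),
#'   with attribute `clamped` listing clamped rows.
#' @export
generate_core_plate <- function(profile, n_replicates = 3, duration_h = 24,
                                noise_cv = NULL) {
  stopifnot(n_replicates >= 1)
  cv <- noise_cv %||% profile$noise_cv
  base <- profile$base
  set.seed(profile$seed + 1L)
  mets <- names(base$fresh_medium)
  cell_time <- base$cells * duration_h
  rows <- list()
  for (m in mets) {
    rate <- profile$ground_truth_fluxes[[paste0("EX_", m)]]
    fresh <- base$fresh_medium[[m]]
    spent_true <- fresh + rate * cell_time * base$gdw_per_cell * 60 /
      base$medium_volume
    for (r in seq_len(n_replicates)) {
      rows[[length(rows) + 1]] <- data.frame(
        metabolite_id = m, sample_type = "spent",
        concentration = noisy(spent_true, cv),
        medium_volume = base$medium_volume, cell_time_integral = cell_time,
        replicate = r, condition_label = profile$label,
        stringsAsFactors = FALSE)
      rows[[length(rows) + 1]] <- data.frame(
        metabolite_id = m, sample_type = "fresh",
        concentration = noisy(fresh, cv),
        medium_volume = base$medium_volume, cell_time_integral = NA_real_,
        replicate = r, condition_label = profile$label,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  clamped <- which(out$concentration == 0 & out$sample_type == "spent" &
                     base$fresh_medium[out$metabolite_id] > 0)
  attr(out, "clamped") <- clamped
  out
}

#' Exact standard error of a recovered CORE rate under the noise model
#'
#' The generator perturbs spent and fresh concentrations with multiplicative
#' Gaussian noise of coefficient of variation `cv`; the recovered rate is a
#' linear function of the two concentration means, so its standard error has
#' the closed form `cv * sqrt(spent^2 + fresh^2) / sqrt(n)` times the
#' volume/biomass conversion factor. Used to check recovery calibration.
#'
#' @param profile a `condition_profile`.
#' @param metabolite_id base metabolite name (e.g. `"glc"`).
#' @param n_replicates replicates per plate.
#' @param duration_h assay duration used by the plate generator.
#' @return standard error of the recovered rate (µmol/min/gDW).
#' @export
core_rate_se <- function(profile, metabolite_id, n_replicates = 3,
                         duration_h = 24) {
  base <- profile$base
  cv <- profile$noise_cv
  cell_time <- base$cells * duration_h
  k <- base$medium_volume / (cell_time * base$gdw_per_cell * 60)
  fresh <- base$fresh_medium[[metabolite_id]]
  rate <- profile$ground_truth_fluxes[[paste0("EX_", metabolite_id)]]
  spent <- fresh + rate / k
  cv * sqrt(spent^2 + fresh^2) / sqrt(n_replicates) * k
}

#' Synthetic complex-resolved respirometry plate
#'
#' Emits substrate- and inhibitor-phase wells for the CI/CII protocol
#' (glutamate/malate, rotenone, succinate, antimycin A), the CIII protocol
#' (duroquinol, antimycin A) and the CIV protocol (TMPD/ascorbate, azide).
#' Substrate-phase per-protein rates equal the profile's scaled complex
#' capacity (converted to pmol O2/min/µg protein) plus a residual
#' non-complex rate; inhibitor phases carry the residual only. Raw rates
#' scale with per-well protein mass; both get multiplicative noise.
#'
#' @inheritParams generate_core_plate
#' @param n_wells wells per injection phase.
#' @param protein_ug_per_gdw unit bridge (must match the one used when
#'   constraints are rebuilt from the plate).
#' @return data.frame in the rate-plate layout (see [read_rate_table()]).
#' @export
generate_ocr_plate <- function(profile, n_wells = 5, noise_cv = NULL,
                               protein_ug_per_gdw = 5e5) {
  stopifnot(n_wells >= 1)
  cv <- noise_cv %||% profile$noise_cv
  base <- profile$base
  set.seed(profile$seed + 2L)
  caps <- base$rc_base * profile$rc_capacity_scale[names(base$rc_base)]
  # invert the flux bound bridge: cap [umol/min/gDW] -> pmol O2/min/ug
  ocr <- caps / (1e-6 * protein_ug_per_gdw * 2)
  phase_rate <- c(glutamate_malate = unname(ocr["CI"]) + base$ocr_residual,
                  rotenone = base$ocr_residual,
                  succinate = unname(ocr["CII"]) + base$ocr_residual,
                  antimycin = base$ocr_residual,
                  duroquinol = unname(ocr["CIII"]) + base$ocr_residual,
                  tmpd_ascorbate = unname(ocr["CIV"]) + base$ocr_residual,
                  azide = base$ocr_residual)
  rows <- list()
  for (ph in names(phase_rate)) {
    for (w in seq_len(n_wells)) {
      protein <- max(1, base$protein_per_well * (1 + cv * stats::rnorm(1)))
      rows[[length(rows) + 1]] <- data.frame(
        well_id = sprintf("%s_%d", ph, w), injection_phase = ph,
        raw_rate = noisy(phase_rate[[ph]] * protein, cv),
        protein_mass = protein, condition_label = profile$label,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Synthetic isotopologue intensity tables
#'
#' True mass-isotopologue distributions come from the tracer simulator run
#' on the profile's ground-truth fluxes ([simulate_13c()] for 13C tracers,
#' [simulate_2h_hydride()] for 2H); intensities are fractions times a
#' random per-sample total-ion scale, with multiplicative noise, so that
#' [isotopologue_fractions()] renormalizes back to the truth (exactly at
#' zero noise).
#'
#' @inheritParams generate_core_plate
#' @param tracer a `tracer_spec` or shorthand string.
#' @param metabolites metabolites to report; default: a measurement-like
#'   panel of cytosolic/extracellular species for 13C tracers, or the
#'   hydride acceptors for 2H.
#' @param n_replicates samples per condition.
#' @return data.frame in the isotopologue-table layout
#'   (see [read_isotopologue_table()]).
#' @export
generate_labeling_tables <- function(profile, tracer, noise_cv = NULL,
                                     metabolites = NULL, n_replicates = 3) {
  cv <- noise_cv %||% profile$noise_cv
  base <- profile$base
  net <- atom_transition_network(profile$model)
  if (is.character(tracer)) tracer <- parse_tracer(tracer, profile$model)
  set.seed(profile$seed + 3L)
  if (tracer$isotope == "13C") {
    truth <- simulate_13c(net, profile$ground_truth_fluxes, tracer)
    dists <- pool_isotopologues(truth, profile$model,
                                profile$ground_truth_fluxes)
    if (!is.null(metabolites)) dists <- dists[intersect(metabolites, names(dists))]
  } else {
    hs <- simulate_2h_hydride(net, profile$ground_truth_fluxes, tracer)
    dists <- hs$labeling
    names(dists) <- sub("_[cm]$", "", names(dists))
    if (!is.null(metabolites)) dists <- dists[intersect(metabolites, names(dists))]
  }
  rows <- list()
  for (r in seq_len(n_replicates)) {
    sid <- sprintf("%s_rep%d", profile$label, r)
    for (m in names(dists)) {
      scale <- base$ion_scale * exp(if (cv > 0) stats::rnorm(1, 0, 0.2) else 0)
      frac <- dists[[m]]
      rows[[length(rows) + 1]] <- data.frame(
        sample_id = sid, condition_label = profile$label, metabolite_id = m,
        mass_shift = seq_along(frac) - 1,
        intensity = noisy(unname(frac) * scale, cv),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Generate and write a full synthetic dataset
#'
#' Bundles the CORE plate, the respirometry plate and one isotopologue table
#' per tracer, with a provenance block; `write_dataset()` writes each table
#' as CSV plus a provenance JSON. Regenerating with the same profile is
#' byte-identical.
#'
#' @inheritParams generate_core_plate
#' @param tracers character vector of tracer shorthands.
#' @param n_wells wells per respirometry phase.
#' @return object of class `synthetic_dataset`.
#' @export
generate_dataset <- function(profile, n_replicates = 3, duration_h = 24,
                             n_wells = 5,
                             tracers = c("U-13C-glutamine", "U-13C-glucose")) {
  labeling <- lapply(tracers, function(tr)
    generate_labeling_tables(profile, tr, n_replicates = n_replicates))
  names(labeling) <- tracers
  structure(list(
    core = generate_core_plate(profile, n_replicates, duration_h),
    ocr = generate_ocr_plate(profile, n_wells),
    labeling = labeling,
    provenance = list(label = profile$label, h = profile$h,
                      seed = profile$seed, alpha = profile$alpha,
                      beta = profile$beta, noise_cv = profile$noise_cv,
                      n_replicates = n_replicates, duration_h = duration_h,
                      n_wells = n_wells,
                      generator = paste0("mtflux ", utils::packageVersion("mtflux")))
  ), class = "synthetic_dataset")
}

#' @rdname generate_dataset
#' @param dataset a `synthetic_dataset`.
#' @param dir output directory (created if needed).
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(dataset$core, file.path(dir, "core_plate.csv"),
                   row.names = FALSE)
  utils::write.csv(dataset$ocr, file.path(dir, "ocr_plate.csv"),
                   row.names = FALSE)
  for (tr in names(dataset$labeling)) {
    fn <- paste0("labeling_", gsub("[^A-Za-z0-9]+", "_", tr), ".csv")
    utils::write.csv(dataset$labeling[[tr]], file.path(dir, fn),
                     row.names = FALSE)
  }
  jsonlite::write_json(dataset$provenance, file.path(dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
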