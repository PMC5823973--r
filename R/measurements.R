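# Normalization of raw plate / LC-MS style measurements and their conversion
# into model-ready exchange fluxes and respiratory capacities.

#' Exchange flux from spent/fresh medium concentrations
#'
#' Consumption-and-release (CORE) logic: the concentration change of a
#' metabolite over the culture interval, scaled by medium volume and divided
#' by the integrated cell exposure and the dry weight per cell, gives a
#' specific exchange rate. Negative rates are net consumption, positive net
#' release (constraint-based-modeling sign convention).
#'
#' @param spent_conc,fresh_conc metabolite concentration in spent and fresh
#'   medium (µM).
#' @param medium_volume culture volume (L).
#' @param cell_time_integral integrated cell exposure (cell·h).
#' @param gdw_per_cell dry weight per cell (g); default 3e-10 g/cell. The
#'   value is a configuration constant, not a measurement; override and log
#'   it for your cell type.
#' @return rate in µmol/min/gDW.
#' @examples
#' # 4 mM fresh glutamine, 3 mM left after culture: consumption
#' compute_exchange_flux(3000, 4000, 1e-3, 1e6, 3e-10)
#' @export
compute_exchange_flux <- function(spent_conc, fresh_conc, medium_volume,
                                  cell_time_integral, gdw_per_cell = 3e-10) {
  if (any(medium_volume <= 0)) stop("medium_volume must be positive")
  if (any(cell_time_integral <= 0)) stop("cell_time_integral must be positive")
  if (any(gdw_per_cell <= 0)) stop("gdw_per_cell must be positive")
  # µM * L = µmol; cell·h * g/cell = g·h; /60 -> per minute
  (spent_conc - fresh_conc) * medium_volume /
    (cell_time_integral * gdw_per_cell * 60)
}

#' Normalize isotopologue intensities to fractions of the total pool
#'
#' Divides each mass-shift intensity of a metabolite by the metabolite's
#' total isotopologue intensity, yielding the proportion-of-total-pool
#' vector m+0..m+N. Row order in the input is irrelevant; mass shifts absent
#' from the table are filled with zero up to the largest observed shift (or
#' `n_carbons` if supplied).
#'
#' @param table data.frame with columns `metabolite_id`, `mass_shift`,
#'   `intensity` (a `RawIntensityTable`; extra columns ignored). If several
#'   rows share a mass shift (replicates), intensities are summed.
#' @param metabolite_id metabolite to extract.
#' @param n_carbons optional carbon count; pads the vector to length
#'   `n_carbons + 1`.
#' @return object of class `isotopologue_distribution`: numeric vector of
#'   fractions named `m+0`, `m+1`, ... summing to 1.
#' @export
isotopologue_fractions <- function(table, metabolite_id, n_carbons = NULL) {
  rows <- table[table$metabolite_id == metabolite_id, , drop = FALSE]
  if (!nrow(rows)) stop("no rows for metabolite ", metabolite_id)
  if (any(rows$intensity < 0)) stop("negative intensity for ", metabolite_id)
  if (any(rows$mass_shift < 0)) stop("negative mass shift for ", metabolite_id)
  max_shift <- max(rows$mass_shift, n_carbons %||% 0)
  v <- numeric(max_shift + 1)
  agg <- tapply(rows$intensity, rows$mass_shift, sum)
  v[as.integer(names(agg)) + 1] <- agg
  tot <- sum(v)
  if (tot <= 0) {
    stop("all-zero intensities for ", metabolite_id, ": distribution undefined")
  }
  structure(stats::setNames(v / tot, paste0("m+", seq_along(v) - 1)),
            metabolite_id = metabolite_id,
            class = "isotopologue_distribution")
}

#' @export
print.isotopologue_distribution <- function(x, ...) {
  cat("Isotopologue distribution for ", attr(x, "metabolite_id"), ":\n", sep = "")
  print(round(unclass(x), 4))
  invisible(x)
}

#' Normalize each sample to its total ion sum
#'
#' Divides every intensity by the total intensity of its sample so that
#' per-sample totals equal 1; removes between-sample loading differences.
#'
#' @param table data.frame with columns `sample_id` and `intensity` (other
#'   columns preserved).
#' @return the table with normalized intensities.
#' @export
total_ion_sum_normalize <- function(table) {
  totals <- tapply(table$intensity, table$sample_id, sum)
  if (any(totals <= 0)) {
    stop("zero total ion sum for sample(s): ",
         paste(names(totals)[totals <= 0], collapse = ", "))
  }
  table$intensity <- as.numeric(table$intensity / totals[as.character(table$sample_id)])
  table
}

#' Normalize a plate rate to well protein content
#'
#' @param raw_rate measured OCR or ECAR.
#' @param protein_mass protein in the well (µg), > 0.
#' @return rate per µg protein.
#' @export
normalize_rate_to_protein <- function(raw_rate, protein_mass) {
  if (any(protein_mass <= 0)) stop("protein_mass must be positive")
  raw_rate / protein_mass
}

# which inhibitor terminates which substrate phase in the permeabilized-cell
# protocol: CI (glutamate/malate) is ended by rotenone, CII (succinate, after
# rotenone) by antimycin A, CIII (duroquinol) by antimycin A, CIV
# (TMPD/ascorbate) by azide.
complex_phase_map <- list(
  CI   = c(substrate = "glutamate_malate", inhibitor = "rotenone"),
  CII  = c(substrate = "succinate",        inhibitor = "antimycin"),
  CIII = c(substrate = "duroquinol",       inhibitor = "antimycin"),
  CIV  = c(substrate = "tmpd_ascorbate",   inhibitor = "azide")
)

#' Complex-resolved respiration from a substrate/inhibitor plate
#'
#' Computes, for each respiratory complex, the mean protein-normalized OCR
#' of its substrate phase minus the mean of the matching inhibitor phase,
#' floored at zero (a post-inhibition rate above the substrate rate is
#' measurement noise). Phase labels follow the permeabilized-cell protocol:
#' glutamate/malate terminated by rotenone (CI), succinate by antimycin A
#' (CII), duroquinol by antimycin A (CIII), TMPD/ascorbate by azide (CIV).
#'
#' @param wells data.frame with columns `injection_phase` (one of
#'   `glutamate_malate`, `rotenone`, `succinate`, `antimycin`, `duroquinol`,
#'   `tmpd_ascorbate`, `azide`), `raw_rate` and `protein_mass` (µg), one row
#'   per well measurement.
#' @param complexes complexes to extract (default CI..CIV as available).
#' @return data.frame with columns `complex_id` and `ocr`
#'   (pmol O2/min/µg protein, >= 0).
#' @export
extract_complex_ocr <- function(wells, complexes = names(complex_phase_map)) {
  rate <- normalize_rate_to_protein(wells$raw_rate, wells$protein_mass)
  phase_mean <- function(phase, cx) {
    r <- rate[wells$injection_phase == phase]
    if (!length(r)) {
      stop("complex ", cx, ": no wells for phase '", phase, "'")
    }
    mean(r)
  }
  rows <- lapply(complexes, function(cx) {
    ph <- complex_phase_map[[cx]]
    if (is.null(ph)) stop("unknown complex: ", cx)
    ocr <- phase_mean(ph[["substrate"]], cx) - phase_mean(ph[["inhibitor"]], cx)
    data.frame(complex_id = cx, ocr = max(0, ocr), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Redox index from a calibrated NAD(P)H fluorescence time series
#'
#' Rescales a basal fluorescence value against the cyanide plateau (maximal
#' reduction, set to 100) and the FCCP plateau (maximal oxidation, set to 0),
#' clamped to [0, 100].
#'
#' @param basal basal fluorescence (a.u.).
#' @param cn_plateau mean fluorescence after cyanide addition.
#' @param fccp_plateau mean fluorescence after FCCP addition.
#' @return percent reduced, in [0, 100].
#' @export
nadph_redox_index <- function(basal, cn_plateau, fccp_plateau) {
  if (any(abs(cn_plateau - fccp_plateau) < .Machine$double.eps^0.5)) {
    stop("degenerate calibration: cyanide and FCCP plateaus coincide")
  }
  pmin(100, pmax(0, 100 * (basal - fccp_plateau) / (cn_plateau - fccp_plateau)))
}

#' Natural-abundance correction of an isotopologue distribution
#'
#' Optional classical correction: the measured distribution is modeled as
#' `M = C x` where `C[i, j]` is the binomial probability that a molecule with
#' j tracer atoms shows i heavy atoms given natural abundance `p` at the
#' remaining positions; the corrected distribution solves the triangular
#' system and is clipped/renormalized. Off by default throughout the package,
#' matching the uncorrected proportion-of-total-pool convention.
#'
#' @param fractions an `isotopologue_distribution` (or plain numeric vector
#'   m+0..m+N).
#' @param p natural abundance of the heavy isotope (default 0.011 for 13C).
#' @return corrected fraction vector of the same length.
#' @export
correct_natural_abundance <- function(fractions, p = 0.011) {
  n <- length(fractions) - 1
  C <- matrix(0, n + 1, n + 1)
  for (j in 0:n) {
    # j tracer-labeled positions fixed; n - j positions free to be heavy
    for (i in j:n) {
      C[i + 1, j + 1] <- stats::dbinom(i - j, n - j, p)
    }
  }
  x <- solve(C, as.numeric(fractions))
  x[x < 0] <- 0
  structure(stats::setNames(x / sum(x), names(fractions)),
            metabolite_id = attr(fractions, "metabolite_id"),
            class = class(fractions))
}

#' CORE exchange fluxes from a plate table
#'
#' Converts a consumption-and-release plate (replicate spent-medium
#' concentrations plus fresh-medium blanks) into per-metabolite exchange
#' rates with standard errors. Replicate rates are averaged; the standard
#' error is the sample SD over sqrt(n); with a single replicate the SE is 0
#' with a warning.
#'
#' @param plate data.frame with columns `metabolite_id`, `sample_type`
#'   (`"spent"` or `"fresh"`), `concentration` (µM), `medium_volume` (L),
#'   `cell_time_integral` (cell·h; ignored for fresh rows), `replicate`.
#' @param gdw_per_cell dry weight per cell (g).
#' @return data.frame with columns `metabolite_id`, `rate`,
#'   `standard_error`, `n` (a `CoreFlux` table).
#' @export
core_flux_from_plate <- function(plate, gdw_per_cell = 3e-10) {
  mets <- unique(plate$metabolite_id)
  rows <- lapply(mets, function(m) {
    sub <- plate[plate$metabolite_id == m, , drop = FALSE]
    fresh <- sub$concentration[sub$sample_type == "fresh"]
    if (!length(fresh)) stop("no fresh-medium blank for ", m)
    spent <- sub[sub$sample_type == "spent", , drop = FALSE]
    if (!nrow(spent)) stop("no spent-medium rows for ", m)
    rates <- compute_exchange_flux(spent$concentration, mean(fresh),
                                   spent$medium_volume,
                                   spent$cell_time_integral, gdw_per_cell)
    n <- length(rates)
    se <- if (n >= 2) stats::sd(rates) / sqrt(n) else {
      warning("single replicate for ", m, "; standard error set to 0",
              call. = FALSE)
      0
    }
    data.frame(metabolite_id = m, rate = mean(rates), standard_error = se,
               n = n, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# ---- delimited-text readers ----

#' Read measurement tables from delimited text
#'
#' Three thin readers for the package's tabular dialects (comma- or
#' tab-separated, detected from the extension: `.tsv`/`.tab` vs anything
#' else). Required columns: CORE plates — `metabolite_id`, `sample_type`,
#' `concentration`, `medium_volume`, `cell_time_integral`, `replicate`;
#' rate plates — `well_id`, `injection_phase`, `raw_rate`, `protein_mass`;
#' isotopologue tables — `sample_id`, `condition_label`, `metabolite_id`,
#' `mass_shift`, `intensity`.
#'
#' @param path file path.
#' @return data.frame.
#' @export
read_core_table <- function(path) {
  read_measurement_table(path, c("metabolite_id", "sample_type", "concentration",
                                 "medium_volume", "cell_time_integral", "replicate"))
}

#' @rdname read_core_table
#' @export
read_rate_table <- function(path) {
  read_measurement_table(path, c("well_id", "injection_phase", "raw_rate",
                                 "protein_mass"))
}

#' @rdname read_core_table
#' @export
read_isotopologue_table <- function(path) {
  tab <- read_measurement_table(path, c("sample_id", "condition_label",
                                        "metabolite_id", "mass_shift", "intensity"))
  if (any(tab$intensity < 0)) stop("negative intensities in ", path)
  key <- paste(tab$sample_id, tab$metabolite_id, tab$mass_shift)
  if (anyDuplicated(key)) {
    stop("duplicate (sample, metabolite, mass_shift) rows in ", path)
  }
  tab
}

read_measurement_table <- function(path, required) {
  sep <- if (grepl("\\.(tsv|tab)$", path, ignore.case = TRUE)) "\t" else ","
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE)
  missing <- setdiff(required, names(tab))
  if (length(missing)) {
    stop("missing column(s) in ", path, ": ", paste(missing, collapse = ", "))
  }
  tab
}
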