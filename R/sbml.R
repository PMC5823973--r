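# Minimal SBML Level 3 (fbc v2) import/export: species, reactions,
# stoichiometry, flux bounds and the active objective. Atom maps and hydride
# annotations are not part of SBML fbc and travel only in the JSON dialect.

sbml_ns <- c(s = "http://www.sbml.org/sbml/level3/version1/core",
             fbc = "http://www.sbml.org/sbml/level3/version1/fbc/version2")

#' @rdname load_model
#' @export
read_model_sbml <- function(path) {
  if (!requireNamespace("xml2", quietly = TRUE)) {
    stop("SBML import requires the xml2 package")
  }
  doc <- xml2::read_xml(path)
  ns <- sbml_ns
  sp <- xml2::xml_find_all(doc, ".//s:listOfSpecies/s:species", ns)
  mets <- data.frame(
    id = xml2::xml_attr(sp, "id"),
    name = xml2::xml_attr(sp, "name"),
    compartment = xml2::xml_attr(sp, "compartment"),
    n_carbons = {
      nc <- xml2::xml_attr(sp, "ncarbons")
      ifelse(is.na(nc), 0L, as.integer(nc))
    },
    formula = xml2::xml_attr(sp, "chemicalFormula"),
    stringsAsFactors = FALSE)
  mets$name[is.na(mets$name)] <- mets$id[is.na(mets$name)]

  params <- xml2::xml_find_all(doc, ".//s:listOfParameters/s:parameter", ns)
  pvals <- stats::setNames(as.numeric(xml2::xml_attr(params, "value")),
                           xml2::xml_attr(params, "id"))

  rnodes <- xml2::xml_find_all(doc, ".//s:listOfReactions/s:reaction", ns)
  rxns <- lapply(rnodes, function(rn) {
    rid <- xml2::xml_attr(rn, "id")
    rs <- xml2::xml_find_all(rn, "./s:listOfReactants/s:speciesReference", ns)
    ps <- xml2::xml_find_all(rn, "./s:listOfProducts/s:speciesReference", ns)
    stoich <- c(
      stats::setNames(-as.numeric(xml2::xml_attr(rs, "stoichiometry")),
                      xml2::xml_attr(rs, "species")),
      stats::setNames(as.numeric(xml2::xml_attr(ps, "stoichiometry")),
                      xml2::xml_attr(ps, "species")))
    tp <- tapply(stoich, names(stoich), sum)  # merge duplicate species
    stoich <- stats::setNames(as.numeric(tp), names(tp))
    lb_ref <- xml2::xml_attr(rn, "fbc:lowerFluxBound", ns = ns)
    ub_ref <- xml2::xml_attr(rn, "fbc:upperFluxBound", ns = ns)
    list(id = rid, stoichiometry = stoich[abs(stoich) > 0],
         lb = unname(pvals[lb_ref]), ub = unname(pvals[ub_ref]),
         subsystem = NA_character_)
  })

  obj <- xml2::xml_find_first(
    doc, ".//fbc:listOfObjectives/fbc:objective/fbc:listOfFluxObjectives/fbc:fluxObjective", ns)
  objective <- xml2::xml_attr(obj, "fbc:reaction", ns = ns)
  mid <- xml2::xml_attr(xml2::xml_find_first(doc, ".//s:model", ns), "id")
  metabolic_model(mets, rxns, objective = objective, id = mid %||% "model")
}

#' @rdname load_model
#' @export
write_model_sbml <- function(model, path) {
  if (!requireNamespace("xml2", quietly = TRUE)) {
    stop("SBML export requires the xml2 package")
  }
  esc <- function(x) gsub("&", "&amp;", x, fixed = TRUE)
  bnds <- reaction_bounds(model)
  pids <- character(0); pvals <- numeric(0)
  pid_for <- function(v) {
    hit <- which(pvals == v)
    if (length(hit)) return(pids[hit[1]])
    id <- sprintf("fb_%d", length(pids) + 1)
    pids <<- c(pids, id); pvals <<- c(pvals, v)
    id
  }
  rx_xml <- vapply(model$reactions, function(r) {
    side <- function(coefs, tag) {
      if (!length(coefs)) return("")
      refs <- paste0(sprintf(
        '        <speciesReference species="%s" stoichiometry="%g" constant="true"/>',
        names(coefs), abs(unname(coefs))), collapse = "\n")
      sprintf("      <listOf%s>\n%s\n      </listOf%s>", tag, refs, tag)
    }
    st <- r$stoichiometry
    paste0(sprintf(
      '    <reaction id="%s" reversible="%s" fast="false" fbc:lowerFluxBound="%s" fbc:upperFluxBound="%s">\n',
      r$id, tolower(r$lb < 0), pid_for(r$lb), pid_for(r$ub)),
      side(st[st < 0], "Reactants"), "\n",
      side(st[st > 0], "Products"), "\n    </reaction>")
  }, "")
  met_xml <- vapply(seq_len(nrow(model$metabolites)), function(i) {
    m <- model$metabolites[i, ]
    sprintf(paste0('    <species id="%s" name="%s" compartment="%s" ncarbons="%d"',
                   ' hasOnlySubstanceUnits="false" boundaryCondition="false" constant="false"/>'),
            m$id, esc(m$name), m$compartment, m$n_carbons)
  }, "")
  par_xml <- sprintf('    <parameter id="%s" value="%g" constant="true"/>', pids, pvals)
  comp_xml <- sprintf('    <compartment id="%s" constant="true"/>', model$compartments)
  doc <- paste0(
    '<?xml version="1.0" encoding="UTF-8"?>\n',
    '<sbml xmlns="', sbml_ns[["s"]], '" xmlns:fbc="', sbml_ns[["fbc"]],
    '" level="3" version="1" fbc:required="false">\n',
    '  <model id="', model$id, '" fbc:strict="true">\n',
    "  <listOfCompartments>\n", paste(comp_xml, collapse = "\n"),
    "\n  </listOfCompartments>\n",
    "  <listOfSpecies>\n", paste(met_xml, collapse = "\n"), "\n  </listOfSpecies>\n",
    "  <listOfParameters>\n", paste(par_xml, collapse = "\n"), "\n  </listOfParameters>\n",
    "  <listOfReactions>\n", paste(rx_xml, collapse = "\n"), "\n  </listOfReactions>\n",
    "  <fbc:listOfObjectives fbc:activeObjective=\"obj\">\n",
    '    <fbc:objective fbc:id="obj" fbc:type="maximize">\n',
    "      <fbc:listOfFluxObjectives>\n",
    sprintf('        <fbc:fluxObjective fbc:reaction="%s" fbc:coefficient="1"/>\n',
            model$objective),
    "      </fbc:listOfFluxObjectives>\n",
    "    </fbc:objective>\n",
    "  </fbc:listOfObjectives>\n",
    "  </model>\n</sbml>\n")
  writeLines(doc, path)
  invisible(path)
}
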