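# Builds inst/extdata/reference_model.json, the packaged central-carbon
# reconstruction. Run from the repository root:
#   Rscript data-raw/reference_model.R
# Atom-map conventions: one lowercase letter per carbon; letters are local to
# a reaction. Carbon slot layouts (fixed per metabolite across reactions):
#   glucose a..f = C1..C6; triose slots follow the classic aldolase split
#   (DHAP = glucose C3,C2,C1; GAP = glucose C4,C5,C6); citrate/isocitrate
#   slots 1-4 = oxaloacetate moiety, slots 5-6 = acetyl moiety, with the
#   carboxylation-derived carbon entering slot 4 via the "abcde + f" layout
#   used for IDH; 2-oxoglutarate a..e = C1..C5 (C1 lost at OGDH).

devtools::load_all(".", quiet = TRUE)

M <- 1000  # default structural bound, umol/min/gDW

met <- function(id, name, comp, nc, formula = NA_character_) {
  data.frame(id = id, name = name, compartment = comp, n_carbons = nc,
             formula = formula, stringsAsFactors = FALSE)
}

mets <- rbind(
  # extracellular
  met("glc_e",  "D-glucose",        "e", 6, "C6H12O6"),
  met("gln_e",  "L-glutamine",      "e", 5, "C5H10N2O3"),
  met("glu_e",  "L-glutamate",      "e", 5),
  met("lac_e",  "L-lactate",        "e", 3, "C3H6O3"),
  met("pyr_e",  "pyruvate",         "e", 3, "C3H4O3"),
  met("asp_e",  "L-aspartate",      "e", 4),
  met("mal_e",  "L-malate",         "e", 4, "C4H6O5"),
  met("fum_e",  "fumarate",         "e", 4, "C4H4O4"),
  met("ala_e",  "L-alanine",        "e", 3),
  met("nh4_e",  "ammonium",         "e", 0),
  met("o2_e",   "oxygen",           "e", 0, "O2"),
  met("co2_e",  "carbon dioxide",   "e", 1, "CO2"),
  met("pi_e",   "phosphate",        "e", 0),
  met("h2o_e",  "water",            "e", 0, "H2O"),
  # cytosol
  met("glc_c",  "D-glucose",        "c", 6),
  met("g6p_c",  "glucose 6-phosphate", "c", 6),
  met("f6p_c",  "fructose 6-phosphate", "c", 6),
  met("fbp_c",  "fructose 1,6-bisphosphate", "c", 6),
  met("dhap_c", "dihydroxyacetone phosphate", "c", 3),
  met("gap_c",  "glyceraldehyde 3-phosphate", "c", 3),
  met("bpg13_c","1,3-bisphosphoglycerate", "c", 3),
  met("pg3_c",  "3-phosphoglycerate", "c", 3),
  met("pg2_c",  "2-phosphoglycerate", "c", 3),
  met("pep_c",  "phosphoenolpyruvate", "c", 3),
  met("pyr_c",  "pyruvate",         "c", 3),
  met("lac_c",  "L-lactate",        "c", 3),
  met("g3p_c",  "glycerol 3-phosphate", "c", 3),
  met("gln_c",  "L-glutamine",      "c", 5),
  met("glu_c",  "L-glutamate",      "c", 5),
  met("akg_c",  "2-oxoglutarate",   "c", 5),
  met("icit_c", "isocitrate",       "c", 6),
  met("acon_c", "cis-aconitate",    "c", 6),
  met("cit_c",  "citrate",          "c", 6),
  met("oaa_c",  "oxaloacetate",     "c", 4),
  met("mal_c",  "L-malate",         "c", 4),
  met("fum_c",  "fumarate",         "c", 4),
  met("asp_c",  "L-aspartate",      "c", 4),
  met("ala_c",  "L-alanine",        "c", 3),
  met("accoa_c","acetyl-CoA (acetyl unit)", "c", 2),
  met("coa_c",  "coenzyme A",       "c", 0),
  met("nad_c",  "NAD+ (cytosolic)", "c", 0),
  met("nadh_c", "NADH (cytosolic)", "c", 0),
  met("nadp_c", "NADP+ (cytosolic)","c", 0),
  met("nadph_c","NADPH (cytosolic)","c", 0),
  met("atp_c",  "ATP (cytosolic)",  "c", 0),
  met("adp_c",  "ADP (cytosolic)",  "c", 0),
  met("pi_c",   "phosphate",        "c", 0),
  met("co2_c",  "carbon dioxide",   "c", 1),
  met("nh4_c",  "ammonium",         "c", 0),
  met("h2o_c",  "water",            "c", 0),
  # mitochondrion
  met("pyr_m",  "pyruvate",         "m", 3),
  met("accoa_m","acetyl-CoA (acetyl unit)", "m", 2),
  met("coa_m",  "coenzyme A",       "m", 0),
  met("cit_m",  "citrate",          "m", 6),
  met("icit_m", "isocitrate",       "m", 6),
  met("akg_m",  "2-oxoglutarate",   "m", 5),
  met("succoa_m","succinyl-CoA (succinyl unit)", "m", 4),
  met("succ_m", "succinate",        "m", 4),
  met("fum_m",  "fumarate",         "m", 4),
  met("mal_m",  "L-malate",         "m", 4),
  met("oaa_m",  "oxaloacetate",     "m", 4),
  met("glu_m",  "L-glutamate",      "m", 5),
  met("asp_m",  "L-aspartate",      "m", 4),
  met("nad_m",  "NAD+ (matrix)",    "m", 0),
  met("nadh_m", "NADH (matrix)",    "m", 0),
  met("q_m",    "ubiquinone",       "m", 0),
  met("qh2_m",  "ubiquinol",        "m", 0),
  met("cytc_ox_m", "cytochrome c (oxidized)", "m", 0),
  met("cytc_red_m","cytochrome c (reduced)",  "m", 0),
  met("o2_m",   "oxygen",           "m", 0),
  met("co2_m",  "carbon dioxide",   "m", 1),
  met("atp_m",  "ATP (matrix)",     "m", 0),
  met("adp_m",  "ADP (matrix)",     "m", 0),
  met("pi_m",   "phosphate",        "m", 0),
  met("h2o_m",  "water",            "m", 0),
  met("nh4_m",  "ammonium",         "m", 0),
  met("pmf_m",  "proton-motive force (pumped H+)", "m", 0)
)

rxn <- function(id, stoich, lb, ub, subsystem, map = NULL, hydride = NULL) {
  list(id = id, stoichiometry = stoich, lb = lb, ub = ub, subsystem = subsystem,
       atom_map = map, hydride_map = hydride)
}
am <- function(lhs, rhs) list(lhs = lhs, rhs = rhs)

# structural transporter capacities (umol/min/gDW); see the methods vignette
LAC_VMAX <- 1.6   # monocarboxylate (lactate) export capacity
GAA_VMAX <- 2.0   # electrogenic glutamate/aspartate antiporter capacity
GPD2_VMAX <- 0.1  # mitochondrial glycerol-3-phosphate dehydrogenase capacity
CIC_VMAX <- 0.05  # citrate/malate antiporter (citrate export) capacity
NADPH_DEMAND <- 0.05  # biosynthetic NADPH demand ceiling

rxns <- list(
  # ---- exchanges (positive flux = secretion, negative = uptake) ----
  rxn("EX_glc", c(glc_e = -1), -10, 0,   "exchange"),
  rxn("EX_gln", c(gln_e = -1), -10, 0,   "exchange"),
  rxn("EX_glu", c(glu_e = -1), -1,  10,  "exchange"),
  rxn("EX_lac", c(lac_e = -1), -1,  50,  "exchange"),
  rxn("EX_pyr", c(pyr_e = -1), -10, 50,  "exchange"),
  rxn("EX_asp", c(asp_e = -1), -10, 50,  "exchange"),
  rxn("EX_mal", c(mal_e = -1), 0,   50,  "exchange"),
  rxn("EX_fum", c(fum_e = -1), 0,   50,  "exchange"),
  rxn("EX_ala", c(ala_e = -1), 0,   50,  "exchange"),
  rxn("EX_nh4", c(nh4_e = -1), 0,   50,  "exchange"),
  rxn("EX_o2",  c(o2_e  = -1), -50, 0,   "exchange"),
  rxn("EX_co2", c(co2_e = -1), -50, 50,  "exchange"),
  rxn("EX_pi",  c(pi_e  = -1), -50, 50,  "exchange"),
  rxn("EX_h2o", c(h2o_e = -1), -M,  M,   "exchange"),

  # ---- transport ----
  rxn("GLCt", c(glc_e = -1, glc_c = 1), 0, M, "transport",
      am("glc_e:abcdef", "glc_c:abcdef")),
  rxn("GLNt", c(gln_e = -1, gln_c = 1), 0, M, "transport",
      am("gln_e:abcde", "gln_c:abcde")),
  rxn("LACt", c(lac_c = -1, lac_e = 1), -1, LAC_VMAX, "transport",
      am("lac_c:abc", "lac_e:abc")),
  rxn("PYRt", c(pyr_c = -1, pyr_e = 1), -M, M, "transport",
      am("pyr_c:abc", "pyr_e:abc")),
  rxn("GLUt", c(glu_c = -1, glu_e = 1), -M, M, "transport",
      am("glu_c:abcde", "glu_e:abcde")),
  rxn("ASPt", c(asp_e = -1, asp_c = 1), -M, M, "transport",
      am("asp_e:abcd", "asp_c:abcd")),
  rxn("MALt", c(mal_c = -1, mal_e = 1), 0, M, "transport",
      am("mal_c:abcd", "mal_e:abcd")),
  rxn("FUMt", c(fum_c = -1, fum_e = 1), 0, M, "transport",
      am("fum_c:abcd", "fum_e:abcd")),
  rxn("ALAt", c(ala_c = -1, ala_e = 1), 0, M, "transport",
      am("ala_c:abc", "ala_e:abc")),
  rxn("NH4t",  c(nh4_c = -1, nh4_e = 1), -M, M, "transport"),
  rxn("NH4tm", c(nh4_m = -1, nh4_c = 1), 0, M, "transport"),
  rxn("O2t",   c(o2_e = -1, o2_m = 1), 0, M, "transport"),
  rxn("CO2t",  c(co2_c = -1, co2_e = 1), -M, M, "transport",
      am("co2_c:a", "co2_e:a")),
  rxn("CO2tm", c(co2_m = -1, co2_c = 1), 0, M, "transport",
      am("co2_m:a", "co2_c:a")),
  rxn("H2Ot",  c(h2o_c = -1, h2o_e = 1), -M, M, "transport"),
  rxn("H2Otm", c(h2o_m = -1, h2o_c = 1), -M, M, "transport"),
  rxn("PIt",   c(pi_e = -1, pi_c = 1), -M, M, "transport"),
  rxn("PIC",   c(pi_c = -1, pi_m = 1), 0, M, "transport"),
  rxn("ANT",   c(atp_m = -1, adp_c = -1, atp_c = 1, adp_m = 1), 0, M, "transport"),
  rxn("MPC",   c(pyr_c = -1, pyr_m = 1), 0, M, "transport",
      am("pyr_c:abc", "pyr_m:abc")),
  rxn("CIC",   c(cit_m = -1, mal_c = -1, cit_c = 1, mal_m = 1), 0, CIC_VMAX,
      "transport",
      am(c("cit_m:abcdef", "mal_c:ghij"), c("cit_c:abcdef", "mal_m:ghij"))),
  rxn("OGC",   c(akg_m = -1, mal_c = -1, akg_c = 1, mal_m = 1), -M, M, "mas",
      am(c("akg_m:abcde", "mal_c:fghi"), c("akg_c:abcde", "mal_m:fghi"))),
  rxn("GAA",   c(glu_c = -1, asp_m = -1, pmf_m = -1, glu_m = 1, asp_c = 1),
      0, GAA_VMAX, "mas",
      am(c("glu_c:abcde", "asp_m:fghi"), c("glu_m:abcde", "asp_c:fghi"))),
  rxn("GC",    c(glu_c = -1, pmf_m = -1, glu_m = 1), 0, M, "transport",
      am("glu_c:abcde", "glu_m:abcde")),

  # ---- glycolysis ----
  rxn("HK",  c(glc_c = -1, atp_c = -1, g6p_c = 1, adp_c = 1), 0, M, "glycolysis",
      am("glc_c:abcdef", "g6p_c:abcdef")),
  rxn("PGI", c(g6p_c = -1, f6p_c = 1), -M, M, "glycolysis",
      am("g6p_c:abcdef", "f6p_c:abcdef")),
  rxn("PFK", c(f6p_c = -1, atp_c = -1, fbp_c = 1, adp_c = 1), 0, M, "glycolysis",
      am("f6p_c:abcdef", "fbp_c:abcdef")),
  rxn("ALD", c(fbp_c = -1, dhap_c = 1, gap_c = 1), -M, M, "glycolysis",
      am("fbp_c:abcdef", c("dhap_c:cba", "gap_c:def"))),
  rxn("TPI", c(dhap_c = -1, gap_c = 1), -M, M, "glycolysis",
      am("dhap_c:abc", "gap_c:abc")),
  rxn("GAPDH", c(gap_c = -1, nad_c = -1, pi_c = -1, bpg13_c = 1, nadh_c = 1),
      -M, M, "glycolysis",
      am("gap_c:abc", "bpg13_c:abc"),
      list(donor = "gap_c:1", pool = "nadh_c")),
  rxn("PGK", c(bpg13_c = -1, adp_c = -1, pg3_c = 1, atp_c = 1), -M, M, "glycolysis",
      am("bpg13_c:abc", "pg3_c:abc")),
  rxn("PGM", c(pg3_c = -1, pg2_c = 1), -M, M, "glycolysis",
      am("pg3_c:abc", "pg2_c:abc")),
  rxn("ENO", c(pg2_c = -1, pep_c = 1, h2o_c = 1), -M, M, "glycolysis",
      am("pg2_c:abc", "pep_c:abc")),
  rxn("PK",  c(pep_c = -1, adp_c = -1, pyr_c = 1, atp_c = 1), 0, M, "glycolysis",
      am("pep_c:abc", "pyr_c:abc")),
  rxn("LDH", c(pyr_c = -1, nadh_c = -1, lac_c = 1, nad_c = 1), -M, M, "glycolysis",
      am("pyr_c:abc", "lac_c:abc"),
      list(pool = "nadh_c", acceptor = "lac_c:2")),
  rxn("GPD1", c(dhap_c = -1, nadh_c = -1, g3p_c = 1, nad_c = 1), -M, M,
      "g3p_shuttle",
      am("dhap_c:abc", "g3p_c:abc"),
      list(pool = "nadh_c", acceptor = "g3p_c:2")),
  rxn("GPD2", c(g3p_c = -1, q_m = -1, dhap_c = 1, qh2_m = 1), 0, GPD2_VMAX,
      "g3p_shuttle",
      am("g3p_c:abc", "dhap_c:abc")),

  # ---- pyruvate oxidation and TCA cycle ----
  rxn("PDH", c(pyr_m = -1, coa_m = -1, nad_m = -1,
               accoa_m = 1, co2_m = 1, nadh_m = 1), 0, M, "tca",
      am("pyr_m:abc", c("co2_m:a", "accoa_m:bc"))),
  rxn("CS",  c(oaa_m = -1, accoa_m = -1, h2o_m = -1, cit_m = 1, coa_m = 1),
      0, M, "tca",
      am(c("oaa_m:abcd", "accoa_m:ef"), "cit_m:abcdef")),
  rxn("ACO2", c(cit_m = -1, icit_m = 1), -M, M, "tca",
      am("cit_m:abcdef", "icit_m:abcdef")),
  rxn("IDH3", c(icit_m = -1, nad_m = -1, akg_m = 1, co2_m = 1, nadh_m = 1),
      0, M, "tca",
      am("icit_m:abcdef", c("akg_m:abcef", "co2_m:d"))),
  rxn("OGDH", c(akg_m = -1, nad_m = -1, coa_m = -1,
                succoa_m = 1, co2_m = 1, nadh_m = 1), 0, M, "tca",
      am("akg_m:abcde", c("co2_m:a", "succoa_m:bcde"))),
  rxn("SCS", c(succoa_m = -1, adp_m = -1, pi_m = -1,
               succ_m = 1, atp_m = 1, coa_m = 1), -M, M, "tca",
      am("succoa_m:abcd", "succ_m:abcd")),
  rxn("CII", c(succ_m = -1, q_m = -1, fum_m = 1, qh2_m = 1), 0, M, "oxphos",
      am("succ_m:abcd", "fum_m:abcd")),
  rxn("FH",  c(fum_m = -1, h2o_m = -1, mal_m = 1), -M, M, "tca",
      am("fum_m:abcd", "mal_m:abcd")),
  rxn("MDH2", c(mal_m = -1, nad_m = -1, oaa_m = 1, nadh_m = 1), -M, M, "tca",
      am("mal_m:abcd", "oaa_m:abcd")),

  # ---- glutaminolysis and transamination ----
  rxn("GLS", c(gln_c = -1, h2o_c = -1, glu_c = 1, nh4_c = 1), 0, M,
      "glutaminolysis",
      am("gln_c:abcde", "glu_c:abcde")),
  rxn("GDH", c(glu_m = -1, nad_m = -1, h2o_m = -1,
               akg_m = 1, nadh_m = 1, nh4_m = 1), 0, M, "glutaminolysis",
      am("glu_m:abcde", "akg_m:abcde")),
  rxn("GOT1", c(asp_c = -1, akg_c = -1, oaa_c = 1, glu_c = 1), -M, M, "mas",
      am(c("asp_c:abcd", "akg_c:efghi"), c("oaa_c:abcd", "glu_c:efghi"))),
  rxn("GOT2", c(asp_m = -1, akg_m = -1, oaa_m = 1, glu_m = 1), -M, M, "mas",
      am(c("asp_m:abcd", "akg_m:efghi"), c("oaa_m:abcd", "glu_m:efghi"))),
  rxn("ALT", c(glu_c = -1, pyr_c = -1, akg_c = 1, ala_c = 1), -M, M,
      "glutaminolysis",
      am(c("glu_c:abcde", "pyr_c:fgh"), c("akg_c:abcde", "ala_c:fgh"))),

  # ---- malate-aspartate shuttle (cytosolic leg) ----
  rxn("MDH1", c(oaa_c = -1, nadh_c = -1, mal_c = 1, nad_c = 1), -M, M, "mas",
      am("oaa_c:abcd", "mal_c:abcd"),
      list(pool = "nadh_c", acceptor = "mal_c:2")),

  # ---- cytosolic reductive carboxylation branch ----
  rxn("IDH1", c(akg_c = -1, co2_c = -1, nadph_c = -1, icit_c = 1, nadp_c = 1),
      -M, M, "reductive_carboxylation",
      am(c("akg_c:abcde", "co2_c:f"), "icit_c:abcfde")),
  rxn("ACO1A", c(cit_c = -1, acon_c = 1), -M, M, "reductive_carboxylation",
      am("cit_c:abcdef", "acon_c:abcdef")),
  rxn("ACO1B", c(acon_c = -1, icit_c = 1), -M, M, "reductive_carboxylation",
      am("acon_c:abcdef", "icit_c:abcdef")),
  rxn("ACL", c(cit_c = -1, atp_c = -1, coa_c = -1,
               accoa_c = 1, oaa_c = 1, adp_c = 1, pi_c = 1), 0, M,
      "reductive_carboxylation",
      am("cit_c:abcdef", c("oaa_c:abcd", "accoa_c:ef"))),
  rxn("FHc", c(fum_c = -1, h2o_c = -1, mal_c = 1), -M, M,
      "reductive_carboxylation",
      am("fum_c:abcd", "mal_c:abcd")),
  rxn("ME1", c(mal_c = -1, nadp_c = -1, pyr_c = 1, co2_c = 1, nadph_c = 1),
      0, M, "reductive_carboxylation",
      am("mal_c:abcd", c("pyr_c:abc", "co2_c:d"))),
  rxn("LIPID", c(accoa_c = -1, coa_c = 1), 0, 5, "biomass_precursor"),
  rxn("NADPHS", c(nadph_c = -1, nadp_c = 1), 0, NADPH_DEMAND, "cofactor"),

  # ---- respiratory chain, proton-motive force, ATP ----
  rxn("CI",   c(nadh_m = -1, q_m = -1, nad_m = 1, qh2_m = 1, pmf_m = 4),
      0, M, "oxphos"),
  rxn("CIII", c(qh2_m = -1, cytc_ox_m = -2, q_m = 1, cytc_red_m = 2, pmf_m = 4),
      0, M, "oxphos"),
  rxn("CIV",  c(cytc_red_m = -2, o2_m = -0.5, cytc_ox_m = 2, h2o_m = 1, pmf_m = 2),
      0, M, "oxphos"),
  rxn("ATPS", c(adp_m = -1, pi_m = -1, pmf_m = -4, atp_m = 1, h2o_m = 1),
      0, M, "oxphos"),
  rxn("HLEAK", c(pmf_m = -1), 0, M, "oxphos"),
  rxn("ATPM", c(atp_c = -1, h2o_c = -1, adp_c = 1, pi_c = 1), 0, M, "demand")
)

model <- metabolic_model(
  mets, rxns, objective = "ATPM",
  compartments = c("e", "c", "m"),
  symmetric = list(fum_c = c(4, 3, 2, 1),
                   fum_m = c(4, 3, 2, 1),
                   succ_m = c(4, 3, 2, 1)),
  id = "central_carbon_reference")

rep <- validate_atom_maps(model)
stopifnot(nrow(rep$violations) == 0)
write_model_json(model, "inst/extdata/reference_model.json")
cat("wrote", length(model$reactions), "reactions,",
    nrow(model$metabolites), "metabolites\n")
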