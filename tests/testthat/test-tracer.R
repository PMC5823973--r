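# Tracer parsing, single-route propagation, EMU simulation against the
# brute-force isotopomer oracle, and deuterium hydride transfer.

test_that("tracer shorthand parses to substrate, isotope and positions", {
  m <- build_reference_network()
  tr <- parse_tracer("U-13C-glutamine", m)
  expect_equal(tr$substrate, "gln_e")
  expect_equal(tr$positions, 1:5)
  tr2 <- parse_tracer("1-13C-glutamine", m)
  expect_equal(tr2$positions, 1L)
  tr3 <- parse_tracer("4-2H-glucose", m)
  expect_equal(tr3$isotope, "2H")
  expect_equal(tr3$substrate, "glc_e")
  expect_error(parse_tracer("7-13C-glutamine", m), "5-carbon")
  expect_error(parse_tracer("garbage"), "shorthand")
  expect_error(tracer_spec("gln_e", "13C", 1:2, enrichment = 1.2), "enrichment")
})

test_that("route propagation reproduces the canonical labeling schematics", {
  net <- atom_transition_network(build_reference_network())
  reductive <- c("GLNt", "GLS", "ALT", "IDH1", "ACO1B", "ACO1A")
  # uniformly labeled glutamine through reductive carboxylation: citrate
  # keeps all five glutamine carbons (the fixed CO2 is unlabeled)
  r1 <- route_masks(net, reductive, "U-13C-glutamine")
  expect_equal(r1[["icit_c"]], 5)
  expect_equal(r1[["acon_c"]], 5)
  expect_equal(r1[["cit_c"]], 5)
  # onward through citrate cleavage and cytosolic MDH: malate keeps 3,
  # the acetyl unit takes 2
  r2 <- route_masks(net, c(reductive, "ACL", "MDH1"), "U-13C-glutamine")
  expect_equal(r2[["mal_c"]], 3)
  expect_equal(r2[["accoa_c"]], 2)
  # glutamine C1 is retained by the reductive route into both citrate and
  # malate (it is lost as CO2 on the oxidative route)
  r4 <- route_masks(net, c(reductive, "ACL", "MDH1"), "1-13C-glutamine")
  expect_equal(r4[["cit_c"]], 1)
  expect_equal(r4[["mal_c"]], 1)
  ox <- c("GLNt", "GLS", "ALT", "OGC", "OGDH", "SCS", "CII", "FH", "MDH2", "CS")
  r4b <- route_masks(net, ox, "1-13C-glutamine")
  expect_false("cit_m" %in% names(r4b))  # label left as CO2 at OGDH
  # uniformly labeled aspartate via GOT1 and MDH1: malate m+4
  r5 <- route_masks(net, c("ASPt", "GOT1", "MDH1"), "U-13C-aspartate")
  expect_equal(r5[["mal_c"]], 4)
  # glycolysis: glucose to lactate m+3
  glyc <- c("GLCt", "HK", "PGI", "PFK", "ALD", "GAPDH", "PGK", "PGM", "ENO",
            "PK", "LDH", "LACt")
  r6 <- route_masks(net, glyc, "U-13C-glucose")
  expect_equal(r6[["lac_e"]], 3)
  # one oxidative TCA turn from glutamine: citrate m+4
  r7 <- route_masks(net, ox, "U-13C-glutamine")
  expect_equal(r7[["cit_m"]], 4)
  # disconnected route errors at the break point
  expect_error(route_masks(net, c("GLNt", "HK"), "U-13C-glutamine"),
               "disconnected at HK")
})

test_that("EMU simulation handles anchors: no label in, none out", {
  m <- build_reference_network()
  p <- make_profile(0.45)
  tr <- tracer_spec("gln_e", "13C", 1:5, enrichment = 0)
  st <- simulate_13c(p$model, p$ground_truth_fluxes, tr)
  for (mid in st) expect_equal(unname(mid[1]), 1, tolerance = 1e-9)
})

test_that("distributions sum to one with shifts bounded by carbon count", {
  p <- make_profile(0.80)
  st <- simulate_13c(p$model, p$ground_truth_fluxes, "U-13C-glutamine")
  nc <- setNames(p$model$metabolites$n_carbons, p$model$metabolites$id)
  for (m in names(st)) {
    expect_equal(sum(st[[m]]), 1, tolerance = 1e-9)
    expect_length(st[[m]], nc[[m]] + 1)
    expect_true(all(st[[m]] >= -1e-12))
  }
})

test_that("EMU equals brute-force isotopomer simulation on random networks", {
  for (seed in 1:20) {
    ne <- random_emu_network(seed, with_symmetry = seed %% 3 == 0)
    emu <- simulate_13c(ne$model, ne$fluxes, ne$tracer)
    bf <- brute_force_isotopomers(ne$model, ne$fluxes, ne$tracer)
    common <- intersect(names(emu), names(bf))
    expect_gt(length(common), 0)
    for (met in common) {
      expect_equal(unname(emu[[met]]), unname(bf[[met]]), tolerance = 1e-9,
                   info = sprintf("seed %d, %s", seed, met))
    }
  }
})

test_that("label through fumarate is invariant under the symmetry permutation", {
  # positional check via single-atom EMUs: position i and its mirror must
  # carry equal enrichment after scrambling at production
  p <- make_profile(0.45)
  tr <- parse_tracer("U-13C-aspartate", p$model)
  net <- atom_transition_network(p$model)
  for (pos in 1:2) {
    e1 <- simulate_13c(net, p$ground_truth_fluxes, tr, metabolites = "fum_m",
                       .atoms = pos)
    e2 <- simulate_13c(net, p$ground_truth_fluxes, tr, metabolites = "fum_m",
                       .atoms = 5 - pos)
    expect_equal(e1$fum_m, e2$fum_m, tolerance = 1e-9)
  }
})

test_that("labeled fractions are linear in tracer enrichment", {
  ne <- random_emu_network(5)
  tr1 <- ne$tracer; tr1$enrichment <- 1
  tr0 <- ne$tracer; tr0$enrichment <- 0
  p <- 0.35
  trp <- ne$tracer; trp$enrichment <- p
  s1 <- simulate_13c(ne$model, ne$fluxes, tr1)
  s0 <- simulate_13c(ne$model, ne$fluxes, tr0)
  sp <- simulate_13c(ne$model, ne$fluxes, trp)
  for (m in names(sp)) {
    expect_equal(unname(sp[[m]]), unname(p * s1[[m]] + (1 - p) * s0[[m]]),
                 tolerance = 1e-9, info = m)
  }
})

test_that("route masks agree with EMU when flux is confined to the route", {
  # glycolysis-only flux: lactate from the full simulator must be pure m+3,
  # the route mask's prediction
  m <- build_reference_network()
  mc <- apply_constraints(m, constraint_set(
    data.frame(reaction = c("EX_glc", "EX_gln", "EX_pyr", "EX_asp", "EX_glu"),
               lb = c(-0.5, 0, 0, 0, 0), ub = c(-0.5, 0, 0, 0, 0)),
    data.frame(reaction = c("CI", "CII", "CIII", "CIV"), ub = 0)))
  f <- fba(mc)
  st <- simulate_13c(mc, f, "U-13C-glucose")
  expect_equal(unname(st$lac_e[["m+3"]]), 1, tolerance = 1e-9)
  net <- atom_transition_network(m)
  rm <- route_masks(net, c("GLCt", "HK", "PGI", "PFK", "ALD", "GAPDH", "PGK",
                           "PGM", "ENO", "PK", "LDH", "LACt"), "U-13C-glucose")
  expect_equal(unname(rm[["lac_e"]]), 3)
})

test_that("missing atom maps on flux-carrying reactions are reported", {
  m <- build_reference_network()
  m$reactions$LDH$atom_map <- NULL
  p <- make_profile(0.45)
  expect_error(simulate_13c(m, p$ground_truth_fluxes, "U-13C-glucose"), "LDH")
})

test_that("deuterium rides GAPDH-derived NADH into malate as m+1", {
  # confined scenario: lactate dehydrogenase and the glycerophosphate
  # shuttle blocked, so MDH1 is the only cytosolic NADH consumer
  m <- build_reference_network()
  for (rid in c("LDH", "GPD1")) {
    m$reactions[[rid]]$lb <- 0
    m$reactions[[rid]]$ub <- 0
  }
  mc <- apply_constraints(m, constraint_set(
    data.frame(reaction = c("EX_glc", "EX_gln"), lb = c(-0.5, -1),
               ub = c(-0.5, 0))))
  f <- fba(mc)
  expect_equal(f$status, "optimal")
  hy <- simulate_2h_hydride(mc, f, "4-2H-glucose")
  # sole donor, sole acceptor; half the GAP pool carries the C4 deuteron
  # (the DHAP-derived half lost it to solvent-free bookkeeping at C1)
  expect_equal(hy$donors$reaction, "GAPDH")
  expect_equal(hy$acceptors$reaction, "MDH1")
  expect_equal(hy$acceptors$flux_share, 1)
  expect_equal(hy$pool_fraction, 0.5, tolerance = 1e-9)
  expect_equal(unname(hy$labeling$mal_c[["m+1"]]), hy$pool_fraction)
  # the labeled malate species is the m+1 isotopologue
  expect_equal(names(which(hy$labeling$mal_c > 0)), c("m+0", "m+1"))
})

test_that("a fully deuterated sole NADH source gives product m+1 fraction 1", {
  # toy: substrate S3 (3 carbons, 2H at position 1) -> GAP-like donor ->
  # pool -> single acceptor product
  mets <- data.frame(id = c("s_e", "g", "p", "q", "nad", "nadh"),
                     name = c("s_e", "g", "p", "q", "nad", "nadh"),
                     compartment = c("e", "c", "c", "c", "c", "c"),
                     n_carbons = c(3, 3, 3, 3, 0, 0), stringsAsFactors = FALSE)
  rxns <- list(
    mk_rxn("EX_s", c(s_e = -1), -10, 0),
    mk_rxn("UP", c(s_e = -1, g = 1), 0, 10,
           map = list(lhs = "s_e:abc", rhs = "g:abc")),
    mk_rxn("DHG", c(g = -1, nad = -1, p = 1, nadh = 1), 0, 10,
           map = list(lhs = "g:abc", rhs = "p:abc"),
           hydride = list(donor = "g:1", pool = "nadh")),
    mk_rxn("RED", c(p = -1, nadh = -1, q = 1, nad = 1), 0, 10,
           map = list(lhs = "p:abc", rhs = "q:abc"),
           hydride = list(pool = "nadh", acceptor = "q:2")),
    mk_rxn("OUT", c(q = -1), 0, 10))
  tm <- metabolic_model(mets, rxns, objective = "OUT")
  f <- fba(tm)
  hy <- simulate_2h_hydride(tm, f, tracer_spec("s_e", "2H", 1))
  expect_equal(hy$pool_fraction, 1, tolerance = 1e-9)
  expect_equal(unname(hy$labeling$q[["m+1"]]), 1, tolerance = 1e-9)
  # two sources at equal flux, one unlabeled: pool mixes to one half
  mets2 <- rbind(mets, data.frame(id = c("u_e", "w"), name = c("u_e", "w"),
                                  compartment = c("e", "c"), n_carbons = 3))
  rxns2 <- c(rxns, list(
    mk_rxn("EX_u", c(u_e = -1), -10, 0),
    mk_rxn("UP2", c(u_e = -1, w = 1), 0, 10,
           map = list(lhs = "u_e:abc", rhs = "w:abc")),
    mk_rxn("DHU", c(w = -1, nad = -1, p = 1, nadh = 1), 0, 10,
           map = list(lhs = "w:abc", rhs = "p:abc"),
           hydride = list(donor = "w:1", pool = "nadh"))))
  tm2 <- metabolic_model(mets2, rxns2, objective = "OUT")
  tm2$reactions$DHG$ub <- 1
  tm2$reactions$DHU$lb <- 1  # force equal flux through both donors
  tm2$reactions$DHU$ub <- 1
  tm2$reactions$DHG$lb <- 1
  f2 <- fba(tm2)
  hy2 <- simulate_2h_hydride(tm2, f2, tracer_spec("s_e", "2H", 1))
  expect_equal(hy2$pool_fraction, 0.5, tolerance = 1e-9)
})

test_that("hydride errors are informative", {
  m <- build_reference_network()
  p <- make_profile(0.45)
  expect_error(simulate_2h_hydride(m, p$ground_truth_fluxes, "U-13C-glucose"),
               "2H")
  m2 <- m
  for (rid in names(m2$reactions)) m2$reactions[[rid]]$hydride_map <- NULL
  expect_error(simulate_2h_hydride(m2, p$ground_truth_fluxes, "4-2H-glucose"),
               "hydride")
})
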