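# FBA, FVA, constraint application and elastic relaxation.

test_that("hand-solved toy programs come out right", {
  # chain with uptake 10
  f <- fba(toy_chain_model())
  expect_equal(f$status, "optimal")
  expect_equal(f$objective_value, 10)
  # two parallel paths, 2 vs 1 ATP per substrate: all flux on the good one
  f2 <- fba(toy_parallel_model())
  expect_equal(f2$objective_value, 20)
  expect_equal(f2$fluxes[["PATH1"]], 10)
  expect_equal(f2$fluxes[["PATH2"]], 0)
  # coef() is the flux vector
  expect_equal(coef(f2), f2$fluxes)
})

test_that("optimal flux vectors satisfy mass balance and bounds", {
  m <- build_reference_network()
  f <- fba(m)
  S <- stoichiometric_matrix(m)
  expect_lt(max(abs(S %*% f$fluxes)), 1e-6)
  bnd <- cbind(vapply(m$reactions, `[[`, 0, "lb"),
               vapply(m$reactions, `[[`, 0, "ub"))
  expect_true(all(f$fluxes >= bnd[, 1] - 1e-6 & f$fluxes <= bnd[, 2] + 1e-6))
})

test_that("tightening a bound never increases the optimum", {
  m <- make_profile(0.45)$model
  z0 <- fba(m)$objective_value
  set.seed(7)
  for (rid in sample(names(m$reactions), 12)) {
    m2 <- m
    r <- m2$reactions[[rid]]
    m2$reactions[[rid]]$ub <- r$lb + 0.5 * (r$ub - r$lb)
    f2 <- fba(m2)
    z2 <- if (f2$status == "optimal") f2$objective_value else 0
    expect_lte(z2, z0 + 1e-6)
  }
})

test_that("FVA separates unique from degenerate fluxes", {
  # equal-yield parallel paths: alternate optima, nonzero width
  m_eq <- toy_parallel_model(yield1 = 1, yield2 = 1)
  fv <- fva(m_eq)
  expect_gt(fv$width[fv$reaction == "PATH1"], 1)
  expect_gt(fv$width[fv$reaction == "PATH2"], 1)
  expect_false(fv$unique[fv$reaction == "PATH1"])
  # single chain: everything unique
  fv2 <- fva(toy_chain_model())
  expect_true(all(fv2$unique))
  # FBA flux contained in its FVA range at gamma = 1
  f <- fba(m_eq)
  expect_true(all(f$fluxes[fv$reaction] >= fv$flux_min - 1e-6 &
                    f$fluxes[fv$reaction] <= fv$flux_max + 1e-6))
})

test_that("FVA ranges nest as gamma decreases and re-solve at bounds", {
  m <- make_profile(0.80)$model
  rxns <- c("IDH1", "MDH1", "LDH", "EX_lac", "GPD2", "ACL")
  fv1 <- fva(m, gamma = 1, reactions = rxns)
  fv9 <- fva(m, gamma = 0.9, reactions = rxns)
  expect_true(all(fv9$flux_min <= fv1$flux_min + 1e-6))
  expect_true(all(fv9$flux_max >= fv1$flux_max - 1e-6))
  # fixing a reaction at its reported extremum stays feasible with
  # objective >= gamma * Z*
  zstar <- attr(fv1, "objective_value")
  for (i in seq_len(nrow(fv1))) {
    m2 <- m
    m2$reactions[[fv1$reaction[i]]]$lb <- fv1$flux_min[i] - 1e-9
    m2$reactions[[fv1$reaction[i]]]$ub <- fv1$flux_min[i] + 1e-9
    f2 <- fba(m2)
    expect_equal(f2$status, "optimal", info = fv1$reaction[i])
    expect_gte(f2$objective_value, zstar - 1e-6)
  }
})

test_that("constraints tighten bounds by intersection only", {
  m <- build_reference_network()
  # empty set is the identity
  m0 <- apply_constraints(m, constraint_set())
  expect_equal(reaction_bounds(m0), reaction_bounds(m))
  # measured rate +/- k SE maps to an interval
  cf <- data.frame(metabolite_id = "glc", rate = -2, standard_error = 0.1)
  cs <- build_constraints(cf, k = 1)
  m1 <- apply_constraints(m, cs)
  expect_equal(m1$reactions$EX_glc$lb, -2.1)
  expect_equal(m1$reactions$EX_glc$ub, -1.9)
  expect_equal(m$reactions$EX_glc$lb, -10)  # original untouched
  # measurement beyond structure is clipped with a warning
  cf2 <- data.frame(metabolite_id = "glc", rate = -9.95, standard_error = 0.2)
  expect_warning(m2 <- apply_constraints(m, build_constraints(cf2, k = 1)),
                 "structural")
  expect_equal(m2$reactions$EX_glc$lb, -10)
  # conflict with structural irreversibility errors, naming the reaction
  cf3 <- data.frame(metabolite_id = "mal", rate = -3, standard_error = 0.1)
  expect_error(apply_constraints(m, build_constraints(cf3, k = 1)), "EX_mal")
})

test_that("OCR caps convert units through the documented bridge", {
  ocr <- data.frame(complex_id = c("CI", "CIV"), ocr = c(4, 6))
  cs <- build_constraints(complex_ocr = ocr)
  expect_equal(cs$complex_caps$ub[cs$complex_caps$reaction == "CI"],
               4 * 1e-6 * 5e5 * 2)
  m <- apply_constraints(build_reference_network(), cs)
  expect_equal(m$reactions$CI$ub, 4.0)
  expect_equal(m$reactions$CIV$ub, 6.0)
})

test_that("constraint sets survive a JSON round trip", {
  cs <- constraint_set(
    data.frame(reaction = c("EX_glc", "EX_lac"), lb = c(-2.1, 1.4),
               ub = c(-1.9, 1.7)),
    data.frame(reaction = c("CI", "CIII"), ub = c(1.5, 1.7)))
  path <- withr::local_tempfile(fileext = ".json")
  write_constraints(cs, path)
  cs2 <- read_constraints(path)
  expect_equal(cs2$exchange_bounds, cs$exchange_bounds)
  expect_equal(cs2$complex_caps, cs$complex_caps)
})

test_that("elastic relaxation is the identity on feasible models", {
  m <- make_profile(0.45)$model
  r <- elastic_relax(m)
  expect_equal(r$total_slack, 0)
  expect_equal(reaction_bounds(r$model), reaction_bounds(m))
})

test_that("elastic relaxation localizes slack on the conflicting measurements", {
  m <- build_reference_network()
  # glucose uptake too small to cover a forced lactate secretion
  cs <- constraint_set(data.frame(
    reaction = c("EX_glc", "EX_lac", "EX_gln", "EX_pyr", "EX_asp", "EX_glu"),
    lb = c(-0.1, 1.0, 0, 0, 0, 0),
    ub = c(-0.1, 1.1, 0, 0, 0, 0)))
  mc <- apply_constraints(m, cs)
  expect_equal(fba(mc)$status, "infeasible")
  r <- elastic_relax(mc)
  expect_gt(r$total_slack, 0)
  # the slack report total is the L1 objective
  expect_equal(r$total_slack,
               sum(r$slack$slack_lower) + sum(r$slack$slack_upper))
  # slack sits on the carbon-conflicted exchanges, not elsewhere
  hot <- r$slack$reaction[r$slack$slack_lower + r$slack$slack_upper > 1e-9]
  expect_true(all(hot %in% c("EX_glc", "EX_lac")))
  expect_equal(fba(r$model)$status, "optimal")
})
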