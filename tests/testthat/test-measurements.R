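# Normalization operations on plate and LC-MS style measurements.

test_that("exchange flux follows the CORE formula with the right sign", {
  # no net change -> zero rate
  expect_equal(compute_exchange_flux(500, 500, 1e-3, 1e6, 3e-10), 0)
  # standard-medium glutamine: 4 mM fresh, 3 mM spent, 1 mL, 1e6 cell h:
  # 1 umol consumed over 1e6 cell h * 3e-10 g/cell * 60 min/h of exposure
  got <- compute_exchange_flux(3000, 4000, 1e-3, 1e6, 3e-10)
  expect_equal(got, -1 / (1e6 * 3e-10 * 60))
  expect_lt(got, 0)
  # secretion is positive
  expect_gt(compute_exchange_flux(1500, 0, 1e-3, 1e6, 3e-10), 0)
  # linear in the concentration difference, antisymmetric in spent/fresh
  a <- compute_exchange_flux(1200, 1000, 1e-3, 1e6, 3e-10)
  b <- compute_exchange_flux(1400, 1000, 1e-3, 1e6, 3e-10)
  expect_equal(b, 2 * a)
  expect_equal(compute_exchange_flux(1000, 1200, 1e-3, 1e6, 3e-10), -a)
  expect_error(compute_exchange_flux(1, 2, 0, 1e6, 3e-10), "volume")
  expect_error(compute_exchange_flux(1, 2, 1e-3, -5, 3e-10), "cell_time")
})

test_that("isotopologue fractions normalize per metabolite and ignore row order", {
  tab <- data.frame(metabolite_id = "cit", mass_shift = 0:2,
                    intensity = c(2, 1, 1))
  fr <- isotopologue_fractions(tab, "cit")
  expect_equal(as.numeric(fr), c(0.5, 0.25, 0.25))
  expect_equal(sum(fr), 1, tolerance = 1e-9)
  # single nonzero species
  tab1 <- data.frame(metabolite_id = "x", mass_shift = 0:2,
                     intensity = c(7, 0, 0))
  expect_equal(as.numeric(isotopologue_fractions(tab1, "x")), c(1, 0, 0))
  # permutation invariance and scale invariance
  fr2 <- isotopologue_fractions(tab[c(3, 1, 2), ], "cit")
  expect_equal(fr2, fr)
  tab$intensity <- tab$intensity * 7.3
  expect_equal(isotopologue_fractions(tab, "cit"), fr)
  # all-zero is an error naming the metabolite
  tab0 <- data.frame(metabolite_id = "dead", mass_shift = 0:1, intensity = 0)
  expect_error(isotopologue_fractions(tab0, "dead"), "dead")
  # padding to carbon count
  fr3 <- isotopologue_fractions(tab1, "x", n_carbons = 4)
  expect_length(fr3, 5)
})

test_that("total ion sum normalization makes per-sample totals one", {
  tab <- data.frame(sample_id = c("s1", "s1", "s2"),
                    metabolite_id = c("a", "b", "a"),
                    intensity = c(3, 1, 10))
  out <- total_ion_sum_normalize(tab)
  expect_equal(out$intensity, c(0.75, 0.25, 1))
  # doubling all intensities of one sample changes nothing
  tab2 <- tab
  tab2$intensity[tab2$sample_id == "s1"] <- 2 * tab2$intensity[tab2$sample_id == "s1"]
  expect_equal(total_ion_sum_normalize(tab2), out)
  tab$intensity[3] <- 0
  expect_error(total_ion_sum_normalize(tab), "s2")
})

test_that("protein normalization and complex OCR extraction follow the protocol", {
  expect_equal(normalize_rate_to_protein(100, 10), 10)
  expect_equal(normalize_rate_to_protein(0, 5), 0)
  expect_equal(normalize_rate_to_protein(120, 8), 15)
  expect_error(normalize_rate_to_protein(10, 0), "protein")

  wells <- data.frame(
    injection_phase = c("glutamate_malate", "rotenone", "succinate",
                        "antimycin", "duroquinol", "tmpd_ascorbate", "azide"),
    raw_rate = c(50, 10, 30, 10, 45, 60, 12), protein_mass = 1)
  ocr <- extract_complex_ocr(wells)
  expect_equal(ocr$ocr[ocr$complex_id == "CI"], 40)
  expect_equal(ocr$ocr[ocr$complex_id == "CII"], 20)
  expect_equal(ocr$ocr[ocr$complex_id == "CIII"], 35)
  expect_equal(ocr$ocr[ocr$complex_id == "CIV"], 48)

  # replicate averaging then subtraction; permutation invariance; floor at 0
  reps <- data.frame(
    injection_phase = c(rep("glutamate_malate", 3), "rotenone"),
    raw_rate = c(30, 40, 50, 20), protein_mass = 1)
  expect_equal(extract_complex_ocr(reps, "CI")$ocr, 20)
  expect_equal(extract_complex_ocr(reps[sample(4), ], "CI")$ocr, 20)
  flo <- data.frame(injection_phase = c("glutamate_malate", "rotenone"),
                    raw_rate = c(5, 9), protein_mass = 1)
  expect_equal(extract_complex_ocr(flo, "CI")$ocr, 0)
  # missing phase errors name the complex
  expect_error(extract_complex_ocr(flo, "CIV"), "CIV")
})

test_that("redox index is anchored, clamped and monotone", {
  expect_equal(nadph_redox_index(80, 80, 20), 100)
  expect_equal(nadph_redox_index(20, 80, 20), 0)
  expect_equal(nadph_redox_index(50, 80, 20), 50)
  expect_equal(nadph_redox_index(120, 80, 20), 100)  # clamp
  expect_equal(nadph_redox_index(0, 80, 20), 0)      # clamp
  b <- seq(10, 90, by = 5)
  expect_true(all(diff(nadph_redox_index(b, 80, 20)) >= 0))
  expect_error(nadph_redox_index(50, 40, 40), "calibration")
})

test_that("natural-abundance correction inverts the binomial convolution", {
  # pure m+0 measured with p = 0 stays put
  x <- c(1, 0, 0, 0)
  expect_equal(unname(correct_natural_abundance(x, p = 0)), x)
  # forward-convolve a known vector, then correct it back
  p <- 0.011
  true_frac <- c(0.6, 0.1, 0.3, 0)
  n <- 3
  C <- sapply(0:n, function(j) sapply(0:n, function(i)
    if (i >= j) dbinom(i - j, n - j, p) else 0))
  measured <- as.numeric(C %*% true_frac)
  rec <- correct_natural_abundance(measured, p = p)
  expect_equal(unname(rec), true_frac, tolerance = 1e-9)
})

test_that("CORE plate conversion averages replicates and reports SE", {
  plate <- data.frame(
    metabolite_id = "glc",
    sample_type = c("fresh", "spent", "spent", "spent"),
    concentration = c(1000, 900, 910, 890),
    medium_volume = 1e-3,
    cell_time_integral = c(NA, 1e6, 1e6, 1e6),
    replicate = c(1, 1, 2, 3))
  cf <- core_flux_from_plate(plate)
  rates <- compute_exchange_flux(c(900, 910, 890), 1000, 1e-3, 1e6)
  expect_equal(cf$rate, mean(rates))
  expect_equal(cf$standard_error, sd(rates) / sqrt(3))
  # single replicate: SE 0 with a warning
  p1 <- plate[1:2, ]
  expect_warning(cf1 <- core_flux_from_plate(p1), "single replicate")
  expect_equal(cf1$standard_error, 0)
  expect_error(core_flux_from_plate(plate[-1, ]), "fresh")
})

test_that("delimited readers enforce their column contracts", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines("sample_id,condition_label,metabolite_id,mass_shift,intensity\ns1,mT7,cit,0,100", path)
  tab <- read_isotopologue_table(path)
  expect_equal(tab$intensity, 100)
  writeLines("sample_id,foo\ns1,1", path)
  expect_error(read_isotopologue_table(path), "missing column")
  # duplicate (sample, metabolite, shift) rows are rejected
  writeLines(c("sample_id,condition_label,metabolite_id,mass_shift,intensity",
               "s1,mT7,cit,0,100", "s1,mT7,cit,0,90"), path)
  expect_error(read_isotopologue_table(path), "duplicate")
})
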