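test_that("the packaged reference panel matches its provenance", {
  panel <- reference_panel()
  expect_equal(length(unique(panel$metadata$sample_id)), 36)
  expect_equal(sum(panel$metadata$protein_type == "whey"), 27)
  expect_false("Mg" %in% panel$concentrations$element)

  sn12 <- subset(panel$concentrations, sample_id == "P12" & element == "Sn")
  expect_equal(sn12$status, "quantified")
  expect_equal(sn12$value, 329.7)

  tox <- tox_reference()
  expect_equal(tox$rfd[tox$element == "Tl"], 0.01)
  expect_setequal(tox$element[tox$in_hi_list], hi_elements)
  expect_setequal(tox$element[tox$in_cr_list], cr_elements)
  # list membership implies the needed reference value exists
  expect_true(all(!is.na(tox$rfd[tox$in_hi_list])))
  expect_true(all(!is.na(tox$csf[tox$in_cr_list])))
})

test_that("generation is deterministic and element-stream stable", {
  spec <- generator_spec(n_samples = 10, seed = 17)
  a <- generate_panel(spec)
  b <- generate_panel(spec)
  expect_identical(a$truth, b$truth)
  expect_identical(a$readings, b$readings)
  expect_identical(a$panel$concentrations, b$panel$concentrations)

  # adding an element must not perturb the other elements' draws
  small <- generate_panel(generator_spec(n_samples = 10, seed = 17,
                                         elements = c("Cd", "Pb")))
  wide <- generate_panel(generator_spec(n_samples = 10, seed = 17,
                                        elements = c("Cd", "Pb", "Ba")))
  expect_identical(small$truth,
                   wide$truth[wide$truth$element %in% c("Cd", "Pb"), ])

  # written simulations are reproducible files
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_simulation(a, d1); write_simulation(b, d2)
  for (f in c("panel.csv", "meta.csv", "readings.csv", "truth.csv")) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  }
})

test_that("a noiseless panel recovers the true concentrations and risks", {
  spec <- generator_spec(n_samples = 12, seed = 7, noise_rsd = 0,
                         loq_limits = numeric(0), upper_calibration = Inf)
  sim <- generate_panel(spec)
  conc <- sim$panel$concentrations
  expect_true(all(conc$status == "quantified"))
  merged <- merge(conc, sim$truth, by = c("sample_id", "element"))
  expect_lt(max(abs(merged$value - merged$true_conc) / merged$true_conc),
            1e-9)

  # end-to-end: assessing the generated panel equals closed-form hand
  # values computed from the truth
  tox <- tox_reference()
  res <- assess_panel(sim$panel, tox, servings = 1L)
  rfd <- setNames(tox$rfd, tox$element)
  meta <- sim$panel$metadata
  truth <- merge(sim$truth, meta[, c("sample_id", "serving_mass_g")])
  truth <- truth[truth$element %in% hi_elements, ]
  truth$hq <- (truth$true_conc * truth$serving_mass_g / 1000 / 70) /
    rfd[truth$element]
  hand <- tapply(truth$hq, truth$sample_id, sum)
  got <- setNames(res$hi$hi, res$hi$sample_id)[names(hand)]
  expect_lt(max(abs(got - hand) / hand), 1e-9)
})

test_that("censoring and truncation respond to their limits", {
  # a true concentration below the reporting limit is recorded as censored
  spec <- generator_spec(n_samples = 5, seed = 2, elements = "Li",
                         ranges = list(Li = c(5, 5)),
                         loq_limits = c(Li = 17.4), noise_rsd = 0)
  conc <- generate_panel(spec)$panel$concentrations
  expect_true(all(conc$status == "below_limit"))
  expect_true(all(conc$limit == 17.4))

  # raising a reporting limit never un-censors a value
  n_cens <- vapply(c(0, 30, 80, 200), function(loq) {
    spec <- generator_spec(n_samples = 30, seed = 9, elements = "Li",
                           ranges = list(Li = c(10, 150)),
                           loq_limits = c(Li = loq))
    sum(generate_panel(spec)$panel$concentrations$status == "below_limit")
  }, numeric(1))
  expect_true(all(diff(n_cens) >= 0))

  # solution readings above the top calibration standard are above-range:
  # 1000 ug/kg at ~0.45 g in 10 mL at DF 5 reads ~9 ug/L in solution
  spec <- generator_spec(n_samples = 5, seed = 2, elements = "Fe",
                         ranges = list(Fe = c(1000, 1000)), noise_rsd = 0,
                         upper_calibration = 50)
  conc <- generate_panel(spec)$panel$concentrations
  expect_true(all(conc$status == "quantified"))
  spec$upper_calibration <- 1
  conc_hi <- generate_panel(spec)$panel$concentrations
  expect_true(all(conc_hi$status == "above_range"))
})

test_that("multiplicative noise reproduces its nominal RSD", {
  spec <- generator_spec(n_samples = 1000, seed = 21, elements = "Cd",
                         ranges = list(Cd = c(500, 500)),
                         noise_rsd = c(Cd = 5),
                         loq_limits = numeric(0), upper_calibration = Inf)
  sim <- generate_panel(spec)
  conc <- sim$panel$concentrations$value
  empirical_rsd <- sd(conc) / mean(conc) * 100
  expect_true(abs(empirical_rsd - 5) < 0.5)
})
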