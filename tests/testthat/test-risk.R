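test_that("estimated daily intake follows the intake equation", {
  expect_equal(compute_edi(5.6, 60), 5.6 * 0.060 / 70)
  expect_equal(compute_edi(5.6, 60), 4.8e-3)
  expect_equal(signif(compute_edi(58.1, 60), 2), 0.05)
  expect_equal(compute_edi(0, 30), 0)
  # servings and body weight enter multiplicatively
  expect_equal(compute_edi(100, 30, servings = 3), 3 * compute_edi(100, 30))
  expect_equal(compute_edi(100, 30, body_weight = 35),
               2 * compute_edi(100, 30))
  expect_error(compute_edi(1, 0), "serving_mass_g")
})

test_that("hazard quotient is intake over reference dose", {
  edi_tl <- compute_edi(3.1, 60)            # largest single HQ term of P1
  expect_equal(compute_hq(edi_tl, 0.01), 3.1 * 0.060 / 70 / 0.01)
  expect_equal(round(compute_hq(edi_tl, 0.01), 4), 0.2657)
  expect_equal(compute_hq(0, 1), 0)
  expect_equal(compute_hq(0.3, 0.3), 1.0)
  expect_error(compute_hq(1, 0), "positive")
})

test_that("hazard index matches an independent term-by-term sum", {
  panel <- reference_panel()
  tox <- tox_reference()
  res <- assess_panel(panel, tox, servings = c(1L, 3L))

  # brute-force oracle: loop over samples and the hazard-list elements,
  # resolving censored values to zero, skipping above-range entries
  rfd <- setNames(tox$rfd, tox$element)
  meta <- panel$metadata
  for (sid in c("P1", "P12", "P31", "P36")) {
    conc <- panel$concentrations
    conc <- conc[conc$sample_id == sid, ]
    sm <- meta$serving_mass_g[meta$sample_id == sid]
    hand <- 0
    for (el in hi_elements) {
      row <- conc[conc$element == el, ]
      if (nrow(row) == 0 || row$status == "above_range") next
      c_res <- if (row$status == "quantified") row$value else 0
      hand <- hand + (c_res * sm / 1000 / 70) / rfd[[el]]
    }
    got <- res$hi$hi[res$hi$sample_id == sid & res$hi$servings == 1]
    expect_equal(got, hand, tolerance = 1e-12)
  }
})

test_that("slope-factor conventions are inverses through CSF squared", {
  edi <- compute_edi(5.6, 60)
  expect_equal(compute_cr(edi, 4300, "table_match"), edi / 4300)
  expect_equal(compute_cr(edi, 4300, "literal_eq5"), edi * 4300)
  for (csf in c(8.5, 380, 4300)) {
    expect_equal(compute_cr(1.7e-2, csf, "literal_eq5") /
                   compute_cr(1.7e-2, csf, "table_match"),
                 csf^2)
  }
  expect_error(compute_cr(1, -1), "positive")
})

test_that("risk classifications use strict cuts with inclusive low side", {
  expect_equal(classify_hi(c(0.956, 2.868, 1.0)),
               c("low", "elevated", "low"))
  expect_equal(classify_cr(c(1.1e-6, 5.0e-3, 1e-4)),
               c("low", "elevated", "low"))
  expect_equal(classify_cr(2e-3, threshold = 1e-3), "elevated")
  expect_equal(percent_of_reference(1.127, 45), 100 * 1.127 / 45)
  expect_error(percent_of_reference(1, 0), "positive")
})

test_that("EDI, HI and CR are linear in servings across the whole panel", {
  res <- assess_panel(reference_panel(), servings = c(1L, 2L, 3L))
  hi <- tidyr::pivot_wider(res$hi[, c("sample_id", "servings", "hi")],
                           names_from = "servings", values_from = "hi")
  expect_equal(hi$`3`, 3 * hi$`1`, tolerance = 1e-12)
  expect_equal(hi$`2`, 2 * hi$`1`, tolerance = 1e-12)
  cr <- tidyr::pivot_wider(
    res$cr[, c("sample_id", "element", "servings", "cr")],
    names_from = "servings", values_from = "cr")
  expect_equal(cr$`3`, 3 * cr$`1`, tolerance = 1e-12)
})

test_that("hazard index is monotone in censor policy and in concentrations", {
  panel <- reference_panel()
  his <- lapply(c("zero", "half_limit", "at_limit"), function(p) {
    compute_hi(panel, config = assessment_config(censor_policy = p),
               servings = 1L)$hi
  })
  expect_true(all(his[[1]] <= his[[2]] + 1e-15))
  expect_true(all(his[[2]] <= his[[3]] + 1e-15))

  # raising any single quantified concentration never lowers HI or CR
  set.seed(5)
  base <- assess_panel(panel, servings = 1L)
  conc <- panel$concentrations
  idx <- sample(which(conc$status == "quantified" &
                        conc$element %in% hi_elements), 10)
  for (i in idx) {
    bumped <- panel
    bumped$concentrations$value[i] <- conc$value[i] * 2 + 1
    res <- assess_panel(bumped, servings = 1L)
    expect_true(all(res$hi$hi >= base$hi$hi - 1e-15))
    expect_true(all(res$cr$cr >= base$cr$cr - 1e-15, na.rm = TRUE))
  }
})

test_that("exceedance counting is strict and serving-specific", {
  res <- assess_panel(tiny_panel(), servings = c(1L, 3L))
  # A1: Cd 58.1 at 60 g -> CR 1.31e-4; A2: Cd 40 at 30 g crosses 1e-4
  # only at three servings; A3's censored Cd carries zero risk
  expect_equal(count_exceedances(res, "cr", 1e-4, 1, element = "Cd"), 1L)
  expect_equal(count_exceedances(res, "cr", 1e-4, 3, element = "Cd"), 2L)
  expect_equal(count_exceedances(res, "hi", 1, 1), 0L)
  expect_error(count_exceedances(res, "cr", 1e-4, 1), "element")
})

test_that("report tables round as documented", {
  res <- assess_panel(reference_panel())
  hi <- hi_table(res)
  expect_equal(hi$hi_servings_1[hi$sample_id == "P1"], 0.955)
  cr <- cr_table(res)
  expect_equal(cr$cr_Pb_1[cr$sample_id == "P1"], 5.0e-3)
  expect_equal(cr$cr_Be_1[cr$sample_id == "P2"], 0)  # censored -> zero risk
})
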