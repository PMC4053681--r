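# qPCR standard curves, absolute quantification, theoretical population
# bands and assay bookkeeping.

test_that("standard-curve efficiency follows E = 10^(-1/slope) - 1", {
  # perfect doubling: slope -1/log10(2)
  run1 <- simulate_qpcr_run(1.0, 40, sd_cq = 0, seed = 1)
  sc1 <- fit_standard_curve(run1$records)
  expect_equal(sc1$slope, -1 / log10(2), tolerance = 1e-10)
  expect_equal(sc1$efficiency, 1, tolerance = 1e-10)

  # slope -4.3394 corresponds to E = 0.70
  lg <- 1:9
  df <- data.frame(copies = 10^lg, cq = 40 - 4.3394 * lg)
  expect_equal(fit_standard_curve(df)$efficiency, 0.70, tolerance = 1e-4)

  # noiseless generated runs refit exactly
  for (e in c(0.70, 0.73)) {
    run <- simulate_qpcr_run(e, 38, sd_cq = 0, seed = 2)
    expect_equal(fit_standard_curve(run$records)$efficiency, e,
                 tolerance = 1e-10)
  }

  expect_error(fit_standard_curve(data.frame(copies = 10^(1:5),
                                             cq = 20 + (1:5))),
               "assay failure")
  expect_error(fit_standard_curve(data.frame(copies = c(10, 100),
                                             cq = c(30, 27))),
               "copy levels")
})

test_that("quantification inverts the standard model across 8 orders", {
  unknowns <- 10^(1.5 + 0:7)
  run <- simulate_qpcr_run(0.73, 39, sd_cq = 0, unknown_copies = unknowns,
                           seed = 4)
  sc <- fit_standard_curve(run$records)
  cq_u <- run$records$cq[run$records$role == "unknown"]
  got <- quantify_copies(cq_u, sc)
  expect_equal(got$copies_per_reaction, unknowns, tolerance = 1e-6)

  # Cq exactly at the 1e9 standard returns 1e9 copies
  cq9 <- predict(sc, 1e9)
  expect_equal(quantify_copies(cq9, sc)$copies_per_reaction, 1e9,
               tolerance = 1e-9)

  # volume arithmetic: 1:500 dilution, 50 ul elution, 5 ul template, 0.5 g
  q <- quantify_copies(cq9, sc, dilution = 500, soil_dw_g = 0.5,
                       elution_ul = 50, template_ul = 5)
  factor_oracle <- 500 * 50 / (5 * 0.5)
  expect_equal(factor_oracle, 1e4)
  expect_equal(q$copies_per_g_dw, 1e9 * factor_oracle, tolerance = 1e-9)

  # extrapolation beyond the standards is flagged
  expect_warning(quantify_copies(predict(sc, 1e10), sc), "outside")
})

test_that("theoretical population bands reproduce the printed-input arithmetic", {
  co_soil_pmol <- convert_mol(11, "nmol", "pmol")        # 11 nmol g-1 h-1
  act_low <- convert_mol(29, "zmol", "pmol")
  act_high <- convert_mol(2171, "zmol", "pmol")
  band <- theoretical_band(co_soil_pmol, act_low, act_high)
  expect_equal(band$n_upper, 11e-9 / 29e-21, tolerance = 1e-12)
  expect_equal(band$n_lower, 11e-9 / 2171e-21, tolerance = 1e-12)
  expect_equal(band$n_upper, 3.79e11, tolerance = 0.01)
  expect_equal(band$n_lower, 5.07e9, tolerance = 0.01)
  expect_lte(band$n_lower, band$n_upper)

  # homogeneity: degree 1 in the soil rate, degree -1 in specific activity
  b2 <- theoretical_band(2 * co_soil_pmol, act_low, act_high)
  expect_equal(b2$n_upper, 2 * band$n_upper, tolerance = 1e-12)
  b3 <- theoretical_band(co_soil_pmol, 3 * act_low, 3 * act_high)
  expect_equal(b3$n_upper, band$n_upper / 3, tolerance = 1e-12)

  expect_equal(theoretical_band(0, act_low, act_high)$n_upper, 0)
  expect_error(theoretical_band(1, act_high, act_low), "swapped")
})

test_that("band consistency classification is a monotone closed-interval test", {
  band <- theoretical_band(convert_mol(11, "nmol", "pmol"),
                           convert_mol(29, "zmol", "pmol"),
                           convert_mol(2171, "zmol", "pmol"))
  expect_identical(band_consistency(band, 1e10), "within")
  expect_identical(band_consistency(band, 1e9), "below")
  expect_identical(band_consistency(band, 1e12), "above")
  # boundary: closed interval
  expect_identical(band_consistency(band, band$n_upper), "within")
  expect_identical(band_consistency(band, band$n_lower), "within")
  # monotone in abundance
  cls <- band_consistency(band, 10^seq(7, 13, 0.5))
  ord <- c(below = 1L, within = 2L, above = 3L)
  expect_true(all(diff(ord[cls]) >= 0))
})

test_that("amplicon lengths come from primer-name coordinates", {
  assays <- coxl_assays()
  t1 <- amplicon_length(assays[assays$assay == "type_I", ])
  expect_identical(as.integer(t1), 252L)
  expect_true(attr(t1, "matches_printed"))

  expect_message(
    uni <- amplicon_length(assays[assays$assay == "universal", ]),
    "800")
  expect_identical(as.integer(uni), 791L)
  expect_false(attr(uni, "matches_printed"))

  expect_message(
    dp <- amplicon_length(assays[assays$assay == "delta_proteo", ]),
    "291")
  expect_identical(as.integer(dp), 318L)

  zero <- list(fwd_name = "x-100-forward", rev_name = "x-100-reverse")
  expect_warning(z <- amplicon_length(zero), "invalid")
  expect_false(attr(z, "valid"))
  expect_error(amplicon_length(list(fwd_name = "fwd", rev_name = "rev")),
               "parse")
})

test_that("qPCR records round-trip through CSV", {
  run <- simulate_qpcr_run(0.7, 40, sd_cq = 0.1, unknown_copies = 1e6,
                           seed = 8)
  path <- tempfile(fileext = ".csv")
  write_qpcr_csv(run$records, path)
  back <- read_qpcr_csv(path)
  expect_equal(back$cq, run$records$cq, tolerance = 1e-9)
  expect_identical(back$role, run$records$role)
})
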