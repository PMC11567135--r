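test_that("dilution space ratio matches printed values and warns out of band", {
  expect_equal(round(dilution_space_ratio(1539.2, 1476.1), 3), 1.043)
  expect_equal(round(dilution_space_ratio(2024.2, 1944.0), 3), 1.041)
  expect_equal(dilution_space_ratio(1500, 1500), 1)
  expect_warning(dilution_space_ratio(1700, 1500), "outside")
  expect_error(dilution_space_ratio(1500, 0), "positive")
})

test_that("corrected dilution space: printed rows and exact construction", {
  # back-checked against the printed FFM of the same rows
  expect_equal(corrected_dilution_space(1539.2, 1476.1), 1470.8,
               tolerance = 0.1 / 1470.8)
  expect_equal(corrected_dilution_space(2024.2, 1944.0), 1935.6,
               tolerance = 0.1 / 1935.6)
  # ND = 1.043 N, NO = 1.007 N recovers N exactly for any N
  for (n in c(1, 1500, 2500))
    expect_equal(corrected_dilution_space(1.043 * n, 1.007 * n), n,
                 tolerance = 1e-12)
})

test_that("body composition reproduces printed FFM and handles boundaries", {
  bc1 <- body_composition(48, 1539.2, 1476.1)
  expect_equal(bc1$ffm_kg, 36.2, tolerance = 0.1 / 36.2)
  bc2 <- body_composition(52, 2024.2, 1944.0)
  expect_equal(bc2$ffm_kg, 47.7, tolerance = 0.1 / 47.7)
  expect_equal(bc1$tbw_kg / bc1$ncorr_mol, 0.01802, tolerance = 1e-12)

  # TBW = 0.732 * body mass exactly => FM = 0, fat% = 0
  cfg <- dlw_config()
  mass <- 50
  ncorr <- cfg$hydration * mass / cfg$kg_per_mol_water
  bc0 <- body_composition(mass, 1.043 * ncorr, 1.007 * ncorr)
  expect_equal(bc0$fm_kg, 0, tolerance = 1e-9)
  expect_equal(bc0$fat_pct, 0, tolerance = 1e-9)

  # negative FM: warn-and-pass-through by default, clamp on request
  ncorr_big <- cfg$hydration * mass * 1.1 / cfg$kg_per_mol_water
  expect_warning(bcn <- body_composition(mass, 1.043 * ncorr_big,
                                         1.007 * ncorr_big), "negative fat")
  expect_lt(bcn$fm_kg, 0)
  cfg_clamp <- dlw_config(negative_fm_policy = "clamp")
  expect_warning(bcc <- body_composition(mass, 1.043 * ncorr_big,
                                         1.007 * ncorr_big, cfg_clamp),
                 "clamped")
  expect_equal(bcc$fm_kg, 0)
})

test_that("CO2 production: scale, boundaries, linearity, unit identity", {
  ncorr <- corrected_dilution_space(1539.2, 1476.1)
  co2 <- co2_production(0.2269, 0.2604, ncorr)
  expect_equal(co2$rco2_mol_day, 17.1, tolerance = 0.01)
  expect_equal(co2$rco2_l_day, 381, tolerance = 0.005)
  expect_equal(co2$rco2_l_day / co2$rco2_mol_day, 22.26, tolerance = 1e-12)

  # delta = 0 boundary gives zero production
  kd <- 0.2
  expect_equal(co2_production(kd, 1.043 / 1.007 * kd, 1500)$rco2_mol_day, 0,
               tolerance = 1e-12)
  # reversed rates are physiologically invalid and name both rates
  expect_error(co2_production(0.26, 0.20, 1500), "kO")
  # linear in Ncorr
  a <- co2_production(0.2269, 0.2604, 1000)$rco2_mol_day
  b <- co2_production(0.2269, 0.2604, 2000)$rco2_mol_day
  expect_equal(b, 2 * a, tolerance = 1e-12)
})

test_that("TEE conversion uses the FQ-dependent energy equivalent", {
  expect_equal(tee_from_co2(0), 0)
  expect_equal(tee_from_co2(100), 100 * (1.106 + 3.94 / 0.86),
               tolerance = 1e-12)
  expect_equal(tee_from_co2(100, dlw_config(fq = 0.80)),
               100 * (1.106 + 3.94 / 0.80), tolerance = 1e-12)
  expect_error(dlw_config(fq = 1.2), "fq")
})

test_that("water turnover reproduces printed rows", {
  expect_equal(water_turnover(0.2269, 1539.2), 6.63, tolerance = 0.01 / 6.63)
  expect_equal(water_turnover(0.2038, 2024.2), 7.83, tolerance = 0.01 / 7.83)
  expect_equal(water_turnover(0.3678, 1942.4), 13.56, tolerance = 0.01 / 13.56)
})

test_that("TEE is monotone in kO; WT is monotone in kD and ND", {
  ncorr <- 1500
  kos <- seq(0.25, 0.40, by = 0.01)
  tees <- tee_from_co2(co2_production(0.22, kos, ncorr)$rco2_l_day)
  expect_true(all(diff(tees) > 0))
  expect_true(all(diff(water_turnover(seq(0.1, 0.4, 0.02), 1500)) > 0))
  expect_true(all(diff(water_turnover(0.22, seq(1200, 2200, 100))) > 0))
})

test_that("process_cohort derives the fixture and isolates bad rows", {
  derived <- fixture_derived()
  expect_equal(nrow(derived), 34)
  expect_equal(max(derived$tee_kcal_day), 4172, tolerance = 0.01)
  expect_equal(nrow(attr(derived, "rejected")), 0)

  # metabolic-water consistency: turnover exceeds CO2-implied metabolic water
  # (roughly 0.55 g water per litre CO2 from macronutrient oxidation)
  expect_true(all(derived$wt_l_day > 0.55e-3 * derived$rco2_l_day))

  inp <- cohort_inputs()
  # one corrupted row is rejected, the rest processed
  iso_bad <- inp$isotopes
  iso_bad$no_mol[5] <- 0
  expect_warning(d2 <- process_cohort(inp$participants, iso_bad), "rejected")
  expect_equal(nrow(d2), 33)
  rej <- attr(d2, "rejected")
  expect_equal(rej$participant_id, inp$participants$participant_id[5])

  # empty input: empty output with a warning, not an error
  expect_warning(d0 <- process_cohort(inp$participants[0, ], inp$isotopes[0, ]),
                 "empty")
  expect_equal(nrow(d0), 0)

  # schema violations are itemised
  expect_error(process_cohort(inp$participants[, -5], inp$isotopes),
               "body_mass_kg")
  dup <- rbind(inp$participants, inp$participants[1, ])
  expect_error(process_cohort(dup, inp$isotopes), "duplicated")
})

test_that("a lower food quotient rescales TEE by the closed-form factor", {
  inp <- cohort_inputs()
  d86 <- process_cohort(inp$participants, inp$isotopes)
  d80 <- process_cohort(inp$participants, inp$isotopes, dlw_config(fq = 0.80))
  factor80 <- (1.106 + 3.94 / 0.80) / (1.106 + 3.94 / 0.86)
  expect_equal(d80$tee_kcal_day, d86$tee_kcal_day * factor80,
               tolerance = 1e-12)
  # and WT is untouched by FQ
  expect_equal(d80$wt_l_day, d86$wt_l_day, tolerance = 1e-12)
})

test_that("presentation rounding happens only at CSV output", {
  derived <- fixture_derived()
  path <- tempfile(fileext = ".csv")
  write_cohort_csv(derived, path)
  back <- read.csv(path)
  expect_equal(back$tee_kcal_day, signif(derived$tee_kcal_day, 4))
  expect_false(isTRUE(all.equal(derived$tee_kcal_day,
                                signif(derived$tee_kcal_day, 4),
                                tolerance = 1e-12)))
})
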