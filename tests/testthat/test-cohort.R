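test_that("the packaged arm table has the expected shape and passes validation", {
  arms <- ra223_study_arms()
  expect_equal(nrow(arms), 8)
  expect_setequal(unique(arms$study_id), c("A", "B", "C", "D"))
  expect_equal(sum(arms$n_patients), 64 + 122 + 921 + 49)
  # neutropenia not reported for study D
  expect_true(is.na(arms$tox_n[arms$study_id == "D"]))
  cohort <- ra223_cohort()
  expect_true("eqd2_rn_gy" %in% names(cohort))
  expect_equal(nrow(cohort), 8)
  expect_equal(cohort$eqd2_rn_gy[cohort$activity_kbq_kg == 0], c(0, 0))
})

test_that("arm validation rejects malformed tables", {
  arms <- ra223_study_arms()
  bad <- arms; bad$os2y_n[1] <- bad$n_patients[1] + 1
  expect_error(validate_study_arms(bad), "exceed")
  bad <- arms; bad$mbq_per_cycle[bad$activity_kbq_kg == 0][1] <- 1
  expect_error(validate_study_arms(bad), "placebo")
  expect_error(validate_study_arms(arms[0, ]), "non-empty")
  expect_error(validate_study_arms(arms[, -2]), "lacks column")
})

test_that("weight-based activity conversion matches printed MBq per cycle", {
  expect_equal(injected_activity_per_cycle(25, 70), 1.75)
  expect_equal(injected_activity_per_cycle(50, 70), 3.5)
  expect_equal(injected_activity_per_cycle(80, 70), 5.6)
  expect_equal(injected_activity_per_cycle(0, 93), 0)
  # printed values override the computed ones (55 kBq/kg arm implies 75 kg)
  expect_equal(injected_activity_per_cycle(55, 70, printed_mbq = 4.125),
               4.125)
  expect_equal(injected_activity_per_cycle(c(50, 55), 70,
                                           printed_mbq = c(NA, 4.125)),
               c(3.5, 4.125))
})

test_that("two-point calibration solves the quadratic map exactly", {
  rn <- ra223_printed_eqd2_rn()
  cal <- calibrate_rn_model(rn[rn$activity_kbq_kg %in% c(25, 50), ])

  # independent closed-form 2x2 solve: y/A = c1 + c2*A at per-cycle scale
  y1 <- 34.2 / 3; y2 <- 77.4 / 3
  c2 <- (y2 / 50 - y1 / 25) / (50 - 25)
  c1 <- y1 / 25 - c2 * 25
  expect_equal(cal$c1, c1, tolerance = 1e-12)
  expect_equal(cal$c2, c2, tolerance = 1e-12)

  # source arms are reproduced exactly
  expect_equal(predict(cal, c(25, 50), 3), c(34.2, 77.4))
  # extrapolation to 80 kBq/kg lands near the published per-cycle value
  expect_equal(predict(cal, 80, 1), 140.7 / 3, tolerance = 0.5 / (140.7 / 3))
})

test_that("calibration recovers a known generator and degenerates cleanly", {
  a <- c(20, 45, 70, 95)
  truth <- c(c1 = 0.31, c2 = 0.0017)
  arms <- data.frame(activity_kbq_kg = a, n_cycles = c(3, 3, 6, 6),
                     eqd2_rn_gy = (truth["c1"] * a + truth["c2"] * a^2) *
                       c(3, 3, 6, 6))
  cal <- calibrate_rn_model(arms)
  expect_equal(cal$c1, 0.31, tolerance = 1e-9)
  expect_equal(cal$c2, 0.0017, tolerance = 1e-9)

  # purely linear generator: fitted quadratic term vanishes
  lin <- data.frame(activity_kbq_kg = a, n_cycles = 1,
                    eqd2_rn_gy = 0.5 * a)
  expect_equal(calibrate_rn_model(lin)$c2, 0, tolerance = 1e-9)

  dup <- data.frame(activity_kbq_kg = c(50, 50), n_cycles = 1,
                    eqd2_rn_gy = c(10, 11))
  expect_error(calibrate_rn_model(dup), "distinct")
})

test_that("population EQD2 combines the two modalities as an affine mix", {
  expect_equal(round_half_up(eqd2_tot(34.2, 0.29, 12.0), 1), 37.7)
  expect_equal(eqd2_tot(103.2, 1.00, 32.5), 135.7)
  expect_equal(eqd2_tot(42, 0, 99), 42)
  expect_error(eqd2_tot(10, 1.2, 10), "\\[0, 1\\]")
})

test_that("dose tables reproduce the published per-arm EQD2 cells", {
  arms <- fixture_arms()
  sc8 <- dose_scenario(8, 1)
  tab8 <- format_dose_table(build_dose_table(arms, sc8))

  # study C treated arm under the single-fraction scenario
  c50 <- tab8[tab8$study_id == "C" & tab8$activity_kbq_kg == 50, ]
  expect_equal(c50$eqd2_rn, 154.8)
  expect_equal(c50$eqd2_ebrt_weighted, 1.9)
  expect_equal(c50$eqd2_tot, 156.7)

  # 80 kBq/kg arm under the 20 Gy / 5 fr scenario
  tab20 <- format_dose_table(build_dose_table(arms, dose_scenario(20, 5)))
  b80 <- tab20[tab20$activity_kbq_kg == 80, ]
  expect_equal(b80$eqd2_tot, 149.1)

  # all-placebo arms with f = 0 give zero total
  placebo <- arms
  placebo$activity_kbq_kg <- 0
  placebo$mbq_per_cycle <- 0
  placebo$eqd2_rn_gy <- 0
  placebo$f_ebrt_pct <- 0
  placebo$f_ebrt_n <- 0
  tabp <- build_dose_table(placebo, sc8)
  expect_equal(tabp$eqd2_tot, rep(0, 8))
})

test_that("dose-table invariants hold across scenarios", {
  arms <- fixture_arms()
  tabs <- lapply(fixture_scenarios(), function(sc)
    build_dose_table(arms, sc))

  # additivity audit over every cell, pre-rounding
  for (tab in tabs)
    expect_equal(tab$eqd2_tot, tab$eqd2_rn + tab$eqd2_ebrt_weighted)

  # the radionuclide column does not depend on the EBRT scenario
  expect_equal(tabs[[1]]$eqd2_rn, tabs[[2]]$eqd2_rn)
  expect_equal(tabs[[2]]$eqd2_rn, tabs[[3]]$eqd2_rn)

  # totals are monotone in the scenario's EQD2_EBRT (for arms with f > 0)
  expect_true(all(tabs[[2]]$eqd2_tot >= tabs[[1]]$eqd2_tot))
  expect_true(all(tabs[[3]]$eqd2_tot >= tabs[[2]]$eqd2_tot))

  # cycle-count rescaling: 6 cycles instead of 3 doubles the calibrated dose
  cal <- calibrate_rn_model(ra223_printed_eqd2_rn())
  expect_equal(predict(cal, 50, 6), 2 * predict(cal, 50, 3))
})

test_that("mechanistic pathway feeds the dose table", {
  arms <- fixture_arms()
  template <- rn_dose_model(c("Ra-223" = 5000, "Rn-219" = 2000),
                            injected_activity = 1)
  tab <- build_dose_table(arms, dose_scenario(8, 1), rn_dose = template)
  expect_equal(tab$eqd2_rn[arms$activity_kbq_kg == 0], c(0, 0))
  # doubling cycles at equal activity doubles the component (B50 vs C50
  # arms share 3.5 MBq/cycle but have 3 vs 6 cycles)
  b50 <- tab$eqd2_rn[arms$study_id == "B" & arms$activity_kbq_kg == 50]
  c50 <- tab$eqd2_rn[arms$study_id == "C" & arms$activity_kbq_kg == 50]
  expect_equal(c50, 2 * b50)

  # missing dose source for active arms is a configuration error
  noRN <- ra223_study_arms()
  expect_error(build_dose_table(noRN, dose_scenario(8, 1)), "dose source")
})
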