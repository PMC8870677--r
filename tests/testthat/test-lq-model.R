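test_that("BED of fractionated EBRT matches the closed form", {
  expect_equal(bed_ebrt(ebrt_schedule(8, 1)), 14.4)
  expect_equal(bed_ebrt(ebrt_schedule(30, 10)), 39.0)
  expect_equal(bed_ebrt(ebrt_schedule(20, 5)), 28.0)
  expect_equal(bed_ebrt(ebrt_schedule(0, 1)), 0)

  # BED >= physical dose, equality only at zero dose
  for (D in c(0.5, 2, 8, 30, 74)) {
    for (nf in c(1, 5, 37)) {
      bed <- bed_ebrt(ebrt_schedule(D, nf))
      expect_gt(bed, D)
    }
  }
})

test_that("EQD2 conversion is the stated linear map", {
  expect_equal(eqd2_from_bed(14.4), 12.0)
  expect_equal(round_half_up(eqd2_from_bed(28.0), 1), 23.3)
  expect_equal(eqd2_from_bed(0), 0)

  # linearity / order preservation
  bed <- c(3, 17.5, 100)
  expect_equal(eqd2_from_bed(2.5 * bed), 2.5 * eqd2_from_bed(bed))
  expect_error(eqd2_from_bed(-1), "non-negative")

  # a 2 Gy/fr schedule is its own EQD2 (round trip)
  p <- lq_params()
  for (nf in c(1, 5, 30)) {
    sched <- ebrt_schedule(2 * nf, nf)
    expect_equal(eqd2_from_bed(bed_ebrt(sched, p), p), sched$total_dose)
  }
})

test_that("RBE_max reproduces the reference value and its limits", {
  expect_equal(round(rbe_max(lq_params()), 2), 5.96)
  expect_equal(rbe_max(lq_params(rbe_exp = 1)), 1.0)
  # with no dose-per-fraction correction the experimental RBE is returned
  expect_equal(rbe_max(lq_params(rbe_exp = 5, d_ref = 1e-12)), 5,
               tolerance = 1e-9)
  expect_error(lq_params(rbe_exp = 0), ">= 1")
})

test_that("initial dose rate is the product of its three inputs", {
  expect_equal(dose_rate(1, 1, 1), 1)
  expect_equal(dose_rate(0.7, 0, 2), 0)
  expect_equal(dose_rate(0.5, 3.5, 0.00253), 0.5 * 3.5 * 0.00253)
  expect_error(dose_rate(-1, 1, 1), "non-negative")
})

test_that("mixture BED: double-sum route equals the squared-sum closed form", {
  set.seed(11)
  chain <- ra223_chain()
  for (rep in 1:20) {
    coefs <- stats::runif(7, 0, 500)
    names(coefs) <- chain$nuclides$name
    m <- rn_dose_model(coefs, injected_activity = stats::runif(1, 0.5, 6),
                       n_cycles = sample(1:6, 1),
                       decay_constant = stats::runif(1, 1e-4, 0.1))
    expect_equal(bed_rn(m, method = "double_sum"),
                 bed_rn(m, method = "closed_form"), tolerance = 1e-12)
  }

  # the identity behind it: full Cartesian double sum == (sum)^2
  for (len in 1:7) {
    r <- stats::runif(len, 0, 3)
    ss <- 0
    for (i in seq_along(r)) for (j in seq_along(r)) ss <- ss + r[i] * r[j]
    expect_equal(ss, sum(r)^2, tolerance = 1e-12)
  }
})

test_that("mixture BED is linear in cycles and has the low-lambda limit", {
  coefs <- c("Ra-223" = 300, "Rn-219" = 120, "Pb-211" = 80)
  m3 <- rn_dose_model(coefs, injected_activity = 3.5, n_cycles = 3)
  m6 <- rn_dose_model(coefs, injected_activity = 3.5, n_cycles = 6)
  expect_equal(bed_rn(m6), 2 * bed_rn(m3))
  expect_equal(eqd2_rn(m6), 2 * eqd2_rn(m3))

  # as lambda -> 0 at fixed total physical dose, BED -> n_c * RBE_max * D_tot
  m0 <- rn_dose_model(c("Ra-223" = 100), injected_activity = 10,
                      n_cycles = 2, decay_constant = 1e-9)
  d_tot <- 100 * 10 / 1000
  expect_equal(bed_rn(m0), 2 * rbe_max(lq_params()) * d_tot,
               tolerance = 1e-6)

  # monotone non-decreasing in each coefficient and in injected activity
  base <- bed_rn(rn_dose_model(coefs, injected_activity = 3.5, n_cycles = 3))
  up <- coefs; up["Rn-219"] <- up["Rn-219"] + 50
  expect_gt(bed_rn(rn_dose_model(up, injected_activity = 3.5, n_cycles = 3)),
            base)
  expect_gt(bed_rn(rn_dose_model(coefs, injected_activity = 4, n_cycles = 3)),
            base)
})

test_that("mixture BED handles degenerate inputs as specified", {
  empty <- rn_dose_model(stats::setNames(numeric(0), character(0)),
                         injected_activity = 3.5, n_cycles = 3)
  expect_warning(val <- bed_rn(empty), "empty")
  expect_equal(val, 0)
  expect_error(rn_dose_model(c("Ra-223" = 1), injected_activity = 1,
                             decay_constant = 0), "positive")
  expect_error(rn_dose_model(c("U-235" = 1), injected_activity = 1),
               "U-235")
})

test_that("emission-weighted variant down-weights beta/gamma nuclides", {
  p <- lq_params()
  alpha_only <- rn_dose_model(c("Ra-223" = 200), injected_activity = 3.5,
                              n_cycles = 1)
  beta_only <- rn_dose_model(c("Pb-211" = 200), injected_activity = 3.5,
                             n_cycles = 1)
  # global weighting treats them identically
  expect_equal(bed_rn(alpha_only, p), bed_rn(beta_only, p))
  # per-emission weighting applies RBE_photon = 1 to the beta emitter
  expect_gt(bed_rn(alpha_only, p, emission_weighted = TRUE),
            bed_rn(beta_only, p, emission_weighted = TRUE))
  d_tot <- 200 * 3.5 / 1000
  lam <- ra223_lambda()
  expect_equal(bed_rn(beta_only, p, emission_weighted = TRUE),
               1 * d_tot + lam * d_tot^2 / (10 * (1.4 + lam)))
})

test_that("residence time follows single-phase kinetics", {
  lam <- ra223_lambda()
  expect_equal(residence_time(1, lam), rate_to_half_life(lam) / log(2))
  expect_equal(residence_time(0, 0.01), 0)
  expect_equal(residence_time(0.5, 0.00253), 0.5 / 0.00253)
  expect_error(residence_time(1.2, 0.01), "\\[0, 1\\]")
  expect_error(residence_time(0.5, 0), "positive")
})

test_that("report-time rounding rounds halves away from zero", {
  expect_equal(round_half_up(5.25, 1), 5.3)
  expect_equal(round_half_up(-5.25, 1), -5.3)
  expect_equal(round_half_up(37.68, 1), 37.7)
  expect_equal(round_half_up(2.5, 0), 3)
})
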