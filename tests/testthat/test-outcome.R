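test_that("outcome datasets join doses and counts and drop missing arms", {
  arms <- fixture_arms()
  tab <- build_dose_table(arms, dose_scenario(8, 1))
  os <- outcome_dataset(tab, arms, "os_2y")
  expect_equal(nrow(os), 8)
  expect_equal(sum(os$events), 10 + 4 + 15 + 17 + 20 + 184 + 55 + 24)
  tox <- outcome_dataset(tab, arms, "tox")
  expect_equal(nrow(tox), 7)
  expect_false("D" %in% tox$study_id)
  expect_identical(attr(tox, "endpoint"), "tox")
})

test_that("grouped-binomial fit equals the expanded Bernoulli fit", {
  data <- toy_outcome_data()
  fit <- fit_logistic(data, variant = "fixed")
  long <- expand_bernoulli(data)
  oracle <- stats::glm(y ~ eqd2_tot, family = stats::binomial(), data = long)
  expect_equal(unname(coef(fit)), unname(stats::coef(oracle)),
               tolerance = 1e-8)
  expect_equal(unname(fit$se),
               unname(sqrt(diag(stats::vcov(oracle)))), tolerance = 1e-6)
})

test_that("constant event proportions give slope zero and logit(p) intercept", {
  d <- data.frame(study_id = c("X", "Y", "Z"),
                  eqd2_tot = c(5, 60, 120),
                  events = c(1, 2, 3), n = c(4, 8, 12))  # all p = 0.25
  fit <- fit_logistic(d, variant = "fixed")
  expect_equal(coef(fit)[["slope"]], 0, tolerance = 1e-8)
  expect_equal(coef(fit)[["intercept"]], stats::qlogis(0.25),
               tolerance = 1e-8)
})

test_that("dose shifts reparameterise the intercept and leave the slope", {
  data <- toy_outcome_data()
  f0 <- fit_logistic(data)
  shifted <- data; shifted$eqd2_tot <- shifted$eqd2_tot + 25
  f1 <- fit_logistic(shifted)
  expect_equal(coef(f1)[["slope"]], coef(f0)[["slope"]], tolerance = 1e-8)
  expect_equal(coef(f1)[["intercept"]],
               coef(f0)[["intercept"]] - 25 * coef(f0)[["slope"]],
               tolerance = 1e-8)
})

test_that("degenerate and separated outcomes are flagged, not reported", {
  d <- toy_outcome_data()
  d$events <- c(0, 0, 0)
  fit <- fit_logistic(d)
  expect_false(fit$converged)
  expect_match(paste(fit$diagnostics, collapse = " "), "degenerate")
  expect_error(predict(fit, c(0, 50)), "non-converged")

  sep <- data.frame(study_id = c("X", "Y", "Z", "W"),
                    eqd2_tot = c(1, 2, 100, 101),
                    events = c(0, 0, 20, 20), n = rep(20, 4))
  fit2 <- suppressWarnings(fit_logistic(sep))
  expect_false(fit2$converged)
})

test_that("prediction curves are monotone with bands containing the estimate", {
  arms <- fixture_arms()
  tab <- build_dose_table(arms, dose_scenario(8, 1))
  for (ep in c("os_2y", "tox")) {
    fit <- fit_logistic(outcome_dataset(tab, arms, ep))
    grid <- seq(0, 200, by = 1)
    pr <- predict(fit, grid)
    expect_true(all(diff(pr$prob) > 0))  # positive slope -> increasing
    expect_true(all(pr$lower <= pr$prob & pr$prob <= pr$upper))
    expect_true(all(pr$lower >= 0 & pr$upper <= 1))
  }

  # closed-form check of the inverse-logit prediction
  fit <- fit_logistic(outcome_dataset(tab, arms, "os_2y"))
  fit$coefficients <- c(intercept = -1.364, slope = 0.006)
  pr <- predict(fit, 156.7)
  expect_equal(pr$prob, stats::plogis(-1.364 + 0.006 * 156.7),
               tolerance = 1e-12)
  expect_equal(round(pr$prob, 4), 0.3956)
})

test_that("band width grows with distance from the weighted dose centre", {
  arms <- fixture_arms()
  tab <- build_dose_table(arms, dose_scenario(8, 1))
  data <- outcome_dataset(tab, arms, "os_2y")
  fit <- fit_logistic(data)
  # centre of the design on the linear-predictor scale: where the variance
  # of the linear predictor is minimal
  grid <- seq(0, 200, by = 0.5)
  X <- cbind(1, grid)
  v <- rowSums((X %*% fit$vcov) * X)
  centre <- grid[which.min(v)]
  right <- grid >= centre
  expect_true(all(diff(v[right]) >= 0))
  expect_true(all(diff(v[!right]) <= 0))
})

test_that("random-intercept variant fits and matches the fixed slope sign", {
  arms <- fixture_arms()
  tab <- build_dose_table(arms, dose_scenario(8, 1))
  data <- outcome_dataset(tab, arms, "os_2y")
  fx <- fit_logistic(data, "fixed")
  rnd <- fit_logistic(data, "random_intercept")
  expect_true(rnd$converged)
  expect_equal(sign(coef(rnd)[["slope"]]), sign(coef(fx)[["slope"]]))
  expect_true(is.matrix(rnd$vcov) && all(dim(rnd$vcov) == 2))
  # covariance is symmetric positive semi-definite
  expect_equal(rnd$vcov, t(rnd$vcov), tolerance = 1e-10)
  expect_true(all(eigen(rnd$vcov, symmetric = TRUE)$values > -1e-12))
})

test_that("schedule comparison tabulates per-scenario slopes", {
  arms <- fixture_arms()
  fits <- lapply(fixture_scenarios(), function(sc)
    fit_logistic(outcome_dataset(build_dose_table(arms, sc), arms, "os_2y")))
  cmp <- compare_schedule_effect(fits)
  expect_equal(nrow(cmp), 3)
  expect_true(all(cmp$slope > 0))
  expect_true(all(cmp$p_slope < 0.05))

  # identical datasets give identical rows
  same <- compare_schedule_effect(list(a = fits[[1]], b = fits[[1]]))
  expect_equal(same$slope[1], same$slope[2])

  expect_error(compare_schedule_effect(fits[1]), ">= 2")
  tox <- fit_logistic(outcome_dataset(
    build_dose_table(arms, dose_scenario(8, 1)), arms, "tox"))
  expect_error(compare_schedule_effect(list(fits[[1]], tox)), "mix")
})
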