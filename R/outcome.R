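#' Assemble an arm-level outcome dataset for dose-response modelling
#'
#' Joins a per-arm dose table with the outcome counts of the study-arm
#' table for one endpoint. Arms with a missing outcome are dropped (study D
#' did not report neutropenia, so the toxicity dataset has 7 of the 8
#' arms).
#'
#' @param dose_table Output of [build_dose_table()].
#' @param arms Study-arm data.frame aligned row-by-row with `dose_table`
#'   (the same table the dose table was built from).
#' @param endpoint `"os_2y"` (two-year overall survival) or `"tox"`
#'   (grade >=2 neutropenia).
#'
#' @return A data.frame with columns `study_id`, `eqd2_tot` (Gy), `events`,
#'   `n`, and attribute `"endpoint"`.
#' @examples
#' arms <- ra223_cohort()
#' tab <- build_dose_table(arms, dose_scenario(8, 1))
#' outcome_dataset(tab, arms, "tox")  # 7 rows: study D lacks toxicity data
#' @export
outcome_dataset <- function(dose_table, arms, endpoint = c("os_2y", "tox")) {
  endpoint <- match.arg(endpoint)
  if (nrow(dose_table) != nrow(arms) ||
      !all(dose_table$study_id == arms$study_id))
    stop("'dose_table' and 'arms' must be row-aligned")
  events <- if (endpoint == "os_2y") arms$os2y_n else arms$tox_n
  keep <- !is.na(events)
  out <- data.frame(study_id = arms$study_id[keep],
                    eqd2_tot = dose_table$eqd2_tot[keep],
                    events = events[keep],
                    n = arms$n_patients[keep],
                    stringsAsFactors = FALSE)
  if (any(out$events > out$n)) stop("events exceed arm size")
  if (any(out$n <= 0)) stop("arm sizes must be positive")
  attr(out, "endpoint") <- endpoint
  attr(out, "scenario") <- attr(dose_table, "scenario")
  out
}

#' Sample-size-weighted logistic dose-response model
#'
#' Fits a logistic regression of arm-level event proportions on total
#' equieffective dose, with each arm weighted by its sample size through
#' the grouped-binomial likelihood (`events` successes out of `n` trials
#' per arm) — the likelihood-exact meaning of weighting by sample size.
#' Two variants are available:
#' \describe{
#'   \item{`"fixed"`}{ordinary grouped-binomial GLM
#'     (`glm(cbind(events, n - events) ~ eqd2_tot, binomial)`).}
#'   \item{`"random_intercept"`}{adds a Gaussian random intercept per study
#'     (`lme4::glmer`), absorbing residual between-study heterogeneity not
#'     explained by dose. The dose is rescaled internally (divided by 100)
#'     for numerical conditioning and the coefficients mapped back to the
#'     per-Gy scale.}
#' }
#' Wald standard errors, z statistics and two-sided normal p-values are
#' reported for both. Complete separation and degenerate outcomes
#' (all-zero or all-`n` events) are detected and flagged: the fit is
#' returned with `converged = FALSE` and a diagnostic message instead of
#' silently unusable estimates.
#'
#' @param data An [outcome_dataset()] (columns `study_id`, `eqd2_tot`,
#'   `events`, `n`).
#' @param variant `"fixed"` (default) or `"random_intercept"`.
#'
#' @return An object of class `"logistic_fit"`: list with `coefficients`
#'   (intercept, slope), `se`, `z`, `p`, `vcov` (2x2), `variant`,
#'   `converged`, `diagnostics`, `endpoint`, `scenario`, the fitted model
#'   object and the data.
#' @examples
#' arms <- ra223_cohort()
#' tab <- build_dose_table(arms, dose_scenario(8, 1))
#' fit <- fit_logistic(outcome_dataset(tab, arms, "os_2y"))
#' coef(fit)
#' @export
fit_logistic <- function(data, variant = c("fixed", "random_intercept")) {
  variant <- match.arg(variant)
  req <- c("study_id", "eqd2_tot", "events", "n")
  if (!is.data.frame(data) || !all(req %in% names(data)))
    stop("'data' must have columns ", paste(req, collapse = ", "))
  if (nrow(data) < 3)
    stop("need >= 3 arms to fit a two-parameter dose-response model")
  if (length(unique(data$eqd2_tot)) < 2)
    stop("need >= 2 distinct dose values")

  diagnostics <- character(0)
  if (all(data$events == 0) || all(data$events == data$n))
    diagnostics <- c(diagnostics,
                     "degenerate outcome: all arms have 0% or 100% events")

  if (variant == "fixed") {
    fit <- stats::glm(cbind(events, n - events) ~ eqd2_tot,
                      family = stats::binomial(), data = data)
    beta <- stats::coef(fit)
    V <- stats::vcov(fit)
    conv <- isTRUE(fit$converged)
    if (max(abs(stats::predict(fit, type = "link"))) > 15) {
      diagnostics <- c(diagnostics,
                       "possible complete separation: |linear predictor| > 15")
      conv <- FALSE
    }
  } else {
    scale <- 100  # fit on dose/100 for conditioning; map back below
    d2 <- data
    d2$dose_s <- d2$eqd2_tot / scale
    fit <- lme4::glmer(cbind(events, n - events) ~ dose_s + (1 | study_id),
                       family = stats::binomial(), data = d2)
    beta <- lme4::fixef(fit)
    V <- as.matrix(stats::vcov(fit))
    beta[2] <- beta[2] / scale
    V[1, 2] <- V[2, 1] <- V[1, 2] / scale
    V[2, 2] <- V[2, 2] / scale^2
    msgs <- fit@optinfo$conv$lme4$messages
    conv <- length(msgs) == 0
    if (!conv) diagnostics <- c(diagnostics, unlist(msgs))
  }
  if (length(diagnostics) > 0) conv <- FALSE

  beta <- stats::setNames(as.numeric(beta), c("intercept", "slope"))
  se <- stats::setNames(sqrt(diag(V)), c("intercept", "slope"))
  z <- beta / se
  structure(list(coefficients = beta, se = se, z = z,
                 p = 2 * stats::pnorm(-abs(z)),
                 vcov = unname(as.matrix(V)),
                 variant = variant, converged = conv,
                 diagnostics = diagnostics,
                 endpoint = attr(data, "endpoint"),
                 scenario = attr(data, "scenario"),
                 model = fit, data = data),
            class = "logistic_fit")
}

#' @export
coef.logistic_fit <- function(object, ...) object$coefficients

#' @export
vcov.logistic_fit <- function(object, ...) object$vcov

#' @export
print.logistic_fit <- function(x, ...) {
  cat(sprintf("Weighted logistic dose-response model (%s%s%s)\n",
              x$variant,
              if (!is.null(x$endpoint)) paste0(", endpoint: ", x$endpoint)
              else "",
              if (!is.null(x$scenario)) paste0(", EBRT: ", x$scenario)
              else ""))
  tab <- data.frame(beta = x$coefficients, SE = x$se, z = x$z,
                    `p value` = format.pval(x$p, digits = 3),
                    check.names = FALSE,
                    row.names = c("Intercept", "EQD2_TOT"))
  print(tab, digits = 4)
  if (!x$converged)
    cat("NOT CONVERGED:", paste(x$diagnostics, collapse = "; "), "\n")
  invisible(x)
}

#' Predicted dose-response curve with 95% confidence band
#'
#' Inverse-logit of the fitted linear predictor over a dose grid, with a
#' pointwise confidence band computed by the delta method on the linear
#' predictor scale and then transformed (so the band always lies in
#' \[0, 1\] and contains the point estimate). For the random-intercept
#' variant the prediction uses the fixed effects only (study-level curve).
#'
#' @param object A converged [fit_logistic()] result.
#' @param eqd2_grid Doses (Gy) at which to predict.
#' @param level Confidence level (default 0.95).
#' @param ... Unused.
#'
#' @return A data.frame with columns `eqd2_tot`, `prob`, `lower`, `upper`.
#' @export
predict.logistic_fit <- function(object, eqd2_grid, level = 0.95, ...) {
  if (!object$converged)
    stop("refusing to predict from a non-converged fit: ",
         paste(object$diagnostics, collapse = "; "))
  stopifnot(is.numeric(eqd2_grid), all(is.finite(eqd2_grid)))
  X <- cbind(1, eqd2_grid)
  lp <- drop(X %*% object$coefficients)
  se <- sqrt(rowSums((X %*% object$vcov) * X))
  q <- stats::qnorm(1 - (1 - level) / 2)
  data.frame(eqd2_tot = eqd2_grid,
             prob = stats::plogis(lp),
             lower = stats::plogis(lp - q * se),
             upper = stats::plogis(lp + q * se))
}

#' Compare the dose effect across EBRT scenarios
#'
#' Tabulates the fitted slope (per Gy), its standard error and Wald p-value
#' for the same endpoint fitted under two or more EBRT scenarios, so the
#' sensitivity of the dose-response to the assumed EBRT schedule can be
#' inspected. Interpretation is left to the user.
#'
#' @param fits A named list of [fit_logistic()] results on the same
#'   endpoint, one per scenario.
#'
#' @return A data.frame with one row per scenario: `scenario`, `variant`,
#'   `intercept`, `slope`, `se_slope`, `z_slope`, `p_slope`.
#' @export
compare_schedule_effect <- function(fits) {
  if (!is.list(fits) || length(fits) < 2)
    stop("need fits from >= 2 scenarios to compare")
  if (!all(vapply(fits, inherits, logical(1), "logistic_fit")))
    stop("all elements must be 'logistic_fit' objects")
  endpoints <- unique(vapply(fits, function(f) f$endpoint %||% NA_character_,
                             character(1)))
  if (length(endpoints) != 1)
    stop("fits mix endpoints: ", paste(endpoints, collapse = ", "))
  scen <- names(fits)
  if (is.null(scen))
    scen <- vapply(fits, function(f) f$scenario %||% "?", character(1))
  data.frame(scenario = scen,
             variant = vapply(fits, function(f) f$variant, character(1)),
             intercept = vapply(fits, function(f) f$coefficients[1],
                                numeric(1)),
             slope = vapply(fits, function(f) f$coefficients[2], numeric(1)),
             se_slope = vapply(fits, function(f) f$se[2], numeric(1)),
             z_slope = vapply(fits, function(f) f$z[2], numeric(1)),
             p_slope = vapply(fits, function(f) f$p[2], numeric(1)),
             row.names = NULL, stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Plot an arm-level dose-response fit
#'
#' Base-graphics rendering of the fitted curve with its 95% band (shaded)
#' and the observed arm proportions as points whose area is proportional to
#' arm size.
#'
#' @param x A converged [fit_logistic()] object.
#' @param eqd2_grid Dose grid for the curve; defaults to 0 to the maximum
#'   observed dose plus 10%.
#' @param ... Passed to [graphics::plot()].
#' @return The prediction data.frame, invisibly.
#' @export
plot.logistic_fit <- function(x, eqd2_grid = NULL, ...) {
  d <- x$data
  if (is.null(eqd2_grid))
    eqd2_grid <- seq(0, max(d$eqd2_tot) * 1.1, length.out = 200)
  pr <- predict(x, eqd2_grid)
  ylab <- switch(x$endpoint %||% "prob",
                 os_2y = "2-year overall survival probability",
                 tox = "Probability of grade >=2 neutropenia",
                 "Event probability")
  graphics::plot(pr$eqd2_tot, pr$prob, type = "n", ylim = c(0, 1),
                 xlab = expression(EQD2[TOT] ~ "(Gy)"), ylab = ylab, ...)
  graphics::polygon(c(pr$eqd2_tot, rev(pr$eqd2_tot)),
                    c(pr$lower, rev(pr$upper)),
                    col = grDevices::grey(0.85), border = NA)
  graphics::lines(pr$eqd2_tot, pr$prob, lwd = 2)
  graphics::points(d$eqd2_tot, d$events / d$n, pch = 21,
                   bg = "steelblue", cex = sqrt(d$n / mean(d$n)) * 1.5)
  invisible(pr)
}
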