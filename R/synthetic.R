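#' Known logistic dose-response truth for simulation studies
#'
#' @param intercept Intercept on the logit scale.
#' @param slope Slope in logit units per Gy.
#' @param seed Integer RNG seed making downstream simulation reproducible.
#'
#' @return An object of class `"synthetic_truth"`.
#' @examples
#' synthetic_truth(-1.364, 0.006, seed = 1)
#' @export
synthetic_truth <- function(intercept, slope, seed = 1L) {
  stopifnot(is.numeric(intercept), is.numeric(slope),
            is.numeric(seed), length(seed) == 1L)
  structure(list(intercept = intercept, slope = slope,
                 seed = as.integer(seed)),
            class = "synthetic_truth")
}

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  }
  set.seed(seed)
  code
}

#' Generate a synthetic lesion-level dosimetry dataset
#'
#' Emulates a lesion-level bone-metastasis dosimetry study: `n_lesions`
#' lesions spread over `n_patients` patients (each patient gets at least
#' one), with lesion masses sampled log-uniformly over `mass_range` and
#' absorbed dose per injected activity following a decreasing exponential
#' in lesion mass,
#' \deqn{dose/activity = a\, e^{-b \cdot mass} \cdot \varepsilon,}
#' where \eqn{\varepsilon} is multiplicative lognormal noise with unit mean
#' and coefficient of variation `noise_cv`. A mono-exponential residence
#' time is attached per lesion from a sampled uptake fraction. The defaults
#' (24 lesions, 9 patients) mirror the size of the published lesion set the
#' virtual cohort rests on; the curve parameters are free configuration,
#' since the underlying per-lesion values are not published.
#'
#' @param n_patients Number of patients (> 0; default 9).
#' @param n_lesions Number of lesions (>= `n_patients`; default 24).
#' @param mass_range Lesion mass range in grams (default 2 to 100 g).
#' @param curve_params Numeric `c(a, b)`: amplitude in Gy/MBq and mass
#'   decay rate in 1/g (both > 0; default `c(1.0, 0.025)`).
#' @param noise_cv Coefficient of variation of the multiplicative noise
#'   (in \[0, 1); default 0.2).
#' @param decay_constant Effective clearance rate used for the residence
#'   times, h^-1 (default [ra223_lambda()]).
#' @param seed Integer seed; the output is a pure function of the
#'   arguments.
#'
#' @return A data.frame with one row per lesion: `patient_id`, `lesion_id`,
#'   `mass_g`, `dose_per_activity_gy_mbq`, `residence_time_h`.
#' @examples
#' lesions <- generate_lesion_set(seed = 7)
#' fit_dose_mass_curve(lesions)
#' @export
generate_lesion_set <- function(n_patients = 9, n_lesions = 24,
                                mass_range = c(2, 100),
                                curve_params = c(a = 1.0, b = 0.025),
                                noise_cv = 0.2,
                                decay_constant = ra223_lambda(),
                                seed = 1L) {
  stopifnot(n_patients > 0, n_lesions > 0,
            length(mass_range) == 2L, all(mass_range > 0),
            mass_range[1] < mass_range[2],
            length(curve_params) == 2L)
  a <- curve_params[[1]]; b <- curve_params[[2]]
  if (a <= 0 || b <= 0) stop("curve parameters 'a' and 'b' must be positive")
  if (noise_cv < 0 || noise_cv >= 1) stop("'noise_cv' must lie in [0, 1)")
  if (n_lesions < n_patients)
    stop("'n_lesions' must be >= 'n_patients' (every patient has a lesion)")

  with_seed(seed, {
    mass <- exp(stats::runif(n_lesions, log(mass_range[1]),
                             log(mass_range[2])))
    noise <- if (noise_cv == 0) rep(1, n_lesions) else {
      sdlog <- sqrt(log(1 + noise_cv^2))
      stats::rlnorm(n_lesions, meanlog = -sdlog^2 / 2, sdlog = sdlog)
    }
    patient <- sort(c(seq_len(n_patients),
                      sample.int(n_patients, n_lesions - n_patients,
                                 replace = TRUE)))
    uptake <- stats::runif(n_lesions, 0.1, 0.9)
    data.frame(patient_id = patient,
               lesion_id = seq_len(n_lesions),
               mass_g = mass,
               dose_per_activity_gy_mbq = a * exp(-b * mass) * noise,
               residence_time_h = residence_time(uptake, decay_constant))
  })
}

#' Fit the exponential dose-versus-mass curve
#'
#' Nonlinear least-squares fit of
#' `dose_per_activity = a * exp(-b * mass)` to a lesion set, initialised
#' from the log-linear regression of log-dose on mass (which is already
#' exact on noiseless data). Levenberg-Marquardt is used for robustness on
#' zero-residual and noisy inputs alike.
#'
#' @param records A lesion data.frame with columns `mass_g` and
#'   `dose_per_activity_gy_mbq` (>= 3 rows, non-degenerate masses).
#'
#' @return An object of class `"dose_mass_fit"`: list with `a`, `b`,
#'   `residual_sd`, `n`, and the underlying `nls` fit.
#' @export
fit_dose_mass_curve <- function(records) {
  stopifnot(is.data.frame(records),
            all(c("mass_g", "dose_per_activity_gy_mbq") %in% names(records)))
  if (nrow(records) < 3)
    stop("need >= 3 lesions to fit a two-parameter curve")
  if (stats::sd(records$mass_g) == 0)
    stop("singular fit: lesion masses are degenerate (all equal)")
  if (any(records$dose_per_activity_gy_mbq <= 0))
    stop("doses must be positive for the exponential model")

  ll <- stats::lm(log(dose_per_activity_gy_mbq) ~ mass_g, data = records)
  start <- list(a = exp(stats::coef(ll)[[1]]), b = -stats::coef(ll)[[2]])
  fit <- minpack.lm::nlsLM(dose_per_activity_gy_mbq ~ a * exp(-b * mass_g),
                           data = records, start = start)
  cf <- stats::coef(fit)
  structure(list(a = unname(cf["a"]), b = unname(cf["b"]),
                 residual_sd = stats::sigma(fit), n = nrow(records),
                 fit = fit),
            class = "dose_mass_fit")
}

#' @export
print.dose_mass_fit <- function(x, ...) {
  cat("Exponential dose-vs-mass fit: dose/activity = a * exp(-b * mass)\n")
  cat(sprintf("  a = %.4g Gy/MBq, b = %.4g 1/g (n = %d, residual SD = %.3g)\n",
              x$a, x$b, x$n, x$residual_sd))
  invisible(x)
}

#' Simulate arm-level binomial outcomes from a known dose-response
#'
#' Draws independent event counts per arm,
#' `events ~ Binomial(n, plogis(intercept + slope * eqd2_tot))`, from a
#' [synthetic_truth()] on a given dose design. Used for parameter-recovery
#' experiments on the outcome model.
#'
#' @param truth A [synthetic_truth()].
#' @param dose_table A dose table ([build_dose_table()]) or any data.frame
#'   with columns `study_id` and `eqd2_tot`.
#' @param n_per_arm Arm sizes (positive; recycled if scalar).
#' @param seed Optional seed overriding `truth$seed` (used to vary
#'   replicates in simulation loops).
#'
#' @return An arm-level outcome data.frame (`study_id`, `eqd2_tot`,
#'   `events`, `n`) suitable for [fit_logistic()], with attribute
#'   `"endpoint"` set to `"os_2y"` pro forma.
#' @examples
#' tab <- build_dose_table(ra223_cohort(), dose_scenario(8, 1))
#' truth <- synthetic_truth(-1.364, 0.006, seed = 3)
#' simulate_cohort_outcomes(truth, tab, tab$n_patients)
#' @export
simulate_cohort_outcomes <- function(truth, dose_table, n_per_arm,
                                     seed = NULL) {
  if (!inherits(truth, "synthetic_truth"))
    stop("'truth' must be a 'synthetic_truth' object")
  stopifnot(all(is.finite(dose_table$eqd2_tot)), all(n_per_arm > 0))
  n <- rep_len(as.integer(n_per_arm), nrow(dose_table))
  p <- stats::plogis(truth$intercept + truth$slope * dose_table$eqd2_tot)
  events <- with_seed(seed %||% truth$seed,
                      stats::rbinom(length(p), n, p))
  out <- data.frame(study_id = dose_table$study_id,
                    eqd2_tot = dose_table$eqd2_tot,
                    events = events, n = n, stringsAsFactors = FALSE)
  attr(out, "endpoint") <- "os_2y"
  out
}
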