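#' Arm-level summaries of the pooled Ra-223 trials
#'
#' `ra223_study_arms()` loads the packaged arm table: one row per treatment
#' subgroup of the four randomized Ra-223 trials in metastatic
#' castration-resistant prostate cancer, with patient counts, injected
#' activity, number of cycles, the fraction also receiving EBRT, and the
#' two outcome summaries (two-year overall survival and grade >=2
#' neutropenia). `ra223_printed_eqd2_rn()` loads the published per-arm EQD2
#' of the radionuclide component, and `ra223_cohort()` returns the arm
#' table with that `eqd2_rn_gy` column merged in.
#'
#' @param path Path to a CSV in the same dialect; defaults to the packaged
#'   fixture.
#'
#' @return A data.frame of study arms (see the column comments in the
#'   packaged CSV), validated by `validate_study_arms()`.
#' @examples
#' arms <- ra223_study_arms()
#' nrow(arms)  # 8 arms across 4 studies
#' @export
ra223_study_arms <- function(path = system.file("extdata", "study_arms.csv",
                                                package = "radcomb")) {
  arms <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  validate_study_arms(arms)
  arms
}

#' @rdname ra223_study_arms
#' @export
ra223_printed_eqd2_rn <- function(path = system.file("extdata",
                                                     "arm_eqd2_rn.csv",
                                                     package = "radcomb")) {
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' @rdname ra223_study_arms
#' @export
ra223_cohort <- function() {
  merge(ra223_study_arms(), ra223_printed_eqd2_rn()[, c(
    "study_id", "activity_kbq_kg", "eqd2_rn_gy")],
    by = c("study_id", "activity_kbq_kg"), sort = FALSE)
}

#' @param arms A data.frame of study arms.
#' @rdname ra223_study_arms
#' @export
validate_study_arms <- function(arms) {
  if (!is.data.frame(arms) || nrow(arms) == 0)
    stop("study-arm table must be a non-empty data.frame")
  required <- c("study_id", "n_patients", "activity_kbq_kg", "mbq_per_cycle",
                "n_cycles", "f_ebrt_pct", "f_ebrt_n", "os2y_pct", "os2y_n",
                "tox_pct", "tox_n", "os_extraction")
  missing <- setdiff(required, names(arms))
  if (length(missing) > 0)
    stop("study-arm table lacks column(s): ", paste(missing, collapse = ", "))
  if (any(arms$f_ebrt_pct < 0 | arms$f_ebrt_pct > 100))
    stop("'f_ebrt_pct' must lie in [0, 100]")
  if (any(arms$f_ebrt_n > arms$n_patients))
    stop("EBRT counts exceed arm size")
  if (any(arms$os2y_n > arms$n_patients, na.rm = TRUE) ||
      any(arms$tox_n > arms$n_patients, na.rm = TRUE))
    stop("outcome event counts exceed arm size")
  if (any(arms$activity_kbq_kg == 0 & arms$mbq_per_cycle != 0))
    stop("placebo arms must have mbq_per_cycle = 0")
  if (!all(arms$os_extraction %in% c("text", "kaplan_meier")))
    stop("'os_extraction' must be 'text' or 'kaplan_meier'")
  invisible(arms)
}

#' Injected activity per cycle from weight-based prescription
#'
#' Ra-223 is prescribed per kg of body weight; the activity per cycle in
#' MBq is `activity_per_kg * reference_weight / 1000`. When the trial
#' printed an explicit MBq/cycle for the arm, that printed value takes
#' precedence (trials used their own cohort weights: 55 kBq/kg with a
#' printed 4.125 MBq/cycle implies 75 kg, not the 70 kg default).
#' Vectorised.
#'
#' @param activity_per_kg Prescribed activity, kBq per kg (>= 0).
#' @param reference_weight Reference patient weight in kg (default 70).
#' @param printed_mbq Optional printed MBq/cycle; non-`NA` entries override
#'   the computed value.
#'
#' @return Injected activity per cycle in MBq.
#' @examples
#' injected_activity_per_cycle(50, 70)  # 3.5 MBq
#' @export
injected_activity_per_cycle <- function(activity_per_kg,
                                        reference_weight = 70,
                                        printed_mbq = NULL) {
  if (any(activity_per_kg < 0) || any(reference_weight < 0))
    stop("activity and weight must be non-negative")
  computed <- activity_per_kg * reference_weight / 1000
  if (is.null(printed_mbq)) return(computed)
  ifelse(is.na(printed_mbq), computed, printed_mbq)
}

#' Calibrate an effective activity-to-EQD2 map for the Ra-223 component
#'
#' The per-nuclide dose coefficients and effective decay constant behind
#' the published per-arm EQD2 values are not themselves published, so the
#' activity dependence is re-parameterised effectively: per-cycle
#' \deqn{EQD2_{RN}(A)/n_c = c_1 A + c_2 A^2} with `A` in kBq/kg. This is
#' the same linear-plus-quadratic structure the mixture BED has in total
#' dose. Two distinct activities determine (c1, c2) exactly; three or more
#' are fitted by least squares. Placebo (zero-activity) arms are ignored.
#'
#' @param arms A data.frame with columns `activity_kbq_kg`, `n_cycles` and
#'   `eqd2_rn_gy` (one row per calibration arm), e.g. a subset of
#'   [ra223_printed_eqd2_rn()].
#'
#' @return An object of class `"rn_calibration"` with fields `c1`
#'   (Gy per kBq/kg per cycle), `c2` (Gy per (kBq/kg)^2 per cycle) and
#'   `source_arms`.
#' @examples
#' cal <- calibrate_rn_model(ra223_printed_eqd2_rn()[3:4, ])
#' predict(cal, activity_kbq_kg = 80, n_cycles = 3)
#' @export
calibrate_rn_model <- function(arms) {
  stopifnot(is.data.frame(arms),
            all(c("activity_kbq_kg", "n_cycles", "eqd2_rn_gy") %in%
                  names(arms)))
  arms <- arms[arms$activity_kbq_kg > 0, , drop = FALSE]
  a <- arms$activity_kbq_kg
  if (length(unique(a)) < 2)
    stop("calibration needs >= 2 distinct nonzero activities; got ",
         length(unique(a)))
  y <- arms$eqd2_rn_gy / arms$n_cycles
  if (length(a) == 2) {
    coefs <- solve(cbind(a, a^2), y)
  } else {
    coefs <- stats::coef(stats::lm(y ~ 0 + a + I(a^2)))
  }
  structure(list(c1 = unname(coefs[1]), c2 = unname(coefs[2]),
                 source_arms = arms),
            class = "rn_calibration")
}

#' @export
print.rn_calibration <- function(x, ...) {
  cat("Effective Ra-223 activity -> EQD2 calibration (per cycle)\n")
  cat(sprintf("  EQD2/cycle = %.6g * A + %.6g * A^2   [A in kBq/kg]\n",
              x$c1, x$c2))
  cat(sprintf("  calibrated on %d arm(s)\n", nrow(x$source_arms)))
  invisible(x)
}

#' Predict per-arm EQD2 of the Ra-223 component from a calibration
#'
#' @param object An [calibrate_rn_model()] result.
#' @param activity_kbq_kg Activity in kBq/kg (vectorised).
#' @param n_cycles Number of cycles (vectorised or scalar).
#' @param ... Unused.
#' @return Predicted EQD2 in Gy.
#' @export
predict.rn_calibration <- function(object, activity_kbq_kg, n_cycles = 1,
                                   ...) {
  (object$c1 * activity_kbq_kg + object$c2 * activity_kbq_kg^2) * n_cycles
}

#' An EBRT scenario: one schedule applied uniformly to a cohort
#'
#' Couples an [ebrt_schedule()] with its precomputed BED and EQD2 under a
#' given parameter set. `default_scenarios()` returns the three scenarios
#' used for the pooled-cohort dose tables: 8 Gy in 1 fraction, 20 Gy in 5
#' fractions, and 30 Gy in 10 fractions.
#'
#' @param total_dose,n_fractions,label Passed to [ebrt_schedule()].
#' @inheritParams bed_ebrt
#'
#' @return An object of class `"dose_scenario"` with fields `schedule`,
#'   `bed_ebrt` and `eqd2_ebrt` (both Gy).
#' @examples
#' dose_scenario(8, 1)  # EQD2_EBRT = 12 Gy
#' @export
dose_scenario <- function(total_dose, n_fractions, label = NULL,
                          params = lq_params()) {
  schedule <- ebrt_schedule(total_dose, n_fractions, label)
  bed <- bed_ebrt(schedule, params)
  structure(list(schedule = schedule, bed_ebrt = bed,
                 eqd2_ebrt = eqd2_from_bed(bed, params)),
            class = "dose_scenario")
}

#' @rdname dose_scenario
#' @export
default_scenarios <- function(params = lq_params()) {
  list(`8Gy_1fr` = dose_scenario(8, 1, params = params),
       `20Gy_5fr` = dose_scenario(20, 5, params = params),
       `30Gy_10fr` = dose_scenario(30, 10, params = params))
}

#' @export
print.dose_scenario <- function(x, ...) {
  cat(sprintf("EBRT scenario %s: BED = %.1f Gy, EQD2 = %.1f Gy\n",
              x$schedule$label, x$bed_ebrt, x$eqd2_ebrt))
  invisible(x)
}

#' Population-level total EQD2 of combined Ra-223 + EBRT treatment
#'
#' The arm-level total equieffective dose is the radionuclide component
#' plus the EBRT component weighted by the fraction `f` of the arm's
#' patients who also received EBRT:
#' \deqn{EQD2_{TOT} = EQD2_{RN} + f \cdot EQD2_{EBRT}.}
#' Vectorised.
#'
#' @param eqd2_rn EQD2 of the Ra-223 component, Gy (>= 0).
#' @param f_ebrt Fraction of patients receiving EBRT, in \[0, 1\].
#' @param eqd2_ebrt EQD2 of the EBRT schedule, Gy (>= 0).
#'
#' @return Total EQD2 in Gy.
#' @examples
#' eqd2_tot(34.2, 0.29, 12)  # 37.68 Gy
#' @export
eqd2_tot <- function(eqd2_rn, f_ebrt, eqd2_ebrt) {
  if (any(f_ebrt < 0 | f_ebrt > 1))
    stop("'f_ebrt' must lie in [0, 1]")
  if (any(eqd2_rn < 0) || any(eqd2_ebrt < 0))
    stop("doses must be non-negative")
  eqd2_rn + f_ebrt * eqd2_ebrt
}

#' Build the per-arm dose table for one EBRT scenario
#'
#' Computes, for every study arm, the EQD2 of the Ra-223 component, the
#' population-weighted EBRT component `f * EQD2_EBRT`, and their total
#' [eqd2_tot()]. The Ra-223 component can come from three sources:
#' a numeric vector of published per-arm EQD2 values (the default workflow,
#' via `arms$eqd2_rn_gy` or the `rn_dose` argument), an
#' [calibrate_rn_model()] calibration, or a full mechanistic
#' [rn_dose_model()] template whose injected activity and cycle count are
#' filled in per arm.
#'
#' The EBRT weight `f` defaults to the printed percentage
#' (`f_ebrt_pct / 100`); `f_source = "count"` uses `f_ebrt_n / n_patients`
#' instead. The published one-decimal tables are reproduced with the
#' percentage convention.
#'
#' @param arms Study-arm data.frame (see [ra223_study_arms()]); may carry
#'   an `eqd2_rn_gy` column.
#' @param scenario A [dose_scenario()].
#' @param rn_dose Per-arm EQD2_RN source: numeric vector (Gy, one per arm),
#'   an `rn_calibration`, an `rn_dose_model` template, or `NULL` to use
#'   `arms$eqd2_rn_gy`.
#' @param f_source `"percent"` (default) or `"count"`.
#'
#' @return A data.frame with one row per arm: `study_id`,
#'   `activity_kbq_kg`, `n_patients`, `f_ebrt`, `eqd2_rn`,
#'   `eqd2_ebrt_weighted`, `eqd2_tot` (all doses unrounded, Gy) and the
#'   scenario label as attribute `"scenario"`. Use [format_dose_table()]
#'   for the one-decimal report form.
#' @examples
#' tab <- build_dose_table(ra223_cohort(), dose_scenario(8, 1))
#' format_dose_table(tab)
#' @export
build_dose_table <- function(arms, scenario, rn_dose = NULL,
                             f_source = c("percent", "count")) {
  validate_study_arms(arms)
  if (!inherits(scenario, "dose_scenario"))
    stop("'scenario' must be a 'dose_scenario' object")
  f_source <- match.arg(f_source)

  rn <- resolve_rn_dose(arms, rn_dose)
  f <- if (f_source == "percent") arms$f_ebrt_pct / 100
       else arms$f_ebrt_n / arms$n_patients
  weighted <- f * scenario$eqd2_ebrt
  out <- data.frame(study_id = arms$study_id,
                    activity_kbq_kg = arms$activity_kbq_kg,
                    n_patients = arms$n_patients,
                    f_ebrt = f,
                    eqd2_rn = rn,
                    eqd2_ebrt_weighted = weighted,
                    eqd2_tot = eqd2_tot(rn, f, scenario$eqd2_ebrt),
                    stringsAsFactors = FALSE)
  attr(out, "scenario") <- scenario$schedule$label
  attr(out, "eqd2_ebrt") <- scenario$eqd2_ebrt
  out
}

resolve_rn_dose <- function(arms, rn_dose) {
  if (is.null(rn_dose)) {
    if (!"eqd2_rn_gy" %in% names(arms))
      stop("no Ra-223 dose source: supply 'rn_dose' or an 'eqd2_rn_gy' ",
           "column (see ra223_cohort())")
    rn <- arms$eqd2_rn_gy
  } else if (is.numeric(rn_dose)) {
    if (length(rn_dose) != nrow(arms))
      stop("'rn_dose' must have one EQD2 value per arm")
    rn <- rn_dose
  } else if (inherits(rn_dose, "rn_calibration")) {
    rn <- predict(rn_dose, arms$activity_kbq_kg, arms$n_cycles)
  } else if (inherits(rn_dose, "rn_dose_model")) {
    rn <- vapply(seq_len(nrow(arms)), function(i) {
      if (arms$mbq_per_cycle[i] == 0) return(0)
      m <- rn_dose_model(rn_dose$dose_coefficients,
                         injected_activity = arms$mbq_per_cycle[i],
                         n_cycles = arms$n_cycles[i],
                         decay_constant = rn_dose$decay_constant,
                         chain = rn_dose$chain)
      eqd2_rn(m)
    }, numeric(1))
  } else {
    stop("'rn_dose' must be numeric, an 'rn_calibration' or an ",
         "'rn_dose_model'")
  }
  if (any(is.na(rn) & arms$activity_kbq_kg > 0))
    stop("missing Ra-223 dose for arm(s) with nonzero activity")
  rn[arms$activity_kbq_kg == 0] <- 0
  rn
}

#' One-decimal report form of a dose table
#'
#' Applies report-time rounding ([round_half_up()], one decimal) to the
#' dose columns, mirroring the published table layout. Internal
#' computations remain full precision.
#'
#' @param dose_table Output of [build_dose_table()].
#' @return A data.frame with `f_ebrt` as a percentage and doses rounded to
#'   one decimal.
#' @export
format_dose_table <- function(dose_table) {
  out <- dose_table
  out$f_ebrt_pct <- round_half_up(100 * out$f_ebrt, 0)
  out$f_ebrt <- NULL
  for (col in c("eqd2_rn", "eqd2_ebrt_weighted", "eqd2_tot"))
    out[[col]] <- round_half_up(out[[col]], 1)
  out[, c("study_id", "activity_kbq_kg", "n_patients", "f_ebrt_pct",
          "eqd2_rn", "eqd2_ebrt_weighted", "eqd2_tot")]
}
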