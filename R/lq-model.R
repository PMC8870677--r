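#' Radiobiological parameter set for BED/EQD2 calculations
#'
#' Bundles the linear-quadratic (LQ) model constants used throughout the
#' package: the fractionation-sensitivity ratio \eqn{\alpha/\beta}, the
#' first-order sublethal-damage repair rate \eqn{\mu}, the experimental
#' relative biological effectiveness of alpha particles, the RBE assigned to
#' photon/electron emissions, and the reference dose per fraction used for
#' EQD2 conversion.
#'
#' @param alpha_beta \eqn{\alpha/\beta} ratio in Gy (default 10, the
#'   conventional value for tumours and acute effects).
#' @param mu Sublethal-damage repair rate constant in h^-1 (default 1.4).
#' @param rbe_exp Experimental RBE of alpha particles, dimensionless
#'   (default 5).
#' @param rbe_photon RBE assigned to gamma/beta emissions (default 1).
#' @param d_ref Reference dose per fraction in Gy used for EQD2 (default 2).
#'
#' @return An object of class `"lq_params"`: a named list with the five
#'   fields above.
#' @examples
#' p <- lq_params()
#' rbe_max(p)
#' @export
lq_params <- function(alpha_beta = 10, mu = 1.4, rbe_exp = 5,
                      rbe_photon = 1, d_ref = 2) {
  stopifnot(is.numeric(alpha_beta), length(alpha_beta) == 1L,
            is.numeric(mu), length(mu) == 1L,
            is.numeric(rbe_exp), length(rbe_exp) == 1L,
            is.numeric(rbe_photon), length(rbe_photon) == 1L,
            is.numeric(d_ref), length(d_ref) == 1L)
  if (!is.finite(alpha_beta) || alpha_beta <= 0)
    stop("'alpha_beta' must be a positive, finite dose ratio in Gy")
  if (!is.finite(mu) || mu <= 0)
    stop("'mu' must be a positive repair rate in h^-1")
  if (!is.finite(rbe_exp) || rbe_exp < 1)
    stop("'rbe_exp' must be >= 1")
  if (!is.finite(rbe_photon) || rbe_photon <= 0)
    stop("'rbe_photon' must be positive")
  if (!is.finite(d_ref) || d_ref <= 0)
    stop("'d_ref' must be a positive reference dose per fraction in Gy")
  structure(list(alpha_beta = alpha_beta, mu = mu, rbe_exp = rbe_exp,
                 rbe_photon = rbe_photon, d_ref = d_ref),
            class = "lq_params")
}

#' @export
print.lq_params <- function(x, ...) {
  cat("LQ radiobiological parameters\n")
  cat(sprintf("  alpha/beta : %g Gy\n", x$alpha_beta))
  cat(sprintf("  mu         : %g h^-1\n", x$mu))
  cat(sprintf("  RBE_exp    : %g (alpha)\n", x$rbe_exp))
  cat(sprintf("  RBE_photon : %g (gamma/beta)\n", x$rbe_photon))
  cat(sprintf("  d_ref      : %g Gy/fraction\n", x$d_ref))
  invisible(x)
}

as_lq_params <- function(params) {
  if (inherits(params, "lq_params")) return(params)
  if (is.list(params)) return(do.call(lq_params, params))
  stop("'params' must be an 'lq_params' object (see lq_params())")
}

#' External-beam radiotherapy schedule
#'
#' A fractionated EBRT prescription: total dose `D` delivered in
#' `n_fractions` equal fractions of `D / n_fractions` Gy each.
#'
#' @param total_dose Total prescribed dose in Gy (>= 0).
#' @param n_fractions Number of fractions (integer >= 1).
#' @param label Optional free-text label, e.g. `"8 Gy in 1 fr"`.
#'
#' @return An object of class `"ebrt_schedule"` with fields `total_dose`,
#'   `n_fractions`, `dose_per_fraction` and `label`.
#' @examples
#' ebrt_schedule(30, 10)
#' @export
ebrt_schedule <- function(total_dose, n_fractions, label = NULL) {
  stopifnot(is.numeric(total_dose), length(total_dose) == 1L,
            is.numeric(n_fractions), length(n_fractions) == 1L)
  if (!is.finite(total_dose) || total_dose < 0)
    stop("'total_dose' must be a non-negative dose in Gy")
  if (!is.finite(n_fractions) || n_fractions < 1 ||
      n_fractions != round(n_fractions))
    stop("'n_fractions' must be an integer >= 1")
  if (is.null(label))
    label <- sprintf("%g Gy in %d fr", total_dose, as.integer(n_fractions))
  structure(list(total_dose = total_dose,
                 n_fractions = as.integer(n_fractions),
                 dose_per_fraction = total_dose / n_fractions,
                 label = label),
            class = "ebrt_schedule")
}

#' @export
print.ebrt_schedule <- function(x, ...) {
  cat(sprintf("EBRT schedule: %s (%g Gy/fr)\n", x$label, x$dose_per_fraction))
  invisible(x)
}

#' Biologically effective dose of a fractionated EBRT schedule
#'
#' LQ-model BED of a low-LET fractionated schedule:
#' \deqn{BED = D \left[1 + \frac{D/n_f}{\alpha/\beta}\right]}
#' where `D` is the total dose and `n_f` the number of fractions.
#'
#' @param schedule An [ebrt_schedule()].
#' @param params An [lq_params()] parameter set.
#'
#' @return BED in Gy (always >= the physical dose).
#' @examples
#' bed_ebrt(ebrt_schedule(8, 1))    # 14.4 Gy
#' bed_ebrt(ebrt_schedule(30, 10))  # 39.0 Gy
#' @export
bed_ebrt <- function(schedule, params = lq_params()) {
  if (!inherits(schedule, "ebrt_schedule"))
    stop("'schedule' must be an 'ebrt_schedule' object")
  params <- as_lq_params(params)
  D <- schedule$total_dose
  D * (1 + schedule$dose_per_fraction / params$alpha_beta)
}

#' Convert a BED to its 2 Gy-per-fraction equieffective dose
#'
#' \deqn{EQD2 = \frac{BED}{1 + d_{ref}/(\alpha/\beta)}}
#' With the defaults (\eqn{\alpha/\beta} = 10 Gy, d_ref = 2 Gy) the divisor
#' is 1.2. Vectorised over `bed`.
#'
#' @param bed Biologically effective dose(s) in Gy (>= 0).
#' @inheritParams bed_ebrt
#'
#' @return EQD2 in Gy, same length as `bed`.
#' @examples
#' eqd2_from_bed(14.4)  # 12
#' @export
eqd2_from_bed <- function(bed, params = lq_params()) {
  params <- as_lq_params(params)
  if (!is.numeric(bed) || any(!is.finite(bed)) || any(bed < 0))
    stop("'bed' must be non-negative and finite (Gy)")
  bed / (1 + params$d_ref / params$alpha_beta)
}

#' Maximum RBE used to weight the alpha-dose linear term
#'
#' Low-dose-limit RBE for high-LET alpha irradiation relative to a
#' fractionated low-LET reference delivering `d_ref` Gy per fraction:
#' \deqn{RBE_{max} = RBE_{exp} + \frac{d_{ref}}{\alpha/\beta}\,
#'   \frac{RBE_{exp}^2 - 1}{RBE_{exp}}}
#' With the package defaults (RBE_exp = 5, d_ref = 2 Gy,
#' \eqn{\alpha/\beta} = 10 Gy) this evaluates to 5.96.
#'
#' @inheritParams bed_ebrt
#'
#' @return Dimensionless RBE_max (>= `rbe_exp`).
#' @examples
#' rbe_max(lq_params())  # 5.96
#' @export
rbe_max <- function(params = lq_params()) {
  params <- as_lq_params(params)
  if (params$rbe_exp <= 0)
    stop("'rbe_exp' must be positive")
  r <- params$rbe_exp
  r + params$d_ref / params$alpha_beta * (r^2 - 1) / r
}

#' Initial dose rate of one decay-chain nuclide
#'
#' For a nuclide with mean absorbed dose per injected activity `D_i`
#' (mGy/MBq) and a mono-exponential effective washout at rate `lambda`
#' (h^-1) after injecting `A_inj` MBq, the dose rate at time zero is
#' \deqn{R_i = D_i \cdot A_{inj} \cdot \lambda \quad [\mathrm{mGy/h}].}
#' Vectorised over all arguments.
#'
#' @param dose_coefficient Mean absorbed dose per injected activity,
#'   mGy/MBq (>= 0).
#' @param injected_activity Injected activity in MBq (>= 0).
#' @param decay_constant Effective decay rate in h^-1 (>= 0).
#'
#' @return Initial dose rate in mGy/h.
#' @export
dose_rate <- function(dose_coefficient, injected_activity, decay_constant) {
  if (!is.numeric(dose_coefficient) || any(dose_coefficient < 0) ||
      !is.numeric(injected_activity) || any(injected_activity < 0) ||
      !is.numeric(decay_constant) || any(decay_constant < 0))
    stop("all arguments must be non-negative")
  dose_coefficient * injected_activity * decay_constant
}

#' Effective decay constant of Ra-223
#'
#' Physical decay rate of Ra-223 (half-life 11.43 d) expressed in h^-1,
#' used as the default effective decay constant when no patient-specific
#' washout is supplied. `half_life_to_rate()` and `rate_to_half_life()`
#' convert between a half-life in hours and a rate constant.
#'
#' @return Decay rate in h^-1 (about 0.002527).
#' @examples
#' rate_to_half_life(ra223_lambda()) / 24  # 11.43 days
#' @export
ra223_lambda <- function() log(2) / (11.43 * 24)

#' @param half_life Half-life in hours (> 0).
#' @rdname ra223_lambda
#' @export
half_life_to_rate <- function(half_life) {
  stopifnot(is.numeric(half_life), all(half_life > 0))
  log(2) / half_life
}

#' @param rate Decay rate in h^-1 (> 0).
#' @rdname ra223_lambda
#' @export
rate_to_half_life <- function(rate) {
  stopifnot(is.numeric(rate), all(rate > 0))
  log(2) / rate
}

#' Radionuclide therapy dose model for the Ra-223 decay chain
#'
#' Describes one course of Ra-223 therapy: per-nuclide mean absorbed dose
#' coefficients (mGy/MBq, from e.g. a spherical-model dosimetry code), a
#' single effective decay constant shared by the parent and all daughters
#' (secular equilibrium), the injected activity per cycle, and the number
#' of cycles.
#'
#' @param dose_coefficients Named numeric vector: nuclide name ->
#'   mean absorbed dose per injected activity, mGy/MBq (all >= 0). Names
#'   must be a subset of the nuclides in `chain`.
#' @param injected_activity Injected activity per cycle, MBq (>= 0).
#' @param n_cycles Number of treatment cycles (integer >= 0).
#' @param decay_constant Effective decay rate in h^-1 (> 0); defaults to
#'   the Ra-223 physical constant [ra223_lambda()].
#' @param chain A [decay_chain] object; defaults to [ra223_chain()].
#'
#' @return An object of class `"rn_dose_model"`.
#' @examples
#' m <- rn_dose_model(c("Ra-223" = 200, "Rn-219" = 150),
#'                    injected_activity = 3.5, n_cycles = 6)
#' bed_rn(m)
#' @export
rn_dose_model <- function(dose_coefficients, injected_activity,
                          n_cycles = 1, decay_constant = ra223_lambda(),
                          chain = ra223_chain()) {
  if (!inherits(chain, "decay_chain"))
    stop("'chain' must be a 'decay_chain' object")
  if (!is.numeric(dose_coefficients) ||
      (length(dose_coefficients) > 0 && is.null(names(dose_coefficients))))
    stop("'dose_coefficients' must be a named numeric vector (nuclide -> mGy/MBq)")
  if (any(dose_coefficients < 0))
    stop("dose coefficients must be non-negative")
  unknown <- setdiff(names(dose_coefficients), chain$nuclides$name)
  if (length(unknown) > 0)
    stop("dose coefficient(s) for nuclide(s) not in the decay chain: ",
         paste(unknown, collapse = ", "))
  if (!is.numeric(decay_constant) || length(decay_constant) != 1L ||
      !is.finite(decay_constant) || decay_constant <= 0)
    stop("'decay_constant' must be a positive rate in h^-1")
  if (!is.numeric(injected_activity) || length(injected_activity) != 1L ||
      injected_activity < 0)
    stop("'injected_activity' must be >= 0 MBq")
  if (!is.numeric(n_cycles) || length(n_cycles) != 1L || n_cycles < 0 ||
      n_cycles != round(n_cycles))
    stop("'n_cycles' must be a non-negative integer")
  structure(list(dose_coefficients = dose_coefficients,
                 injected_activity = injected_activity,
                 n_cycles = as.integer(n_cycles),
                 decay_constant = decay_constant,
                 chain = chain),
            class = "rn_dose_model")
}

#' @export
print.rn_dose_model <- function(x, ...) {
  cat("Radionuclide dose model (Ra-223 chain, secular equilibrium)\n")
  cat(sprintf("  nuclides with coefficients: %d\n", length(x$dose_coefficients)))
  cat(sprintf("  injected activity : %g MBq/cycle x %d cycle(s)\n",
              x$injected_activity, x$n_cycles))
  cat(sprintf("  effective lambda  : %g h^-1 (T_eff = %.1f h)\n",
              x$decay_constant, rate_to_half_life(x$decay_constant)))
  invisible(x)
}

#' BED of a continuously decaying alpha-emitter mixture
#'
#' Permanent-implant LQ BED for the exponentially decaying dose rate of the
#' Ra-223 decay-chain mixture. With per-nuclide initial dose rates
#' \eqn{R_i = D_i A_{inj} \lambda} the model is
#' \deqn{BED_{RN} = n_c \frac{\sum_i R_i}{\lambda}\left\{RBE_{max} +
#'   \frac{\sum_i\sum_j R_i R_j}{(\alpha/\beta)(\mu+\lambda)\sum_i R_i}
#'   \right\}}
#' where the Cartesian double sum over the chain equals
#' \eqn{(\sum_i R_i)^2}, so that with total physical dose per cycle
#' \eqn{D_{tot} = \sum_i D_i A_{inj}} the expression reduces to the closed
#' form \eqn{n_c [RBE_{max} D_{tot} + \lambda D_{tot}^2 /
#' ((\alpha/\beta)(\mu+\lambda))]}. Both evaluation routes are implemented;
#' they agree to machine precision and `method` selects one explicitly.
#'
#' Dose coefficients are in mGy/MBq; the result is converted to Gy.
#'
#' @param model An [rn_dose_model()].
#' @inheritParams bed_ebrt
#' @param method `"closed_form"` (default) or `"double_sum"` (explicit
#'   nested loop over nuclide pairs).
#' @param emission_weighted If `TRUE`, the linear term weights each
#'   nuclide's contribution by RBE_max for alpha emitters and by
#'   `rbe_photon` for beta/gamma emitters, using the chain's emission
#'   metadata. The default `FALSE` applies the single global RBE_max to the
#'   whole mixture.
#'
#' @return BED in Gy, linear in the number of cycles.
#' @examples
#' m <- rn_dose_model(c("Ra-223" = 100), injected_activity = 10, n_cycles = 1)
#' bed_rn(m)  # 1 Gy physical dose, RBE-weighted plus quadratic repair term
#' @export
bed_rn <- function(model, params = lq_params(),
                   method = c("closed_form", "double_sum"),
                   emission_weighted = FALSE) {
  if (!inherits(model, "rn_dose_model"))
    stop("'model' must be an 'rn_dose_model' object")
  params <- as_lq_params(params)
  method <- match.arg(method)

  dc <- model$dose_coefficients
  if (length(dc) == 0 || sum(dc) == 0 || model$injected_activity == 0 ||
      model$n_cycles == 0) {
    if (model$n_cycles > 0 && length(dc) == 0)
      warning("empty decay chain coefficients: BED_RN is 0")
    return(0)
  }

  lam <- model$decay_constant
  ab <- params$alpha_beta
  mu <- params$mu
  rmax <- rbe_max(params)

  ## per-nuclide physical dose per cycle, converted mGy -> Gy
  d_gy <- dc * model$injected_activity / 1000
  d_tot <- sum(d_gy)

  if (emission_weighted) {
    emis <- model$chain$nuclides$primary_emission[
      match(names(dc), model$chain$nuclides$name)]
    w <- ifelse(emis == "alpha", rmax, params$rbe_photon)
    linear <- sum(w * d_gy)
  } else {
    linear <- rmax * d_tot
  }

  if (method == "closed_form") {
    quad <- lam * d_tot^2 / (ab * (mu + lam))
    return(unname(model$n_cycles * (linear + quad)))
  }

  ## explicit Eq.-style route: initial dose rates in Gy/h, nested double sum
  r <- d_gy * lam
  s <- sum(r)
  ss <- 0
  for (i in seq_along(r)) for (j in seq_along(r)) ss <- ss + r[i] * r[j]
  brace <- if (emission_weighted) {
    linear / d_tot + ss / (ab * (mu + lam) * s)
  } else {
    rmax + ss / (ab * (mu + lam) * s)
  }
  unname(model$n_cycles * (s / lam) * brace)
}

#' EQD2 of the radionuclide mixture
#'
#' Composition [eqd2_from_bed()] of [bed_rn()]: the 2 Gy-per-fraction
#' equieffective dose of the Ra-223 decay-chain mixture.
#'
#' @inheritParams bed_rn
#' @return EQD2 in Gy.
#' @export
eqd2_rn <- function(model, params = lq_params(),
                    method = c("closed_form", "double_sum"),
                    emission_weighted = FALSE) {
  eqd2_from_bed(bed_rn(model, params, method, emission_weighted), params)
}

#' Mono-exponential residence time
#'
#' Time-integrated activity in a source region per unit injected activity
#' under single-phase kinetics: a fraction `uptake_fraction` of the
#' injected activity is taken up instantaneously and clears at the
#' effective rate `decay_constant`, giving
#' \eqn{\tau = u / \lambda} hours.
#'
#' @param uptake_fraction Fraction of injected activity in the region
#'   (in \[0, 1\]).
#' @param decay_constant Effective clearance rate in h^-1 (> 0).
#'
#' @return Residence time in hours.
#' @examples
#' residence_time(1, ra223_lambda())  # T_phys / ln 2
#' @export
residence_time <- function(uptake_fraction, decay_constant) {
  if (!is.numeric(uptake_fraction) || any(uptake_fraction < 0) ||
      any(uptake_fraction > 1))
    stop("'uptake_fraction' must lie in [0, 1]")
  if (!is.numeric(decay_constant) || any(decay_constant <= 0))
    stop("'decay_constant' must be positive (h^-1)")
  uptake_fraction / decay_constant
}

#' Round half away from zero
#'
#' Report-time rounding used when reproducing printed one-decimal tables:
#' exact halves round away from zero (so 5.25 -> 5.3 at one decimal),
#' unlike [round()]'s round-half-even. Internal computation is never
#' rounded; this is applied only when formatting output.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places (default 1).
#' @return `x` rounded to `digits` decimals.
#' @export
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
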