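#' The Ra-223 decay chain
#'
#' Registry of the seven nuclides contributing dose in Ra-223 therapy, in
#' decay order, with each nuclide's primary emission. Ra-223 decays through
#' Rn-219, Po-215, Pb-211, Bi-211 and (via the minor beta branch of Bi-211)
#' Po-211 or (main branch) Tl-207 to stable Pb-207. The beta branch of
#' Po-215 (branching ratio below 0.001%) is omitted and its decay treated
#' as pure alpha to Pb-211; the omission is recorded in
#' `omitted_branches`.
#'
#' All daughters are assumed in secular equilibrium with the parent: a
#' single effective decay constant and residence time apply to the whole
#' chain, so no Bateman solver is needed. Emission metadata is used only
#' for optional per-emission RBE weighting in [bed_rn()].
#'
#' @return An object of class `"decay_chain"`: a list with
#'   `nuclides` (data.frame: `name`, `primary_emission`, `notes`) and
#'   `omitted_branches` (data.frame: `parent`, `mode`, `reason`).
#' @examples
#' ra223_chain()
#' @export
ra223_chain <- function() {
  nuclides <- data.frame(
    name = c("Ra-223", "Rn-219", "Po-215", "Pb-211", "Bi-211", "Po-211",
             "Tl-207"),
    primary_emission = c("alpha", "alpha", "alpha", "beta", "alpha",
                         "alpha", "beta"),
    notes = c("parent, T1/2 = 11.43 d",
              "T1/2 = 3.96 s",
              "T1/2 = 1.78 ms; beta branch omitted",
              "T1/2 = 36.1 min",
              "T1/2 = 2.14 min; 99.7% alpha to Tl-207",
              "minor branch via Bi-211 beta decay (0.28%)",
              "T1/2 = 4.77 min; beta to stable Pb-207"),
    stringsAsFactors = FALSE
  )
  omitted <- data.frame(
    parent = "Po-215",
    mode = "beta",
    reason = "branching ratio < 0.001%; treated as pure alpha decay to Pb-211",
    stringsAsFactors = FALSE
  )
  structure(list(nuclides = nuclides, omitted_branches = omitted),
            class = "decay_chain")
}

#' @export
print.decay_chain <- function(x, ...) {
  cat(sprintf("Decay chain with %d nuclides:\n", nrow(x$nuclides)))
  for (i in seq_len(nrow(x$nuclides)))
    cat(sprintf("  %-7s (%s) %s\n", x$nuclides$name[i],
                x$nuclides$primary_emission[i], x$nuclides$notes[i]))
  if (nrow(x$omitted_branches) > 0) {
    cat("Omitted branches:\n")
    for (i in seq_len(nrow(x$omitted_branches)))
      cat(sprintf("  %s (%s): %s\n", x$omitted_branches$parent[i],
                  x$omitted_branches$mode[i], x$omitted_branches$reason[i]))
  }
  invisible(x)
}

#' Total initial dose rate of a decay-chain mixture
#'
#' Sums the per-nuclide initial dose rates [dose_rate()] over the chain
#' under the secular-equilibrium assumption (one shared decay constant).
#' Nuclides without a supplied coefficient contribute zero.
#'
#' @param chain A [ra223_chain()]-style `decay_chain` object.
#' @param coefficients Named numeric vector: nuclide -> mean absorbed dose
#'   per injected activity, mGy/MBq. Names must be a subset of the chain.
#' @param injected_activity Injected activity in MBq (>= 0).
#' @param decay_constant Effective decay rate in h^-1 (>= 0).
#'
#' @return Total initial dose rate in mGy/h.
#' @examples
#' total_initial_dose_rate(ra223_chain(), c("Ra-223" = 1), 2, 0.5)
#' @export
total_initial_dose_rate <- function(chain, coefficients, injected_activity,
                                    decay_constant) {
  if (!inherits(chain, "decay_chain"))
    stop("'chain' must be a 'decay_chain' object")
  if (length(coefficients) == 0) return(0)
  if (is.null(names(coefficients)))
    stop("'coefficients' must be named by nuclide")
  unknown <- setdiff(names(coefficients), chain$nuclides$name)
  if (length(unknown) > 0)
    stop("coefficient(s) for nuclide(s) not in the decay chain: ",
         paste(unknown, collapse = ", "))
  sum(dose_rate(coefficients, injected_activity, decay_constant))
}

#' Serialise a decay chain and its dose coefficients to/from JSON
#'
#' `chain_to_json()` writes (or returns) a JSON representation of the chain
#' plus an optional nuclide -> coefficient map; `chain_from_json()` reads
#' it back, validating the nuclide set.
#'
#' @param chain A `decay_chain` object.
#' @param coefficients Optional named numeric vector of dose coefficients
#'   (mGy/MBq).
#' @param path Optional file path; if `NULL` the JSON string is returned.
#'
#' @return `chain_to_json()`: the JSON string (invisibly, if written to
#'   `path`). `chain_from_json()`: a list with elements `chain` and
#'   `coefficients`.
#' @export
chain_to_json <- function(chain, coefficients = NULL, path = NULL) {
  if (!inherits(chain, "decay_chain"))
    stop("'chain' must be a 'decay_chain' object")
  obj <- list(nuclides = chain$nuclides,
              omitted_branches = chain$omitted_branches)
  if (!is.null(coefficients)) {
    unknown <- setdiff(names(coefficients), chain$nuclides$name)
    if (length(unknown) > 0)
      stop("coefficient(s) for unknown nuclide(s): ",
           paste(unknown, collapse = ", "))
    obj$coefficients <- as.list(coefficients)
  }
  txt <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}

#' @param json JSON string (used when `path` is `NULL`).
#' @rdname chain_to_json
#' @export
chain_from_json <- function(path = NULL, json = NULL) {
  obj <- if (!is.null(path)) jsonlite::fromJSON(path)
         else jsonlite::fromJSON(json)
  chain <- structure(list(nuclides = obj$nuclides,
                          omitted_branches = obj$omitted_branches),
                     class = "decay_chain")
  if (anyDuplicated(chain$nuclides$name))
    stop("duplicate nuclide names in serialized chain")
  coefficients <- NULL
  if (!is.null(obj$coefficients))
    coefficients <- unlist(obj$coefficients)
  list(chain = chain, coefficients = coefficients)
}
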