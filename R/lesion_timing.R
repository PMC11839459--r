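#' Time a lesion call in molecular time
#'
#' The molecular time of the lesion node is the latest possible acquisition
#' time of the lesion; the molecular time of the repair/loss node is the
#' earliest possible resolution; their difference is the MMLD. Lesions whose
#' node lies before the developmental cutoff (default 50 mutations, the cord
#' blood burden) are classified in utero.
#'
#' @param call a pass PVV call ([walk_lesion_path()]) or a classified MAV
#'   ([classify_mav()], category simple or separated).
#' @param tree phylogeny.
#' @param config a [pipeline_config()].
#' @return list: `latest_acquisition`, `earliest_resolution`, `mmld`
#'   (mutations), `in_utero`, `chronological_duration_low/high` (years at
#'   the configured clock rate; the MMLD is a lower bound so low = 0 is not
#'   reported -- both bounds convert the MMLD).
#' @export
time_lesion <- function(call, tree, config = pipeline_config()) {
  if (!is.null(call$status) && !identical(call$status, "pass"))
    stop("only pass calls can be timed")
  if (!is.null(call$category) && !call$category %in% c("simple", "separated"))
    stop("only simple/separated MAVs can be timed")
  idx <- as_index(tree)
  t0 <- molecular_time(idx, call$lesion_node)
  t1 <- molecular_time(idx, call$repair_node)
  mmld <- t1 - t0
  rate <- config$mutation_rate_per_year
  list(latest_acquisition = t0, earliest_resolution = t1, mmld = mmld,
       in_utero = t0 < config$development_cutoff,
       chronological_duration_low = mmld / (rate + 1),
       chronological_duration_high = mmld / max(rate - 1, 1e-9))
}

#' Convert molecular time to years
#'
#' @param mmld molecular time in mutations.
#' @param rate_per_year clock rate (mutations/year), must be positive.
#' @return years.
#' @export
#' @examples
#' molecular_to_years(21, 15)   # ~1.4 years
molecular_to_years <- function(mmld, rate_per_year) {
  if (any(rate_per_year <= 0)) stop("rate must be positive")
  mmld / rate_per_year
}

#' Expected mutation burden from persistent lesions
#'
#' Product of steady-state lesions per cell, the probability that a lesion
#' generates a mutation at a cell division, and divisions per year.
#'
#' @param lesions_per_cell,misincorporation_prob,divisions_per_year
#'   non-negative scalars.
#' @return mutations per cell per year.
#' @export
#' @examples
#' expected_mutation_rate(8, 0.5, 1)   # 4
expected_mutation_rate <- function(lesions_per_cell, misincorporation_prob,
                                   divisions_per_year) {
  stopifnot(lesions_per_cell >= 0, misincorporation_prob >= 0,
            divisions_per_year >= 0)
  lesions_per_cell * misincorporation_prob * divisions_per_year
}

#' Base-incorporation probability opposite a lesion
#'
#' Point estimate and exact (Clopper-Pearson) 95% confidence interval for
#' the probability of the alternate incorporation, from counts taken in
#' unbiased subclades (lesion paths crossing more than two nodes, first two
#' detection-constrained subclades excluded -- the counts arrive
#' pre-filtered).
#'
#' @param n_alt_incorporations,n_ref_incorporations counts.
#' @return list: `estimate`, `ci` (length 2), `n`.
#' @export
#' @examples
#' incorporation_probability(49, 41)$estimate   # 0.544...
incorporation_probability <- function(n_alt_incorporations, n_ref_incorporations) {
  k <- n_alt_incorporations; n <- k + n_ref_incorporations
  if (n == 0) stop("no incorporations")
  lo <- if (k == 0) 0 else qbeta(0.025, k, n - k + 1)
  hi <- if (k == n) 1 else qbeta(0.975, k + 1, n - k)
  list(estimate = k / n, ci = c(lo, hi), n = n)
}
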