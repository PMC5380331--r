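# Tabular synthetic generators: binomial adhesion counts from a Hill curve,
# per-cell detachment thresholds around a median pressure, and power-law
# pulse-energy/pressure calibration pairs.

#' Sample adhesion counts from a Hill adhesion curve
#'
#' Adherent counts are Binomial(n_cells, chi(d)/100) per ligand spacing, with
#' chi(d) the decreasing Hill curve [hill_evaluate()]. The assay this emulates
#' scores 50 cells per spacing condition.
#'
#' @param d_values ligand spacings (nm), > 0.
#' @param chi_min,chi_max baseline and plateau adhesion fractions (percent).
#' @param d_star critical spacing (nm) at the transition midpoint.
#' @param n_coop Hill cooperativity coefficient, > 0.
#' @param n_cells cells seeded per spacing (>= 1); default 50.
#' @param soluble_sdf1a soluble-chemokine concentration recorded with the
#'   condition (ng/mL, bookkeeping only).
#' @param seed integer seed.
#' @return `data.frame` of class `adhesion_counts` with columns `condition`,
#'   `d`, `n_seeded`, `n_adherent`, `soluble_sdf1a`, `chi` (observed percent)
#'   and attribute `truth` holding the generating parameters.
#' @export
make_adhesion_counts <- function(d_values, chi_min = 0, chi_max = 100,
                                 d_star = 27, n_coop = 3, n_cells = 50L,
                                 soluble_sdf1a = 0, seed = NULL) {
  if (any(d_values <= 0)) stop_param("d_values must be positive")
  if (n_cells < 1) stop_param("n_cells must be >= 1")
  if (chi_min < 0 || chi_max > 100 || chi_min > chi_max)
    stop_param("need 0 <= chi_min <= chi_max <= 100")
  if (d_star <= 0 || n_coop <= 0) stop_param("d_star and n_coop must be > 0")
  chi <- hill_evaluate(d_values, chi_min = chi_min, chi_max = chi_max,
                       d_star = d_star, n_coop = n_coop)
  with_seed(seed, {
    k <- stats::rbinom(length(d_values), n_cells, chi / 100)
    out <- data.frame(
      condition = sprintf("d=%gnm", d_values),
      d = d_values,
      n_seeded = as.integer(n_cells),
      n_adherent = as.integer(k),
      soluble_sdf1a = soluble_sdf1a,
      chi = 100 * k / n_cells
    )
    attr(out, "truth") <- list(chi_min = chi_min, chi_max = chi_max,
                               d_star = d_star, n_coop = n_coop,
                               chi_true = chi)
    class(out) <- c("adhesion_counts", class(out))
    out
  })
}

#' Sample detachment outcomes from a logistic threshold model
#'
#' Each cell carries a detachment threshold whose log is logistic with median
#' `log(p_star)` and scale `1/slope`; at applied pressure P a cell detaches if
#' its threshold is <= P. Each pressure step exposes an independent cohort of
#' `n_cells` cells (the escalation protocol of the pressure-wave assay).
#'
#' @param pressures applied pressures (MPa), > 0.
#' @param p_star median detachment threshold (MPa), > 0.
#' @param slope dimensionless steepness (log-pressure logistic slope);
#'   `Inf` yields a step at `p_star`.
#' @param n_cells cells per pressure step; default 50.
#' @param seed integer seed.
#' @return `data.frame` of class `detachment_counts` with columns `P`,
#'   `n_exposed`, `n_detached`, `fraction`; attribute `truth` holds the
#'   generating parameters.
#' @export
make_detachment_data <- function(pressures, p_star = 7, slope = 8,
                                 n_cells = 50L, seed = NULL) {
  if (any(pressures <= 0)) stop_param("pressures must be positive")
  if (p_star <= 0) stop_param("p_star must be > 0")
  if (slope <= 0) stop_param("slope must be > 0")
  if (n_cells < 1) stop_param("n_cells must be >= 1")
  prob <- if (is.finite(slope)) {
    stats::plogis(slope * (log(pressures) - log(p_star)))
  } else as.numeric(pressures >= p_star)
  with_seed(seed, {
    k <- stats::rbinom(length(pressures), n_cells, prob)
    out <- data.frame(P = pressures, n_exposed = as.integer(n_cells),
                      n_detached = as.integer(k),
                      fraction = k / n_cells)
    attr(out, "truth") <- list(p_star = p_star, slope = slope, prob = prob)
    class(out) <- c("detachment_counts", class(out))
    out
  })
}

#' Generate pulse-energy / pressure calibration pairs
#'
#' `P = prefactor * E^exponent * exp(N(0, rel_noise))`, the multiplicative
#' lognormal noise model for hydrophone calibration scatter.
#'
#' @param energies pulse energies, > 0 (arbitrary but consistent unit).
#' @param prefactor power-law prefactor, > 0.
#' @param exponent power-law exponent; the calibration law this emulates has
#'   exponent 0.47.
#' @param rel_noise relative (log-scale) noise SD, >= 0.
#' @param seed integer seed.
#' @return `data.frame` with columns `E`, `P`; attribute `truth`.
#' @export
make_calibration_data <- function(energies, prefactor = 1, exponent = 0.47,
                                  rel_noise = 0.05, seed = NULL) {
  if (any(energies <= 0)) stop_param("energies must be positive")
  if (prefactor <= 0) stop_param("prefactor must be > 0")
  if (rel_noise < 0) stop_param("rel_noise must be >= 0")
  with_seed(seed, {
    noise <- if (rel_noise > 0) exp(stats::rnorm(length(energies), 0, rel_noise)) else 1
    out <- data.frame(E = energies, P = prefactor * energies^exponent * noise)
    attr(out, "truth") <- list(prefactor = prefactor, exponent = exponent,
                               rel_noise = rel_noise)
    out
  })
}
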