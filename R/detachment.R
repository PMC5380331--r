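# Pressure-wave detachment analytics: pulse-energy -> pressure calibration
# (power law, fitted in log-log space) and the critical detachment pressure
# P* at which 50% of adherent cells detach.

#' Fit the pulse-energy / pressure calibration power law
#'
#' Least-squares line in log-log space: `log P = log(prefactor) +
#' exponent * log E`. The physically sensible exponent lies in (0, 1)
#' (sub-linear growth of the hydrodynamic pressure with pulse energy, ~0.47
#' for the assay this models); fits outside that range are rejected with an
#' error.
#'
#' @param energies pulse energies, > 0 (>= 3 values).
#' @param pressures measured pressures (MPa), > 0, same length.
#' @return object of class `calibration_fit`: `prefactor`, `exponent`,
#'   `exponent_se`, `log_residual_sd`, `energy_range`.
#' @export
fit_calibration <- function(energies, pressures) {
  if (length(energies) < 3L) stop_param("calibration needs >= 3 pairs")
  if (length(pressures) != length(energies))
    stop_param("energies and pressures must have equal length")
  if (any(energies <= 0) || any(pressures <= 0))
    stop_param("energies and pressures must be positive")
  fit <- stats::lm(log(pressures) ~ log(energies))
  expo <- unname(stats::coef(fit)[2])
  if (!is.finite(expo) || expo < 1e-6 || expo >= 1)
    stop_param("fitted exponent %.3f outside (0, 1): not a valid pressure calibration", expo)
  structure(list(
    prefactor = exp(unname(stats::coef(fit)[1])),
    exponent = expo,
    exponent_se = unname(suppressWarnings(summary(fit))$coefficients[2, 2]),
    log_residual_sd = stats::sd(stats::residuals(fit)),
    energy_range = range(energies)
  ), class = "calibration_fit")
}

#' @export
print.calibration_fit <- function(x, ...) {
  cat(sprintf("<calibration_fit> P = %.4g * E^%.3f (SE %.3f), valid E in [%g, %g]\n",
              x$prefactor, x$exponent, x$exponent_se,
              x$energy_range[1], x$energy_range[2]))
  invisible(x)
}

#' Pressure from pulse energy via a fitted calibration
#'
#' @param energies pulse energies; values outside the calibration's validity
#'   range trigger a warning.
#' @param cal a [fit_calibration()] result.
#' @return pressures (MPa).
#' @export
pressure_from_energy <- function(energies, cal) {
  stopifnot(inherits(cal, "calibration_fit"))
  if (any(energies < cal$energy_range[1]) || any(energies > cal$energy_range[2]))
    warning("energy outside the calibration validity range; extrapolating")
  cal$prefactor * energies^cal$exponent
}

#' Estimate the critical detachment pressure P*
#'
#' Logistic dose-response fit (binomial likelihood, logit link on log
#' pressure) of the detached fraction; `P*` is the pressure detaching 50% of
#' cells. A seeded parametric bootstrap gives the confidence interval. When
#' the logistic fit fails (e.g. complete separation), a monotone
#' (isotonic-regression) interpolation at 0.5 is used instead and flagged in
#' the output.
#'
#' @param P applied pressures (MPa), > 0; or a `detachment_counts` table as
#'   sole argument.
#' @param n_exposed,n_detached cohort sizes and detached counts per pressure.
#' @param n_boot bootstrap replicates for the CI.
#' @param conf_level CI level.
#' @param extrapolate allow P* outside the bracketing of 0.5 (otherwise
#'   fractions must span both sides of 0.5).
#' @param seed integer seed for the bootstrap.
#' @return object of class `detachment_curve`: `p_star` (MPa), `ci`, `slope`
#'   (logit slope vs log P, NA for the interpolation fallback), `method`
#'   (`"logistic"` or `"interpolation"`), `data`.
#' @export
estimate_critical_pressure <- function(P, n_exposed = NULL, n_detached = NULL,
                                       n_boot = 500L, conf_level = 0.95,
                                       extrapolate = FALSE, seed = NULL) {
  if (inherits(P, "detachment_counts")) {
    tab <- P
    P <- tab$P; n_exposed <- tab$n_exposed; n_detached <- tab$n_detached
  }
  if (any(P <= 0)) stop_param("pressures must be positive")
  stopifnot(length(n_exposed) == length(P), length(n_detached) == length(P))
  if (any(n_detached < 0) || any(n_detached > n_exposed))
    stop_param("need 0 <= n_detached <= n_exposed")
  frac <- n_detached / n_exposed
  if (!extrapolate && (all(frac > 0.5) || all(frac < 0.5)))
    stop_param("detached fractions do not bracket 0.5; set extrapolate = TRUE to force")

  est <- p_star_point(P, n_exposed, n_detached)

  ci <- c(NA_real_, NA_real_)
  if (n_boot > 0) {
    boot <- with_seed(seed, {
      vapply(seq_len(n_boot), function(i) {
        k <- stats::rbinom(length(P), n_exposed, pmin(pmax(frac, 0), 1))
        tryCatch(p_star_point(P, n_exposed, k)$p_star,
                 error = function(e) NA_real_)
      }, numeric(1))
    })
    alpha <- 1 - conf_level
    ci <- unname(stats::quantile(boot, c(alpha / 2, 1 - alpha / 2), na.rm = TRUE))
  }
  structure(list(p_star = est$p_star, ci = ci, slope = est$slope,
                 method = est$method, conf_level = conf_level,
                 data = data.frame(P = P, n_exposed = n_exposed,
                                   n_detached = n_detached, fraction = frac)),
            class = "detachment_curve")
}

# Point estimate: binomial GLM on log pressure, isotonic interpolation as
# fallback on separation / non-convergence / non-positive slope.
p_star_point <- function(P, n_exposed, n_detached) {
  ord <- order(P)
  P <- P[ord]; n_exposed <- n_exposed[ord]; n_detached <- n_detached[ord]
  frac <- n_detached / n_exposed
  fit <- withCallingHandlers(
    tryCatch(stats::glm(cbind(n_detached, n_exposed - n_detached) ~ log(P),
                        family = stats::binomial()),
             error = function(e) NULL),
    warning = function(w) invokeRestart("muffleWarning"))
  if (!is.null(fit) && fit$converged) {
    b <- stats::coef(fit)
    if (is.finite(b[2]) && b[2] > 0 && abs(b[2]) < 50) {
      return(list(p_star = unname(exp(-b[1] / b[2])), slope = unname(b[2]),
                  method = "logistic"))
    }
  }
  # monotone interpolation fallback
  iso <- stats::isoreg(log(P), frac)
  yf <- iso$yf[order(iso$ord %||% seq_along(P))]
  if (all(yf < 0.5)) return(list(p_star = max(P), slope = NA_real_,
                                 method = "interpolation"))
  if (all(yf > 0.5)) return(list(p_star = min(P), slope = NA_real_,
                                 method = "interpolation"))
  i_hi <- which(yf >= 0.5)[1]
  if (yf[i_hi] == 0.5 || i_hi == 1L) {
    lp <- log(P)[i_hi]
  } else {
    i_lo <- i_hi - 1L
    lp <- log(P)[i_lo] + (0.5 - yf[i_lo]) / (yf[i_hi] - yf[i_lo]) *
      (log(P)[i_hi] - log(P)[i_lo])
  }
  list(p_star = exp(lp), slope = NA_real_, method = "interpolation")
}

#' @export
print.detachment_curve <- function(x, ...) {
  cat(sprintf("<detachment_curve> P* = %.2f MPa [%.2f, %.2f] (%s fit, %d pressures)\n",
              x$p_star, x$ci[1], x$ci[2], x$method, nrow(x$data)))
  invisible(x)
}
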