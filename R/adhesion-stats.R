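# Ligand-spacing model, adhesion-fraction bookkeeping, and Hill fits of the
# unbinding transition (fraction adherent or tight-adhesion area vs mean
# ligand spacing).

#' Mean ligand spacing from the anchor-lipid molar fraction
#'
#' Anchor lipids are incorporated monomerically into the matrix lipid, so the
#' average lateral distance between anchors (and hence ligands) follows from
#' the molar fraction `x` and the area per lipid: `d = sqrt(A_lipid / x)`
#' (square-lattice convention; the hexagonal-packing alternative, larger by
#' `sqrt(2/sqrt(3)) ~ 7%`, is available via `lattice = "hexagonal"`).
#'
#' @param x anchor molar fraction, in (0, 1].
#' @param a_lipid area per lipid in Angstrom^2 (default 65).
#' @param lattice `"square"` (default) or `"hexagonal"`.
#' @return mean spacing d in nm.
#' @seealso [spacing_to_fraction()] for the inverse.
#' @export
mean_ligand_spacing <- function(x, a_lipid = 65, lattice = c("square", "hexagonal")) {
  lattice <- match.arg(lattice)
  if (any(x <= 0) || any(x > 1)) stop_param("x must be in (0, 1]")
  if (a_lipid <= 0) stop_param("a_lipid must be > 0")
  d_ang <- sqrt(a_lipid / x)
  if (lattice == "hexagonal") d_ang <- d_ang * sqrt(2 / sqrt(3))
  d_ang / 10 # Angstrom -> nm
}

#' Anchor molar fraction from a target mean ligand spacing
#'
#' Inverse of [mean_ligand_spacing()].
#'
#' @param d mean spacing (nm), > 0.
#' @inheritParams mean_ligand_spacing
#' @return molar fraction x.
#' @export
spacing_to_fraction <- function(d, a_lipid = 65, lattice = c("square", "hexagonal")) {
  lattice <- match.arg(lattice)
  if (any(d <= 0)) stop_param("d must be > 0")
  d_ang <- d * 10
  if (lattice == "hexagonal") d_ang <- d_ang / sqrt(2 / sqrt(3))
  x <- a_lipid / d_ang^2
  if (any(x > 1 + 1e-9))
    stop_param("spacing %g nm requires molar fraction > 1", min(d))
  pmin(x, 1)
}

#' Decreasing Hill curve of adhesion vs ligand spacing
#'
#' `chi(d) = chi_min + (chi_max - chi_min) / (1 + (d / d_star)^n_coop)`:
#' adhesion transitions from the `chi_max` plateau (bound, dense ligands) to
#' the `chi_min` baseline (unbound, sparse ligands) with midpoint at the
#' critical distance `d_star` and steepness `n_coop`.
#'
#' @param d ligand spacing(s), nm, > 0.
#' @param chi_min,chi_max baseline and plateau levels (percent for fractions,
#'   um^2 when fitting adhesion areas).
#' @param d_star critical distance (nm), > 0.
#' @param n_coop cooperativity coefficient, > 0.
#' @param fit optionally, a `hill_fit` object supplying all four parameters.
#' @return chi(d), same units as `chi_min`/`chi_max`.
#' @export
hill_evaluate <- function(d, chi_min = 0, chi_max = 100, d_star = 27,
                          n_coop = 3, fit = NULL) {
  if (!is.null(fit)) {
    stopifnot(inherits(fit, "hill_fit"))
    chi_min <- fit$par[["chi_min"]]; chi_max <- fit$par[["chi_max"]]
    d_star <- fit$par[["d_star"]]; n_coop <- fit$par[["n_coop"]]
  }
  if (any(d <= 0)) stop_param("d must be > 0")
  if (d_star <= 0 || n_coop <= 0) stop_param("d_star and n_coop must be > 0")
  chi_min + (chi_max - chi_min) / (1 + (d / d_star)^n_coop)
}

#' Fit the Hill unbinding transition
#'
#' Weighted nonlinear least squares of the decreasing Hill curve to adhesion
#' fractions (binomial weights from the counts, with an Agresti-style floor
#' `p~ = (k + 0.5)/(n + 1)` so saturated points keep finite weight) or to
#' tight-adhesion areas (weights `1/sd^2`). A fixed multi-start grid over
#' `d_star` (geometric middle of the sampled range x {0.5, 1, 2}) and
#' `n_coop` in {1, 3} avoids local minima; optimization is bounded L-BFGS-B
#' on `(chi_min, chi_max, log d_star, log n_coop)`. Standard errors come
#' from the Gauss-Newton covariance `(J' W J)^-1 * s^2` at the optimum.
#'
#' @param d ligand spacings (nm); >= 4 distinct values required, or an
#'   `adhesion_counts` table as sole argument.
#' @param response observed response: fractions in percent, or areas (um^2).
#' @param n_seeded cell counts per point (binomial weighting; fractions).
#' @param sd response SDs per point (area weighting).
#' @param response_type `"fraction"` or `"area"` (bookkeeping; both share the
#'   identical code path, the area fit simply replaces chi by A).
#' @param chi_max_limit upper box bound for the plateau (default 100 for
#'   fractions, unbounded for areas).
#' @return object of class `hill_fit`: `par` (chi_min, chi_max, d_star,
#'   n_coop), `se`, `residual_norm`, `converged`, `extrapolated` (TRUE when
#'   d_star falls outside the sampled range), `response_type`, `data`.
#' @export
hill_fit <- function(d, response = NULL, n_seeded = NULL, sd = NULL,
                     response_type = c("fraction", "area"),
                     chi_max_limit = NULL) {
  if (inherits(d, "adhesion_counts")) {
    tab <- d
    d <- tab$d
    response <- 100 * tab$n_adherent / tab$n_seeded
    n_seeded <- tab$n_seeded
  }
  response_type <- match.arg(response_type)
  if (length(unique(d)) < 4L)
    stop_param("hill_fit needs >= 4 distinct d values (4 free parameters)")
  stopifnot(length(response) == length(d))
  if (any(d <= 0)) stop_param("d must be > 0")

  w <- if (!is.null(n_seeded)) {
    k <- response / 100 * n_seeded
    p <- (k + 0.5) / (n_seeded + 1)
    n_seeded / (p * (1 - p) * 100^2) # var of chi in percent^2
  } else if (!is.null(sd)) {
    1 / pmax(sd, 0.05 * stats::median(sd[sd > 0]))^2
  } else {
    rep(1, length(d))
  }

  hi_chi <- chi_max_limit %||%
    (if (response_type == "fraction") 100 else 2 * max(response))
  obj <- function(par) {
    pred <- par[1] + (par[2] - par[1]) / (1 + (d / exp(par[3]))^exp(par[4]))
    sum(w * (response - pred)^2)
  }
  d_mid <- sqrt(min(d) * max(d))
  starts <- expand.grid(ds = d_mid * c(0.5, 1, 2), nc = c(1, 3))
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    par0 <- c(min(response), max(response), log(starts$ds[i]), log(starts$nc[i]))
    fit <- tryCatch(
      stats::optim(par0, obj, method = "L-BFGS-B",
                   lower = c(0, 0, log(min(d) / 20), log(0.05)),
                   upper = c(hi_chi, hi_chi, log(max(d) * 20), log(40)),
                   control = list(maxit = 500)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
  }
  if (is.null(best))
    stop_param("Hill fit failed to converge from all starts")
  par <- c(chi_min = best$par[1], chi_max = best$par[2],
           d_star = exp(best$par[3]), n_coop = exp(best$par[4]))
  if (par[["chi_min"]] > par[["chi_max"]]) { # orientation guard
    par[c("chi_min", "chi_max")] <- par[c("chi_max", "chi_min")]
  }

  # Gauss-Newton covariance on the natural scale
  jac <- hill_jacobian(d, par)
  se <- rep(NA_real_, 4L)
  dof <- length(d) - 4L
  if (dof > 0) {
    s2 <- best$value / dof
    JtWJ <- t(jac) %*% (w * jac)
    cv <- tryCatch(solve(JtWJ) * s2, error = function(e) NULL)
    if (!is.null(cv)) se <- sqrt(pmax(diag(cv), 0))
  }
  names(se) <- names(par)
  extrapolated <- par[["d_star"]] < min(d) || par[["d_star"]] > max(d)
  structure(list(par = par, se = se, residual_norm = best$value,
                 converged = best$convergence == 0,
                 extrapolated = extrapolated,
                 response_type = response_type,
                 data = data.frame(d = d, response = response, weight = w)),
            class = "hill_fit")
}

hill_jacobian <- function(d, par) {
  cmin <- par[["chi_min"]]; cmax <- par[["chi_max"]]
  ds <- par[["d_star"]]; nc <- par[["n_coop"]]
  q <- (d / ds)^nc
  den <- 1 + q
  cbind(
    chi_min = 1 - 1 / den,
    chi_max = 1 / den,
    d_star = (cmax - cmin) * q * nc / (ds * den^2),
    n_coop = -(cmax - cmin) * q * log(d / ds) / den^2
  )
}

#' @export
print.hill_fit <- function(x, ...) {
  cat(sprintf("<hill_fit> (%s) chi_min = %.2f, chi_max = %.2f, d* = %.2f nm (SE %.2f), n = %.2f (SE %.2f)%s\n",
              x$response_type, x$par[["chi_min"]], x$par[["chi_max"]],
              x$par[["d_star"]], x$se[["d_star"]], x$par[["n_coop"]],
              x$se[["n_coop"]],
              if (x$extrapolated) " [d* outside sampled range]" else ""))
  invisible(x)
}

#' Fraction of adherent cells with a Wilson 95% interval
#'
#' @param n_seeded cells seeded, > 0.
#' @param n_adherent cells scored adherent, `0 <= n_adherent <= n_seeded`.
#' @param conf_level confidence level for the Wilson score interval.
#' @return list with `chi` (percent), `ci` (percent, length 2), counts.
#' @export
fraction_adherent <- function(n_seeded, n_adherent, conf_level = 0.95) {
  if (any(n_seeded <= 0)) stop_param("n_seeded must be > 0")
  if (any(n_adherent < 0) || any(n_adherent > n_seeded))
    stop_param("need 0 <= n_adherent <= n_seeded")
  p <- n_adherent / n_seeded
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  denom <- 1 + z^2 / n_seeded
  centre <- (p + z^2 / (2 * n_seeded)) / denom
  half <- z * sqrt(p * (1 - p) / n_seeded + z^2 / (4 * n_seeded^2)) / denom
  list(chi = 100 * p,
       ci = 100 * c(lower = max(0, centre - half), upper = min(1, centre + half)),
       n_seeded = n_seeded, n_adherent = n_adherent,
       conf_level = conf_level)
}
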