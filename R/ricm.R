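# Reflection interference contrast microscopy (RICM): scalar two-beam
# interference model with a finite illumination numerical aperture (INA),
# illumination-profile correction, first-branch height inversion, and the
# tight-adhesion area measure.
#
# Model: the reflection at the glass/membrane/medium stack interferes with
# the reflection at the medium/cytosol interface a height h above it. With
# the optical path 4*pi*n3*h/lambda and incidence angles up to
# arcsin(INA/n3), averaging the interference cosine over the illumination
# cone damps fringe visibility with height (sinc envelope) and slightly
# stretches the fringe period:
#
#   I(h)/I_bg = 1 + V0 * sinc(phi*(1-c)/2) * cos(phi*(1+c)/2 + pi),
#   phi = 4*pi*n3*h/lambda,  c = cos(asin(INA/n3)),
#   V0 from normal-incidence Fresnel amplitudes of the layer stack.
#
# Contact (h = 0) is the exact global intensity minimum; INA = 0 recovers a
# strictly periodic fringe of period lambda/(2*n3).

#' Optical model for RICM imaging
#'
#' Defaults are the acquisition conditions the package models: green
#' illumination at 546 nm, INA ~ 0.64, glass/lipid-membrane/medium/cytosol
#' refractive indices 1.525 / 1.486 / 1.335 / 1.37.
#'
#' @param wavelength illumination wavelength (nm).
#' @param ina illumination numerical aperture; `0 <= ina < n3`.
#' @param n1,n2,n3,n_cyt refractive indices of glass, lipid membrane, medium,
#'   cytosol (all > 1).
#' @param membrane_thickness supported-membrane thickness (nm), used for the
#'   thin-film reflection amplitude of the substrate stack.
#' @param pixel_size um per pixel for derived area measures.
#' @return object of class `optical_model`.
#' @export
optical_model <- function(wavelength = 546, ina = 0.64,
                          n1 = 1.525, n2 = 1.486, n3 = 1.335, n_cyt = 1.37,
                          membrane_thickness = 4, pixel_size = 0.2) {
  if (wavelength <= 0) stop_param("wavelength must be > 0")
  if (ina < 0 || ina >= n3) stop_param("need 0 <= ina < n3")
  if (any(c(n1, n2, n3, n_cyt) <= 1)) stop_param("refractive indices must be > 1")
  if (pixel_size <= 0) stop_param("pixel_size must be > 0")
  structure(list(wavelength = wavelength, ina = ina, n1 = n1, n2 = n2,
                 n3 = n3, n_cyt = n_cyt,
                 membrane_thickness = membrane_thickness,
                 pixel_size = pixel_size),
            class = "optical_model")
}

# Normal-incidence amplitude of the glass/membrane/medium stack (thin-film
# formula; only the magnitude is used) and of the medium/cytosol interface.
fresnel_amplitudes <- function(optics) {
  ra <- (optics$n1 - optics$n2) / (optics$n1 + optics$n2)
  rb <- (optics$n2 - optics$n3) / (optics$n2 + optics$n3)
  beta <- 2 * pi * optics$n2 * optics$membrane_thickness / optics$wavelength
  r1 <- (ra + rb * exp(2i * beta)) / (1 + ra * rb * exp(2i * beta))
  a1 <- Mod(r1)
  a2 <- abs((optics$n3 - optics$n_cyt) / (optics$n3 + optics$n_cyt)) * (1 - a1^2)
  list(a1 = a1, a2 = a2, visibility = 2 * a1 * a2 / (a1^2 + a2^2))
}

#' Forward RICM intensity for a membrane-substrate separation
#'
#' @param h height(s) in nm, >= 0. Vector or matrix.
#' @param optics an [optical_model()].
#' @return normalized intensity (background-fringe mean = 1), same shape as
#'   `h`.
#' @export
forward_intensity <- function(h, optics = optical_model()) {
  if (any(h < 0)) stop_param("heights must be >= 0")
  fr <- fresnel_amplitudes(optics)
  cc <- cos(asin(optics$ina / optics$n3))
  phi <- 4 * pi * optics$n3 * h / optics$wavelength
  arg_env <- phi * (1 - cc) / 2
  env <- ifelse(arg_env == 0, 1, sin(arg_env) / arg_env)
  out <- 1 + fr$visibility * env * cos(phi * (1 + cc) / 2 + pi)
  if (is.matrix(h)) matrix(out, nrow(h), ncol(h)) else out
}

#' Height limit of the first monotone interference branch
#'
#' The interference phase alone would put the first maximum-intensity turning
#' point at `lambda / (2 * n3 * (1 + cos(asin(ina/n3))))` (equal to
#' `lambda / (4 * n3)` for INA = 0), but the finite-INA visibility envelope
#' decays with height and pulls the true turning point slightly below that;
#' the limit is therefore located numerically as the argmax of the forward
#' intensity. Heights up to this limit are uniquely invertible.
#'
#' @param optics an [optical_model()].
#' @return branch limit in nm.
#' @export
first_branch_limit <- function(optics = optical_model()) {
  cc <- cos(asin(optics$ina / optics$n3))
  h_nom <- optics$wavelength / (2 * optics$n3 * (1 + cc))
  if (optics$ina == 0) return(h_nom)
  stats::optimize(function(h) forward_intensity(h, optics),
                  c(0.5 * h_nom, h_nom), maximum = TRUE)$maximum
}

#' Correct an RICM stack for the parabolic illumination profile
#'
#' Divides each frame by a robustly least-squares-fitted 2-D paraboloid of the
#' cell-free background and aggregates the sequence (temporal mean by default)
#' to suppress shot noise. Output is normalized so the background sits near 1.
#'
#' @param stack rows x cols x frames array (>= 2 frames) or a single matrix
#'   (profile correction only, no noise suppression).
#' @param order polynomial order of the background surface (1 or 2).
#' @param stat temporal aggregator, `"mean"` (default; variance drops as 1/n)
#'   or `"median"` (robust alternative).
#' @param normalize `"scale_preserving"` (default) divides by the fitted
#'   profile rescaled to unit mean, flattening the illumination while keeping
#'   the absolute intensity scale that [reconstruct_height()] needs;
#'   `"background_unit"` divides by the full fitted profile so the fitted
#'   background level maps to 1.
#' @return list with `stack` (corrected frames), `aggregate` (corrected
#'   noise-suppressed frame), `profile` (fitted illumination surface), `stat`.
#' @export
correct_illumination <- function(stack, order = 2, stat = c("mean", "median"),
                                 normalize = c("scale_preserving",
                                               "background_unit")) {
  stat <- match.arg(stat)
  normalize <- match.arg(normalize)
  if (is.matrix(stack)) stack <- array(stack, c(dim(stack), 1L))
  stopifnot(length(dim(stack)) == 3L)
  n_frames <- dim(stack)[3]
  if (n_frames < 2L)
    stop_param("illumination correction with noise suppression needs >= 2 frames")
  agg0 <- apply(stack, c(1, 2), if (stat == "mean") mean else stats::median)
  nr <- nrow(agg0); nc <- ncol(agg0)
  x <- rep((seq_len(nc) - (nc + 1) / 2) / nc, each = nr)
  y <- rep((seq_len(nr) - (nr + 1) / 2) / nr, times = nc)
  X <- if (order >= 2) cbind(1, x, y, x^2, y^2, x * y) else cbind(1, x, y)
  z <- as.vector(agg0)
  # initial background guess by intensity: the cell footprint sits far from
  # the spatial median, while genuine illumination falloff stays within a few
  # robust SDs of it
  s0 <- stats::mad(z)
  keep <- if (s0 > 0) abs(z - stats::median(z)) < 5 * s0 else rep(TRUE, length(z))
  if (sum(keep) <= ncol(X)) keep <- rep(TRUE, length(z))
  for (it in 1:4) { # robust refit: cell pixels are outliers vs the background
    fit <- stats::lm.fit(X[keep, , drop = FALSE], z[keep])
    resid_all <- z - X %*% fit$coefficients
    s <- stats::mad(resid_all[keep]) # MAD: immune to a large cell footprint
    if (!is.finite(s) || s < 1e-8 * mean(abs(z))) break
    keep_new <- abs(resid_all) < 4 * s
    if (sum(keep_new) <= ncol(X)) break
    keep <- keep_new
  }
  profile <- matrix(X %*% fit$coefficients, nr, nc)
  if (any(profile <= 0)) stop_param("fitted illumination profile is not positive")
  divisor <- if (normalize == "scale_preserving") profile / mean(profile) else profile
  corrected <- array(0, dim(stack))
  for (k in seq_len(n_frames)) corrected[, , k] <- stack[, , k] / divisor
  list(stack = corrected, aggregate = agg0 / divisor, profile = profile,
       stat = stat, normalize = normalize)
}

#' Reconstruct a height map from a corrected RICM sequence
#'
#' Inverts [forward_intensity()] on the first monotone branch
#' (`h` in `[0, first_branch_limit()]`) by precomputed lookup with linear
#' interpolation. The per-pixel temporal standard deviation of the sequence is
#' propagated to a height uncertainty via the local slope `|dI/dh|`. Pixels
#' whose mean intensity leaves the invertible range (beyond a small noise
#' allowance) are flagged invalid rather than clipped silently; more than 20%
#' invalid pixels triggers a warning.
#'
#' @param corrected corrected stack (rows x cols x frames) or the list
#'   returned by [correct_illumination()], or a single matrix (then
#'   `height_std` is `NA`).
#' @param optics an [optical_model()].
#' @param lookup_n lookup-table resolution.
#' @param range_tol fraction of the intensity span by which a pixel may
#'   overshoot the model range (shot noise) and still be clamped valid.
#' @return object of class `height_map`: `mean_height` (nm), `height_std`
#'   (nm), `valid_mask`, `pixel_size` (um), `optics`, `n_frames`.
#' @export
reconstruct_height <- function(corrected, optics = optical_model(),
                               lookup_n = 4096L, range_tol = 0.02) {
  if (is.list(corrected) && !is.null(corrected$stack)) corrected <- corrected$stack
  if (is.matrix(corrected)) corrected <- array(corrected, c(dim(corrected), 1L))
  n_frames <- dim(corrected)[3]
  imean <- apply(corrected, c(1, 2), mean)

  hb <- first_branch_limit(optics)
  hgrid <- seq(0, hb, length.out = lookup_n)
  itab <- forward_intensity(hgrid, optics)
  if (any(diff(itab) <= 0))
    stop_param("forward model is not monotone on the first branch; check optics")
  span <- itab[lookup_n] - itab[1]
  lo <- itab[1] - range_tol * span
  hi <- itab[lookup_n] + range_tol * span
  valid <- imean >= lo & imean <= hi
  invert <- function(iv) {
    stats::approx(itab, hgrid,
                  xout = pmin(pmax(iv, itab[1]), itab[lookup_n]))$y
  }
  # mean height from the temporal-mean intensity (noise is tamed before the
  # nonlinear inversion); fluctuation from per-frame inversions, which stays
  # finite where the fringe slope vanishes (contact, branch end)
  h <- matrix(invert(imean), nrow(imean))
  h[!valid] <- NA_real_
  hsd <- if (n_frames >= 2L) {
    hframes <- vapply(seq_len(n_frames),
                      function(k) invert(corrected[, , k]),
                      numeric(length(imean)))
    matrix(apply(hframes, 1L, stats::sd), nrow(imean))
  } else matrix(NA_real_, nrow(imean), ncol(imean))
  hsd[!valid] <- NA_real_
  n_bad <- sum(!valid)
  if (n_bad > 0.2 * length(valid))
    warning(sprintf("%d of %d pixels outside the invertible intensity range",
                    n_bad, length(valid)))
  structure(list(mean_height = h, height_std = hsd, valid_mask = valid,
                 pixel_size = optics$pixel_size, optics = optics,
                 n_frames = n_frames),
            class = "height_map")
}

#' @export
print.height_map <- function(x, ...) {
  cat(sprintf("<height_map> %d x %d px (%.3g um/px), %d frames, %.1f%% valid\n",
              nrow(x$mean_height), ncol(x$mean_height), x$pixel_size,
              x$n_frames, 100 * mean(x$valid_mask)))
  invisible(x)
}

#' Area of tight adhesion from a height map
#'
#' Counts pixels whose mean height and temporal height SD both fall below
#' their thresholds, restricted to the largest connected component (one cell
#' per region of interest), and converts to um^2. An empty footprint returns
#' area 0 with `empty = TRUE` rather than an error.
#'
#' @param hm a [height_map][reconstruct_height()].
#' @param h_max mean-height threshold (nm), > 0; default 40.
#' @param std_max height-SD threshold (nm), > 0; default 10. Ignored (with
#'   all pixels passing) when the map carries no std channel.
#' @return object of class `tight_adhesion`: `area_um2`, `mask` (footprint),
#'   `h_max`, `std_max`, `empty`, `pixel_size`.
#' @export
tight_adhesion_area <- function(hm, h_max = 40, std_max = 10) {
  stopifnot(inherits(hm, "height_map"))
  if (h_max <= 0 || std_max <= 0) stop_param("thresholds must be > 0")
  sel <- hm$valid_mask & !is.na(hm$mean_height) & hm$mean_height <= h_max
  if (!all(is.na(hm$height_std))) {
    sel <- sel & !is.na(hm$height_std) & hm$height_std <= std_max
  }
  if (!any(sel)) {
    return(structure(list(area_um2 = 0, mask = sel, h_max = h_max,
                          std_max = std_max, empty = TRUE,
                          pixel_size = hm$pixel_size),
                     class = "tight_adhesion"))
  }
  fp <- largest_component(sel)
  structure(list(area_um2 = sum(fp) * hm$pixel_size^2, mask = fp,
                 h_max = h_max, std_max = std_max, empty = FALSE,
                 pixel_size = hm$pixel_size),
            class = "tight_adhesion")
}

#' @export
print.tight_adhesion <- function(x, ...) {
  cat(sprintf("<tight_adhesion> area = %.2f um^2 (h <= %g nm, sd <= %g nm)%s\n",
              x$area_um2, x$h_max, x$std_max,
              if (x$empty) " [empty footprint]" else ""))
  invisible(x)
}
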