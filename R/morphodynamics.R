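# Contour-fluctuation spectroscopy: drift correction of image stacks, cell
# contour extraction, radial amplitude maps r(theta, t) in the
# center-of-mass frame, spatio-temporal autocorrelation, angular Fourier
# mode power spectra, and the three-way motion classification
# (rotational / oscillatory / translational).

# ---- drift correction ------------------------------------------------------

#' Drift-correct an image stack by cross-correlation
#'
#' Integer-pixel registration of each frame against a running reference (the
#' previously registered frame) using the FFT cross-correlation peak. Frames
#' whose normalized peak correlation falls below `confidence_floor` are
#' flagged and inherit the previous shift.
#'
#' @param stack rows x cols x frames array, >= 2 frames.
#' @param confidence_floor minimum normalized correlation at the peak.
#' @param max_shift largest per-frame displacement considered (pixels);
#'   defaults to a third of the smaller image dimension.
#' @return list with `stack` (registered), `shifts` (frames x 2, cumulative
#'   row/col shifts applied), `flagged` (logical per frame).
#' @export
drift_correct <- function(stack, confidence_floor = 0.2, max_shift = NULL) {
  stopifnot(length(dim(stack)) == 3L, dim(stack)[3] >= 2L)
  n <- dim(stack)[3]
  max_shift <- max_shift %||% (min(dim(stack)[1:2]) %/% 3L)
  shifts <- matrix(0L, n, 2L, dimnames = list(NULL, c("row", "col")))
  flagged <- logical(n)
  # correlate on absolute-deviation maps: the cell body mass dominates the
  # alignment instead of the thin bright halo, which is ambiguous under
  # rotation of an elongated cell
  dev_of <- function(m) abs(m - stats::median(m))
  out <- stack
  ref <- out[, , 1]
  for (k in 2:n) {
    cc <- xcorr_peak(dev_of(ref), dev_of(stack[, , k]), max_shift = max_shift)
    if (cc$confidence < confidence_floor) {
      flagged[k] <- TRUE
      shifts[k, ] <- shifts[k - 1L, ]
    } else {
      shifts[k, ] <- -cc$shift # undo measured displacement
    }
    out[, , k] <- shift_matrix(stack[, , k], shifts[k, 1], shifts[k, 2])
    ref <- out[, , k]
  }
  list(stack = out, shifts = shifts, flagged = flagged)
}

# Cross-correlation peak of b relative to a (positive shift = b displaced by
# +shift w.r.t. a), with a normalized confidence score. The peak search is
# restricted to displacements within max_shift.
xcorr_peak <- function(a, b, max_shift = Inf) {
  a0 <- a - mean(a); b0 <- b - mean(b)
  num <- Re(stats::fft(stats::fft(a0) * Conj(stats::fft(b0)), inverse = TRUE)) /
    length(a0)
  nr <- nrow(a); nc <- ncol(a)
  if (is.finite(max_shift)) {
    dr_grid <- c(0:(nr - 1)); dr_grid[dr_grid > nr / 2] <- dr_grid[dr_grid > nr / 2] - nr
    dc_grid <- c(0:(nc - 1)); dc_grid[dc_grid > nc / 2] <- dc_grid[dc_grid > nc / 2] - nc
    num[abs(dr_grid) > max_shift, ] <- -Inf
    num[, abs(dc_grid) > max_shift] <- -Inf
  }
  pk <- which(num == max(num), arr.ind = TRUE)[1, ]
  dr <- pk[1] - 1L; if (dr > nr / 2) dr <- dr - nr
  dc <- pk[2] - 1L; if (dc > nc / 2) dc <- dc - nc
  denom <- sqrt(sum(a0^2) * sum(b0^2))
  conf <- if (denom > 0) max(num) / denom else 0
  list(shift = c(-dr, -dc), confidence = conf)
}

# Integer shift with edge padding by the matrix median.
shift_matrix <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(stats::median(m), nr, nc)
  src_r <- seq_len(nr) - dr
  src_c <- seq_len(nc) - dc
  ok_r <- src_r >= 1 & src_r <= nr
  ok_c <- src_c >= 1 & src_c <= nc
  out[which(ok_r), which(ok_c)] <- m[src_r[ok_r], src_c[ok_c]]
  out
}

# ---- contour extraction ----------------------------------------------------

box_smooth <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  acc <- m; cnt <- matrix(1, nr, nc)
  for (d in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1),
                 c(1, 1), c(1, -1), c(-1, 1), c(-1, -1))) {
    sh <- shift_matrix(m, d[1], d[2])
    acc <- acc + sh
    cnt <- cnt + 1
  }
  acc / cnt
}

dilate1 <- function(mask) {
  out <- mask
  out[-1, ] <- out[-1, ] | mask[-nrow(mask), ]
  out[-nrow(mask), ] <- out[-nrow(mask), ] | mask[-1, ]
  out[, -1] <- out[, -1] | mask[, -ncol(mask)]
  out[, -ncol(mask)] <- out[, -ncol(mask)] | mask[, -1]
  out
}

erode1 <- function(mask) !dilate1(!mask)

sample_bilinear <- function(img, ri, ci) {
  nr <- nrow(img); nc <- ncol(img)
  ri <- pmin(pmax(ri, 1), nr); ci <- pmin(pmax(ci, 1), nc)
  r0 <- pmin(floor(ri), nr - 1L); c0 <- pmin(floor(ci), nc - 1L)
  fr <- ri - r0; fc <- ci - c0
  img[cbind(r0, c0)] * (1 - fr) * (1 - fc) +
    img[cbind(r0 + 1, c0)] * fr * (1 - fc) +
    img[cbind(r0, c0 + 1)] * (1 - fr) * fc +
    img[cbind(r0 + 1, c0 + 1)] * fr * fc
}

#' Extract a closed cell contour from a single frame
#'
#' Local-contrast thresholding of the smoothed absolute deviation from the
#' background level, morphological closing, largest connected component with
#' hole filling, then a sub-pixel radial boundary: along each of `n_boundary`
#' rays from the mask centroid the bright halo ridge is located by parabolic
#' interpolation (falling back to the mask 0.5-crossing when no ridge is
#' present).
#'
#' @param frame image matrix.
#' @param pixel_size um per pixel (for the returned polygon coordinates,
#'   image-centred).
#' @param threshold_frac deviation threshold as a fraction of the maximum
#'   smoothed deviation.
#' @param min_area_px minimum component area in pixels.
#' @param closing_radius iterations of dilation/erosion for closing.
#' @param n_boundary number of boundary vertices.
#' @param frame_index frame number used in error messages.
#' @return n x 2 polygon matrix (um), with attributes `center_px` and
#'   `center_um`.
#' @export
extract_contour <- function(frame, pixel_size = 0.2, threshold_frac = 0.25,
                            min_area_px = 25L, closing_radius = 2L,
                            n_boundary = 360L, frame_index = NA) {
  med <- stats::median(frame)
  dev <- box_smooth(abs(frame - med))
  mx <- max(dev)
  if (mx <= .Machine$double.eps)
    stop_param("no cell found in frame %s: image is flat", frame_index)
  mask <- dev > threshold_frac * mx
  for (i in seq_len(closing_radius)) mask <- dilate1(mask)
  for (i in seq_len(closing_radius)) mask <- erode1(mask)
  if (!any(mask))
    stop_param("no component above threshold in frame %s", frame_index)
  mask <- fill_holes(largest_component(mask))
  if (sum(mask) < min_area_px)
    stop_param("largest component in frame %s below minimum area (%d px)",
               frame_index, min_area_px)
  idx <- which(mask, arr.ind = TRUE)
  ctr <- colMeans(idx) # (row, col) centroid in pixel units
  nr <- nrow(frame); nc <- ncol(frame)
  theta <- seq(0, 2 * pi, length.out = n_boundary + 1L)[-(n_boundary + 1L)]
  maskn <- mask * 1
  fsm <- box_smooth(frame)
  r_out <- numeric(n_boundary)
  rmax <- sqrt(nr^2 + nc^2) / 2
  step <- 0.25
  rs <- seq(step, rmax, by = step)
  for (j in seq_len(n_boundary)) {
    # pixel-space ray: x (cols) = cos, y (rows) = sin
    ci <- ctr[2] + rs * cos(theta[j])
    ri <- ctr[1] + rs * sin(theta[j])
    inb <- ci >= 1 & ci <= nc & ri >= 1 & ri <= nr
    mv <- sample_bilinear(maskn, ri[inb], ci[inb])
    hit <- which(mv >= 0.5)
    if (!length(hit))
      stop_param("ray %d finds no mask boundary in frame %s", j, frame_index)
    k_edge <- max(hit) # outermost mask sample
    r_mask <- rs[inb][k_edge]
    # refine by the 0.5 crossing between k_edge and the next sample
    if (k_edge < sum(inb)) {
      v1 <- mv[k_edge]; v2 <- mv[k_edge + 1L]
      if (v1 != v2) r_mask <- r_mask + step * (v1 - 0.5) / (v1 - v2)
    }
    # halo refinement: the bright rim straddles the true boundary, so its
    # intensity-plateau centroid locates the edge without the halo-width bias
    # the mask boundary carries
    wsel <- which(rs[inb] > r_mask - 6 & rs[inb] <= r_mask + 0.5)
    refined <- FALSE
    if (length(wsel) >= 5L) {
      iv <- sample_bilinear(fsm, ri[inb][wsel], ci[inb][wsel])
      vmax <- max(iv); vmin <- min(iv)
      if (vmax - vmin > 0.2 * vmax) { # bright halo present
        pk <- which.max(iv)
        half <- (vmax + vmin) / 2
        lo_i <- pk; while (lo_i > 1L && iv[lo_i - 1L] >= half) lo_i <- lo_i - 1L
        hi_i <- pk; while (hi_i < length(iv) && iv[hi_i + 1L] >= half) hi_i <- hi_i + 1L
        run <- lo_i:hi_i
        r_out[j] <- sum(rs[inb][wsel[run]] * iv[run]) / sum(iv[run])
        refined <- TRUE
      }
    }
    if (!refined) r_out[j] <- r_mask
  }
  cx_um <- (ctr[2] - (nc + 1) / 2) * pixel_size
  cy_um <- (ctr[1] - (nr + 1) / 2) * pixel_size
  poly <- cbind(x = cx_um + r_out * pixel_size * cos(theta),
                y = cy_um + r_out * pixel_size * sin(theta))
  attr(poly, "center_px") <- ctr
  attr(poly, "center_um") <- c(cx_um, cy_um)
  poly
}

# ---- amplitude map ---------------------------------------------------------

# Exact radii of a star-shaped polygon about `ctr` on the angle grid `theta`.
# Returns NULL when the polygon is not star-shaped about ctr (vertex angles
# not sortable into a single monotone cycle with unique ray hits).
ray_radii <- function(poly, ctr, theta) {
  px <- poly[, 1] - ctr[1]; py <- poly[, 2] - ctr[2]
  vth <- atan2(py, px) %% (2 * pi)
  ord <- order(vth)
  vth_s <- vth[ord]
  if (anyDuplicated(vth_s)) return(NULL)
  n <- length(vth_s)
  e1 <- seq_len(nrow(poly))
  e2 <- c(e1[-1], e1[1])
  ux <- cos(theta); uy <- sin(theta)
  # vectorised straddle search: for each theta find the edge whose sorted
  # vertex angles bracket it (valid for star-shaped polygons)
  idx <- findInterval(theta %% (2 * pi), vth_s)
  idx[idx == 0L] <- n
  a <- ord[idx]
  b_pos <- idx %% n + 1L
  b <- ord[b_pos]
  # the bracketing vertices must be polygon neighbours, else not star-shaped
  neigh <- (e2[a] == b) | (e2[b] == a)
  if (!all(neigh)) return(NULL)
  ax <- px[a]; ay <- py[a]
  dx <- px[b] - ax; dy <- py[b] - ay
  cross_ud <- ux * dy - uy * dx
  if (any(abs(cross_ud) < 1e-14)) return(NULL)
  s <- (ax * dy - ay * dx) / cross_ud
  if (any(s <= 0)) return(NULL)
  s
}

# Fallback: count all ray/edge crossings; exactly one required per ray.
ray_radii_full <- function(poly, ctr, theta) {
  px <- poly[, 1] - ctr[1]; py <- poly[, 2] - ctr[2]
  n <- nrow(poly)
  e2 <- c(seq_len(n)[-1], 1L)
  dx <- px[e2] - px; dy <- py[e2] - py
  r_out <- numeric(length(theta))
  ok <- logical(length(theta))
  for (j in seq_along(theta)) {
    ux <- cos(theta[j]); uy <- sin(theta[j])
    cross_ud <- ux * dy - uy * dx
    t <- (px * uy - py * ux) / -cross_ud
    s <- (px * dy - py * dx) / cross_ud
    hit <- is.finite(t) & t >= 0 & t < 1 & s > 0
    if (sum(hit) == 1L) {
      r_out[j] <- s[hit]
      ok[j] <- TRUE
    }
  }
  list(r = r_out, ok = ok)
}

#' Amplitude map r(theta, t) of a contour time series
#'
#' For each frame the polygon's area centroid defines the inertial
#' (center-of-mass) frame; the radial distance to the contour is sampled on a
#' fixed angular grid by exact ray/polygon intersection. Frames whose polygon
#' is not star-shaped about its centroid are flagged: isolated bad frames
#' (fewer than 3 consecutive) are repaired by temporal interpolation,
#' longer runs abort.
#'
#' @param contours a `contour_series` or list of n x 2 polygon matrices.
#' @param time frame timestamps (s); defaults to the series' or 0,1,2,...
#' @param n_theta angular bins over the full circle (default 360).
#' @return object of class `amplitude_map`: `r` (n_theta x n_frames, um),
#'   `theta_deg`, `time`, `centers` (n_frames x 2, um), `repaired` (logical).
#' @export
amplitude_map <- function(contours, time = NULL, n_theta = 360L) {
  polys <- if (inherits(contours, "contour_series")) contours$polygons else contours
  if (is.null(time)) {
    time <- if (inherits(contours, "contour_series")) contours$time
    else seq_along(polys) - 1
  }
  n_frames <- length(polys)
  theta <- seq(0, 2 * pi, length.out = n_theta + 1L)[-(n_theta + 1L)]
  r <- matrix(NA_real_, n_theta, n_frames)
  centers <- matrix(0, n_frames, 2L)
  bad <- logical(n_frames)
  for (k in seq_len(n_frames)) {
    ctr <- polygon_centroid(polys[[k]])
    centers[k, ] <- ctr
    rr <- ray_radii(polys[[k]], ctr, theta)
    if (is.null(rr)) {
      full <- ray_radii_full(polys[[k]], ctr, theta)
      if (all(full$ok)) rr <- full$r else bad[k] <- TRUE
    }
    if (!bad[k]) r[, k] <- rr
  }
  if (any(bad)) {
    runs <- rle(bad)
    if (any(runs$lengths[runs$values] >= 3L))
      stop_param("%d consecutive non-star-shaped frames; cell aborted",
                 max(runs$lengths[runs$values]))
    good <- which(!bad)
    if (length(good) < 2L) stop_param("too few valid frames")
    for (k in which(bad)) {
      r[, k] <- apply(r[, good, drop = FALSE], 1, function(v)
        stats::approx(time[good], v, xout = time[k], rule = 2)$y)
    }
  }
  if (any(r <= 0)) stop_param("non-positive radius in amplitude map")
  structure(list(r = r, theta_deg = theta * 180 / pi, time = time,
                 centers = centers, repaired = bad),
            class = "amplitude_map")
}

#' @export
print.amplitude_map <- function(x, ...) {
  cat(sprintf("<amplitude_map> %d theta bins x %d frames, mean radius %.2f um\n",
              nrow(x$r), ncol(x$r), mean(x$r)))
  invisible(x)
}

# ---- autocorrelation -------------------------------------------------------

#' Spatio-temporal autocorrelation of an amplitude map
#'
#' The global mean radius is subtracted; correlation is circular in the
#' angular lag and unbiased (divide-by-overlap) in the temporal lag, with
#' maximum lag half the record to bound estimator variance. Normalized by the
#' zero-lag value, so `gamma[dtheta = 0, dt = 0] = 1`.
#'
#' @param am an [amplitude_map()].
#' @param max_lag maximum temporal lag in frames; default `n_frames %/% 2`.
#' @return object of class `autocorr_map`: `gamma` (n_theta x (2*max_lag+1)
#'   matrix over angular lag x signed temporal lag), `dtheta_deg`, `dt`
#'   (signed lags, s), `normalization`.
#' @export
autocorrelation_map <- function(am, max_lag = NULL) {
  stopifnot(inherits(am, "amplitude_map"))
  nt <- ncol(am$r)
  if (nt < 8L) stop_param("autocorrelation needs >= 8 frames")
  n_theta <- nrow(am$r)
  max_lag <- max_lag %||% (nt %/% 2L)
  max_lag <- min(max_lag, nt - 2L)
  delta <- am$r - mean(am$r)
  v0 <- mean(delta^2)
  if (v0 <= .Machine$double.eps)
    stop_param("zero-variance amplitude map: autocorrelation undefined")
  Fm <- stats::mvfft(delta)
  gamma <- matrix(0, n_theta, 2L * max_lag + 1L)
  for (dt in 0:max_lag) {
    cols1 <- seq_len(nt - dt)
    cols2 <- cols1 + dt
    S <- rowSums(Conj(Fm[, cols1, drop = FALSE]) * Fm[, cols2, drop = FALSE])
    cc <- Re(stats::fft(S, inverse = TRUE)) / n_theta # circular sum over theta
    g <- cc / (n_theta * (nt - dt))
    gamma[, max_lag + 1L + dt] <- g
    # negative temporal lag by the symmetry gamma(-dtheta, -dt) = gamma(dtheta, dt)
    gamma[, max_lag + 1L - dt] <- g[c(1L, rev(seq_len(n_theta - 1L) + 1L))]
  }
  gamma <- gamma / gamma[1L, max_lag + 1L]
  dt_s <- c(-rev(seq_len(max_lag)), 0, seq_len(max_lag)) *
    (if (nt > 1) diff(am$time[1:2]) else 1)
  structure(list(gamma = gamma, dtheta_deg = am$theta_deg, dt = dt_s,
                 max_lag = max_lag, normalization = "variance_normalized"),
            class = "autocorr_map")
}

#' @export
print.autocorr_map <- function(x, ...) {
  cat(sprintf("<autocorr_map> %d angular x %d temporal lags (max %g s)\n",
              nrow(x$gamma), ncol(x$gamma), max(x$dt)))
  invisible(x)
}

# ---- mode power spectrum ---------------------------------------------------

#' Angular Fourier mode power spectrum of an amplitude map
#'
#' Per frame, complex coefficients `c_m = (1/n_theta) * sum_theta r(theta) *
#' exp(-i m theta)`. `P_m` is the time average of `|c_m|^2` for `m >= 1`
#' (one-sided convention, so a static `r = R + a cos(2 theta)` gives
#' `P_2 = a^2/4`) and of `(c_0 - mean radius)^2` for `m = 0` (size
#' fluctuation). The total power sums `P_m` over `total_range`
#' (default m = 2..10: m = 0 is size, m = 1 is nulled by the center-of-mass
#' frame); the variant including m = 1 is also reported.
#'
#' @param am an [amplitude_map()].
#' @param max_mode highest mode M (must satisfy `M < n_theta / 2`).
#' @param total_range integer (lo, hi) range summed into `total_power`.
#' @return object of class `mode_spectrum`: `mode` (0..M), `power` (um^2),
#'   `total_power`, `total_power_with_m1`, `mode_range_for_total`.
#' @export
mode_power_spectrum <- function(am, max_mode = 10L, total_range = c(2L, 10L)) {
  stopifnot(inherits(am, "amplitude_map"))
  n_theta <- nrow(am$r)
  if (max_mode >= n_theta / 2)
    stop_param("max_mode = %d aliases: need max_mode < n_theta/2 = %g",
               max_mode, n_theta / 2)
  cm <- stats::mvfft(am$r) / n_theta
  rbar <- mean(am$r)
  powers <- numeric(max_mode + 1L)
  powers[1] <- mean((Re(cm[1L, ]) - rbar)^2)
  for (m in seq_len(max_mode)) {
    powers[m + 1L] <- mean(Mod(cm[m + 1L, ])^2)
  }
  lo <- max(total_range[1], 0L); hi <- min(total_range[2], max_mode)
  total <- sum(powers[(lo:hi) + 1L])
  total_m1 <- sum(powers[(max(1L, min(lo, 1L)):hi) + 1L])
  structure(list(mode = 0:max_mode, power = powers, total_power = total,
                 total_power_with_m1 = total_m1,
                 mode_range_for_total = c(lo, hi)),
            class = "mode_spectrum")
}

#' @export
print.mode_spectrum <- function(x, ...) {
  dom <- x$mode[x$mode >= 1][which.max(x$power[x$mode >= 1])]
  cat(sprintf("<mode_spectrum> m = 0..%d, dominant m = %d, total P(m=%d..%d) = %.4g um^2\n",
              max(x$mode), dom, x$mode_range_for_total[1],
              x$mode_range_for_total[2], x$total_power))
  invisible(x)
}

#' Index of the dominant deformation mode (argmax over m >= 1)
#'
#' @param spectrum a [mode_power_spectrum()] result.
#' @param m_range modes considered (default 1..10).
#' @return integer mode number.
#' @export
dominant_mode <- function(spectrum, m_range = c(1L, 10L)) {
  sel <- spectrum$mode >= m_range[1] & spectrum$mode <= m_range[2]
  spectrum$mode[sel][which.max(spectrum$power[sel])]
}

# ---- motion classification -------------------------------------------------

#' Classify cell motion from amplitude map, autocorrelation and track
#'
#' Decision rules on three features: (i) the mode-2 share of deformation
#' power `P_2 / sum(P_m, m = 1..10)`, (ii) a temporal periodicity score of
#' the autocorrelation at zero angular lag (depth of the anti-correlation dip
#' plus recovery, in [0, ~1]), and (iii) center-of-mass displacement per
#' frame relative to the mean radius. Translational motion wins when (iii)
#' dominates; oscillatory needs both a mode-2-dominated spectrum and a
#' periodic autocorrelation; otherwise the map is featureless / quickly
#' decaying and the label is rotational. If all three features sit within
#' `ambiguity_margin` (relative) of their thresholds the label is
#' `"ambiguous"`.
#'
#' @param am an [amplitude_map()].
#' @param ac optional precomputed [autocorrelation_map()].
#' @param spectrum optional precomputed [mode_power_spectrum()].
#' @param center_track optional n_frames x 2 center positions (um); defaults
#'   to the amplitude map's centroid track.
#' @param drift_threshold threshold on feature (iii).
#' @param mode2_threshold threshold on feature (i).
#' @param periodicity_threshold threshold on feature (ii).
#' @param ambiguity_margin relative band around all thresholds that flags an
#'   ambiguous cell.
#' @return object of class `motion_class`: `label`, `features` (named
#'   numeric), `thresholds`.
#' @export
classify_motion <- function(am, ac = NULL, spectrum = NULL,
                            center_track = NULL,
                            drift_threshold = 0.04,
                            mode2_threshold = 0.5,
                            periodicity_threshold = 0.3,
                            ambiguity_margin = 0.15) {
  stopifnot(inherits(am, "amplitude_map"))
  ac <- ac %||% autocorrelation_map(am)
  spectrum <- spectrum %||% mode_power_spectrum(am, max_mode = 10L)
  center_track <- center_track %||% am$centers

  p <- spectrum$power[spectrum$mode >= 1 & spectrum$mode <= 10]
  mode2_frac <- spectrum$power[spectrum$mode == 2] / sum(p)

  g0 <- ac$gamma[1L, ac$dt >= 0] # zero angular lag, dt = 0..max
  periodicity <- periodicity_score(g0)

  disp <- sqrt(rowSums(diff(center_track)^2))
  drift_ratio <- mean(disp) / mean(am$r)

  feats <- c(mode2_fraction = unname(mode2_frac),
             periodicity = unname(periodicity),
             drift_ratio = unname(drift_ratio))
  thr <- c(mode2_fraction = mode2_threshold,
           periodicity = periodicity_threshold,
           drift_ratio = drift_threshold)

  near <- abs(feats - thr) <= ambiguity_margin * thr
  label <- if (all(near)) {
    "ambiguous"
  } else if (drift_ratio > drift_threshold) {
    "translational"
  } else if (mode2_frac > mode2_threshold && periodicity > periodicity_threshold) {
    "oscillatory"
  } else {
    "rotational"
  }
  structure(list(label = label, features = feats, thresholds = thr),
            class = "motion_class")
}

# Depth-and-recovery score of an autocorrelation trace g(dt), g(0) = 1:
# oscillatory traces dip negative and recover; monotone decays score ~ 0.
periodicity_score <- function(g0) {
  n <- length(g0)
  if (n < 3L) return(0)
  i_min <- which.min(g0[-1L]) + 1L
  g_min <- g0[i_min]
  if (i_min >= n) return(max(0, -g_min) / 2)
  rec <- max(g0[(i_min + 1L):n])
  max(0, (rec - g_min) / 2)
}

#' @export
print.motion_class <- function(x, ...) {
  cat(sprintf("<motion_class> %s (m2 frac %.2f, periodicity %.2f, drift %.3f)\n",
              x$label, x$features["mode2_fraction"], x$features["periodicity"],
              x$features["drift_ratio"]))
  invisible(x)
}
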