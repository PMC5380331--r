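# Synthetic cell-contour time series emulating the three locomotion
# phenotypes seen for stem cells on ligand-functionalized membranes:
# rotational (round cell, slow rigid rotation of a weak irregularity),
# oscillatory (mode-2 pseudopod elongation alternating between perpendicular
# axes), translational (mild static deformation plus center-of-mass drift).

#' Motion parameters for the synthetic contour generator
#'
#' Defaults describe the imaging conditions of the time-lapse assay the
#' generator emulates: frames every 40 s (0.025 Hz), 90 frames (1 h), cells of
#' ~5 um radius with ~1 um pseudopod elongation. The oscillation period is the
#' time for a full elongate-retract-elongate-perpendicular cycle, i.e. the
#' elongation axis switches every half period.
#'
#' @param motion_class one of `"rotational"`, `"oscillatory"`,
#'   `"translational"`.
#' @param base_radius mean cell radius (um), > 0.
#' @param mode2_amplitude elongation amplitude (um); must stay below
#'   `base_radius` so contours remain star-shaped.
#' @param oscillation_period full oscillation cycle (s); axis switches every
#'   half period. Must be positive.
#' @param rotation_rate rigid rotation rate (degrees/s) for the rotational
#'   class.
#' @param drift_velocity center-of-mass drift speed (um/s) for the
#'   translational class.
#' @param contour_noise_sd per-vertex radial noise SD (um).
#' @param n_frames number of frames, >= 2.
#' @param frame_interval time between frames (s).
#' @param n_vertices polygon vertices per frame.
#' @param seed integer seed; identical parameters + seed give bit-identical
#'   series.
#' @return an object of class `motion_params`.
#' @export
motion_params <- function(motion_class = c("rotational", "oscillatory", "translational"),
                          base_radius = 5,
                          mode2_amplitude = 1,
                          oscillation_period = 800,
                          rotation_rate = 0.04,
                          drift_velocity = 0.01,
                          contour_noise_sd = 0.1,
                          n_frames = 90,
                          frame_interval = 40,
                          n_vertices = 180,
                          seed = NULL) {
  motion_class <- match.arg(motion_class)
  if (!is.numeric(base_radius) || base_radius <= 0)
    stop_param("base_radius must be > 0")
  if (mode2_amplitude < 0 || mode2_amplitude >= base_radius)
    stop_param("mode2_amplitude must be in [0, base_radius) to keep contours star-shaped")
  if (oscillation_period <= 0) stop_param("oscillation_period must be positive")
  if (contour_noise_sd < 0) stop_param("contour_noise_sd must be >= 0")
  if (n_frames < 2) stop_param("n_frames must be >= 2")
  if (frame_interval <= 0) stop_param("frame_interval must be positive")
  if (n_vertices < 8) stop_param("n_vertices must be >= 8")
  structure(list(
    motion_class = motion_class, base_radius = base_radius,
    mode2_amplitude = mode2_amplitude, oscillation_period = oscillation_period,
    rotation_rate = rotation_rate, drift_velocity = drift_velocity,
    contour_noise_sd = contour_noise_sd, n_frames = as.integer(n_frames),
    frame_interval = frame_interval, n_vertices = as.integer(n_vertices),
    seed = seed
  ), class = "motion_params")
}

# Elongation axis for the oscillatory class: square wave 0 <-> 90 degrees
# switching every half period, with smoothstep transitions each taking 10% of
# the period. The record starts mid-plateau (axis 0), so the first switch
# happens a quarter period in.
oscillation_axis <- function(t, period) {
  v <- (2 * t / period + 0.5) %% 2   # one unit per half period
  k <- round(v)                      # nearest switch index
  d <- v - k
  w <- 0.1                           # half-width of transition, in v units
  plateau <- floor(v) %% 2
  from <- (k - 1) %% 2
  to <- k %% 2
  s <- smoothstep((d + w) / (2 * w))
  frac <- ifelse(abs(d) < w, from + (to - from) * s, plateau)
  (pi / 2) * frac
}

#' Generate a synthetic contour time series with known ground truth
#'
#' Produces per-frame closed polygons (absolute coordinates, um) plus the
#' noise-free radial ground truth. All three classes build the contour as
#' `r(theta, t) = base_radius + deformation(theta, t) + noise`, so every frame
#' is star-shaped about its own center by construction.
#'
#' * `oscillatory`: `deformation = a * cos(2 * (theta - psi(t)))` with the
#'   elongation axis `psi` switching between 0 and 90 degrees every half
#'   `oscillation_period` (smooth 10%-period transitions).
#' * `rotational`: a fixed irregular shape (modes 2-5, amplitudes
#'   0.25 * `mode2_amplitude` x (0.45, 0.30, 0.15, 0.10), seeded random
#'   phases) rotating rigidly at `rotation_rate`.
#' * `translational`: a mild static deformation (half amplitude, modes 2-3)
#'   with the center of mass drifting at `drift_velocity` along a seeded
#'   random direction.
#'
#' @param params a [motion_params()] object.
#' @return object of class `contour_series`: list with `polygons` (list of
#'   n x 2 matrices), `time` (s), `centers` (ground-truth centers, n_frames x 2),
#'   `theta` (vertex angles, radians), `r` (vertex radii incl. noise,
#'   n_vertices x n_frames), `r_true` (noise-free radii), and `params`.
#' @export
make_contour_series <- function(params) {
  stopifnot(inherits(params, "motion_params"))
  p <- params
  with_seed(p$seed, {
    theta <- seq(0, 2 * pi, length.out = p$n_vertices + 1L)[-(p$n_vertices + 1L)]
    tt <- (seq_len(p$n_frames) - 1L) * p$frame_interval
    centers <- matrix(0, p$n_frames, 2L)
    r_true <- matrix(p$base_radius, p$n_vertices, p$n_frames)

    if (p$motion_class == "oscillatory") {
      psi <- oscillation_axis(tt, p$oscillation_period)
      for (k in seq_len(p$n_frames)) {
        r_true[, k] <- p$base_radius +
          p$mode2_amplitude * cos(2 * (theta - psi[k]))
      }
    } else if (p$motion_class == "rotational") {
      amp <- 0.25 * p$mode2_amplitude * c(0.45, 0.30, 0.15, 0.10)
      phase <- stats::runif(4L, 0, 2 * pi)
      omega <- p$rotation_rate * pi / 180 # rad/s
      for (k in seq_len(p$n_frames)) {
        th <- theta - omega * tt[k]
        defo <- amp[1] * cos(2 * th + phase[1]) + amp[2] * cos(3 * th + phase[2]) +
          amp[3] * cos(4 * th + phase[3]) + amp[4] * cos(5 * th + phase[4])
        r_true[, k] <- p$base_radius + defo
      }
    } else { # translational
      amp <- 0.5 * p$mode2_amplitude * c(0.7, 0.3)
      phase <- stats::runif(2L, 0, 2 * pi)
      defo <- amp[1] * cos(2 * theta + phase[1]) + amp[2] * cos(3 * theta + phase[2])
      dir <- stats::runif(1L, 0, 2 * pi)
      for (k in seq_len(p$n_frames)) {
        r_true[, k] <- p$base_radius + defo
        centers[k, ] <- p$drift_velocity * tt[k] * c(cos(dir), sin(dir))
      }
    }

    noise <- if (p$contour_noise_sd > 0) {
      matrix(stats::rnorm(p$n_vertices * p$n_frames, 0, p$contour_noise_sd),
             p$n_vertices, p$n_frames)
    } else matrix(0, p$n_vertices, p$n_frames)
    r <- r_true + noise
    if (any(r <= 0))
      stop_param("noise drove a contour radius non-positive; reduce contour_noise_sd")

    polygons <- lapply(seq_len(p$n_frames), function(k) {
      cbind(x = centers[k, 1] + r[, k] * cos(theta),
            y = centers[k, 2] + r[, k] * sin(theta))
    })
    structure(list(polygons = polygons, time = tt, centers = centers,
                   theta = theta, r = r, r_true = r_true, params = p),
              class = "contour_series")
  })
}

#' @export
print.contour_series <- function(x, ...) {
  cat(sprintf("<contour_series> %s: %d frames x %d vertices, dt = %g s\n",
              x$params$motion_class, x$params$n_frames, x$params$n_vertices,
              x$params$frame_interval))
  invisible(x)
}
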