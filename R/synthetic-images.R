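# Synthetic image rendering: phase-contrast-like frames from contour series
# and RICM interferograms from known height maps. Both return ground truth
# alongside the data so downstream estimators can be scored against it.

#' Imaging scene parameters
#'
#' @param pixel_size um per pixel, > 0.
#' @param image_shape integer (rows, cols).
#' @param photon_budget expected photon counts per background pixel; shot
#'   noise is Poisson at this budget. Use `Inf` for a noiseless render.
#' @param background_level background intensity (arbitrary units).
#' @return object of class `scene_params`.
#' @export
scene_params <- function(pixel_size = 0.2, image_shape = c(128L, 128L),
                         photon_budget = 1000, background_level = 1) {
  if (pixel_size <= 0) stop_param("pixel_size must be > 0")
  if (photon_budget <= 0) stop_param("photon_budget must be > 0")
  if (length(image_shape) != 2L || any(image_shape < 8))
    stop_param("image_shape must be (rows, cols), each >= 8")
  if (background_level <= 0) stop_param("background_level must be > 0")
  structure(list(pixel_size = pixel_size,
                 image_shape = as.integer(image_shape),
                 photon_budget = photon_budget,
                 background_level = background_level),
            class = "scene_params")
}

# Pixel-centre coordinate grids, origin at the image centre (um).
# Rows map to y (increasing downwards is irrelevant here), cols to x.
scene_grid <- function(scene) {
  nr <- scene$image_shape[1]; nc <- scene$image_shape[2]
  x <- (seq_len(nc) - (nc + 1) / 2) * scene$pixel_size
  y <- (seq_len(nr) - (nr + 1) / 2) * scene$pixel_size
  list(x = matrix(x, nr, nc, byrow = TRUE), y = matrix(y, nr, nc))
}

apply_shot_noise <- function(img, photon_budget) {
  if (!is.finite(photon_budget)) return(img)
  matrix(stats::rpois(length(img), pmax(img, 0) * photon_budget),
         nrow(img), ncol(img)) / photon_budget
}

# Periodic linear interpolation of radii sampled at `theta` onto `th`.
interp_radius <- function(theta, r, th) {
  n <- length(theta)
  stats::approx(c(theta, theta[1] + 2 * pi), c(r, r[1]),
                xout = th %% (2 * pi), rule = 2)$y
}

#' Render a phase-contrast-like image stack from a contour series
#'
#' Produces a dark cell body with a bright halo centred on the contour, over a
#' uniform background, plus Poisson shot noise at the scene's photon budget.
#' The ground-truth pixel masks are returned alongside.
#'
#' @param contours a `contour_series` from [make_contour_series()], or a list
#'   of n x 2 polygon matrices (um, image-centred coordinates).
#' @param scene a [scene_params()] object.
#' @param halo_width half-width of the bright halo (um).
#' @param body_level cell-interior intensity relative to background.
#' @param halo_level halo intensity relative to background.
#' @param seed integer seed for the shot noise.
#' @return list with `images` (rows x cols x frames array), `masks`
#'   (logical ground-truth cell masks), `scene`, and `contours`.
#' @export
render_phase_contrast <- function(contours, scene = scene_params(),
                                  halo_width = 0.3, body_level = 0.6,
                                  halo_level = 1.6, seed = NULL) {
  polys <- if (inherits(contours, "contour_series")) contours$polygons else contours
  stopifnot(length(polys) >= 1L)
  g <- scene_grid(scene)
  half_x <- max(abs(g$x)); half_y <- max(abs(g$y))
  nr <- scene$image_shape[1]; nc <- scene$image_shape[2]
  images <- array(0, c(nr, nc, length(polys)))
  masks <- array(FALSE, c(nr, nc, length(polys)))
  with_seed(seed, {
    for (k in seq_along(polys)) {
      p <- polys[[k]]
      if (any(abs(p[, 1]) > half_x) || any(abs(p[, 2]) > half_y))
        stop_param("contour exits the image frame at frame %d", k)
      ctr <- polygon_centroid(p)
      vtheta <- atan2(p[, 2] - ctr[2], p[, 1] - ctr[1]) %% (2 * pi)
      ord <- order(vtheta)
      vr <- sqrt((p[, 1] - ctr[1])^2 + (p[, 2] - ctr[2])^2)
      pth <- atan2(g$y - ctr[2], g$x - ctr[1])
      pr <- sqrt((g$x - ctr[1])^2 + (g$y - ctr[2])^2)
      rb <- matrix(interp_radius(vtheta[ord], vr[ord], pth), nr, nc)
      inside <- pr <= rb
      halo <- abs(pr - rb) <= halo_width
      img <- matrix(scene$background_level, nr, nc)
      img[inside] <- scene$background_level * body_level
      img[halo] <- scene$background_level * halo_level
      images[, , k] <- apply_shot_noise(img, scene$photon_budget)
      masks[, , k] <- inside
    }
  })
  list(images = images, masks = masks, scene = scene, contours = contours)
}

#' Render an RICM interferogram scene from a known height profile
#'
#' Builds a ground-truth membrane-substrate height map on the pixel grid,
#' pushes it through the finite-INA two-beam interference model
#' ([forward_intensity()]), and adds Poisson shot noise per frame. A sequence
#' of frames (default 20, matching the acquisition protocol the model
#' emulates) shares the truth and differs only in noise.
#'
#' @param height_profile either a function `h(rho)` of radial distance from
#'   the image centre (um) returning heights in nm, or a rows x cols matrix
#'   of heights (nm).
#' @param optics an [optical_model()].
#' @param scene a [scene_params()].
#' @param n_frames frames in the rendered sequence.
#' @param invertible if `TRUE` (default), refuse height maps leaving the
#'   first monotone interference branch, so round-trip reconstruction is
#'   well-posed.
#' @param seed integer seed for the shot noise.
#' @return list with `height` (ground-truth matrix, nm), `images`
#'   (rows x cols x n_frames), `optics`, `scene`.
#' @export
make_ricm_scene <- function(height_profile, optics = optical_model(),
                            scene = scene_params(), n_frames = 20L,
                            invertible = TRUE, seed = NULL) {
  g <- scene_grid(scene)
  h <- if (is.function(height_profile)) {
    rho <- sqrt(g$x^2 + g$y^2)
    matrix(height_profile(rho), nrow(rho), ncol(rho))
  } else {
    stopifnot(is.matrix(height_profile),
              all(dim(height_profile) == scene$image_shape))
    height_profile
  }
  if (any(h < 0)) stop_param("heights must be >= 0")
  hb <- first_branch_limit(optics)
  if (invertible && any(h > hb))
    stop_param("heights exceed the first interference branch (%.1f nm); pass invertible = FALSE", hb)
  ideal <- forward_intensity(h, optics) * scene$background_level
  images <- array(0, c(dim(h), n_frames))
  with_seed(seed, {
    for (k in seq_len(n_frames)) {
      images[, , k] <- apply_shot_noise(ideal, scene$photon_budget)
    }
  })
  list(height = h, images = images, ideal = ideal,
       optics = optics, scene = scene)
}
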