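# Rendering: mask area oracle, Poisson-noise contract, frame-exit errors,
# RICM scene construction, PGM round trip.

test_that("noise-free disc render has mask area within 2% of pi r^2", {
  disc <- make_contour_series(motion_params("oscillatory", mode2_amplitude = 0,
                                            contour_noise_sd = 0, n_frames = 2,
                                            seed = 1))
  sc <- scene_params(pixel_size = 0.2, image_shape = c(96, 96),
                     photon_budget = Inf)
  rp <- render_phase_contrast(disc, sc)
  area <- sum(rp$masks[, , 1]) * sc$pixel_size^2
  expect_lt(abs(area - pi * 25) / (pi * 25), 0.02)
})

test_that("infinite photon budget renders exactly the noiseless image", {
  disc <- make_contour_series(motion_params("rotational", n_frames = 2, seed = 2))
  sc_inf <- scene_params(photon_budget = Inf, image_shape = c(64, 64))
  a <- render_phase_contrast(disc, sc_inf, seed = 1)
  b <- render_phase_contrast(disc, sc_inf, seed = 99)
  expect_identical(a$images, b$images) # no stochastic term left
  sc_noisy <- scene_params(photon_budget = 500, image_shape = c(64, 64))
  n1 <- render_phase_contrast(disc, sc_noisy, seed = 4)
  n2 <- render_phase_contrast(disc, sc_noisy, seed = 4)
  expect_identical(n1$images, n2$images) # seeded RNG contract
  expect_false(identical(n1$images, a$images))
})

test_that("a contour leaving the frame raises an error naming the frame", {
  cs <- make_contour_series(motion_params("translational", drift_velocity = 0.2,
                                          n_frames = 12, seed = 3))
  sc <- scene_params(pixel_size = 0.2, image_shape = c(64, 64))
  expect_error(render_phase_contrast(cs, sc), "frame [0-9]+")
})

test_that("two frames with a known 3-px shift cross-correlate at (3, 0)", {
  disc <- make_contour_series(motion_params("oscillatory", mode2_amplitude = 0,
                                            contour_noise_sd = 0, n_frames = 2,
                                            seed = 1))
  rp <- render_phase_contrast(disc, scene_params(photon_budget = Inf,
                                                 image_shape = c(64, 64)))
  a <- rp$images[, , 1]
  b <- hscadhesion:::shift_matrix(a, 3, 0)
  # brute-force correlation oracle over candidate shifts
  best <- c(NA, NA); best_v <- -Inf
  for (dr in -5:5) for (dc in -5:5) {
    v <- sum(a * hscadhesion:::shift_matrix(b, dr, dc))
    if (v > best_v) { best_v <- v; best <- c(dr, dc) }
  }
  expect_equal(best, c(-3, 0)) # undoing the shift maximises overlap
  pk <- hscadhesion:::xcorr_peak(a, b)
  expect_equal(unname(pk$shift), c(3, 0))
})

test_that("make_ricm_scene applies the forward model pixelwise with seeded noise", {
  opt <- optical_model()
  sc <- scene_params(pixel_size = 0.2, image_shape = c(48, 48),
                     photon_budget = 2000)
  z <- make_ricm_scene(tight_disc_profile, opt, sc, n_frames = 3, seed = 11)
  expect_equal(z$ideal, forward_intensity(z$height, opt), tolerance = 1e-12)
  z2 <- make_ricm_scene(tight_disc_profile, opt, sc, n_frames = 3, seed = 11)
  expect_identical(z$images, z2$images)
  # flat h = 0 scene is the uniform intensity minimum
  flat <- make_ricm_scene(function(rho) rho * 0, opt,
                          scene_params(image_shape = c(16, 16),
                                       photon_budget = Inf), n_frames = 2)
  expect_equal(max(flat$ideal) - min(flat$ideal), 0)
  expect_equal(flat$ideal[1, 1], min(forward_intensity(seq(0, 100, 1), opt)))
})

test_that("ricm scenes leaving the first branch are refused when invertibility is requested", {
  opt <- optical_model()
  hb <- first_branch_limit(opt)
  too_high <- function(rho) rho * 0 + hb + 5
  expect_error(make_ricm_scene(too_high, opt,
                               scene_params(image_shape = c(16, 16))),
               "first interference branch")
  expect_silent(make_ricm_scene(too_high, opt,
                                scene_params(image_shape = c(16, 16)),
                                invertible = FALSE, seed = 1))
})

test_that("PGM stack IO round-trips within quantisation error", {
  x <- array(runif(32 * 16 * 3, 0, 2), c(32, 16, 3))
  p <- withr::local_tempfile(fileext = ".pgm")
  write_pgm_stack(x, p)
  y <- read_pgm_stack(p)
  expect_equal(dim(y), dim(x))
  expect_lt(max(abs(x - y)), 2 / 65535 * max(x))
})
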