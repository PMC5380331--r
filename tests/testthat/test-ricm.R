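# RICM optics: forward model, illumination correction, first-branch height
# inversion, tight-adhesion area.

test_that("contact is dark and the INA = 0 model is strictly periodic", {
  opt <- optical_model()
  h <- seq(0, 400, by = 0.5)
  I <- forward_intensity(h, opt)
  expect_equal(which.min(I), 1L) # h = 0 global minimum
  expect_error(forward_intensity(-1, opt), ">= 0")

  opt0 <- optical_model(ina = 0)
  period <- 546 / (2 * 1.335) # 204.49 nm
  h0 <- seq(0, 300, by = 1)
  expect_equal(forward_intensity(h0, opt0),
               forward_intensity(h0 + period, opt0), tolerance = 1e-9)
  expect_equal(first_branch_limit(opt0), 546 / (4 * 1.335))
})

test_that("finite-INA visibility envelope decreases with height", {
  # brute-force quadrature oracle for the angular average of the cosine
  opt <- optical_model()
  cmax <- cos(asin(opt$ina / opt$n3))
  brute_env <- function(h) {
    phi <- 4 * pi * opt$n3 * h / opt$wavelength
    u <- seq(cmax, 1, length.out = 20001)
    vals <- cos(phi * u + pi)
    mean(vals)
  }
  hs <- seq(5, 500, by = 5)
  model <- forward_intensity(hs, opt)
  fr <- hscadhesion:::fresnel_amplitudes(opt)
  oracle <- 1 + fr$visibility * vapply(hs, brute_env, numeric(1))
  expect_equal(model, oracle, tolerance = 1e-5)
  # fringe-visibility envelope decreasing in h: brute-force complex quadrature
  # of the angular average, |mean(exp(i phi u))| over the illumination cone
  brute_vis <- function(h) {
    phi <- 4 * pi * opt$n3 * h / opt$wavelength
    u <- seq(cmax, 1, length.out = 5001)
    Mod(mean(exp(1i * phi * u)))
  }
  vis <- vapply(seq(0, 800, by = 10), brute_vis, numeric(1))
  expect_true(all(diff(vis) < 0))
})

test_that("illumination correction flattens a paraboloid and suppresses noise", {
  # flat unit stack is unchanged
  flat <- array(1, c(32, 32, 3))
  cf <- correct_illumination(flat)
  expect_equal(cf$aggregate, matrix(1, 32, 32), tolerance = 1e-10)

  # synthetic paraboloid x flat scene -> residual flat within 0.5%
  xg <- (seq_len(64) - 32.5) / 64
  par2d <- 1 - 0.3 * outer(xg^2, rep(1, 64)) - 0.3 * outer(rep(1, 64), xg^2)
  st <- array(rep(2 * par2d, 4), c(64, 64, 4))
  cc <- correct_illumination(st)
  expect_lt((max(cc$aggregate) - min(cc$aggregate)) / mean(cc$aggregate), 0.005)

  # 20 Poisson frames: per-pixel noise reduced by ~ sqrt(20) vs single frame
  set.seed(42)
  st2 <- array(rpois(48 * 48 * 20, 200) / 200, c(48, 48, 20))
  c2 <- correct_illumination(st2)
  ratio <- sd(st2[, , 1]) / sd(c2$aggregate)
  expect_gt(ratio, sqrt(20) * 0.95)

  expect_error(correct_illumination(matrix(1, 8, 8)), "frames")
})

test_that("noise-free forward/inverse round trip is exact to < 2 nm", {
  opt <- optical_model()
  sc <- make_ricm_scene(tight_disc_profile, opt,
                        scene_params(pixel_size = 0.2, image_shape = c(64, 64),
                                     photon_budget = Inf),
                        n_frames = 2, seed = 1)
  hm <- reconstruct_height(sc$images, opt)
  expect_true(all(hm$valid_mask))
  expect_lt(max(abs(hm$mean_height - sc$height)), 2)
  # uniform image at I(0) inverts to h = 0 everywhere
  u <- array(forward_intensity(0, opt), c(16, 16, 2))
  h0 <- reconstruct_height(u, opt)
  expect_equal(max(h0$mean_height), 0, tolerance = 1e-9)
})

test_that("noisy round trip: RMS < 5 nm at photon budget 1e4, and error shrinks with budget", {
  opt <- optical_model(pixel_size = 0.1)
  scene <- function(budget) scene_params(pixel_size = 0.1,
                                         image_shape = c(96, 96),
                                         photon_budget = budget)
  truth <- make_ricm_scene(tight_disc_profile, opt, scene(Inf), n_frames = 2,
                           seed = 1)$height
  rms <- vapply(c(1e3, 1e4, 1e5), function(b) {
    sc <- make_ricm_scene(tight_disc_profile, opt, scene(b), n_frames = 20,
                          seed = 7)
    hm <- reconstruct_height(correct_illumination(sc$images), opt)
    sqrt(mean((hm$mean_height[hm$valid_mask] - truth[hm$valid_mask])^2))
  }, numeric(1))
  expect_lt(rms[2], 5)
  expect_true(all(diff(rms) < 0)) # monotone in photon budget
})

test_that("pixels outside the invertible range are flagged, with a warning over 20%", {
  opt <- optical_model()
  bad <- array(10, c(10, 10, 2)) # far above any model intensity
  expect_warning(hm <- reconstruct_height(bad, opt), "outside")
  expect_true(all(!hm$valid_mask))
})

test_that("tight-adhesion area matches the disc oracle and its invariances", {
  opt <- optical_model(pixel_size = 0.1)
  sc <- make_ricm_scene(tight_disc_profile, opt,
                        scene_params(pixel_size = 0.1, image_shape = c(96, 96),
                                     photon_budget = Inf),
                        n_frames = 2, seed = 1)
  hm <- reconstruct_height(sc$images, opt)
  ta <- tight_adhesion_area(hm)
  expect_lt(abs(ta$area_um2 - 16.0), 0.3) # pi * 2.26^2 = 16.05
  expect_false(ta$empty)

  # all pixels above h_max -> 0 with empty flag, not an error
  flat50 <- reconstruct_height(array(forward_intensity(50, opt),
                                     c(16, 16, 2)), opt)
  ta0 <- tight_adhesion_area(flat50, h_max = 40)
  expect_equal(ta0$area_um2, 0)
  expect_true(ta0$empty)

  # rotation by 90 deg and whole-pixel translation leave the area unchanged
  rot <- hm
  rot$mean_height <- t(hm$mean_height)[ncol(hm$mean_height):1, ]
  rot$height_std <- t(hm$height_std)[ncol(hm$height_std):1, ]
  rot$valid_mask <- t(hm$valid_mask)[ncol(hm$valid_mask):1, ]
  expect_equal(tight_adhesion_area(rot)$area_um2, ta$area_um2)
  sh <- hm
  sh$mean_height <- hscadhesion:::shift_matrix(hm$mean_height, 5, -3)
  sh$height_std <- hscadhesion:::shift_matrix(hm$height_std, 5, -3)
  sh$valid_mask <- hscadhesion:::shift_matrix(hm$valid_mask * 1, 5, -3) > 0.5
  expect_equal(tight_adhesion_area(sh)$area_um2, ta$area_um2)

  # discretisation convergence: halving the pixel size changes area < 2%
  opt2 <- optical_model(pixel_size = 0.05)
  sc2 <- make_ricm_scene(tight_disc_profile, opt2,
                         scene_params(pixel_size = 0.05,
                                      image_shape = c(192, 192),
                                      photon_budget = Inf),
                         n_frames = 2, seed = 1)
  ta2 <- tight_adhesion_area(reconstruct_height(sc2$images, opt2))
  expect_lt(abs(ta2$area_um2 - ta$area_um2) / ta$area_um2, 0.02)
})
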