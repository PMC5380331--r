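# Morphodynamics: drift correction, contour extraction, amplitude maps,
# autocorrelation, mode spectra, classification.

test_that("drift correction recovers synthetic shifts and leaves still stacks alone", {
  disc <- make_contour_series(motion_params("oscillatory", mode2_amplitude = 0,
                                            contour_noise_sd = 0, n_frames = 2,
                                            seed = 1))
  base <- render_phase_contrast(disc, scene_params(photon_budget = Inf,
                                                   image_shape = c(64, 64)))$images[, , 1]
  still <- array(rep(base, 4), c(64, 64, 4))
  d0 <- drift_correct(still)
  expect_true(all(d0$shifts == 0))

  drifted <- array(0, c(64, 64, 5))
  for (k in 1:5) drifted[, , k] <- hscadhesion:::shift_matrix(base, 2 * (k - 1), k - 1)
  dc <- drift_correct(drifted)
  expect_equal(dc$shifts[, "row"], c(0, -2, -4, -6, -8))
  expect_equal(dc$shifts[, "col"], c(0, -1, -2, -3, -4))
  expect_false(any(dc$flagged))
})

test_that("drift + deformation leaves residual centre motion below 1 px/frame", {
  cs <- make_contour_series(motion_params("rotational", seed = 13, n_frames = 6,
                                          rotation_rate = 0.2,
                                          contour_noise_sd = 0.05))
  sc <- scene_params(pixel_size = 0.2, image_shape = c(96, 96),
                     photon_budget = Inf)
  rp <- render_phase_contrast(cs, sc)
  drifted <- array(0, dim(rp$images))
  for (k in 1:6) drifted[, , k] <- hscadhesion:::shift_matrix(rp$images[, , k],
                                                              2 * (k - 1), 0)
  reg <- drift_correct(drifted)
  centers <- t(vapply(1:6, function(k) {
    attr(extract_contour(reg$stack[, , k], pixel_size = 0.2,
                         frame_index = k), "center_px")
  }, numeric(2)))
  step <- sqrt(rowSums(diff(centers)^2))
  expect_lt(max(step), 1)
})

test_that("contour extraction recovers disc radius and ellipse aspect ratio", {
  disc <- make_contour_series(motion_params("oscillatory", mode2_amplitude = 0,
                                            contour_noise_sd = 0, n_frames = 2,
                                            seed = 1))
  rp <- render_phase_contrast(disc, scene_params(pixel_size = 0.2,
                                                 image_shape = c(96, 96),
                                                 photon_budget = Inf))
  poly <- extract_contour(rp$images[, , 1], pixel_size = 0.2)
  r_eq <- sqrt(abs(hscadhesion:::polygon_area(poly)) / pi)
  expect_lt(abs(r_eq - 5) / 5, 0.02)

  ell <- ellipse_polygon(6, 4)
  rpe <- render_phase_contrast(list(ell), scene_params(pixel_size = 0.2,
                                                       image_shape = c(96, 96),
                                                       photon_budget = Inf))
  pe <- extract_contour(rpe$images[, , 1], pixel_size = 0.2)
  ex <- pe[, 1] - attr(pe, "center_um")[1]
  ey <- pe[, 2] - attr(pe, "center_um")[2]
  aspect <- max(abs(ex)) / max(abs(ey))
  expect_lt(abs(aspect - 1.5) / 1.5, 0.03)

  expect_error(extract_contour(matrix(1, 32, 32), frame_index = 7), "7")
})

test_that("amplitude map reproduces circles, ellipses and the oscillatory closed form", {
  # circle with an offset centre: r(theta) = R in the centre-of-mass frame
  th <- theta_grid(500)
  circ <- cbind(3 + 5 * cos(th), -2 + 5 * sin(th))
  am <- amplitude_map(list(circ, circ), n_theta = 360)
  expect_lt(max(abs(am$r - 5)), 1e-3) # chord-vs-arc discretisation only
  expect_equal(am$centers[1, ], c(3, -2), tolerance = 1e-5)

  # dense-polygon ellipse oracle
  ame <- amplitude_map(list(ellipse_polygon(6, 4)), n_theta = 360)
  oracle <- ellipse_radius(ame$theta_deg, 6, 4)
  expect_lt(max(abs(ame$r[, 1] - oracle) / oracle), 0.01)

  # generator oscillatory series matches R + a*cos(2(theta - psi)) within noise
  cs <- make_contour_series(motion_params("oscillatory", contour_noise_sd = 0.05,
                                          n_frames = 12, seed = 21))
  amg <- amplitude_map(cs, n_theta = 180)
  interp_truth <- apply(cs$r_true, 2, function(v)
    approx(c(cs$theta, 2 * pi), c(v, v[1]), xout = amg$theta_deg * pi / 180)$y)
  expect_lt(max(abs(amg$r - interp_truth)), 0.25) # few noise SDs
})

test_that("autocorrelation map normalization, symmetry and closed form hold", {
  nt <- 40L
  th <- theta_grid(90)
  omega <- 2 * pi / 10 # 10-frame period
  r <- 5 + outer(cos(2 * th), cos(omega * (0:(nt - 1))))
  am <- am_from_matrix(r)
  ac <- autocorrelation_map(am)
  i0 <- which(ac$dt == 0)
  expect_equal(ac$gamma[1, i0], 1)
  expect_true(all(abs(ac$gamma) <= 1 + 1e-8))
  # gamma(dtheta, dt) == gamma(-dtheta, -dt)
  flip_th <- c(1L, rev(seq_len(nrow(ac$gamma))[-1]))
  expect_equal(ac$gamma, ac$gamma[flip_th, rev(seq_len(ncol(ac$gamma)))],
               tolerance = 1e-10)
  # closed form cos(2 dtheta) * cos(omega dt); the finite-window estimator
  # deviates from it by a few percent except at whole-period lags
  lag_frames <- ac$dt[ac$dt >= 0] / 40
  oracle <- outer(cos(2 * th), cos(omega * lag_frames))
  expect_lt(max(abs(ac$gamma[, ac$dt >= 0] - oracle)), 0.08)
  ridge <- ac$gamma[, i0 + 10] # one temporal period later
  expect_gt(ridge[1], 0.99) # dtheta = 0
  expect_gt(ridge[which.min(abs(ac$dtheta_deg - 180))], 0.99)

  expect_error(autocorrelation_map(am_from_matrix(r[, 1:4])), ">= 8")
  expect_error(autocorrelation_map(am_from_matrix(matrix(5, 90, 20))),
               "zero-variance")
})

test_that("white-noise amplitude maps stay at the autocorrelation noise floor", {
  set.seed(99)
  r <- 5 + matrix(rnorm(180 * 60, 0, 0.2), 180, 60)
  ac <- autocorrelation_map(am_from_matrix(r))
  g <- ac$gamma[, ac$dt >= 0]
  g[1, 1] <- NA # zero lag
  n_eff <- 180 * (60 - ac$max_lag)
  frac_above <- mean(abs(g) > 3 / sqrt(n_eff), na.rm = TRUE)
  expect_lt(frac_above, 0.02) # ~ 3-sigma exceedances only
  expect_lt(max(abs(g), na.rm = TRUE), 6 / sqrt(n_eff))
})

test_that("mode spectrum: circle, static mode-2 and Parseval", {
  th <- theta_grid(360)
  # circle: no deformation power
  spc <- mode_power_spectrum(am_from_matrix(matrix(5, 360, 4) + 0))
  expect_equal(sum(spc$power[spc$mode >= 1]), 0, tolerance = 1e-20)
  # static r = R + a cos(2 theta): P2 = a^2/4 one-sided, others zero
  a <- 0.8
  r2 <- matrix(5 + a * cos(2 * th), 360, 5)
  sp2 <- mode_power_spectrum(am_from_matrix(r2))
  expect_equal(sp2$power[sp2$mode == 2], a^2 / 4, tolerance = 1e-12)
  expect_lt(max(sp2$power[!(sp2$mode %in% c(0, 2))]), 1e-20)
  expect_error(mode_power_spectrum(am_from_matrix(r2), max_mode = 180), "alias")

  # Parseval (counting +-m) against the direct mean squared deviation
  set.seed(5)
  rr <- 5 + 0.5 * cos(2 * th) %o% cos(0.3 * (0:19)) +
    0.2 * cos(5 * th + 1) %o% rep(1, 20)
  am <- am_from_matrix(rr)
  sp <- mode_power_spectrum(am, max_mode = 179L)
  msd <- mean((rr - mean(rr))^2)
  tot <- sp$power[1] + 2 * sum(sp$power[-1])
  expect_equal(tot, msd, tolerance = 1e-10)

  # injected modes recovered with < 1% amplitude error at 360 bins
  inj <- 5 + 0.5 * cos(3 * th - 0.7) + 0.2 * cos(7 * th + 0.1)
  spi <- mode_power_spectrum(am_from_matrix(matrix(inj, 360, 3)))
  expect_equal(2 * sqrt(spi$power[spi$mode == 3]), 0.5, tolerance = 0.01)
  expect_equal(2 * sqrt(spi$power[spi$mode == 7]), 0.2, tolerance = 0.01)

  # spectrum invariant under a global rotation of all contours
  csr <- make_contour_series(motion_params("oscillatory", seed = 3, n_frames = 10))
  rot <- lapply(csr$polygons, function(p) {
    ang <- 0.7
    cbind(p[, 1] * cos(ang) - p[, 2] * sin(ang),
          p[, 1] * sin(ang) + p[, 2] * cos(ang))
  })
  sp_a <- mode_power_spectrum(amplitude_map(csr))
  sp_b <- mode_power_spectrum(amplitude_map(rot, time = csr$time))
  # deformation powers move phase only; m = 0 differs at the ray-sampling
  # discretisation level and is excluded
  expect_equal(sp_a$power[-1], sp_b$power[-1], tolerance = 1e-3)
})

test_that("non-star-shaped frames are repaired when isolated, aborted when run long", {
  th <- theta_grid(200)
  good <- cbind(5 * cos(th), 5 * sin(th))
  hook <- cbind(c(5 * cos(th), 2 + 1.5 * cos(rev(th))),
                c(5 * sin(th), 1.5 * sin(rev(th)))) # self-overlapping blob
  polys <- c(rep(list(good), 4), list(hook), rep(list(good), 4))
  am <- amplitude_map(polys, n_theta = 90)
  expect_true(am$repaired[5])
  expect_equal(am$r[, 5], rep(5, 90), tolerance = 2e-3) # interpolated
  polys_bad <- c(rep(list(good), 2), rep(list(hook), 3), rep(list(good), 2))
  expect_error(amplitude_map(polys_bad, n_theta = 90), "consecutive")
})

test_that("the three generator classes are classified correctly with a feature report", {
  for (cls in c("rotational", "oscillatory", "translational")) {
    cs <- make_contour_series(motion_params(cls, seed = 17))
    cl <- classify_motion(amplitude_map(cs))
    expect_equal(cl$label, cls)
    expect_named(cl$features, c("mode2_fraction", "periodicity", "drift_ratio"))
  }
})

test_that("classification accuracy >= 95% over a seeded 60-cell grid", {
  grid <- expand.grid(cls = c("rotational", "oscillatory", "translational"),
                      R = c(4, 5, 6), a = c(0.8, 1.0, 1.2),
                      stringsAsFactors = FALSE)
  grid <- grid[rep(seq_len(nrow(grid)), length.out = 60), ]
  hits <- vapply(seq_len(60), function(i) {
    mp <- motion_params(grid$cls[i], base_radius = grid$R[i],
                        mode2_amplitude = grid$a[i], seed = 1000 + i)
    classify_motion(amplitude_map(make_contour_series(mp)))$label == grid$cls[i]
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})
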