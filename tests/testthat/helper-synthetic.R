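# Shared fixtures, built in code at test time.

# Dense polygon approximating an ellipse with semi-axes a, b (um).
ellipse_polygon <- function(a, b, n = 2000L) {
  th <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  cbind(x = a * cos(th), y = b * sin(th))
}

# Closed-form radial function of an origin-centred ellipse.
ellipse_radius <- function(theta_deg, a, b) {
  th <- theta_deg * pi / 180
  a * b / sqrt((b * cos(th))^2 + (a * sin(th))^2)
}

# Amplitude map built directly from an r(theta, t) matrix (bypasses polygon
# extraction) for spectral oracles.
am_from_matrix <- function(r, dt = 40) {
  structure(list(r = r, theta_deg = seq(0, 359, length.out = nrow(r)),
                 time = (seq_len(ncol(r)) - 1) * dt,
                 centers = matrix(0, ncol(r), 2L),
                 repaired = logical(ncol(r))),
            class = "amplitude_map")
}

theta_grid <- function(n = 360L) seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]

# Step-profile tight-adhesion scene used by the RICM round-trip tests:
# contact disc of radius 2.26 um (area pi * 2.26^2 ~ 16.0 um^2) with a steep
# rim at 100 nm, inside the first interference branch.
tight_disc_profile <- function(rho) ifelse(rho <= 2.26, 0, 100)
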