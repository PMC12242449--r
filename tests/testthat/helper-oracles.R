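# Shared fixtures and independent oracles, built in code at test time.

# trapezoidal integral on an arbitrary grid (independent of the package's
# cell-weight quadrature)
trapz <- function(x, y) sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)

# high-resolution oracle for the dry-limit waveform: integrate the
# closed-form curvature on a fine grid and compute gauged amplitude features
# by trapezoidal quadrature, independently of the package's grid and weights
oracle_lowfric_features <- function(beta_re, beta_im, n = 1, n_fine = 40001) {
  s <- seq(0, 1, length.out = n_fine)
  dpsi <- exp(beta_re * s / 2) * sin(n * pi * (s - 1)) *
    exp(1i * beta_im * s / 2)
  psi <- cumsum(c(0, diff(s) * (head(dpsi, -1) + tail(dpsi, -1)) / 2))
  psi <- psi - trapz(s, psi)
  a <- Mod(psi)
  g0 <- trapz(s, a)
  c(abar1 = 3 * trapz(s, a * (2 * s - 1)) / g0,
    abar2 = 5 * trapz(s, a * (6 * s^2 - 6 * s + 1)) / g0)
}

# plane-wave ground truth: constant amplitude, linear phase (lambda = L)
plane_wave_truth <- function(a0 = 0.5, f = 50, L = 11.8, n_points = 25L,
                             static_amplitude = 0, harmonic_fraction = 0) {
  s <- seq(0, 1, length.out = n_points)
  axoneme_truth("plane", f, L,
                a_profile = rep(a0, n_points),
                phi_profile = -2 * pi * s,
                static_profile = static_amplitude * (2 * s - 1),
                harmonic_fraction = harmonic_fraction)
}

quick_acq <- function(n_frames = 512L, noise_sd = 0, seed = 1L,
                      n_points = 25L, fps = 1000)
  acquisition_spec(fps = fps, n_frames = n_frames, n_points = n_points,
                   noise_sd = noise_sd, seed = seed)

# a small wild-type-like condition for fast end-to-end tests
small_wt_spec <- function(n_axonemes = 2L)
  condition_spec("wt", n_axonemes = n_axonemes, f_mean = 60, f_sd = 5,
                 L_mean = 11.8, L_sd = 0.5, a0_mean = 0.45, a0_sd = 0.05,
                 abar1_mean = 0, abar1_sd = 0.03,
                 abar2_mean = 0.3, abar2_sd = 0.05)

# build a tangent_field directly from an analytic psi(s, t) matrix
field_from_psi <- function(psi, fps = 1000, L = 11.8) {
  psi <- psi - rowMeans(psi)
  psi <- sweep(psi, 2L, colMeans(psi))
  structure(list(psi = psi, s = midpoint_grid(ncol(psi)),
                 static = rep(0, ncol(psi)), L = L, dt = 1 / fps, fps = fps,
                 axoneme_id = "synthetic", condition = "synthetic",
                 viscosity_factor = 1),
            class = "tangent_field")
}
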