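test_that("Machin numbers follow the defining arithmetic and viscous scaling", {
  mp <- machin_numbers(f = 50, L = 11.8)
  expect_equal(mp$Mabar, 2 * pi * 50 * 0.0049 * 11.8^4 / 580)
  expect_equal(mp$Mabar, 51.46, tolerance = 1e-3)   # ~50 for typical axonemes
  expect_equal(mp$Ma, mp$Mabar / (2 * pi)^4)

  mp_ficoll <- machin_numbers(50, 11.8, viscosity_factor = 1.6)
  expect_equal(mp_ficoll$Mabar, 1.6 * mp$Mabar)

  # Mabar = 50 corresponds to Ma ~ 0.032, inside the low-friction regime
  expect_equal(50 / (2 * pi)^4, 0.0321, tolerance = 1e-2)

  expect_error(machin_numbers(-1, 10), "must be > 0")
  expect_error(machin_numbers(50, 0), "must be > 0")
})

test_that("characteristic roots satisfy Vieta and the zero-friction limit", {
  # Mabar = 0: double root at 0 plus the quadratic pair c(1 +/- d)
  k <- 3 * pi^2
  beta <- complex(imaginary = -4 * pi)
  cr <- characteristic_roots(k, beta, 0)
  r <- cr$roots[order(Mod(cr$roots))]
  expect_lt(max(Mod(r[1:2])), 1e-6)
  cc <- beta / 2
  dd <- sqrt(1 + 4 * k / beta^2)
  expect_lt(min(Mod(r[3] - cc * (1 + dd)), Mod(r[3] - cc * (1 - dd))), 1e-8)
  expect_lt(min(Mod(r[4] - cc * (1 + dd)), Mod(r[4] - cc * (1 - dd))), 1e-8)

  # Vieta: sum of roots equals beta, product equals i*Mabar
  set.seed(7)
  for (i in 1:10) {
    k <- runif(1, 1, 40)
    beta <- complex(real = rnorm(1), imaginary = -runif(1, 3, 15))
    Mabar <- runif(1, 0, 100)
    r <- characteristic_roots(k, beta, Mabar)$roots
    expect_lt(Mod(sum(r) - beta), 1e-8 * max(1, Mod(beta)))
    expect_lt(Mod(prod(r) - complex(imaginary = Mabar)), 1e-6 * max(1, Mabar))
  }

  expect_true(any(characteristic_roots(0, 0 + 0i, 0)$degenerate))
})

test_that("dry-friction relation reproduces the plane-wave stiffness and inverts", {
  expect_equal(dry_friction_relation(beta_im = -4 * pi), 3 * pi^2)
  expect_equal(dry_friction_relation(beta_im = -8 * pi, n = 2), 12 * pi^2)
  expect_error(dry_friction_relation(beta_im = -2 * pi), "no real stiffness")
  # inverse: k back to beta'' on the forward branch
  expect_equal(dry_friction_relation(k = 3 * pi^2), -4 * pi)
  for (k in c(5, 15, 40))
    expect_equal(dry_friction_relation(beta_im = dry_friction_relation(k = k)),
                 k, tolerance = 1e-12)
})

test_that("low-friction waveform: wavelength law, branch condition, symmetry", {
  lf <- lowfriction_waveform(0, -4 * pi, 1)
  expect_identical(lf$lam_over_L, 1)
  expect_lt(Mod(lf$c * lf$d - 1i * pi), 1e-10)       # c d = i pi n
  # distal curvature vanishes exactly by construction (evaluate at s = 1)
  lf_incl <- lowfriction_waveform(0, -4 * pi, 1, s = seq(0, 1, 1 / 24))
  expect_identical(Mod(lf_incl$dpsi[length(lf_incl$dpsi)]), 0)

  # beta' = 0: |psi(s)| symmetric about s = 1/2, so asymmetry vanishes
  for (bim in c(-4 * pi, -10, -7)) {
    lf <- lowfriction_waveform(0, bim, 1)
    co <- legendre_decompose(Mod(lf$psi), lf$s)
    expect_lt(abs(co[["g1"]] / co[["g0"]]), 1e-6)
  }

  # parabolicity of |psi| for beta'' = -10 against the independent
  # high-resolution quadrature oracle
  orc <- oracle_lowfric_features(0, -10, 1)
  lf <- lowfriction_waveform(0, -10, 1)
  co <- legendre_decompose(Mod(lf$psi), lf$s)
  expect_equal(co[["g2"]] / co[["g0"]], unname(orc["abar2"]),
               tolerance = 0.06)
  expect_equal(unname(orc["abar2"]), 0.347, tolerance = 0.01)

  # solvability residual vanishes on the chi_b -> 0 branch
  expect_lt(Mod(lf$solvability(0, lf$c, lf$k)), 1e-10)
  expect_error(lowfriction_waveform(0, 2, 1), "beta_im")
})

test_that("full solver satisfies boundary conditions and global balance", {
  set.seed(11)
  for (i in 1:12) {
    k <- runif(1, 5, 40)
    bre <- runif(1, -2, 2)
    bim <- runif(1, -14, -6)
    Mabar <- runif(1, 0.1, 120)
    w <- predict_waveform(k, bre, bim, Mabar)
    expect_lt(max(w$residuals), 1e-8)
    expect_equal(mean(Mod(w$psi)^2), 1, tolerance = 1e-9)  # unit rms
  }
})

test_that("full solver reduces to the dry-friction closed form at low Mabar", {
  for (bim in c(-4 * pi, -10)) {
    k <- dry_friction_relation(beta_im = bim)
    w <- predict_waveform(k, 0, bim, 1e-4)
    lf <- lowfriction_waveform(0, bim, 1)
    z <- sum(Conj(w$dpsi) * lf$dpsi) / sum(Mod(w$dpsi)^2)
    rel <- sqrt(sum(Mod(lf$dpsi - z * w$dpsi)^2) / sum(Mod(lf$dpsi)^2))
    expect_lt(rel, 0.01)
    expect_lt(Mod(w$chi_b), 1e-3)   # basal response vanishes in the limit
  }
})

test_that("wild-type-like parameters give a mid-dip, forward-travelling wave", {
  w <- predict_waveform(20, 0.15, -9.6, 50)
  a <- Mod(w$psi)
  i_min <- which.min(a)
  expect_gt(i_min, 5)
  expect_lt(i_min, 20)
  ph <- unwrap_phase(Arg(w$psi))
  expect_lt(ph[length(ph)] - ph[1], -pi)  # phase decreases base to tip
})

test_that("wavenumber counts unwrapped curvature phase turns", {
  s <- seq(0, 1, length.out = 25)
  expect_equal(wavenumber_of(exp(-2i * pi * s)), 1, tolerance = 1e-10)
  expect_equal(wavenumber_of(exp(-4i * pi * s)), 2, tolerance = 1e-10)
  expect_equal(wavenumber_of(rep(1 + 0i, 24)), 0)
  expect_error(wavenumber_of(rep(0i, 24)), "zero")
})

test_that("dry-branch wavelength read off the curvature phase matches -4pi/beta''", {
  for (bim in c(-10, -4 * pi, -14)) {
    k <- dry_friction_relation(beta_im = bim)
    w <- predict_waveform(k, 0, bim, 1e-3)
    ph <- unwrap_phase(Arg(w$dpsi))
    slope <- coef(lm(ph ~ w$s))[[2]]
    expect_equal(-2 * pi / slope, -4 * pi / bim, tolerance = 0.01)
  }
})
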