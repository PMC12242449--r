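model_mode <- function(k, bre, bim, Mabar = 50, f = 50, L = 11.8,
                       id = "model", cond = "model") {
  w <- predict_waveform(k, bre, bim, Mabar)
  list(psi1 = w$psi, a = Mod(w$psi), phi = unwrap_phase(Arg(w$psi)),
       s = w$s, f = f, L = L, Q = 100, harmonic_fraction = 0,
       viscosity_factor = Mabar / machin_numbers(f, L)$Mabar,
       axoneme_id = id, condition = cond)
}

test_that("complex R^2 has the projection-score identities", {
  set.seed(2)
  x <- complex(real = rnorm(24), imaginary = rnorm(24))
  expect_equal(r2_score(x, x)$r2, 1)
  expect_equal(r2_score(x, x)$z_scale, 1 + 0i)

  sc <- r2_score(x / (2i), x)
  expect_equal(sc$r2, 1)
  expect_equal(sc$z_scale, 2i)

  # orthogonal mean-subtracted profiles score zero
  s <- midpoint_grid(24)
  u <- exp(2i * pi * s); u <- u - mean(u)
  v <- exp(4i * pi * s); v <- v - mean(v)
  v <- v - u * sum(Conj(u) * v) / sum(Mod(u)^2)
  expect_equal(r2_score(u, v)$r2, 0, tolerance = 1e-10)

  expect_error(r2_score(x, rep(0i, 24)), "zero experimental")
  expect_error(r2_score(x[1:10], x), "one grid")
})

test_that("r2 degrades monotonically with orthogonal noise", {
  set.seed(4)
  x <- complex(real = rnorm(24), imaginary = rnorm(24))
  x <- x - mean(x)
  nz <- complex(real = rnorm(24), imaginary = rnorm(24))
  nz <- nz - mean(nz)
  nz <- nz - x * sum(Conj(x) * nz) / sum(Mod(x)^2)
  r2s <- vapply(c(0, 0.1, 0.3, 0.8), function(eps)
    r2_score(x, x + eps * nz)$r2, numeric(1))
  expect_true(all(diff(r2s) < 0))
})

test_that("noiseless model waveforms are recovered with their parameters", {
  for (p in list(c(20, 0.15, -9.6), c(10, -2, -14))) {
    fit <- fit_axoneme(model_mode(p[1], p[2], p[3]))
    expect_gt(fit$r2, 0.999)
    expect_lt(abs(fit$k - p[1]) / p[1], 0.01)
    expect_lt(abs(fit$beta_re - p[2]), max(0.01 * abs(p[2]), 0.02))
    expect_lt(abs(fit$beta_im - p[3]) / abs(p[3]), 0.01)
    expect_lt(fit$beta_im, 0)
  }
})

test_that("refitting from the returned parameters is idempotent", {
  fit <- fit_axoneme(model_mode(20, 0.15, -9.6))
  refit <- fit_axoneme(fit$mode,
                       starts = list(self = coef(fit)))
  expect_equal(refit$r2, fit$r2, tolerance = 1e-6)
})

test_that("plane-wave-like input at small Mabar lands on the plane-wave point", {
  lf <- lowfriction_waveform(0, -4 * pi, 1)
  mode <- list(psi1 = lf$psi - mean(lf$psi), s = lf$s, f = 50, L = 11.8,
               viscosity_factor = 1, axoneme_id = "pw", condition = "pw")
  mp <- machin_numbers(50, 11.8)
  mp$Mabar <- 0.05   # deep low-friction regime
  fit <- fit_axoneme(mode, mp = mp)
  expect_gt(fit$r2, 0.999)
  expect_equal(fit$beta_im, -4 * pi, tolerance = 0.02)
  expect_equal(fit$k, 3 * pi^2, tolerance = 0.05)
})

test_that("fitted parameters collapse onto the dry-friction curve at low Mabar", {
  for (bim in c(-8, -10, -12)) {
    k_true <- dry_friction_relation(beta_im = bim)
    w <- predict_waveform(k_true, 0, bim, 0.5)
    mode <- list(psi1 = w$psi, s = w$s, f = 50, L = 11.8,
                 viscosity_factor = 1, axoneme_id = "dry", condition = "dry")
    mp <- machin_numbers(50, 11.8); mp$Mabar <- 0.5
    fit <- fit_axoneme(mode, mp = mp)
    k_dry <- (fit$beta_im^2 - 4 * pi^2) / 4
    expect_lt(abs(fit$k - k_dry) / k_dry, 0.05)
  }
})

test_that("recovery tolerates measurement noise on the mode", {
  set.seed(6)
  m <- model_mode(20, 0, -10)
  scale <- sqrt(mean(Mod(m$psi1)^2))
  m$psi1 <- m$psi1 + 0.05 * scale *
    complex(real = rnorm(24), imaginary = rnorm(24)) / sqrt(2)
  fit <- fit_axoneme(m)
  expect_lt(abs(fit$beta_im - (-10)) / 10, 0.10)
})

test_that("degenerate modes raise errors instead of fake fits", {
  m <- model_mode(20, 0, -10)
  m$psi1 <- rep(0i, 24)
  expect_error(fit_axoneme(m), "zero")
})

test_that("fit_axoneme returns a standard modelling object", {
  m <- model_mode(20, 0.15, -9.6)
  fit <- fit_axoneme(m)
  expect_s3_class(fit, "machin_fit")
  expect_named(coef(fit), c("k", "beta_re", "beta_im"))
  expect_length(predict(fit), 24L)
  expect_lt(sqrt(mean(Mod(residuals(fit))^2)), 1e-3)
  expect_output(print(fit), "Mechanochemical")
  expect_output(print(summary(fit)), "boundary-condition")
  sims <- simulate(fit, nsim = 1, seed = 2,
                   acq = acquisition_spec(n_frames = 128, seed = 2))
  expect_s3_class(sims[[1]], "tracked_series")
  expect_equal(dim(sims[[1]]$xy), c(128L, 25L, 2L))
})

test_that("dataset-level fits summarize recovery and shape correlations", {
  set.seed(10)
  bres <- seq(-2, 2, length.out = 6)
  modes <- lapply(seq_along(bres), function(i)
    model_mode(20, bres[i], -10, id = sprintf("m%02d", i), cond = "var"))
  fits <- fit_dataset(modes)
  expect_equal(fits$summary$fraction_r2_above_0.9, 1.0)
  expect_true(all(fits$results$ok))
  # amplitude asymmetry tracks the instantaneous response coefficient
  cors <- fits$summary$shape_correlations
  expect_gt(cors["beta_re", "abar1"], 0.9)

  # failures become flagged rows, not aborts
  modes_bad <- modes
  modes_bad[[2]]$psi1 <- rep(0i, 24)
  fits_bad <- fit_dataset(modes_bad)
  expect_false(fits_bad$results$ok[2])
  expect_equal(sum(fits_bad$results$ok), 5L)

  expect_error(fit_dataset(list()), "non-empty")
})
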