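test_that("default conditions span the documented phenomenology", {
  specs <- default_conditions()
  expect_gte(length(specs), 8)
  f_means <- vapply(specs, `[[`, numeric(1), "f_mean")
  L_means <- vapply(specs, `[[`, numeric(1), "L_mean")
  expect_true(all(f_means >= 15 & f_means <= 160))
  expect_true(all(L_means >= 7.2 & L_means <= 15.4))
  expect_lt(specs$taxol_like$abar1_mean, 0)
  expect_gt(specs$calcium_like$abar1_mean, 0)
  expect_true(all(vapply(specs, `[[`, numeric(1), "harmonic_fraction") < 0.1))
  expect_lt(specs$oda1_like$f_mean, specs$wildtype$f_mean / 1.5)
  expect_lt(specs$mbo2_like$L_mean, 9)
  # within/between variance design: documented sds are carried in the specs
  expect_true(all(vapply(specs, `[[`, numeric(1), "f_sd") > 0))
})

test_that("synthesized coordinates invert exactly to the tangent angle", {
  # with 26 points, s = 0.5 is a chord midpoint
  truth <- plane_wave_truth(a0 = 0.5, f = 50, n_points = 26L)
  acq <- quick_acq(n_frames = 128L, noise_sd = 0, n_points = 26L)
  ser <- synthesize_axoneme(truth, acq, seed = 1)
  i_mid <- 13L  # chord from point 13 to 14: midpoint s = 0.5
  for (fr in c(1L, 17L, 100L)) {
    dx <- ser$xy[fr, i_mid + 1L, 1L] - ser$xy[fr, i_mid, 1L]
    dy <- ser$xy[fr, i_mid + 1L, 2L] - ser$xy[fr, i_mid, 2L]
    t_fr <- (fr - 1L) / acq$fps
    expected <- 0.5 * cos(2 * pi * 50 * t_fr + (-2 * pi * 0.5))
    expect_equal(atan2(dy, dx), expected, tolerance = 1e-12)
  }
})

test_that("generation is deterministic given a seed", {
  truth <- plane_wave_truth()
  acq <- quick_acq(n_frames = 64L, noise_sd = 0.01)
  s1 <- synthesize_axoneme(truth, acq, seed = 99)
  s2 <- synthesize_axoneme(truth, acq, seed = 99)
  expect_identical(s1$xy, s2$xy)
  d1 <- generate_dataset(list(small_wt_spec()), quick_acq(n_frames = 64L,
                                                          seed = 5))
  d2 <- generate_dataset(list(small_wt_spec()), quick_acq(n_frames = 64L,
                                                          seed = 5))
  expect_identical(d1$series[[1]]$xy, d2$series[[1]]$xy)
  expect_identical(d1$manifest, d2$manifest)
})

test_that("contour length is preserved without noise", {
  truth <- plane_wave_truth(L = 11.8)
  ser <- synthesize_axoneme(truth, quick_acq(n_frames = 64L), seed = 1)
  lens <- apply(ser$xy, 1L, function(m)
    sum(sqrt(diff(m[, 1])^2 + diff(m[, 2])^2)))
  expect_lt(max(abs(lens - 11.8)) / 11.8, 1e-3)
})

test_that("second harmonic carries the specified power fraction", {
  # 50 Hz with 1000 fps over 1000 frames: both tones are bin-centred
  truth <- plane_wave_truth(f = 50, harmonic_fraction = 0.10)
  ser <- synthesize_axoneme(truth, quick_acq(n_frames = 1000L), seed = 2)
  sp <- beat_spectrum(tangent_field(ser))
  expect_equal(sp$harmonic_fraction, 0.10, tolerance = 0.01)
})

test_that("dataset generation validates and counts correctly", {
  acq <- quick_acq(n_frames = 64L)
  spec2 <- small_wt_spec(3L)
  spec3 <- condition_spec("other", n_axonemes = 3L, f_mean = 40,
                          L_mean = 10, a0_mean = 0.4)
  d <- generate_dataset(list(spec2, spec3), acq)
  expect_equal(nrow(d$manifest), 6L)
  expect_equal(length(d$series), 6L)
  expect_true(all(c("f", "L", "a0", "abar1", "abar2", "seed") %in%
                    names(d$manifest)))

  expect_error(generate_dataset(list(spec2, spec2), acq), "duplicate")
  expect_error(generate_dataset(list(), acq), "non-empty")
})

test_that("zero spread makes all axonemes of a condition identical", {
  spec <- condition_spec("fixed", n_axonemes = 3L, f_mean = 50, f_sd = 0,
                         L_mean = 11, L_sd = 0, a0_mean = 0.4, a0_sd = 0,
                         abar1_sd = 0, abar2_sd = 0, harmonic_fraction = 0)
  d <- generate_dataset(list(spec), quick_acq(n_frames = 64L))
  expect_identical(d$series[[1]]$xy, d$series[[2]]$xy)
  expect_identical(d$series[[2]]$xy, d$series[[3]]$xy)
})

test_that("acquisition validation catches unphysical settings", {
  expect_error(acquisition_spec(noise_sd = -1), "noise_sd")
  expect_error(acquisition_spec(n_points = 3), "n_points")
  truth <- plane_wave_truth(f = 600)
  expect_error(synthesize_axoneme(truth, quick_acq(n_frames = 64L), seed = 1),
               "Nyquist")
  # the second harmonic must also stay below Nyquist
  truth2 <- plane_wave_truth(f = 300, harmonic_fraction = 0.05)
  expect_error(synthesize_axoneme(truth2, quick_acq(n_frames = 64L), seed = 1),
               "Nyquist")
})

test_that("generated beats are fundamental-mode dominated", {
  specs <- default_conditions()
  specs <- lapply(specs, function(sp) { sp$n_axonemes <- 1L; sp })
  d <- generate_dataset(specs, quick_acq(n_frames = 256L, noise_sd = 0.01,
                                         seed = 3))
  for (ser in d$series) {
    sp <- beat_spectrum(tangent_field(ser))
    expect_gte(1 - sp$harmonic_fraction, 0.9)
  }
})

test_that("round trip from generator truth through the pipeline", {
  d <- generate_dataset(list(small_wt_spec(3L)),
                        quick_acq(n_frames = 1024L, noise_sd = 0.01,
                                  seed = 11))
  for (i in 1:3) {
    md <- fundamental_mode(tangent_field(d$series[[i]]))
    ft <- shape_features(md)
    tr <- d$manifest[i, ]
    expect_lt(abs(md$f - tr$f), 1000 / 1024)          # within one bin
    expect_lt(abs(ft$abar1 - tr$abar1), 0.02)
    expect_lt(abs(ft$abar2 - tr$abar2), 0.02)
    expect_lt(abs(ft$a0 - tr$a0), 0.02)
    expect_lt(abs(md$L - tr$L) / tr$L, 0.005)
  }
})
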