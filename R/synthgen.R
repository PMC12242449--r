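# Synthetic tracked-filament generator. Emulates the statistical structure of
# high-speed recordings of isolated beating axonemes: travelling-wave tangent
# angle dynamics psi(s,t) = static(s) + a(s) cos(2 pi f t + phi(s)) (+ a weak
# second harmonic), hierarchical axoneme-within-condition variability, and
# isotropic localization noise on the tracked coordinates.

#' Condition specification for the synthetic generator
#'
#' Describes one experimental condition (a genotype, ATP level, temperature,
#' viscosity, ...) as the condition-level means and standard deviations from
#' which per-axoneme beat parameters are drawn.
#'
#' @param name condition label.
#' @param n_axonemes number of axonemes to generate.
#' @param f_mean,f_sd beat frequency mean/sd in Hz.
#' @param L_mean,L_sd filament length mean/sd in micrometres.
#' @param a0_mean,a0_sd mean tangent-angle amplitude in rad.
#' @param abar1_mean,abar1_sd normalized amplitude asymmetry (dimensionless).
#' @param abar2_mean,abar2_sd normalized amplitude parabolicity.
#' @param harmonic_fraction fraction of dynamic power carried by the second
#'   harmonic, in \[0, 1); realistic beats keep it below 0.1.
#' @param static_amplitude amplitude (rad) of the static, time-averaged
#'   curvature mode, modelled as a constant-curvature arc.
#' @param viscosity_factor multiplier on the normal friction coefficient
#'   (>= 1; e.g. 1.1/1.6/3.2 for 1%/5%/10% Ficoll).
#' @param mode `"empirical"` draws amplitude/phase profiles from the Legendre
#'   parameterization; `"mechanical"` derives them from the mechanochemical
#'   model with parameters `mech_params`.
#' @param mech_params for `mode = "mechanical"`: named list or vector with
#'   `k`, `beta_re`, `beta_im`.
#' @return an object of class `condition_spec` (a validated named list).
#' @seealso [default_conditions()], [generate_dataset()]
#' @export
condition_spec <- function(name, n_axonemes = 5L,
                           f_mean, f_sd = 0,
                           L_mean, L_sd = 0,
                           a0_mean, a0_sd = 0,
                           abar1_mean = 0, abar1_sd = 0,
                           abar2_mean = 0.3, abar2_sd = 0,
                           harmonic_fraction = 0.05,
                           static_amplitude = 0.2,
                           viscosity_factor = 1,
                           mode = c("empirical", "mechanical"),
                           mech_params = NULL) {
  mode <- match.arg(mode)
  stopifnot_scalar(f_mean = f_mean, L_mean = L_mean, a0_mean = a0_mean,
                   viscosity_factor = viscosity_factor, positive = TRUE)
  sds <- c(f_sd = f_sd, L_sd = L_sd, a0_sd = a0_sd,
           abar1_sd = abar1_sd, abar2_sd = abar2_sd)
  if (any(sds < 0)) stop("standard deviations must be >= 0")
  if (harmonic_fraction < 0 || harmonic_fraction >= 1)
    stop("'harmonic_fraction' must be in [0, 1)")
  if (viscosity_factor < 1) stop("'viscosity_factor' must be >= 1")
  if (mode == "mechanical") {
    mech_params <- as.list(mech_params)
    if (!all(c("k", "beta_re", "beta_im") %in% names(mech_params)))
      stop("'mech_params' must provide k, beta_re, beta_im")
  }
  structure(
    list(name = as.character(name), n_axonemes = as.integer(n_axonemes),
         f_mean = f_mean, f_sd = f_sd, L_mean = L_mean, L_sd = L_sd,
         a0_mean = a0_mean, a0_sd = a0_sd,
         abar1_mean = abar1_mean, abar1_sd = abar1_sd,
         abar2_mean = abar2_mean, abar2_sd = abar2_sd,
         harmonic_fraction = harmonic_fraction,
         static_amplitude = static_amplitude,
         viscosity_factor = viscosity_factor,
         mode = mode, mech_params = mech_params),
    class = "condition_spec")
}

#' Acquisition settings of the synthetic camera
#'
#' @param fps frame rate in frames per second.
#' @param n_frames number of recorded frames.
#' @param n_points number of tracked points along the filament (>= 5); the
#'   tangent angle is defined on the `n_points - 1` chord midpoints.
#' @param noise_sd isotropic localization noise per coordinate, micrometres.
#' @param seed integer seed for the generator.
#' @return an object of class `acquisition_spec`.
#' @export
acquisition_spec <- function(fps = 1000, n_frames = 3000, n_points = 25L,
                             noise_sd = 0.01, seed = 1L) {
  stopifnot_scalar(fps = fps, positive = TRUE)
  if (n_points < 5L) stop("'n_points' must be >= 5")
  if (noise_sd < 0) stop("'noise_sd' must be >= 0")
  if (n_frames < 2L) stop("'n_frames' must be >= 2")
  structure(list(fps = fps, n_frames = as.integer(n_frames),
                 n_points = as.integer(n_points), noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "acquisition_spec")
}

#' Ground-truth description of one synthetic axoneme
#'
#' Profiles are sampled on the inclusive uniform grid `s = seq(0, 1,
#' length.out = n_points)`; the synthesizer interpolates them to chord
#' midpoints when integrating the filament shape.
#'
#' @param condition condition label.
#' @param f beat frequency (Hz).
#' @param L length (um).
#' @param a_profile amplitude profile a(s) in rad.
#' @param phi_profile phase profile phi(s) in rad.
#' @param static_profile static (time-averaged) tangent-angle profile in rad.
#' @param harmonic_fraction fraction of dynamic power in the second harmonic.
#' @return an object of class `axoneme_truth`.
#' @export
axoneme_truth <- function(condition, f, L, a_profile, phi_profile,
                          static_profile = rep(0, length(a_profile)),
                          harmonic_fraction = 0) {
  stopifnot_scalar(f = f, L = L, positive = TRUE)
  n <- length(a_profile)
  if (length(phi_profile) != n || length(static_profile) != n)
    stop("profiles must share one grid")
  if (any(a_profile < 0)) stop("'a_profile' must be non-negative")
  structure(list(condition = as.character(condition), f = f, L = L,
                 s = seq(0, 1, length.out = n),
                 a_profile = a_profile, phi_profile = phi_profile,
                 static_profile = static_profile,
                 harmonic_fraction = harmonic_fraction),
            class = "axoneme_truth")
}

#' Default synthetic conditions
#'
#' Returns eight condition specifications spanning the phenomenology of
#' beating *Chlamydomonas*-like axonemes under genetic and environmental
#' perturbations: a wild-type-like reference, low ATP (slow beat), high
#' temperature (fast beat), raised viscosity, an outer-dynein-arm mutant
#' analogue (halved frequency, long), an *mbo2*-like analogue (short, large
#' amplitude, slow, no static mode), a taxol-like condition (small distally
#' decaying amplitude, fast) and a calcium-like condition (distally growing
#' amplitude). All mean frequencies lie in 15-160 Hz and mean lengths in
#' 7.2-15.4 um. The within-condition frequency sd (12 Hz) is set so that the
#' between/within frequency variance ratio of the generated population is of
#' order the ~7 seen across real condition panels. All numbers are generator
#' choices, not measurements.
#'
#' @return named list of [condition_spec()] objects.
#' @examples
#' names(default_conditions())
#' @export
default_conditions <- function() {
  specs <- list(
    condition_spec("wildtype",  n_axonemes = 6L, f_mean = 60,  f_sd = 12,
                   L_mean = 11.8, L_sd = 0.8, a0_mean = 0.45, a0_sd = 0.12,
                   abar1_mean = 0,     abar1_sd = 0.05,
                   abar2_mean = 0.30,  abar2_sd = 0.07),
    condition_spec("low_atp",   n_axonemes = 6L, f_mean = 25,  f_sd = 12,
                   L_mean = 11.8, L_sd = 0.8, a0_mean = 0.48, a0_sd = 0.12,
                   abar1_mean = 0,     abar1_sd = 0.05,
                   abar2_mean = 0.30,  abar2_sd = 0.07),
    condition_spec("high_temp", n_axonemes = 6L, f_mean = 110, f_sd = 12,
                   L_mean = 11.8, L_sd = 0.8, a0_mean = 0.42, a0_sd = 0.12,
                   abar1_mean = 0,     abar1_sd = 0.05,
                   abar2_mean = 0.28,  abar2_sd = 0.07),
    condition_spec("ficoll_5pct", n_axonemes = 6L, f_mean = 40, f_sd = 12,
                   L_mean = 11.8, L_sd = 0.8, a0_mean = 0.45, a0_sd = 0.12,
                   abar1_mean = 0,     abar1_sd = 0.05,
                   abar2_mean = 0.30,  abar2_sd = 0.07,
                   viscosity_factor = 1.6),
    condition_spec("oda1_like", n_axonemes = 6L, f_mean = 30,  f_sd = 12,
                   L_mean = 13.5, L_sd = 0.9, a0_mean = 0.50, a0_sd = 0.12,
                   abar1_mean = 0,     abar1_sd = 0.05,
                   abar2_mean = 0.05,  abar2_sd = 0.05),
    condition_spec("mbo2_like", n_axonemes = 6L, f_mean = 25,  f_sd = 12,
                   L_mean = 8.0,  L_sd = 0.5, a0_mean = 0.60, a0_sd = 0.12,
                   abar1_mean = 0,     abar1_sd = 0.05,
                   abar2_mean = 0.30,  abar2_sd = 0.07,
                   static_amplitude = 0),
    condition_spec("taxol_like", n_axonemes = 6L, f_mean = 100, f_sd = 12,
                   L_mean = 11.5, L_sd = 0.8, a0_mean = 0.30, a0_sd = 0.12,
                   abar1_mean = -0.25, abar1_sd = 0.07,
                   abar2_mean = 0.15,  abar2_sd = 0.07),
    condition_spec("calcium_like", n_axonemes = 6L, f_mean = 55, f_sd = 12,
                   L_mean = 11.8, L_sd = 0.8, a0_mean = 0.45, a0_sd = 0.12,
                   abar1_mean = 0.20,  abar1_sd = 0.07,
                   abar2_mean = 0.25,  abar2_sd = 0.07)
  )
  names(specs) <- vapply(specs, `[[`, character(1), "name")
  specs
}

# Build amplitude/phase profiles whose measured shape features are exactly
# the prescribed ones. "Measured" means what the analysis pipeline reports:
# the mode a(s) e^{i phi(s)} interpolated to the chord-midpoint grid,
# co-swimming-gauged there (zero complex mean), and Legendre-decomposed with
# midpoint weights. The raw Legendre construction differs from this both by
# the gauge constant and by the quadrature convention, so a damped
# fixed-point iteration adjusts the construction parameters until the
# pipeline-convention features hit the targets.
gauge_mode_profiles <- function(a0, abar1, abar2, phi1, phi2, s,
                                tol = 1e-8, max_iter = 120L) {
  target <- c(a0, abar1, abar2, phi1, phi2)
  l1 <- 2 * s - 1
  l2 <- 6 * s^2 - 6 * s + 1
  sm <- midpoint_grid(length(s) - 1L)
  p <- target
  a <- phi <- NULL
  for (it in seq_len(max_iter)) {
    a <- p[1L] * (1 + p[2L] * l1 + p[3L] * l2)
    a <- pmax(a, 0.01 * p[1L])
    phi <- p[4L] * l1 + p[5L] * l2
    am <- stats::approx(s, a, sm)$y
    phm <- stats::approx(s, phi, sm)$y
    m <- am * exp(1i * phm)
    m <- m - mean(m)
    amp <- Mod(m)
    ph <- unwrap_phase(Arg(m))
    ca <- legendre_decompose(amp, sm)
    cp <- legendre_decompose(ph, sm)
    got <- c(ca[[1L]], ca[[2L]] / ca[[1L]], ca[[3L]] / ca[[1L]],
             cp[[2L]], cp[[3L]])
    err <- target - got
    if (max(abs(err) / c(a0, 1, 1, 1, 1)) < tol) break
    p <- p + 0.8 * err
  }
  list(a_profile = a, phi_profile = phi)
}

# truncated-normal draw by rejection (physical lower bounds)
rnorm_trunc <- function(n, mean, sd, lower = -Inf) {
  if (sd == 0) return(rep(mean, n))
  x <- stats::rnorm(n, mean, sd)
  while (any(bad <- x <= lower))
    x[bad] <- stats::rnorm(sum(bad), mean, sd)
  x
}

#' Synthesize a tracked coordinate series from a ground-truth axoneme
#'
#' Builds the tangent-angle field \eqn{\psi(s,t) = \psi_0(s) + a(s)
#' \cos(2\pi f t + \phi(s))} (plus an optional second harmonic at \eqn{2f}
#' with doubled phase slope carrying the specified power fraction),
#' integrates it from a fixed base point into (x, y) coordinates at
#' `n_points` equally spaced arc positions with segment length
#' `L / (n_points - 1)`, and adds i.i.d. Gaussian localization noise to every
#' coordinate. Swimming translation and rotation are not simulated; the
#' downstream tangent-angle analysis is invariant to them.
#'
#' @param truth an [axoneme_truth()] object.
#' @param acq an [acquisition_spec()] object.
#' @param seed integer seed; `NULL` (default) continues the ambient RNG
#'   stream, which is what [generate_dataset()] relies on.
#' @param axoneme_id label for the generated series.
#' @param viscosity_factor carried through to the series for later model
#'   fitting.
#' @return an object of class `tracked_series`: list with `axoneme_id`,
#'   `condition`, `fps`, `viscosity_factor` and `xy`, a numeric array of
#'   dimension `(n_frames, n_points, 2)` in micrometres.
#' @export
synthesize_axoneme <- function(truth, acq, seed = NULL,
                               axoneme_id = truth$condition,
                               viscosity_factor = 1) {
  stopifnot(inherits(truth, "axoneme_truth"), inherits(acq, "acquisition_spec"))
  f_top <- if (truth$harmonic_fraction > 0) 2 * truth$f else truth$f
  if (acq$fps <= 2 * f_top)
    stop(sprintf("Nyquist violation: fps = %g <= 2 x %g Hz", acq$fps, f_top))
  if (!is.null(seed)) set.seed(seed)

  n_pts <- acq$n_points
  s_mid <- midpoint_grid(n_pts - 1L)
  interp <- function(y) stats::approx(truth$s, y, s_mid)$y
  a <- interp(truth$a_profile)
  phi <- interp(truth$phi_profile)
  stat <- interp(truth$static_profile)

  tt <- (seq_len(acq$n_frames) - 1L) / acq$fps
  # amplitude ratio of the second harmonic from its dynamic power fraction
  r2h <- sqrt(truth$harmonic_fraction / (1 - truth$harmonic_fraction))

  # psi: n_frames x (n_pts - 1)
  phase1 <- outer(2 * pi * truth$f * tt, phi, `+`)
  psi <- sweep(cos(phase1), 2L, a, `*`)
  if (r2h > 0) {
    phase2 <- outer(2 * pi * 2 * truth$f * tt, 2 * phi, `+`)
    psi <- psi + sweep(cos(phase2), 2L, r2h * a, `*`)
  }
  psi <- sweep(psi, 2L, stat, `+`)

  ds <- truth$L / (n_pts - 1L)
  xy <- array(0, dim = c(acq$n_frames, n_pts, 2L))
  xy[, -1L, 1L] <- t(apply(ds * cos(psi), 1L, cumsum))
  xy[, -1L, 2L] <- t(apply(ds * sin(psi), 1L, cumsum))
  if (acq$noise_sd > 0)
    xy <- xy + stats::rnorm(length(xy), sd = acq$noise_sd)

  structure(list(axoneme_id = as.character(axoneme_id),
                 condition = truth$condition, fps = acq$fps,
                 viscosity_factor = viscosity_factor, xy = xy),
            class = "tracked_series")
}

#' @export
print.tracked_series <- function(x, ...) {
  d <- dim(x$xy)
  cat(sprintf("Tracked series '%s' (%s): %d frames x %d points @ %g fps\n",
              x$axoneme_id, x$condition, d[1], d[2], x$fps))
  invisible(x)
}

# Build the truth profiles for one axoneme drawn from a condition spec.
draw_axoneme_truth <- function(spec, n_points, fps,
                               kappa = 580, xi_n = 0.0049) {
  f <- rnorm_trunc(1, spec$f_mean, spec$f_sd, lower = 5)
  L <- rnorm_trunc(1, spec$L_mean, spec$L_sd, lower = 2)
  a0 <- rnorm_trunc(1, spec$a0_mean, spec$a0_sd, lower = 0)
  s <- seq(0, 1, length.out = n_points)

  if (spec$mode == "empirical") {
    abar1 <- stats::rnorm(1, spec$abar1_mean, spec$abar1_sd)
    abar2 <- stats::rnorm(1, spec$abar2_mean, spec$abar2_sd)
    phi1 <- -pi                 # lambda = L, the typically observed ratio
    phi2 <- -abar1              # emulate the asymmetry/phase anti-correlation
    prof <- gauge_mode_profiles(a0, abar1, abar2, phi1, phi2, s)
    a_prof <- prof$a_profile
    phi_prof <- prof$phi_profile
    mech <- list(k = NA_real_, beta_re = NA_real_, beta_im = NA_real_)
  } else {
    mech <- spec$mech_params
    Mabar <- machin_numbers(f, L, kappa, xi_n, spec$viscosity_factor)$Mabar
    w <- predict_waveform(mech$k, mech$beta_re, mech$beta_im, Mabar, s = s)
    a_raw <- Mod(w$psi)
    a_prof <- a_raw * (a0 / arc_integral(a_raw, s))
    phi_prof <- unwrap_phase(Arg(w$psi))
    phi_prof <- phi_prof - phi_prof[1]
    co <- legendre_decompose(a_prof, s)
    abar1 <- co[["g1"]] / co[["g0"]]
    abar2 <- co[["g2"]] / co[["g0"]]
    pc <- legendre_decompose(phi_prof, s)
    phi1 <- pc[["g1"]]; phi2 <- pc[["g2"]]
  }
  static_prof <- spec$static_amplitude * (2 * s - 1)

  truth <- axoneme_truth(spec$name, f, L, a_prof, phi_prof, static_prof,
                         spec$harmonic_fraction)
  list(truth = truth,
       row = data.frame(condition = spec$name, f = f, L = L, a0 = a0,
                        abar1 = abar1, abar2 = abar2,
                        phi1 = phi1, phi2 = phi2,
                        harmonic_fraction = spec$harmonic_fraction,
                        static_amplitude = spec$static_amplitude,
                        viscosity_factor = spec$viscosity_factor,
                        mode = spec$mode,
                        k = mech$k, beta_re = mech$beta_re,
                        beta_im = mech$beta_im))
}

#' Generate a hierarchical synthetic dataset
#'
#' Per-axoneme beat parameters are drawn from each condition's means and
#' standard deviations (normal at both levels, truncated at physical bounds
#' f > 5 Hz, L > 2 um, a0 > 0), each axoneme is synthesized with
#' [synthesize_axoneme()], and a manifest of ground-truth parameters is
#' assembled. Optionally writes the tracked-series file and manifest as CSV.
#'
#' @param specs list of [condition_spec()] objects (unique names).
#' @param acq an [acquisition_spec()]; its `seed` drives all randomness.
#' @param dir optional output directory; when given, writes
#'   `tracked.csv` and `manifest.csv` there.
#' @return list with `series` (list of `tracked_series`), `manifest`
#'   (data.frame, one row per axoneme with truth parameters and the dataset
#'   seed) and `acq`.
#' @examples
#' specs <- default_conditions()[c("wildtype", "taxol_like")]
#' specs <- lapply(specs, function(sp) { sp$n_axonemes <- 2L; sp })
#' d <- generate_dataset(specs, acquisition_spec(n_frames = 128, seed = 7))
#' d$manifest[, c("axoneme_id", "condition", "f", "L")]
#' @export
generate_dataset <- function(specs, acq = acquisition_spec(), dir = NULL) {
  if (length(specs) == 0) stop("'specs' must be non-empty")
  if (inherits(specs, "condition_spec")) specs <- list(specs)
  nm <- vapply(specs, `[[`, character(1), "name")
  if (anyDuplicated(nm)) stop("duplicate condition names: ",
                              paste(unique(nm[duplicated(nm)]), collapse = ", "))
  set.seed(acq$seed)
  series <- list()
  manifest <- NULL
  for (spec in specs) {
    for (i in seq_len(spec$n_axonemes)) {
      dr <- draw_axoneme_truth(spec, acq$n_points, acq$fps)
      id <- sprintf("%s_%02d", spec$name, i)
      ser <- synthesize_axoneme(dr$truth, acq, seed = NULL, axoneme_id = id,
                                viscosity_factor = spec$viscosity_factor)
      series[[id]] <- ser
      manifest <- rbind(manifest,
                        cbind(data.frame(axoneme_id = id), dr$row,
                              data.frame(fps = acq$fps, seed = acq$seed)))
    }
  }
  out <- list(series = series, manifest = manifest, acq = acq)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    write_tracked(series, file.path(dir, "tracked.csv"))
    utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                     row.names = FALSE)
  }
  out
}
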