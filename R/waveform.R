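# From tracked coordinates to the fundamental-mode description
# {f, a(s), phi(s), L} of the beat, via the tangent angle psi(s, t).

hann_window <- function(n) 0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1L) / n)

#' Tangent-angle field of a tracked series
#'
#' Computes per-frame tangent angles as the chord angles of consecutive
#' tracked points, evaluated at the chord midpoints and linearly resampled to
#' the uniform midpoint grid (for equally spaced points the chords already
#' live there). Two gauge corrections are then applied: the per-frame
#' arc-length mean is subtracted (co-swimming frame, removing rigid-body
#' rotation) and the per-position time mean is subtracted (static-mode
#' removal), leaving only the dynamic shape modes.
#'
#' @param series a `tracked_series` (see [synthesize_axoneme()],
#'   [read_tracked()]).
#' @return an object of class `tangent_field`: list with `psi` (matrix,
#'   frames x arc positions, rad), `s` (midpoint grid), `static` (the removed
#'   static profile), `L` (time-averaged contour length, um), `dt` (s), plus
#'   the series metadata.
#' @export
tangent_field <- function(series) {
  stopifnot(inherits(series, "tracked_series"))
  d <- dim(series$xy)
  n_frames <- d[1]; n_pts <- d[2]
  if (n_frames < 64L) stop("need at least 64 frames")
  s_grid <- midpoint_grid(n_pts - 1L)

  psi <- matrix(NA_real_, n_frames, n_pts - 1L)
  Ls <- numeric(n_frames)
  for (fr in seq_len(n_frames)) {
    dx <- diff(series$xy[fr, , 1L])
    dy <- diff(series$xy[fr, , 2L])
    seg <- sqrt(dx^2 + dy^2)
    if (any(seg <= 0))
      stop(sprintf("frame %d: non-monotone arc length (zero-length segment)",
                   fr - 1L))
    Ls[fr] <- sum(seg)
    ang <- unwrap_phase(atan2(dy, dx))
    cs <- cumsum(seg)
    s_mid <- (c(0, utils::head(cs, -1)) + cs) / (2 * Ls[fr])
    psi[fr, ] <- stats::approx(s_mid, ang, s_grid, rule = 2)$y
  }
  psi <- psi - rowMeans(psi)          # co-swimming gauge
  static <- colMeans(psi)
  psi <- sweep(psi, 2L, static)       # static-mode removal

  structure(list(psi = psi, s = s_grid, static = static,
                 L = mean(Ls), dt = 1 / series$fps,
                 fps = series$fps, axoneme_id = series$axoneme_id,
                 condition = series$condition,
                 viscosity_factor = series$viscosity_factor),
            class = "tangent_field")
}

# parabolic interpolation of a spectral peak on log power; returns the
# refined peak location in (fractional) bin units
refine_peak <- function(p, i) {
  if (i <= 1L || i >= length(p)) return(i)
  y <- log(pmax(p[(i - 1L):(i + 1L)], 1e-300))
  den <- y[1] - 2 * y[2] + y[3]
  if (den >= 0) return(i)
  i + 0.5 * (y[1] - y[3]) / den
}

#' Beat spectrum of a tangent-angle field
#'
#' Hann-windowed periodogram of the tangent angle at every arc position. The
#' local beat frequency f(s) is the parabolic-interpolated peak (excluding
#' the zero-frequency bin) and the beat frequency is its arc-length mean,
#' \eqn{f = \langle f(s) \rangle}. The Q-factor is the peak frequency of the
#' arc-length-averaged power spectral density divided by its full width at
#' half maximum. The harmonic fraction is the power within one bin of the
#' harmonics \eqn{m f, m \ge 2} relative to the power in all harmonic
#' neighbourhoods \eqn{m \ge 1}.
#'
#' @param field a [tangent_field()].
#' @return an object of class `beat_spectrum`: list with `freq` (Hz), `psd`
#'   (matrix, frequency x arc position), `psd_mean` (arc-length average),
#'   `f_of_s`, `f`, `Q`, `harmonic_fraction`, `df` (bin width).
#' @export
beat_spectrum <- function(field) {
  stopifnot(inherits(field, "tangent_field"))
  N <- nrow(field$psi)
  if (N < 64L) stop("need at least 64 frames")
  fs <- 1 / field$dt
  w <- hann_window(N)
  n_keep <- floor(N / 2) + 1L
  freq <- (seq_len(n_keep) - 1L) * fs / N

  X <- stats::mvfft(field$psi * w)
  psd <- Mod(X[seq_len(n_keep), , drop = FALSE])^2 / (sum(w^2) * fs)

  psd_mean <- rowMeans(psd)
  if (max(psd_mean[-1L]) <= 0) stop("no oscillation detected")

  f_of_s <- apply(psd, 2L, function(p) {
    i <- which.max(p[-1L]) + 1L
    (refine_peak(p, i) - 1) * fs / N
  })
  f <- mean(f_of_s)

  ip <- which.max(psd_mean[-1L]) + 1L
  f_peak <- (refine_peak(psd_mean, ip) - 1) * fs / N
  half <- psd_mean[ip] / 2
  # FWHM by linear interpolation of the half-maximum crossings
  lo <- ip
  while (lo > 1L && psd_mean[lo] > half) lo <- lo - 1L
  hi <- ip
  while (hi < n_keep && psd_mean[hi] > half) hi <- hi + 1L
  cross <- function(i1, i2) {
    if (psd_mean[i1] == psd_mean[i2]) return(freq[i1])
    freq[i1] + (half - psd_mean[i1]) / (psd_mean[i2] - psd_mean[i1]) *
      (freq[i2] - freq[i1])
  }
  fwhm <- cross(hi - 1L, hi) - cross(lo + 1L, lo)
  Q <- f_peak / max(fwhm, fs / N)  # floor at one bin

  b1 <- max(round(f / (fs / N)), 1L)
  m_max <- floor((n_keep - 2L) / b1)
  p_m <- vapply(seq_len(max(m_max, 1L)), function(m) {
    idx <- (m * b1 - 1L):(m * b1 + 1L) + 1L
    idx <- idx[idx >= 2L & idx <= n_keep]
    sum(psd_mean[idx])
  }, numeric(1))
  harmonic_fraction <-
    if (length(p_m) > 1L) sum(p_m[-1L]) / sum(p_m) else 0

  structure(list(freq = freq, psd = psd, psd_mean = psd_mean,
                 f_of_s = f_of_s, f = f, Q = Q,
                 harmonic_fraction = harmonic_fraction, df = fs / N),
            class = "beat_spectrum")
}

#' @export
print.beat_spectrum <- function(x, ...) {
  cat(sprintf(
    "Beat spectrum: f = %.3f Hz (bin %.3f Hz), Q = %.1f, harmonics = %.1f%%\n",
    x$f, x$df, x$Q, 100 * x$harmonic_fraction))
  invisible(x)
}

#' Complex fundamental mode of the beat
#'
#' Extracts the first temporal Fourier mode \eqn{\psi_1(s)} of the tangent
#' angle at the beat frequency: at each arc position the Hann-windowed
#' discrete Fourier transform is evaluated at the interpolated spectral peak
#' frequency (window gain compensated), so that
#' \eqn{\psi(s, t) \approx \mathrm{Re}[\psi_1(s) e^{2\pi i f t}]} with
#' \eqn{a(s) = |\psi_1|} and \eqn{\phi(s) = \arg \psi_1}. The phase is
#' unwrapped along arc length and a global phase is removed so that
#' \eqn{\phi} at the first grid point is zero (the time origin is arbitrary).
#'
#' @param field a [tangent_field()].
#' @param spectrum a [beat_spectrum()] of the same field; computed on the
#'   fly when omitted.
#' @return an object of class `fundamental_mode`: list with `psi1` (complex
#'   profile on the midpoint grid), `a`, `phi`, `s`, `f`, `L`, `Q`,
#'   `harmonic_fraction`, and the series metadata.
#' @export
fundamental_mode <- function(field, spectrum = beat_spectrum(field)) {
  stopifnot(inherits(field, "tangent_field"),
            inherits(spectrum, "beat_spectrum"))
  N <- nrow(field$psi)
  f <- spectrum$f
  if (N * field$dt * f < 2) stop("fewer than 2 beat cycles in the record")
  if (spectrum$harmonic_fraction > 0.1)
    warning(sprintf("harmonic fraction %.2f > 0.1: fundamental mode is a poor summary",
                    spectrum$harmonic_fraction))
  w <- hann_window(N)
  tt <- (seq_len(N) - 1L) * field$dt
  e <- exp(-2i * pi * f * tt)
  psi1 <- as.vector(crossprod(field$psi * w, e)) * 2 / sum(w)

  phi <- unwrap_phase(Arg(psi1))
  psi1 <- psi1 * exp(-1i * phi[1L])
  phi <- phi - phi[1L]

  structure(list(psi1 = psi1, a = Mod(psi1), phi = phi, s = field$s,
                 f = f, L = field$L, Q = spectrum$Q,
                 harmonic_fraction = spectrum$harmonic_fraction,
                 axoneme_id = field$axoneme_id, condition = field$condition,
                 viscosity_factor = field$viscosity_factor),
            class = "fundamental_mode")
}

#' @export
print.fundamental_mode <- function(x, ...) {
  cat(sprintf("Fundamental mode '%s' (%s):\n", x$axoneme_id, x$condition))
  cat(sprintf("  f = %.2f Hz, L = %.2f um, Q = %.1f, harmonics = %.1f%%\n",
              x$f, x$L, x$Q, 100 * x$harmonic_fraction))
  cat(sprintf("  %d arc points, mean amplitude %.3f rad\n",
              length(x$a), mean(x$a)))
  invisible(x)
}

#' @export
plot.fundamental_mode <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  graphics::plot(x$s, x$a, type = "b", xlab = "s", ylab = "amplitude (rad)",
                 main = x$axoneme_id, ...)
  graphics::plot(x$s, x$phi, type = "b", xlab = "s", ylab = "phase (rad)",
                 main = sprintf("f = %.1f Hz", x$f), ...)
  invisible(x)
}

#' Write per-axoneme mode tables
#'
#' Writes the fundamental-mode profile as a comma-separated table with
#' columns `s`, `a_rad`, `phi_rad` plus a one-row summary file
#' (`f_Hz`, `L_um`, `Q`, `harmonic_fraction`).
#'
#' @param mode a [fundamental_mode()].
#' @param file path of the profile table; the summary is written next to it
#'   with suffix `_summary.csv`.
#' @return invisibly, the profile data.frame.
#' @export
write_mode <- function(mode, file) {
  stopifnot(inherits(mode, "fundamental_mode"))
  prof <- data.frame(s = mode$s, a_rad = mode$a, phi_rad = mode$phi)
  utils::write.csv(prof, file, row.names = FALSE)
  smry <- data.frame(axoneme_id = mode$axoneme_id, condition = mode$condition,
                     f_Hz = mode$f, L_um = mode$L, Q = mode$Q,
                     harmonic_fraction = mode$harmonic_fraction)
  utils::write.csv(smry, sub("\\.csv$", "_summary.csv", file),
                   row.names = FALSE)
  invisible(prof)
}
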