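# Mechanochemical model of the axonemal beat: the linearized force balance
# ("Machin equation") for the complex fundamental mode psi(s),
#
#   i Mabar psi = -psi'''' + d^2/ds^2 f_sl,   f_sl = k Delta + beta psi',
#
# with sliding Delta(s) = Delta_b + psi(s) - psi(0), boundary conditions
# psi'(0) = F_b, psi'(1) = 0, psi''(0) = f_sl(0), psi''(1) = f_sl(1), and the
# global sliding balance int_0^1 f_sl ds = F_b = chi_b Delta_b. Arc length is
# measured in units of the filament length L, so k, beta = beta' + i beta''
# and chi_b are dimensionless.

#' Machin numbers of a beating filament
#'
#' Computes the dimensionless ratio of normal viscous to elastic bending
#' forces, \eqn{\bar{Ma} = 2\pi f \xi_n L^4 / \kappa}, and the Machin number
#' \eqn{Ma = \bar{Ma} / (2\pi)^4}. Defaults are the flexural rigidity and
#' normal friction coefficient of reactivated *Chlamydomonas* axonemes in
#' aqueous buffer; crowding agents that raise the fluid viscosity scale
#' \eqn{\xi_n} through `viscosity_factor` (1.1, 1.6 and 3.2 for 1%, 5% and
#' 10% Ficoll).
#'
#' @param f beat frequency in Hz.
#' @param L filament length in micrometres.
#' @param kappa flexural rigidity in pN um^2.
#' @param xi_n normal friction coefficient in pN s um^-2.
#' @param viscosity_factor multiplier on `xi_n` (dimensionless, >= 1 for
#'   viscous media).
#' @return an object of class `machin_params`: a list with `f`, `L`, `kappa`,
#'   `xi_n`, `viscosity_factor`, `omega` (rad/s), `Mabar` and `Ma`.
#' @examples
#' machin_numbers(f = 50, L = 11.8)  # Mabar ~ 51.5, Ma ~ 0.033
#' @export
machin_numbers <- function(f, L, kappa = 580, xi_n = 0.0049,
                           viscosity_factor = 1) {
  stopifnot_scalar(f = f, L = L, kappa = kappa, xi_n = xi_n,
                   viscosity_factor = viscosity_factor, positive = TRUE)
  Mabar <- 2 * pi * f * (xi_n * viscosity_factor) * L^4 / kappa
  structure(
    list(f = f, L = L, kappa = kappa, xi_n = xi_n,
         viscosity_factor = viscosity_factor,
         omega = 2 * pi * f, Mabar = Mabar, Ma = Mabar / (2 * pi)^4),
    class = "machin_params")
}

#' @export
print.machin_params <- function(x, ...) {
  cat("Machin numbers: f =", x$f, "Hz, L =", x$L, "um\n")
  cat(sprintf("  Mabar = %.4g   Ma = Mabar/(2*pi)^4 = %.4g\n", x$Mabar, x$Ma))
  cat(sprintf("  kappa = %g pN um^2, xi_n = %g pN s um^-2 (x%g viscosity)\n",
              x$kappa, x$xi_n, x$viscosity_factor))
  invisible(x)
}

#' Characteristic roots of the Machin equation
#'
#' Roots of the quartic \eqn{x^4 - \beta x^3 - k x^2 + i\bar{Ma} = 0}
#' obtained from the exponential ansatz \eqn{\psi \propto e^{xs}}. Near-equal
#' pairs are flagged so the solver can switch to a confluent basis.
#'
#' @param k dimensionless sliding stiffness.
#' @param beta complex curvature-response coefficient \eqn{\beta' + i\beta''}.
#' @param Mabar dimensionless viscous-elastic ratio (see [machin_numbers()]).
#' @return list with `roots` (complex length 4) and logical `degenerate`
#'   marking roots within 1e-6 of an earlier root.
#' @examples
#' characteristic_roots(3 * pi^2, complex(imaginary = -4 * pi), 0)
#' @export
characteristic_roots <- function(k, beta, Mabar) {
  beta <- as.complex(beta)
  r <- polyroot(c(complex(imaginary = Mabar), 0 + 0i, -k - 0i, -beta, 1 + 0i))
  degen <- vapply(seq_along(r), function(j) {
    j > 1L && any(Mod(r[seq_len(j - 1L)] - r[j]) < 1e-6)
  }, logical(1))
  list(roots = r, degenerate = degen)
}

# Basis functions e^{x s} (or the confluent s e^{x s} for repeated roots)
# with first/second derivatives and the exact integral over [0,1].
machin_basis <- function(roots, degenerate) {
  lapply(seq_along(roots), function(j) {
    x <- roots[j]
    if (!degenerate[j]) {
      list(f  = function(s) exp(x * s),
           d1 = function(s) x * exp(x * s),
           d2 = function(s) x^2 * exp(x * s),
           I  = if (Mod(x) < 1e-12) 1 + 0i else (exp(x) - 1) / x)
    } else {
      list(f  = function(s) s * exp(x * s),
           d1 = function(s) (1 + x * s) * exp(x * s),
           d2 = function(s) (2 * x + x^2 * s) * exp(x * s),
           I  = if (Mod(x) < 1e-12) 0.5 + 0i else ((x - 1) * exp(x) + 1) / x^2)
    }
  })
}

# 5x5 homogeneous system in (A1..A4, Delta_b): rows are the four boundary
# conditions and the global sliding balance. chi_b enters only the Delta_b
# column (rows 1 and 5), so det is affine in chi_b.
machin_system <- function(k, beta, basis, chi_b) {
  M <- matrix(0 + 0i, 5L, 5L)
  for (j in 1:4) {
    b <- basis[[j]]
    f0 <- b$f(0); f1 <- b$f(1)
    d10 <- b$d1(0); d11 <- b$d1(1)
    M[1L, j] <- d10                                    # psi'(0) = chi_b Delta_b
    M[2L, j] <- d11                                    # psi'(1) = 0
    M[3L, j] <- b$d2(0) - beta * d10                   # psi''(0) = f_sl(0)
    M[4L, j] <- b$d2(1) - k * (f1 - f0) - beta * d11   # psi''(1) = f_sl(1)
    M[5L, j] <- k * (b$I - f0) + beta * (f1 - f0)      # global balance
  }
  M[1L, 5L] <- -chi_b
  M[3L, 5L] <- -k
  M[4L, 5L] <- -k
  M[5L, 5L] <- k - chi_b
  M
}

#' Solve the mechanochemical model for the predicted waveform
#'
#' Given the three motor/stiffness parameters and \eqn{\bar{Ma}}, assembles
#' the boundary-value problem for the complex fundamental mode and closes it
#' by solving the solvability condition \eqn{\det M(\chi_b) = 0} for the
#' complex basal response \eqn{\chi_b} (the determinant is affine in
#' \eqn{\chi_b}, giving a closed-form root). The nullspace of the singular
#' system yields the waveform, which is returned in the co-swimming gauge
#' (exact arc-length mean \eqn{\int_0^1 \psi\, ds} subtracted) and normalized
#' to unit root-mean-square on the grid.
#'
#' @param k sliding stiffness (> 0, dimensionless).
#' @param beta_re,beta_im instantaneous (\eqn{\beta'}) and dynamic
#'   (\eqn{\beta''}) curvature-response coefficients; forward (base-to-tip)
#'   propagation corresponds to \eqn{\beta'' < 0}.
#' @param Mabar dimensionless viscous-elastic ratio (> 0).
#' @param s arc-length grid the waveform is evaluated on; defaults to the
#'   24-point chord-midpoint grid used for experimental modes.
#' @return an object of class `machin_waveform`: list with `psi` (complex
#'   tangent-angle profile), `dpsi` (curvature \eqn{\partial_s\psi}), `f_sl`
#'   (sliding-force density), `Delta_b`, `F_b`, `chi_b`, `n_wave` (wavenumber
#'   of the curvature profile), `s`, the input parameters, boundary/balance
#'   `residuals` (relative), and `norm = "unit-rms, zero arc-length mean"`.
#' @examples
#' w <- predict_waveform(k = 20, beta_re = 0.15, beta_im = -9.6, Mabar = 50)
#' round(Mod(w$psi), 2)  # amplitude dip in the middle
#' @export
predict_waveform <- function(k, beta_re, beta_im, Mabar, s = midpoint_grid(24)) {
  stopifnot_scalar(k = k, Mabar = Mabar, positive = TRUE)
  stopifnot_scalar(beta_re = beta_re, beta_im = beta_im)
  beta <- complex(real = beta_re, imaginary = beta_im)
  cr <- characteristic_roots(k, beta, Mabar)
  basis <- machin_basis(cr$roots, cr$degenerate)

  d0 <- cplx_det(machin_system(k, beta, basis, 0 + 0i))
  d1 <- cplx_det(machin_system(k, beta, basis, 1 + 0i))
  if (Mod(d0 - d1) < 1e-300)
    stop("degenerate solvability condition: determinant does not depend on chi_b")
  chi_b <- d0 / (d0 - d1)

  M <- machin_system(k, beta, basis, chi_b)
  sv <- svd(M)
  if (sv$d[1] / max(sv$d[4], 1e-300) > 1e12 && sv$d[4] / sv$d[1] > 1e-12)
    stop("singular nullspace extraction: system is ill-conditioned")
  v <- sv$v[, 5L]
  A <- v[1:4]
  Delta_b <- v[5L]

  eval_sum <- function(fun, ss) {
    m <- vapply(1:4, function(j) A[j] * fun[[j]](ss), complex(length(ss)))
    if (length(ss) == 1L) sum(m) else rowSums(m)
  }
  fs <- lapply(basis, `[[`, "f")
  d1s <- lapply(basis, `[[`, "d1")
  d2s <- lapply(basis, `[[`, "d2")

  psi_raw <- eval_sum(fs, s)
  dpsi <- eval_sum(d1s, s)
  psi0 <- eval_sum(fs, 0)               # psi at the base, pre-gauge
  Ipsi <- sum(vapply(1:4, function(j) A[j] * basis[[j]]$I, complex(1)))

  f_sl <- k * (Delta_b + psi_raw - psi0) + beta * dpsi
  F_b <- chi_b * Delta_b

  # self-consistency residuals, relative to the profile scale
  scale0 <- max(Mod(psi_raw - Ipsi))
  res <- c(
    dpsi_tip   = Mod(eval_sum(d1s, 1)),
    basal_force = Mod(eval_sum(d1s, 0) - F_b),
    torque_base = Mod(eval_sum(d2s, 0) -
                        (k * Delta_b + beta * eval_sum(d1s, 0))),
    torque_tip  = Mod(eval_sum(d2s, 1) -
                        (k * (Delta_b + eval_sum(fs, 1) - psi0) +
                           beta * eval_sum(d1s, 1))),
    global_balance = Mod(k * (Delta_b + Ipsi - psi0) +
                           beta * (eval_sum(fs, 1) - psi0) - F_b)
  ) / scale0

  # co-swimming gauge (exact integral) and unit-rms normalization
  psi <- psi_raw - Ipsi
  z <- sqrt(mean(Mod(psi)^2))
  psi <- psi / z
  dpsi <- dpsi / z
  f_sl <- f_sl / z
  Delta_b <- Delta_b / z
  F_b <- F_b / z

  w <- structure(
    list(psi = psi, dpsi = dpsi, f_sl = f_sl, Delta_b = Delta_b, F_b = F_b,
         chi_b = chi_b, s = s, k = k, beta_re = beta_re, beta_im = beta_im,
         Mabar = Mabar, residuals = res, degenerate = any(cr$degenerate),
         norm = "unit-rms, zero arc-length mean"),
    class = "machin_waveform")
  w$n_wave <- wavenumber_of(w)
  if (Re(chi_b) < 0)
    attr(w, "chi_b_warning") <- "solved chi_b has negative real part"
  w
}

#' @export
print.machin_waveform <- function(x, ...) {
  cat(sprintf(
    "Machin-model waveform: k = %.4g, beta = %.4g %+.4gi, Mabar = %.4g\n",
    x$k, x$beta_re, x$beta_im, x$Mabar))
  cat(sprintf("  chi_b = %.4g %+.4gi, n_wave = %.3g, max residual = %.2e\n",
              Re(x$chi_b), Im(x$chi_b), x$n_wave, max(x$residuals)))
  if (!is.null(attr(x, "chi_b_warning")))
    cat("  warning:", attr(x, "chi_b_warning"), "\n")
  invisible(x)
}

#' Wavenumber of a model waveform
#'
#' Total unwrapped phase change of the curvature profile
#' \eqn{\partial_s\psi} across the filament, divided by \eqn{2\pi}
#' (absolute value). Used to select the lowest-wavenumber solution branch.
#'
#' @param w a `machin_waveform`, or a complex curvature profile.
#' @return non-negative number.
#' @export
wavenumber_of <- function(w) {
  dpsi <- if (inherits(w, "machin_waveform")) w$dpsi else as.complex(w)
  if (all(Mod(dpsi) < 1e-300)) stop("zero curvature profile")
  ph <- unwrap_phase(Arg(dpsi))
  abs(ph[length(ph)] - ph[1]) / (2 * pi)
}

#' Dry-friction relation between sliding stiffness and dynamic response
#'
#' In the low-friction limit \eqn{\bar{Ma} \to 0} with vanishing basal
#' response, solutions exist only on discrete branches
#' \eqn{\beta\sqrt{1 + 4k/\beta^2} = 2\pi i n}. For real stiffness this
#' forces \eqn{\beta' = 0} and gives the closed form
#' \eqn{k = ((\beta'')^2 - 4\pi^2 n^2)/4}; the plane-wave point
#' \eqn{\beta'' = -4\pi}, \eqn{n = 1} yields \eqn{k = 3\pi^2}.
#'
#' @param beta_im dynamic curvature response \eqn{\beta''} (< 0 for forward
#'   propagation). Exactly one of `beta_im` and `k` must be given.
#' @param k sliding stiffness; when supplied, the relation is inverted for
#'   the forward-propagating branch \eqn{\beta'' < 0}.
#' @param n positive integer branch index.
#' @return `k` (when `beta_im` is given) or `beta_im` (when `k` is given).
#' @examples
#' dry_friction_relation(beta_im = -4 * pi)        # 3 pi^2
#' dry_friction_relation(k = 3 * pi^2)             # -4 pi
#' @export
dry_friction_relation <- function(beta_im = NULL, k = NULL, n = 1L) {
  if (n < 1 || n != round(n)) stop("'n' must be a positive integer")
  if (is.null(k) == is.null(beta_im))
    stop("supply exactly one of 'beta_im' and 'k'")
  if (!is.null(beta_im)) {
    kk <- (beta_im^2 - 4 * pi^2 * n^2) / 4
    if (kk <= 0)
      stop("no real stiffness on this branch: |beta''| <= 2*pi*n")
    kk
  } else {
    if (k <= 0) stop("'k' must be > 0")
    -2 * sqrt(k + pi^2 * n^2)
  }
}

#' Analytic waveform in the low-friction (dry) limit
#'
#' In the limit \eqn{\bar{Ma} \to 0}, \eqn{\chi_b \to 0} the curvature takes
#' the closed form
#' \eqn{\partial_s\psi = e^{\beta' s/2} \sin(n\pi(s-1)) e^{i\beta'' s/2}}
#' on the branch \eqn{cd = i\pi n} with \eqn{c = \beta/2},
#' \eqn{d = \sqrt{1 + 4k/\beta^2}}. The phase of the curvature is linear in
#' \eqn{s} with slope \eqn{\beta''/2}, so the wavelength-to-length ratio is
#' \eqn{\lambda/L = -4\pi/\beta''} (for \eqn{n = 1}); \eqn{\beta'' = -4\pi}
#' gives \eqn{\lambda = L}, the typical observation. The tangent angle is
#' recovered by cumulative integration on a fine grid with the additive
#' constant fixed by the zero arc-length mean (co-swimming gauge).
#'
#' @param beta_re instantaneous curvature response \eqn{\beta'}; sets the
#'   proximal-distal amplitude asymmetry.
#' @param beta_im dynamic curvature response \eqn{\beta''} (must be < 0).
#' @param n positive integer branch index.
#' @param s grid for the returned profiles (default 24-point midpoint grid).
#' @return an object of class `lowfriction_waveform`: list with `psi`,
#'   `dpsi`, `s`, `c`, `d` (complex branch constants satisfying
#'   \eqn{cd = i\pi n}), `k` (complex stiffness from the branch condition),
#'   `n`, `lam_over_L` (\eqn{-4\pi/(n\beta'')}), and `solvability`, a
#'   function `(chi_b, c, k)` returning the residual of the finite-basal
#'   condition \eqn{\tanh(cd) + \chi_b c d/(\chi_b c + k)}.
#' @examples
#' lf <- lowfriction_waveform(0, -4 * pi, 1)
#' lf$lam_over_L  # exactly 1
#' @export
lowfriction_waveform <- function(beta_re, beta_im, n = 1L,
                                 s = midpoint_grid(24)) {
  stopifnot_scalar(beta_re = beta_re, beta_im = beta_im)
  if (beta_im >= 0) stop("'beta_im' must be < 0 (forward propagation)")
  if (n < 1 || n != round(n)) stop("'n' must be a positive integer")

  beta <- complex(real = beta_re, imaginary = beta_im)
  cc <- beta / 2
  dd <- 1i * pi * n / cc            # branch condition c d = i pi n
  # complex stiffness implied by d = sqrt(1 + 4k/beta^2):
  # k = c^2 (d^2 - 1) = -pi^2 n^2 - c^2
  k_cplx <- -pi^2 * n^2 - cc^2

  dpsi_fun <- function(ss)
    exp(beta_re * ss / 2) * sin(n * pi * (ss - 1)) *
      exp(1i * beta_im * ss / 2)

  # integrate curvature on a fine grid; gauge by zero arc-length mean
  sf <- seq(0, 1, length.out = 8193L)
  dp <- dpsi_fun(sf)
  h <- sf[2] - sf[1]
  psi_f <- cumsum(c(0, h * (utils::head(dp, -1) + utils::tail(dp, -1)) / 2))
  psi_f <- psi_f - (h * (sum(psi_f) - (psi_f[1] + psi_f[length(psi_f)]) / 2))
  psi <- stats::approx(sf, Re(psi_f), s)$y +
    1i * stats::approx(sf, Im(psi_f), s)$y

  structure(
    list(psi = psi, dpsi = dpsi_fun(s), s = s,
         c = cc, d = dd, k = k_cplx, n = n,
         beta_re = beta_re, beta_im = beta_im,
         lam_over_L = -4 * pi / (n * beta_im),
         solvability = function(chi_b, c, k)
           tanh(c * sqrt(1 + k / c^2)) +
             chi_b * c * sqrt(1 + k / c^2) / (chi_b * c + k)),
    class = "lowfriction_waveform")
}

#' @export
print.lowfriction_waveform <- function(x, ...) {
  cat(sprintf(
    "Low-friction waveform: beta = %.4g %+.4gi, branch n = %d\n",
    x$beta_re, x$beta_im, x$n))
  cat(sprintf("  lambda/L = %.4g, complex k = %.4g %+.4gi\n",
              x$lam_over_L, Re(x$k), Im(x$k)))
  invisible(x)
}
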