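# Behavioural shape space: Legendre coordinates of the amplitude and phase
# profiles and dataset-level statistics (variance explained, principal
# components, variance components, energetic envelopes).

#' Shape features of a fundamental mode
#'
#' Decomposes the amplitude and phase profiles into shifted Legendre
#' polynomials up to order 2. Amplitude coefficients are normalized by the
#' mean amplitude \eqn{a_0} (asymmetry \eqn{\bar{a}_1 = a_1/a_0},
#' parabolicity \eqn{\bar{a}_2 = a_2/a_0}); the first-order phase
#' coefficient defines the wavelength through \eqn{\phi_1 = -\pi L/\lambda}.
#' A non-negative \eqn{\phi_1} (no forward-travelling wave) raises a warning
#' and the wavelength is reported signed.
#'
#' @param mode a [fundamental_mode()], or any list with fields `a`, `phi`,
#'   `s`, `f`, `L` (and optionally `Q`, `condition`, `axoneme_id`).
#' @return an object of class `shape_features`: list with `a0`, `a1`, `a2`,
#'   `abar1`, `abar2`, `phi1`, `phi2`, `lam` (um), `lam_over_L`, `f`, `L`,
#'   `Q`, `condition`, `axoneme_id`.
#' @examples
#' m <- list(a = rep(0.5, 24), phi = -2 * pi * midpoint_grid(24),
#'           s = midpoint_grid(24), f = 50, L = 11)
#' shape_features(m)$lam_over_L  # ~1: phase slope -2*pi means lambda = L
#' @export
shape_features <- function(mode) {
  an <- legendre_decompose(mode$a, mode$s, 2L)
  if (an[["g0"]] <= 0) stop("mean amplitude a0 must be > 0")
  pn <- legendre_decompose(mode$phi, mode$s, 2L)
  phi1 <- pn[["g1"]]
  if (phi1 >= 0)
    warning("no forward-travelling wave: phi1 >= 0; wavelength reported signed")
  structure(
    list(a0 = an[["g0"]], a1 = an[["g1"]], a2 = an[["g2"]],
         abar1 = an[["g1"]] / an[["g0"]], abar2 = an[["g2"]] / an[["g0"]],
         phi1 = phi1, phi2 = pn[["g2"]],
         lam = -pi * mode$L / phi1, lam_over_L = -pi / phi1,
         f = mode$f, L = mode$L, Q = mode$Q %||% NA_real_,
         condition = mode$condition %||% NA_character_,
         axoneme_id = mode$axoneme_id %||% NA_character_),
    class = "shape_features")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.shape_features <- function(x, ...) {
  cat(sprintf("Shape features '%s' (%s):\n", x$axoneme_id, x$condition))
  cat(sprintf("  a0 = %.3f rad, abar1 = %+.3f, abar2 = %+.3f\n",
              x$a0, x$abar1, x$abar2))
  cat(sprintf("  phi1 = %+.3f, phi2 = %+.3f, lambda/L = %.3f\n",
              x$phi1, x$phi2, x$lam_over_L))
  invisible(x)
}

#' @export
as.data.frame.shape_features <- function(x, ...) {
  data.frame(axoneme_id = x$axoneme_id, condition = x$condition,
             f_Hz = x$f, a0_rad = x$a0, abar1 = x$abar1, abar2 = x$abar2,
             phi1_rad = x$phi1, phi2_rad = x$phi2, L_um = x$L,
             lam_um = x$lam, lam_over_L = x$lam_over_L, Q = x$Q)
}

#' Behavioural-space table of a set of modes
#'
#' @param modes list of [fundamental_mode()] objects.
#' @return data.frame with one row per axoneme (columns `axoneme_id`,
#'   `condition`, `f_Hz`, `a0_rad`, `abar1`, `abar2`, `phi1_rad`,
#'   `phi2_rad`, `L_um`, `lam_um`, `lam_over_L`, `Q`).
#' @export
shape_table <- function(modes) {
  do.call(rbind, lapply(modes, function(m) as.data.frame(shape_features(m))))
}

#' Fraction of profile variance explained by Legendre orders
#'
#' For a set of normalized profiles, computes for each order \eqn{n} the
#' pooled fraction \eqn{1 - \sum_i \|g_i - \Pi_{\le n} g_i\|^2 /
#' \sum_i \|g_i - \bar{g}_{0,i}\|^2}, where \eqn{\Pi_{\le n}} is the
#' least-squares projection onto polynomials of order \eqn{\le n} on the
#' common grid and \eqn{\bar{g}_{0,i}} the order-0 (mean) part of each
#' profile. The order-0 content is excluded from the denominator because
#' only shape, not overall magnitude, is of interest. Fractions are
#' non-decreasing in \eqn{n} by construction.
#'
#' @param profiles matrix with one row per axoneme, columns sampled at `s`.
#' @param s common arc-length grid.
#' @param max_order highest order reported.
#' @return named numeric vector `order0 ... order<max_order>`.
#' @export
variance_explained <- function(profiles, s = midpoint_grid(ncol(profiles)),
                               max_order = 5L) {
  profiles <- as.matrix(profiles)
  if (nrow(profiles) < 2L) stop("need at least 2 profiles")
  P <- legendre_basis(s, max_order)
  res <- numeric(max_order + 1L)
  for (n in 0:max_order) {
    Pn <- P[, seq_len(n + 1L), drop = FALSE]
    H <- Pn %*% solve(crossprod(Pn), t(Pn))
    R <- profiles - profiles %*% t(H)
    res[n + 1L] <- sum(R^2)
  }
  denom <- res[1L]  # residual after removing the order-0 (mean) part
  if (denom <= 0) stop("profiles have no variance beyond their means")
  out <- 1 - res / denom
  names(out) <- paste0("order", 0:max_order)
  out
}

#' Correlation of Legendre coefficients with principal components
#'
#' Performs a principal-component analysis of the mean-centred normalized
#' amplitude profiles \eqn{a(s)/a_0} and reports Pearson correlations of the
#' asymmetry and parabolicity coefficients with the first two component
#' scores and with the phase coefficients \eqn{\phi_2, \phi_1}. Component
#' signs are fixed so that \eqn{\mathrm{corr}(\bar{a}_1, pc_1) \ge 0} and
#' \eqn{\mathrm{corr}(\bar{a}_2, pc_2) \ge 0}.
#'
#' @param features data.frame with columns `abar1`, `abar2`, `phi1_rad`
#'   (or `phi1`), `phi2_rad` (or `phi2`), one row per axoneme.
#' @param profiles matrix of normalized amplitude profiles (rows match
#'   `features`).
#' @return a 2 x 4 correlation matrix with rows `abar1`, `abar2` and columns
#'   `pc1`, `pc2`, `phi2`, `phi1`.
#' @export
pca_correlations <- function(features, profiles) {
  profiles <- as.matrix(profiles)
  if (nrow(profiles) < 3L) stop("need at least 3 axonemes")
  if (nrow(profiles) != nrow(features))
    stop("'features' and 'profiles' must have matching rows")
  if (all(apply(profiles, 2L, stats::sd) < 1e-12))
    stop("profiles are constant across axonemes: no variance to decompose")
  phi1 <- features[["phi1_rad"]] %||% features[["phi1"]]
  phi2 <- features[["phi2_rad"]] %||% features[["phi2"]]
  pc <- stats::prcomp(profiles, center = TRUE, scale. = FALSE)
  if (ncol(pc$x) < 2L) stop("rank-deficient profile data")
  sc1 <- pc$x[, 1L]; sc2 <- pc$x[, 2L]
  safe_cor <- function(x, y) {
    if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
    stats::cor(x, y)
  }
  c1 <- safe_cor(features$abar1, sc1)
  if (!is.na(c1) && c1 < 0) sc1 <- -sc1
  c2 <- safe_cor(features$abar2, sc2)
  if (!is.na(c2) && c2 < 0) sc2 <- -sc2
  out <- rbind(
    abar1 = c(safe_cor(features$abar1, sc1), safe_cor(features$abar1, sc2),
              safe_cor(features$abar1, phi2), safe_cor(features$abar1, phi1)),
    abar2 = c(safe_cor(features$abar2, sc1), safe_cor(features$abar2, sc2),
              safe_cor(features$abar2, phi2), safe_cor(features$abar2, phi1)))
  colnames(out) <- c("pc1", "pc2", "phi2", "phi1")
  out
}

#' One-way variance components of a per-axoneme scalar
#'
#' Method-of-moments estimates of the between-condition and within-condition
#' variance of a scalar trait, with the unbalanced-design correction
#' (conditions contribute through the effective replicate number
#' \eqn{n_0 = (N - \sum n_i^2/N)/(a - 1)}). The between component is floored
#' at zero. Conditions with a single axoneme are excluded with a warning.
#'
#' @param values numeric vector, one value per axoneme.
#' @param labels condition label per axoneme.
#' @return list with `between`, `within`, `ratio` (= between/within; `Inf`
#'   with `degenerate = TRUE` when the within variance is 0),
#'   `n_conditions`, `n_total` and `excluded` (labels dropped).
#' @examples
#' set.seed(1)
#' g <- rep(1:10, each = 8)
#' x <- rnorm(10, sd = 4)[g] + rnorm(80)
#' variance_components(x, g)$ratio  # ~16
#' @export
variance_components <- function(values, labels) {
  labels <- as.character(labels)
  stopifnot(length(values) == length(labels))
  n_i <- table(labels)
  excluded <- names(n_i)[n_i < 2L]
  if (length(excluded) > 0) {
    warning("excluding conditions with a single axoneme: ",
            paste(excluded, collapse = ", "))
    keep <- !(labels %in% excluded)
    values <- values[keep]; labels <- labels[keep]
    n_i <- table(labels)
  }
  a <- length(n_i)
  if (a < 2L) stop("need at least 2 conditions with >= 2 axonemes")
  N <- length(values)
  means <- tapply(values, labels, mean)
  vars <- tapply(values, labels, stats::var)
  msw <- sum((n_i - 1L) * vars) / (N - a)
  grand <- mean(values)
  msb <- sum(n_i * (means - grand)^2) / (a - 1L)
  n0 <- (N - sum(n_i^2) / N) / (a - 1L)
  between <- max((msb - msw) / n0, 0)
  degenerate <- msw <= 0
  list(between = between, within = msw,
       ratio = if (degenerate) Inf else between / msw,
       degenerate = degenerate,
       n_conditions = a, n_total = N, excluded = excluded)
}

#' Energetic amplitude-frequency envelopes
#'
#' If the energy available per beat bounds the dissipation, the mean
#' amplitude is limited by \eqn{a_0 \propto f^{-1/2}} when elastic
#' dissipation (\eqn{\propto a_0^2 f}) dominates and by
#' \eqn{a_0 \propto f^{-1}} when viscous dissipation (\eqn{\propto a_0^2
#' f^2}) dominates. This returns the tightest such bounding curves over a
#' behavioural table.
#'
#' @param features data.frame with columns `a0_rad` (or `a0`) and `f_Hz`
#'   (or `f`).
#' @return list with constants `A_elastic` (= max \eqn{a_0 f^{1/2}}),
#'   `A_viscous` (= max \eqn{a_0 f}) and the two envelope functions
#'   `elastic(f)`, `viscous(f)`.
#' @export
energetics_envelope <- function(features) {
  a0 <- features[["a0_rad"]] %||% features[["a0"]]
  f <- features[["f_Hz"]] %||% features[["f"]]
  if (is.null(a0) || is.null(f) || length(a0) == 0)
    stop("'features' must contain a0 and f columns")
  A_el <- max(a0 * sqrt(f))
  A_vis <- max(a0 * f)
  list(A_elastic = A_el, A_viscous = A_vis,
       elastic = function(f) A_el / sqrt(f),
       viscous = function(f) A_vis / f)
}
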