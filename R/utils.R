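# Internal numerical helpers shared across modules.

# Determinant of a (possibly complex) square matrix by LU with partial
# pivoting. base::det() rejects complex input.
cplx_det <- function(M) {
  n <- nrow(M)
  d <- 1 + 0i
  for (j in seq_len(n - 1L)) {
    p <- which.max(Mod(M[j:n, j])) + j - 1L
    if (Mod(M[p, j]) == 0) return(0 + 0i)
    if (p != j) {
      tmp <- M[j, ]; M[j, ] <- M[p, ]; M[p, ] <- tmp
      d <- -d
    }
    d <- d * M[j, j]
    M[(j + 1L):n, ] <- M[(j + 1L):n, ] -
      outer(M[(j + 1L):n, j] / M[j, j], M[j, ])
  }
  d * M[n, n]
}

#' Unwrap a phase sequence
#'
#' Removes 2*pi jumps from a phase sequence along its natural ordering,
#' e.g. the argument of a complex mode profile along arc length.
#'
#' @param phi numeric vector of phases in radians.
#' @return numeric vector with jumps larger than pi folded out.
#' @export
unwrap_phase <- function(phi) {
  if (length(phi) < 2L) return(phi)
  d <- diff(phi)
  phi - c(0, cumsum(2 * pi * round(d / (2 * pi))))
}

# Quadrature weights for integrating over [0,1] from samples at `s`.
# Each sample owns the cell between the midpoints of its neighbours, with the
# first and last cells extended to 0 and 1. On an inclusive uniform grid this
# is the trapezoidal rule; on a midpoint grid it is the midpoint rule (which
# covers the whole interval and preserves the s -> 1-s symmetry).
cell_weights <- function(s) {
  if (is.unsorted(s, strictly = TRUE))
    stop("arc-length grid must be strictly increasing")
  if (s[1] < -1e-12 || s[length(s)] > 1 + 1e-12)
    stop("arc-length grid must lie in [0, 1]")
  edges <- c(0, (utils::head(s, -1) + utils::tail(s, -1)) / 2, 1)
  diff(edges)
}

# Integral over [0,1] using cell weights; `y` may be complex.
arc_integral <- function(y, s) sum(cell_weights(s) * y)

#' Uniform midpoint grid on \[0, 1\]
#'
#' Arc-length positions of the chord midpoints of `n + 1` equally spaced
#' tracked points: `(2i - 1)/(2n)`, `i = 1..n`. This is the native grid of
#' tangent-angle profiles (24 points for 25-point tracks); plain means on it
#' are midpoint-rule integrals over the full interval, and it is symmetric
#' under `s -> 1 - s`, so symmetric amplitude profiles keep zero asymmetry.
#'
#' @param n number of chords (grid points).
#' @return numeric vector of length `n`.
#' @export
midpoint_grid <- function(n) (2 * seq_len(n) - 1) / (2 * n)

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

stopifnot_scalar <- function(..., positive = FALSE) {
  args <- list(...)
  nm <- names(args)
  for (i in seq_along(args)) {
    if (!is_scalar_number(args[[i]]))
      stop(sprintf("'%s' must be a finite numeric scalar", nm[i]), call. = FALSE)
    if (positive && args[[i]] <= 0)
      stop(sprintf("'%s' must be > 0", nm[i]), call. = FALSE)
  }
  invisible(TRUE)
}
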