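#' Shifted Legendre polynomials on [0, 1]
#'
#' Evaluates the shifted Legendre polynomials \eqn{\ell_n(s)} used to
#' decompose amplitude and phase profiles. They are normalized so that
#' \eqn{\int_0^1 \ell_n \ell_m \, ds = \delta_{nm} / (2n + 1)}; the first
#' three are \eqn{\ell_0 = 1}, \eqn{\ell_1 = 2s - 1} and
#' \eqn{\ell_2 = 6s^2 - 6s + 1}.
#'
#' @param s numeric vector of arc-length positions in \[0, 1\].
#' @param max_order highest polynomial order to evaluate.
#' @return a matrix with `length(s)` rows and `max_order + 1` columns, column
#'   `n + 1` holding \eqn{\ell_n(s)}.
#' @examples
#' legendre_basis(seq(0, 1, 0.25), 2)
#' @export
legendre_basis <- function(s, max_order = 2L) {
  if (max_order < 0) stop("'max_order' must be >= 0")
  x <- 2 * s - 1  # map to the standard Legendre argument
  P <- matrix(NA_real_, length(s), max_order + 1L)
  P[, 1L] <- 1
  if (max_order >= 1L) P[, 2L] <- x
  if (max_order >= 2L) {
    for (n in 2:max_order) {
      # Bonnet recursion for standard Legendre polynomials
      P[, n + 1L] <- ((2 * n - 1) * x * P[, n] - (n - 1) * P[, n - 1L]) / n
    }
  }
  colnames(P) <- paste0("l", 0:max_order)
  P
}

#' Decompose a profile into shifted Legendre coefficients
#'
#' Computes the expansion coefficients
#' \eqn{g_n = (2n + 1) \int_0^1 g(s) \ell_n(s) \, ds} from samples on a
#' grid. Each sample is weighted by the cell it owns in \[0, 1\] (midpoint
#' rule on a midpoint grid, trapezoidal rule on an inclusive uniform grid),
#' and the small discrete non-orthogonality of the sampled basis is removed
#' through the Gram matrix (weighted least squares), so the decomposition is
#' exact on polynomials up to `max_order` on any grid. \eqn{g_0} is the
#' arc-length mean of the profile.
#'
#' @param g numeric (or complex) profile sampled at `s`.
#' @param s arc-length grid in \[0, 1\]; defaults to the uniform midpoint
#'   grid with `length(g)` cells.
#' @param max_order highest order returned.
#' @return named numeric vector `g0 ... g<max_order>`.
#' @seealso [legendre_reconstruct()], [shape_features()]
#' @examples
#' s <- (2 * (1:24) - 1) / 48
#' legendre_decompose(2 * s - 1, s)  # close to (0, 1, 0)
#' @export
legendre_decompose <- function(g, s = midpoint_grid(length(g)), max_order = 2L) {
  if (length(g) != length(s)) stop("'g' and 's' must have the same length")
  if (max_order >= length(g) - 2L)
    stop("'max_order' must be smaller than the number of grid points minus 2")
  w <- cell_weights(s)
  P <- legendre_basis(s, max_order)
  G <- crossprod(P, w * P)           # ~ diag(1/(2n+1)) + O(h^2)
  gn <- as.vector(solve(G, crossprod(P, w * g)))
  names(gn) <- paste0("g", 0:max_order)
  gn
}

#' Reconstruct a profile from shifted Legendre coefficients
#'
#' @param gn coefficient vector as returned by [legendre_decompose()].
#' @param s arc-length grid to evaluate on.
#' @return numeric vector of the truncated series \eqn{\sum_n g_n \ell_n(s)}.
#' @export
legendre_reconstruct <- function(gn, s) {
  P <- legendre_basis(s, length(gn) - 1L)
  as.vector(P %*% gn)
}
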