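#' Gauss--Legendre quadrature nodes and weights
#'
#' Nodes and weights for n-point Gauss--Legendre quadrature on \[-1, 1\],
#' computed by the Golub--Welsch eigenvalue method. Deterministic; used both
#' for the default angular grid (nodes in cos(theta)) and for projecting
#' angular envelopes onto Legendre polynomials.
#'
#' @param n number of nodes (>= 1)
#' @return list with `nodes` (ascending) and `weights`
#' @export
gauss_legendre <- function(n) {
  n <- as.integer(n)
  if (n < 1L) stop("gauss_legendre: n must be >= 1")
  if (n == 1L) return(list(nodes = 0, weights = 2))
  k <- seq_len(n - 1L)
  b <- k / sqrt(4 * k^2 - 1)
  J <- matrix(0, n, n)
  J[cbind(k, k + 1L)] <- b
  J[cbind(k + 1L, k)] <- b
  e <- eigen(J, symmetric = TRUE)
  ord <- order(e$values)
  list(nodes = e$values[ord], weights = 2 * (e$vectors[1, ord])^2)
}

#' Legendre polynomial design matrix
#'
#' Evaluates P_0(x)..P_lmax(x) by the three-term recursion.
#'
#' @param x numeric vector in \[-1, 1\]
#' @param lmax maximum degree
#' @return matrix of dim `length(x) x (lmax + 1)`
#' @export
legendre_matrix <- function(x, lmax) {
  x <- as.numeric(x)
  P <- matrix(0, length(x), lmax + 1L)
  P[, 1] <- 1
  if (lmax >= 1L) P[, 2] <- x
  if (lmax >= 2L) {
    for (l in 2:lmax) {
      P[, l + 1L] <- ((2 * l - 1) * x * P[, l] - (l - 1) * P[, l - 1L]) / l
    }
  }
  P
}

# Derivative dP_l/dx via (x^2-1)/l * P_l' = x P_l - P_{l-1}; safe at |x|=1 by recursion:
# P_l'(x) = l * (x*P_l - P_{l-1}) / (x^2 - 1) is singular at poles, so use
# P_l'(x) recursion: P_l' = P_{l-2}' + (2l-1) P_{l-1}
legendre_deriv_matrix <- function(x, lmax) {
  P <- legendre_matrix(x, lmax)
  dP <- matrix(0, length(x), lmax + 1L)
  if (lmax >= 1L) dP[, 2] <- 1
  if (lmax >= 2L) {
    for (l in 2:lmax) dP[, l + 1L] <- dP[, l - 1L] + (2 * l - 1) * P[, l]
  }
  dP
}

#' Project angular samples onto Legendre polynomials in cos(theta)
#'
#' Least-squares coefficients c_lambda such that
#' `sum_lambda c_lambda P_lambda(cos theta_k)` best reproduces `values`.
#' When the theta nodes are Gauss--Legendre abscissae in cos(theta) the
#' least-squares solution coincides with the quadrature projection. With
#' `lambda_max + 1 == length(theta_deg)` the reproduction is exact
#' (interpolation).
#'
#' @param theta_deg distinct polar angles in degrees, in \[0, 180\]
#' @param values energies (or any samples) at `theta_deg`
#' @param lambda_max highest Legendre order retained
#' @return numeric vector of coefficients, length `lambda_max + 1`
#' @export
legendre_project <- function(theta_deg, values, lambda_max) {
  theta_deg <- as.numeric(theta_deg)
  values <- as.numeric(values)
  if (anyDuplicated(theta_deg)) stop("legendre_project: theta nodes must be distinct")
  if (any(!is.finite(values))) stop("legendre_project: values must be finite")
  if (lambda_max + 1L > length(theta_deg)) {
    stop("legendre_project: underdetermined (lambda_max + 1 > number of theta nodes)")
  }
  x <- cos(theta_deg * pi / 180)
  P <- legendre_matrix(x, lambda_max)
  qr.coef(qr(P), values)
}

# Project a smooth function f(theta_deg) onto P_0..P_lmax by high-order
# Gauss-Legendre quadrature in x = cos(theta). Returns exact coefficients for
# band-limited f; used to band-limit the synthetic angular envelopes.
project_function_legendre <- function(f, lmax, nquad = 120L) {
  gl <- gauss_legendre(nquad)
  th <- acos(gl$nodes) * 180 / pi
  fx <- f(th)
  P <- legendre_matrix(gl$nodes, lmax)
  vapply(seq_len(lmax + 1L), function(j) {
    l <- j - 1L
    (2 * l + 1) / 2 * sum(gl$weights * fx * P[, j])
  }, numeric(1))
}
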