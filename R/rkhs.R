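#' Kernel specification for RKHS surface fitting
#'
#' @param n radial-kernel smoothness order (integer >= 2); the fitted radial
#'   functions have `n - 1` continuous derivatives across nodes.
#' @param m radial-kernel asymptotic-decay order (integer >= 0); the kernel
#'   decays as `R^-(m+1)` at long range (default m = 5, a dispersion-like
#'   R^-6 tail).
#' @param sigma_phi width of the Gaussian doming kernel, degrees (default
#'   10, twice the default node spacing, for accurate off-node interpolation)
#' @param regularization non-negative Tikhonov weight added to the Gram
#'   system (0 = pure interpolation)
#' @return object of class `kernel_spec`
#' @export
kernel_spec <- function(n = 2L, m = 5L, sigma_phi = 10, regularization = 0) {
  n <- as.integer(n); m <- as.integer(m)
  if (n < 2L) stop("kernel_spec: n must be >= 2")
  if (m < 0L) stop("kernel_spec: m must be >= 0")
  if (sigma_phi <= 0) stop("kernel_spec: sigma_phi must be > 0")
  if (regularization < 0) stop("kernel_spec: regularization must be >= 0")
  structure(list(n = n, m = m, sigma_phi = sigma_phi,
                 regularization = regularization),
            class = "kernel_spec")
}

#' Radial reproducing kernel
#'
#' Reciprocal-power reproducing kernel of smoothness `n` and decay `m`:
#' \deqn{q_{n,m}(x, x') = n^2 B(m+1, n)\, x_>^{-(m+1)}
#'   \,{}_2F_1(-n+1, m+1; n+m+1; x_</x_>)}
#' where the hypergeometric factor is a finite polynomial. Symmetric,
#' strictly positive for positive arguments, and decaying as `R^-(m+1)` at
#' long range; the Gram matrix on distinct nodes is symmetric positive
#' definite.
#'
#' @param R,R_prime distances (A), must be > 0; recycled to common length
#' @param n,m kernel orders (see [kernel_spec()])
#' @return numeric vector of kernel values
#' @export
radial_kernel <- function(R, R_prime, n = 2L, m = 5L) {
  if (any(R <= 0) || any(R_prime <= 0)) {
    stop("radial_kernel: distances must be > 0")
  }
  n <- as.integer(n); m <- as.integer(m)
  if (n < 2L || m < 0L) stop("radial_kernel: require n >= 2, m >= 0")
  lo <- pmin(R, R_prime); hi <- pmax(R, R_prime)
  z <- lo / hi
  coef <- hyp2f1_poly_coefs(n, m)
  poly <- numeric(length(z))
  for (k in seq_along(coef)) poly <- poly + coef[k] * z^(k - 1)
  n^2 * beta(m + 1, n) * hi^(-(m + 1)) * poly
}

# finite 2F1(-n+1, m+1; n+m+1; z) series coefficients, k = 0..n-1
hyp2f1_poly_coefs <- function(n, m) {
  k <- 0:(n - 1L)
  vapply(k, function(kk) {
    if (kk == 0L) return(1)
    num1 <- prod(-n + 1 + 0:(kk - 1L))    # (-n+1)_k
    num2 <- prod(m + 1 + 0:(kk - 1L))     # (m+1)_k
    den <- prod(n + m + 1 + 0:(kk - 1L))  # (n+m+1)_k
    num1 * num2 / (den * factorial(kk))
  }, numeric(1))
}

#' Gaussian reproducing kernel over the doming angle
#'
#' `exp(-(phi - phi_prime)^2 / (2 sigma^2))`; unity at zero separation.
#'
#' @param phi,phi_prime doming angles, degrees
#' @param sigma_phi kernel width, degrees (> 0)
#' @return numeric vector of kernel values
#' @export
gaussian_kernel <- function(phi, phi_prime, sigma_phi = 10) {
  if (sigma_phi <= 0) stop("gaussian_kernel: sigma_phi must be > 0")
  exp(-(phi - phi_prime)^2 / (2 * sigma_phi^2))
}

#' Fit an RKHS surface to a tabulated energy grid
#'
#' Implements the expansion
#' \deqn{V(R,\theta,\varphi) = \sum_{\lambda=0}^{\lambda_{max}}
#'   V_\lambda(R,\varphi) P_\lambda(\cos\theta) + V_c(\varphi)} with
#' \deqn{V_\lambda(R,\varphi) = \sum_{i,j} \beta_{\lambda,i,j}\,
#'   \kappa(R, R_i)\, \Gamma(\varphi, \varphi_j).}
#' The harmonic doming term `V_c` is subtracted before projection and
#' re-added at evaluation. Per (R_i, phi_j) node column the angular values
#' are least-squares projected onto Legendre polynomials; per lambda the
#' coefficients beta solve the (radial x Gaussian) Gram system through a
#' Cholesky factorization, optionally stabilized by a Tikhonov term.
#'
#' @param grid a [sample_grid()] result (or object with the same fields)
#' @param state `"doublet"` or `"quartet"`
#' @param kernel a [kernel_spec()]
#' @param lambda_max highest Legendre order (default 10)
#' @param vc list(k, phi_e) doming parameters; defaults taken from the grid's
#'   surface spec when present
#' @param asymptote energy origin to subtract before fitting (defaults to the
#'   grid spec's asymptote, else 0)
#' @return object of class `rkhs_surface`
#' @export
fit_rkhs <- function(grid, state = c("doublet", "quartet"),
                     kernel = kernel_spec(), lambda_max = 10L,
                     vc = NULL, asymptote = NULL) {
  state <- match.arg(state)
  if (!state %in% names(grid$energy)) stop("fit_rkhs: grid lacks state ", state)
  if (is.null(vc)) {
    vc <- if (!is.null(grid$spec)) grid$spec$doming else list(k = 0.02, phi_e = 0)
  }
  if (is.null(asymptote)) {
    asymptote <- if (!is.null(grid$spec)) grid$spec$asymptote else 0
  }
  lambda_max <- as.integer(lambda_max)
  Rn <- grid$R_nodes; tn <- grid$theta_nodes; pn <- grid$phi_nodes
  if (lambda_max + 1L > length(tn)) {
    stop("fit_rkhs: lambda_max + 1 exceeds the number of theta nodes")
  }
  E <- grid$energy[[state]]
  if (any(!is.finite(E))) stop("fit_rkhs: grid energies must be finite")
  vc_vals <- 0.5 * vc$k * (pn - vc$phi_e)^2
  E <- sweep(E, 3L, vc_vals + asymptote)

  # angular projection per (R_i, phi_j): C[lambda, i, j]
  x <- cos(tn * pi / 180)
  P <- legendre_matrix(x, lambda_max)
  Pproj <- solve(crossprod(P), t(P))
  nR <- length(Rn); nphi <- length(pn); nl <- lambda_max + 1L
  C <- array(0, dim = c(nl, nR, nphi))
  for (j in seq_len(nphi)) C[, , j] <- Pproj %*% t(E[, , j])

  KR <- outer(Rn, Rn, radial_kernel, n = kernel$n, m = kernel$m)
  Kp <- outer(pn, pn, gaussian_kernel, sigma_phi = kernel$sigma_phi)
  M <- kronecker(KR, Kp)
  if (kernel$regularization > 0) {
    diag(M) <- diag(M) + kernel$regularization
  }
  ch <- tryCatch(chol(M), error = function(e) NULL)
  if (is.null(ch)) {
    stop("fit_rkhs: Gram system is numerically singular; ",
         "increase kernel_spec(regularization = ...)")
  }
  beta <- array(0, dim = c(nl, nR, nphi))
  for (l in seq_len(nl)) {
    rhs <- as.vector(t(C[l, , ]))  # index (i-1)*nphi + j, matching kronecker(KR, Kp)
    b <- backsolve(ch, forwardsolve(t(ch), rhs))
    beta[l, , ] <- matrix(b, nR, nphi, byrow = TRUE)
  }

  surf <- structure(list(state = state, beta = beta, R_nodes = Rn,
                         phi_nodes = pn, lambda_max = lambda_max,
                         kernel = kernel, vc = vc, asymptote = asymptote),
                    class = "rkhs_surface")
  pts <- expand.grid(R = Rn, theta = tn, phi = pn, KEEP.OUT.ATTRS = FALSE)
  fitted <- rkhs_evaluate(surf, pts$R, pts$theta, pts$phi)
  resid <- fitted - as.vector(grid$energy[[state]])
  surf$diagnostics <- list(max_node_residual = max(abs(resid)),
                           rms_node_residual = sqrt(mean(resid^2)),
                           gram_condition = kappa(M, exact = FALSE))
  surf
}

#' @export
print.rkhs_surface <- function(x, ...) {
  cat(sprintf("RKHS surface (%s): %d x %d radial/doming nodes, lambda_max = %d\n",
              x$state, length(x$R_nodes), length(x$phi_nodes), x$lambda_max))
  cat(sprintf("  kernel n = %d, m = %d, sigma_phi = %.1f deg, regularization = %g\n",
              x$kernel$n, x$kernel$m, x$kernel$sigma_phi, x$kernel$regularization))
  if (!is.null(x$diagnostics)) {
    cat(sprintf("  max node residual = %.3g kcal/mol, Gram condition ~ %.3g\n",
                x$diagnostics$max_node_residual, x$diagnostics$gram_condition))
  }
  invisible(x)
}

check_eval_domain <- function(R, theta) {
  if (any(R <= 0)) stop("rkhs surface: R must be > 0")
  if (any(theta < 0 | theta > 180)) {
    stop("rkhs surface: theta must lie in [0, 180] degrees")
  }
}

#' Evaluate an RKHS surface
#'
#' @param surface an [fit_rkhs()] result
#' @param R distances (A, > 0)
#' @param theta polar angles (degrees, in \[0, 180\])
#' @param phi doming angles (degrees); defaults to phi_e
#' @return energies in kcal/mol
#' @export
rkhs_evaluate <- function(surface, R, theta, phi = surface$vc$phi_e) {
  stopifnot(inherits(surface, "rkhs_surface"))
  pts <- vec_recycle(R, theta, phi)
  check_eval_domain(pts$a, pts$b)
  out <- cpp_rkhs_eval(surface$beta, surface$R_nodes, surface$phi_nodes,
                       surface$kernel$n, surface$kernel$m,
                       surface$kernel$sigma_phi, surface$vc$k,
                       surface$vc$phi_e, surface$asymptote,
                       pts$a, pts$b, pts$c, FALSE)
  out[, 1]
}

#' Gradient of an RKHS surface
#'
#' Analytic derivatives of the kernel expansion (plus the doming term) with
#' respect to R, theta and phi.
#'
#' @inheritParams rkhs_evaluate
#' @return matrix with columns `dR` (kcal/mol/A), `dtheta`, `dphi`
#'   (kcal/mol/deg)
#' @export
rkhs_gradient <- function(surface, R, theta, phi = surface$vc$phi_e) {
  stopifnot(inherits(surface, "rkhs_surface"))
  pts <- vec_recycle(R, theta, phi)
  check_eval_domain(pts$a, pts$b)
  out <- cpp_rkhs_eval(surface$beta, surface$R_nodes, surface$phi_nodes,
                       surface$kernel$n, surface$kernel$m,
                       surface$kernel$sigma_phi, surface$vc$k,
                       surface$vc$phi_e, surface$asymptote,
                       pts$a, pts$b, pts$c, TRUE)
  gr <- out[, 2:4, drop = FALSE]
  colnames(gr) <- c("dR", "dtheta", "dphi")
  gr
}

vec_recycle <- function(a, b, c) {
  n <- max(length(a), length(b), length(c))
  list(a = rep_len(as.numeric(a), n), b = rep_len(as.numeric(b), n),
       c = rep_len(as.numeric(c), n))
}
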