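#' Specification of the synthetic two-state reference surfaces
#'
#' Collects every constant that defines the analytic doublet/quartet reference
#' potentials: the two bound-state minima of the doublet (FeNO and FeON), the
#' repulsive background, the quartet shape (short-range wall, shallow
#' long-range well, and the calibrated Mp...NO shelf near the crossing
#' region), and the harmonic iron-doming term Vc(phi) = k/2 (phi - phi_e)^2.
#'
#' Defaults are the package's one-time calibration: the doublet minima are
#' pinned at (R = 2.37 A, theta = 160 deg, 21 kcal/mol) and (R = 2.48 A,
#' theta = 27 deg, 6 kcal/mol), and the quartet shelf is tuned so that the
#' lowest adiabat at R = 2.4 A with shift Delta = 5 kcal/mol crosses near
#' theta = 55 and 120 deg with barriers of 3.5 and 1 kcal/mol in the
#' FeON -> FeNO direction.
#'
#' Units: A (distances), degrees (angles), kcal/mol (energies),
#' kcal/mol/deg^2 (doming stiffness).
#'
#' @param fe_no_min list(R, theta, depth, alpha, kappa): primary FeNO well.
#'   `alpha` (1/A) is the radial Morse width, `kappa` the angular von-Mises
#'   concentration (dimensionless; larger = narrower well).
#' @param fe_on_min list(R, theta, depth, alpha, kappa): secondary FeON well.
#' @param background list(height, decay, R_ref): repulsive floor
#'   `height * exp(-decay (R - R_ref))` carried by the angular region between
#'   the two wells.
#' @param quartet list(wall_steepness, faint_depth, faint_R, shelf_depth,
#'   shelf_R, shelf_alpha, shelf_center, shelf_width, shelf_power): quartet
#'   shape. `faint_*` is the shallow long-range well away from the crossing
#'   region; `shelf_*` the calibrated Mp...NO well.
#' @param doming list(k, phi_e): harmonic doming term.
#' @param asymptote dissociation-limit energy of the (unshifted) doublet;
#'   defines the zero of energy.
#' @param lambda_max Legendre order used to band-limit the angular envelopes.
#' @return object of class `surface_spec`
#' @export
surface_spec <- function(fe_no_min = list(R = 2.37, theta = 160, depth = 21,
                                          alpha = 2.0, kappa = 5.91,
                                          depth_scale = 1.00562),
                         fe_on_min = list(R = 2.48, theta = 27, depth = 6,
                                          alpha = 2.0, kappa = 4.335,
                                          depth_scale = 0.98926),
                         background = list(height = 3.0, decay = 3.0, R_ref = 2.4),
                         quartet = list(wall_steepness = 2.0, faint_depth = 1.0,
                                        faint_R = 3.2, shelf_depth = 9.79,
                                        shelf_R = 2.45, shelf_alpha = 5.0,
                                        shelf_center = 88.94, shelf_width = 52.42,
                                        shelf_power = 6),
                         doming = list(k = 0.02, phi_e = 0),
                         asymptote = 0,
                         lambda_max = 10L) {
  spec <- structure(list(fe_no_min = fe_no_min, fe_on_min = fe_on_min,
                         background = background, quartet = quartet,
                         doming = doming, asymptote = asymptote,
                         lambda_max = as.integer(lambda_max)),
                    class = "surface_spec")
  validate_surface_spec(spec)
  spec
}

validate_surface_spec <- function(spec) {
  need <- function(ok, field) if (!isTRUE(ok)) stop("surface_spec: invalid field `", field, "`", call. = FALSE)
  fn <- spec$fe_no_min; fo <- spec$fe_on_min
  need(is.numeric(fn$depth) && is.numeric(fo$depth) && fn$depth > fo$depth && fo$depth > 0,
       "fe_no_min$depth > fe_on_min$depth > 0")
  need(fn$R > 0 && fo$R > 0, "fe_no_min$R / fe_on_min$R")
  need(fn$theta >= 0 && fn$theta <= 180 && fo$theta >= 0 && fo$theta <= 180,
       "fe_no_min$theta / fe_on_min$theta")
  need(fn$alpha > 0 && fo$alpha > 0, "radial widths (alpha)")
  need(fn$kappa > 0 && fo$kappa > 0, "angular widths (kappa)")
  need(spec$background$height >= 0 && spec$background$decay > 0, "background")
  q <- spec$quartet
  need(q$wall_steepness > 0, "quartet$wall_steepness")
  need(q$faint_depth >= 0 && q$faint_R > 0, "quartet$faint_depth / faint_R")
  need(q$shelf_depth >= 0 && q$shelf_R > 0 && q$shelf_alpha > 0 &&
         q$shelf_width > 0 && q$shelf_power >= 2, "quartet$shelf")
  need(spec$doming$k > 0, "doming$k")
  need(is.finite(spec$asymptote), "asymptote")
  invisible(spec)
}

# Morse-type well: depth D at Re, -> 0 as R -> Inf, repulsive core at short R.
morse_well <- function(R, D, Re, a) {
  e <- exp(-a * (R - Re))
  D * ((1 - e)^2 - 1)
}
morse_well_deriv <- function(R, D, Re, a) {
  e <- exp(-a * (R - Re))
  2 * D * a * (1 - e) * e
}

#' Build the analytic two-state reference surfaces
#'
#' Constructs smooth doublet (2A) and quartet (4A) energy functions of
#' (R, theta, phi) from a [surface_spec()]. The angular structure is carried
#' by envelopes expressed exactly in the span of the Legendre polynomials
#' P_0..P_10 (in cos theta), so the surfaces are by construction representable
#' by the package's finite angular expansion; the radial structure is a sum of
#' Morse-type wells and an exponential background, all of which vanish at the
#' dissociation limit.
#'
#' @param spec a [surface_spec()]
#' @param verify if `TRUE` (default) check the built doublet surface against
#'   the spec's stationary points and raise a calibration-failure error when a
#'   constraint is missed.
#' @return object of class `two_state_reference` with elements `V2A`, `V4A`
#'   (vectorized `function(R, theta, phi)`), `grad2A`, `grad4A` (returning a
#'   3-column matrix dV/dR, dV/dtheta, dV/dphi in kcal/mol per A / deg / deg),
#'   the envelope Legendre coefficients, and the spec.
#' @export
make_reference_surfaces <- function(spec = surface_spec(), verify = TRUE) {
  validate_surface_spec(spec)
  lmax <- spec$lambda_max
  vm <- function(center, kappa) {
    force(center); force(kappa)
    function(th) exp(kappa * (cos((th - center) * pi / 180) - 1))
  }
  plateau <- function(center, width, power) {
    force(center); force(width); force(power)
    function(th) exp(-(abs(th - center) / width)^power)
  }
  cNO <- project_function_legendre(vm(spec$fe_no_min$theta, spec$fe_no_min$kappa), lmax)
  cON <- project_function_legendre(vm(spec$fe_on_min$theta, spec$fe_on_min$kappa), lmax)
  e0 <- c(1, rep(0, lmax))
  cBG <- e0 - cNO - cON
  cSH <- project_function_legendre(
    plateau(spec$quartet$shelf_center, spec$quartet$shelf_width, spec$quartet$shelf_power), lmax)
  cFA <- e0 - cSH

  env_eval <- function(coef, th) drop(legendre_matrix(cos(th * pi / 180), lmax) %*% coef)
  env_deriv <- function(coef, th) {
    x <- cos(th * pi / 180)
    drop(legendre_deriv_matrix(x, lmax) %*% coef) * (-sin(th * pi / 180)) * pi / 180
  }

  vc <- function(phi) 0.5 * spec$doming$k * (phi - spec$doming$phi_e)^2
  vc_d <- function(phi) spec$doming$k * (phi - spec$doming$phi_e)

  fn <- spec$fe_no_min; fo <- spec$fe_on_min; bg <- spec$background; q <- spec$quartet
  dsn <- fn$depth_scale %||% 1
  dso <- fo$depth_scale %||% 1
  U_no  <- function(R) morse_well(R, fn$depth * dsn, fn$R, fn$alpha)
  U_on  <- function(R) morse_well(R, fo$depth * dso, fo$R, fo$alpha)
  U_bg  <- function(R) bg$height * exp(-bg$decay * (R - bg$R_ref))
  U_sh  <- function(R) morse_well(R, q$shelf_depth, q$shelf_R, q$shelf_alpha)
  U_fa  <- function(R) morse_well(R, q$faint_depth, q$faint_R, q$wall_steepness)
  dU_no <- function(R) morse_well_deriv(R, fn$depth * dsn, fn$R, fn$alpha)
  dU_on <- function(R) morse_well_deriv(R, fo$depth * dso, fo$R, fo$alpha)
  dU_bg <- function(R) -bg$decay * U_bg(R)
  dU_sh <- function(R) morse_well_deriv(R, q$shelf_depth, q$shelf_R, q$shelf_alpha)
  dU_fa <- function(R) morse_well_deriv(R, q$faint_depth, q$faint_R, q$wall_steepness)

  check_dom <- function(R, theta) {
    if (any(R <= 0)) stop("reference surface: R must be > 0")
    if (any(theta < 0 | theta > 180)) stop("reference surface: theta must lie in [0, 180] degrees")
  }
  V2A <- function(R, theta, phi = spec$doming$phi_e) {
    check_dom(R, theta)
    env_eval(cNO, theta) * U_no(R) + env_eval(cON, theta) * U_on(R) +
      env_eval(cBG, theta) * U_bg(R) + spec$asymptote + vc(phi)
  }
  V4A <- function(R, theta, phi = spec$doming$phi_e) {
    check_dom(R, theta)
    env_eval(cSH, theta) * U_sh(R) + env_eval(cFA, theta) * U_fa(R) +
      spec$asymptote + vc(phi)
  }
  grad2A <- function(R, theta, phi = spec$doming$phi_e) {
    check_dom(R, theta)
    cbind(dR = env_eval(cNO, theta) * dU_no(R) + env_eval(cON, theta) * dU_on(R) +
            env_eval(cBG, theta) * dU_bg(R),
          dtheta = env_deriv(cNO, theta) * U_no(R) + env_deriv(cON, theta) * U_on(R) +
            env_deriv(cBG, theta) * U_bg(R),
          dphi = vc_d(phi) + numeric(length(R)))
  }
  grad4A <- function(R, theta, phi = spec$doming$phi_e) {
    check_dom(R, theta)
    cbind(dR = env_eval(cSH, theta) * dU_sh(R) + env_eval(cFA, theta) * dU_fa(R),
          dtheta = env_deriv(cSH, theta) * U_sh(R) + env_deriv(cFA, theta) * U_fa(R),
          dphi = vc_d(phi) + numeric(length(R)))
  }

  ref <- structure(list(spec = spec, V2A = V2A, V4A = V4A,
                        grad2A = grad2A, grad4A = grad4A,
                        envelopes = list(fe_no = cNO, fe_on = cON, background = cBG,
                                         shelf = cSH, faint = cFA)),
                   class = "two_state_reference")
  if (verify) {
    rep <- verify_constraints(V2A, spec)
    if (!all(rep$pass)) {
      bad <- rep[!rep$pass, , drop = FALSE]
      stop("make_reference_surfaces: calibration failure; achieved values:\n",
           paste(sprintf("  %s: target %.4g achieved %.4g (tol %.3g)",
                         bad$name, bad$target, bad$achieved, bad$tolerance),
                 collapse = "\n"), call. = FALSE)
    }
  }
  ref
}

#' @export
print.two_state_reference <- function(x, ...) {
  cat("Two-state reference surfaces (doublet/quartet)\n")
  cat(sprintf("  FeNO minimum: R = %.2f A, theta = %.0f deg, depth = %.1f kcal/mol\n",
              x$spec$fe_no_min$R, x$spec$fe_no_min$theta, x$spec$fe_no_min$depth))
  cat(sprintf("  FeON minimum: R = %.2f A, theta = %.0f deg, depth = %.1f kcal/mol\n",
              x$spec$fe_on_min$R, x$spec$fe_on_min$theta, x$spec$fe_on_min$depth))
  invisible(x)
}

#' Default grid specification for sampling the reference surfaces
#'
#' 20 radial nodes (denser below 4 A), 21 polar nodes at Gauss--Legendre
#' abscissae in cos(theta), and 5 doming nodes on \[-10, 10\] degrees.
#'
#' @param n_theta number of Gauss--Legendre theta nodes
#' @param phi_nodes doming-angle nodes (degrees)
#' @param R_nodes radial nodes (A)
#' @return list with `R_nodes`, `theta_nodes`, `phi_nodes`
#' @export
default_grid_spec <- function(n_theta = 21L,
                              phi_nodes = seq(-10, 10, by = 5),
                              R_nodes = c(1.8, 1.9, 2.0, 2.1, 2.2, 2.3, 2.4,
                                          2.5, 2.6, 2.7, 2.85, 3.0, 3.2, 3.45,
                                          3.75, 4.2, 4.8, 5.6, 7.0, 10.0)) {
  gl <- gauss_legendre(n_theta)
  list(R_nodes = R_nodes,
       theta_nodes = sort(acos(gl$nodes) * 180 / pi),
       phi_nodes = phi_nodes)
}

#' Sample a two-state energy grid from reference surfaces
#'
#' Tabulates both electronic states on a structured (R, theta, phi) grid,
#' standing in for an ab initio energy table. Optional additive Gaussian
#' noise (for robustness studies) is seeded and reproducible.
#'
#' @param ref a [make_reference_surfaces()] result
#' @param grid_spec list with `R_nodes`, `theta_nodes`, `phi_nodes`
#'   (see [default_grid_spec()])
#' @param noise_sd standard deviation of additive noise, kcal/mol
#' @param seed integer seed, required when `noise_sd > 0`
#' @return object of class `pes_grid`: node vectors plus an `energy` list of
#'   two `|R| x |theta| x |phi|` arrays named `doublet` and `quartet`
#' @export
sample_grid <- function(ref, grid_spec = default_grid_spec(), noise_sd = 0,
                        seed = NULL) {
  stopifnot(inherits(ref, "two_state_reference"))
  Rn <- sort(as.numeric(grid_spec$R_nodes))
  tn <- sort(as.numeric(grid_spec$theta_nodes))
  pn <- sort(as.numeric(grid_spec$phi_nodes))
  if (anyDuplicated(Rn) || anyDuplicated(tn) || anyDuplicated(pn)) {
    stop("sample_grid: duplicate grid nodes")
  }
  if (any(Rn < 1.5) || any(Rn > 12)) stop("sample_grid: R nodes outside reference domain [1.5, 12] A")
  if (any(tn < 0) || any(tn > 180)) stop("sample_grid: theta nodes outside [0, 180] degrees")
  pe <- ref$spec$doming$phi_e
  if (any(pn < pe - 20) || any(pn > pe + 20)) {
    stop("sample_grid: phi nodes outside reference domain [phi_e - 20, phi_e + 20]")
  }
  pts <- expand.grid(R = Rn, theta = tn, phi = pn, KEEP.OUT.ATTRS = FALSE)
  dims <- c(length(Rn), length(tn), length(pn))
  E2 <- array(ref$V2A(pts$R, pts$theta, pts$phi), dim = dims)
  E4 <- array(ref$V4A(pts$R, pts$theta, pts$phi), dim = dims)
  if (noise_sd > 0) {
    if (is.null(seed)) stop("sample_grid: seed required when noise_sd > 0")
    E2 <- E2 + array(local_rnorm(prod(dims), sd = noise_sd, seed = seed), dim = dims)
    E4 <- E4 + array(local_rnorm(prod(dims), sd = noise_sd, seed = seed + 1L), dim = dims)
  }
  structure(list(R_nodes = Rn, theta_nodes = tn, phi_nodes = pn,
                 energy = list(doublet = E2, quartet = E4),
                 spec = ref$spec, noise_sd = noise_sd, seed = seed),
            class = "pes_grid")
}

#' @export
print.pes_grid <- function(x, ...) {
  cat(sprintf("PES grid: %d x %d x %d (R x theta x phi), states: %s\n",
              length(x$R_nodes), length(x$theta_nodes), length(x$phi_nodes),
              paste(names(x$energy), collapse = ", ")))
  invisible(x)
}

# draw normals under a temporary, seeded RNG state without touching the
# caller's .Random.seed
local_rnorm <- function(n, sd, seed) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  stats::rnorm(n, sd = sd)
}

#' Check a doublet surface against its printed stationary points
#'
#' Locates the FeNO and FeON minima of an energy function by multi-start
#' local minimization in (R, theta) at phi = phi_e and reports each
#' constraint (locations, depths, their separation, and the dissociation
#' asymptote) with an achieved value, absolute error and pass flag.
#' Optimizer failures are reported as failed constraints, not raised.
#'
#' @param surface vectorized `function(R, theta, phi)` returning kcal/mol
#' @param spec the [surface_spec()] holding the targets
#' @param tolerances list with elements `R` (A), `theta` (deg), `depth`,
#'   `separation` and `asymptote` (kcal/mol)
#' @return `data.frame` of class `constraint_report`
#' @export
verify_constraints <- function(surface, spec,
                               tolerances = list(R = 0.02, theta = 2,
                                                 depth = 0.05, separation = 0.3,
                                                 asymptote = 0.05)) {
  pe <- spec$doming$phi_e
  obj <- function(p) surface(p[1], p[2], pe)
  minimize <- function(starts, lower, upper) {
    best <- NULL
    for (i in seq_len(nrow(starts))) {
      fit <- tryCatch(
        stats::nlminb(as.numeric(starts[i, ]), obj, lower = lower, upper = upper,
                      control = list(abs.tol = 1e-12, rel.tol = 1e-12)),
        error = function(e) NULL)
      if (!is.null(fit) && (is.null(best) || fit$objective < best$objective)) best <- fit
    }
    best
  }
  g <- expand.grid(R = c(2.1, 2.4, 2.7, 3.1), theta = c(120, 140, 160, 175))
  feno <- minimize(g, lower = c(1.6, 95), upper = c(6, 180))
  g2 <- expand.grid(R = c(2.1, 2.4, 2.7, 3.1), theta = c(10, 27, 45, 70))
  feon <- minimize(g2, lower = c(1.6, 0), upper = c(6, 90))
  asym <- tryCatch(max(abs(surface(12, c(20, 90, 160), pe) - spec$asymptote)),
                   error = function(e) NA_real_)

  row <- function(name, target, achieved, tol) {
    data.frame(name = name, target = target, achieved = achieved,
               abs_error = abs(achieved - target), tolerance = tol,
               pass = is.finite(achieved) && abs(achieved - target) <= tol,
               stringsAsFactors = FALSE)
  }
  dep <- function(fit) if (is.null(fit)) NA_real_ else spec$asymptote - fit$objective
  loc <- function(fit, i) if (is.null(fit)) NA_real_ else fit$par[i]
  rep <- rbind(
    row("feno_R", spec$fe_no_min$R, loc(feno, 1), tolerances$R),
    row("feno_theta", spec$fe_no_min$theta, loc(feno, 2), tolerances$theta),
    row("feno_depth", spec$fe_no_min$depth, dep(feno), tolerances$depth),
    row("feon_R", spec$fe_on_min$R, loc(feon, 1), tolerances$R),
    row("feon_theta", spec$fe_on_min$theta, loc(feon, 2), tolerances$theta),
    row("feon_depth", spec$fe_on_min$depth, dep(feon), tolerances$depth),
    row("separation", spec$fe_no_min$depth - spec$fe_on_min$depth,
        dep(feno) - dep(feon), tolerances$separation),
    row("asymptote", 0, asym, tolerances$asymptote))
  class(rep) <- c("constraint_report", "data.frame")
  rep
}

#' @export
print.constraint_report <- function(x, ...) {
  cat("Constraint report:\n")
  print.data.frame(x, row.names = FALSE, digits = 5)
  invisible(x)
}
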