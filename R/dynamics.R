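# Langevin dynamics of the reduced ligand coordinates (R, theta, phi) on the
# reactive mixed surface, with solvent surrogates replacing explicit solvent.

# effective inertial parameters:
#   R     : NO mass, 30 amu (heme effectively fixed)
#   theta : NO moment of inertia mu d^2 with d(N-O) = 1.151 A
#   phi   : effective doming inertia, set so the doming frequency is ~50 cm^-1
#           with the default stiffness k = 0.02 kcal/mol/deg^2
# converted to degree units for the angular coordinates (KE = m_deg v_deg^2 / 2).
dyn_masses <- function() {
  deg2 <- (pi / 180)^2
  c(R = 30, theta = (14 * 16 / 30) * 1.151^2 * deg2, phi = 309.7 * deg2)
}

#' Solvent surrogate for the Langevin dynamics
#'
#' Replaces explicit solvent with per-coordinate friction, temperature, and
#' (for caging solvents) a harmonic radial wall. Defaults are the package's
#' declared calibration: gas is frictionless (NVE), pure water is moderate
#' friction with free diffusion to an outer reflecting boundary (the finite
#' simulation box), glycerol/water adds strong friction plus a solvent-cage
#' wall that confines the photodissociated ligand near the iron, and
#' water+ions behaves like water with friction scaled by 1.6 and a soft cage.
#'
#' @param label one of `"gas"`, `"water"`, `"glycerol_water"`, `"water_ions"`
#' @param temperature temperature, K
#' @param gamma named friction vector `c(R=, theta=, phi=)` in 1/ps
#'   (overrides the label default)
#' @param cage `c(R_cage, k_wall)` in A and kcal/mol/A^2 (0 0 = none)
#' @param outer_wall reflecting boundary radius, A (0 = none)
#' @param visc_activation Arrhenius activation energy (kcal/mol) scaling the
#'   friction with temperature relative to 300 K (`gamma(T) = gamma_300
#'   exp(Ea/kB (1/T - 1/300))`); default 4.2 for water-like solvents,
#'   10 for the glycerol mixture, 0 for gas
#' @param hot_drag `c(v_cut, rate)`: radial speed above `v_cut` (A/fs)
#'   relaxes toward it at `rate` (1/fs), modelling the fast collisional
#'   cooling of a ballistic (photodissociated) ligand by the solvent;
#'   thermal motion (|v| ~ 0.003 A/fs) is unaffected. `c(0, 0)` disables.
#' @param entropic_R include the 3-D radial-measure surrogate force
#'   `+2 kB T / R` (free energy `-2 kB T ln R`), representing the growth of
#'   accessible solvent volume with distance; on for the diffusive solvents
#'   (water, water+ions), off for the caging glycerol/water mixture and gas
#' @return object of class `solvent_model`
#' @export
solvent_model <- function(label = c("water", "glycerol_water", "gas", "water_ions"),
                          temperature = 300, gamma = NULL, cage = NULL,
                          outer_wall = NULL, entropic_R = NULL,
                          visc_activation = NULL, hot_drag = NULL) {
  label <- match.arg(label)
  if (temperature <= 0) stop("solvent_model: temperature must be > 0")
  defaults <- switch(label,
    gas = list(gamma = c(R = 0, theta = 0, phi = 0), cage = c(0, 0), outer = 0,
               entropic = FALSE, visc = 0, hot = c(0, 0)),
    water = list(gamma = c(R = 5, theta = 30, phi = 5), cage = c(0, 0),
                 outer = 15, entropic = TRUE, visc = 4.2,
                 hot = c(0.0065, 0.04)),
    glycerol_water = list(gamma = c(R = 15, theta = 400, phi = 15),
                          cage = c(5.2, 5), outer = 20, entropic = FALSE,
                          visc = 10, hot = c(0, 0)),
    water_ions = list(gamma = c(R = 8, theta = 48, phi = 8), cage = c(6, 0.5),
                      outer = 15, entropic = TRUE, visc = 4.2,
                      hot = c(0.0065, 0.04)))
  gamma <- gamma %||% defaults$gamma
  cage <- cage %||% defaults$cage
  outer_wall <- outer_wall %||% defaults$outer
  entropic_R <- entropic_R %||% defaults$entropic
  visc_activation <- visc_activation %||% defaults$visc
  hot_drag <- hot_drag %||% defaults$hot
  if (any(gamma < 0)) stop("solvent_model: friction must be >= 0")
  if (cage[2] > 0 && cage[1] <= 3) stop("solvent_model: cage onset must be > 3 A")
  # Arrhenius viscosity scaling of the friction about the 300 K reference
  gamma <- gamma * exp((visc_activation / 0.0019872041) *
                         (1 / temperature - 1 / 300))
  structure(list(label = label, temperature = temperature, gamma = gamma,
                 cage = cage, outer_wall = outer_wall,
                 entropic_R = isTRUE(entropic_R),
                 visc_activation = visc_activation, hot_drag = hot_drag),
            class = "solvent_model")
}

#' @export
print.solvent_model <- function(x, ...) {
  cat(sprintf("Solvent surrogate `%s`: T = %g K, gamma = (%g, %g, %g)/ps",
              x$label, x$temperature, x$gamma[1], x$gamma[2], x$gamma[3]))
  if (x$cage[2] > 0) cat(sprintf(", cage at %g A (k = %g)", x$cage[1], x$cage[2]))
  cat("\n")
  invisible(x)
}

#' Rebinding detection criterion
#'
#' A trajectory counts as rebound at the first instant from which the
#' dominant-state weight, distance and orientation conditions hold
#' continuously for the sustain window (which suppresses transient
#' recrossings).
#'
#' @param weight_min minimum doublet weight w_2A
#' @param R_max maximum Fe-ligand distance, A
#' @param theta_min minimum orientation angle, degrees
#' @param sustain_fs sustain window, fs
#' @export
rebind_criterion <- function(weight_min = 0.9, R_max = 2.8, theta_min = 120,
                             sustain_fs = 200) {
  list(weight_min = weight_min, R_max = R_max, theta_min = theta_min,
       sustain_fs = sustain_fs)
}

# Fe-oop surrogate: out-of-plane distance from the doming angle, A/deg
OOP_SCALE <- 0.05

propagate_raw <- function(model, solvent, state, dt_fs, nsteps, mode,
                          seed, stream, rebind = NULL, restraint = rep(0, 6),
                          record_stride = 0L, gamma_override = NULL) {
  gam <- (gamma_override %||% solvent$gamma) * 1e-3   # 1/ps -> 1/fs
  reb <- if (is.null(rebind)) c(0, 0, 0, 0, 0) else
    c(1, rebind$weight_min, rebind$R_max, rebind$theta_min, rebind$sustain_fs)
  cpp_propagate(surf_to_cpp(model$surface_2A), surf_to_cpp(model$surface_4A),
                model$delta, model$mix_width, model_env_vec(model),
                as.numeric(state), dt_fs, as.integer(nsteps), gam,
                solvent$temperature, dyn_masses(), as.integer(mode),
                as.numeric(solvent$cage), solvent$outer_wall,
                as.numeric(solvent$entropic_R),
                as.numeric(solvent$hot_drag), as.numeric(restraint),
                reb, as.numeric(seed),
                as.numeric(stream), as.integer(record_stride))
}

#' Sample thermalized bound-state (FeNO) initial conditions
#'
#' Runs one long thermostatted trajectory confined to the FeNO basin on the
#' doublet surface and decimates it at `interval_ps` (emulating saving
#' coordinates and velocities every 5 ps of an equilibrium run). Velocities
#' are Maxwell-distributed at the solvent temperature. If the unconstrained
#' trajectory leaves the basin it is resampled under a flat-bottom restraint
#' with a warning.
#'
#' @param model a [two_state_model()]
#' @param solvent a [solvent_model()]
#' @param n number of snapshots
#' @param interval_ps decimation interval, ps
#' @param seed integer seed (deterministic snapshots)
#' @param equilibration_ps discarded equilibration stretch, ps
#' @param dt_fs integration time step, fs
#' @return `data.frame` of class `dyn_states` with one row per snapshot
#'   (R, theta, phi, vR, vtheta, vphi)
#' @export
sample_bound_ensemble <- function(model, solvent, n = 500, interval_ps = 5,
                                  seed = 1, equilibration_ps = 20, dt_fs = 1) {
  stopifnot(inherits(model, "two_state_model"), inherits(solvent, "solvent_model"))
  if (n < 1) stop("sample_bound_ensemble: n must be >= 1")
  gam <- solvent$gamma
  if (all(gam == 0)) gam <- c(R = 2, theta = 2, phi = 2)  # thermalize gas-phase sampling
  run <- function(restr) {
    x0 <- c(2.37, 160, model$surface_2A$vc$phi_e, 0, 0, 0)
    eq <- propagate_raw(model, solvent, x0, dt_fs,
                        round(equilibration_ps * 1000 / dt_fs), mode = 0,
                        seed = seed, stream = 0, restraint = restr,
                        gamma_override = gam)
    stride <- round(interval_ps * 1000 / dt_fs)
    pr <- propagate_raw(model, solvent, eq$state, dt_fs, n * stride, mode = 0,
                        seed = seed, stream = 1, restraint = restr,
                        record_stride = stride, gamma_override = gam)
    rec <- pr$records
    rec[-1, , drop = FALSE]   # drop the t = 0 snapshot
  }
  rec <- run(rep(0, 6))
  ok <- all(rec[, "R"] >= 2.0 & rec[, "R"] <= 3.2 &
              rec[, "theta"] >= 120 & rec[, "theta"] <= 180)
  if (!ok) {
    warning("sample_bound_ensemble: trajectory left the FeNO basin; ",
            "resampling under a flat-bottom restraint")
    rec <- run(c(50, 2.0, 3.2, 0.5, 120, 180))
  }
  out <- data.frame(R = rec[, "R"], theta = rec[, "theta"], phi = rec[, "phi"],
                    vR = rec[, "vR"], vtheta = rec[, "vtheta"],
                    vphi = rec[, "vphi"])
  class(out) <- c("dyn_states", "data.frame")
  out
}

#' Photodissociation under the sudden approximation
#'
#' Each bound-state snapshot is switched instantaneously to the (shifted)
#' repulsive quartet surface and propagated for `duration_fs` (default
#' 500 fs) without any rebinding; the resulting states are the initial
#' conditions of the rebinding simulations. In the gas phase the propagation
#' is energy conserving; a drift above 1 kcal/mol raises an
#' integrator-stability error. The default step is 0.25 fs here (only)
#' because the excited-state repulsive wall is the stiffest feature of the
#' model; 1 fs on that wall conserves energy only to a few 1e-3 kcal/mol.
#'
#' @param states a [sample_bound_ensemble()] result (or 1-row equivalent)
#' @param model a [two_state_model()]
#' @param solvent a [solvent_model()]
#' @param duration_fs excited-state propagation time, fs
#' @param seed integer seed
#' @param dt_fs time step, fs
#' @return `data.frame` of class `dyn_states` of post-photodissociation states
#' @export
photodissociate <- function(states, model, solvent, duration_fs = 500,
                            seed = 1, dt_fs = 0.25) {
  stopifnot(inherits(model, "two_state_model"), inherits(solvent, "solvent_model"))
  states <- as.data.frame(states)
  out <- states
  gas <- all(solvent$gamma == 0)
  for (i in seq_len(nrow(states))) {
    pr <- propagate_raw(model, solvent, as.numeric(states[i, 1:6]), dt_fs,
                        round(duration_fs / dt_fs), mode = 1,
                        seed = seed, stream = i)
    if (gas && abs(pr$energy_final - pr$energy_initial) > 1) {
      stop("photodissociate: integrator instability (|dE| = ",
           signif(abs(pr$energy_final - pr$energy_initial), 3),
           " kcal/mol); reduce dt_fs")
    }
    out[i, 1:6] <- pr$state
  }
  class(out) <- c("dyn_states", "data.frame")
  out
}

#' Propagate one reactive (rebinding) trajectory
#'
#' Langevin propagation on the mixed reactive surface from a
#' post-photodissociation state. Records the first time the rebinding
#' criterion holds for its sustain window, or censors at `t_sim_ps`.
#' Beyond the radial domain the potential is at its asymptote and the ligand
#' diffuses freely (return remains possible); an optional outer reflecting
#' wall represents the finite solvent box.
#'
#' @param state numeric length-6 state (R, theta, phi, vR, vtheta, vphi) or a
#'   1-row `dyn_states`
#' @param model a [two_state_model()]
#' @param solvent a [solvent_model()]
#' @param t_sim_ps maximum simulation time, ps
#' @param seed integer seed
#' @param criterion a [rebind_criterion()]
#' @param stream per-trajectory stream index (used by [run_ensemble()])
#' @param dt_fs time step, fs
#' @return one-row `data.frame`: `R0`, `theta0`, `tau_ps` (NA if censored),
#'   `censored`, `phi_at_rebind`, `d_at_rebind` (A)
#' @export
propagate_reactive <- function(state, model, solvent, t_sim_ps, seed = 1,
                               criterion = rebind_criterion(), stream = 1,
                               dt_fs = 1) {
  state <- as.numeric(state)[1:6]
  pr <- propagate_raw(model, solvent, state, dt_fs,
                      round(t_sim_ps * 1000 / dt_fs), mode = 2,
                      seed = seed, stream = stream, rebind = criterion)
  if (isTRUE(pr$blown_up)) {
    stop("propagate_reactive: numeric overflow in trajectory stream ", stream)
  }
  phi_e <- model$surface_2A$vc$phi_e
  data.frame(R0 = state[1], theta0 = state[2],
             tau_ps = pr$rebind_time_ps,
             censored = is.na(pr$rebind_time_ps),
             phi_at_rebind = pr$phi_at_rebind,
             d_at_rebind = OOP_SCALE * (pr$phi_at_rebind - phi_e))
}

#' Run an ensemble of rebinding trajectories
#'
#' Per-trajectory random streams are derived deterministically from the base
#' seed, so results are independent of execution order and byte-identical
#' across reruns. Trajectories that fail numerically are listed in the
#' metadata rather than aborting the ensemble.
#'
#' @param states a `dyn_states` data.frame of initial conditions
#' @param model a [two_state_model()]
#' @param solvent a [solvent_model()]
#' @param t_sim_ps per-trajectory simulation time, ps
#' @param seed base integer seed
#' @param criterion a [rebind_criterion()]
#' @param dt_fs time step, fs
#' @return object of class `rebinding_ensemble`: `records` data.frame
#'   (id, seed, stream, R0, theta0, tau_ps, censored, phi_at_rebind,
#'   d_at_rebind) plus `metadata`
#' @export
run_ensemble <- function(states, model, solvent, t_sim_ps, seed = 1,
                         criterion = rebind_criterion(), dt_fs = 1) {
  states <- as.data.frame(states)
  n <- nrow(states)
  if (n < 1) stop("run_ensemble: need at least one initial state")
  rows <- vector("list", n)
  failures <- integer(0)
  for (i in seq_len(n)) {
    rows[[i]] <- tryCatch(
      cbind(id = i, seed = seed, stream = i,
            propagate_reactive(states[i, ], model, solvent, t_sim_ps,
                               seed = seed, criterion = criterion,
                               stream = i, dt_fs = dt_fs)),
      error = function(e) {
        failures <<- c(failures, i)
        data.frame(id = i, seed = seed, stream = i, R0 = states$R[i],
                   theta0 = states$theta[i], tau_ps = NA_real_,
                   censored = TRUE, phi_at_rebind = NA_real_,
                   d_at_rebind = NA_real_)
      })
  }
  records <- do.call(rbind, rows)
  rownames(records) <- NULL
  structure(list(records = records,
                 metadata = list(n = n, t_sim_ps = t_sim_ps, seed = seed,
                                 delta = model$delta,
                                 environment = model$environment,
                                 solvent = solvent$label,
                                 temperature = solvent$temperature,
                                 criterion = criterion, failures = failures)),
            class = "rebinding_ensemble")
}

#' @export
print.rebinding_ensemble <- function(x, ...) {
  md <- x$metadata
  cat(sprintf("Rebinding ensemble: n = %d, solvent = %s, Delta = %g kcal/mol, T = %g K, t_sim = %g ps\n",
              md$n, md$solvent, md$delta, md$temperature, md$t_sim_ps))
  cat(sprintf("  rebound %d / %d (fraction %.3f)\n",
              sum(!x$records$censored), md$n, mean(!x$records$censored)))
  invisible(x)
}

#' First-passage isomerization ensemble (FeON -> FeNO)
#'
#' Initial conditions are decimated snapshots of a thermostatted trajectory
#' restrained to the FeON basin (flat-bottom angular and radial restraints,
#' emulating a harmonic FeON restraint with a constrained Fe-O distance);
#' the restraint is released for production, which runs on the reactive
#' mixed surface until first passage into the FeNO basin or censoring.
#'
#' @param model a [two_state_model()]
#' @param environment environment label (sets both the angular bias and the
#'   matching solvent surrogate unless `solvent` is given)
#' @param n number of trajectories
#' @param t_sim_ps per-trajectory time, ps
#' @param seed base seed
#' @param solvent optional [solvent_model()] override
#' @param interval_ps snapshot decimation interval, ps
#' @param dt_fs time step, fs
#' @return a `rebinding_ensemble` whose `tau_ps` are first-passage
#'   isomerization times
#' @export
isomerization_ensemble <- function(model, environment = "gas", n = 500,
                                   t_sim_ps = 1000, seed = 1, solvent = NULL,
                                   interval_ps = 5, dt_fs = 1) {
  model <- apply_environment_bias(model, environment)
  solvent <- solvent %||% solvent_model(if (environment == "gas") "gas" else environment)
  gam <- solvent$gamma
  if (all(gam == 0)) gam <- c(R = 2, theta = 2, phi = 2)
  restr <- c(50, 2.3, 2.7, 0.5, 10, 45)   # FeON basin flat-bottom restraints
  x0 <- c(2.48, 27, model$surface_2A$vc$phi_e, 0, 0, 0)
  eq <- propagate_raw(model, solvent, x0, dt_fs, round(20 * 1000 / dt_fs),
                      mode = 0, seed = seed, stream = 0, restraint = restr,
                      gamma_override = gam)
  stride <- round(interval_ps * 1000 / dt_fs)
  pr <- propagate_raw(model, solvent, eq$state, dt_fs, n * stride, mode = 0,
                      seed = seed, stream = 1, restraint = restr,
                      record_stride = stride, gamma_override = gam)
  rec <- pr$records[-1, , drop = FALSE]
  states <- data.frame(R = rec[, "R"], theta = rec[, "theta"],
                       phi = rec[, "phi"], vR = rec[, "vR"],
                       vtheta = rec[, "vtheta"], vphi = rec[, "vphi"])
  class(states) <- c("dyn_states", "data.frame")
  out <- run_ensemble(states, model, solvent, t_sim_ps, seed = seed + 1)
  out$metadata$kind <- "isomerization"
  out
}
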