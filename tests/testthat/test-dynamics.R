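test_that("solvent_model validates and applies its defaults", {
  expect_error(solvent_model("water", temperature = -5), "temperature")
  expect_error(solvent_model("water", gamma = c(R = -1, theta = 5, phi = 5)),
               "friction")
  expect_error(solvent_model("glycerol_water", cage = c(2.5, 10)), "cage onset")
  gas <- solvent_model("gas")
  expect_true(all(gas$gamma == 0))
  gw <- solvent_model("glycerol_water")
  expect_gt(gw$cage[2], 0)
  expect_false(gw$entropic_R)
  expect_true(solvent_model("water")$entropic_R)
  # viscosity scaling: colder water is more viscous
  g283 <- solvent_model("water", temperature = 283)$gamma
  g300 <- solvent_model("water", temperature = 300)$gamma
  expect_true(all(g283 > 1.4 * g300 & g283 < 1.7 * g300))
})

test_that("bound-state sampling is confined, thermal, and seed-reproducible", {
  model <- fx_model(7.5)
  solv <- solvent_model("glycerol_water")
  b1 <- sample_bound_ensemble(model, solv, n = 120, seed = 5)
  expect_equal(nrow(b1), 120L)
  expect_true(all(b1$R >= 2.0 & b1$R <= 3.2))
  expect_true(all(b1$theta >= 120 & b1$theta <= 180))
  b2 <- sample_bound_ensemble(model, solv, n = 120, seed = 5)
  expect_identical(b1, b2)
  # equipartition: mean kinetic energy (3/2) kB T within 5%
  ms <- hemekin:::dyn_masses()
  ke <- 0.5 * (ms[1] * b1$vR^2 + ms[2] * b1$vtheta^2 + ms[3] * b1$vphi^2) / 4.184e-4
  expect_equal(mean(ke), 1.5 * 0.0019872041 * 300, tolerance = 0.05)
})

test_that("gas-phase photodissociation is monotone outward and energy conserving", {
  model <- fx_model(7.5)
  gas <- solvent_model("gas")
  start <- data.frame(R = 2.37, theta = 160, phi = 0, vR = 0, vtheta = 0, vphi = 0)
  out <- photodissociate(start, model, gas)
  expect_gt(out$R[1], start$R[1])  # repulsive quartet pushes outward
  rec <- hemekin:::propagate_raw(model, gas, as.numeric(start[1, ]), 0.25, 2000,
                                 mode = 1, seed = 8, stream = 1,
                                 record_stride = 5)
  expect_true(all(diff(rec$records[, "R"]) > -1e-9))
  expect_lt(abs(rec$energy_final - rec$energy_initial), 1e-3)
})

test_that("photodissociated distance distributions reflect the solvent", {
  model <- fx_model(7.5)
  gw <- solvent_model("glycerol_water"); w <- solvent_model("water")
  b_gw <- sample_bound_ensemble(model, gw, n = 150, seed = 5)
  b_w <- sample_bound_ensemble(model, w, n = 150, seed = 5)
  p_gw <- photodissociate(b_gw, model, gw, seed = 6)
  p_w <- photodissociate(b_w, model, w, seed = 6)
  mode_of <- function(x) { d <- density(x); d$x[which.max(d$y)] }
  # caged ligand stays near the iron (~3 A); in water it travels further (~3.9 A)
  expect_equal(mode_of(p_gw$R), 3.0, tolerance = 0.45)
  expect_equal(mode_of(p_w$R), 3.9, tolerance = 0.55)
  # the water distribution is much broader than the caged one
  expect_gt(sd(p_w$R), 1.3 * sd(p_gw$R))
})

test_that("gas-phase NVE drift on the mixed surface is below 1e-3 kcal/mol/ps", {
  model <- fx_model(7.5)
  gas <- solvent_model("gas")
  pr <- hemekin:::propagate_raw(model, gas, c(2.6, 150, 2, 0.003, 0.05, 0.05),
                                1, 10000, mode = 2, seed = 3, stream = 1)
  expect_lt(abs(pr$energy_final - pr$energy_initial) / 10, 1e-3)
})

test_that("Langevin thermostat reproduces the harmonic position variance", {
  kB <- 0.0019872041
  x <- hemekin:::cpp_langevin_harmonic(50, 30, 5e-3, 300, 1, 2e6, 7, 10)
  expect_equal(var(x), kB * 300 / 50, tolerance = 0.03)
})

test_that("reactive propagation: censoring, determinism, and monotone censoring", {
  model <- fx_model(10)
  solv <- solvent_model("glycerol_water")
  state <- c(3.5, 150, 0, 0, 0, 0)
  r1 <- propagate_reactive(state, model, solv, t_sim_ps = 5, seed = 4, stream = 2)
  r2 <- propagate_reactive(state, model, solv, t_sim_ps = 5, seed = 4, stream = 2)
  expect_identical(r1, r2)
  # near the funnel this state rebinds quickly
  expect_false(r1$censored)
  # a raised censoring horizon cannot un-rebind a trajectory
  r3 <- propagate_reactive(state, model, solv, t_sim_ps = 10, seed = 4, stream = 2)
  expect_equal(r3$tau_ps, r1$tau_ps)
  # a tiny horizon censors
  r4 <- propagate_reactive(state, model, solv, t_sim_ps = 0.01, seed = 4, stream = 2)
  expect_true(r4$censored)
  expect_true(is.na(r4$tau_ps))
})

test_that("escaped ligands keep propagating and can return", {
  model <- fx_model(7.5)
  solv <- solvent_model("water")
  # launch outward from beyond the potential range
  r <- propagate_reactive(c(13, 150, 0, 0.005, 0, 0), model, solv,
                          t_sim_ps = 50, seed = 9, stream = 1)
  expect_true(is.data.frame(r))  # no error at the domain ceiling
})

test_that("ensembles are seed-deterministic and order-independent", {
  model <- fx_model(10)
  solv <- solvent_model("glycerol_water")
  bound <- sample_bound_ensemble(model, solv, n = 8, seed = 5)
  post <- photodissociate(bound, model, solv, seed = 6)
  e1 <- run_ensemble(post, model, solv, t_sim_ps = 3, seed = 7)
  e2 <- run_ensemble(post, model, solv, t_sim_ps = 3, seed = 7)
  expect_identical(e1$records, e2$records)
  # per-trajectory records depend only on (state, stream): recomputing one
  # trajectory in isolation reproduces its ensemble row
  for (i in c(2L, 5L)) {
    solo <- propagate_reactive(post[i, ], model, solv, t_sim_ps = 3, seed = 7,
                               stream = i)
    expect_equal(solo$tau_ps, e1$records$tau_ps[i])
    expect_equal(solo$censored, e1$records$censored[i])
  }
})

test_that("a stiff cage inside the crossing radius forces sub-ps geminate rebinding", {
  model <- fx_model(10)
  solv <- solvent_model("glycerol_water", cage = c(3.05, 200))
  bound <- sample_bound_ensemble(model, solv, n = 30, seed = 5)
  post <- photodissociate(bound, model, solv, seed = 6)
  ens <- run_ensemble(post, model, solv, t_sim_ps = 5, seed = 7)
  expect_true(all(!ens$records$censored))
  expect_lt(quantile(ens$records$tau_ps, 0.9), 1.5)
})

test_that("isomerization first passage responds to the barrier height", {
  model <- fx_model(7.5)
  # a +50 kcal/mol bias across the crossing region makes FeON inescapable
  model$env_params$blocked <- c(50, 80, 25, 0, 130, 12)
  # hot positive control: thermal activation over the calibrated ~3.5 kcal/mol
  # exit barrier is fast at 900 K, so first passages are observable at 40 ps
  hot <- solvent_model("water", temperature = 900)
  iso_hot <- isomerization_ensemble(model, "gas", n = 10, t_sim_ps = 40,
                                    seed = 31, solvent = hot)
  iso_block <- isomerization_ensemble(model, "blocked", n = 10, t_sim_ps = 40,
                                      seed = 31, solvent = hot)
  expect_true(all(iso_hot$records$theta0 <= 60))   # sampled in the FeON basin
  expect_gt(rebinding_fraction(iso_hot), rebinding_fraction(iso_block))
  expect_equal(rebinding_fraction(iso_block), 0)   # unreachable barrier
})
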