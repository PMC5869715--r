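test_that("two_state_model validates its arguments", {
  expect_error(two_state_model(fx_surface("doublet"), fx_surface("quartet"),
                               delta = -1), "delta")
  expect_error(two_state_model(fx_surface("doublet"), fx_surface("quartet"),
                               mix_width = 0), "mix_width")
  expect_error(two_state_model(fx_surface("doublet"), fx_surface("quartet"),
                               environment = "vacuum"), "environment")
})

test_that("mixed energy is bounded by the state energies and matches an R oracle", {
  model <- fx_model(7.5)
  set.seed(21)
  R <- runif(200, 2.0, 9); th <- runif(200, 5, 175); ph <- runif(200, -9, 9)
  v2 <- rkhs_evaluate(model$surface_2A, R, th, ph)
  v4 <- rkhs_evaluate(model$surface_4A, R, th, ph) + model$delta
  mx <- mixed_energy(model, R, th, ph)
  expect_true(all(mx$energy <= pmax(v2, v4) + 1e-9))
  expect_true(all(mx$energy >= pmin(v2, v4) - 1e-9))
  # independent scalar re-implementation of the exponential weights
  softmix <- function(a, b, w) {
    m <- pmin(a, b)
    wa <- exp(-(a - m) / w); wb <- exp(-(b - m) / w)
    (wa * a + wb * b) / (wa + wb)
  }
  expect_equal(mx$energy, softmix(v2, v4, model$mix_width), tolerance = 1e-9)
  # and symmetry of the oracle implies state-relabeling invariance
  expect_equal(softmix(v2, v4, 0.5), softmix(v4, v2, 0.5), tolerance = 1e-12)
})

test_that("equal state energies give weight 1/2; narrow mixing gives the minimum", {
  model <- fx_model(7.5)
  # locate a crossing point on the theta scan and evaluate there
  sc <- adiabatic_scan(model, "theta", c(100, 125), fixed = list(R = 2.4),
                       n_points = 4000)
  i <- which.min(abs(sc$V_2A - sc$V_4A_shifted))
  expect_equal(sc$w_2A[i], 0.5, tolerance = 0.01)
  expect_equal(sc$V_mixed[i], sc$V_2A[i], tolerance = 0.01)
  narrow <- two_state_model(model$surface_2A, model$surface_4A, delta = 7.5,
                            mix_width = 1e-6)
  set.seed(22)
  R <- runif(50, 2.1, 8); th <- runif(50, 10, 170)
  v2 <- rkhs_evaluate(narrow$surface_2A, R, th, 0)
  v4 <- rkhs_evaluate(narrow$surface_4A, R, th, 0) + 7.5
  expect_equal(mixed_energy(narrow, R, th, 0)$energy, pmin(v2, v4),
               tolerance = 1e-4)
})

test_that("degenerate model (identical states) mixes to the common surface", {
  s <- fx_surface("doublet")
  m <- two_state_model(s, s, delta = 1e-12, mix_width = 0.5)
  set.seed(23)
  R <- runif(50, 2.1, 8); th <- runif(50, 10, 170)
  expect_equal(mixed_energy(m, R, th, 0)$energy, rkhs_evaluate(s, R, th, 0),
               tolerance = 1e-9)
})

test_that("asymptotic gap equals Delta for every tested shift", {
  for (delta in c(5, 7.5, 10)) {
    model <- fx_model(delta)
    th <- c(20, 90, 160)
    for (R in c(10, 11, 12)) {
      v2 <- rkhs_evaluate(model$surface_2A, R, th, 0)
      v4 <- rkhs_evaluate(model$surface_4A, R, th, 0) + delta
      expect_true(all(abs((v4 - v2) - delta) <= 0.05))
    }
  }
})

test_that("adiabatic scans are deterministic and validate input", {
  model <- fx_model(5)
  s1 <- adiabatic_scan(model, "theta", c(10, 170), fixed = list(R = 2.4))
  s2 <- adiabatic_scan(model, "theta", c(10, 170), fixed = list(R = 2.4))
  expect_identical(s1, s2)
  expect_error(adiabatic_scan(model, "theta", c(10, 10)), "degenerate")
  expect_error(adiabatic_scan(model, "theta", c(10, 170), n_points = 5), "n_points")
})

test_that("theta scan crossings and R-scan minimum sit at the printed locations", {
  model <- fx_model(5)
  sc <- adiabatic_scan(model, "theta", c(10, 170), fixed = list(R = 2.4),
                       n_points = 800)
  crossings <- sc$coord[which(diff(sc$w_2A > 0.5) != 0)]
  expect_equal(crossings[1], 55, tolerance = 3)
  expect_equal(crossings[2], 120, tolerance = 3)
  rsc <- adiabatic_scan(model, "R", c(1.9, 10), fixed = list(theta = 160),
                        n_points = 800)
  ext <- locate_barriers(rsc)$extrema
  mins <- ext[ext$kind == "minimum", ]
  expect_equal(nrow(mins), 1L)
  expect_equal(mins$position, 2.37, tolerance = 0.03)
})

test_that("locate_barriers recovers a known analytic profile and handles edge cases", {
  # synthetic two-well trace with exactly known extrema
  x <- seq(0, 10, length.out = 300)
  y <- cos(x)  # minima at pi, 3pi; maxima at 0, 2pi
  prof <- data.frame(coord = x, V_2A = y, V_4A_shifted = y, V_mixed = y,
                     w_2A = 0.5)
  out <- locate_barriers(prof)
  # one interior max (x = 2 pi) preceded by the minimum at x = pi: barrier 2
  expect_equal(out$barriers$height, 2, tolerance = 1e-3)
  expect_equal(out$barriers$at_maximum, 2 * pi, tolerance = 1e-3)
  expect_equal(out$barriers$from_minimum, pi, tolerance = 1e-3)
  # strictly monotone profile: no barriers, not an error
  prof2 <- data.frame(coord = x, V_2A = x, V_4A_shifted = x, V_mixed = x,
                      w_2A = 0.5)
  expect_equal(nrow(locate_barriers(prof2)$barriers), 0L)
  expect_error(locate_barriers(prof[1:10, ]), ">= 20")
  # direction matters: max at x = 2 then min at x = 5 gives a barrier only
  # when walking in reverse
  y3 <- ifelse(x < 2, x, ifelse(x < 5, 2 - (x - 2) * 5 / 3, -3 + (x - 5)))
  prof3 <- data.frame(coord = x, V_2A = y3, V_4A_shifted = y3, V_mixed = y3,
                      w_2A = 0.5)
  expect_equal(nrow(locate_barriers(prof3)$barriers), 0L)
  rv <- locate_barriers(prof3, "reverse")$barriers
  expect_equal(rv$height, 5, tolerance = 0.1)
})

test_that("calibrated barriers match the printed values (Delta = 5)", {
  model <- fx_model(5)
  sc <- adiabatic_scan(model, "theta", c(10, 170), fixed = list(R = 2.4),
                       n_points = 400)
  b <- locate_barriers(sc)$barriers
  expect_gte(nrow(b), 2L)
  expect_equal(b$height[1], 3.5, tolerance = 0.3)
  expect_equal(b$height[2], 1.0, tolerance = 0.3)
  expect_true(all(b$height >= 0))
})

test_that("environment bias: gas is the identity, caging raises the first barrier", {
  model <- fx_model(7.5)
  set.seed(24)
  R <- runif(100, 2.1, 9); th <- runif(100, 5, 175)
  gas <- apply_environment_bias(model, "gas")
  expect_equal(mixed_energy(gas, R, th, 0)$energy,
               mixed_energy(model, R, th, 0)$energy, tolerance = 1e-12)
  expect_error(apply_environment_bias(model, "syrup"), "unknown environment")
  barrier1 <- function(env) {
    m <- apply_environment_bias(model, env)
    sc <- adiabatic_scan(m, "theta", c(10, 170), fixed = list(R = 2.4),
                         n_points = 400)
    locate_barriers(sc)$barriers$height[1]
  }
  b_gas <- barrier1("gas"); b_w <- barrier1("water"); b_gw <- barrier1("glycerol_water")
  expect_gt(b_w, b_gas)
  expect_gt(b_gw, b_w)
  # all-zero bias parameters behave exactly like gas, whatever the label
  zeroed <- model
  zeroed$env_params <- lapply(zeroed$env_params, function(x) x * c(0, 1, 1, 0, 1, 1))
  zeroed <- apply_environment_bias(zeroed, "glycerol_water")
  expect_equal(mixed_energy(zeroed, R, th, 0)$energy,
               mixed_energy(gas, R, th, 0)$energy, tolerance = 1e-12)
})
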