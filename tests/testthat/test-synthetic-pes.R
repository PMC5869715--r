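test_that("surface_spec validation names the offending field", {
  expect_error(surface_spec(fe_no_min = list(R = 2.37, theta = 160, depth = 5,
                                             alpha = 2, kappa = 6)),
               "fe_no_min\\$depth")
  expect_error(surface_spec(doming = list(k = -1, phi_e = 0)), "doming\\$k")
  expect_error(surface_spec(quartet = list(wall_steepness = -1, faint_depth = 1,
                                           faint_R = 3.2, shelf_depth = 9,
                                           shelf_R = 2.4, shelf_alpha = 5,
                                           shelf_center = 89, shelf_width = 50,
                                           shelf_power = 6)),
               "wall_steepness")
})

test_that("default reference surfaces hit the printed stationary points", {
  ref <- fx_reference()
  rep <- verify_constraints(ref$V2A, ref$spec)
  expect_true(all(rep$pass), info = paste(capture.output(print(rep)), collapse = "\n"))
  # separation equals the depth difference of the two wells
  sep <- rep$achieved[rep$name == "separation"]
  expect_equal(sep, 21 - 6, tolerance = 0.3)
})

test_that("both states reach their common asymptote at long range", {
  ref <- fx_reference()
  th <- c(10, 55, 90, 120, 160)
  expect_true(all(abs(ref$V2A(12, th, 0)) <= 0.05))
  # quartet - doublet gap vanishes before any shift is applied
  expect_true(all(abs(ref$V4A(12, th, 0) - ref$V2A(12, th, 0)) <= 0.05))
})

test_that("the quartet is repulsive at the FeNO geometry with a shallow outer well", {
  ref <- fx_reference()
  expect_gt(ref$V4A(2.37, 160, 0), 0)
  # shallow long-range well on the theta = 160 cut, about 1 kcal/mol near 3.2 A
  rr <- seq(2.8, 4.5, by = 0.01)
  cut <- ref$V4A(rr, 160, 0)
  expect_lt(min(cut), -0.5)
  expect_gt(min(cut), -1.6)
  expect_equal(rr[which.min(cut)], 3.2, tolerance = 0.25)
})

test_that("reference evaluation is deterministic and C1 (gradient matches FD)", {
  ref <- fx_reference()
  set.seed(7)
  R <- runif(100, 2.0, 10); th <- runif(100, 5, 175); ph <- runif(100, -15, 15)
  expect_identical(ref$V2A(R, th, ph), ref$V2A(R, th, ph))
  h <- 1e-5
  for (st in c("2A", "4A")) {
    f <- ref[[paste0("V", st)]]; g <- ref[[paste0("grad", st)]](R, th, ph)
    fd <- cbind((f(R + h, th, ph) - f(R - h, th, ph)) / (2 * h),
                (f(R, th + h, ph) - f(R, th - h, ph)) / (2 * h),
                (f(R, th, ph + h) - f(R, th, ph - h)) / (2 * h))
    expect_lt(max(abs(g - fd)), 1e-4)
  }
})

test_that("sample_grid tabulates the reference exactly and validates ranges", {
  ref <- fx_reference()
  gs <- default_grid_spec(n_theta = 13)
  grid <- sample_grid(ref, gs)
  pts <- expand.grid(R = grid$R_nodes, theta = grid$theta_nodes,
                     phi = grid$phi_nodes, KEEP.OUT.ATTRS = FALSE)
  expect_equal(as.vector(grid$energy$doublet),
               ref$V2A(pts$R, pts$theta, pts$phi), tolerance = 1e-12)
  expect_error(sample_grid(ref, list(R_nodes = c(0.5, 2), theta_nodes = c(10, 90),
                                     phi_nodes = 0)), "domain")
  expect_error(sample_grid(ref, list(R_nodes = c(2, 2, 3), theta_nodes = c(10, 90),
                                     phi_nodes = 0)), "duplicate")
  expect_error(sample_grid(ref, list(R_nodes = c(2, 3), theta_nodes = c(10, 200),
                                     phi_nodes = 0)), "theta")
})

test_that("seeded grid noise is reproducible and seed-sensitive", {
  ref <- fx_reference()
  gs <- default_grid_spec(n_theta = 13)
  g1 <- sample_grid(ref, gs, noise_sd = 0.1, seed = 1)
  g2 <- sample_grid(ref, gs, noise_sd = 0.1, seed = 1)
  g3 <- sample_grid(ref, gs, noise_sd = 0.1, seed = 2)
  expect_identical(g1$energy$doublet, g2$energy$doublet)
  expect_false(identical(g1$energy$doublet, g3$energy$doublet))
  expect_error(sample_grid(ref, gs, noise_sd = 0.1), "seed")
})

test_that("default grid resolves the FeNO well to within 0.3 kcal/mol", {
  # oracle: dense reference evaluation over the well region
  ref <- fx_reference()
  dense <- expand.grid(R = seq(2.1, 2.7, by = 0.005),
                       theta = seq(140, 180, by = 0.25))
  true_min <- min(ref$V2A(dense$R, dense$theta, 0))
  grid_min <- min(fx_grid()$energy$doublet)
  expect_equal(true_min, -21, tolerance = 0.05)
  expect_lt(abs(grid_min - true_min), 0.3)
})

test_that("verify_constraints flags a deliberately mis-calibrated surface", {
  ref <- fx_reference()
  shifted <- function(R, theta, phi) ref$V2A(R, theta, phi) -
    exp(-((theta - 160) / 10)^2) * exp(-((R - 2.37) / 0.2)^2)  # ~1 kcal deeper FeNO
  rep <- verify_constraints(shifted, ref$spec)
  row <- rep[rep$name == "feno_depth", ]
  expect_false(row$pass)
  expect_equal(row$abs_error, 1, tolerance = 0.15)
  # a surface the optimizer cannot evaluate yields failed entries, not errors
  bad <- function(R, theta, phi) stop("no evaluation")
  rep2 <- expect_error(verify_constraints(bad, ref$spec), NA)
  expect_false(all(rep2$pass))
})

test_that("calibration failure raises an informative error", {
  spec <- surface_spec()
  spec$fe_no_min$depth_scale <- 1.1   # breaks the depth calibration
  expect_error(make_reference_surfaces(spec), "calibration failure")
})
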