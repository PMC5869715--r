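test_that("survival_curve counts events with censoring by construction", {
  ens <- fake_ensemble(c(1, 2, 3, 4), rep(FALSE, 4), t_sim = 10)
  crv <- survival_curve(ens)
  expect_equal(survival_at(crv, 2.5), 0.5)
  expect_equal(survival_at(crv, 0), 1)
  expect_equal(survival_at(crv, 10), 0)
  all_cens <- fake_ensemble(rep(NA, 5), rep(TRUE, 5), t_sim = 10)
  crv2 <- survival_curve(all_cens)
  expect_true(all(survival_at(crv2, c(0, 5, 9.9)) == 1))
  expect_error(survival_curve(fake_ensemble(numeric(0), logical(0))), "empty")
})

test_that("empirical survival of exponential draws matches the closed form", {
  set.seed(41)
  tau <- rexp(500, rate = 1 / 5)
  cens <- tau > 100
  ens <- fake_ensemble(pmin(tau, 100), cens, t_sim = 100)
  crv <- survival_curve(ens)
  s5 <- survival_at(crv, 5)
  p <- exp(-1)
  expect_lt(abs(s5 - p), 3 * sqrt(p * (1 - p) / 500))
  # survival curves are non-increasing within [0, 1]
  expect_true(all(diff(crv$survival) <= 0))
  expect_true(all(crv$survival >= 0 & crv$survival <= 1))
  # rebinding fraction complements S(t_sim)
  expect_equal(rebinding_fraction(ens), 1 - survival_at(crv, 100 - 1e-9))
})

test_that("a noiseless single exponential is recovered exactly", {
  # synthetic exact curve (not an empirical step function)
  tgrid <- exp(seq(log(0.05), log(100), length.out = 200))
  crv <- structure(list(times = tgrid, survival = exp(-tgrid / 5), n = 200,
                        n_censored = 0, t_sim_ps = 100),
                   class = "survival_curve")
  fit <- fit_survival(crv, n_components = 1, with_static = FALSE, seed = 2)
  expect_equal(fit$timescales_ps, 5, tolerance = 1e-3)
  expect_equal(fit$amplitudes, 1, tolerance = 1e-3)
  expect_true(fit$converged)
})

test_that("censored bi-exponential parameters are recovered within 10%", {
  # generator follows the printed pure-water fit shape
  a <- c(0.38, 0.25); tau <- c(10.7, 192.3); a3 <- 0.37
  gen <- function(n, seed) {
    set.seed(seed)
    comp <- sample.int(3, n, replace = TRUE, prob = c(a, a3))
    t <- ifelse(comp == 1, rexp(n, 1 / tau[1]),
                ifelse(comp == 2, rexp(n, 1 / tau[2]), Inf))
    fake_ensemble(pmin(t, 1000), t > 1000, t_sim = 1000)
  }
  fits <- lapply(1:20, function(s) {
    fit_survival(survival_curve(gen(500, s)), 2, TRUE, seed = s)
  })
  t1 <- median(vapply(fits, function(f) f$timescales_ps[1], numeric(1)))
  t2 <- median(vapply(fits, function(f) f$timescales_ps[2], numeric(1)))
  expect_equal(t1, tau[1], tolerance = 0.10)
  expect_equal(t2, tau[2], tolerance = 0.10)
  # amplitudes and static offset are also close (looser, they trade off)
  a3hat <- median(vapply(fits, function(f) f$static, numeric(1)))
  expect_equal(a3hat, a3, tolerance = 0.15)
})

test_that("fit respects its preconditions and best-of-multistart contract", {
  ens <- fake_ensemble(c(1, 2, 3), rep(FALSE, 3), t_sim = 10)
  expect_error(fit_survival(survival_curve(ens), 2), ">= 10 distinct")
  set.seed(43)
  t <- rexp(200, 1 / 5)
  crv <- survival_curve(fake_ensemble(pmin(t, 50), t > 50, t_sim = 50))
  best <- fit_survival(crv, 2, TRUE, n_starts = 10, seed = 1)
  singles <- vapply(1:8, function(s)
    fit_survival(crv, 2, TRUE, n_starts = 1, seed = s)$residual, numeric(1))
  expect_true(all(best$residual <= singles + 1e-10))
  # timescales come out sorted
  expect_true(all(diff(best$timescales_ps) >= 0))
})

test_that("estimator consistency: recovery error shrinks with n", {
  err_at <- function(n) {
    errs <- vapply(1:8, function(s) {
      set.seed(1000 + s)
      t <- rexp(n, 1 / 5)
      crv <- survival_curve(fake_ensemble(pmin(t, 100), t > 100, t_sim = 100))
      abs(fit_survival(crv, 1, FALSE, seed = s)$timescales_ps - 5)
    }, numeric(1))
    median(errs)
  }
  e100 <- err_at(100); e2000 <- err_at(2000)
  expect_lt(e2000, e100)
  expect_lt(e2000 / 5, 0.05)
})

test_that("evaluate_survival_model matches its closed form and the printed example", {
  # printed pure-water parameters reproduce the 0.63 rebinding fraction
  fit <- list(amplitudes = c(0.35, 0.20), timescales_ps = c(10.7, 192.3),
              static = 0.37)
  expect_equal(round(1 - evaluate_survival_model(fit, 1000), 2), 0.63)
  expect_equal(evaluate_survival_model(fit, 0), sum(fit$amplitudes) + fit$static)
  expect_equal(evaluate_survival_model(fit, 1e9), fit$static, tolerance = 1e-12)
  expect_error(evaluate_survival_model(fit, -1), "t must be")
  # brute-force agreement at random parameters
  set.seed(44)
  for (i in 1:5) {
    f <- list(amplitudes = runif(2), timescales_ps = sort(runif(2, 1, 100)),
              static = runif(1))
    t <- runif(20, 0, 500)
    brute <- f$static + f$amplitudes[1] * exp(-t / f$timescales_ps[1]) +
      f$amplitudes[2] * exp(-t / f$timescales_ps[2])
    expect_equal(evaluate_survival_model(f, t), brute, tolerance = 1e-12)
  }
})

test_that("rebinding_fraction counts censored trajectories", {
  tau <- c(rep(1, 315), rep(NA, 185))
  ens <- fake_ensemble(tau, is.na(tau), t_sim = 1000)
  expect_equal(rebinding_fraction(ens), 0.63)
  expect_equal(rebinding_fraction(fake_ensemble(rep(NA, 5), rep(TRUE, 5))), 0)
  expect_equal(rebinding_fraction(fake_ensemble(1:5, rep(FALSE, 5))), 1)
})

test_that("select_model prefers the generating form and breaks ties to simplicity", {
  pick_k <- function(seed, two_comp) {
    set.seed(seed)
    n <- 300
    if (two_comp) {
      comp <- sample.int(3, n, TRUE, prob = c(0.35, 0.28, 0.37))
      t <- ifelse(comp == 1, rexp(n, 1 / 10.7),
                  ifelse(comp == 2, rexp(n, 1 / 192.3), Inf))
    } else {
      t <- rexp(n, 1 / 20)
    }
    crv <- survival_curve(fake_ensemble(pmin(t, 1000), t > 1000, t_sim = 1000))
    fits <- list(fit_survival(crv, 1, FALSE, seed = seed),
                 fit_survival(crv, 2, TRUE, seed = seed))
    select_model(fits, crv)$n_components
  }
  single <- vapply(1:20, pick_k, numeric(1), two_comp = FALSE)
  double <- vapply(1:20, pick_k, numeric(1), two_comp = TRUE)
  expect_gte(mean(single == 1), 0.9)
  expect_gte(mean(double == 2), 0.9)
  # identical candidates: fewer parameters win
  crv <- survival_curve(fake_ensemble(rexp(100, 1 / 5), rep(FALSE, 100), t_sim = 1e6))
  f1 <- fit_survival(crv, 1, FALSE, seed = 1)
  f2 <- f1; f2$n_parameters <- 5
  expect_equal(select_model(list(f2, f1), crv)$n_parameters, f1$n_parameters)
})
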