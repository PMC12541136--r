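# Lambert W, Rogers random-predator prediction, generalized depletion solver.

test_that("lambert_w0 matches reference values and its defining identity", {
  # frozen references (scipy.special.lambertw / mpmath)
  ref <- c(-0.357402956181389, 0.000999001497338531, 0.3517337112491958,
           0.5671432904097838, 1.745528002740699, 20.02868541330495,
           684.2472086297608)
  expect_equal(lambert_w0(c(-0.25, 0.001, 0.5, 1, 10, 1e10, 1e300)), ref,
               tolerance = 1e-12)
  w <- lambert_w0(10^seq(-8, 8, length.out = 30))
  expect_equal(w * exp(w), 10^seq(-8, 8, length.out = 30), tolerance = 1e-12)
  expect_warning(out <- lambert_w0(-1), "below -1/e")
  expect_true(is.nan(out))
})

test_that("lambert_w0_exp handles arguments far beyond overflow", {
  # frozen mpmath values of W0(e^z)
  expect_equal(lambert_w0_exp(c(700, 800, 5000)),
               c(693.4583088790255, 793.323768578489, 4991.484511358231),
               tolerance = 1e-12)
  z <- c(-5, 0, 3, 650)
  expect_equal(lambert_w0_exp(z), lambert_w0(exp(z)), tolerance = 1e-12)
  w <- lambert_w0_exp(1e6)
  expect_equal(w + log(w), 1e6, tolerance = 1e-9)
})

test_that("rogers_eaten reproduces closed forms and the ODE oracle", {
  expect_equal(rogers_eaten(holling_params(1, 0.05), trial_conditions(0)), 0)
  expect_equal(rogers_eaten(holling_params(0.8, 0), trial_conditions(30)),
               30 * (1 - exp(-0.8)), tolerance = 1e-12)
  # frozen scipy value (lambertw route, checked against solve_ivp)
  expect_equal(rogers_eaten(holling_params(0.5, 0.04), trial_conditions(30)),
               8.45268700509893, tolerance = 1e-10)
  # overflow regime: a*th*n0 huge; must be finite and < n0
  big <- rogers_eaten(holling_params(50, 0.5), trial_conditions(1000))
  expect_true(is.finite(big) && big > 0 && big < 1000)
  expect_error(rogers_eaten(holling_params(1, 0.1), trial_conditions(10, t = -1)))
})

test_that("rogers_eaten is monotone in a, T and N0, and bounded", {
  a_grid <- c(0.05, 0.2, 1, 5)
  ne_a <- vapply(a_grid, function(a)
    rogers_eaten(holling_params(a, 0.04), trial_conditions(30)), 0)
  expect_true(all(diff(ne_a) > 0))
  t_grid <- c(0.25, 0.5, 1, 2)
  ne_t <- vapply(t_grid, function(t)
    rogers_eaten(holling_params(0.5, 0.04), trial_conditions(30, t = t)), 0)
  expect_true(all(diff(ne_t) > 0))
  n_grid <- c(1, 5, 30, 120)
  ne_n <- vapply(n_grid, function(n)
    rogers_eaten(holling_params(0.5, 0.04), trial_conditions(n)), 0)
  expect_true(all(diff(ne_n) > 0))
  expect_true(all(ne_n >= 0 & ne_n < n_grid))
})

test_that("generalized depletion agrees with independent integrators", {
  # frozen scipy solve_ivp (rtol 1e-12) references
  expect_equal(depletion_eaten_generalized(gen_params(0.1, 0.5, 0.05),
                                           trial_conditions(50)),
               11.8270965800955, tolerance = 1e-8)
  expect_equal(depletion_eaten_generalized(gen_params(0.02, 1, 0.04),
                                           trial_conditions(20)),
               4.87196300995597, tolerance = 1e-8)
  expect_equal(depletion_eaten_generalized(gen_params(2, -0.5, 0.01),
                                           trial_conditions(10)),
               5.1013425692483, tolerance = 1e-8)
  # in-package adaptive RK route agrees with the implicit quadrature
  for (par in list(c(0.1, 0.5, 0.05, 50), c(0.3, 1, 0.02, 80),
                   c(0.8, -0.3, 0.05, 15))) {
    p <- gen_params(par[1], par[2], par[3])
    cond <- trial_conditions(par[4])
    expect_equal(depletion_eaten_generalized(p, cond, method = "ode"),
                 depletion_eaten_generalized(p, cond), tolerance = 1e-6)
  }
  # naive fixed-step RK4 oracle
  p <- gen_params(0.1, 0.5, 0.05)
  expect_equal(depletion_eaten_generalized(p, trial_conditions(50)),
               rk4_eaten(function(n) feeding_rate(p, n), 50, h = 1e-4),
               tolerance = 1e-7)
  expect_equal(depletion_eaten_generalized(gen_params(1e-12, 0.5, 0.05),
                                           trial_conditions(50)),
               0, tolerance = 1e-9)
})

test_that("q < 0 exhausts prey in finite time; q = 0 reduces to Rogers", {
  # extinction time G(N0)/P is analytic; pick parameters past it
  expect_equal(depletion_eaten_generalized(gen_params(50, -0.5, 0.001),
                                           trial_conditions(10)), 10)
  set.seed(7)
  for (i in 1:20) {
    a <- 10^runif(1, -2, 1); th <- runif(1, 0, 0.1); n0 <- sample(c(1, 10, 100), 1)
    expect_equal(depletion_eaten_generalized(gen_params(a, 0, th),
                                             trial_conditions(n0)),
                 rogers_eaten(holling_params(a, th), trial_conditions(n0)),
                 tolerance = 1e-8)
  }
})

test_that("ode_depletion is an accurate adaptive integrator", {
  # pure exponential decay has an exact solution
  nt <- ode_depletion(function(n) 0.7 * n, 50, 1)
  expect_equal(nt, 50 * exp(-0.7), tolerance = 1e-8)
  # multiple predators scale the clock
  n2 <- ode_depletion(function(n) 0.7 * n, 50, 0.5, p_pred = 2)
  expect_equal(n2, nt, tolerance = 1e-8)
  expect_equal(ode_depletion(function(n) n, 0, 1), 0)
})
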