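# Binomial depletion likelihood, MLE machinery, information criteria,
# profile confidence intervals.

const_pred <- function(ne) function(params, trials) rep(ne, nrow(trials))

one_trial <- function(n0, eaten) {
  feeding_trials(data.frame(species = "ambush", complexity_level = 0,
                            n_initial = n0, n_eaten = eaten))
}

test_that("nll_trials matches the binomial pmf oracle and is additive", {
  tr <- one_trial(10, 5)
  expect_equal(nll_trials(const_pred(5), NULL, tr),
               binom_nll_oracle(5, 10, 0.5), tolerance = 1e-12)
  # frozen: -log(C(10,5) * 0.5^10)
  expect_equal(nll_trials(const_pred(5), NULL, tr), 1.40204271808803,
               tolerance = 1e-12)
  # clipped boundary: eaten 0 predicted 0 contributes ~0
  expect_lt(nll_trials(const_pred(0), NULL, one_trial(10, 0)), 1e-6)
  two <- feeding_trials(rbind(one_trial(10, 5), one_trial(10, 5)))
  expect_equal(nll_trials(const_pred(5), NULL, two),
               2 * nll_trials(const_pred(5), NULL, tr), tolerance = 1e-12)
  expect_error(nll_trials(function(p, t) rep(NaN, nrow(t)), NULL, tr),
               "non-finite prediction for trial 1")
})

test_that("nll is invariant to trial order and additive over subsets", {
  tr <- simulate_trials(default_design("ambush"), truth_preset("5R"), seed = 3)
  model <- suite_model("5R")
  pred <- function(p, t) habfr:::predict_eaten_suite(model, p, t)
  par <- c(log10(28), log10(15), log10(57))
  full <- nll_trials(pred, par, tr)
  set.seed(1)
  perm <- tr[sample(nrow(tr)), ]
  expect_equal(nll_trials(pred, par, perm), full, tolerance = 1e-10)
  half <- seq_len(nrow(tr)) <= nrow(tr) / 2
  expect_equal(nll_trials(pred, par, tr[half, ]) +
                 nll_trials(pred, par, tr[!half, ]), full, tolerance = 1e-10)
})

test_that("information criteria follow their definitions", {
  ic <- information_criteria(0, 3, exp(2))
  expect_equal(unname(ic), c(6, 6))
  # AIC differences are invariant to a common logLik shift
  d1 <- information_criteria(-10, 2, 50)["aic"] -
    information_criteria(-12, 4, 50)["aic"]
  d2 <- information_criteria(-10 + 7, 2, 50)["aic"] -
    information_criteria(-12 + 7, 4, 50)["aic"]
  expect_equal(unname(d1), unname(d2))
  expect_error(information_criteria(0, 0, 10))
})

test_that("fit_mle recovers the generating type II parameters", {
  # ~210 trials from a habitat-blind truth a = 0.3, th = 0.05
  truth <- ground_truth(suite_model("1H"), c(th = log10(0.05), a = log10(0.3)))
  tr <- simulate_trials(default_design("ambush", replicates = 6), truth, seed = 21)
  fit <- fit_mle("1H", tr, quick_cfg(starts = 4, seed = 2))
  expect_true(fit$converged)
  a_hat <- 10^fit$coef[["a"]]
  th_hat <- 10^fit$coef[["th"]]
  expect_lt(abs(a_hat - 0.3) / 0.3, 0.15)
  expect_lt(abs(th_hat - 0.05) / 0.05, 0.15)
  expect_equal(fit$aic, 2 * 2 - 2 * fit$loglik)
  expect_equal(fit$bic, 2 * log(nrow(tr)) - 2 * fit$loglik)
})

test_that("1H and 1R are the same model in different coordinates", {
  truth <- ground_truth(suite_model("1H"), c(th = log10(0.05), a = log10(0.3)))
  tr <- simulate_trials(default_design("ambush"), truth, seed = 5)
  fh <- fit_mle("1H", tr, quick_cfg(starts = 3, seed = 7))
  fr <- fit_mle("1R", tr, quick_cfg(starts = 3, seed = 7))
  expect_equal(fh$loglik, fr$loglik, tolerance = 1e-6)
  a <- 10^fh$coef[["a"]]; th <- 10^fh$coef[["th"]]
  expect_equal(10^fr$coef[["fmax"]], 1 / th, tolerance = 1e-3)
  expect_equal(10^fr$coef[["nhalf"]], 1 / (a * th), tolerance = 1e-3)
})

test_that("df bookkeeping requires enough data and treatments", {
  tr <- simulate_trials(cell_design(level = 0), flat_truth(), seed = 1)
  expect_error(fit_mle("5R", tr, quick_cfg()), "structure-absent and -present")
  expect_error(fit_mle("15H", tr, quick_cfg()), "five complexity levels")
  expect_error(fit_mle("1H", tr[1:1, ], quick_cfg()), "cannot identify")
})

# a synthetic fr_fit with an exactly quadratic NLL, for which the profile
# interval must coincide with the Wald interval
quadratic_fit <- function(center = c(x = 1, y = 2), vcov = diag(c(0.04, 0.09)),
                          lower = NULL, upper = NULL) {
  prec <- solve(vcov)
  nll_fn <- function(p) 0.5 * drop(t(p - center) %*% prec %*% (p - center)) + 3
  structure(list(name = "QUAD", family = "T", coef = center, vcov = vcov,
                 vcov_ok = TRUE, loglik = -3, df = length(center),
                 n = 10, nll_fn = nll_fn, lower = lower, upper = upper,
                 config = fit_config()), class = "fr_fit")
}

test_that("profile_ci equals Wald on a quadratic likelihood", {
  fit <- quadratic_fit()
  ci <- profile_ci(fit, "x", level = 0.95)
  expect_equal(ci$method, "profile")
  z <- qnorm(0.975)
  expect_equal(ci$lower, 1 - z * 0.2, tolerance = 0.01)
  expect_equal(ci$upper, 1 + z * 0.2, tolerance = 0.01)
  ci2 <- profile_ci(fit, 2, level = 0.9)
  expect_equal(ci2$upper - ci2$lower, 2 * qnorm(0.95) * 0.3, tolerance = 0.01)
})

test_that("profile_ci flags box boundaries instead of silent symmetry", {
  fit <- quadratic_fit(lower = c(0.9, -Inf), upper = c(Inf, Inf))
  ci <- profile_ci(fit, "x", level = 0.95)
  expect_true(ci$boundary)
  expect_equal(ci$lower, 0.9)
  expect_equal(ci$upper, 1 + qnorm(0.975) * 0.2, tolerance = 0.01)
})

test_that("nominal 95% intervals cover the truth in repeated sampling", {
  # scaled down from the 100-replicate design for runtime; Wald intervals,
  # which the profile reduces to at this n
  truth <- ground_truth(suite_model("1H"), c(th = log10(0.05), a = log10(0.3)))
  design <- default_design("ambush", replicates = 6)
  rec <- recovery_experiment(truth, design, n_replicates = 40, seed = 11,
                             config = quick_cfg(starts = 2))
  expect_equal(length(rec$failures), 0L)
  expect_true(all(rec$summary$coverage >= 0.9))
})
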