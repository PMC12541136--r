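# The 32-model factorial suite: specs, habitat links, ranking, prediction bands.

test_that("build_suite enumerates the factorial grid", {
  specs <- build_suite()
  expect_length(specs, 32L)
  expect_setequal(names(specs), c(paste0(1:16, "H"), paste0(1:16, "R")))
  s15 <- specs[["15H"]]
  expect_equal(s15[c("family", "hyp1", "hyp2", "par1", "par2", "df")],
               list(family = "H", hyp1 = "three", hyp2 = "two",
                    par1 = "th", par2 = "a", df = 7L))
  s5 <- specs[["5R"]]
  expect_equal(s5[c("family", "hyp1", "hyp2", "df")],
               list(family = "R", hyp1 = "one", hyp2 = "zero", df = 3L))
  expect_equal(specs[["1H"]]$df, 2L)
  # index encoding k = 4*h1 + h2 + 1
  hyps <- c("zero", "one", "two", "three")
  for (s in specs) {
    expect_equal(s$index,
                 4L * (match(s$hyp1, hyps) - 1L) + (match(s$hyp2, hyps) - 1L) + 1L)
    expect_equal(s$df, unname(habfr:::hyp_df[s$hyp1] + habfr:::hyp_df[s$hyp2]))
  }
  expect_error(suite_model("17H"), "unknown model")
})

test_that("parameter_value maps treatments under each hypothesis", {
  tr3 <- data.frame(complexity_level = 3, n_rings = 3, structure_present = TRUE)
  expect_equal(parameter_value("two", c(0, -0.144), tr3), 10^(-0.432))
  tr0 <- data.frame(complexity_level = 0, n_rings = 0, structure_present = FALSE)
  expect_equal(parameter_value("one", c(log10(2), log10(9)), tr0), 2)
  lv <- data.frame(complexity_level = 0:4, n_rings = c(0, 2, 2, 3, 3),
                   structure_present = c(FALSE, TRUE, TRUE, TRUE, TRUE))
  expect_equal(parameter_value("three", log10(1:5), lv), 1:5)
  expect_equal(parameter_value("zero", log10(7), lv), rep(7, 5))
  bad <- data.frame(complexity_level = 9, n_rings = 0, structure_present = FALSE)
  expect_error(parameter_value("three", log10(1:5), bad), "unknown complexity level")
  expect_true(all(parameter_value("two", c(-2, -0.5), lv) > 0))
})

fake_suite <- function(tab) {
  tab$dAIC <- tab$AIC - min(tab$AIC)
  tab$dBIC <- tab$BIC - min(tab$BIC)
  structure(list(species = "x", fits = list(), table = tab,
                 best = list(AIC = tab$model[which.min(tab$AIC)],
                             BIC = tab$model[which.min(tab$BIC)])),
            class = "fr_suite")
}

test_that("rank_table orders by delta with df and name tie-breaks", {
  tab <- data.frame(model = c("9R", "1H", "6R", "6H"),
                    family = c("R", "H", "R", "H"),
                    df = c(3L, 2L, 4L, 4L),
                    logLik = c(-10, -12, -9.5, -9.5),
                    AIC = c(26, 28, 27, 27),
                    BIC = c(26.5, 28.2, 27.8, 27.8),
                    converged = TRUE)
  rk <- rank_table(fake_suite(tab), "AIC")
  expect_equal(rk$delta[1], 0)
  expect_equal(rk$model, c("9R", "6H", "6R", "1H"))  # tie 6H/6R broken by name
  # permutation invariance
  rk2 <- rank_table(fake_suite(tab[c(3, 1, 4, 2), ]), "AIC")
  expect_equal(rk2, rk)
})

test_that("fit_suite ranks the generating structure near the top", {
  # scaled down from a 25-seed selection-consistency experiment (runtime);
  # the generating model is 5R (df 3): the winner must be indistinguishable
  # from the refitted 5R at equal df
  wins <- 0L
  for (s in 1:4) {
    tr <- simulate_trials(default_design("ambush"), truth_preset("5R"),
                          seed = 600 + s)
    sw <- fit_suite(tr, quick_cfg(starts = 2, seed = s))
    expect_equal(nrow(sw$table), 32L)
    expect_equal(min(sw$table$dAIC), 0)
    top <- rank_table(sw, "AIC")[1, ]
    if (top$df == 3 && abs(sw$fits[[top$model]]$aic - sw$fits[["5R"]]$aic) < 4)
      wins <- wins + 1L
  }
  expect_gte(wins, 3L)
})

test_that("suite fitting is reproducible given the seed", {
  tr <- simulate_trials(default_design("ambush"), truth_preset("5R"), seed = 8)
  f1 <- fit_mle("7R", tr, quick_cfg(starts = 3, seed = 42))
  f2 <- fit_mle("7R", tr, quick_cfg(starts = 3, seed = 42))
  expect_identical(f1$coef, f2$coef)
  expect_identical(f1$loglik, f2$loglik)
})

test_that("predict_with_bands covers the point prediction and degenerates", {
  tr <- simulate_trials(default_design("ambush"), truth_preset("5R"), seed = 13)
  fit <- fit_mle("5R", tr, quick_cfg(starts = 3, seed = 1))
  grid <- c(1, 5, 20, 60, 120)
  pb <- predict_with_bands(fit, list(complexity_level = 2), grid,
                           n_boot = 200, seed = 5)
  expect_equal(attr(pb, "method"), "parametric")
  expect_true(all(pb$lower <= pb$fit & pb$fit <= pb$upper))
  expect_true(all(pb$fit > 0 & pb$fit < grid))
  # vanishing covariance -> vanishing band
  tiny <- fit
  tiny$vcov <- diag(1e-18, fit$df)
  pb0 <- predict_with_bands(tiny, list(complexity_level = 2), grid,
                            n_boot = 200, seed = 5)
  expect_lt(max(pb0$upper - pb0$lower), 1e-6)
  # low-density width is generous relative to the asymptote
  expect_gt((pb$upper[1] - pb$lower[1]) / pb$fit[1],
            (pb$upper[5] - pb$lower[5]) / pb$fit[5] / 10)
})

test_that("singular covariance falls back to a refit bootstrap, flagged", {
  tr <- simulate_trials(default_design("ambush"), truth_preset("5R"), seed = 17)
  fit <- fit_mle("1H", tr, quick_cfg(starts = 2, seed = 3))
  fit$vcov_ok <- FALSE
  pb <- predict_with_bands(fit, list(complexity_level = 0), c(5, 50),
                           n_boot = 8, seed = 2)
  expect_equal(attr(pb, "method"), "refit")
  expect_true(all(pb$lower <= pb$fit & pb$fit <= pb$upper))
})
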