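#' Habitat hypotheses and the 32-model suite
#'
#' Each functional-response parameter can depend on the habitat treatment in
#' four ways ("hypotheses"):
#'
#' * `zero` — habitat has no effect: 1 coefficient.
#' * `one` — structure presence has an effect (absent/present): 2
#'   coefficients.
#' * `two` — the amount of structure has an effect, modeled as a log10-linear
#'   regression on the ring count (0, 2 or 3 rings):
#'   `log10(par) = intercept + slope * n_rings`, 2 coefficients.
#' * `three` — each complexity level 0-4 has its own value: 5 coefficients.
#'
#' Crossing the four hypotheses over the two parameters of the type II
#' response, in both the Holling (`th`, `a`) and Real (`fmax`, `nhalf`)
#' parameterizations, yields 16 "H" + 16 "R" models. Model `k` (1-16)
#' encodes hypothesis `h1` on the first parameter (handling time or maximum
#' feeding rate) and `h2` on the second (attack rate or half-saturation
#' density) via `k = 4*h1 + h2 + 1` with `h` in 0:3 ordered
#' (zero, one, two, three).
#'
#' @return `build_suite()`: a named list of 32 `fr_model_spec` objects,
#'   `"1H"` ... `"16H"`, `"1R"` ... `"16R"`.
#' @export
#' @examples
#' specs <- build_suite()
#' specs[["15H"]]$df  # 7: five handling times + amount intercept and slope
build_suite <- function() {
  hyps <- c("zero", "one", "two", "three")
  specs <- list()
  for (family in c("H", "R")) {
    for (h1 in 0:3) for (h2 in 0:3) {
      k <- 4L * h1 + h2 + 1L
      specs[[paste0(k, family)]] <-
        model_spec(k, family, hyps[h1 + 1L], hyps[h2 + 1L])
    }
  }
  specs[c(paste0(1:16, "H"), paste0(1:16, "R"))]
}

hyp_df <- c(zero = 1L, one = 2L, two = 2L, three = 5L)

model_spec <- function(index, family, hyp1, hyp2) {
  stopifnot(family %in% c("H", "R"), hyp1 %in% names(hyp_df),
            hyp2 %in% names(hyp_df))
  par1 <- if (family == "H") "th" else "fmax"
  par2 <- if (family == "H") "a" else "nhalf"
  structure(list(
    name = paste0(index, family), index = as.integer(index), family = family,
    hyp1 = hyp1, hyp2 = hyp2, par1 = par1, par2 = par2,
    df = unname(hyp_df[hyp1] + hyp_df[hyp2])), class = "fr_model_spec")
}

#' Look up one model of the suite by name
#'
#' @param name e.g. `"5R"` or `"15H"`.
#' @return an `fr_model_spec`.
#' @export
suite_model <- function(name) {
  specs <- build_suite()
  if (!name %in% names(specs)) stop("unknown model name: ", name)
  specs[[name]]
}

#' @export
print.fr_model_spec <- function(x, ...) {
  cat(sprintf("Model %s: %s ~ %s, %s ~ %s (df = %d)\n", x$name,
              x$par1, x$hyp1, x$par2, x$hyp2, x$df))
  invisible(x)
}

# link-scale coefficient names for one parameter under one hypothesis
hyp_coef_names <- function(hyp, par) {
  switch(hyp,
         zero = par,
         one = paste0(par, c("_absent", "_present")),
         two = paste0(par, c("_intercept", "_slope")),
         three = paste0(par, "_L", 0:4))
}

model_coef_names <- function(spec) {
  c(hyp_coef_names(spec$hyp1, spec$par1), hyp_coef_names(spec$hyp2, spec$par2))
}

#' Natural-scale parameter value per trial under a habitat hypothesis
#'
#' Maps link-scale coefficients and a treatment descriptor to the
#' natural-scale parameter of each trial. All coefficients live on the
#' log10 scale except the `two`-hypothesis slope, which is a log10-scale
#' change per plastic-plant ring.
#'
#' @param hyp `"zero"`, `"one"`, `"two"` or `"three"`.
#' @param coefs numeric vector of length 1, 2, 2 or 5 (see [build_suite()]).
#' @param treatment data.frame with columns `complexity_level`, `n_rings`,
#'   `structure_present` (one row per trial).
#' @return positive numeric vector, one value per row of `treatment`.
#' @export
#' @examples
#' tr <- data.frame(complexity_level = 3, n_rings = 3, structure_present = TRUE)
#' parameter_value("two", c(0, -0.144), tr)  # 10^(-0.432)
parameter_value <- function(hyp, coefs, treatment) {
  n <- nrow(treatment)
  stopifnot(length(coefs) == hyp_df[[hyp]])
  lvl <- treatment$complexity_level
  if (any(is.na(lvl) | lvl < 0 | lvl > 4)) stop("parameter_value: unknown complexity level")
  switch(hyp,
         zero = rep(10^coefs[1], n),
         one = 10^coefs[1 + as.integer(treatment$structure_present)],
         two = 10^(coefs[1] + coefs[2] * treatment$n_rings),
         three = 10^coefs[lvl + 1L])
}

# per-trial Holling (a, th) rates implied by a model's coefficients
model_rates <- function(spec, coefs, trials) {
  k1 <- hyp_df[[spec$hyp1]]
  v1 <- parameter_value(spec$hyp1, coefs[seq_len(k1)], trials)
  v2 <- parameter_value(spec$hyp2, coefs[-seq_len(k1)], trials)
  if (spec$family == "H") list(a = v2, th = v1)
  else list(a = v1 / v2, th = 1 / v1)
}

# expected eaten per trial for a type II suite model (Rogers prediction)
predict_eaten_suite <- function(spec, coefs, trials) {
  r <- model_rates(spec, coefs, trials)
  rogers_eaten_vec(r$a, r$th, trials$n_initial, trials$duration_d)
}

# treatments a model needs must all occur in the data
check_design <- function(spec, trials) {
  for (hyp in c(spec$hyp1, spec$hyp2)) {
    if (hyp == "one" && length(unique(trials$structure_present)) < 2L)
      stop("model ", spec$name, ": needs both structure-absent and -present trials")
    if (hyp == "two" && length(unique(trials$n_rings)) < 2L)
      stop("model ", spec$name, ": needs at least two ring counts")
    if (hyp == "three" && !all(0:4 %in% trials$complexity_level))
      stop("model ", spec$name, ": needs all five complexity levels")
  }
  invisible(TRUE)
}

#' Fit one suite model by maximum likelihood
#'
#' Minimizes the binomial depletion NLL ([nll_trials()] with the Rogers
#' prediction) over the model's link-scale coefficients, restarting the
#' optimizer from `config$starts` Latin-hypercube points. Deterministic
#' given (data, config).
#'
#' @param model an `fr_model_spec` (see [build_suite()], [suite_model()])
#'   or a model name.
#' @param trials a `feeding_trials` table (normally one species).
#' @param config a [fit_config()].
#' @return an `fr_fit`: link/natural estimates with CIs, logLik, df,
#'   AIC/BIC, convergence diagnostics.
#' @export
fit_mle <- function(model, trials, config = fit_config()) {
  if (is.character(model)) model <- suite_model(model)
  stopifnot(inherits(model, "fr_model_spec"))
  trials <- feeding_trials(trials)
  if (nrow(trials) < model$df)
    stop("fit_mle: ", nrow(trials), " trials cannot identify ", model$df, " parameters")
  check_design(model, trials)

  fmax0 <- max(max(trials$n_eaten / trials$duration_d), 1)
  nhalf0 <- stats::median(trials$n_initial)
  anchor_for <- function(par) switch(par,
    th = log10(1 / fmax0), a = log10(fmax0 / nhalf0),
    fmax = log10(fmax0), nhalf = log10(nhalf0))
  nm <- model_coef_names(model)
  center <- stats::setNames(numeric(length(nm)), nm)
  spread <- rep(config$spread, length(nm))
  k1 <- hyp_df[[model$hyp1]]
  center[seq_len(k1)] <- anchor_for(model$par1)
  center[-seq_len(k1)] <- anchor_for(model$par2)
  slope_idx <- grep("_slope$", nm)
  center[slope_idx] <- 0
  spread[slope_idx] <- 0.2

  nll <- function(par) nll_trials(
    function(p, tr) predict_eaten_suite(model, p, tr), par, trials)
  opt <- with_seed(config$seed,
                   optimize_multistart(nll, center, spread, config))
  make_fit(model$name, model$family, nm, nll, opt, trials, config,
           model = model)
}

#' Fit the full 32-model suite to one species
#'
#' Fits every model of [build_suite()] with [fit_mle()] and computes dAIC
#' and dBIC relative to the per-criterion minimum across successful fits.
#' Per-model failures are recorded, not fatal.
#'
#' @param trials a `feeding_trials` table for a single species.
#' @param config a [fit_config()].
#' @param models optionally a subset of specs (named list) to fit.
#' @return an `fr_suite`: `$fits` (named list of `fr_fit`), `$table`
#'   (model, family, df, logLik, AIC, BIC, dAIC, dBIC, converged),
#'   `$best` (model name with lowest AIC and lowest BIC), `$failures`.
#' @export
fit_suite <- function(trials, config = fit_config(), models = build_suite()) {
  trials <- feeding_trials(trials)
  if (length(unique(trials$species)) > 1L)
    stop("fit_suite: fit one species at a time (found: ",
         paste(unique(trials$species), collapse = ", "), ")")
  fits <- list(); failures <- character()
  for (nmod in names(models)) {
    f <- tryCatch(fit_mle(models[[nmod]], trials, config),
                  error = function(e) conditionMessage(e))
    if (inherits(f, "fr_fit")) fits[[nmod]] <- f
    else failures[nmod] <- f
  }
  if (!length(fits)) stop("fit_suite: every model failed")
  tab <- data.frame(
    model = names(fits),
    family = vapply(fits, function(f) f$family, ""),
    df = vapply(fits, function(f) f$df, 0L),
    logLik = vapply(fits, function(f) f$loglik, 0),
    AIC = vapply(fits, function(f) f$aic, 0),
    BIC = vapply(fits, function(f) f$bic, 0),
    converged = vapply(fits, function(f) f$converged, TRUE),
    row.names = NULL)
  tab$dAIC <- tab$AIC - min(tab$AIC)
  tab$dBIC <- tab$BIC - min(tab$BIC)
  structure(list(
    species = unique(trials$species), fits = fits, table = tab,
    best = list(AIC = tab$model[which.min(tab$AIC)],
                BIC = tab$model[which.min(tab$BIC)]),
    failures = failures, config = config), class = "fr_suite")
}

#' @export
print.fr_suite <- function(x, ...) {
  cat("Functional response model suite:", x$species, "—",
      nrow(x$table), "fits,", length(x$failures), "failures\n")
  cat("Best by AIC:", x$best$AIC, "| best by BIC:", x$best$BIC, "\n")
  print(utils::head(rank_table(x, "AIC"), 6), digits = 4)
  invisible(x)
}

#' Rank fitted models by an information criterion
#'
#' @param suite an `fr_suite`.
#' @param criterion `"AIC"` or `"BIC"`.
#' @return data.frame (model, df, delta) in ascending delta; ties broken
#'   by smaller df, then model name.
#' @export
rank_table <- function(suite, criterion = c("AIC", "BIC")) {
  criterion <- match.arg(criterion)
  tab <- suite$table
  delta <- tab[[paste0("d", criterion)]]
  out <- data.frame(model = tab$model, df = tab$df, delta = delta)
  # order on the reported precision (3 decimals) so that matched H/R pairs,
  # equal up to optimizer noise, tie deterministically by df then name
  out <- out[order(round(out$delta, 3), out$df, out$model), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Predicted feeding curve with bootstrap confidence band
#'
#' Point predictions are the Rogers expected-eaten values on a grid of
#' initial densities for one habitat treatment. The 95% band comes from a
#' parametric bootstrap: coefficient vectors are drawn from the fit's
#' asymptotic normal on the link scale (Cholesky of the inverse Hessian)
#' and the prediction quantiles taken pointwise. If the covariance is
#' singular, trials are resampled and the model refitted (`n_boot` capped
#' at 50), flagged in the `method` attribute.
#'
#' @param fit an `fr_fit` from [fit_mle()].
#' @param treatment one-row data.frame or list with `complexity_level`
#'   (ring count and presence derived if absent).
#' @param densities numeric vector of initial prey densities.
#' @param n_boot bootstrap draws.
#' @param seed RNG seed.
#' @param level band level.
#' @return data.frame (n_initial, fit, lower, upper) with attribute
#'   `method` = "parametric" or "refit".
#' @export
predict_with_bands <- function(fit, treatment, densities, n_boot = 500L,
                               seed = 1L, level = 0.95) {
  stopifnot(inherits(fit, "fr_fit"), !is.null(fit$model))
  lvl <- as.integer(treatment$complexity_level)
  grid <- data.frame(
    complexity_level = lvl,
    n_rings = treatment$n_rings %||% rings_for_level(lvl),
    structure_present = treatment$structure_present %||% (rings_for_level(lvl) > 0),
    n_initial = as.numeric(densities), duration_d = 1)
  point <- predict_eaten_suite(fit$model, fit$coef, grid)
  alpha <- (1 - level) / 2
  ch <- if (fit$vcov_ok) tryCatch(chol(fit$vcov), error = function(e) NULL) else NULL
  if (!is.null(ch)) {
    method <- "parametric"
    draws <- with_seed(seed, {
      z <- matrix(stats::rnorm(n_boot * fit$df), n_boot, fit$df)
      sweep(z %*% ch, 2, fit$coef, "+")
    })
  } else {
    method <- "refit"
    n_boot <- min(n_boot, 50L)
    cfg <- fit$config; cfg$starts <- 2L
    draws <- with_seed(seed, {
      m <- matrix(NA_real_, n_boot, fit$df)
      for (b in seq_len(n_boot)) {
        idx <- sample.int(nrow(fit$trials), replace = TRUE)
        cfg$seed <- sample.int(.Machine$integer.max - 1L, 1L)
        fb <- tryCatch(fit_mle(fit$model, fit$trials[idx, ], cfg),
                       error = function(e) NULL)
        if (!is.null(fb)) m[b, ] <- fb$coef
      }
      m[stats::complete.cases(m), , drop = FALSE]
    })
  }
  curves <- apply(draws, 1, function(p) {
    tryCatch(predict_eaten_suite(fit$model, p, grid),
             error = function(e) rep(NA_real_, nrow(grid)))
  })
  curves <- matrix(curves, nrow = nrow(grid))
  qs <- apply(curves, 1, stats::quantile,
              probs = c(alpha, 1 - alpha), na.rm = TRUE)
  out <- data.frame(n_initial = grid$n_initial, fit = point,
                    lower = pmin(qs[1, ], point), upper = pmax(qs[2, ], point))
  attr(out, "method") <- method
  out
}
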