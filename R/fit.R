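#' Fitting configuration
#'
#' Controls the maximum-likelihood machinery. Estimation is done on a
#' log10 link scale for all positive parameters (attack rate, handling
#' time, maximum feeding rate, half-saturation density, attack
#' coefficient); the shape parameter q is fitted on the identity scale
#' with the box constraint q in (-0.99, 3). Depletion likelihoods can be
#' multimodal at small sample sizes, so the optimizer is restarted from
#' `starts` Latin-hypercube points spread `spread` log10 units around
#' data-driven anchors (max observed eaten/T for the maximum feeding rate,
#' the median offered density for the half-saturation density, q = 0).
#'
#' @param starts number of multi-start points (>= 1).
#' @param seed integer seed making the start draws (and hence the whole
#'   fit) reproducible.
#' @param ci_level two-sided confidence level in (0, 1).
#' @param ci_method `"wald"` (default, from the inverse Hessian on the link
#'   scale) or `"profile"` (likelihood profiling of every parameter).
#' @param maxit Nelder-Mead iteration cap per start.
#' @param reltol relative convergence tolerance on the negative
#'   log-likelihood.
#' @param spread half-width of the multi-start cloud, in log10 units.
#' @return a `fit_config` list.
#' @export
fit_config <- function(starts = 10L, seed = 1L, ci_level = 0.95,
                       ci_method = c("wald", "profile"),
                       maxit = 500L, reltol = 1e-10, spread = 0.6) {
  ci_method <- match.arg(ci_method)
  stopifnot(starts >= 1, ci_level > 0, ci_level < 1, maxit >= 1,
            reltol > 0, spread > 0)
  structure(list(starts = as.integer(starts), seed = as.integer(seed),
                 ci_level = ci_level, ci_method = ci_method,
                 maxit = as.integer(maxit), reltol = reltol,
                 spread = spread),
            class = "fit_config")
}

# run expr with a given seed, restoring the caller's RNG state afterwards
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# Latin-hypercube start matrix centered on `center`; row 1 is the center
lhs_starts <- function(center, spread, n) {
  k <- length(center)
  m <- matrix(0, n, k)
  for (j in seq_len(k)) {
    u <- (sample.int(n) - stats::runif(n)) / n
    m[, j] <- center[j] + spread[j] * (2 * u - 1)
  }
  m[1, ] <- center
  colnames(m) <- names(center)
  m
}

#' Binomial negative log-likelihood of feeding trials
#'
#' Each trial contributes `-log Binomial(eaten | n0, p)` with
#' `p = Ne/n0`, where `Ne` is the model's expected number eaten under
#' depletion. `p` is clipped to `[1e-9, 1 - 1e-9]` so boundary predictions
#' stay finite.
#'
#' @param predict_eaten function `(params, trials) -> Ne` returning the
#'   expected eaten count per trial (vector of length `nrow(trials)` in
#'   `[0, n_initial]`).
#' @param params parameter object/vector forwarded to `predict_eaten`.
#' @param trials a `feeding_trials` table.
#' @return scalar negative log-likelihood.
#' @export
nll_trials <- function(predict_eaten, params, trials) {
  ne <- predict_eaten(params, trials)
  if (length(ne) != nrow(trials))
    stop("nll_trials: prediction length ", length(ne), " != ", nrow(trials), " trials")
  if (any(!is.finite(ne))) {
    i <- which(!is.finite(ne))[1]
    stop("nll_trials: non-finite prediction for trial ", i,
         " (species ", trials$species[i], ", level ", trials$complexity_level[i],
         ", n_initial ", trials$n_initial[i], ")")
  }
  p <- pmin(pmax(ne / trials$n_initial, 1e-9), 1 - 1e-9)
  -sum(stats::dbinom(trials$n_eaten, trials$n_initial, p, log = TRUE))
}

#' AIC and BIC from a log-likelihood
#'
#' `AIC = 2*df - 2*logLik`; `BIC = df*log(n) - 2*logLik`, with `n` the
#' number of trials entering the fit.
#'
#' @param loglik maximized log-likelihood.
#' @param df number of free parameters (>= 1).
#' @param n number of observations (>= 1).
#' @return named numeric vector `c(aic = , bic = )`.
#' @export
information_criteria <- function(loglik, df, n) {
  stopifnot(df >= 1, n >= 1, is.finite(loglik))
  c(aic = 2 * df - 2 * loglik, bic = df * log(n) - 2 * loglik)
}

# internal: minimize a link-scale NLL with multi-start NM + BFGS polish.
# Returns list(par, value, convergence, starts) — RNG must be seeded by caller.
optimize_multistart <- function(nll, center, spread, config, lower = NULL,
                                upper = NULL) {
  k <- length(center)
  safe_nll <- function(par) {
    if (any(!is.finite(par)) || any(abs(par) > 16)) return(1e10 + sum(par^2))
    if (!is.null(lower) && any(par < lower))
      return(1e10 + sum((pmax(lower - par, 0))^2) * 1e4)
    if (!is.null(upper) && any(par > upper))
      return(1e10 + sum((pmax(par - upper, 0))^2) * 1e4)
    v <- tryCatch(nll(par), error = function(e) NA_real_)
    if (!is.finite(v)) 1e10 else v
  }
  starts <- lhs_starts(center, rep_len(spread, k), config$starts)
  diag_df <- data.frame(start = seq_len(config$starts), nll = NA_real_,
                        convergence = NA_integer_)
  best <- NULL
  for (s in seq_len(config$starts)) {
    # quasi-Newton per start (fast on this smooth likelihood); simplex
    # fallback when it fails. Only the winner gets the expensive polish.
    r1 <- tryCatch({
      r <- stats::nlminb(starts[s, ], safe_nll,
                         control = list(rel.tol = 1e-12,
                                        iter.max = config$maxit,
                                        eval.max = 2L * config$maxit))
      list(par = r$par, value = r$objective, convergence = r$convergence)
    }, error = function(e) NULL)
    if (is.null(r1) || !is.finite(r1$value) || r1$value >= 1e10)
      r1 <- tryCatch(
        stats::optim(starts[s, ], safe_nll, method = "Nelder-Mead",
                     control = list(maxit = config$maxit * k, reltol = 1e-9)),
        error = function(e) NULL)
    if (is.null(r1)) next
    diag_df$nll[s] <- r1$value
    diag_df$convergence[s] <- r1$convergence
    if (is.null(best) || r1$value < best$value) best <- r1
  }
  if (!is.null(best)) {
    r2 <- tryCatch(
      stats::optim(best$par, safe_nll, method = "BFGS",
                   control = list(maxit = 300, reltol = config$reltol)),
      error = function(e) NULL)
    if (!is.null(r2) && is.finite(r2$value) && r2$value <= best$value)
      best <- r2
  }
  if (is.null(best) || best$value >= 1e10)
    stop("optimize_multistart: no start converged to a finite optimum; per-start log:\n",
         paste(utils::capture.output(print(diag_df)), collapse = "\n"))
  names(best$par) <- names(center)
  list(par = best$par, value = best$value, convergence = best$convergence,
       starts = diag_df)
}

# internal: assemble an fr_fit object from an optimizer result
make_fit <- function(name, family, coef_info, nll_fn, opt, trials, config,
                     model = NULL, lower = NULL, upper = NULL) {
  df <- length(opt$par)
  n <- nrow(trials)
  loglik <- -opt$value
  ic <- information_criteria(loglik, df, n)
  hess <- tryCatch(stats::optimHess(opt$par, function(p) {
    v <- tryCatch(nll_fn(p), error = function(e) NA_real_)
    if (is.finite(v)) v else 1e10
  }), error = function(e) NULL)
  vcov <- matrix(NA_real_, df, df)
  vcov_ok <- FALSE
  if (!is.null(hess)) {
    vc <- tryCatch(solve(hess), error = function(e) NULL)
    if (!is.null(vc) && all(is.finite(diag(vc))) && all(diag(vc) > 0)) {
      vcov <- vc
      vcov_ok <- TRUE
    }
  }
  dimnames(vcov) <- list(names(opt$par), names(opt$par))
  fit <- structure(list(
    name = name, family = family, model = model,
    coef = opt$par, coef_info = coef_info,
    vcov = vcov, vcov_ok = vcov_ok,
    loglik = loglik, df = df, n = n,
    aic = unname(ic["aic"]), bic = unname(ic["bic"]),
    converged = opt$convergence == 0,
    starts = opt$starts,
    nll_fn = nll_fn, lower = lower, upper = upper,
    trials = trials, config = config), class = "fr_fit")
  fit$estimates <- fit_estimates(fit)
  fit
}

# natural-scale value of one link coefficient (slopes and q are identity)
natural_scale <- function(name, v) {
  if (grepl("(_slope|^q)$", name)) v else 10^v
}

# estimate table with Wald (or profile) CIs
fit_estimates <- function(fit, ci_method = NULL, level = NULL) {
  ci_method <- ci_method %||% fit$config$ci_method
  level <- level %||% fit$config$ci_level
  z <- stats::qnorm(1 - (1 - level) / 2)
  se <- sqrt(pmax(diag(fit$vcov), 0))
  nm <- names(fit$coef)
  lo <- hi <- rep(NA_real_, length(nm))
  method <- rep(ci_method, length(nm))
  for (i in seq_along(nm)) {
    if (ci_method == "profile") {
      ci <- tryCatch(profile_ci(fit, i, level), error = function(e) NULL)
      if (!is.null(ci)) { lo[i] <- ci$lower; hi[i] <- ci$upper; next }
      method[i] <- "wald"
    }
    lo[i] <- fit$coef[i] - z * se[i]
    hi[i] <- fit$coef[i] + z * se[i]
  }
  data.frame(
    term = nm,
    link_estimate = unname(fit$coef),
    link_se = unname(se),
    estimate = vapply(seq_along(nm), function(i) natural_scale(nm[i], fit$coef[i]), 0),
    lower = vapply(seq_along(nm), function(i) natural_scale(nm[i], lo[i]), 0),
    upper = vapply(seq_along(nm), function(i) natural_scale(nm[i], hi[i]), 0),
    ci_method = method,
    row.names = NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.fr_fit <- function(x, ...) {
  cat("Functional response fit:", x$name,
      sprintf("(df = %d, n = %d)\n", x$df, x$n))
  cat(sprintf("  logLik %.4f | AIC %.3f | BIC %.3f | converged: %s\n",
              x$loglik, x$aic, x$bic, x$converged))
  print(x$estimates[, c("term", "estimate", "lower", "upper")], digits = 4)
  invisible(x)
}

#' @export
logLik.fr_fit <- function(object, ...) {
  structure(object$loglik, df = object$df, nobs = object$n, class = "logLik")
}

#' Profile-likelihood confidence interval
#'
#' Profiles the negative log-likelihood along one link-scale parameter: the
#' bound is where the profiled NLL rises `qchisq(level, 1)/2` units
#' (1.92 at 0.95) above the minimum, re-optimizing all other parameters at
#' each step. If a side never crosses the cutoff within the search range
#' the interval is open on that side (`-Inf`/`Inf`, flagged); if the inner
#' optimization fails the Wald interval is returned with
#' `method = "wald"`. Bounds hitting a box constraint (the shape parameter
#' q) are flagged `boundary`.
#'
#' @param fit an `fr_fit` object.
#' @param parameter index or name of the link coefficient.
#' @param level confidence level.
#' @return list with `lower`, `upper` (link scale), `level`, `method`,
#'   and logical flags `open_lower`, `open_upper`, `boundary`.
#' @export
profile_ci <- function(fit, parameter, level = 0.95) {
  stopifnot(inherits(fit, "fr_fit"))
  idx <- if (is.character(parameter)) match(parameter, names(fit$coef)) else as.integer(parameter)
  if (is.na(idx) || idx < 1 || idx > fit$df) stop("profile_ci: unknown parameter")
  est <- fit$coef[idx]
  nll0 <- -fit$loglik
  target <- nll0 + stats::qchisq(level, 1) / 2
  se <- sqrt(diag(fit$vcov))[idx]
  if (!is.finite(se) || se <= 0) se <- 0.25
  box_lo <- if (!is.null(fit$lower)) fit$lower[idx] else -Inf
  box_hi <- if (!is.null(fit$upper)) fit$upper[idx] else Inf

  prof <- function(v) {
    if (fit$df == 1L) return(fit$nll_fn(v))
    obj <- function(o) {
      p <- numeric(fit$df); p[idx] <- v; p[-idx] <- o
      val <- tryCatch(fit$nll_fn(p), error = function(e) NA_real_)
      if (is.finite(val)) val else 1e10
    }
    st <- fit$coef[-idx]
    r <- tryCatch(
      stats::nlminb(st, obj, control = list(rel.tol = 1e-11, iter.max = 300)),
      error = function(e) NULL)
    if (is.null(r) || !is.finite(r$objective) || r$objective >= 1e10)
      r <- tryCatch(
        stats::optim(st, obj,
                     method = if (length(st) == 1L) "BFGS" else "Nelder-Mead",
                     control = list(maxit = 400 * length(st), reltol = 1e-10)),
        error = function(e) NULL)
    if (is.null(r)) NA_real_
    else if (!is.null(r$objective)) r$objective else r$value
  }

  wald <- function() {
    z <- stats::qnorm(1 - (1 - level) / 2)
    list(lower = est - z * se, upper = est + z * se, level = level,
         method = "wald", open_lower = FALSE, open_upper = FALSE,
         boundary = FALSE)
  }

  side <- function(s) {
    lim <- if (s < 0) box_lo else box_hi
    d <- se
    v_in <- est
    for (i in 1:14) {
      v <- est + s * d
      at_box <- (s < 0 && v <= lim) || (s > 0 && v >= lim)
      if (at_box) v <- lim
      g <- prof(v) - target
      if (is.na(g)) return(list(bound = NA_real_, open = FALSE, boundary = FALSE, failed = TRUE))
      if (g >= 0) {
        root <- tryCatch(
          stats::uniroot(function(u) prof(u) - target,
                         lower = min(v_in, v), upper = max(v_in, v),
                         tol = max(se * 1e-3, 1e-8))$root,
          error = function(e) NA_real_)
        if (is.na(root)) return(list(bound = v, open = FALSE, boundary = at_box, failed = FALSE))
        return(list(bound = root, open = FALSE, boundary = FALSE, failed = FALSE))
      }
      if (at_box) return(list(bound = lim, open = FALSE, boundary = TRUE, failed = FALSE))
      v_in <- v
      d <- d * 2
    }
    list(bound = s * Inf, open = TRUE, boundary = FALSE, failed = FALSE)
  }

  lo <- side(-1)
  hi <- side(1)
  if (isTRUE(lo$failed) || isTRUE(hi$failed)) return(wald())
  list(lower = lo$bound, upper = hi$bound, level = level, method = "profile",
       open_lower = lo$open, open_upper = hi$open,
       boundary = lo$boundary || hi$boundary)
}
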