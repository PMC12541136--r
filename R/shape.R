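#' Fit the generalized (type II/III) functional response to one treatment
#'
#' Estimates the attack coefficient `b`, shape parameter `q` and handling
#' time `th` of the generalized response by maximizing the binomial
#' depletion likelihood, with the expected eaten count obtained by
#' integrating the within-trial prey decline
#' ([depletion_eaten_generalized()]). `b` and `th` are fitted on the log10
#' link scale; `q` on the identity scale inside the box (-0.99, 3).
#'
#' @param trials feeding trials of one species at one complexity level.
#' @param config a [fit_config()].
#' @return an `fr_fit` with coefficients `log10_b`, `q`, `log10_th`.
#' @export
fit_generalized <- function(trials, config = fit_config()) {
  trials <- feeding_trials(trials)
  if (length(unique(trials$species)) > 1L ||
      length(unique(trials$complexity_level)) > 1L)
    stop("fit_generalized: expects one species at one complexity level")
  fmax0 <- max(max(trials$n_eaten / trials$duration_d), 1)
  nhalf0 <- stats::median(trials$n_initial)
  center <- c(log10_b = log10(fmax0 / nhalf0), q = 0,
              log10_th = log10(1 / fmax0))
  spread <- c(config$spread, 0.4, config$spread)
  lower <- c(-16, -0.99, -16)
  upper <- c(16, 3, 16)
  nll <- function(par) nll_trials(
    function(p, tr) gen_eaten_vec(10^p[1], p[2], 10^p[3],
                                  tr$n_initial, tr$duration_d),
    par, trials)
  opt <- with_seed(config$seed,
                   optimize_multistart(nll, center, spread, config,
                                       lower = lower, upper = upper))
  make_fit("GEN", "G", names(center), nll, opt, trials, config,
           lower = lower, upper = upper)
}

#' Type II vs type III shape test
#'
#' Fits the generalized functional response to one species x complexity
#' cell and asks whether the shape parameter q differs from zero. The q
#' confidence interval is a profile-likelihood interval ([profile_ci()]).
#' A type III response is assigned only when q is significantly *greater*
#' than zero (profile lower bound > 0); otherwise the hyperbolic type II
#' is retained.
#'
#' @inheritParams fit_generalized
#' @return an `fr_shape_test`: list with `q`, `ci` (lower/upper),
#'   `significant`, `type` ("II"/"III"), and the underlying `fit`.
#' @export
test_shape <- function(trials, config = fit_config()) {
  fit <- fit_generalized(trials, config)
  ci <- profile_ci(fit, "q", level = config$ci_level)
  q_hat <- unname(fit$coef["q"])
  significant <- is.finite(ci$lower) && is.finite(ci$upper) &&
    (ci$lower > 0 || ci$upper < 0)
  type <- if (q_hat > 0 && is.finite(ci$lower) && ci$lower > 0) "III" else "II"
  structure(list(
    species = unique(fit$trials$species),
    complexity_level = unique(fit$trials$complexity_level),
    q = q_hat, ci = c(lower = ci$lower, upper = ci$upper),
    ci_method = ci$method, significant = significant, type = type,
    fit = fit), class = "fr_shape_test")
}

#' @export
print.fr_shape_test <- function(x, ...) {
  cat(sprintf("Shape test: %s, level %d — q = %.3f [%.3f, %.3f] %s -> type %s\n",
              x$species, x$complexity_level, x$q, x$ci["lower"], x$ci["upper"],
              if (x$significant) "significant" else "n.s.", x$type))
  invisible(x)
}

#' Shape tests for every species x complexity cell
#'
#' @param trials a `feeding_trials` table (any number of species/levels).
#' @param config a [fit_config()].
#' @return data.frame with one row per cell: species, complexity_level, q,
#'   q_lower, q_upper, significance, type.
#' @export
shape_table <- function(trials, config = fit_config()) {
  trials <- feeding_trials(trials)
  cells <- unique(trials[, c("species", "complexity_level")])
  cells <- cells[order(cells$species, cells$complexity_level), ]
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    sub <- trials[trials$species == cells$species[i] &
                    trials$complexity_level == cells$complexity_level[i], ]
    st <- tryCatch(test_shape(sub, config), error = function(e) NULL)
    if (is.null(st))
      return(data.frame(species = cells$species[i],
                        complexity_level = cells$complexity_level[i],
                        q = NA_real_, q_lower = NA_real_, q_upper = NA_real_,
                        significance = "fit failed", type = NA_character_))
    data.frame(species = st$species, complexity_level = st$complexity_level,
               q = st$q, q_lower = unname(st$ci["lower"]),
               q_upper = unname(st$ci["upper"]),
               significance = if (st$significant) "significant" else "n.s.",
               type = st$type)
  })
  do.call(rbind, rows)
}
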