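#' Default feeding-trial designs
#'
#' The two designs emulated by the generator: an ambush predator offered
#' prey densities 1, 3, 5, 10, 30, 80 and 120 per microcosm (default 3
#' replicates per density x level), and a pursuit predator offered the same
#' densities plus 180 (default 6 replicates), each crossed with the five
#' habitat complexity levels (ring counts 0/2/2/3/3) in 24 h (1 day)
#' trials. Defaults give 105 + 240 = 345 microcosms, close to the 297 of
#' the original campaign, whose per-cell replication varied from 1 to 6.
#'
#' @param species `"ambush"` or `"pursuit"`.
#' @param replicates replicates per density x level cell (default 3 for
#'   ambush, 6 for pursuit).
#' @return an `fr_design` data.frame: one row per cell with columns
#'   species, complexity_level, n_rings, structure_present, n_initial,
#'   replicates, duration_d.
#' @export
default_design <- function(species = c("ambush", "pursuit"),
                           replicates = NULL) {
  species <- match.arg(species)
  dens <- if (species == "ambush") c(1, 3, 5, 10, 30, 80, 120)
          else c(1, 3, 5, 10, 30, 80, 120, 180)
  reps <- replicates %||% if (species == "ambush") 3L else 6L
  stopifnot(reps >= 1)
  g <- expand.grid(complexity_level = 0:4, n_initial = dens,
                   KEEP.OUT.ATTRS = FALSE)
  g$species <- species
  g$n_rings <- rings_for_level(g$complexity_level)
  g$structure_present <- g$n_rings > 0L
  g$replicates <- as.integer(reps)
  g$duration_d <- 1
  g <- g[order(g$complexity_level, g$n_initial),
         c("species", "complexity_level", "n_rings", "structure_present",
           "n_initial", "replicates", "duration_d")]
  rownames(g) <- NULL
  class(g) <- c("fr_design", "data.frame")
  g
}

#' Ground-truth presets for the generator
#'
#' Named parameter sets, on the link (log10) scale, used as generating
#' truths in tests and recovery experiments:
#'
#' * `"5R"` — presence/absence effect on the maximum feeding rate
#'   (28 prey/day without structure, 15 with), constant half-saturation
#'   density (57 prey/arena): the selected model for the ambush predator.
#' * `"15H"` — a separate handling time per complexity level
#'   (1/31, 1/18, 1/28, 1/22, 1/19 day) and a log10-linear decline of the
#'   attack rate with ring count (slope -0.144/ring, intercept
#'   log10(3*28/57), i.e. three times the ambush attack rate in the open
#'   arena): the selected model for the pursuit predator.
#' * `"1H"` — habitat-blind baseline, a = 0.3, th = 0.05.
#'
#' @param name `"5R"`, `"15H"` or `"1H"`.
#' @param q optional shape parameter; when non-NULL trials are generated
#'   from the generalized response with attack coefficient b equal to the
#'   model's per-trial attack rate.
#' @return an `fr_truth`: list(model = `fr_model_spec`, coef = named link
#'   vector, q).
#' @export
truth_preset <- function(name = c("5R", "15H", "1H"), q = NULL) {
  name <- match.arg(name)
  coef <- switch(name,
    "5R" = c(fmax_absent = log10(28), fmax_present = log10(15),
             nhalf = log10(57)),
    "15H" = c(stats::setNames(log10(1 / c(31, 18, 28, 22, 19)),
                              paste0("th_L", 0:4)),
              a_intercept = log10(3 * 28 / 57), a_slope = -0.144),
    "1H" = c(th = log10(0.05), a = log10(0.3)))
  ground_truth(suite_model(name), coef, q = q)
}

#' @rdname truth_preset
#' @param model an `fr_model_spec`.
#' @param coef named link-scale coefficient vector matching the model's
#'   layout.
#' @export
ground_truth <- function(model, coef, q = NULL) {
  stopifnot(inherits(model, "fr_model_spec"))
  nm <- model_coef_names(model)
  if (!identical(names(coef), nm))
    stop("ground_truth: coefficient names must be exactly: ",
         paste(nm, collapse = ", "))
  if (!is.null(q)) stopifnot(is.numeric(q), length(q) == 1L, q > -1)
  structure(list(model = model, coef = coef, q = q), class = "fr_truth")
}

#' Simulate feeding trials from a known truth
#'
#' Expands the design into individual microcosms and draws the eaten count
#' of each trial as `Binomial(n0, Ne/n0)`, where `Ne` is the deterministic
#' depletion expectation at the treatment's parameters — the same
#' expectation the likelihood uses, so the generator and the fitted model
#' agree by construction. `noise = "none"` replaces the draw by the
#' rounded expectation (a near-deterministic limit for recovery checks).
#'
#' @param design an `fr_design` (see [default_design()]).
#' @param truth an `fr_truth` (see [truth_preset()]).
#' @param seed integer seed; the same seed yields the identical dataset.
#' @param noise `"binomial"` or `"none"`.
#' @return a `feeding_trials` table with one row per microcosm.
#' @export
simulate_trials <- function(design, truth, seed = 1L,
                            noise = c("binomial", "none")) {
  noise <- match.arg(noise)
  stopifnot(inherits(truth, "fr_truth"))
  idx <- rep(seq_len(nrow(design)), design$replicates)
  tr <- design[idx, c("species", "complexity_level", "n_rings",
                      "structure_present", "n_initial", "duration_d")]
  tr$block <- paste0("b", unlist(lapply(design$replicates, seq_len)))
  rownames(tr) <- NULL
  r <- model_rates(truth$model, truth$coef, tr)
  ne <- if (is.null(truth$q)) {
    rogers_eaten_vec(r$a, r$th, tr$n_initial, tr$duration_d)
  } else {
    # generalized truth: b plays the role of the attack rate at N = 1
    gen_eaten_vec(r$a, truth$q, r$th, tr$n_initial, tr$duration_d)
  }
  tr$n_eaten <- if (noise == "binomial") {
    with_seed(seed, stats::rbinom(nrow(tr), tr$n_initial,
                                  pmin(pmax(ne / tr$n_initial, 0), 1)))
  } else {
    pmin(as.integer(round(ne)), tr$n_initial)
  }
  feeding_trials(tr)
}

#' Event-based stochastic depletion simulation
#'
#' An independent oracle for the depletion expectation: individual prey
#' deaths are simulated as a pure death process whose state-dependent rate
#' is `p_pred * F(N)` (exponential waiting times, Gillespie algorithm)
#' until the trial ends or the arena is empty. Its mean approaches the
#' deterministic ODE solution as `n0` grows (they differ at order 1/n0),
#' which is why the binomial generator above — not this one — is the
#' default data generator.
#'
#' @param p a `holling_params` or `gen_params`.
#' @param cond `trial_conditions`.
#' @param seed integer seed.
#' @return integer number of prey eaten, in `[0, n0]`.
#' @export
stochastic_depletion_sim <- function(p, cond, seed = 1L) {
  if (!inherits(cond, "trial_conditions")) cond <- trial_conditions(cond)
  stopifnot(inherits(p, "holling_params") || inherits(p, "gen_params"))
  with_seed(seed, {
    n <- cond$n0
    tt <- 0
    deaths <- 0L
    while (n > 0) {
      rate <- cond$p_pred * feeding_rate(p, n)
      if (rate <= 0) break
      tt <- tt + stats::rexp(1, rate)
      if (tt > cond$t) break
      n <- n - 1
      deaths <- deaths + 1L
    }
    deaths
  })
}

#' Simulate-and-refit recovery experiment
#'
#' For each replicate: simulate trials from the truth, refit (either the
#' generating model alone or the whole 32-model suite), and record the
#' estimate, relative error and Wald-CI coverage of every coefficient,
#' plus the AIC/BIC-best model when the suite is fitted. Per-replicate
#' failures are recorded and skipped.
#'
#' @param truth an `fr_truth`.
#' @param design an `fr_design`.
#' @param n_replicates number of simulate/refit cycles.
#' @param seed master seed; replicate seeds are drawn from it.
#' @param config a [fit_config()]; its seed is overridden per replicate.
#' @param fit `"model"` (refit the generating model) or `"suite"`.
#' @return an `fr_recovery`: `$results` (long data.frame: replicate, term,
#'   true, estimate, rel_error, covered), `$best` (per-replicate best
#'   model, suite mode only), `$summary` (median |rel_error| and coverage
#'   per term), `$failures`.
#' @export
recovery_experiment <- function(truth, design, n_replicates = 25L, seed = 1L,
                                config = fit_config(), fit = c("model", "suite")) {
  fit <- match.arg(fit)
  stopifnot(n_replicates >= 1)
  seeds <- with_seed(seed, sample.int(.Machine$integer.max - 1L, n_replicates))
  res <- list(); best <- list(); failures <- character()
  true_nat <- vapply(seq_along(truth$coef),
                     function(i) natural_scale(names(truth$coef)[i], truth$coef[i]), 0)
  for (r in seq_len(n_replicates)) {
    cfg <- config; cfg$seed <- seeds[r]
    dat <- simulate_trials(design, truth, seed = seeds[r])
    out <- tryCatch({
      if (fit == "suite") {
        sw <- fit_suite(dat, cfg)
        best[[length(best) + 1L]] <- data.frame(
          replicate = r, best_aic = sw$best$AIC, best_bic = sw$best$BIC)
        sw$fits[[truth$model$name]]
      } else {
        fit_mle(truth$model, dat, cfg)
      }
    }, error = function(e) conditionMessage(e))
    if (!inherits(out, "fr_fit")) {
      failures[as.character(r)] <- as.character(out)
      next
    }
    est <- out$estimates
    truth_tab <- data.frame(term = names(truth$coef), true = true_nat)
    m <- merge(est, truth_tab, by = "term", sort = FALSE)
    slope <- grepl("_slope$", m$term)
    denom <- ifelse(slope & m$true == 0, 1, abs(m$true))
    res[[length(res) + 1L]] <- data.frame(
      replicate = r, term = m$term, true = m$true, estimate = m$estimate,
      rel_error = (m$estimate - m$true) / denom,
      covered = m$lower <= m$true & m$true <= m$upper)
  }
  if (!length(res)) stop("recovery_experiment: every replicate failed")
  results <- do.call(rbind, res)
  summ <- do.call(rbind, lapply(split(results, results$term), function(d)
    data.frame(term = d$term[1],
               median_abs_rel_error = stats::median(abs(d$rel_error)),
               coverage = mean(d$covered), n = nrow(d))))
  rownames(summ) <- NULL
  structure(list(results = results,
                 best = if (length(best)) do.call(rbind, best) else NULL,
                 summary = summ, failures = failures,
                 truth = truth, n_replicates = n_replicates),
            class = "fr_recovery")
}

#' @export
print.fr_recovery <- function(x, ...) {
  cat("Recovery experiment:", x$truth$model$name, "truth,",
      x$n_replicates, "replicates,", length(x$failures), "failures\n")
  print(x$summary, digits = 3)
  invisible(x)
}
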