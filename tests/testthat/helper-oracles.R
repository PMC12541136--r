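# Shared fixtures and independent numerical oracles.

quick_cfg <- function(starts = 3L, seed = 1L, ...) {
  fit_config(starts = starts, seed = seed, ...)
}

# deliberately naive fixed-step classical RK4 integrator of
# dN/dt = -rate(N); independent of the package's adaptive solver
rk4_eaten <- function(rate, n0, t = 1, h = 1e-4) {
  n <- n0
  steps <- ceiling(t / h)
  h <- t / steps
  for (i in seq_len(steps)) {
    k1 <- -rate(n)
    k2 <- -rate(max(n + h / 2 * k1, 0))
    k3 <- -rate(max(n + h / 2 * k2, 0))
    k4 <- -rate(max(n + h * k3, 0))
    n <- n + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    if (n <= 0) { n <- 0; break }
  }
  n0 - n
}

# binomial pmf negative log-likelihood from first principles
binom_nll_oracle <- function(eaten, n0, p) {
  -(log(choose(n0, eaten)) + eaten * log(p) + (n0 - eaten) * log(1 - p))
}

# one species x one complexity-level design cell
cell_design <- function(species = "ambush", level = 0L, replicates = 3L) {
  d <- default_design(species, replicates = replicates)
  d[d$complexity_level == level, ]
}

# type II truth with a single (a, th) everywhere; defaults echo the
# open-arena estimates fmax = 28, nhalf = 57
flat_truth <- function(a = 28 / 57, th = 1 / 28, q = NULL) {
  ground_truth(suite_model("1H"), c(th = log10(th), a = log10(a)), q = q)
}
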