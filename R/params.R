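#' Functional-response parameter bundles
#'
#' Three interchangeable descriptions of a saturating functional response:
#'
#' * `holling_params(a, th)` — attack rate `a` (arena/day) and handling time
#'   `th` (day/prey), the classic disc-equation coordinates.
#' * `real_params(fmax, nhalf)` — maximum feeding rate `fmax = 1/th`
#'   (prey/day) and half-saturation density `nhalf = 1/(a*th)` (prey/arena),
#'   the Michaelis–Menten-style coordinates.
#' * `gen_params(b, q, th)` — generalized response with attack coefficient
#'   `b` and shape parameter `q`; the attack rate is the power law
#'   `a = b * N^q`, so `q = 0` recovers the hyperbolic type II response and
#'   `q = 1` a "strict" sigmoid type III response.
#'
#' @param a attack rate, > 0.
#' @param th handling time, >= 0 (0 is the linear, non-saturating limit).
#' @param fmax maximum feeding rate, > 0.
#' @param nhalf half-saturation prey density, > 0.
#' @param b attack coefficient, > 0.
#' @param q shape parameter, > -1 (dimensionless).
#' @return an object of class `holling_params`, `real_params` or
#'   `gen_params`; a named list of validated numeric scalars.
#' @name fr_params
NULL

#' @rdname fr_params
#' @export
holling_params <- function(a, th) {
  stopifnot(is.numeric(a), length(a) == 1L, is.finite(a), a > 0,
            is.numeric(th), length(th) == 1L, is.finite(th), th >= 0)
  structure(list(a = as.numeric(a), th = as.numeric(th)),
            class = "holling_params")
}

#' @rdname fr_params
#' @export
real_params <- function(fmax, nhalf) {
  stopifnot(is.numeric(fmax), length(fmax) == 1L, is.finite(fmax), fmax > 0,
            is.numeric(nhalf), length(nhalf) == 1L, is.finite(nhalf), nhalf > 0)
  structure(list(fmax = as.numeric(fmax), nhalf = as.numeric(nhalf)),
            class = "real_params")
}

#' @rdname fr_params
#' @export
gen_params <- function(b, q, th) {
  stopifnot(is.numeric(b), length(b) == 1L, is.finite(b), b > 0,
            is.numeric(q), length(q) == 1L, is.finite(q),
            is.numeric(th), length(th) == 1L, is.finite(th), th >= 0)
  if (q <= -1) stop("gen_params: shape parameter q must be > -1")
  structure(list(b = as.numeric(b), q = as.numeric(q), th = as.numeric(th)),
            class = "gen_params")
}

#' Convert between Holling and Real parameterizations
#'
#' The identities are `fmax = 1/th`, `nhalf = 1/(a*th)` and inversely
#' `th = 1/fmax`, `a = fmax/nhalf`. The round trip is exact up to floating
#' point. `th = 0` has no Real-coordinate image (infinite `fmax`) and is
#' rejected.
#'
#' @param p a `holling_params` or `real_params` object.
#' @return the converted parameter bundle.
#' @export
#' @examples
#' holling_to_real(holling_params(a = 2, th = 0.05))  # fmax 20, nhalf 10
holling_to_real <- function(p) {
  stopifnot(inherits(p, "holling_params"))
  if (p$th <= 0) stop("holling_to_real: th = 0 has no Real-coordinate image (fmax infinite)")
  real_params(fmax = 1 / p$th, nhalf = 1 / (p$a * p$th))
}

#' @rdname holling_to_real
#' @export
real_to_holling <- function(p) {
  stopifnot(inherits(p, "real_params"))
  holling_params(a = p$fmax / p$nhalf, th = 1 / p$fmax)
}

check_density <- function(n) {
  if (!is.numeric(n) || any(!is.finite(n)) || any(n < 0))
    stop("prey density N must be finite and >= 0")
  as.numeric(n)
}

#' Instantaneous feeding rate
#'
#' Per-predator feeding rate F(N) at prey density `N` (vectorized over `N`):
#' `a*N / (1 + a*th*N)` in Holling coordinates, `fmax*N / (nhalf + N)` in
#' Real coordinates, and `b*N^(1+q) / (1 + b*th*N^(1+q))` for the
#' generalized response.
#'
#' @param p a parameter bundle (see [fr_params]).
#' @param n prey density (prey per arena), >= 0; vectorized.
#' @return feeding rate in prey per day, same length as `n`.
#' @export
feeding_rate <- function(p, n) UseMethod("feeding_rate")

#' @export
feeding_rate.holling_params <- function(p, n) {
  n <- check_density(n)
  p$a * n / (1 + p$a * p$th * n)
}

#' @export
feeding_rate.real_params <- function(p, n) {
  n <- check_density(n)
  p$fmax * n / (p$nhalf + n)
}

#' @export
feeding_rate.gen_params <- function(p, n) {
  n <- check_density(n)
  np <- n^(1 + p$q)
  p$b * np / (1 + p$b * p$th * np)
}

#' Per-capita predation risk
#'
#' The risk F(N)/N experienced by one prey individual (per day). For a
#' hyperbolic type II response (q = 0) risk declines monotonically with
#' prey density; for q > 0 it initially rises, the signature of a
#' stabilizing type III response.
#'
#' @inheritParams feeding_rate
#' @param n prey density, strictly > 0 (risk per individual is undefined in
#'   an empty arena).
#' @return per-capita risk (1/day), same length as `n`.
#' @export
predation_risk <- function(p, n) {
  if (!is.numeric(n) || any(!is.finite(n)) || any(n <= 0))
    stop("predation_risk: N must be > 0")
  feeding_rate(p, n) / n
}

#' Trial conditions
#'
#' Experimental conditions of one feeding trial: initial prey count `n0`,
#' duration `t` in days (the study design uses 24 h, `t = 1`), and the
#' number of predators `p_pred` (1 throughout; kept general as a rate
#' multiplier).
#'
#' @param n0 initial prey count, integer >= 0.
#' @param t trial duration in days, > 0.
#' @param p_pred number of predators, integer >= 1.
#' @return a `trial_conditions` object.
#' @export
trial_conditions <- function(n0, t = 1, p_pred = 1) {
  stopifnot(is.numeric(n0), length(n0) == 1L, is.finite(n0), n0 >= 0,
            abs(n0 - round(n0)) < 1e-8,
            is.numeric(t), length(t) == 1L, is.finite(t), t > 0,
            is.numeric(p_pred), length(p_pred) == 1L, p_pred >= 1)
  structure(list(n0 = as.numeric(round(n0)), t = as.numeric(t),
                 p_pred = as.numeric(p_pred)),
            class = "trial_conditions")
}
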