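#' Lambert W function, principal branch
#'
#' Solves `w * exp(w) = x` for `w >= -1`, i.e. the principal branch W0.
#' Vectorized over `x`. The domain is `x >= -1/e`; values below the branch
#' point return `NaN` with a warning.
#'
#' @param x numeric vector, `x >= -1/e`.
#' @return numeric vector of the same length as `x`.
#' @seealso [lambert_w0_exp()] for the overflow-safe form W0(exp(z)).
#' @export
#' @examples
#' lambert_w0(1)            # 0.567143...
#' lambert_w0(exp(1))       # exactly 1
lambert_w0 <- function(x) {
  x <- as.numeric(x)
  out <- rep(NaN, length(x))
  bad <- is.na(x) | x < -exp(-1) - 1e-12
  if (any(bad & !is.na(x))) warning("lambert_w0: argument below -1/e, returning NaN")
  ok <- !bad
  if (!any(ok)) return(out)
  xv <- x[ok]
  # initial guess by region
  w <- numeric(length(xv))
  near_branch <- xv < -0.25
  small <- !near_branch & xv < 1
  big <- xv >= 1
  if (any(near_branch)) {
    # series around the branch point x = -1/e
    p <- sqrt(2 * (exp(1) * xv[near_branch] + 1))
    w[near_branch] <- -1 + p - p^2 / 3 + 11 * p^3 / 72
  }
  if (any(small)) {
    z <- xv[small]
    w[small] <- z * (1 - z + 1.5 * z^2)  # Taylor at 0
  }
  if (any(big)) {
    L1 <- log(xv[big])
    L2 <- log(pmax(L1, 1e-300))
    w[big] <- pmax(L1 - L2 + L2 / L1, 0.5)
  }
  # Halley iterations
  for (i in 1:30) {
    ew <- exp(w)
    f <- w * ew - xv
    wp1 <- w + 1
    step <- f / (ew * wp1 - (w + 2) * f / (2 * wp1))
    w_new <- w - step
    w_new[wp1 <= 0] <- -1 + 1e-12  # clamp at branch point
    if (all(abs(w_new - w) <= 1e-14 * (abs(w_new) + 1e-14))) { w <- w_new; break }
    w <- w_new
  }
  out[ok] <- w
  out
}

#' Overflow-safe W0(exp(z))
#'
#' Evaluates the principal Lambert W branch at `exp(z)` without forming
#' `exp(z)`, which overflows for `z > ~709`. For moderate `z` this simply
#' calls [lambert_w0()]; for large `z` it iterates the asymptotic fixed
#' point `w <- z - log(w)`, which converges rapidly because the map is a
#' contraction for large `z`.
#'
#' Needed by the Rogers random-predator prediction, whose W argument
#' `a*Th*N0*exp(-a*(P*T - Th*N0))` overflows when `a*Th*N0` is large.
#'
#' @param z numeric vector; the log of the W argument.
#' @return numeric vector, `W0(exp(z))`.
#' @export
lambert_w0_exp <- function(z) {
  z <- as.numeric(z)
  out <- numeric(length(z))
  lo <- is.na(z) | z <= 690
  if (any(lo)) out[lo] <- lambert_w0(exp(z[lo]))
  if (any(!lo)) {
    zz <- z[!lo]
    w <- zz - log(zz)
    for (i in 1:50) {
      w_new <- zz - log(w)
      if (all(abs(w_new - w) <= 1e-15 * abs(w_new))) { w <- w_new; break }
      w <- w_new
    }
    out[!lo] <- w
  }
  out
}
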