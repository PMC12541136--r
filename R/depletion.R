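#' Expected prey eaten under type II depletion (Rogers random-predator)
#'
#' In a non-replacement trial the prey density declines as prey are eaten,
#' so the naive disc equation overestimates consumption. Integrating the
#' depletion dynamics `dN/dt = -P * a*N / (1 + a*th*N)` over the trial gives
#' the Rogers random-predator solution, expressible through the principal
#' Lambert W branch:
#'
#' `Ne = N0 - W0( a*th*N0 * exp(-a*(P*T - th*N0)) ) / (a*th)`
#'
#' For `th = 0` the dynamics are purely exponential and
#' `Ne = N0 * (1 - exp(-a*P*T))`. The W argument is evaluated in the log
#' domain ([lambert_w0_exp()]) so large `a*th*N0` cannot overflow.
#'
#' @param p `holling_params`.
#' @param cond `trial_conditions` (or an integer `n0` shortcut with `t`,
#'   `p_pred` defaults of 1).
#' @return expected number of prey eaten, a scalar in `[0, n0]`.
#' @export
#' @examples
#' rogers_eaten(holling_params(0.5, 0.04), trial_conditions(30))
rogers_eaten <- function(p, cond) {
  stopifnot(inherits(p, "holling_params"))
  if (!inherits(cond, "trial_conditions")) cond <- trial_conditions(cond)
  rogers_eaten_vec(p$a, p$th, cond$n0, cond$t, cond$p_pred)
}

# vectorized workhorse used by the likelihood layer: a, th, n0 recycled
rogers_eaten_vec <- function(a, th, n0, t = 1, p_pred = 1) {
  k <- max(length(a), length(th), length(n0), length(t), length(p_pred))
  a <- rep_len(as.numeric(a), k); th <- rep_len(as.numeric(th), k)
  n0 <- rep_len(as.numeric(n0), k); t <- rep_len(as.numeric(t), k)
  p_pred <- rep_len(as.numeric(p_pred), k)
  if (any(a < 0) || any(th < 0) || any(n0 < 0) || any(t <= 0))
    stop("rogers_eaten: need a >= 0, th >= 0, n0 >= 0, t > 0")
  ne <- numeric(k)
  zero <- n0 == 0 | a == 0
  lin <- !zero & th == 0
  sat <- !zero & th > 0
  if (any(lin)) ne[lin] <- n0[lin] * (1 - exp(-a[lin] * p_pred[lin] * t[lin]))
  if (any(sat)) {
    z <- log(a[sat] * th[sat] * n0[sat]) -
      a[sat] * (p_pred[sat] * t[sat] - th[sat] * n0[sat])
    ne[sat] <- n0[sat] - lambert_w0_exp(z) / (a[sat] * th[sat])
  }
  pmin(pmax(ne, 0), n0)
}

#' Expected prey eaten under generalized (type II/III) depletion
#'
#' Integrates `dN/dt = -P * b*N^(1+q) / (1 + b*th*N^(1+q))` from `N0` over
#' the trial and returns `N0 - N(T)`. The ODE is separable, so by default
#' the implicit time-of-passage equation
#'
#' `G(N0) - G(N) = P*T`, with `G(N) = th*N + log(N)/b` (q = 0) or
#' `G(N) = th*N - N^(-q)/(q*b)` (q != 0),
#'
#' is solved exactly by a safeguarded bisection/Newton root find (method
#' `"implicit"`, vectorized and used inside the likelihood). Method `"ode"`
#' integrates the dynamics with the adaptive Runge-Kutta of
#' [ode_depletion()] and serves as an independent numerical route. For
#' `-1 < q < 0` prey can be exhausted in finite time; the extinction time is
#' detected analytically and the state is absorbed at 0.
#'
#' @param p `gen_params`.
#' @param cond `trial_conditions`.
#' @param method `"implicit"` (exact quadrature, default) or `"ode"`.
#' @param tol relative tolerance for the `"ode"` route.
#' @return expected number of prey eaten, scalar in `[0, n0]`.
#' @export
depletion_eaten_generalized <- function(p, cond, method = c("implicit", "ode"),
                                        tol = 1e-8) {
  stopifnot(inherits(p, "gen_params"))
  if (!inherits(cond, "trial_conditions")) cond <- trial_conditions(cond)
  method <- match.arg(method)
  if (method == "implicit") {
    gen_eaten_vec(p$b, p$q, p$th, cond$n0, cond$t, cond$p_pred)
  } else {
    rate <- function(n) feeding_rate(p, n)
    nt <- ode_depletion(rate, n0 = cond$n0, t = cond$t, p_pred = cond$p_pred,
                        rtol = tol, atol = 1e-10)
    min(max(cond$n0 - nt, 0), cond$n0)
  }
}

# time-of-passage potential G(N); increasing in N, G -> -Inf (q >= 0) or
# 0 (q < 0) as N -> 0+
gen_potential <- function(n, b, q, th) {
  if (abs(q) < 1e-12) th * n + log(n) / b else th * n - n^(-q) / (q * b)
}

# vectorized exact solver for the separable generalized depletion ODE
gen_eaten_vec <- function(b, q, th, n0, t = 1, p_pred = 1) {
  k <- max(length(b), length(q), length(th), length(n0), length(t), length(p_pred))
  b <- rep_len(as.numeric(b), k); q <- rep_len(as.numeric(q), k)
  th <- rep_len(as.numeric(th), k); n0 <- rep_len(as.numeric(n0), k)
  t <- rep_len(as.numeric(t), k); p_pred <- rep_len(as.numeric(p_pred), k)
  if (any(q <= -1)) stop("depletion_eaten_generalized: q must be > -1")
  if (any(b < 0) || any(th < 0) || any(n0 < 0) || any(t <= 0))
    stop("depletion_eaten_generalized: need b >= 0, th >= 0, n0 >= 0, t > 0")
  ne <- numeric(k)
  act <- n0 > 0 & b > 0
  if (!any(act)) return(ne)
  bb <- b[act]; qq <- q[act]; tt <- th[act]; nn <- n0[act]
  target <- mapply(gen_potential, nn, bb, qq, tt) - p_pred[act] * t[act]
  # q < 0: finite extinction time when G(N0) - 0 <= P*T
  extinct <- qq < 0 & target <= 0
  res <- nn  # eaten = n0 where extinct
  todo <- !extinct
  if (any(todo)) {
    bi <- bb[todo]; qi <- qq[todo]; ti <- tt[todo]; ni <- nn[todo]
    tg <- target[todo]
    pt <- (p_pred[act] * t[act])[todo]
    # bracket in x = log(N): solution lies in (0, N0]; the feeding rate
    # never exceeds F(N0), so eaten <= P*T*F(N0) gives a sharp lower bound
    hi <- log(ni)
    np0 <- ni^(1 + qi)
    lo_n <- ni - pt * bi * np0 / (1 + bi * ti * np0)
    lo <- hi - 750
    pos <- is.finite(lo_n) & lo_n > 0
    lo[pos] <- log(lo_n[pos]) - 1e-6
    g_of <- function(x) {
      n <- exp(x)
      ifelse(abs(qi) < 1e-12, ti * n + x / bi, ti * n - exp(-qi * x) / (qi * bi))
    }
    bad <- g_of(lo) > tg  # guard against rounding at the bound
    lo[bad] <- hi[bad] - 750
    for (i in 1:90) {
      if (max(hi - lo) < 1e-9) break
      mid <- (lo + hi) / 2
      gm <- g_of(mid)
      up <- !is.finite(gm) | gm < tg   # need larger N
      lo <- ifelse(up, mid, lo)
      hi <- ifelse(up, hi, mid)
    }
    x <- (lo + hi) / 2
    # Newton polish: d/dx G(e^x) = th*N + N^(-q)/b
    for (i in 1:4) {
      n <- exp(x)
      gp <- ti * n + n^(-qi) / bi
      step <- (g_of(x) - tg) / gp
      step[!is.finite(step)] <- 0
      x <- pmin(x - step, log(ni))
    }
    res[todo] <- ni - exp(x)
  }
  ne[act] <- res
  pmin(pmax(ne, 0), n0)
}

#' Adaptive Runge-Kutta integration of a depletion process
#'
#' Integrates `dN/dt = -p_pred * rate(N)` from `N(0) = n0` to time `t` with
#' an embedded Cash-Karp 4(5) pair and proportional step control. The state
#' is floored at 0 (absorbing: an emptied arena stays empty). This is the
#' package's generic ODE route; the Lambert-W and implicit-quadrature paths
#' are cross-checked against it.
#'
#' @param rate function of N returning the per-predator feeding rate, >= 0.
#' @param n0 initial prey density.
#' @param t integration time (days).
#' @param p_pred predator count multiplying the rate.
#' @param rtol,atol relative/absolute error tolerances.
#' @param max_steps safety cap on accepted+rejected steps.
#' @return N(t), a scalar in `[0, n0]`.
#' @export
ode_depletion <- function(rate, n0, t, p_pred = 1, rtol = 1e-8, atol = 1e-10,
                          max_steps = 100000L) {
  stopifnot(is.function(rate), n0 >= 0, t > 0)
  if (n0 == 0) return(0)
  # Cash-Karp tableau
  a2 <- 1/5; a3 <- c(3/40, 9/40); a4 <- c(3/10, -9/10, 6/5)
  a5 <- c(-11/54, 5/2, -70/27, 35/27)
  a6 <- c(1631/55296, 175/512, 575/13824, 44275/110592, 253/4096)
  b5 <- c(37/378, 0, 250/621, 125/594, 0, 512/1771)
  b4 <- c(2825/27648, 0, 18575/48384, 13525/55296, 277/14336, 1/4)
  f <- function(n) -p_pred * rate(max(n, 0))
  n <- n0; tt <- 0; h <- t / 100
  steps <- 0L
  while (tt < t) {
    steps <- steps + 1L
    if (steps > max_steps)
      stop("ode_depletion: step limit exceeded (rtol=", rtol, ", t reached=", tt, ")")
    h <- min(h, t - tt)
    k1 <- f(n)
    k2 <- f(n + h * a2 * k1)
    k3 <- f(n + h * (a3[1] * k1 + a3[2] * k2))
    k4 <- f(n + h * (a4[1] * k1 + a4[2] * k2 + a4[3] * k3))
    k5 <- f(n + h * (a5[1] * k1 + a5[2] * k2 + a5[3] * k3 + a5[4] * k4))
    k6 <- f(n + h * (a6[1] * k1 + a6[2] * k2 + a6[3] * k3 + a6[4] * k4 + a6[5] * k5))
    ks <- c(k1, k2, k3, k4, k5, k6)
    n5 <- n + h * sum(b5 * ks)
    n4 <- n + h * sum(b4 * ks)
    err <- abs(n5 - n4)
    sc <- atol + rtol * max(abs(n), abs(n5))
    if (err <= sc || h < 1e-14) {
      tt <- tt + h
      n <- max(n5, 0)
      if (n == 0) break
    }
    fac <- if (err > 0) 0.9 * (sc / err)^0.2 else 5
    h <- h * min(max(fac, 0.2), 5)
  }
  min(max(n, 0), n0)
}
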