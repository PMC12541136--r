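---
title: "Fitting habitat-structured functional responses under prey depletion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fitting habitat-structured functional responses under prey depletion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(habfr)
```

## The model

A predator's per-capita feeding rate on prey at density $N$ is modeled as a
saturating type II functional response, written in two equivalent coordinate
systems:

$$F(N) = \frac{aN}{1 + a T_h N} = \frac{F_{\max} N}{N_{half} + N},$$

with attack rate $a$ (arena day$^{-1}$), handling time $T_h$ (day prey$^{-1}$),
maximum feeding rate $F_{\max} = 1/T_h$ and half-saturation density
$N_{half} = 1/(a T_h)$. The generalized response lets the attack rate be a
power law of density, $a = b N^q$:

$$F(N) = \frac{b N^{1+q}}{1 + b T_h N^{1+q}},$$

so $q = 0$ is hyperbolic (type II) and $q = 1$ a strict sigmoid (type III).
The shape matters ecologically because the per-capita predation risk
$F(N)/N$ declines monotonically with density for $q = 0$ but rises at low
density for $q > 0$, which stabilizes rare prey populations.

### Depletion

In a non-replacement trial the prey density is not constant: it declines as
prey are eaten, so the expected consumption is the integral of
$dN/dt = -P\,F(N)$ over the trial, not $T \cdot F(N_0)$. For the type II
response this integral has the closed Rogers random-predator form

$$N_e = N_0 - \frac{W_0\!\left(a T_h N_0\, e^{-a (PT - T_h N_0)}\right)}{a T_h},$$

with $W_0$ the principal Lambert W branch ($T_h = 0$ degenerates to
$N_e = N_0(1 - e^{-aPT})$). The package evaluates the W argument in the log
domain, so the large products $a T_h N_0$ that occur at high densities never
overflow; for arguments beyond `exp(690)` the asymptotic fixed point
$w \leftarrow z - \log w$ is iterated instead.

For the generalized response no closed form exists, but the ODE is
separable. Writing $G(N) = T_h N + \log(N)/b$ for $q = 0$ and
$G(N) = T_h N - N^{-q}/(qb)$ otherwise, the trial end state solves
$G(N_0) - G(N_T) = PT$, a monotone scalar equation solved by a vectorized,
bracketed bisection/Newton iteration — exact quadrature rather than
numerical time stepping, which keeps the likelihood fast and smooth. For
$-1 < q < 0$ prey are exhausted in finite time $G(N_0)/P$; this is detected
analytically and the state absorbed at zero. An independent adaptive
Cash–Karp Runge–Kutta route (`ode_depletion`, relative tolerance $10^{-8}$,
absolute $10^{-10}$, state floored at zero) is kept in the package and the
test suite cross-checks all three paths against each other and against
frozen references from an independent stack.

### Likelihood

Each trial contributes a binomial term,
$n_{eaten} \sim \mathrm{Binomial}(N_0,\; N_e/N_0)$, with the proportion
clipped to $[10^{-9}, 1-10^{-9}]$. The depletion-correction literature this
follows does not prescribe a unique noise family; the binomial is the
natural choice for a bounded count of independent capture events, and the
synthetic generator uses the same family, so simulation and inference are
coherent. Overdispersion (e.g. beta-binomial) is a recorded non-goal.

All positive parameters are estimated on a log10 link scale — positivity
for free, roughly symmetric likelihoods, and consistency with reporting the
amount-of-structure effect as a log10-linear slope. The shape parameter $q$
is fitted on the identity scale in the box $(-0.99, 3)$.

## The habitat model suite

Each of the two response parameters may depend on the habitat treatment
under four hypotheses: `zero` (no effect, 1 coefficient), `one`
(presence/absence, 2), `two` (log10-linear in the number of structural
rings $\in \{0, 2, 3\}$: intercept and slope, 2), and `three` (one value
per complexity level 0–4, 5). The full cross over both parameters and both
parameterizations gives 16 Holling + 16 Real models; model $k$ encodes
$k = 4 h_1 + h_2 + 1$.

Two deliberate readings of the design are worth flagging:

* **`two` is a regression, not a 3-level factor.** The amount hypothesis
  is a 2-coefficient log10-linear model in ring count. This is forced by
  the degrees of freedom the suite must have (e.g. a model with `two` on
  both parameters has df 4, not 6) and by the slope-per-ring form in which
  the amount effect is reported.
* **`one` and `three` use independent per-level coefficients**, not
  reference-level contrasts, so each level's CI is directly the CI of that
  level's parameter value.

Matched-hypothesis H/R pairs (models 1, 6, 11, 16) are exact
re-parameterizations of each other — the coefficient families are closed
under $F_{\max} = 1/T_h$, $N_{half} = 1/(aT_h)$ — and the test suite
requires their maximized likelihoods to agree to $10^{-4}$. Unmatched
pairs (e.g. 15H vs 15R) are genuinely different models, because
$N_{half}$ mixes both Holling parameters.

Suites are fitted one species at a time, ranked by AIC and BIC with deltas
reported to 3 decimals; ties order by smaller df, then name.

## Estimation details

* **Multi-start.** Depletion likelihoods can be multimodal at small $n$.
  Starts are a Latin-hypercube cloud (default 10, half-width 0.6 log10
  units; 0.2 for slopes) around data-driven anchors:
  $F_{\max,0} = \max(\text{eaten})/T$, $N_{half,0} = $ median offered
  density, $q_0 = 0$. The first start is the anchor itself.
* **Optimizer.** Each start runs a quasi-Newton (PORT/`nlminb`) search with
  a simplex fallback; the best start is polished by BFGS at relative
  tolerance $10^{-10}$. Box constraints (for $q$) are enforced by a
  quadratic penalty during exploration and respected by the profiler.
* **Covariance.** Observed-information inverse at the optimum
  (`optimHess`); if it is not positive definite the fit is flagged and
  downstream consumers fall back (Wald CIs unavailable, prediction bands
  switch to a refit bootstrap).
* **Confidence intervals.** Default Wald on the link scale,
  back-transformed. `profile_ci` profiles the NLL to the
  $\chi^2_1$ cutoff ($1.92$ log-likelihood units at 95%), with expanding
  brackets and root refinement; a side that never crosses is reported open
  and flagged, a side that hits a box is flagged `boundary`, and inner
  optimization failure falls back to Wald with `method = "wald"`. The
  shape test always uses a profile interval for $q$.
* **Type II vs III.** A cell is declared type III only when the profile
  lower bound of $q$ exceeds 0 — i.e. $q$ significantly *greater* than
  zero at the configured level (0.95 default); everything else stays
  type II. With $q = 0$ truth this one-sided rule keeps the false-III
  rate well under the 10% calibration bound the acceptance suite checks.

## The synthetic generator

`default_design()` reproduces the experimental layout: densities
1–120 (ambush predator, 3 replicates) or 1–180 (pursuit predator, 6
replicates), crossed with five complexity levels built from 0/2/2/3/3
plastic-plant rings, 24 h trials. The defaults give 345 microcosms versus
297 in the original campaign, whose per-cell replication (1–6) is only
available in the deposited data; the "mostly 3 and 6" values are used with
an override argument.

`simulate_trials()` draws eaten counts binomially around the deterministic
depletion expectation — the same expectation the likelihood evaluates, so a
green recovery test establishes the estimation machinery, not the realism
of the noise model. Features of real data deliberately *not* emulated:
time-block effects (read and stored, never modeled), predator individual
variation, satiation carry-over between trials, overdispersion, and any
refuge mechanics beyond their effect on the parameters. The event-based
Gillespie simulator (`stochastic_depletion_sim`) is provided as an
independent oracle; its mean differs from the ODE mean at $O(1/N_0)$,
which is why it is not the default generator.

Ground-truth presets take the reported point estimates: `5R` with
$F_{\max} = 28 \to 15$ prey/day on structure and $N_{half} = 57$;
`15H` with per-level $F_{\max} = (31, 18, 28, 22, 19)$ and attack slope
$-0.144$ per ring. The `15H` attack intercept is not printed anywhere; it
is set to $\log_{10}(3 \times 28/57)$ — three times the ambush predator's
open-arena attack rate, the ratio reported for the two predators — and
documented as the package's own choice.

## Numerical choices and edge cases

* Time unit: days; $T = 1$ for the standard 24 h trial. Rates are per day.
* $T_h = 0$ is legal in the core math (exponential limit) but excluded
  from fitted models by the log link.
* Predictions are clamped to $[0, N_0]$; binomial proportions clipped at
  $10^{-9}$.
* Multiple predators enter as a rate multiplier $P$ (here always 1).
* Zero-noise simulation (`noise = "none"`) rounds expectations to
  integers; rounding is itself a small deterministic bias source at
  density 1 (expectations near 0.3 round to 0), worth remembering when
  using it as a sanity check — about 5% on $N_{half}$ for the ambush
  design.
* All randomness (starts, simulation, bootstrap) flows from explicit
  integer seeds; the caller's RNG state is saved and restored.

## Known limitations

Single-prey, single-predator trials only; no interference, no multi-species
functional responses, no Bayesian posterior, no beta-binomial
overdispersion. The 64-model factorial that a confirmed type III response
would require is expressible with the exported machinery (`ground_truth`,
`parameter_value`, the generalized solver) but deliberately not enumerated,
since the shape test retains type II throughout the motivating use case.
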