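# habfr

Functional-response estimation for predators feeding in structured habitats,
from non-replacement feeding trials.

## The problem

A feeding trial offers one predator `N0` prey in a microcosm for time `T`
(here: 24 h) and counts how many were eaten. The per-capita feeding rate
follows a saturating (type II) functional response,

    F(N) = a N / (1 + a Th N)          (Holling: attack rate a, handling time Th)
         = Fmax N / (Nhalf + N)        (Real: Fmax = 1/Th, Nhalf = 1/(a Th))

or, allowing the attack rate itself to rise with prey density
(`a = b N^q`), the generalized response

    F(N) = b N^(1+q) / (1 + b Th N^(1+q))

which is hyperbolic type II at `q = 0` and a "strict" sigmoid type III at
`q = 1`. Because prey are not replaced, the density declines within the
trial and naive fits of F(N0) are biased. habfr integrates the depletion
dynamics `dN/dt = -P F(N)`: in closed form for the type II model (the
Rogers random-predator equation, via the Lambert W function) and by exact
quadrature of the separable ODE for the generalized model. The eaten count
is modeled as `Binomial(N0, Ne/N0)` with `Ne` the expected depletion, and
parameters are estimated by maximum likelihood on a log10 link scale.

The habitat question — does physical structure change feeding? — is asked
through a factorial model suite. Each response parameter may depend on the
treatment in four ways: not at all (`zero`), on structure presence
(`one`), log10-linearly on the number of structural elements (`two`:
`log10 par = intercept + slope * n_rings`), or freely per complexity level
0–4 (`three`). Crossed over the two parameters of both the Holling and
Real parameterizations this yields 32 models (`1H`–`16H`, `1R`–`16R`),
compared by AIC and BIC. The two parameterizations matter: when the two
parameters track *different* habitat predictors, the H and R families are
genuinely different hypotheses, not coordinate changes.

## Worked example

Simulate the pursuit-predator design (densities 1–180, five complexity
levels, 6 replicates, 240 microcosms) from the `15H` preset — a distinct
handling time per complexity level and an attack rate falling by
10^(-0.144) per added plant ring — then refit and test the response shape:

```r
library(habfr)
design <- default_design("pursuit")
trials <- simulate_trials(design, truth_preset("15H"), seed = 42)
cfg <- fit_config(starts = 6, seed = 7)
fit <- fit_mle("15H", trials, cfg)
print(fit)
#> Functional response fit: 15H (df = 7, n = 240)
#>   logLik -485.2834 | AIC 984.567 | BIC 1008.931 | converged: TRUE
#>          term estimate    lower    upper
#> 1       th_L0  0.02979  0.02625  0.03381
#> 2       th_L1  0.06119  0.05292  0.07075
#> 3       th_L2  0.03153  0.02742  0.03626
#> 4       th_L3  0.04255  0.03594  0.05038
#> 5       th_L4  0.05330  0.04517  0.06290
#> 6 a_intercept  1.15492  0.93211  1.43098
#> 7     a_slope -0.11508 -0.15901 -0.07116

test_shape(trials[trials$complexity_level == 0, ], cfg)
#> Shape test: pursuit, level 0 — q = 0.052 [-0.166, 0.329] n.s. -> type II
```

Reading the output: `th_L0 = 0.0298` day/prey is the open-arena handling
time, i.e. a maximum feeding rate of `1/0.0298 ≈ 34` prey/day, dropping to
`1/0.0612 ≈ 16` at level 1 (the generating values were 31 and 18). The
attack rate declines with structure: `a_slope = -0.115` log10 units per
ring (truth -0.144, inside the 95% CI). The shape test retains the
hyperbolic type II response (`q` n.s. against 0), as it should for data
generated with `q = 0`.

Model selection over the whole suite (`fit_suite(trials, cfg)`), ranking
(`rank_table(suite, "AIC")`), profile intervals (`profile_ci(fit, "a_slope")`)
and bootstrap prediction bands (`predict_with_bands(fit, ...)`) follow the
same pattern; see the vignette in `vignettes/` for the statistical details.

## Command line

```sh
Rscript inst/cli/habfr.R simulate  --species pursuit --truth 15H --seed 1 --out trials.csv
Rscript inst/cli/habfr.R fit-shape --input trials.csv --seed 1 --out shape.csv
Rscript inst/cli/habfr.R fit-suite --input trials.csv --seed 1 --out out/
Rscript inst/cli/habfr.R rank      --suite out/suite_pursuit.json --criterion BIC --out rank.csv
Rscript inst/cli/habfr.R report    --input trials.csv --model 15H --seed 1 --out report/
```

Every command is driven by one `--seed` and writes a JSON manifest (package
version, seed, config, input digests) next to its outputs.

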