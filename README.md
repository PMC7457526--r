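# gpgee

Group-penalized generalized estimating equations (GPGEE) for clustered
responses measured on a condition-by-channel grid — the layout of
event-related potential (ERP) studies, where each subject contributes an EEG
amplitude for every combination of J stimulus conditions and K scalp
electrodes, and a high-dimensional panel of clinical covariates is screened
for association with the response.

## The model

For subject *i* with responses vectorized condition-major,
Y<sub>i</sub> = (Y<sub>i11</sub>, …, Y<sub>i1K</sub>, Y<sub>i21</sub>, …, Y<sub>iJK</sub>)ᵀ,
the marginal model is

> g(μ<sub>ijk</sub>) = X<sub>i</sub>ᵀβ + condition<sub>j</sub> + channel<sub>k</sub>,  Var(Y<sub>ijk</sub>) = φ·v(μ<sub>ijk</sub>),  Cov(Y<sub>i</sub>) = V<sub>i</sub>,

estimated by GEE with a working correlation R that may be **separable**:
R = B ⊗ Σ, with B a J×J condition-level and Σ a K×K channel-level
correlation (e.g. unstructured across 2 conditions, AR1 across channels —
channels closer on the scalp are more correlated). Covariates are selected
in **groups** through a group SCAD penalty on the L1 norm of each coefficient
block: the penalized estimating function

> U(β) = S(β) − n·q<sup>G</sup><sub>λ</sub>(β)·sign(β)

is solved by a minorization–maximization Newton–Raphson iteration, starting
from the independence-GEE estimator, with the penalty level λ tuned by a
clustered-data BIC over a 30-point grid. A multi-level factor (say, 13
channels coded as 12 dummies) forms one group and is kept or dropped as a
whole. Singleton groups recover the coefficient-wise SCAD-penalized GEE
(PGEE) as a special case.

The package also ships the simulation harness used to validate the method:
Gaussian responses with separable B ⊗ Σ errors, 8 covariate groups of 5 with
mixed strong/weak/null signals, and a five-estimator comparison summarizing
exact/over/under-selection rates and estimation error.

## Worked example

Simulate one benchmark dataset (50 subjects, 2 conditions × 10 channels,
40 covariates in 8 groups of 5) and fit the correctly structured GPGEE:

```r
library(gpgee)

sim <- simulate_table1_data(table1_design(n = 50), seed = 2)
df  <- tibble::as_tibble(sim)   # long format: subject, condition, channel, response, x1..x40

fit <- gpgee(df,
             covariate_groups  = table1_covariate_groups(),
             include_intercept = FALSE, condition_term = FALSE,
             channel_term      = FALSE,
             corstr            = "kron:unstructured,ar1")
fit
#> <gpgee> group-penalized GEE fit
#>   subjects: 50  grid: 2 conditions x 10 channels
#>   correlation: kronecker
#>   lambda (BIC): 21.39  selected groups: 4 of 8
#>   converged: TRUE in 51 iterations

tidy(fit)[c(1, 6, 15, 16, 21), ]
#> # A tibble: 5 x 5
#>   term  estimate group penalized selected
#> 1 x1      1.54       1 TRUE      TRUE
#> 2 x6      3.05       2 TRUE      TRUE
#> 3 x15     0.0708     3 TRUE      TRUE
#> 4 x16     0.0533     4 TRUE      TRUE
#> 5 x21     0          5 TRUE      FALSE

fit$correlation$Sigma[1, 2]   # estimated channel AR1 coefficient
#> [1] 0.903
```

The fit recovers exactly the four signal-bearing groups (the generating
coefficients are 2,1,1,1,1 | 3,3,3,3,0 | 0,0,0,0,0.1 | 0.1,1,1,1,0 | 0…0),
estimates the strong coefficients near their true values with some shrinkage
(1.54 for a true 2, 3.05 for a true 3), keeps the weak 0.1 signals in the
model through their groups, zeroes all four pure-noise groups, and estimates
the channel autocorrelation at 0.903 against a true 0.9. `glance(fit)` gives
the one-row fit summary, `autoplot(fit)` the BIC tuning path.

Selection benchmark (any subset of the five models), e.g. two models at
reduced size:

```r
run_table1(reps = 100, seed = 1, models = c(1, 5), ns = 50)
```

A thin command-line wrapper with `fit`, `simulate` and `table1` subcommands
is installed at `system.file("cli", "gpgee.R", package = "gpgee")`.

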