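# dpskewmix

Differentially private density estimation with multivariate skew-normal
mixtures.

## What problem this solves

Analysts who must release density estimates from confidential records —
anthropometric surveys, spatial traces, clinical measurements — face two
problems at once: real data are skewed, so Gaussian mixtures misfit them,
and releasing fitted parameters leaks information about individual
records.  `dpskewmix` fits a finite mixture of multivariate skew-normal
components

f(x; Θ) = Σₖ πₖ · 2 φ_p(x; ξₖ, Σₖ) Φ(αₖᵀ σₖ⁻¹ (x − ξₖ)),  σₖ = (Σₖ ⊙ I_p)^½,

by an EM algorithm built on the half-normal stochastic representation
(X = ξ + ητ + W, τ half-normal, W ~ N_p(0, Λ), Λ = Σ − ηηᵀ), and makes the
fit ε-differentially private by perturbing each iteration's M-step
estimates (π, ξₖ, ηₖ, Λₖ) with Laplace noise calibrated by closed-form
remove-one L1 sensitivities:

- S(π) = G/n
- S(ξ) = 4G(R − R₃)/n
- S(η) = 2G·R·R₁/(n·R₂)
- S(Λ) = 2G(R² + 4R·R₁·R₃ + 4R₂·R₃²)/n

under record clipping ‖xᵢ‖₁ ≤ R and moment/η clipping (R₁, R₂, R₃).  Noisy
parameters are repaired before re-entering the loop: weights renormalized
onto the simplex with ζ-smoothing, conditional scales symmetrized,
PSD-projected by the minimal diagonal shift and eigenvalue-floored, and the
skewness reconstructed from (Λ̂, η̂) with boundary guards.  A differentially
private Gaussian-mixture baseline, a brute-force sensitivity auditor,
synthetic-data generators and sweep harnesses (privacy budget ε; mixture
order G with AIC/BIC) round out the toolkit.

## Worked example

```r
library(dpskewmix)

scn <- default_scenarios()$recovery   # n = 2000, two skewed components
d   <- generate_mixture(scn)

# non-private fit
fit <- fit_em(d$data, G = 2, seed = 1)
fit
#> non-private MSNM mixture fit: G = 2, p = 2, n = 2000
#> iterations: 70 (converged)   mean log-likelihood: -0.6198
#> AIC: 2509.39   BIC: 2593.40

recovery_report(scn$params, fit$params)
#>   component  pi_abs_err location_linf location_l2 scale_frob alpha_sign_agree
#> 1         1 0.009999997    0.04714652  0.04967836 0.02257698                1
#> 2         2 0.009999997    0.02094920  0.02478647 0.00895864                1

# private fit: eps = 10 split over T = 10 iterations
bounds <- sensitivity_bounds(R = scn$clip_radius)   # R = 3, public
pfit <- fit_dp_msnm(d$data, G = 2, eps_total = 10, T_iter = 10,
                    bounds = bounds, seed = 42)
sum(pfit$noise_audit$epsilon)
#> [1] 10
```

The non-private fit converges to the generating parameters (location
errors < 0.05, weight errors 0.01, all skewness signs right).  The private
fit spends exactly its budget — the `noise_audit` log records every Laplace
draw's iteration, target, sensitivity, per-draw ε and scale — and returns
valid (simplex, PSD) parameters; at n = 2000 its parameter error is
dominated by the calibrated noise, which is the honest price of ε = 10 at
that sample size (see the methods vignette for the regime analysis).

Command-line use (`inst/cli/dpskewmix.R`):

```sh
Rscript inst/cli/dpskewmix.R simulate --scenario recovery --seed 1 --out data.csv
Rscript inst/cli/dpskewmix.R fit --input data.csv --components 2 \
    --epsilon 10 --iters 10 --clip-radius 3 --seed 42 --out fit.json
Rscript inst/cli/dpskewmix.R sweep --mode epsilon --scenario recovery --out sweep.csv
```

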